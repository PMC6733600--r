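test_that("alignment reproduces identity and single-mismatch scores", {
  a <- align_glocal("ACGTACGTAC", "ACGTACGTAC")[[1]]
  expect_equal(a$score, 10)
  expect_equal(a$nm, 0L)
  expect_equal(nrow(a$events), 0L)

  a <- align_glocal("ACGT", "AGGT")[[1]]
  expect_equal(a$score, 3 - 3)
  expect_equal(a$nm, 1L)
  expect_equal(a$events$kind, "sub")
  expect_equal(a$events$apos, 2L)
})

test_that("alignment scores equal the brute-force affine-gap oracle", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(1:30, 1); m <- sample(1:30, 1)
    # half the cases: related sequences (mutated copies), half: random
    if (i %% 2 == 0) {
      b <- random_dna(m)
      a <- strsplit(b, "")[[1]]
      k <- min(n, m)
      a <- a[1:k]
      nmut <- sample(0:3, 1)
      if (nmut > 0) {
        at <- sample(k, min(nmut, k))
        a[at] <- sample(c("A", "C", "G", "T"), length(at), replace = TRUE)
      }
      a <- paste(a, collapse = "")
    } else {
      a <- random_dna(n); b <- random_dna(m)
    }
    got <- align_glocal(a, b, window = 100L)[[1]]$score
    expect_equal(got, nw_affine_oracle(a, b), info = paste(a, b))
  }
})

test_that("edit-structure classes follow the length/NM definitions", {
  ref <- example_locus()
  L <- ref$length
  s <- strsplit(ref$sequence, "")[[1]]

  sub90 <- s; sub90[90] <- if (s[90] == "A") "G" else "A"
  del7 <- s[-200]
  ins7 <- append(s, "T", after = 150)
  both <- s; both[90] <- if (s[90] == "A") "G" else "A"
  both <- both[-300]
  reads <- data.frame(
    id = c("zero", "sub", "del", "ins", "both", "short"),
    seq = c(paste(s, collapse = ""), paste(sub90, collapse = ""),
            paste(del7, collapse = ""), paste(ins7, collapse = ""),
            paste(both, collapse = ""), "ACGTACGT"),
    stringsAsFactors = FALSE)
  cv <- call_variants(reads, ref)
  expect_equal(cv$profiles$class,
               c("zero", "single_sub", "single_del", "single_ins",
                 "multi", "unaligned"))
  # classification is a partition
  expect_equal(sum(table(cv$profiles$class)), nrow(reads))
  # the substitution event is at amplicon position 90, reported vs TSS
  ev <- cv$events[cv$events$id == "sub", ]
  expect_equal(ev$apos, 90L)
  expect_equal(ev$pos, amplicon_to_tss(90L, ref))
  expect_equal(ev$kind, "sub")
  # the deletion read is one base short
  expect_equal(cv$profiles$read_len[cv$profiles$class == "single_del"], L - 1L)
})

test_that("single_sub calls equal the planted truth without seq errors", {
  ref <- tiny_locus()
  cfg <- sim_config(mu = 0.01, n_clones = 400L, seed = 13,
                    read_length = 50L, seq_error = 0)
  pool <- mutagenize_pool(ref, cfg)
  rd <- sequence_reads(pool, cfg)
  pr <- prep_sample(rd$fwd, rd$rev)
  cv <- call_variants(pr$merged, ref, window = 10L)
  # merged reads reconstruct the clones exactly
  cid <- as.integer(sub(".*:(\\d+):.*", "\\1", pr$merged$id))
  expect_identical(pr$merged$seq, pool$sequences[cid])
  # single_sub events match the truth table (position, ref, alt)
  ss <- cv$profiles$id[cv$profiles$class == "single_sub"]
  ev <- cv$events[cv$events$id %in% ss, ]
  scid <- as.integer(sub(".*:(\\d+):.*", "\\1", ev$id))
  truth_keys <- paste(pool$truth$clone_id, pool$truth$pos,
                      pool$truth$ref, pool$truth$alt)
  expect_true(all(paste(scid, ev$pos, ev$ref, ev$alt) %in% truth_keys))
  # and every truth single-sub clone is called single_sub
  per_clone <- split(pool$truth$kind, pool$truth$clone_id)
  singles <- as.integer(names(per_clone)[vapply(per_clone, function(k)
    length(k) == 1 && k == "sub", TRUE)])
  called <- sort(unique(scid))
  expect_setequal(called, singles)
})

test_that("mutation histogram counts length-conserving reads", {
  ref <- tiny_locus()
  zero <- data.frame(id = c("a", "b"), seq = ref$sequence,
                     stringsAsFactors = FALSE)
  cv <- call_variants(zero, ref)
  h <- mutation_histogram(cv, ref)
  expect_equal(unname(h), c(2L, rep(0L, 10)))

  cfg <- sim_config(mu = 0.02, n_clones = 300L, seed = 17, delta = 0,
                    read_length = 50L, seq_error = 0)
  pool <- mutagenize_pool(ref, cfg)
  rd <- sequence_reads(pool, cfg)
  pr <- prep_sample(rd$fwd, rd$rev)
  cv <- call_variants(pr$merged, ref, window = 10L)
  h <- mutation_histogram(cv, ref)
  # substitutions only: histogram equals the truth mutation-count table
  cid <- as.integer(sub(".*:(\\d+):.*", "\\1", pr$merged$id))
  truth_counts <- tabulate(pool$n_mut[cid] + 1L, nbins = 11L)
  expect_equal(unname(h), truth_counts)
  expect_equal(sum(h), sum(cv$profiles$read_len == ref$length &
                             cv$profiles$class != "unaligned"))
})
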