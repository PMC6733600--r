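test_that("reference construction is deterministic, bounded and verbatim", {
  r1 <- make_reference(length = 426, seed = 1)
  r2 <- make_reference(length = 426, seed = 1)
  expect_identical(r1$sequence, r2$sequence)
  expect_false(identical(r1$sequence, make_reference(426, seed = 2)$sequence))

  bad <- data.frame(name = "f", start = 1L, end = 500L, strand = "+")
  expect_error(make_reference(length = 426, features = bad, tss_offset = 46),
               "outside the amplicon")

  seq426 <- paste(rep("ACGT", 107), collapse = "")
  seq426 <- substr(seq426, 1, 426)
  r3 <- make_reference(sequence = seq426, tss_offset = 46)
  expect_identical(r3$sequence, seq426)
  expect_equal(r3$length, 426L)
})

test_that("mutagenesis matches its binomial event model", {
  ref <- example_locus()
  cfg0 <- sim_config(mu = 0, n_clones = 50L, seed = 5)
  p0 <- mutagenize_pool(ref, cfg0)
  expect_equal(nrow(p0$truth), 0L)
  expect_true(all(p0$sequences == ref$sequence))

  # fraction of clones with >= 1 mutation vs closed form 1-(1-mu)^L
  mu <- 0.002; n <- 1e5
  cfg <- sim_config(mu = mu, n_clones = n, seed = 11, delta = 0)
  pool <- mutagenize_pool(ref, cfg, build_sequences = FALSE)
  p_hat <- mean(pool$n_mut > 0)
  p_exp <- 1 - (1 - mu)^ref$length
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(p_hat - p_exp), 3 * se)

  # per-k fractions follow Binomial(L, mu)
  for (k in 0:2) {
    pk <- dbinom(k, ref$length, mu)
    expect_lt(abs(mean(pool$n_mut == k) - pk),
              3 * sqrt(pk * (1 - pk) / n) + 1e-12)
  }
})

test_that("substitution spectrum honours the transition weight", {
  ref <- example_locus()
  cfg <- sim_config(mu = 0.01, kappa = 4, delta = 0, n_clones = 2e4,
                    seed = 21)
  pool <- mutagenize_pool(ref, cfg, build_sequences = FALSE)
  g <- pool$truth[pool$truth$ref == "G", ]
  frac_ga <- mean(g$alt == "A")
  n <- nrow(g)
  expect_gt(n, 5000)
  expect_lt(abs(frac_ga - 4 / 6), 3 * sqrt(4 / 6 * 2 / 6 / n))
  # transversions split evenly
  expect_lt(abs(mean(g$alt[g$alt != "A"] == "C") - 0.5), 0.05)
})

test_that("selection keeps exactly the rescued clones, in order", {
  ref <- example_locus()
  cfgu <- sim_config(n_clones = 500L, seed = 9, condition = "unselected")
  pool <- mutagenize_pool(ref, cfgu, build_sequences = FALSE)
  su <- apply_selection(pool, cfgu, ref)
  expect_identical(su$clone_id, pool$clone_id)

  sup <- data.frame(pos = 43L, alt = "ANY")
  cfgs <- sim_config(mu = 0.01, n_clones = 3000L, seed = 10,
                     condition = "selected", suppressors = sup)
  pool <- mutagenize_pool(ref, cfgs, build_sequences = FALSE)
  ss <- apply_selection(pool, cfgs, ref)
  expect_gt(length(ss$clone_id), 0)
  # every survivor carries a mutation at +43
  has43 <- tapply(ss$truth$pos == 43L, ss$truth$clone_id, any)
  expect_true(all(ss$clone_id %in% as.integer(names(has43)[has43])))
  # survivors preserve input order and are a subset
  expect_identical(ss$clone_id, sort(ss$clone_id))
  expect_true(all(ss$clone_id %in% pool$clone_id))
  # strict selection: every survivor is mutated
  expect_true(all(ss$n_mut >= 1L))
})

test_that("base-specific suppressors require the matching substitution", {
  ref <- example_locus()
  sup <- data.frame(pos = 43L, alt = "A")
  cfg <- sim_config(mu = 0.01, n_clones = 5000L, seed = 12,
                    condition = "selected", suppressors = sup)
  pool <- mutagenize_pool(ref, cfg, build_sequences = FALSE)
  ss <- apply_selection(pool, cfg, ref)
  ev <- ss$truth[ss$truth$pos == 43L, ]
  hits <- ev[ev$alt == "A" & ev$kind == "sub", ]
  expect_setequal(ss$clone_id, unique(hits$clone_id))
})

test_that("sequencing is deterministic per seed and error-calibrated", {
  ref <- tiny_locus()
  cfg <- sim_config(n_clones = 150L, seed = 31, read_length = 50L,
                    seq_error = 0, mu = 0.005)
  pool <- mutagenize_pool(ref, cfg)
  rd1 <- sequence_reads(pool, cfg, seed = 31)
  rd2 <- sequence_reads(pool, cfg, seed = 31)
  expect_identical(rd1, rd2)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(rd1$fwd, f1); write_fastq(rd2$fwd, f2)
  expect_identical(readLines(f1), readLines(f2))

  # error rate: with mu=0 every mismatch to the reference is a seq error
  cfge <- sim_config(n_clones = 400L, seed = 32, read_length = 50L,
                     seq_error = 0.015, mu = 0)
  poole <- mutagenize_pool(ref, cfge)
  rde <- sequence_reads(poole, cfge, seed = 32)
  refprefix <- strsplit(substr(ref$sequence, 1, 50), "")[[1]]
  nerr <- vapply(strsplit(rde$fwd$seq, ""), function(s)
    sum(s != refprefix), integer(1))
  expected <- 0.015 * 50
  expect_lt(abs(mean(nerr) - expected),
            3 * sqrt(expected / 400))  # ~Poisson s.e.
  # constant quality encodes the error rate
  expect_equal(unique(unlist(qual_to_int(rde$fwd$qual[1]))),
               round(-10 * log10(0.015)))
})

test_that("truth-level observation agrees with its clone pool", {
  ref <- example_locus()
  cfg <- sim_config(mu = 0.002, n_clones = 4000L, seed = 41, delta = 0.04)
  pool <- mutagenize_pool(ref, cfg, build_sequences = FALSE)
  tp <- tally_truth_profiles(pool, ref, seq_error = 0, seed = 1)
  expect_equal(nrow(tp$profiles), 4000L)
  # classes reflect exact event counts
  one_sub <- tapply(pool$truth$kind == "sub", pool$truth$clone_id, function(x)
    length(x) == 1 && all(x))
  n_single_truth <- sum(one_sub)
  expect_equal(sum(tp$profiles$class == "single_sub"), n_single_truth)
  expect_equal(sum(tp$profiles$class == "zero"), sum(pool$n_mut == 0))
  # events are exactly the truth events
  expect_equal(nrow(tp$events), nrow(pool$truth))
  expect_setequal(paste(tp$events$pos, tp$events$alt, tp$events$kind),
                  paste(pool$truth$pos, pool$truth$alt, pool$truth$kind))
})
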