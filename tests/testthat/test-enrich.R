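test_that("positional counts tally single-substitution events", {
  ref <- tiny_locus()
  calls <- list(
    s1 = calls_from_events(ref, pos = c(5L, 5L, 9L), alt = c("G", "T", "A")))
  cm <- positional_counts(calls, ref, conditions = "WT")
  expect_equal(unname(cm["5", "s1"]), 2L)
  expect_equal(unname(cm["9", "s1"]), 1L)
  expect_equal(sum(cm), 3L)
})

test_that("nucleotide counts marginalize to positional counts", {
  ref <- tiny_locus()  # no engineered positions
  set.seed(5)
  pos <- sample(amplicon_to_tss(stat_positions(ref), ref), 120, replace = TRUE)
  alt <- vapply(pos, function(p) {
    a <- tss_to_amplicon(p, ref)
    sample(setdiff(c("A", "C", "G", "T"),
                   substring(ref$sequence, a, a)), 1)
  }, "")
  calls <- list(s1 = calls_from_events(ref, pos, alt))
  cp <- positional_counts(calls, ref, "WT")
  cn <- nucleotide_counts(calls, ref, "WT")
  by_pos <- rowsum(cn[, 1], sub("^\\+", "", sub(":.*", "", rownames(cn))))
  expect_equal(unname(by_pos[rownames(cp), 1]), unname(cp[, 1]))
  expect_equal(sum(cn), sum(cp))
})

test_that("engineered-position reads are excluded from nucleotide counts", {
  ref <- example_locus()
  calls <- list(s1 = calls_from_events(ref, pos = c(87L, 43L),
                                       alt = c("T", "A")))
  cn <- nucleotide_counts(calls, ref, "selected")
  expect_equal(sum(cn), 1L)  # the +87 read is dropped
  expect_equal(unname(attr(cn, "exclusions")["s1"]), 1L)
  expect_false(any(grepl("^\\+87:", rownames(cn)[cn[, 1] > 0])))
  cp <- positional_counts(calls, ref, "selected")
  expect_equal(sum(cp), 2L)  # positional analysis keeps it
})

test_that("median-of-ratios size factors match the hand-computed fixture", {
  m <- matrix(c(10, 30, 20, 60), 2, 2)
  sf <- median_ratio_size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)

  # identical samples get equal factors; scaling is equivariant
  m2 <- matrix(rpois(40, 50), 20, 2)
  m2[, 2] <- m2[, 1]
  sf2 <- median_ratio_size_factors(m2)
  expect_equal(sf2[1], sf2[2])
  m3 <- m2; m3[, 2] <- m3[, 2] * 4L
  sf3 <- median_ratio_size_factors(m3)
  expect_equal(unname(sf3[2] / sf3[1]), 4, tolerance = 1e-10)

  expect_warning(median_ratio_size_factors(matrix(c(0, 1, 2, 0), 2, 2)),
                 "total-count")
})

test_that("BH adjustment matches the step-up oracle and handles NAs", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  p <- c(0.01, NA, 0.04)
  out <- bh_adjust(p)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], bh_oracle(p[c(1, 3)]))

  set.seed(9)
  for (i in 1:300) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # idempotent and monotone in sorted-p order
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("NB Wald test: flat units, invariances and NA handling", {
  set.seed(4)
  m <- matrix(rnbinom(100 * 6, mu = 100, size = 20), 100, 6)
  m[1, ] <- 50L      # identical counts in every sample
  m[2, ] <- 0L       # all-zero unit
  rownames(m) <- paste0("u", 1:100)
  cond <- rep(c("WT", "selected"), each = 3)
  et <- nb_wald_test(m, cond, size_factors = rep(1, 6))
  expect_equal(et$log2FoldChange[1], 0, tolerance = 1e-6)
  expect_true(is.na(et$pvalue[2]))
  expect_true(is.na(et$significant[2]))
  expect_true(all(et$padj >= et$pvalue - 1e-12, na.rm = TRUE))

  # invariant to sample column order
  perm <- c(4, 1, 5, 2, 6, 3)
  et2 <- nb_wald_test(m[, perm], cond[perm], size_factors = rep(1, 6))
  expect_equal(et2$pvalue, et$pvalue, tolerance = 1e-8)
  expect_equal(et2$log2FoldChange, et$log2FoldChange, tolerance = 1e-8)
})

test_that("NB Wald test is roughly calibrated under the null", {
  set.seed(14)
  m <- matrix(rnbinom(500 * 6, mu = 200, size = 1 / 0.05), 500, 6)
  rownames(m) <- paste0("u", 1:500)
  et <- nb_wald_test(m, rep(c("WT", "selected"), each = 3))
  expect_lt(mean(et$pvalue < 0.05, na.rm = TRUE), 0.10)
  expect_gt(mean(et$pvalue < 0.05, na.rm = TRUE), 0.01)
})

test_that("NB results track the established count-model implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(23)
  n <- 150
  m <- matrix(rnbinom(n * 6, mu = 150, size = 1 / 0.05), n, 6)
  m[1:10, 4:6] <- rnbinom(30, mu = 150 * 6, size = 1 / 0.05)
  rownames(m) <- paste0("u", 1:n)
  colnames(m) <- paste0("s", 1:6)
  cond <- rep(c("WT", "selected"), each = 3)
  et <- nb_wald_test(m, cond)

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      m, S4Vectors::DataFrame(condition = factor(cond, c("WT", "selected"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds)
  })
  # size factors: same median-of-ratios definition
  expect_equal(unname(attr(et, "size_factors")),
               unname(DESeq2::sizeFactors(dds)), tolerance = 1e-6)
  # fold-changes agree closely; calls agree on the strong effects
  ok <- !is.na(res$padj)
  expect_gt(cor(et$log2FoldChange[ok], res$log2FoldChange[ok]), 0.98)
  expect_true(all(et$significant[1:10]))
  expect_true(all(res$padj[1:10] < 0.05))
})

test_that("TMM log matrix is composition-normalised and median-centred", {
  set.seed(6)
  m <- matrix(rpois(60, 100) + 1L, 30, 2)
  m[, 2] <- m[, 1]
  v <- tmm_log_matrix(m)
  expect_equal(unname(attr(v, "tmm_factors")), c(1, 1), tolerance = 1e-10)
  expect_true(all(abs(v) < 1e-10))

  m3 <- cbind(m[, 1], m[, 1] * 2L)
  v3 <- tmm_log_matrix(m3)
  expect_equal(unname(attr(v3, "tmm_factors")[2]), 1, tolerance = 0.01)

  m4 <- matrix(rpois(120, 80) + 1L, 30, 4)
  v4 <- tmm_log_matrix(m4)
  expect_true(all(abs(apply(v4, 1, median)) < 1e-12))
  expect_error(tmm_log_matrix(cbind(m[, 1], 0L)), "zero library")
})

test_that("sample clustering matches an average-linkage oracle", {
  set.seed(8)
  base <- matrix(rnorm(50 * 5), 50, 5)
  colnames(base) <- paste0("s", 1:5)
  base[, 5] <- base[, 4]  # duplicate sample
  hc <- cluster_samples(base + matrix(rnorm(250, sd = 1e-9), 50, 5))
  first <- hc$merge[1, ]
  expect_setequal(abs(first), c(4, 5))
  expect_lt(hc$height[1], 1e-6)

  for (i in 1:20) {
    m <- matrix(rnorm(40 * 5), 40, 5)
    colnames(m) <- paste0("s", 1:5)
    hc <- cluster_samples(m)
    got <- as.matrix(stats::cophenetic(hc))
    want <- avg_linkage_cophenetic(as.dist(1 - cor(m)))
    dimnames(want) <- dimnames(got)
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_error(cluster_samples(cbind(a = rep(1, 5), b = rnorm(5))),
               "constant column")
})

test_that("replicates cluster by condition on simulated screens", {
  ref <- tiny_locus()
  mono <- 0
  for (s in 1:15) {
    sim <- sim_screen_calls(ref, n_clones = 30000L, seed = 100L + s,
                            suppressors = data.frame(pos = c(12L, 25L, 33L),
                                                     alt = "ANY"),
                            depth_selected = 10000L)
    cp <- positional_counts(sim$calls, ref, sim$conditions)
    hc <- cluster_samples(tmm_log_matrix(cp))
    grp <- cutree(hc, k = 2)
    if (length(unique(grp[1:3])) == 1 && length(unique(grp[4:6])) == 1)
      mono <- mono + 1
  }
  expect_gte(mono, 14)
})
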