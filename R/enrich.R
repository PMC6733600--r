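#' Positional count matrix across samples
#'
#' For each sample, counts the single-substitution reads whose event falls
#' at each amplicon position (regardless of the substituted base), excluding
#' the primer-margin positions at the extremities. With `class =
#' "single_del"` or `"single_ins"` the same tally is produced for
#' single-base indel reads.
#'
#' @param calls_by_sample named list of `variant_calls` (one per sample).
#' @param ref a `locus_reference`.
#' @param conditions character vector, condition of each sample ("WT" or
#'   "selected"); defaults to the sample name with a trailing "_<rep>"
#'   stripped.
#' @param class read class to tally.
#' @return an integer matrix (class `count_matrix`), rows = TSS-relative
#'   positions, columns = samples; attributes `samples` (data.frame) and
#'   `unit_type`.
#' @export
positional_counts <- function(calls_by_sample, ref, conditions = NULL,
                              class = c("single_sub", "single_del",
                                        "single_ins")) {
  class <- match.arg(class)
  kind <- c(single_sub = "sub", single_del = "del", single_ins = "ins")[class]
  units <- amplicon_to_tss(stat_positions(ref), ref)
  counts <- vapply(calls_by_sample, function(calls) {
    ids <- calls$profiles$id[calls$profiles$class == class]
    ev <- calls$events[calls$events$id %in% ids &
                         calls$events$kind == kind, , drop = FALSE]
    as.integer(table(factor(ev$pos, levels = units)))
  }, integer(length(units)))
  rownames(counts) <- as.character(units)
  finish_count_matrix(counts, calls_by_sample, conditions,
                      unit_type = paste0("position_", kind))
}

#' Nucleotide-specific count matrix
#'
#' Units are (position, alternative base) pairs. Single-substitution reads
#' whose event lies at an engineered position are excluded from every
#' sample (their counts are reported in the `exclusions` attribute), and
#' unit keys use the wild-type reference base so that samples aligned
#' against the engineered (selected-construct) reference are comparable
#' with wild-type samples.
#'
#' @inheritParams positional_counts
#' @return a `count_matrix` with unit keys "pos:ref>alt", e.g.
#'   "+43:G>A"; attribute `exclusions` gives the per-sample number of
#'   excluded reads.
#' @export
nucleotide_counts <- function(calls_by_sample, ref, conditions = NULL) {
  pos_a <- stat_positions(ref)
  pos_t <- amplicon_to_tss(pos_a, ref)
  wt <- substring(ref$sequence, pos_a, pos_a)
  alts <- c("A", "C", "G", "T")
  grid <- data.frame(pos = rep(pos_t, each = 4L),
                     ref = rep(wt, each = 4L),
                     alt = rep(alts, length(pos_t)))
  grid <- grid[grid$alt != grid$ref, , drop = FALSE]
  keys <- paste0(ifelse(grid$pos > 0, "+", ""), grid$pos, ":",
                 grid$ref, ">", grid$alt)
  eng_pos <- if (!is.null(ref$engineered)) ref$engineered$pos else integer()
  exclusions <- integer(length(calls_by_sample))
  counts <- vapply(seq_along(calls_by_sample), function(s) {
    calls <- calls_by_sample[[s]]
    ids <- calls$profiles$id[calls$profiles$class == "single_sub"]
    ev <- calls$events[calls$events$id %in% ids &
                         calls$events$kind == "sub", , drop = FALSE]
    drop <- ev$pos %in% eng_pos
    exclusions[s] <<- sum(drop)
    ev <- ev[!drop, , drop = FALSE]
    k <- paste0(ifelse(ev$pos > 0, "+", ""), ev$pos, ":",
                # back-convert: key uses the wild-type base at this position
                wt[match(ev$pos, pos_t)], ">", ev$alt)
    as.integer(table(factor(k, levels = keys)))
  }, integer(length(keys)))
  rownames(counts) <- keys
  m <- finish_count_matrix(counts, calls_by_sample, conditions,
                           unit_type = "nucleotide")
  attr(m, "exclusions") <- setNames(exclusions, colnames(m))
  m
}

#' @keywords internal
finish_count_matrix <- function(counts, calls_by_sample, conditions,
                                unit_type) {
  sn <- names(calls_by_sample)
  if (is.null(sn)) sn <- paste0("sample", seq_len(ncol(counts)))
  colnames(counts) <- sn
  if (is.null(conditions)) conditions <- sub("_[0-9]+$", "", sn)
  attr(counts, "samples") <- data.frame(sample = sn, condition = conditions,
                                        stringsAsFactors = FALSE)
  attr(counts, "unit_type") <- unit_type
  class(counts) <- c("count_matrix", class(counts))
  counts
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over units of the ratio of the sample's count
#' to the unit's geometric mean across samples, computed over units with
#' strictly positive counts in every sample. If no such unit exists, falls
#' back to total-count normalisation with a warning.
#'
#' @param mat count matrix (units x samples).
#' @return positive numeric vector, one factor per sample.
#' @export
median_ratio_size_factors <- function(mat) {
  lg <- rowMeans(log(mat))
  use <- is.finite(lg)
  if (!any(use)) {
    warning("no unit with positive counts in all samples; ",
            "falling back to total-count normalisation")
    libs <- colSums(mat)
    return(libs / exp(mean(log(libs))))
  }
  apply(mat, 2, function(k) exp(median(log(k[use]) - lg[use])))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement; NAs are passed
#' through and do not count toward the number of tests.
#'
#' @param pvalues numeric vector in [0,1], NAs allowed.
#' @return adjusted p-values, same length.
#' @export
bh_adjust <- function(pvalues) {
  out <- rep(NA_real_, length(pvalues))
  ok <- !is.na(pvalues)
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}

#' Replicate-aware negative-binomial Wald test
#'
#' Per unit: a method-of-moments dispersion is estimated from the
#' size-factor-normalised counts, a mean-dispersion trend a1/mean + a0 is
#' fitted across units by iterated gamma regression, the log-dispersion is
#' shrunk toward the trend by maximising a Cox-Reid-adjusted likelihood with
#' a normal prior (sd `prior_sd`) on log dispersion, and a negative-binomial
#' log-linear model with a condition effect and size-factor offsets is
#' fitted at the final dispersion. The Wald statistic for the condition
#' coefficient is referred to a standard normal; p-values are BH-adjusted.
#'
#' @param mat count matrix (units x samples).
#' @param condition factor/character of per-sample conditions; the reference
#'   (denominator) level is "WT" when present, else the first level.
#' @param size_factors per-sample factors; default median-of-ratios.
#' @param alpha significance threshold on the adjusted p-value.
#' @param prior_sd sd of the normal prior on log dispersion.
#' @return an `enrichment_table` data.frame: `unit`, `baseMean`,
#'   `log2FoldChange`, `lfcSE`, `stat`, `pvalue`, `padj`, `significant`,
#'   `dispersion`. Units with all-zero counts carry NAs.
#' @export
nb_wald_test <- function(mat, condition = attr(mat, "samples")$condition,
                         size_factors = NULL, alpha = 0.05, prior_sd = 0.5) {
  m <- unclass(mat)
  if (is.null(condition)) stop("condition labels are required")
  condition <- as.character(condition)
  lev <- unique(condition)
  if (length(lev) != 2L) stop("exactly two conditions are required")
  refl <- if ("WT" %in% lev) "WT" else lev[1]
  altl <- setdiff(lev, refl)
  x2 <- as.numeric(condition == altl)
  if (min(table(condition)) < 2L) stop("need >= 2 replicates per condition")
  if (is.null(size_factors)) size_factors <- median_ratio_size_factors(m)
  sf <- size_factors
  k <- sweep(m, 2, sf, "/")
  baseMean <- rowMeans(k)
  nz <- baseMean > 0

  # method-of-moments dispersions (pooled within-condition variance)
  xi <- mean(1 / sf)
  groups <- split(seq_along(condition), condition)
  vw <- rowSums(vapply(groups, function(g)
    apply(k[, g, drop = FALSE], 1, var) * (length(g) - 1L),
    numeric(nrow(m)))) / (length(condition) - length(groups))
  disp_mom <- (vw - xi * baseMean) / baseMean^2

  trend <- fit_dispersion_trend(baseMean[nz], disp_mom[nz])
  disp_tr <- rep(NA_real_, nrow(m))
  disp_tr[nz] <- pmax(trend$a0 + trend$a1 / baseMean[nz], 1e-8)

  # group means of normalised counts -> fitted mu for dispersion likelihood
  qg <- vapply(groups, function(g) rowMeans(k[, g, drop = FALSE]),
               numeric(nrow(m)))
  gidx <- match(condition, colnames(qg))

  n_unit <- nrow(m)
  dispersion <- rep(NA_real_, n_unit)
  lfc <- se <- stat <- pval <- rep(NA_real_, n_unit)
  X <- cbind(1, x2)
  loff <- log(sf)
  for (u in which(nz)) {
    y <- m[u, ]
    mu0 <- pmax(qg[u, gidx], 1e-8) * sf
    lt <- log(disp_tr[u])
    obj <- function(la) {
      a <- exp(la)
      w <- mu0 / (1 + a * mu0)
      cr <- -0.5 * sum(log(vapply(groups, function(g) sum(w[g]), 0)))
      sum(dnbinom(y, size = 1 / a, mu = mu0, log = TRUE)) + cr -
        (la - lt)^2 / (2 * prior_sd^2)
    }
    opt <- optimize(obj, c(log(1e-8), log(100)), maximum = TRUE)
    a <- exp(opt$maximum)
    dispersion[u] <- a
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(
        X, y, family = MASS::negative.binomial(theta = 1 / a, link = "log"),
        offset = loff, control = list(maxit = 100))),
      error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) next
    b <- fit$coefficients
    muh <- pmax(fit$fitted.values, 1e-10)
    w <- muh / (1 + a * muh)
    xtwx <- crossprod(X, X * w)
    cov <- tryCatch(solve(xtwx), error = function(e) NULL)
    if (is.null(cov)) next
    lfc[u] <- b[2] / log(2)
    se[u] <- sqrt(cov[2, 2]) / log(2)
    stat[u] <- b[2] / sqrt(cov[2, 2])
    pval[u] <- 2 * pnorm(-abs(stat[u]))
  }
  padj <- bh_adjust(pval)
  out <- data.frame(unit = rownames(m), baseMean = baseMean,
                    log2FoldChange = lfc, lfcSE = se, stat = stat,
                    pvalue = pval, padj = padj,
                    significant = !is.na(padj) & padj <= alpha,
                    dispersion = dispersion,
                    stringsAsFactors = FALSE)
  out$significant[is.na(out$padj)] <- NA
  attr(out, "size_factors") <- sf
  attr(out, "dispersion_trend") <- trend
  attr(out, "contrast") <- c(numerator = altl, denominator = refl)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

# iterated gamma regression of dispersion on a1/mean + a0, with outlier
# exclusion; falls back to the median positive dispersion
#' @keywords internal
fit_dispersion_trend <- function(means, disps) {
  ok <- is.finite(disps) & disps > 1e-7 & means > 0
  fallback <- list(a0 = max(median(disps[ok], na.rm = TRUE), 1e-6, na.rm = TRUE),
                   a1 = 0)
  if (sum(ok) < 10) return(fallback)
  d <- disps[ok]; mn <- means[ok]
  use <- rep(TRUE, length(d))
  a0 <- median(d); a1 <- 0
  for (it in 1:4) {
    fit <- tryCatch(
      suppressWarnings(glm(d[use] ~ I(1 / mn[use]),
                           family = Gamma(link = "identity"),
                           start = c(max(a0, 1e-4), max(a1, 1e-4)))),
      error = function(e) NULL)
    if (is.null(fit)) return(fallback)
    a0 <- max(coef(fit)[1], 1e-8); a1 <- max(coef(fit)[2], 0)
    pred <- a0 + a1 / mn
    ratio <- d / pred
    use_new <- ratio < 10 & ratio > 1e-3
    if (all(use_new == use)) break
    use <- use_new
    if (sum(use) < 10) break
  }
  list(a0 = unname(a0), a1 = unname(a1))
}

#' TMM-normalised, median-centred log2 matrix
#'
#' Library sizes are rescaled by trimmed-mean-of-M-values factors (30\%
#' M-trim, 5\% A-trim, reference sample chosen by the upper-quartile rule),
#' counts are converted to log2 counts-per-million with pseudocount 1 (the
#' constant amplicon-length term of an FPKM folds into the centring), and
#' each unit row is median-centred.
#'
#' @param mat count matrix (units x samples).
#' @return numeric matrix, same dimensions; attribute `tmm_factors`.
#' @export
tmm_log_matrix <- function(mat) {
  m <- unclass(mat)
  libs <- colSums(m)
  if (any(libs == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(m)[libs == 0], collapse = ", "))
  nf <- edgeR::calcNormFactors(m, method = "TMM")
  v <- log2(sweep(m, 2, libs * nf, "/") * 1e6 + 1)
  v <- v - apply(v, 1, median)
  attr(v, "tmm_factors") <- nf
  v
}

#' Hierarchical clustering of samples
#'
#' Distance = 1 - Pearson correlation between sample columns; agglomeration
#' by average linkage. All units enter the distance (no significance
#' filter).
#'
#' @param normalized numeric matrix (units x samples), e.g. from
#'   [tmm_log_matrix()].
#' @return an `hclust` tree over samples.
#' @export
cluster_samples <- function(normalized) {
  if (ncol(normalized) < 2L) stop("need >= 2 samples")
  sds <- apply(normalized, 2, stats::sd)
  if (any(sds == 0 | is.na(sds)))
    stop("constant column (correlation undefined) in sample(s): ",
         paste(colnames(normalized)[sds == 0 | is.na(sds)], collapse = ", "))
  d <- as.dist(1 - cor(normalized))
  hclust(d, method = "average")
}

#' Write a sample dendrogram as Newick
#' @param hc an `hclust` object.
#' @param path output file.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Write a count matrix or enrichment table as TSV
#' @param x object to write.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  if (inherits(x, "count_matrix") || is.matrix(x)) {
    df <- data.frame(unit = rownames(x), as.data.frame(unclass(x)),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
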