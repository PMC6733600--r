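#' Positions covered by a feature, in TSS-relative coordinates
#' @param feature one row of a `locus_reference` feature table.
#' @return integer vector of TSS-relative positions (position 0 skipped).
#' @keywords internal
feature_positions <- function(feature) {
  p <- seq.int(feature$start, feature$end)
  p[p != 0L]
}

#' Per-region mutation density
#'
#' Density = number of significant positions inside the feature interval
#' divided by the feature length in nucleotides.
#'
#' @param sig_positions integer vector of significant TSS-relative
#'   positions.
#' @param ref a `locus_reference`.
#' @param features optional subset of feature names; default all.
#' @return data.frame `feature`, `n_sig`, `length_nt`, `density`.
#' @export
mutation_density <- function(sig_positions, ref, features = NULL) {
  f <- ref$features
  if (!is.null(features)) f <- f[f$name %in% features, , drop = FALSE]
  rows <- lapply(seq_len(nrow(f)), function(i) {
    fp <- feature_positions(f[i, ])
    data.frame(feature = f$name[i],
               n_sig = sum(unique(sig_positions) %in% fp),
               length_nt = length(fp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$density <- out$n_sig / out$length_nt
  out
}

#' Minimal functional motif of a feature
#'
#' Positions at which suppressor mutations are selectable are essential for
#' function; the minimal motif keeps the wild-type base at every
#' significant position and masks the rest with N.
#'
#' @param feature_name name of the feature in `ref$features`.
#' @param sig_positions significant TSS-relative positions.
#' @param ref a `locus_reference`.
#' @return list with `feature`, `wt_motif`, `minimal_motif`.
#' @export
minimal_motif <- function(feature_name, sig_positions, ref) {
  f <- ref$features[ref$features$name == feature_name, , drop = FALSE]
  if (!nrow(f)) stop("unknown feature: ", feature_name)
  fp <- feature_positions(f[1, ])
  ap <- tss_to_amplicon(fp, ref)
  wt <- substring(ref$sequence, ap, ap)
  masked <- ifelse(fp %in% sig_positions, wt, "N")
  list(feature = feature_name,
       wt_motif = paste(wt, collapse = ""),
       minimal_motif = paste(masked, collapse = ""))
}

#' Codon position of a TSS-relative coordinate
#'
#' 1, 2 or 3 inside the ORF (its first base is codon position 1), NA
#' outside.
#'
#' @param tss_pos integer vector of TSS-relative positions.
#' @param ref a `locus_reference` with an "ORF" feature (or supply
#'   `orf_start`/`orf_end`).
#' @param orf_start,orf_end ORF bounds, TSS-relative.
#' @return integer vector (1/2/3 or NA).
#' @export
codon_position <- function(tss_pos, ref = NULL, orf_start = NULL,
                           orf_end = NULL) {
  if (is.null(orf_start)) {
    f <- ref$features[ref$features$name == "ORF", , drop = FALSE]
    if (!nrow(f)) stop("no ORF feature")
    orf_start <- f$start[1]; orf_end <- f$end[1]
  }
  out <- rep(NA_integer_, length(tss_pos))
  inside <- tss_pos >= orf_start & tss_pos <= orf_end
  out[inside] <- ((tss_pos[inside] - orf_start) %% 3L) + 1L
  out
}

#' Classify base-pair covariation in a structural alignment
#'
#' For every base pair (i, j) of a dot-bracket structure given in alignment
#' columns, each non-reference row is classified against the reference row:
#' `conserved` (both columns equal the reference), `compensatory` (both
#' differ, pair still canonical), `consistent` (exactly one differs, pair
#' still canonical), `disrupting` (anything else). Canonical pairs are
#' AU/UA, GC/CG and the GU/UG wobbles (T read as U). Rows gapped at i or j
#' are excluded from that pair's tally. The covariation score is the
#' compensatory fraction among non-conserved classified rows.
#'
#' @param alignment named character vector of equal-length gapped sequences.
#' @param structure dot-bracket string, one character per alignment column.
#' @param reference_row name or index of the reference sequence.
#' @return data.frame per pair: `i`, `j`, `ref_pair`, `conserved`,
#'   `consistent`, `compensatory`, `disrupting`, `n_classified`, `score`.
#' @export
covariation_classify <- function(alignment, structure, reference_row = 1L) {
  w <- unique(nchar(alignment))
  if (length(w) != 1L) stop("alignment rows must have equal length")
  if (nchar(structure) != w)
    stop("structure length must match the alignment width")
  pairs <- parse_dotbracket(structure)
  if (!nrow(pairs))
    return(data.frame(i = integer(), j = integer(), ref_pair = character(),
                      conserved = integer(), consistent = integer(),
                      compensatory = integer(), disrupting = integer(),
                      n_classified = integer(), score = numeric()))
  M <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  M[M == "T"] <- "U"
  if (is.character(reference_row))
    reference_row <- match(reference_row, names(alignment))
  refrow <- M[reference_row, ]
  others <- setdiff(seq_len(nrow(M)), reference_row)
  canonical <- c("AU", "UA", "GC", "CG", "GU", "UG")
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs$i[k]; j <- pairs$j[k]
    a <- M[others, i]; b <- M[others, j]
    gap <- a %in% c("-", ".") | b %in% c("-", ".")
    a <- a[!gap]; b <- b[!gap]
    ra <- refrow[i]; rb <- refrow[j]
    same_a <- a == ra; same_b <- b == rb
    canon <- paste0(a, b) %in% canonical
    conserved <- same_a & same_b
    compensatory <- !same_a & !same_b & canon
    consistent <- xor(same_a, same_b) & canon
    disrupting <- !(conserved | compensatory | consistent)
    ncl <- length(a)
    nonc <- sum(!conserved)
    data.frame(i = i, j = j, ref_pair = paste0(ra, rb),
               conserved = sum(conserved), consistent = sum(consistent),
               compensatory = sum(compensatory),
               disrupting = sum(disrupting), n_classified = ncl,
               score = if (nonc > 0) sum(compensatory) / nonc else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @keywords internal
parse_dotbracket <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  stack <- integer(); i <- integer(); j <- integer()
  for (k in seq_along(ch)) {
    if (ch[k] == "(") stack <- c(stack, k)
    else if (ch[k] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      i <- c(i, stack[length(stack)]); j <- c(j, k)
      stack <- stack[-length(stack)]
    } else if (ch[k] != ".") stop("invalid dot-bracket character: ", ch[k])
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  ord <- order(i)
  data.frame(i = i[ord], j = j[ord])
}
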