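#' Build an annotated amplicon reference
#'
#' A `locus_reference` bundles the amplicon sequence with its coordinate
#' system and annotation: the transcription start site (TSS) used for
#' reporting positions, a feature table in TSS-relative coordinates,
#' engineered (construct-defining) positions, and the primer margin excluded
#' from statistics at each extremity.
#'
#' Positions are handled in two systems. Internally everything is 1-based on
#' the amplicon. Reported coordinates are TSS-relative: the TSS is +1, the
#' base before it is -1, and there is no position 0.
#'
#' @param length amplicon length in nt. Ignored when `sequence` is given.
#' @param features data.frame with columns `name`, `start`, `end`, `strand`
#'   (TSS-relative, inclusive; negative = upstream of the TSS).
#' @param tss_offset 1-based amplicon position of the TSS.
#' @param engineered data.frame with columns `pos` (TSS-relative), `wt`,
#'   `engineered` describing construct-defining substitutions (e.g. an
#'   inactivated antisense-promoter -10 box), or NULL.
#' @param seed integer seed for the random sequence draw.
#' @param sequence optional explicit A/C/G/T sequence stored verbatim.
#' @param primer_margin positions at each extremity excluded from statistics.
#' @param id reference name.
#' @return an object of class `locus_reference`.
#' @export
make_reference <- function(length = 426L, features = NULL, tss_offset = 46L,
                           engineered = NULL, seed = 1L, sequence = NULL,
                           primer_margin = 4L, id = "amplicon") {
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (grepl("[^ACGT]", sequence))
      stop("reference sequence must contain only A/C/G/T")
    length <- nchar(sequence)
  } else {
    set.seed(seed)
    sequence <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                      collapse = "")
  }
  length <- as.integer(length)
  tss_offset <- as.integer(tss_offset)
  if (tss_offset < 1L || tss_offset > length)
    stop("tss_offset must lie within the amplicon")
  if (primer_margin < 0L) stop("primer_margin must be >= 0")

  if (is.null(features))
    features <- data.frame(name = character(), start = integer(),
                           end = integer(), strand = character())
  stopifnot(all(c("name", "start", "end") %in% names(features)))
  if (is.null(features$strand)) features$strand <- "+"
  if (anyDuplicated(features$name))
    stop("feature names must be unique")
  ref <- structure(
    list(id = id, sequence = sequence, length = length,
         tss_offset = tss_offset, features = features,
         engineered = engineered, primer_margin = as.integer(primer_margin)),
    class = "locus_reference")
  # validate feature bounds in amplicon space
  if (nrow(features)) {
    a <- tss_to_amplicon(features$start, ref)
    b <- tss_to_amplicon(features$end, ref)
    if (any(a < 1L | b > length | a > b))
      stop("feature interval outside the amplicon: ",
           paste(features$name[a < 1L | b > length | a > b], collapse = ", "))
  }
  if (!is.null(engineered)) {
    stopifnot(all(c("pos", "wt", "engineered") %in% names(engineered)))
    ap <- tss_to_amplicon(engineered$pos, ref)
    if (any(ap < 1L | ap > length))
      stop("engineered position outside the amplicon")
    wt_obs <- substring(sequence, ap, ap)
    if (any(wt_obs != engineered$wt))
      stop("engineered wt base does not match the reference sequence")
  }
  ref
}

#' @export
print.locus_reference <- function(x, ...) {
  cat("locus_reference '", x$id, "': ", x$length, " nt, TSS at amplicon pos ",
      x$tss_offset, "\n", sep = "")
  cat("  features: ", paste(x$features$name, collapse = ", "), "\n", sep = "")
  if (!is.null(x$engineered))
    cat("  engineered positions: ",
        paste0(ifelse(x$engineered$pos > 0, "+", ""), x$engineered$pos,
               " (", x$engineered$wt, ">", x$engineered$engineered, ")",
               collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Convert amplicon coordinates to TSS-relative coordinates
#'
#' The TSS maps to +1 and the base immediately upstream to -1; there is no
#' position 0. `tss_to_amplicon` is the exact inverse.
#'
#' @param pos integer vector of positions.
#' @param ref a `locus_reference`.
#' @return integer vector of converted positions.
#' @export
amplicon_to_tss <- function(pos, ref) {
  if (any(pos < 1L | pos > ref$length))
    stop("position outside the amplicon")
  ifelse(pos >= ref$tss_offset, pos - ref$tss_offset + 1L,
         pos - ref$tss_offset)
}

#' @rdname amplicon_to_tss
#' @export
tss_to_amplicon <- function(pos, ref) {
  if (any(pos == 0L)) stop("TSS-relative coordinates have no position 0")
  out <- ifelse(pos > 0L, pos + ref$tss_offset - 1L, pos + ref$tss_offset)
  as.integer(out)
}

#' Reference carrying the engineered (selected-construct) bases
#'
#' In the selected condition the clones derive from the construct whose
#' engineered positions differ from wild type (the inactivated antitoxin
#' promoter). This returns the same `locus_reference` with those bases
#' substituted into the sequence.
#'
#' @param ref a `locus_reference` with an `engineered` table.
#' @return a `locus_reference`.
#' @export
selected_reference <- function(ref) {
  if (is.null(ref$engineered) || !nrow(ref$engineered)) return(ref)
  s <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  ap <- tss_to_amplicon(ref$engineered$pos, ref)
  s[ap] <- ref$engineered$engineered
  ref$sequence <- paste(s, collapse = "")
  ref
}

#' Example toxin-antitoxin locus emulating the study geometry
#'
#' A 426-nt amplicon with a toxin -10 box (TAGGAT), TSS, 5'UTR containing a
#' Shine-Dalgarno sequence (AAGGAGG), a short ORF, an antisense-promoter -10
#' box inside the ORF whose two adenines (+87, +90) are the engineered
#' positions, and a 3'UTR. Four primer-derived positions at each extremity
#' are excluded from statistics.
#'
#' @param seed seed for the random background sequence.
#' @return a `locus_reference`.
#' @export
example_locus <- function(seed = 42L) {
  L <- 426L; tss <- 46L
  features <- data.frame(
    name   = c("minus10_box", "UTR5", "SD", "ORF", "antitoxin_minus10", "UTR3"),
    start  = c(-12L,  1L, 37L,  52L,  85L, 145L),
    end    = c( -7L, 51L, 43L, 144L,  90L, 377L),
    strand = c("+", "+", "+", "+", "-", "+"))
  set.seed(seed)
  s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  put <- function(s, tss_pos, motif) {
    i <- tss_pos + ifelse(tss_pos > 0, tss - 1L, tss)
    s[seq(i, i + nchar(motif) - 1L)] <- strsplit(motif, "")[[1]]
    s
  }
  s <- put(s, -12L, "TAGGAT")   # toxin -10 box
  s <- put(s, 37L, "AAGGAGG")   # SD
  s <- put(s, 52L, "ATG")       # start codon
  s <- put(s, 142L, "TAA")      # stop codon
  s <- put(s, 85L, "TA")        # antisense -10 region
  s <- put(s, 87L, "A")         # engineered position, wt base
  s <- put(s, 90L, "A")         # engineered position, wt base
  eng <- data.frame(pos = c(87L, 90L), wt = c("A", "A"),
                    engineered = c("G", "C"))
  make_reference(features = features, tss_offset = tss, engineered = eng,
                 sequence = paste(s, collapse = ""), primer_margin = 4L,
                 id = "toxTA_locus")
}

#' Default planted suppressor set for the example locus
#'
#' Twenty TSS-relative positions spread over the regulatory elements and ORF
#' (promoter -10 box, 5'UTR, SD, start codon, coding positions, 3'UTR), any
#' alternative base. Used as the simulator's planted truth.
#'
#' @return data.frame with columns `pos` and `alt` ("ANY").
#' @export
example_suppressors <- function() {
  data.frame(
    pos = c(-26L, -12L, -11L, -7L, 28L, 40L, 43L, 52L, 53L, 54L,
            64L, 78L, 97L, 107L, 120L, 131L, 146L, 160L, 177L, 200L),
    alt = "ANY")
}

#' Positions eligible for statistics (amplicon minus primer margins)
#' @param ref a `locus_reference`.
#' @return integer vector of amplicon positions.
#' @keywords internal
stat_positions <- function(ref) {
  seq.int(ref$primer_margin + 1L, ref$length - ref$primer_margin)
}
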