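#' Global affine-gap alignment of merged reads to the amplicon
#'
#' End-to-end (glocal in spirit: the amplicon is primer-anchored and reads
#' are expected full-length) dynamic-programming alignment with affine gap
#' penalties. A gap of length k scores `gap_open + k * gap_ext`. Tie-breaking
#' is deterministic: mismatch is preferred over gap, gaps are placed
#' leftmost on the reference. Reads whose length falls outside
#' `ref length +/- window` are not aligned and classify as `unaligned`.
#'
#' @param seqs character vector of merged read sequences.
#' @param ref a `locus_reference` (or plain sequence string).
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_ext`
#'   (defaults +1/-3/-5/-2).
#' @param window allowed deviation of read length from reference length.
#' @return list of alignments, each with `score`, `pattern` and `subject`
#'   (gapped strings), `nm` (edit distance: mismatched + inserted + deleted
#'   bases) and `events` (data.frame `apos`, `ref`, `alt`, `kind`); NULL for
#'   out-of-window reads.
#' @export
align_glocal <- function(seqs, ref,
                         scoring = list(match = 1, mismatch = -3,
                                        gap_open = -5, gap_ext = -2),
                         window = 20L) {
  refseq <- if (inherits(ref, "locus_reference")) ref$sequence else ref
  L <- nchar(refseq)
  out <- vector("list", length(seqs))
  inwin <- which(nchar(seqs) >= L - window & nchar(seqs) <= L + window &
                   nchar(seqs) > 0L)
  if (length(inwin)) {
    raw <- .align_affine_cpp(seqs[inwin], refseq,
                             match = scoring$match,
                             mismatch = scoring$mismatch,
                             gap_open = scoring$gap_open,
                             gap_ext = scoring$gap_ext)
    for (k in seq_along(inwin)) {
      al <- raw[[k]]
      ev <- alignment_events(al$pattern, al$subject)
      out[[inwin[k]]] <- list(score = al$score, pattern = al$pattern,
                              subject = al$subject, nm = nrow(ev),
                              events = ev)
    }
  }
  out
}

# derive per-column edit events from a gapped pattern/subject pair
#' @keywords internal
alignment_events <- function(pattern, subject) {
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  s <- strsplit(subject, "", fixed = TRUE)[[1]]
  refpos <- cumsum(s != "-")
  d <- which(p != s)
  if (!length(d))
    return(data.frame(apos = integer(), ref = character(),
                      alt = character(), kind = character(),
                      stringsAsFactors = FALSE))
  kind <- ifelse(s[d] == "-", "ins", ifelse(p[d] == "-", "del", "sub"))
  data.frame(apos = refpos[d],   # for insertions: ref base preceding the gap
             ref = ifelse(kind == "ins", "-", s[d]),
             alt = ifelse(kind == "del", "-", p[d]),
             kind = kind, stringsAsFactors = FALSE)
}

#' Classify merged reads by edit structure
#'
#' Aligns reads and assigns each one to an analysis class: `zero` (full
#' length, no edits), `single_sub` (length L, one substitution),
#' `single_del` (length L-1, one single-base deletion), `single_ins`
#' (length L+1, one single-base insertion), `multi` (anything else that
#' aligned), or `unaligned` (outside the length window). Any read whose
#' alignment mixes a substitution with an indel is `multi` regardless of
#' length.
#'
#' @param reads merged read-set data.frame (`id`, `seq`, ...).
#' @param ref a `locus_reference`.
#' @inheritParams align_glocal
#' @return a `variant_calls` object: `profiles` (data.frame `id`, `class`,
#'   `n_sub`, `read_len`, `score`, `nm`) and `events` (data.frame `id`,
#'   `apos`, `pos` [TSS-relative], `ref`, `alt`, `kind`) restricted to reads
#'   of the three single-event classes plus `multi`.
#' @export
call_variants <- function(reads, ref,
                          scoring = list(match = 1, mismatch = -3,
                                         gap_open = -5, gap_ext = -2),
                          window = 20L) {
  stopifnot(inherits(ref, "locus_reference"))
  aln <- align_glocal(reads$seq, ref, scoring, window)
  L <- ref$length
  n <- nrow(reads)
  class <- character(n); n_sub <- integer(n)
  score <- rep(NA_real_, n); nm <- rep(NA_integer_, n)
  evs <- vector("list", n)
  rl <- nchar(reads$seq)
  for (i in seq_len(n)) {
    a <- aln[[i]]
    if (is.null(a)) { class[i] <- "unaligned"; next }
    e <- a$events
    score[i] <- a$score; nm[i] <- a$nm
    n_sub[i] <- sum(e$kind == "sub")
    n_ins <- sum(e$kind == "ins"); n_del <- sum(e$kind == "del")
    ntot <- nrow(e)
    class[i] <-
      if (ntot == 0L) "zero"
      else if (ntot == 1L && n_sub[i] == 1L && rl[i] == L) "single_sub"
      else if (ntot == 1L && n_del == 1L && rl[i] == L - 1L) "single_del"
      else if (ntot == 1L && n_ins == 1L && rl[i] == L + 1L) "single_ins"
      else "multi"
    if (ntot > 0L) { e$id <- reads$id[i]; evs[[i]] <- e }
  }
  events <- do.call(rbind, evs[!vapply(evs, is.null, TRUE)])
  if (is.null(events))
    events <- data.frame(id = character(), apos = integer(),
                         ref = character(), alt = character(),
                         kind = character(), stringsAsFactors = FALSE)
  # TSS-relative reporting coordinate (insertions before the amplicon start
  # carry apos 0 and get no TSS coordinate)
  events$pos <- rep(NA_integer_, nrow(events))
  okp <- events$apos >= 1L & events$apos <= L
  events$pos[okp] <- amplicon_to_tss(events$apos[okp], ref)
  events <- events[, c("id", "apos", "pos", "ref", "alt", "kind")]
  rownames(events) <- NULL
  profiles <- data.frame(id = reads$id, class = class, n_sub = n_sub,
                         read_len = rl, score = score, nm = nm,
                         stringsAsFactors = FALSE)
  structure(list(profiles = profiles, events = events),
            class = "variant_calls")
}

#' @export
print.variant_calls <- function(x, ...) {
  cat("variant_calls:", nrow(x$profiles), "reads\n")
  print(table(x$profiles$class))
  invisible(x)
}

#' Per-sample histogram of substitutions per read
#'
#' Counts reads carrying 0, 1, ..., 9, and 10-or-more substitutions among
#' the length-conserving aligned reads (read length equal to the reference
#' length), the population the screen's mutation-load figure is drawn from.
#'
#' @param calls a `variant_calls` object.
#' @param ref a `locus_reference`.
#' @return integer vector of length 11 named "0".."9","10+"; its sum equals
#'   the number of length-conserving aligned reads.
#' @export
mutation_histogram <- function(calls, ref) {
  p <- calls$profiles
  keep <- p$class != "unaligned" & p$read_len == ref$length
  k <- pmin(p$n_sub[keep], 10L)
  out <- tabulate(k + 1L, nbins = 11L)
  names(out) <- c(as.character(0:9), "10+")
  out
}
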