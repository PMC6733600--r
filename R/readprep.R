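#' 3' quality trimming by the partial-sum rule
#'
#' From the 3' end, running sums of (threshold - q) are accumulated; the read
#' is cut at the position where the running sum is maximal and positive
#' (the classic BWA/cutadapt `-q` algorithm). Bases and qualities are
#' truncated together; retained bases are an untouched prefix of the input.
#' Reads whose every base falls below the threshold become length-0 reads.
#'
#' @param reads read-set data.frame (`id`, `seq`, `qual`).
#' @param threshold Phred quality threshold (default 28).
#' @return the trimmed read set.
#' @export
trim_3prime_quality <- function(reads, threshold = 28L) {
  keep_len <- vapply(reads$qual, function(qs) {
    n <- nchar(qs)
    if (n == 0L) return(0L)
    q <- utf8ToInt(qs) - 33L
    s <- cumsum(threshold - rev(q))
    mx <- max(s)
    if (mx > 0) n - which.max(s) else n
  }, integer(1), USE.NAMES = FALSE)
  reads$seq <- substring(reads$seq, 1L, keep_len)
  reads$qual <- substring(reads$qual, 1L, keep_len)
  reads
}

#' Mean-quality read filter
#'
#' A read passes if its arithmetic mean Phred quality is at least the
#' threshold ("lower than threshold" fails; a mean of exactly 28 passes at
#' the default). Length-0 reads fail.
#'
#' @param reads read-set data.frame.
#' @param threshold mean Phred threshold (default 28).
#' @return logical vector, TRUE = pass.
#' @export
mean_quality_filter <- function(reads, threshold = 28) {
  vapply(reads$qual, function(qs) {
    if (nchar(qs) == 0L) return(FALSE)
    mean(utf8ToInt(qs) - 33L) >= threshold
  }, logical(1), USE.NAMES = FALSE)
}

#' Synchronize mates after independent filtering
#'
#' Returns exactly the pairs whose two mates both passed the preceding
#' steps, ordered by first-mate appearance. Duplicate read ids within a mate
#' set are an error.
#'
#' @param fwd,rev read sets of the surviving forward and reverse mates.
#' @return list with aligned `fwd` and `rev` read sets.
#' @export
sync_pairs <- function(fwd, rev) {
  if (anyDuplicated(fwd$id) || anyDuplicated(rev$id))
    stop("duplicate read ids in a mate set")
  common <- fwd$id[fwd$id %in% rev$id]
  list(fwd = fwd[match(common, fwd$id), , drop = FALSE],
       rev = rev[match(common, rev$id), , drop = FALSE])
}

#' Merge overlapping mate pairs into single amplicon sequences
#'
#' The reverse mate is reverse-complemented, every overlap length of at
#' least `min_overlap` is scored by its match fraction (N matches nothing),
#' and the best-scoring overlap is kept (ties broken toward the longest
#' overlap). The pair fails if the best match fraction is below `min_frac`.
#' In the overlap, agreeing columns get the summed Phred (capped at 93);
#' disagreeing columns keep the base with the higher Phred (forward wins
#' exact quality ties).
#'
#' @param fwd,rev synchronized read sets.
#' @param min_overlap minimum overlap length (default 30).
#' @param min_frac minimum match fraction in the overlap (default 0.6).
#' @return list with `merged` (data.frame `id`, `seq`, `qual`,
#'   `overlap_len`) and `failed` (data.frame `id`, `reason`).
#' @export
merge_pairs <- function(fwd, rev, min_overlap = 30L, min_frac = 0.6) {
  n <- nrow(fwd)
  merged <- vector("list", n)
  failed <- vector("list", n)
  rc <- revcomp(rev$seq)
  for (i in seq_len(n)) {
    r <- merge_one(fwd$seq[i], fwd$qual[i], rc[i], rev$qual[i],
                   min_overlap, min_frac)
    if (is.character(r)) {
      failed[[i]] <- data.frame(id = fwd$id[i], reason = r,
                                stringsAsFactors = FALSE)
    } else {
      merged[[i]] <- data.frame(id = fwd$id[i], seq = r$seq, qual = r$qual,
                                overlap_len = r$overlap,
                                stringsAsFactors = FALSE)
    }
  }
  mg <- do.call(rbind, merged[!vapply(merged, is.null, TRUE)])
  fl <- do.call(rbind, failed[!vapply(failed, is.null, TRUE)])
  if (is.null(mg))
    mg <- data.frame(id = character(), seq = character(), qual = character(),
                     overlap_len = integer(), stringsAsFactors = FALSE)
  if (is.null(fl))
    fl <- data.frame(id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  list(merged = mg, failed = fl)
}

# merge a single pair; rc = reverse-complemented reverse mate,
# rq = its qualities in original (reverse-read) orientation
#' @keywords internal
merge_one <- function(fs, fq, rc, rq, min_overlap, min_frac) {
  a <- nchar(fs); b <- nchar(rc)
  if (a == 0L || b == 0L) return("empty_mate")
  if (min(a, b) < min_overlap) return("no_overlap")
  F <- charToRaw(fs); R <- charToRaw(rc)
  qf <- utf8ToInt(fq) - 33L
  qr <- rev(utf8ToInt(rq) - 33L)   # reversed to match reverse-complement
  rawN <- charToRaw("N")
  best_frac <- -1; best_ov <- 0L
  for (ov in seq.int(min_overlap, min(a, b))) {
    x <- F[(a - ov + 1L):a]; y <- R[1:ov]
    m <- sum(x == y & x != rawN)
    frac <- m / ov
    if (frac >= best_frac) { best_frac <- frac; best_ov <- ov }
  }
  if (best_frac < min_frac) return("low_identity")
  ov <- best_ov
  xi <- (a - ov + 1L):a
  x <- F[xi]; y <- R[1:ov]
  qx <- qf[xi]; qy <- qr[1:ov]
  qx[x == rawN] <- 0L; qy[y == rawN] <- 0L
  agree <- x == y & x != rawN
  cons <- x; qc <- integer(ov)
  qc[agree] <- pmin(qx[agree] + qy[agree], 93L)
  d <- !agree
  take_rev <- d & (qy > qx)
  cons[take_rev] <- y[take_rev]
  qc[d] <- pmax(qx, qy)[d]  # disagreeing column keeps the winner's quality
  seq <- paste0(substr(fs, 1L, a - ov), rawToChar(cons),
                rawToChar(R[seq_len(b - ov) + ov]))
  qual <- intToUtf8(c(qf[seq_len(a - ov)], qc, qr[seq_len(b - ov) + ov]) + 33L)
  list(seq = seq, qual = qual, overlap = ov)
}

#' Run the full read-preparation stage on one sample
#'
#' Trims 3' ends, applies the mean-quality filter, synchronizes mates and
#' merges the surviving pairs; returns merged reads plus per-stage counts.
#'
#' @param fwd,rev raw read sets of a sample.
#' @param trim_q,mean_q,min_overlap,min_frac stage thresholds.
#' @return list with `merged`, `failed`, and `stats` (named counts: input,
#'   fwd_pass, rev_pass, synced, merged, merge_failed).
#' @export
prep_sample <- function(fwd, rev, trim_q = 28L, mean_q = 28,
                        min_overlap = 30L, min_frac = 0.6) {
  n_in <- nrow(fwd)
  fwd_t <- trim_3prime_quality(fwd, trim_q)
  rev_t <- trim_3prime_quality(rev, trim_q)
  fp <- mean_quality_filter(fwd_t, mean_q)
  rp <- mean_quality_filter(rev_t, mean_q)
  sync <- sync_pairs(fwd_t[fp, , drop = FALSE], rev_t[rp, , drop = FALSE])
  mg <- merge_pairs(sync$fwd, sync$rev, min_overlap, min_frac)
  list(merged = mg$merged, failed = mg$failed,
       stats = c(input = n_in, fwd_pass = sum(fp), rev_pass = sum(rp),
                 synced = nrow(sync$fwd), merged = nrow(mg$merged),
                 merge_failed = nrow(mg$failed)))
}
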