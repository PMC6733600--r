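#' Simulation configuration for a synthetic clone pool
#'
#' Parameters of the generative model behind the screen: error-prone PCR
#' mutagenesis (per-base rate `mu`, transition:transversion weight `kappa`,
#' indel fraction `delta`), lethal selection against a planted suppressor
#' set, and per-base sequencing error with a constant-quality model.
#'
#' Defaults are the study conditions the simulator emulates: `mu` is set so
#' that about 51\% of unselected clones carry at least one mutation
#' (1-(1-mu)^426), `delta = 0.04` (4\% of mutation events are single-base
#' indels), `kappa = 4` (PCR transition bias), 2 x 250 nt overlapping reads,
#' and `seq_error = 0.001` (constant Phred 30, typical of a merged MiSeq
#' amplicon run).
#'
#' @param mu per-base PCR mutation probability.
#' @param kappa transition:transversion weight ratio (each transversion has
#'   weight 1, the transition has weight `kappa`).
#' @param delta fraction of mutation events that are single-base indels.
#' @param suppressors data.frame with columns `pos` (TSS-relative) and `alt`
#'   (alternative base, or "ANY" for any mutation at the position).
#' @param condition "unselected" (WT construct) or "selected" (antitoxin
#'   promoter inactivated; clones derive from the engineered reference).
#' @param n_clones number of clones in the pool.
#' @param read_length sequencing read length (paired-end, overlapping).
#' @param seq_error per-base sequencing substitution error probability.
#' @param seed integer seed; all pool randomness derives from it.
#' @param escape probability that a clone carrying at least one mutation but
#'   no planted suppressor survives selection anyway (leaky toxicity /
#'   revertants). 0 = strict selection.
#' @param mean_reads_per_clone mean sequenced read pairs per surviving clone;
#'   values > 1 draw per-clone copy numbers from 1 + Geometric (PCR
#'   jackpots).
#' @return a `sim_config` list.
#' @export
sim_config <- function(mu = 0.00168, kappa = 4, delta = 0.04,
                       suppressors = example_suppressors(),
                       condition = c("unselected", "selected"),
                       n_clones = 10000L, read_length = 250L,
                       seq_error = 0.001, seed = 1L, escape = 0,
                       mean_reads_per_clone = 1) {
  condition <- match.arg(condition)
  if (mu < 0 || mu > 1 || delta < 0 || delta > 1 ||
      seq_error < 0 || seq_error > 1 || escape < 0 || escape > 1)
    stop("mu, delta, seq_error and escape must lie in [0, 1]")
  if (kappa <= 0) stop("kappa must be > 0")
  if (n_clones <= 0) stop("n_clones must be > 0")
  if (mean_reads_per_clone < 1) stop("mean_reads_per_clone must be >= 1")
  structure(list(mu = mu, kappa = kappa, delta = delta,
                 suppressors = suppressors, condition = condition,
                 n_clones = as.integer(n_clones),
                 read_length = as.integer(read_length),
                 seq_error = seq_error, seed = as.integer(seed),
                 escape = escape,
                 mean_reads_per_clone = mean_reads_per_clone),
            class = "sim_config")
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

#' Mutagenize a clone pool
#'
#' Each clone receives independent per-base mutation events at rate `mu`
#' (so mutation counts are Binomial(L, mu)). A fraction `delta` of events are
#' single-base indels (insertion or deletion with equal probability); the
#' rest are substitutions whose alternative base is drawn with weight `kappa`
#' for the transition and 1 for each transversion. In the selected condition
#' the generation reference carries the engineered bases.
#'
#' @param ref a `locus_reference`.
#' @param config a `sim_config`.
#' @param build_sequences if FALSE, only the truth table is generated (fast
#'   path for pool-scale statistics); mutated sequences are not constructed.
#' @return a `clone_pool`: list with `clone_id`, `n_mut`, `truth` (data.frame
#'   `clone_id`, `pos` in TSS-relative coordinates, `ref`, `alt`, `kind`),
#'   `sequences` (or NULL), `ref_sequence`, `condition`.
#' @export
mutagenize_pool <- function(ref, config, build_sequences = TRUE) {
  stopifnot(inherits(ref, "locus_reference"), inherits(config, "sim_config"))
  gen_ref <- if (config$condition == "selected") selected_reference(ref) else ref
  L <- ref$length
  n <- config$n_clones
  set.seed(config$seed)
  n_mut <- rbinom(n, L, config$mu)

  truth <- data.frame(clone_id = integer(), pos = integer(),
                      ref = character(), alt = character(),
                      kind = character(), stringsAsFactors = FALSE)
  if (sum(n_mut) > 0) {
    clone <- rep.int(seq_len(n)[n_mut > 0], n_mut[n_mut > 0])
    pos <- sample.int(L, length(clone), replace = TRUE)
    # enforce distinct positions within a clone (without-replacement draw)
    repeat {
      dup <- duplicated(paste(clone, pos))
      if (!any(dup)) break
      pos[dup] <- sample.int(L, sum(dup), replace = TRUE)
    }
    refbase <- substring(gen_ref$sequence, pos, pos)
    is_indel <- runif(length(clone)) < config$delta
    is_ins <- is_indel & (runif(length(clone)) < 0.5)
    is_del <- is_indel & !is_ins
    kind <- ifelse(is_ins, "ins", ifelse(is_del, "del", "sub"))
    alt <- character(length(clone))
    # substitutions: transition with weight kappa vs 1 per transversion
    subi <- which(!is_indel)
    if (length(subi)) {
      p_ts <- config$kappa / (config$kappa + 2)
      ts <- runif(length(subi)) < p_ts
      alt[subi[ts]] <- TRANSITION[refbase[subi[ts]]]
      tv <- subi[!ts]
      if (length(tv)) {
        pick <- 1L + (runif(length(tv)) < 0.5)
        alt[tv] <- vapply(seq_along(tv), function(k)
          TRANSVERSIONS[[refbase[tv[k]]]][pick[k]], "")
      }
    }
    alt[is_ins] <- sample(c("A", "C", "G", "T"), sum(is_ins), replace = TRUE)
    alt[is_del] <- "-"
    refcol <- ifelse(is_ins, "-", refbase)
    truth <- data.frame(clone_id = clone,
                        pos = amplicon_to_tss(pos, ref),
                        apos = pos, ref = refcol, alt = alt, kind = kind,
                        stringsAsFactors = FALSE)
    truth <- truth[order(truth$clone_id, truth$apos), , drop = FALSE]
    rownames(truth) <- NULL
  } else {
    truth$apos <- integer()
  }

  sequences <- NULL
  if (build_sequences) {
    sequences <- rep.int(gen_ref$sequence, n)
    if (nrow(truth)) {
      base <- strsplit(gen_ref$sequence, "", fixed = TRUE)[[1]]
      ev_by_clone <- split(seq_len(nrow(truth)), truth$clone_id)
      for (cid_chr in names(ev_by_clone)) {
        idx <- ev_by_clone[[cid_chr]]
        s <- base
        # apply right-to-left so indices stay valid through indels
        for (k in rev(idx)) {
          p <- truth$apos[k]
          if (truth$kind[k] == "sub") s[p] <- truth$alt[k]
          else if (truth$kind[k] == "del") s <- s[-p]
          else s <- append(s, truth$alt[k], after = p)
        }
        sequences[as.integer(cid_chr)] <- paste(s, collapse = "")
      }
    }
  }
  structure(list(clone_id = seq_len(n), n_mut = n_mut, truth = truth,
                 sequences = sequences, ref_sequence = gen_ref$sequence,
                 condition = config$condition, seed = config$seed),
            class = "clone_pool")
}

#' @export
print.clone_pool <- function(x, ...) {
  cat("clone_pool: ", length(x$clone_id), " clones (", x$condition, "), ",
      sum(x$n_mut > 0), " mutated, ", nrow(x$truth), " mutation events\n",
      sep = "")
  invisible(x)
}

#' Apply lethal selection to a clone pool
#'
#' In the unselected condition all clones survive. In the selected condition
#' a clone survives if at least one of its mutations matches the planted
#' suppressor set (position match; base match unless the suppressor's `alt`
#' is "ANY", in which case any substitution or indel at the position
#' rescues). Optionally, mutated clones without a suppressor survive with
#' probability `config$escape` (leaky selection); unmutated clones never
#' survive selection. Survivor order follows input order.
#'
#' @param pool a `clone_pool`.
#' @param config the `sim_config` used to generate it.
#' @param ref the `locus_reference`.
#' @return a `clone_pool` restricted to survivors (original `clone_id`s are
#'   preserved), with a logical attribute-style field `survives` on the input
#'   clones available as `attr(, "survives")`.
#' @export
apply_selection <- function(pool, config, ref) {
  stopifnot(inherits(pool, "clone_pool"), inherits(config, "sim_config"))
  n <- length(pool$clone_id)
  if (config$condition == "unselected") {
    attr(pool, "survives") <- rep(TRUE, n)
    return(pool)
  }
  sup <- config$suppressors
  tr <- pool$truth
  hit <- rep(FALSE, nrow(tr))
  if (!is.null(sup) && nrow(sup) && nrow(tr)) {
    any_rows <- sup$pos[sup$alt == "ANY"]
    hit <- tr$pos %in% any_rows
    spec <- sup[sup$alt != "ANY", , drop = FALSE]
    if (nrow(spec))
      hit <- hit | (paste(tr$pos, tr$alt) %in% paste(spec$pos, spec$alt) &
                      tr$kind == "sub")
  }
  rescued <- unique(tr$clone_id[hit])
  survives <- pool$clone_id %in% rescued
  if (config$escape > 0) {
    set.seed((pool$seed + 77003L) %% .Machine$integer.max)
    eligible <- !survives & pool$n_mut >= 1L
    survives[eligible] <- runif(sum(eligible)) < config$escape
  }
  keep <- which(survives)
  out <- pool
  out$clone_id <- pool$clone_id[keep]
  out$n_mut <- pool$n_mut[keep]
  out$truth <- pool$truth[pool$truth$clone_id %in% out$clone_id, , drop = FALSE]
  rownames(out$truth) <- NULL
  if (!is.null(pool$sequences)) out$sequences <- pool$sequences[keep]
  attr(out, "survives") <- survives
  out
}

#' Generate overlapping paired-end reads from surviving clones
#'
#' The forward read is the first `read_length` bases of the clone; the
#' reverse read is the reverse complement of the last `read_length` bases, so
#' that the two mates overlap over the middle of the amplicon. Per-base
#' substitution errors are applied at rate `seq_error`; qualities are
#' constant at Phred round(-10 log10(seq_error)) (40 when `seq_error` is 0),
#' Sanger encoded. Clones too short for their mates to overlap are skipped
#' with a warning.
#'
#' @param pool a `clone_pool` (survivors), with sequences built.
#' @param config the `sim_config`.
#' @param seed seed for sequencing-error randomness.
#' @param sample_id string used as read-id prefix.
#' @return list with `fwd` and `rev` read sets (data.frames with columns
#'   `id`, `seq`, `qual`).
#' @export
sequence_reads <- function(pool, config, seed = config$seed,
                           sample_id = "sample") {
  stopifnot(inherits(pool, "clone_pool"))
  if (is.null(pool$sequences))
    stop("pool has no sequences; rerun mutagenize_pool(build_sequences=TRUE)")
  rl <- config$read_length
  empty <- data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE)
  if (!length(pool$clone_id)) return(list(fwd = empty, rev = empty))
  set.seed((seed + 13001L) %% .Machine$integer.max)
  lens <- nchar(pool$sequences)
  ok <- lens < 2L * rl
  if (any(!ok))
    warning(sum(!ok), " clone(s) too long for mates to overlap; skipped")
  idx <- which(ok)
  copies <- rep(1L, length(idx))
  if (config$mean_reads_per_clone > 1)
    copies <- 1L + rgeom(length(idx), prob = 1 / config$mean_reads_per_clone)
  reads_idx <- rep.int(idx, copies)
  copy_no <- sequence(copies)
  seqs <- pool$sequences[reads_idx]
  lens <- nchar(seqs)
  rlen <- pmin(rl, lens)
  fwd <- substring(seqs, 1L, rlen)
  rev <- revcomp(substring(seqs, lens - rlen + 1L, lens))
  ids <- paste0(sample_id, ":", pool$clone_id[reads_idx], ":", copy_no)
  q <- if (config$seq_error > 0) as.integer(round(-10 * log10(config$seq_error))) else 40L
  q <- min(q, 93L)
  fwd <- add_seq_errors(fwd, config$seq_error)
  rev <- add_seq_errors(rev, config$seq_error)
  qc <- vapply(nchar(fwd), function(n) strrep(intToUtf8(q + 33L), n), "")
  qr <- vapply(nchar(rev), function(n) strrep(intToUtf8(q + 33L), n), "")
  list(fwd = data.frame(id = ids, seq = fwd, qual = qc,
                        stringsAsFactors = FALSE),
       rev = data.frame(id = ids, seq = rev, qual = qr,
                        stringsAsFactors = FALSE))
}

#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# per-base substitution errors at rate p (uniform over the 3 other bases)
#' @keywords internal
add_seq_errors <- function(seqs, p) {
  if (p <= 0 || !length(seqs)) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, p)
  hit <- which(nerr > 0)
  for (i in hit) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    at <- sample.int(lens[i], nerr[i])
    s[at] <- vapply(s[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "", USE.NAMES = FALSE)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Truth-level observation of a clone pool
#'
#' Emulates, at the event level, what error-free merging and alignment would
#' report for each sequenced read: the clone's true mutations plus per-base
#' sequencing substitution errors (which can add apparent substitutions or,
#' rarely, revert a true one). This is the fast path for pool-scale runs; it
#' produces the same `variant_calls` structure as [call_variants()].
#'
#' @param pool a `clone_pool` (typically survivors).
#' @param ref the `locus_reference` the reads are compared against (use
#'   [selected_reference()] for the selected condition).
#' @param seq_error per-base sequencing error probability.
#' @param seed seed for error randomness.
#' @param depth total number of reads to draw (clones sampled with equal
#'   probability, with replacement, emulating deep PCR amplification of the
#'   pool); NULL = one read per clone.
#' @param sample_id read-id prefix.
#' @return a `variant_calls` object: list with `profiles` (data.frame `id`,
#'   `class`, `n_sub`, `read_len`) and `events` (data.frame `id`, `apos`,
#'   `pos`, `ref`, `alt`, `kind`).
#' @export
tally_truth_profiles <- function(pool, ref, seq_error = 0, seed = 1L,
                                 depth = NULL, sample_id = "sample") {
  stopifnot(inherits(pool, "clone_pool"), inherits(ref, "locus_reference"))
  set.seed((seed + 4242L) %% .Machine$integer.max)
  n <- length(pool$clone_id)
  L <- ref$length
  reads_clone <- if (is.null(depth)) seq_len(n) else
    sample.int(n, depth, replace = TRUE)
  nread <- length(reads_clone)
  ids <- paste0(sample_id, ":", pool$clone_id[reads_clone], ":",
                seq_len(nread))

  tr <- pool$truth
  # true events per read
  ev_rows <- split(seq_len(nrow(tr)), factor(tr$clone_id,
                                             levels = pool$clone_id))
  n_ev_clone <- lengths(ev_rows)
  read_ev_n <- n_ev_clone[reads_clone]
  ev_read <- rep.int(seq_len(nread), read_ev_n)
  ev_tr <- unlist(ev_rows[reads_clone], use.names = FALSE)
  events <- data.frame(id = ids[ev_read],
                       apos = tr$apos[ev_tr], pos = tr$pos[ev_tr],
                       ref = tr$ref[ev_tr], alt = tr$alt[ev_tr],
                       kind = tr$kind[ev_tr], stringsAsFactors = FALSE)

  if (seq_error > 0) {
    nerr <- rbinom(nread, L, seq_error)
    er <- which(nerr > 0)
    if (length(er)) {
      err_read <- rep.int(er, nerr[er])
      err_pos <- sample.int(L, length(err_read), replace = TRUE)
      refbase <- substring(ref$sequence, err_pos, err_pos)
      # current base at that position on this read (ref unless a true sub)
      key <- paste(err_read, err_pos)
      subev <- events$kind == "sub"
      tkey <- paste(match(events$id, ids), events$apos)[subev]
      talt <- events$alt[subev]
      cur <- refbase
      mi <- match(key, tkey)
      cur[!is.na(mi)] <- talt[mi[!is.na(mi)]]
      erralt <- vapply(cur, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "", USE.NAMES = FALSE)
      collide <- !is.na(mi)
      # overwrite collided true substitutions with the error outcome
      if (any(collide)) {
        evidx <- which(subev)[mi[collide]]
        events$alt[evidx] <- erralt[collide]
        drop <- events$alt[evidx] == events$ref[evidx]  # reversion to ref
        if (any(drop)) events <- events[-evidx[drop], , drop = FALSE]
      }
      add <- !collide
      if (any(add)) {
        events <- rbind(events, data.frame(
          id = ids[err_read[add]], apos = err_pos[add],
          pos = amplicon_to_tss(err_pos[add], ref),
          ref = refbase[add], alt = erralt[add], kind = "sub",
          stringsAsFactors = FALSE))
      }
    }
  }

  tabcnt <- function(kind) {
    t <- table(factor(events$id[events$kind == kind], levels = ids))
    as.integer(t)
  }
  n_sub <- tabcnt("sub"); n_ins <- tabcnt("ins"); n_del <- tabcnt("del")
  n_tot <- n_sub + n_ins + n_del
  class <- rep("multi", nread)
  class[n_tot == 0L] <- "zero"
  class[n_tot == 1L & n_sub == 1L] <- "single_sub"
  class[n_tot == 1L & n_del == 1L] <- "single_del"
  class[n_tot == 1L & n_ins == 1L] <- "single_ins"
  profiles <- data.frame(id = ids, class = class, n_sub = n_sub,
                         read_len = L + n_ins - n_del,
                         stringsAsFactors = FALSE)
  events <- events[order(match(events$id, ids), events$apos), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(profiles = profiles, events = events),
            class = "variant_calls")
}
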