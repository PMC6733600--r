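# shared fixtures, built in code

# short locus for read-level tests (reads of 50 nt overlap by 40)
tiny_locus <- function(seed = 3L) {
  feats <- data.frame(name = c("minus10_box", "SD", "ORF"),
                      start = c(-8L, 10L, 20L), end = c(-3L, 16L, 40L),
                      strand = "+")
  make_reference(length = 60L, features = feats, tss_offset = 10L,
                 seed = seed, primer_margin = 2L, id = "tiny")
}

# hand-built variant_calls object (one sample) from an event spec:
# events = data.frame(pos [TSS], alt); all reads are single_sub
calls_from_events <- function(ref, pos, alt, kind = "sub",
                              class = "single_sub") {
  n <- length(pos)
  ids <- paste0("r", seq_len(n))
  apos <- tss_to_amplicon(pos, ref)
  refb <- ifelse(kind == "ins", "-", substring(ref$sequence, apos, apos))
  structure(list(
    profiles = data.frame(id = ids, class = class, n_sub = 1L,
                          read_len = ref$length, stringsAsFactors = FALSE),
    events = data.frame(id = ids, apos = apos, pos = pos, ref = refb,
                        alt = alt, kind = kind, stringsAsFactors = FALSE)),
    class = "variant_calls")
}

# simulated 3 WT + 3 selected count-level screen via the truth path
sim_screen_calls <- function(ref, n_clones = 20000L, seed = 1L,
                             seq_error = 0.001, escape = 0.09,
                             suppressors = example_suppressors(),
                             depth_selected = n_clones) {
  calls <- list(); cond <- character()
  for (r in 1:3) {
    cfg <- sim_config(n_clones = n_clones, condition = "unselected",
                      seed = seed + 100L * r, seq_error = seq_error,
                      suppressors = suppressors)
    pool <- mutagenize_pool(ref, cfg, build_sequences = FALSE)
    surv <- apply_selection(pool, cfg, ref)
    calls[[paste0("WT_", r)]] <-
      tally_truth_profiles(surv, ref, seq_error, seed = seed + 100L * r)
    cond <- c(cond, "WT")
  }
  for (r in 1:3) {
    cfg <- sim_config(n_clones = n_clones, condition = "selected",
                      seed = seed + 100L * r + 50L, seq_error = seq_error,
                      escape = escape, suppressors = suppressors)
    pool <- mutagenize_pool(ref, cfg, build_sequences = FALSE)
    surv <- apply_selection(pool, cfg, ref)
    calls[[paste0("selected_", r)]] <-
      tally_truth_profiles(surv, selected_reference(ref), seq_error,
                           seed = seed + 100L * r + 50L,
                           depth = depth_selected)
    cond <- c(cond, "selected")
  }
  list(calls = calls, conditions = cond)
}
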