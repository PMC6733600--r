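#' Read a locus reference back from FASTA + annotation TSV
#'
#' Counterpart of [write_reference()]; the annotation TSV carries the
#' feature intervals plus the TSS offset and primer margin, and an optional
#' second TSV the engineered positions.
#'
#' @param fasta reference FASTA path.
#' @param features_tsv annotation TSV path.
#' @param engineered_tsv optional TSV with columns `pos`, `wt`,
#'   `engineered`.
#' @return a `locus_reference`.
#' @export
read_reference <- function(fasta, features_tsv, engineered_tsv = NULL) {
  dna <- Biostrings::readDNAStringSet(fasta)
  feats <- read.table(features_tsv, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  eng <- if (!is.null(engineered_tsv))
    read.table(engineered_tsv, header = TRUE, sep = "\t",
               colClasses = c("integer", "character", "character"))
  else NULL
  make_reference(sequence = as.character(dna[[1]]),
                 features = feats[, c("name", "start", "end", "strand")],
                 tss_offset = feats$tss_offset[1],
                 primer_margin = feats$primer_margin[1],
                 engineered = eng, id = names(dna)[1])
}

#' Simulate a full screen and write its inputs to disk
#'
#' Writes the reference (FASTA + annotation + engineered-position TSV),
#' three replicate FASTQ pairs per condition (unselected "WT" and selected),
#' per-sample truth tables of planted mutations, and a manifest echoing all
#' parameters and per-replicate seeds. Deterministic for a fixed seed.
#'
#' @param outdir output directory (created if missing).
#' @param ref a `locus_reference`.
#' @param n_clones clones per replicate pool.
#' @param n_replicates replicates per condition.
#' @param seed master seed; replicate seeds derive from it.
#' @param mu,kappa,delta,seq_error,escape,suppressors,read_length,
#'   mean_reads_per_clone simulator parameters, see [sim_config()].
#' @return invisibly, the manifest list (also written as manifest.yaml).
#' @export
run_simulate <- function(outdir, ref = example_locus(), n_clones = 2000L,
                         n_replicates = 3L, seed = 1L,
                         mu = 0.00168, kappa = 4, delta = 0.04,
                         seq_error = 0.001, escape = 0,
                         suppressors = example_suppressors(),
                         read_length = 250L, mean_reads_per_clone = 1) {
  if (n_clones <= 0) stop("n_clones must be > 0")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_reference(ref, file.path(outdir, "reference.fasta"),
                  file.path(outdir, "features.tsv"))
  if (!is.null(ref$engineered))
    write.table(ref$engineered, file.path(outdir, "engineered.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  samples <- list()
  for (cond in c("unselected", "selected")) {
    cname <- if (cond == "unselected") "WT" else "selected"
    for (r in seq_len(n_replicates)) {
      rseed <- (seed + 1000L * r + ifelse(cond == "selected", 500L, 0L)) %%
        .Machine$integer.max
      cfg <- sim_config(mu = mu, kappa = kappa, delta = delta,
                        suppressors = suppressors, condition = cond,
                        n_clones = n_clones, read_length = read_length,
                        seq_error = seq_error, seed = rseed,
                        escape = escape,
                        mean_reads_per_clone = mean_reads_per_clone)
      pool <- mutagenize_pool(ref, cfg)
      surv <- apply_selection(pool, cfg, ref)
      sid <- paste0(cname, "_", r)
      rd <- sequence_reads(surv, cfg, sample_id = sid)
      f1 <- file.path(outdir, paste0(sid, "_R1.fastq"))
      f2 <- file.path(outdir, paste0(sid, "_R2.fastq"))
      write_fastq(rd$fwd, f1)
      write_fastq(rd$rev, f2)
      write_tsv(surv$truth[, c("clone_id", "pos", "ref", "alt", "kind")],
                file.path(outdir, paste0(sid, "_truth.tsv")))
      samples[[sid]] <- list(name = sid, condition = cname,
                             fastq1 = f1, fastq2 = f2, seed = rseed,
                             n_clones = n_clones,
                             n_survivors = length(surv$clone_id))
    }
  }
  manifest <- list(seed = seed, mu = mu, kappa = kappa, delta = delta,
                   seq_error = seq_error, escape = escape,
                   read_length = read_length, n_clones = n_clones,
                   suppressors = suppressors$pos, samples = samples)
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}

#' Run the analysis pipeline on a set of FASTQ samples
#'
#' Executes read preparation (3' trim, mean-quality filter, pair sync,
#' overlap merge), alignment and edit-structure classification, positional
#' and nucleotide-specific counting, negative-binomial Wald testing with
#' BH-FDR, TMM-normalised sample clustering, and the annotation report.
#' Selected-condition samples are aligned against the engineered reference.
#'
#' @param samples data.frame with columns `name`, `condition` ("WT" or
#'   "selected"), `fastq1`, `fastq2`.
#' @param ref a `locus_reference`.
#' @param outdir optional output directory for TSV/Newick artifacts.
#' @param trim_q,mean_q,min_overlap,min_frac,window,alpha stage thresholds.
#' @param scoring alignment scoring list.
#' @return list with `calls`, `counts_pos`, `counts_nt`, `enrich_pos`,
#'   `enrich_nt`, `histograms`, `tree`, `report`, `stats`.
#' @export
run_pipeline <- function(samples, ref, outdir = NULL,
                         trim_q = 28L, mean_q = 28, min_overlap = 30L,
                         min_frac = 0.6, window = 20L, alpha = 0.05,
                         scoring = list(match = 1, mismatch = -3,
                                        gap_open = -5, gap_ext = -2)) {
  stopifnot(all(c("name", "condition", "fastq1", "fastq2") %in%
                  names(samples)))
  miss <- c(samples$fastq1, samples$fastq2)
  miss <- miss[!file.exists(miss)]
  if (length(miss)) stop("missing input file(s): ",
                         paste(miss, collapse = ", "))
  ref_sel <- selected_reference(ref)
  calls <- list(); stats <- list(); hists <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$name[i]
    fwd <- read_fastq(samples$fastq1[i])
    rev <- read_fastq(samples$fastq2[i])
    if (!nrow(fwd) || !nrow(rev)) stop("empty FASTQ for sample ", sid)
    prep <- prep_sample(fwd, rev, trim_q, mean_q, min_overlap, min_frac)
    if (is.null(prep$merged) || !nrow(prep$merged))
      stop("no merged reads for sample ", sid)
    use_ref <- if (samples$condition[i] == "selected") ref_sel else ref
    cv <- call_variants(prep$merged, use_ref, scoring, window)
    calls[[sid]] <- cv
    stats[[sid]] <- c(prep$stats,
                      aligned = sum(cv$profiles$class != "unaligned"))
    hists[[sid]] <- mutation_histogram(cv, ref)
  }
  conditions <- samples$condition
  cp <- positional_counts(calls, ref, conditions)
  cn <- nucleotide_counts(calls, ref, conditions)
  ep <- nb_wald_test(cp, conditions, alpha = alpha)
  en <- nb_wald_test(cn, conditions, alpha = alpha)
  tree <- tryCatch(cluster_samples(tmm_log_matrix(cp)),
                   error = function(e) NULL)
  rep_tbl <- run_report(ep, ref, alpha = alpha)
  out <- list(calls = calls, counts_pos = cp, counts_nt = cn,
              enrich_pos = ep, enrich_nt = en,
              histograms = do.call(rbind, hists), tree = tree,
              report = rep_tbl, stats = do.call(rbind, stats))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(cp, file.path(outdir, "counts_positional.tsv"))
    write_tsv(cn, file.path(outdir, "counts_nucleotide.tsv"))
    write_tsv(ep, file.path(outdir, "enrichment_positional.tsv"))
    write_tsv(en, file.path(outdir, "enrichment_nucleotide.tsv"))
    write_tsv(data.frame(sample = rownames(out$histograms),
                         out$histograms, check.names = FALSE),
              file.path(outdir, "mutation_histograms.tsv"))
    write_tsv(rep_tbl$positions, file.path(outdir, "report_positions.tsv"))
    write_tsv(rep_tbl$densities, file.path(outdir, "report_densities.tsv"))
    if (!is.null(tree)) write_newick(tree, file.path(outdir, "samples.nwk"))
    write_tsv(data.frame(sample = rownames(out$stats), out$stats),
              file.path(outdir, "stage_counts.tsv"))
  }
  out
}

#' Annotation report: per-position table, densities, minimal motifs
#'
#' Maps a positional enrichment table onto the locus annotation: one row per
#' tested position with its log2 fold-change, adjusted p-value, region and
#' codon position, plus per-feature mutation densities and minimal motifs
#' for the promoter -10 box and SD features (when annotated).
#'
#' @param enrichment positional `enrichment_table`.
#' @param ref a `locus_reference`.
#' @param alpha significance threshold (padj).
#' @return list with `positions` (data.frame), `densities`, `motifs`.
#' @export
run_report <- function(enrichment, ref, alpha = 0.05) {
  pos <- suppressWarnings(as.integer(enrichment$unit))
  if (anyNA(pos))
    stop("enrichment table units are not positional coordinates")
  region <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(ref$features))) {
    fp <- feature_positions(ref$features[i, ])
    hit <- pos %in% fp & is.na(region)
    region[hit] <- ref$features$name[i]
  }
  positions <- data.frame(
    position = pos,
    log2fc = enrichment$log2FoldChange,
    pvalue = enrichment$pvalue,
    padj = enrichment$padj,
    significant = enrichment$significant,
    region = region,
    codon_position = codon_position(pos, ref))
  sig <- pos[!is.na(enrichment$padj) & enrichment$padj <= alpha &
               !is.na(enrichment$log2FoldChange) &
               enrichment$log2FoldChange > 0]
  densities <- mutation_density(sig, ref)
  motifs <- list()
  for (fn in intersect(c("minus10_box", "SD"), ref$features$name))
    motifs[[fn]] <- minimal_motif(fn, sig, ref)
  list(positions = positions, densities = densities, motifs = motifs,
       significant_positions = sig)
}
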