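---
title: "toxscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{toxscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A saturation-mutagenesis suppressor screen on a type I toxin–antitoxin
locus works by brute force: a PCR-mutagenized amplicon library is
transformed into cells whose antitoxin has been inactivated, so that only
clones carrying a mutation that abolishes toxin activity or expression
survive. Deep sequencing of the surviving pool, against an unselected
control pool, turns survival into counts: positions where substitutions are
statistically enriched in the selected condition are suppressor positions,
and their distribution over the locus maps the toxin's functional elements
(promoter −10 box, Shine–Dalgarno sequence, start codon, coding positions,
UTR structure) at single-nucleotide resolution.

`toxscreen` implements that analysis end to end — raw overlapping
paired-end reads to significant positions, minimal functional motifs,
per-region mutation densities and replicate clustering — together with a
synthetic clone-pool generator so every stage is testable without any
external data.

## The generative model

The simulator (`sim_config()`, `mutagenize_pool()`, `apply_selection()`,
`sequence_reads()`) emulates:

* **PCR mutagenesis.** Independent per-base mutation events at rate `mu`,
  so per-clone mutation counts are Binomial(L, `mu`). The default
  `mu = 0.00168` makes roughly 51% of clones carry at least one mutation on
  the 426-nt default amplicon — the mutation load a heavily cycled
  high-fidelity amplification produces in this type of screen. A fraction
  `delta = 0.04` of events are single-base indels; substitutions favour the
  transition with weight `kappa = 4` against 1 per transversion, the
  familiar PCR bias.
* **Lethal selection.** A clone survives iff one of its mutations matches
  the planted suppressor set (position, and base unless "ANY"). An optional
  `escape` probability lets mutated clones without a planted suppressor
  survive anyway; unmutated clones never survive. This models leaky
  toxicity and revertants, and it is statistically essential: under
  perfectly strict selection the selected libraries contain *only*
  suppressor reads, every commonly observed count unit is differential,
  and median-of-ratios normalisation has nothing non-differential to
  anchor on. With escape rate $\varepsilon$ the effective enrichment of a
  planted position after depth normalisation is approximately
  $L(1+\varepsilon) / (k(1+\varepsilon) + (L-k)\varepsilon)$ for $k$
  planted positions on an $L$-position amplicon; $\varepsilon = 0.09$
  yields ≈8-fold at the default geometry ($k=20$, $L=426$), which is the
  regime the package's recovery tests run in.
* **Sequencing.** Forward read = first `read_length` bases, reverse read =
  reverse complement of the last `read_length` bases (2×250 over 426 nt:
  74 nt of overlap). Per-base substitution errors at `seq_error`;
  qualities are constant at Phred −10·log10(`seq_error`). The default is
  `seq_error = 0.001` (Phred 30). A much-quoted "apparent error" figure
  for such screens is ~1.5%, but a constant-quality read at Phred 18
  would be discarded wholesale by the mean-quality-28 filter this very
  pipeline applies, and a 1.5%/base rate is incompatible with the observed
  predominance of single-mutation reads; we therefore treat ~1.5% as an
  apparent, aggregate figure and simulate at the post-filter base error
  rate a MiSeq actually delivers.

What the generator does **not** model: chimeric reads, per-cycle quality
profiles, multi-base indels, insert-size variation. Passing tests on
simulated pools therefore demonstrate correctness of the statistical
machinery under the screen's idealised assumptions, not robustness to
every artifact of real libraries.

### The fast observation path

Building and re-aligning $10^5$ full-length reads per replicate is wasted
work when the reads are generated from known clones. `tally_truth_profiles()`
produces, at the event level, exactly what error-free merging plus
alignment would report (true mutations plus sequencing-error
substitutions, including the rare reversion of a true substitution), in
the same `variant_calls` structure as the read-level path. Pool-scale runs
(the recovery analyses at $10^5$ clones per replicate) use this path; the
read-level path (FASTQ → trim → filter → merge → align) is exercised
end-to-end at hundreds of clones, where the two paths are tested to agree
exactly when `seq_error = 0`.

## Read preparation

* **3' trimming** uses the partial-sum rule: running sums of
  (threshold − q) from the 3' end, cut at the positive maximum
  (threshold 28). Retained bases are always an untouched prefix.
* **Mean-quality filter** discards reads with mean Phred *lower than* 28 —
  a mean of exactly 28 passes. Reads trimmed to length 0 fail the filter
  (the natural reading; the alternative of dropping them earlier changes
  nothing downstream since they cannot merge).
* **Pair synchronisation** keeps exactly the pairs whose both mates
  survived, in first-mate order.
* **Merging** reverse-complements the reverse mate, scores every overlap
  of ≥30 nt by match fraction, takes the best (ties → longest overlap),
  and rejects pairs below 0.6 match fraction. In the overlap, agreeing
  columns get summed Phreds (capped at 93); disagreements keep the
  higher-Phred base, forward mate winning exact ties. This replaces a
  probabilistic assembler's posterior scoring with a deterministic rule
  that is equivalent on high-quality data and exactly testable. N bases
  match nothing and carry Phred 0.

## Alignment and read classification

Merged reads are aligned end-to-end to the amplicon with affine gap
scoring (+1 match, −3 mismatch, gap of length k costs 5 + 2k), in compiled
code. Global rather than local alignment is deliberate: the amplicon is
fixed-length and primer-anchored, and the analysis keys on full-length
classes, which soft-clipping would blur. Tie-breaking is deterministic —
mismatch preferred over gap, gaps leftmost on the reference — and only
matters in pathological equal-score cases. Reads whose length deviates
from the reference by more than 20 nt are not aligned (`unaligned`).

Classes follow the edit structure: `zero` (length L, no edits),
`single_sub` (length L, one mismatch), `single_del`/`single_ins`
(length L∓1, one 1-base gap), `multi` (everything else, including any
read mixing a substitution with an indel, and multi-base gaps counted
per base). Event positions are kept 1-based on the amplicon internally
and converted to TSS-relative coordinates (+1 at the TSS, no zero) only
for reporting.

## Counting and the enrichment test

The **positional** matrix counts single-substitution reads per position
(any alternative base); the **nucleotide-specific** matrix counts per
(position, alternative base). Four primer-derived positions at each
extremity are excluded. For the nucleotide-specific analysis, reads with
a substitution at an engineered (construct-defining) position are removed
from *all* samples and unit keys are expressed against the wild-type base,
so the two conditions — sequenced against different construct references —
share one key space. Single-indel reads can be tallied positionally with
the same machinery.

The differential test is a from-scratch implementation of the standard
negative-binomial count model:

1. size factors by median-of-ratios (fallback to total-count with a
   warning when no unit is positive everywhere);
2. per-unit method-of-moments dispersions from pooled within-condition
   variances of normalised counts;
3. a mean–dispersion trend $\alpha(\bar\mu) = a_1/\bar\mu + a_0$ fitted by
   iterated gamma regression with outlier exclusion;
4. per-unit log-dispersion shrinkage: maximise the Cox–Reid-adjusted NB
   likelihood plus a normal prior (sd 0.5) centred on the trend;
5. an NB log-linear GLM (intercept + condition, size-factor offsets) at
   the final dispersion; Wald statistic for the condition coefficient
   against a standard normal; `log2FoldChange` = coefficient / ln 2;
6. Benjamini–Hochberg adjustment (NAs pass through and do not count
   toward m); significance at padj ≤ 0.05, the "equal or lower than 5%"
   reading.

Independent filtering and fold-change shrinkage are deliberately absent:
the unit count is small (hundreds, not tens of thousands) and raw per-
position log2 ratios are the quantity of interest. Units observed in only
one condition still enter the model — enrichment from zero is the expected
suppressor signature, though the Wald test is conservative under complete
separation. All-zero units get NA p-values. Under null simulations (2000
units, NB mean 200, dispersion 0.05, 3+3) the observed type-I error at
p < 0.05 is ≈0.05, which the acceptance suite checks at ±0.02.

Sample clustering uses TMM scaling factors (30% M-trim, 5% A-trim,
upper-quartile reference), log2 counts-per-million with pseudocount 1
(the constant amplicon-length term of an FPKM folds into the row
centring), row median-centring, 1 − Pearson distance and average linkage,
with no significance filter so all positions contribute.

## Annotation

* **Densities**: significant positions in a feature divided by feature
  length.
* **Minimal motifs**: a position where suppressors are selectable is
  essential, so the minimal functional motif keeps the wild-type base at
  significant positions and masks the rest with N (e.g. a 6-nt −10 box
  TAGGAT with positions 1, 2 and 6 significant gives TANNNT).
* **Codon position**: ((pos − orf_start) mod 3) + 1 inside the ORF.
* **Covariation**: for each base pair of a dot-bracket structure over an
  alignment, non-reference rows are classified conserved / consistent
  (one change, still canonical, G·U counted) / compensatory (two changes,
  still canonical) / disrupting; gapped rows are excluded per pair. The
  published arc-plot tool's internal score formula is not public, so the
  reported score is defined here as the compensatory fraction among
  non-conserved rows — documented and testable.

"Significant position" defaults to the positional analysis at
padj ≤ 0.05 with positive log2 fold-change; the union with
nucleotide-specific hits is available by passing those positions
explicitly.

## Numerical and scale choices

* Recovery analyses run at $10^5$ clones per replicate with the planted
  20-suppressor set and escape 0.09 (the ≈8-fold regime above); the
  count-level recovery simulation uses 400 units, NB mean 200, dispersion
  0.05, 20 planted units at 8-fold, 50 seeds. Read-level end-to-end tests
  run at hundreds of clones on a 60-nt mini-locus (50-nt reads, 40-nt
  overlap) and at 400 clones on the full 426-nt locus.
* Alignment oracle equivalence is checked on random pairs ≤30 nt against
  a brute-force three-state DP written independently in R.
* Dispersion optimisation is bounded on log α ∈ [log 1e−8, log 100];
  gamma trend fits fall back to the median positive dispersion when they
  cannot converge.
* All randomness flows from explicit integer seeds; fixed seeds give
  byte-identical FASTQ output.

## Known limitations

* The Wald test loses power (rather than inflating error) under complete
  separation; a likelihood-ratio option is out of scope.
* Dispersion-estimation internals of established count-model packages
  differ in detail; agreement is close (the test suite cross-checks size
  factors and fold-changes against one) but not bit-exact.
* The simulator's constant-quality model cannot represent within-read
  quality decay, so trimming is only lightly exercised by simulation and
  is instead tested directly on constructed reads.
* Indel placement in repeat runs is reported leftmost; a planted indel
  inside a homopolymer may legitimately surface at a shifted coordinate.
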