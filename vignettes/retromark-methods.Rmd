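---
title: "Transposon expression as a readout of intron retention and readthrough: models and design"
author: "retromark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{retromark methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Locus-level RNA-seq quantification of transposable elements (TEs) in
aging and senescence datasets shows a broad increase across all major
families (LINE, SINE, LTR, DNA). Because roughly 60 % of annotated TEs
lie inside genes (most of those inside introns) and another ~10 % sit
within 5 kb of a gene, the bulk of that signal is plausibly carried by
host transcription rather than by autonomous TE promoters. Two
age-associated defects produce exactly this kind of passenger signal:

* **Intron retention (IR)** — unspliced introns carry their resident TEs
  into the mature RNA pool.
* **Transcriptional readthrough** — termination failure extends
  transcription tens of kb past the polyadenylation site, transcribing
  downstream TEs with a distance-decaying intensity.

`retromark` quantifies both defects and their TE passengers per sample,
asks how much TE variation they explain, and then turns the logic around:
TE loci whose expression change exceeds what their neighborhood predicts
are candidates for autonomous activity, and LINE-1 loci with a functional
promoter or intact ORF1p/ORF2p coding capacity should be enriched among
them.

# Genomic model

## Coordinates and containers

All interval work uses `GenomicRanges` (1-based, closed — the
Bioconductor convention). GTF input/output is 1-based closed, BED
input/output 0-based half-open; conversions happen only at the I/O
boundary, so bin edges, distances and round-trips are exact regardless of
dialect.

## Context classification

A TE locus is *genic* on ≥ 1 bp overlap with any gene; *intronic* if
additionally ≥ 50 % of its length lies inside a single intron (threshold
configurable; the 50 % default avoids labelling exon-edge overlaps as
intronic). Extragenic loci are labelled by edge-to-edge distance to the
nearest gene — within 5 kb, within 100 kb, else intergenic — with
downstream/upstream taken from the nearest gene's strand (unstranded
genes are treated as `+`). Ties are resolved deterministically: nearest
gene by smallest distance then lexicographic id; overlapping several
genes, the one with the greatest overlap. Each locus gets exactly one
label, so the reported fractions (with intronic folded into genic)
partition to 1; a locus close to two genes is counted once, for its
nearest one.

## Readthrough and read-in regions

Readthrough candidate regions derive from the *longest transcript* of
each gene, so that differential 3′-UTR usage cannot masquerade as
readthrough. Ten 10-kb bins tile 0–100 kb past the 3′ end (read-in: before
the 5′ end), strand-aware. A bin is usable only if the nearest neighboring
gene on that side is at least 20 kb away (configurable `isolation_bp`)
and the bin overlaps no gene; bins truncated by a chromosome edge are
dropped. Bin 1 (10–20 kb) is the per-sample statistic — far enough to
avoid 3′-UTR ambiguity, close enough to retain signal under the observed
exponential decay — and all ten bins feed the decay profile. Regions with
mean count below 1 across samples are excluded (the low-coverage
exclusion has no published numeric cutoff; 1 is deliberately mild and
configurable).

# Per-sample statistics

Counts are scaled by median-of-ratios size factors (renormalized to
geometric mean 1). Element counts are divided by their nearest gene's
counts with a pseudocount of 1 in numerator and denominator — the
pseudocount guards sparse elements and makes the degenerate 0/0 case an
uninformative 1. The per-sample class score is the mean log2 of these
ratios over the top-1000 overexpressed elements of the class (ranked by
BH-adjusted p, then |lfc|, then id; "overexpressed" restricts to positive
fold change before ranking). Log base 2 is used everywhere. The
readthrough score aggregates counts-per-kb densities across the filtered
gene set before taking the log2 ratio (robust to zero-count genes);
per-gene ratios are also emitted for locus-level analyses, with an
epsilon of 1e-6 guarding empty numerators.

# Differential expression

The pipeline's DE statistic is ordinary least squares on
`log2(size-factor-normalized count + 1)` with the condition (two-group,
or continuous age centered and scaled so the coefficient reads as fold
change per SD) plus categorical covariates; p-values from the coefficient
t-statistic, BH adjustment within each feature class. This is a
deliberate simplification relative to negative-binomial engines: absolute
p-values differ, but the ranking and the correlational structure the
pipeline consumes are preserved, and the statistic is exactly
reproducible from the definition. Numerically perfect fits (zero residual
variance) collapse to p = 0 or 1 by the coefficient rather than dividing
by a zero standard error. Rank-deficient designs are rejected naming the
collinear columns.

The "higher-than-expected" outlier definition is operationalized as the
residual from OLS of TE fold change on nearest-gene fold change
(intercept included), taking the 250 most positive residuals among TEs
with unadjusted p < 0.05. The unadjusted gate follows the figure this
reproduces; everywhere else adjusted p-values are used. Enrichment of
flagged (promoter-active or ORF-coding) LINE-1s uses a one-sided Fisher
exact test (greater), the natural test for a directional enrichment
hypothesis, against the "all expressed" background — LINE-1s passing the
low-count filter (count ≥ 5 in ≥ 25 % of samples, configurable).

# Correlation analyses

Pearson is the default estimator (Spearman available). The partial
correlation uses the closed form
`r_xy·z = (r_xy − r_xz r_yz) / sqrt((1 − r_xz²)(1 − r_yz²))` with a
t-test on n − 3 df; the nested-model comparison fits `y ~ x1` and
`y ~ x1 + x2` and reports `F = (RSS_r − RSS_f) / (RSS_f / (n − 3))`,
which is algebraically the squared t of x2's coefficient — the test suite
asserts that identity to 1e-10. Each class's score uses its own top-1000
set; the three variables entering the partial correlation are therefore
computed from disjoint element sets.

# LINE-1 coding potential

ORFs are called as maximal ATG-to-stop stretches in the three frames of
the annotated strand (LINE-1 ORFs are sense-strand; a both-strands switch
exists). Within a frame, each inter-stop segment contributes at most one
ORF, starting at its first ATG; codons containing N never start or stop
and translate to X. Candidates longer than 900 nt (ORF1p) or 3400 nt
(ORF2p) are globally aligned (Needleman–Wunsch, BLOSUM62, gap open 11 /
extend 1 — standard protein-alignment defaults, configurable) to the
reference proteins, candidates closest in length to the reference first.
Significance is a permutation p-value over 200 composition-preserving
shuffles of the query: `p = (1 + #{shuffle ≥ observed}) / (n + 1)`, seeded
and bounded below by 1/201, so "p < 0.05" is a well-defined, self-contained
gate. "High sequence similarity" is operationalized solely as this gate —
no additional identity cutoff. Promoter-activity flags are merged from a
user-supplied BED by 50 % reciprocal overlap.

The ORF1p/ORF2p references are supplied by the user as FASTA (UniProt
Q9UN81 and O00370 for human data). The synthetic generator writes its own
randomly generated reference proteins (`orf_refs_synthetic.fasta`,
labelled synthetic) and plants their back-translated coding sequences
into a subset of elements, so the whole detection path is testable
offline.

# The synthetic-data generator

The generator emulates the structure the analysis assumes, with exact
ground-truth labels:

* **Genome layout.** Genes (default 60, two chromosomes) sit in 300-kb
  slots so that every context band up to 100 kb is geometrically
  unambiguous — the intended label of each placed TE is provably the true
  one, which is what makes the classification test exact. Each gene has
  4–7 exons (150–400 bp) and introns of 1.5–4 kb, and two transcripts
  (the full chain plus a shorter isoform) to exercise longest-transcript
  selection. A configurable fraction of genes (default 10 %) receives a
  blocker gene 10 kb downstream so the isolation filter has real work.
* **TE placement.** 2,000 loci by default, drawn from the mixture 60 %
  genic (80 % of those intronic), 5 % + 5 % within 5 kb, 10 % + 10 %
  within 100 kb, 10 % intergenic — the desk-scale analogue of the
  annotation-wide census. Intronic placements keep 500 bp clear of both
  splice junctions, emulating the observed junction-proximal depletion.
  Forty full-length (6 kb) LINE-1s are placed in roomy contexts; twelve
  carry planted ORF1p coding sequences (every second one also ORF2p), and
  60 % of full-length elements (coding ones always) are flagged
  promoter-active.
* **Counts.** Gene means are log-normal(5, 2) — a realistic 4–5 orders of
  magnitude of expression, which matters because only TEs downstream of
  well-expressed genes acquire informative readthrough counts. With
  condition `c_s` in [0, 1] (age/96, or 0/1 senescence), library factor
  `L_s`, and negative-binomial dispersion 0.1:
  * genes: `NB(mu_g L_s)`
  * introns: `NB(mu_g · 0.05 · exp(beta_IR c_s + eta_IR,s) · L_s)`
  * readthrough bin k: `NB(mu_g · 0.03 · exp(−0.5 k) ·
    exp(beta_RT c_s + eta_RT,s) · L_s)`; read-in mirrored with its own
    effect (0 in aging, positive in senescence)
  * TEs: the host component share — gene body, host intron, or distance
    bin, scaled by overlap length over host length — plus a per-element
    background drawn log-normal (median 0.2, log-SD 1.5; pervasive
    transcription and mapping noise, whose expressed tail populates the
    "all expressed" universe the enrichment background needs, while
    staying quieter than the readthrough signal it would otherwise
    drown) plus, for promoter-active LINE-1s, an autonomous term
    `NB(30 · exp(beta_L1 c_s) · L_s)`.
* **Per-sample random effects.** `eta_IR,s` and `eta_RT,s` (SD 0.25) model
  sample-to-sample variability in splicing fidelity and termination
  beyond the condition, shared between each defect and its TE passengers.
  Without them the two defect scores would be deterministic functions of
  the same condition and the partial-correlation / nested-model analyses
  would be degenerate by construction; with them, the readthrough
  association carries sample-specific information that survives
  correction for intron retention — the property the real analysis
  exploits.
* **Effects.** Defaults: `beta_IR = 1.5`; `beta_RT = 1.75` (aging) or 2
  (senescence); `beta_L1 = 0` in aging and 2 in senescence — autonomous
  LINE-1 activation is a senescence phenomenon in this model, so the
  aging preset shows no enrichment of active elements among outliers
  while the senescence preset does. The effect sizes are chosen so that,
  at the study scale of 60 samples, injected effects are recovered as
  score–condition correlations above 0.7 — the generator's design
  specification — while remaining within the plausible 2–7-fold range.

Everything derives from one seed; identical seeds give byte-identical
files and count matrices.

## What the generator does not emulate

No read-level simulation (no FASTQ, no alignment ambiguity, no EM
multimapper assignment — synthetic counts are unambiguous), no GC or
mappability bias, no isoform switching, no correlated placement of TE
families, no assembly gaps (the shuffle control therefore does not avoid
N-runs; an exclude-BED hook exists). Passing tests demonstrate that the
statistics recover the structure they target under this model — not that
any particular real dataset satisfies the model.

# Problem sizes and numerical choices in the test suite

The suite runs the classification ground-truth check at 10,000 loci, the
DE null calibration on ~2,600 filtered null features across classes (120
genes, 5,000 TEs, all effects zero), effect recovery over 20 seeds at 60
samples, enrichment recovery over 20 seeds at the default senescence
scale, ORF brute-force equality on 100 random 3-kb sequences, and
classifier specificity on 40 random 6-kb elements. These sizes were
chosen as the smallest at which each property is statistically decisive.
Fixed seeds make every stochastic assertion reproducible; tolerance
choices (1e-10 for the F/t identity, 1e-12 for closed forms, binomial
3-SE bands for fractions) reflect machine precision versus sampling
noise.

# Known limitations

* The OLS DE statistic understates dispersion for low counts relative to
  negative-binomial models; it is meant for ranking and correlation, not
  for calibrated per-feature inference on real data.
* The outlier definition (regression residual) and the permutation
  alignment p-value are this package's concrete operationalizations of
  qualitative published descriptions; both are documented knobs.
* Ambiguity between a TE downstream of one gene and upstream of another
  is resolved by the nearest-gene rule; on real, dense annotations a
  small fraction of labels will be genuinely ambiguous.
* `junction_density_profile` and `shuffle_loci` treat each sequence name
  independently; no liftover or alt-contig logic.
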