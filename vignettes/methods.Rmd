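---
title: "lincCNV: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lincCNV: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincCNV)
```

# The problem

High-density SNP arrays measure, per probe, a total-intensity dosage
signal (log R ratio, LRR) and an allelic composition signal (B-allele
frequency, BAF). In a matched tumor-normal design, subtracting each
tumor's LRR by its own normal removes germline copy-number variants and
shared technical waves, leaving somatic dosage change. `lincCNV` turns
these paired signals into classified aberration segments, asks which
long intergenic non-coding RNAs (lincRNAs) they hit, and splits every
aberration's footprint into genic, lincRNA and remaining intergenic
base pairs for cohort-level inference.

# Signal model

For a segment of total tumor copy number $C$ in a tumor of purity
$\rho$ (fraction of tumor cells in the specimen), the expected paired
LRR is

$$\mathrm{LRR} = \log_2 \frac{(1-\rho)\,2 + \rho\, C}{2},$$

and at a SNP with $g \in \{0,1,2\}$ B alleles in the germline and $b$
B alleles in the tumor segment,

$$\mathrm{BAF} = \frac{(1-\rho)\,g + \rho\, b}{(1-\rho)\,2 + \rho\, C}.$$

At full purity a heterozygous loss sits at LRR $-1$, a one-copy gain at
$+0.585$, and copy-neutral LOH leaves LRR at 0 while driving BAF at
heterozygous sites to 0 or 1. Homozygous deletions would push LRR to
$-\infty$; real scanners have a dynamic range, modeled as a
configurable floor (default $-2$).

Allelic imbalance is summarized by the *mirrored BAF deviation*:
$\mathrm{mean}\,|\mathrm{BAF} - 0.5|$ over probes heterozygous (AB) in
the matched normal — 0 under balance, approaching 0.5 under complete
LOH. Only normal-heterozygous probes are informative; a segment with no
such probes is classified on LRR alone.

# Conditioning steps

* **Filtering.** chrY probes are dropped (female analysis genome) and
  probes whose normal-sample genotype call failed (NC) are removed; the
  operation is idempotent and order-preserving.
* **Replicates.** Replicate arrays are combined by per-probe arithmetic
  means of LRR and BAF. Genotype disagreements between replicates
  become NC (and fall to the filter) — the conservative choice, since a
  germline call that flips between replicates is not trustworthy.
* **GC wave.** Arrays show a smooth wave correlated with regional GC
  content. The correction fits a line of LRR on the stored per-probe GC
  covariate and subtracts `b * (gc - mean(gc))`, preserving the grand
  mean of LRR exactly. The slope is estimated only on dosage-typical
  probes (LRR within 3 robust standard deviations of the median):
  planted experiments showed that when events cover ~20% of a
  chromosome, a plain least-squares slope absorbs event signal and
  biases corrected paired LRR by ~0.1 in a position-dependent way —
  enough to push borderline single-copy losses past the homozygous
  threshold. Each sample is corrected first and subtracted second (the
  order is not dictated by the data model; correcting first keeps the
  step usable for unpaired QC too).
* **Quality score.** The median absolute difference of
  consecutive-probe LRRs within chromosomes, divided by $\sqrt 2$ — a
  robust per-probe noise estimate that a genuine copy-number step
  barely moves. Lower is better; scores above a configurable 0.02
  gate trigger a warning, not a hard failure, because the gate is a
  vendor QC convention, not a property of this model.

# Segmentation and classification

Breakpoints are found per chromosome by recursive change-point search
with a pooled two-sample t statistic and stopping threshold `T`
(default 5). At each step two candidates are evaluated:

* the **best single split** (left vs right means), and
* the **best contiguous window** of `min_probes`..600 points
  (inside vs outside means).

The stronger candidate is accepted iff $|t| \ge T$, cuts are placed,
and the procedure recurses into the pieces. The window statistic is the
important design choice: a single-split statistic dilutes a short
interior event across half the chromosome — measured on planted data, a
20-probe deletion on a 4300-probe chromosome reaches only
$|t|\approx 2$ at the best split and is found in under 20% of runs,
while the window statistic compares the event against everything else
($|t|\approx 20$) and restores the intended ≥90% recovery for events
of 20–500 probes. Ties resolve to the smallest window, then the
leftmost position, so results are deterministic. Raising `T` can only
remove breakpoints (the recursion tree is data-determined; a higher
threshold only prunes it).

LRR is segmented over all probes; the mirrored BAF deviation is
segmented over the normal-heterozygous subset (breakpoints mapped back
to the full probe grid); the two breakpoint sets are unioned. Each
segment is classified with precedence homozygous loss > gain/loss >
allelic imbalance > neutral:

| class | rule (defaults) |
|---|---|
| homozygous_loss | mean paired LRR ≤ −1.1 |
| gain | mean paired LRR ≥ +0.25 |
| loss | mean paired LRR ≤ −0.25 |
| allelic_imbalance | \|mean LRR\| < 0.25 and BAF deviation ≥ 0.15 |
| neutral | otherwise |

Adjacent same-class segments are merged; non-neutral calls with fewer
than `min_call_probes` (default 5, tunable down to 2 for kb-scale
events) revert to neutral. The thresholds are configuration with
documented defaults — at full purity they sit several noise standard
errors from the expected levels; at purity 0.5 a heterozygous loss
shrinks to LRR $\log_2 0.75 \approx -0.415$ and the fixed cutoffs
degrade predictably (they are not re-estimated per sample).

Segment coordinates come from probe positions. Interior segment
boundaries are placed at the next segment's first probe so that the
segments of a chromosome tile `[first probe, last probe + 1)` without
gaps; only the terminal segment ends at its last probe + 1. A documented
consequence is that a call's bp length extends to the next informative
probe.

# Annotation and compartments

All interval logic is 0-based half-open (BED native; GTF converted on
read), strand-agnostic, and gene-level (a gene's footprint is the span
of its transcripts). The lincRNA reference keeps only candidates with
zero bp of coding overlap — abutting intervals share no base and are
kept. Dissection counts genic bp against the merged union of coding
intervals so no base is double counted; non-lincRNA-intergenic bp is
the exact remainder, so the three tallies always sum to the call
length (an integer identity, asserted at run time before any file is
written). Compartment genome totals exclude chrY. Aggregate frequency
tracks report, per fixed-size bin and per direction, the fraction of
samples with ≥1 bp of overlapping gain (respectively loss; homozygous
losses count as losses).

# Statistics

The Wilcoxon signed-rank test drops zero differences (Wilcoxon's
original rule), assigns average ranks to ties, and for n ≤ 25 computes
the exact null distribution of the positive-rank sum over all $2^n$
sign assignments via a subset-sum convolution on doubled ranks; the
two-tailed p-value is $\min(1,\, 2\min(P(W\le w), P(W\ge w)))$. Larger
n uses the tie-corrected normal approximation with continuity
correction; at the design's cohort size (7 pairs) the exact path always
applies. The fold comparison reports a ratio of means (not a mean of
ratios). Regression is ordinary least squares with
$R^2 = 1 - SS_{res}/SS_{tot}$.

# qPCR arithmetic

Standard curves regress Ct on $\log_{10}$ input over a six-point
serial dilution (64…0.0625 ng); efficiency is $10^{-1/slope} - 1$.
Unknowns are quantified by inverting the curve, replicate wells
averaged within (sample, assay, tissue, input level), and copy ratios
computed per reference as
$(T_{target}/T_{ref}) / (N_{target}/N_{ref})$, then averaged over the
two references (alpha-satellite, albumin) and the two gDNA input
levels, which are treated as independent replicate measurements. The
0.2 cutoff is read as a deviation from unity (loss ⇔ ratio < 0.8,
gain ⇔ ratio > 1.2): the literal reading (ratio < 0.2) could not call
a clonal heterozygous loss, whose expected ratio is 0.5. Both the
cutoff and the reading are configurable; per-reference concurrence is
reported alongside the averaged call. The $2^{-\Delta\Delta Ct}$
comparator is computed in parallel; at 100% efficiency and zero noise
the two routes agree to numerical precision.

# The synthetic generator: what it does and does not emulate

The generator stands in for unreleased primary-culture array data. It
emulates: exponential inter-probe gaps with configurable mean (default
700 bp), a female multi-chromosome toy genome (default three
chromosomes, 10–15 Mb), disjoint coding and strictly-intergenic lincRNA
tracks, per-sample germline genotypes (heterozygosity 0.3, no-call rate
0.002), planted events of every class with purity dilution, Gaussian
LRR/BAF noise, a sinusoidal GC-tracking wave, replicate arrays with
independent noise, and qPCR plates (standards, two input levels,
triplicates, Ct noise, censoring at 40 cycles for zero-dosage targets).
Defaults are stated conditions, not claims about the original assay:
the source study reports neither its noise magnitude nor specimen
purity, so LRR sd 0.15, BAF sd 0.03 and purity 1.0 (primary cultures
are enriched epithelium) are configuration. Not emulated: raw two-color
intensities, cluster-file genotyping, batch effects beyond the GC wave,
subclonal mixtures, linkage between neighboring SNP genotypes, and the
real probe manifest. A green recovery test therefore establishes that
the pipeline inverts *this* signal model at desk scale — not that it
reproduces any published call set.

# Numerical choices and degenerate inputs

* Cancellation guard: mean differences below `1e-8 * max|x|` are
  treated as zero in t statistics, so a numerically constant signal
  can never produce an infinite t from an underflowing pooled variance.
* Deterministic tie-breaks everywhere (leftmost split, smallest
  window); all simulation stages derive independent RNG streams from
  one seed and restore the caller's RNG state.
* Zero total CNV bp in a sample → compartment shares are reported
  absent (NA), never 0/0.
* All differences zero → the signed-rank test refuses loudly; constant
  x → regression refuses; constant GC → correction skipped with a
  warning; A+B = 0 → BAF refuses (uncallable probe); nonpositive
  intensities or quantities refuse.
* BAF is clipped to [0, 1] at generation; with zero tumor DNA content
  (homozygous loss at purity 1) BAF carries no information and is drawn
  uniformly.

# Known limitations

Integer copy number and purity/ploidy are not estimated; breakpoints
are probe-resolution (allelic-imbalance boundaries are additionally
limited to heterozygous-probe resolution, about `1/het_rate` probes);
events shorter than `min_call_probes` are invisible by design; the
fixed LRR thresholds assume near-clonal events; and LOH co-occurring
with loss is reported as a loss (the dosage change wins), with the BAF
deviation still visible on the call record.
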