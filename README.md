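# lincCNV

Copy-number analysis of long intergenic non-coding RNA (lincRNA) loci
from paired tumor-normal SNP-array signals.

Most cancer copy-number studies annotate aberrations against
protein-coding genes. lincRNAs live in the intergenic space that
high-density SNP arrays (~700 bp mean marker spacing) cover well, yet
they are rarely treated as first-class annotation. `lincCNV` implements
the full analysis path for asking *which lincRNAs are hit by somatic
copy-number change, and how much of the aberration burden falls on them*:

1. **Signal model.** Per-probe log R ratio
   `LRR = log2(R_subject / R_expected)` (0 ≈ diploid) and B-allele
   frequency `BAF = B / (A + B)` (≈ 0 / 0.5 / 1 for AA/AB/BB).
   Probe filtering (chrY, no-call genotypes), replicate averaging,
   GC-wave removal by a linear fit of LRR on a per-probe GC covariate,
   and matched-pair adjustment (tumor LRR minus its own normal) to
   cancel germline structure.
2. **Segmentation and calling.** Recursive change-point segmentation of
   the paired LRR and of the mirrored BAF deviation
   `mean |BAF − 0.5|` over probes heterozygous in the normal, using a
   pooled two-sample t statistic with stopping threshold `T` (both the
   best single split and the best contiguous window are tested, so
   short interior events keep power). Segments are classified as
   **gain** (mean LRR ≥ 0.25), **loss** (≤ −0.25), **homozygous loss**
   (≤ −1.1), **allelic imbalance / LOH** (|LRR| < 0.25 and BAF
   deviation ≥ 0.15) or neutral.
3. **lincRNA annotation.** An intergenic-only lincRNA reference
   (candidates overlapping any coding gene are dropped, half-open
   coordinates), call-gene associations with overlap bp and percent of
   gene length, and dissection of every call into genic / lincRNA /
   non-lincRNA-intergenic base pairs (the three tallies sum exactly to
   the call length).
4. **Cohort statistics.** Per-sample compartment shares, exact
   two-tailed Wilcoxon signed-rank test (full 2^n enumeration for
   n ≤ 25), genic/lincRNA fold ratio, OLS regression with R², and
   Circos-format `chrom start end frequency` tracks of per-bin gain and
   loss frequencies.
5. **qPCR validation arithmetic.** Standard curves (Ct vs
   log10 input; efficiency `10^(−1/slope) − 1`), quantification,
   dual-reference (alpha-satellite + albumin) tumor/normal copy ratios
   with a deviation-from-unity cutoff of 0.2, and the `2^−ΔΔCt`
   comparator.
6. **Synthetic cohorts.** A generator that emulates the array design —
   exponential probe spacing, planted gains / losses / homozygous
   losses / copy-neutral LOH with configurable tumor purity, Gaussian
   LRR/BAF noise, a GC-tracking wave, replicate arrays and qPCR Ct
   tables — with the planted truth retained for parameter-recovery
   tests.

## Worked example

```r
library(lincCNV)
cfg <- pipeline_config(out_dir = file.path(tempdir(), "demo"),
  sim = list(seed = 42, n_pairs = 3,
             chrom_lengths = c(chr1 = 5e6, chr2 = 4e6),
             n_coding = 25, n_lincrna = 12))
res <- run_all(cfg)
```

The run logs each stage:

```
simulated 3 pairs, 12857 probes, 8 planted events -> /tmp/.../demo
S01: 12833/12857 probes retained, quality 0.0720, 6 segments, 2 CNV/LOH calls
S03: 12833/12857 probes retained, quality 0.0711, 10 segments, 4 CNV/LOH calls
8 non-neutral calls across 3 samples
6 lincRNA associations; genic/lincRNA fold 13.7
qPCR: 12 targets, 100.0% concordant with truth
```

`cnv_calls(res$segments)` lists the calls; planted states are recovered
with their expected paired-LRR levels (loss ≈ −1, gain ≈ +0.58,
homozygous loss ≈ −2, copy-neutral LOH ≈ 0 with BAF deviation ≈ 0.5):

```
  sample_id chrom   start     end n_probes mean_lrr             class
1       S01  chr1 2885198 2991467      148 -1.01030              loss
2       S01  chr2 2724899 2926421      309  0.57910              gain
3       S02  chr1 4013888 4345557      476  0.00425 allelic_imbalance
7       S03  chr2  452786  680403      307 -2.00631   homozygous_loss
```

`res$summary$associations` holds the lincRNA hits (overlap bp and % of
gene length), `res$summary$stats` the cohort inference (here Wilcoxon
W = 6, p = 0.25, genic-vs-lincRNA regression R² = 0.981), and
`res$qpcr` the per-target validation calls — e.g. a planted
heterozygous loss measured at ratio 0.516 (`2^−ΔΔCt` 0.505), called
`loss` under the 0.2 cutoff, 100% concordant with truth in this run.

A command-line wrapper is installed at `inst/cli/linccnv.R`
(`simulate | call | summarize | qpcr | all`).

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the signal
model and its assumptions, every tunable threshold with its default and
rationale, what the synthetic generator does and does not emulate, and
the numerical choices (tie-breaks, tolerances, degenerate inputs).
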