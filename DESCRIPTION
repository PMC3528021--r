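Package: lincCNV
Title: Paired Tumor-Normal SNP-Array Copy-Number Analysis of Intergenic
    lincRNA Loci
Version: 0.1.0
Authors@R:
    person("lincCNV", "Developers", email = "linccnv@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for discovering copy-number variation (CNV)
    and loss-of-heterozygosity (LOH) at long intergenic non-coding RNA
    (lincRNA) loci from paired tumor-normal SNP-array probe signals.
    Covers the log-R-ratio (LRR) and B-allele-frequency (BAF) signal
    model, probe filtering, replicate combining, GC-wave correction,
    matched-pair adjustment, recursive binary segmentation with
    t-statistic stopping, event classification (gain, loss, homozygous
    loss, allelic imbalance), construction of an intergenic-only lincRNA
    reference, dissection of aberrations into genic, lincRNA and
    non-lincRNA-intergenic compartments, cross-sample frequency
    aggregation in Circos text format, exact Wilcoxon signed-rank and
    linear-regression statistics, and qPCR standard-curve copy-number
    validation arithmetic.  A synthetic-data generator emulating
    high-density array signals with planted aberrations supports
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    tools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
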