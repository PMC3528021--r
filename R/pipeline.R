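#' Pipeline configuration
#'
#' One validated container for every tunable of the end-to-end pipeline.
#' Unknown keys are rejected (both here and when read from file), so a
#' typo in a threshold name fails loudly instead of silently using a
#' default.
#'
#' @param out_dir output directory for every stage.
#' @param sim named list forwarded to [sim_config()].
#' @param calling named list forwarded to [cnv_params()].
#' @param bin_size aggregation bin width (bp) for the Circos frequency
#'   tracks.
#' @param qpcr_cutoff deviation-from-unity cutoff for qPCR loss/gain
#'   calls.
#' @param quality_warn QC warning threshold for [quality_score()]
#'   (lower score = better quality).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = list(), calling = list(),
                            bin_size = 1e6, qpcr_cutoff = 0.2,
                            quality_warn = 0.02) {
  cfg <- list(out_dir = out_dir,
              sim = do.call(sim_config, sim),
              calling = do.call(cnv_params, calling),
              bin_size = bin_size, qpcr_cutoff = qpcr_cutoff,
              quality_warn = quality_warn)
  if (bin_size <= 0) stopf("bin_size must be > 0")
  if (qpcr_cutoff <= 0 || qpcr_cutoff >= 1) {
    stopf("qpcr_cutoff must lie in (0, 1)")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration file (JSON)
#'
#' @param path JSON file with optional keys `out_dir`, `sim`, `calling`,
#'   `bin_size`, `qpcr_cutoff`, `quality_warn`; unknown keys are
#'   rejected.
#' @param config a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("out_dir", "sim", "calling", "bin_size", "qpcr_cutoff",
             "quality_warn")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stopf("unknown configuration key(s): %s",
                             paste(unknown, collapse = ", "))
  if (is.null(raw$out_dir)) stopf("configuration must set out_dir")
  raw$sim <- as.list(raw$sim)
  raw$calling <- as.list(raw$calling)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  out <- list(out_dir = config$out_dir,
              sim = unclass(config$sim)[
                c("seed", "n_pairs", "spacing", "purity", "lrr_sd",
                  "baf_sd", "het_rate", "replicates")],
              calling = unclass(config$calling),
              bin_size = config$bin_size,
              qpcr_cutoff = config$qpcr_cutoff,
              quality_warn = config$quality_warn)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

log_msg <- function(fmt, ...) message(sprintf(fmt, ...))

#' Simulate a complete synthetic cohort to disk
#'
#' Generates the genome and annotation tracks, plants events, simulates
#' paired replicate arrays and qPCR tables, and writes everything plus a
#' JSON manifest under `out_dir`.  Reruns with the same seed are
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (invisibly).
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(file.path(out, "signals"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out)) stopf("cannot create output directory %s", out)
  sc <- config$sim
  world <- simulate_genome(sc)
  truth <- plant_events(sc, world$genome)
  truth <- annotate_truth_lincrnas(truth, world$lincrna)
  sig <- simulate_probe_signals(world$genome, truth, sc)
  qpcr <- simulate_qpcr(truth, sc)

  write_bed(world$coding, file.path(out, "coding.bed"))
  write_bed(world$lincrna, file.path(out, "lincrna.bed"))
  write_truth(truth, file.path(out, "truth.tsv"))
  write_ct_table(qpcr$ct, file.path(out, "qpcr_ct.tsv"))
  write_tsv(qpcr$truth, file.path(out, "qpcr_truth.tsv"))

  manifest <- list(genome = list(lengths = as.list(world$genome$lengths),
                                 female = world$genome$female),
                   seed = sc$seed, n_pairs = sc$n_pairs,
                   samples = list())
  for (s in names(sig$samples)) {
    files <- list(tumor = character(0), normal = character(0))
    for (tissue in c("tumor", "normal")) {
      reps <- sig$samples[[s]][[tissue]]
      for (r in seq_along(reps)) {
        f <- file.path("signals",
                       sprintf("%s_%s_rep%d.tsv", s, tissue, r))
        write_probe_signals(reps[[r]], file.path(out, f))
        files[[tissue]] <- c(files[[tissue]], f)
      }
    }
    manifest$samples[[s]] <- files
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("simulated %d pairs, %d probes, %d planted events -> %s",
          sc$n_pairs, nrow(sig$manifest), nrow(truth), out)
  invisible(manifest)
}

read_manifest <- function(out_dir) {
  path <- file.path(out_dir, "manifest.json")
  if (!file.exists(path)) stopf("no manifest.json under %s; run simulate first",
                                out_dir)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

manifest_genome <- function(manifest) {
  genome_model(unlist(manifest$genome$lengths),
               female = isTRUE(manifest$genome$female))
}

#' Call CNVs for every sample pair on disk
#'
#' Per sample: replicate combining, probe filtering (chrY; no-call
#' genotypes in the normal), per-sample GC correction, matched-pair
#' subtraction, segmentation and classification.  Writes one SEG-style
#' file per sample under `calls/` plus a combined `segments.tsv`, and
#' logs probe and call tallies stage by stage.
#'
#' @param config a [pipeline_config()] whose `out_dir` holds a simulated
#'   (or imported) cohort.
#' @return combined segment data.frame (invisibly).
#' @export
run_call <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  manifest <- read_manifest(out)
  dir.create(file.path(out, "calls"), showWarnings = FALSE)
  all_segs <- list()
  for (s in names(manifest$samples)) {
    files <- manifest$samples[[s]]
    if (is.null(files$tumor) || is.null(files$normal) ||
        !length(files$tumor) || !length(files$normal)) {
      stopf("sample %s is missing a pair member", s)
    }
    read_reps <- function(paths) lapply(file.path(out, paths),
                                        read_probe_signals)
    tumor <- combine_replicates(read_reps(unlist(files$tumor)))
    normal <- combine_replicates(read_reps(unlist(files$normal)))
    n0 <- nrow(normal)
    normal <- filter_probes(normal, drop_nc = TRUE)
    tumor <- filter_probes(tumor, drop_nc = FALSE)
    tumor <- tumor[tumor$probe_id %in% normal$probe_id, , drop = FALSE]
    normal <- normal[normal$probe_id %in% tumor$probe_id, , drop = FALSE]
    tumor <- gc_correct(tumor)
    normal <- gc_correct(normal)
    q <- quality_score(normal, warn_above = config$quality_warn)
    paired <- pair_adjust(tumor, normal)
    segs <- call_cnvs(paired, config$calling)
    segs$sample_id <- s
    n_calls <- sum(segs$class != "neutral")
    log_msg("%s: %d/%d probes retained, quality %.4f, %d segments, %d CNV/LOH calls",
            s, nrow(paired), n0, q, nrow(segs), n_calls)
    write_seg(segs, file.path(out, "calls", paste0(s, ".seg")))
    all_segs[[s]] <- segs
  }
  segs <- do.call(rbind, all_segs)
  rownames(segs) <- NULL
  write_seg(segs, file.path(out, "segments.tsv"))
  invisible(segs)
}

#' Summarize calls: lincRNA associations, compartments, statistics, Circos
#'
#' Builds the intergenic-only lincRNA reference, associates every
#' non-neutral call with the lincRNA genes it overlaps, dissects each
#' call into genic / lincRNA / non-lincRNA-intergenic base pairs
#' (asserting conservation before writing), computes per-sample and
#' cohort compartment percentages with the Wilcoxon signed-rank test,
#' fold ratio and genic-vs-lincRNA regression, and emits per-direction
#' Circos frequency tracks.
#'
#' @param config a [pipeline_config()].
#' @return list with `associations`, `compartments`, `stats` (invisibly).
#' @export
run_summarize <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  manifest <- read_manifest(out)
  genome <- manifest_genome(manifest)
  coding <- read_bed(file.path(out, "coding.bed"), name = "coding")
  linc_raw <- read_bed(file.path(out, "lincrna.bed"), name = "lincRNA")
  linc <- build_intergenic_lincrna_reference(linc_raw, coding)
  if (length(attr(linc, "dropped"))) {
    log_msg("dropped %d non-intergenic lincRNA candidate(s)",
            length(attr(linc, "dropped")))
  }
  segs <- read_seg(file.path(out, "segments.tsv"))
  calls <- cnv_calls(segs)
  log_msg("%d non-neutral calls across %d samples", nrow(calls),
          length(unique(segs$sample_id)))

  assoc <- intersect_calls_with_track(calls, linc)
  comp <- compartment_percentages(calls, coding, linc, genome,
                                  samples = sort(unique(segs$sample_id)))
  # conservation invariants, asserted before anything is written
  stopifnot(all(abs(comp$genic_bp + comp$lincrna_bp + comp$intergenic_bp -
                      comp$cnv_bp) == 0))
  shares <- comp$pct_of_cnv_genic + comp$pct_of_cnv_lincrna +
    comp$pct_of_cnv_intergenic
  stopifnot(all(is.na(shares) | abs(shares - 100) <= 1e-9))

  ok <- !is.na(comp$pct_of_cnv_genic)
  stats <- list(n_samples = nrow(comp), n_with_cnv = sum(ok))
  if (sum(ok) >= 3) {
    fr <- fold_ratio(comp$pct_of_cnv_genic[ok], comp$pct_of_cnv_lincrna[ok])
    wc <- tryCatch(wilcoxon_signed_rank(comp$pct_of_cnv_genic[ok] -
                                          comp$pct_of_cnv_lincrna[ok]),
                   error = function(e) NULL)
    lf <- tryCatch(linear_fit(comp$pct_of_cnv_genic[ok],
                              comp$pct_of_cnv_lincrna[ok]),
                   error = function(e) NULL)
    stats$fold_genic_vs_lincrna <- fr$ratio
    stats$wilcoxon_W <- wc$statistic %||% NA_real_
    stats$wilcoxon_p <- wc$p.value %||% NA_real_
    stats$regression_slope <- lf$slope %||% NA_real_
    stats$regression_intercept <- lf$intercept %||% NA_real_
    stats$regression_r_squared <- lf$r_squared %||% NA_real_
  }
  freq <- aggregate_frequencies(calls, genome,
                                n_samples = length(unique(segs$sample_id)),
                                bin_size = config$bin_size)
  write_tsv(assoc, file.path(out, "associations.tsv"))
  write_tsv(comp, file.path(out, "compartments.tsv"))
  write_tsv(data.frame(metric = names(unlist(stats)),
                       value = unlist(stats)),
            file.path(out, "stats_report.tsv"))
  write_circos(freq$gain, file.path(out, "circos_gains.txt"))
  write_circos(freq$loss, file.path(out, "circos_losses.txt"))
  log_msg("%d lincRNA associations; genic/lincRNA fold %.3g",
          nrow(assoc), stats$fold_genic_vs_lincrna %||% NA)
  invisible(list(associations = assoc, compartments = comp,
                 stats = stats, frequencies = freq))
}

#' Run the qPCR validation arithmetic on the cohort's Ct tables
#'
#' @param config a [pipeline_config()].
#' @return per-target results with truth comparison (invisibly); the
#'   fraction of truth-concordant calls is attached as attribute
#'   `concordance`.
#' @export
run_qpcr <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  ct <- read_ct_table(file.path(out, "qpcr_ct.tsv"))
  res <- analyze_qpcr(ct, cutoff = config$qpcr_cutoff)
  truth_path <- file.path(out, "qpcr_truth.tsv")
  if (file.exists(truth_path)) {
    tr <- read_tsv(truth_path)
    res <- merge(res, tr[, c("sample", "assay", "dosage_ratio", "class")],
                 by = c("sample", "assay"), suffixes = c("", "_truth"))
    expected <- ifelse(res$dosage_ratio < 1 - config$qpcr_cutoff, "loss",
                       ifelse(res$dosage_ratio > 1 + config$qpcr_cutoff,
                              "gain", "normal"))
    res$concordant <- res$class == expected
    attr(res, "concordance") <- mean(res$concordant)
    log_msg("qPCR: %d targets, %.1f%% concordant with truth",
            nrow(res), 100 * mean(res$concordant))
  }
  write_tsv(res, file.path(out, "qpcr_results.tsv"))
  invisible(res)
}

#' Run the whole pipeline: simulate, call, summarize, qPCR
#'
#' @param config a [pipeline_config()].
#' @return list of stage results (invisibly).
#' @export
run_all <- function(config) {
  run_simulate(config)
  segs <- run_call(config)
  summ <- run_summarize(config)
  qp <- run_qpcr(config)
  invisible(list(segments = segs, summary = summ, qpcr = qp))
}
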