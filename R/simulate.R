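#' Simulation configuration
#'
#' Bundles every tunable of the synthetic cohort generator with validated
#' defaults.  The defaults describe a desk-scale stand-in for a paired
#' tumor-normal breast-cancer SNP-array study: seven sample pairs, two
#' replicate arrays per sample, ~700 bp mean probe spacing, a female toy
#' genome of three chromosomes, Gaussian LRR/BAF noise, and a smooth
#' GC-correlated wave artifact.
#'
#' @param seed integer random seed; every downstream simulation derives its
#'   RNG stream from it.
#' @param n_pairs number of tumor-normal sample pairs (default 7).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param female logical; female genome (no chrY).
#' @param n_coding,n_lincrna number of protein-coding and lincRNA genes to
#'   place.
#' @param coding_size,lincrna_size length-2 vectors: min/max gene size (bp),
#'   sampled log-uniformly.
#' @param spacing mean inter-probe gap in bp (exponential gaps; default 700).
#' @param purity tumor cell fraction rho in (0, 1]; scalar or one value per
#'   pair.
#' @param lrr_sd,baf_sd Gaussian noise standard deviations for LRR and BAF.
#' @param het_rate probability that a probe is heterozygous (AB) in a
#'   normal genome.
#' @param nc_rate probability of a no-call (NC) genotype in the normal.
#' @param gc_amplitude,gc_period amplitude (LRR units) and period (bp) of
#'   the sinusoidal GC wave added to every array.
#' @param lrr_floor lower clip for expected LRR (array dynamic range); keeps
#'   homozygous deletions finite.
#' @param replicates replicate arrays per sample (independent noise).
#' @param events optional data.frame of planted events with columns
#'   `sample` (integer pair index), `chrom`, `start`, `end` (0-based
#'   half-open), `cn_total`, `b_copies`.  `NULL` draws random events.
#' @param n_events length-2 integer range: events per sample when drawing
#'   randomly.
#' @param event_size length-2 vector: min/max event size in bp
#'   (log-uniform).
#' @param class_weights named weights over
#'   `gain`, `loss`, `homozygous_loss`, `allelic_imbalance` for random
#'   event classes.
#' @param qpcr list of qPCR simulation settings: `efficiency` (E in (0,1]),
#'   `intercept` (Ct at 1 ng), `ct_sd`, `standards` (dilution quantities,
#'   ng), `input_ng` (unknown-sample input levels), `replicates`
#'   (wells per point), `max_targets` (event-overlapping targets assayed
#'   per sample), `n_neutral_targets` (copy-neutral control targets),
#'   `max_cycles` (Ct censoring limit; a zero-dosage target never
#'   crosses threshold and reports this value).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_pairs = 7L,
                       chrom_lengths = c(chr1 = 15e6, chr2 = 12e6, chr3 = 10e6),
                       female = TRUE,
                       n_coding = 60L,
                       n_lincrna = 25L,
                       coding_size = c(5e3, 2e5),
                       lincrna_size = c(1e3, 5e4),
                       spacing = 700,
                       purity = 1,
                       lrr_sd = 0.15,
                       baf_sd = 0.03,
                       het_rate = 0.3,
                       nc_rate = 0.002,
                       gc_amplitude = 0.05,
                       gc_period = 5e6,
                       lrr_floor = -2,
                       replicates = 2L,
                       events = NULL,
                       n_events = c(2L, 6L),
                       event_size = c(2e4, 3e6),
                       class_weights = c(loss = 0.45, gain = 0.2,
                                         homozygous_loss = 0.1,
                                         allelic_imbalance = 0.25),
                       qpcr = list()) {
  qpcr_defaults <- list(efficiency = 0.95, intercept = 24, ct_sd = 0.1,
                        standards = c(64, 16, 4, 1, 0.25, 0.0625),
                        input_ng = c(40, 10), replicates = 3L,
                        max_targets = 2L, n_neutral_targets = 2L,
                        max_cycles = 40)
  unknown <- setdiff(names(qpcr), names(qpcr_defaults))
  if (length(unknown)) stopf("unknown qpcr settings: %s",
                             paste(unknown, collapse = ", "))
  qpcr <- utils::modifyList(qpcr_defaults, qpcr)

  cfg <- list(seed = as.integer(seed), n_pairs = as.integer(n_pairs),
              chrom_lengths = chrom_lengths, female = female,
              n_coding = as.integer(n_coding),
              n_lincrna = as.integer(n_lincrna),
              coding_size = coding_size, lincrna_size = lincrna_size,
              spacing = spacing, purity = rep_len(purity, n_pairs),
              lrr_sd = lrr_sd, baf_sd = baf_sd, het_rate = het_rate,
              nc_rate = nc_rate, gc_amplitude = gc_amplitude,
              gc_period = gc_period, lrr_floor = lrr_floor,
              replicates = as.integer(replicates), events = events,
              n_events = as.integer(n_events), event_size = event_size,
              class_weights = class_weights, qpcr = qpcr)

  if (!is_scalar_number(cfg$seed)) stopf("seed must be a single integer")
  if (cfg$n_pairs < 1) stopf("n_pairs must be >= 1")
  if (cfg$spacing <= 0) stopf("probe spacing must be > 0")
  if (any(cfg$purity <= 0 | cfg$purity > 1)) {
    stopf("purity must lie in (0, 1]")
  }
  if (cfg$lrr_sd < 0 || cfg$baf_sd < 0) stopf("noise sds must be >= 0")
  if (cfg$het_rate < 0 || cfg$het_rate > 1) stopf("het_rate in [0, 1]")
  if (cfg$replicates < 1) stopf("replicates must be >= 1")
  if (qpcr$efficiency <= 0 || qpcr$efficiency > 1) {
    stopf("qPCR amplification efficiency must lie in (0, 1]")
  }
  if (qpcr$ct_sd < 0) stopf("Ct noise sd must be >= 0")
  if (any(qpcr$standards <= 0)) stopf("dilution quantities must be > 0")
  genome_model(chrom_lengths, female = female)   # validates the genome
  if (!is.null(events)) validate_event_spec(events, cfg)
  structure(cfg, class = "sim_config")
}

# Derive a stage-specific seed so each generator stage has its own stream
# while remaining a pure function of the configured seed.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 20000000L) * 101L + as.integer(stage)
}

validate_event_spec <- function(events, cfg) {
  need <- c("sample", "chrom", "start", "end", "cn_total", "b_copies")
  if (!all(need %in% names(events))) {
    stopf("event spec needs columns: %s", paste(need, collapse = ", "))
  }
  if (any(events$start >= events$end)) stopf("event start must be < end")
  if (any(events$b_copies < 0 | events$b_copies > events$cn_total)) {
    stopf("events need 0 <= b_copies <= cn_total")
  }
  bad <- !(events$chrom %in% names(cfg$chrom_lengths)) |
    events$start < 0 | events$end > cfg$chrom_lengths[events$chrom]
  if (any(bad)) stopf("event interval(s) outside chromosome bounds")
  invisible(events)
}

#' Classify a copy state into an event class
#'
#' `cn_total > 2` is a gain, `1` a loss, `0` a homozygous loss;
#' `cn_total == 2` with both copies from one allele (`b_copies` 0 or 2) is
#' a copy-neutral allelic imbalance (LOH); the diploid heterozygous state
#' (`cn_total = 2`, `b_copies = 1`) is no event (`NA`).
#'
#' @param cn_total total tumor copy number of the segment.
#' @param b_copies B-allele copy number at sites heterozygous in the normal.
#' @return character vector of classes (`NA` for the normal state).
#' @export
event_class_from_state <- function(cn_total, b_copies) {
  cls <- rep(NA_character_, length(cn_total))
  cls[cn_total > 2] <- "gain"
  cls[cn_total == 1] <- "loss"
  cls[cn_total == 0] <- "homozygous_loss"
  cls[cn_total == 2 & b_copies %in% c(0, 2)] <- "allelic_imbalance"
  cls
}

#' Simulate a toy genome with coding and lincRNA annotation tracks
#'
#' Places `n_coding` protein-coding genes and `n_lincrna` lincRNA genes on
#' the configured chromosomes so that all intervals are mutually disjoint:
#' lincRNAs live strictly in intergenic space, matching the definition of
#' a long *intergenic* non-coding RNA.
#'
#' @param config a [sim_config()].
#' @return list with elements `genome` ([genome_model()]), `coding` and
#'   `lincrna` (both [annotation_track()]).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- genome_model(config$chrom_lengths, female = config$female)
  with_seed(stage_seed(config$seed, 1L), {
    placed <- list()   # per chromosome: matrix of [start, end)
    place_genes <- function(n, size_range, prefix) {
      if (n == 0) {
        return(data.frame(chrom = character(), start = numeric(),
                          end = numeric(), gene_id = character()))
      }
      lens <- genome$lengths
      out <- vector("list", n)
      for (i in seq_len(n)) {
        size <- round(exp(runif(1, log(size_range[1]), log(size_range[2]))))
        ok <- FALSE
        for (try in 1:2000) {
          chr <- sample(names(lens), 1, prob = lens)
          if (size >= lens[[chr]]) next
          start <- floor(runif(1, 0, lens[[chr]] - size))
          end <- start + size
          prev <- placed[[chr]]
          if (is.null(prev) ||
              !any(start < prev[, 2] & end > prev[, 1])) {
            placed[[chr]] <<- rbind(prev, c(start, end))
            out[[i]] <- data.frame(chrom = chr, start = start, end = end,
                                   gene_id = sprintf("%s%04d", prefix, i))
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stopf("could not fit %d %s genes into the genome; reduce counts or sizes",
                n, prefix)
        }
      }
      do.call(rbind, out)
    }
    cod <- place_genes(config$n_coding, config$coding_size, "PCG")
    lnc <- place_genes(config$n_lincrna, config$lincrna_size, "LINC")
    list(genome = genome,
         coding = annotation_track(cod$chrom, cod$start, cod$end,
                                   cod$gene_id, "protein_coding",
                                   name = "coding", genome = genome),
         lincrna = annotation_track(lnc$chrom, lnc$start, lnc$end,
                                    lnc$gene_id, "lincRNA",
                                    name = "lincRNA", genome = genome))
  })
}

#' Plant aberration events into a cohort (truth set)
#'
#' Either validates user-specified event coordinates or draws random events
#' per sample (count, class, size and placement from the configuration).
#' Events of one sample never overlap.  The diploid heterozygous state
#' produces no event.
#'
#' @param config a [sim_config()].
#' @param genome the [genome_model()] the events live on.
#' @return a data.frame (class `truth_set`) with columns `sample`,
#'   `sample_id`, `chrom`, `start`, `end`, `cn_total`, `b_copies`, `class`.
#' @export
plant_events <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  state_for_class <- c(gain = 3, loss = 1, homozygous_loss = 0,
                       allelic_imbalance = 2)
  b_for_class <- c(gain = 2, loss = 0, homozygous_loss = 0,
                   allelic_imbalance = 0)
  if (!is.null(config$events)) {
    ev <- validate_event_spec(config$events, config)
    ev$class <- event_class_from_state(ev$cn_total, ev$b_copies)
    ev <- ev[!is.na(ev$class), , drop = FALSE]
    for (s in unique(ev$sample)) {
      sub <- ev[ev$sample == s, , drop = FALSE]
      for (chr in unique(sub$chrom)) {
        x <- sub[sub$chrom == chr, , drop = FALSE]
        x <- x[order(x$start), , drop = FALSE]
        if (nrow(x) > 1 && any(x$start[-1] < x$end[-nrow(x)])) {
          stopf("overlapping events for sample %s on %s", s, chr)
        }
      }
    }
  } else {
    ev <- with_seed(stage_seed(config$seed, 2L), {
      lens <- genome$lengths
      rows <- list()
      for (s in seq_len(config$n_pairs)) {
        n_ev <- sample(config$n_events[1]:config$n_events[2], 1)
        placed <- list()
        for (k in seq_len(n_ev)) {
          cls <- sample(names(config$class_weights), 1,
                        prob = config$class_weights)
          size <- round(exp(runif(1, log(config$event_size[1]),
                                  log(config$event_size[2]))))
          for (try in 1:500) {
            chr <- sample(names(lens), 1, prob = lens)
            if (size >= lens[[chr]]) next
            start <- floor(runif(1, 0, lens[[chr]] - size))
            end <- start + size
            prev <- placed[[chr]]
            if (is.null(prev) ||
                !any(start < prev[, 2] & end > prev[, 1])) {
              placed[[chr]] <- rbind(prev, c(start, end))
              rows[[length(rows) + 1L]] <- data.frame(
                sample = s, chrom = chr, start = start, end = end,
                cn_total = unname(state_for_class[cls]),
                b_copies = unname(b_for_class[cls]), class = cls)
              break
            }
          }
        }
      }
      if (length(rows)) do.call(rbind, rows) else
        data.frame(sample = integer(), chrom = character(),
                   start = numeric(), end = numeric(),
                   cn_total = numeric(), b_copies = numeric(),
                   class = character())
    })
  }
  ev$sample_id <- sprintf("S%02d", ev$sample)
  ev <- ev[order(ev$sample, ev$chrom, ev$start),
           c("sample", "sample_id", "chrom", "start", "end",
             "cn_total", "b_copies", "class")]
  rownames(ev) <- NULL
  class(ev) <- c("truth_set", "data.frame")
  ev
}

#' Annotate truth events with the lincRNA genes they overlap
#'
#' @param truth a truth set from [plant_events()].
#' @param lincrna_track the lincRNA [annotation_track()].
#' @return `truth` with an extra `lincrnas` column (comma-separated gene
#'   ids, empty string when none).
#' @export
annotate_truth_lincrnas <- function(truth, lincrna_track) {
  truth$lincrnas <- vapply(seq_len(nrow(truth)), function(i) {
    sub <- lincrna_track[lincrna_track$chrom == truth$chrom[i] &
                           lincrna_track$start < truth$end[i] &
                           lincrna_track$end > truth$start[i], ]
    paste(sub$gene_id, collapse = ",")
  }, character(1))
  truth
}

# Shared probe manifest: jittered positions (exponential gaps with the
# configured mean), probe ids and a smooth GC covariate in [0, 1].
probe_manifest <- function(genome, config) {
  with_seed(stage_seed(config$seed, 3L), {
    pieces <- lapply(names(genome$lengths), function(chr) {
      len <- genome$lengths[[chr]]
      n_max <- ceiling(len / config$spacing * 1.4) + 10
      pos <- cumsum(rexp(n_max, rate = 1 / config$spacing))
      pos <- floor(pos[pos < len])
      pos <- unique(pos)
      data.frame(chrom = chr, pos = pos,
                 gc = 0.5 + 0.5 * sin(2 * pi * pos / config$gc_period))
    })
    df <- do.call(rbind, pieces)
    df$probe_id <- sprintf("P%07d", seq_len(nrow(df)))
    df[, c("probe_id", "chrom", "pos", "gc")]
  })
}

# Tumor copy state per probe given that sample's truth events.
# Returns list(cn, b) with per-probe totals; b depends on the germline
# genotype: homozygous AA stays 0 B copies, BB tracks cn, and the event's
# b_copies applies at heterozygous sites.
probe_copy_state <- function(manifest, events_s, g) {
  cn <- rep(2, nrow(manifest))
  b <- g
  if (nrow(events_s)) {
    for (i in seq_len(nrow(events_s))) {
      in_ev <- manifest$chrom == events_s$chrom[i] &
        manifest$pos >= events_s$start[i] & manifest$pos < events_s$end[i]
      cn[in_ev] <- events_s$cn_total[i]
      b[in_ev & g == 0] <- 0
      b[in_ev & g == 2] <- events_s$cn_total[i]
      b[in_ev & g == 1] <- events_s$b_copies[i]
    }
  }
  list(cn = cn, b = b)
}

#' Simulate paired tumor-normal probe signals
#'
#' Generates a shared probe manifest and, per sample pair, per-replicate
#' arrays for the normal and the tumor.  Normal LRR is centered on 0; in a
#' planted event the expected tumor LRR is
#' `log2(((1 - rho) * 2 + rho * CN_t) / 2)` (clipped at the configured
#' floor) and the expected tumor BAF at a probe with `g` germline B alleles
#' is `((1 - rho) * g + rho * b) / ((1 - rho) * 2 + rho * CN_t)`.  Gaussian
#' noise and a GC-tracking sinusoidal wave are added; BAF is clipped to
#' `[0, 1]`.
#'
#' @param genome a [genome_model()].
#' @param truth a truth set from [plant_events()].
#' @param config a [sim_config()].
#' @return list with `manifest` (probe_id, chrom, pos, gc) and `samples`,
#'   a named list (one entry per pair, `S01`...) of
#'   `list(tumor = <list of replicate data.frames>, normal = <...>)`.
#'   Each replicate data.frame has columns `probe_id`, `chrom`, `pos`,
#'   `lrr`, `baf`, `genotype`, `gc`.
#' @export
simulate_probe_signals <- function(genome, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  manifest <- probe_manifest(genome, config)
  n_probe <- nrow(manifest)
  wave <- config$gc_amplitude * 2 * (manifest$gc - 0.5)

  samples <- with_seed(stage_seed(config$seed, 4L), {
    out <- vector("list", config$n_pairs)
    names(out) <- sprintf("S%02d", seq_len(config$n_pairs))
    for (s in seq_len(config$n_pairs)) {
      rho <- config$purity[s]
      # germline genotype (shared by tumor and normal of the pair)
      u <- runif(n_probe)
      g <- ifelse(u < config$het_rate, 1L,
                  ifelse(u < config$het_rate + (1 - config$het_rate) / 2,
                         0L, 2L))
      gt <- c("AA", "AB", "BB")[g + 1L]
      nc <- runif(n_probe) < config$nc_rate
      gt[nc] <- "NC"

      ev_s <- truth[truth$sample == s, , drop = FALSE]
      st <- probe_copy_state(manifest, ev_s, g)
      mix <- (1 - rho) * 2 + rho * st$cn
      lrr_t_exp <- ifelse(mix > 0, pmax(log2(mix / 2), config$lrr_floor),
                          config$lrr_floor)
      baf_t_exp <- ifelse(mix > 0, ((1 - rho) * g + rho * st$b) / mix, NA)

      make_array <- function(lrr_exp, baf_exp) {
        lrr <- lrr_exp + wave + rnorm(n_probe, 0, config$lrr_sd)
        baf <- ifelse(is.na(baf_exp), runif(n_probe),
                      baf_exp + rnorm(n_probe, 0, config$baf_sd))
        data.frame(probe_id = manifest$probe_id, chrom = manifest$chrom,
                   pos = manifest$pos, lrr = lrr,
                   baf = pmin(pmax(baf, 0), 1), genotype = gt,
                   gc = manifest$gc, stringsAsFactors = FALSE)
      }
      normal <- lapply(seq_len(config$replicates), function(r)
        make_array(0, g / 2))
      tumor <- lapply(seq_len(config$replicates), function(r)
        make_array(lrr_t_exp, baf_t_exp))
      out[[s]] <- list(tumor = tumor, normal = normal)
    }
    out
  })
  list(manifest = manifest, samples = samples)
}

#' Simulate a qPCR dilution-series standard
#'
#' Ct values follow `Ct = intercept - log10(quantity) / log10(1 + E)` plus
#' Gaussian noise, i.e. a perfectly efficient assay (`E = 1`) loses one
#' cycle per doubling of input.
#'
#' @param quantities input quantities (ng), strictly positive.
#' @param efficiency amplification efficiency E in (0, 1].
#' @param intercept Ct at 1 ng.
#' @param noise_sd Gaussian Ct noise sd.
#' @param replicates wells per dilution point.
#' @return data.frame with columns `quantity`, `replicate`, `ct`.
#' @export
simulate_dilution_standard <- function(quantities = c(64, 16, 4, 1, 0.25, 0.0625),
                                       efficiency = 0.95, intercept = 24,
                                       noise_sd = 0.1, replicates = 3L) {
  if (any(quantities <= 0)) stopf("dilution quantities must be > 0")
  if (efficiency <= 0 || efficiency > 1) stopf("efficiency must be in (0, 1]")
  if (noise_sd < 0) stopf("noise sd must be >= 0")
  q <- rep(quantities, each = replicates)
  ct <- intercept - log10(q) / log10(1 + efficiency) +
    rnorm(length(q), 0, noise_sd)
  data.frame(quantity = q,
             replicate = rep(seq_len(replicates), times = length(quantities)),
             ct = ct)
}

#' Simulate qPCR Ct tables for a cohort
#'
#' Emits, per assay, a dilution-series standard plus unknown-sample wells
#' for tumor and normal at the configured gDNA input levels.  Reference
#' assays (alpha-satellite, albumin) run at copy-neutral dosage; target
#' assays scale the tumor input by the truth copy ratio
#' `((1 - rho) * 2 + rho * CN_t) / 2` of the event covering the target.
#' Copy-neutral control targets at dosage 1 are added per sample.
#'
#' @param truth a truth set, ideally with the `lincrnas` column from
#'   [annotate_truth_lincrnas()] so targets carry gene names.
#' @param config a [sim_config()].
#' @return list with `ct` (columns `sample`, `assay`, `role`
#'   in standard/target/reference, `tissue` in standard/tumor/normal,
#'   `input_ng`, `replicate`, `ct`) and `truth`
#'   (`sample`, `assay`, `dosage_ratio`, `class`).
#' @export
simulate_qpcr <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  qp <- config$qpcr
  with_seed(stage_seed(config$seed, 5L), {
    references <- c("ALPHA_SAT", "ALB")
    # choose per-sample targets: event-overlapping (named by lincRNA when
    # known) plus copy-neutral controls
    targets <- list()
    for (s in unique(truth$sample)) {
      ev_s <- truth[truth$sample == s, , drop = FALSE]
      rho <- config$purity[s]
      take <- head(seq_len(nrow(ev_s)), qp$max_targets)
      for (i in take) {
        nm <- if (!is.null(ev_s$lincrnas) && nzchar(ev_s$lincrnas[i])) {
          strsplit(ev_s$lincrnas[i], ",")[[1]][1]
        } else sprintf("EV_%s_%d", ev_s$sample_id[i], i)
        targets[[length(targets) + 1L]] <- data.frame(
          sample = ev_s$sample_id[i], assay = nm,
          dosage_ratio = ((1 - rho) * 2 + rho * ev_s$cn_total[i]) / 2,
          class = ev_s$class[i])
      }
      for (j in seq_len(qp$n_neutral_targets)) {
        targets[[length(targets) + 1L]] <- data.frame(
          sample = sprintf("S%02d", s), assay = sprintf("NEUT%02d", j),
          dosage_ratio = 1, class = "neutral")
      }
    }
    target_truth <- if (length(targets)) do.call(rbind, targets) else
      data.frame(sample = character(), assay = character(),
                 dosage_ratio = numeric(), class = character())

    slope_ct <- -1 / log10(1 + qp$efficiency)
    # zero dosage (homozygous loss) never crosses threshold: Ct censored
    # at the run's cycle count, like a real thermocycler
    ct_of <- function(q) {
      base <- qp$intercept + slope_ct * log10(q)
      base[!is.finite(base)] <- Inf
      pmin(base + rnorm(length(q), 0, qp$ct_sd), qp$max_cycles)
    }
    rows <- list()
    emit <- function(sample, assay, role, tissue, input_ng, q) {
      n <- qp$replicates
      rows[[length(rows) + 1L]] <<- data.frame(
        sample = sample, assay = assay, role = role, tissue = tissue,
        input_ng = input_ng, replicate = seq_len(n),
        ct = ct_of(rep(q, n)))
    }
    assays <- unique(c(references, target_truth$assay))
    for (a in assays) {
      for (q in qp$standards) emit("standard", a, "standard", "standard", q, q)
    }
    for (k in seq_len(nrow(target_truth))) {
      smp <- target_truth$sample[k]
      a <- target_truth$assay[k]
      dos <- target_truth$dosage_ratio[k]
      for (lvl in qp$input_ng) {
        emit(smp, a, "target", "tumor", lvl, lvl * dos)
        emit(smp, a, "target", "normal", lvl, lvl)
      }
    }
    # reference wells: once per sample, level and tissue
    for (smp in unique(target_truth$sample)) {
      for (lvl in qp$input_ng) {
        for (r in references) {
          emit(smp, r, "reference", "tumor", lvl, lvl)
          emit(smp, r, "reference", "normal", lvl, lvl)
        }
      }
    }
    ct <- do.call(rbind, rows)
    ct <- ct[order(ct$sample, ct$assay, ct$role, ct$tissue,
                   ct$input_ng, ct$replicate), ]
    rownames(ct) <- NULL
    list(ct = ct, truth = target_truth)
  })
}
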