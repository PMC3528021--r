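# Format readers and writers.  Convention: positions and intervals are
# 0-based half-open in memory; tabular probe/segment files are written
# 1-based (probe position, SEG start/end inclusive), BED stays native
# 0-based half-open, GTF is read 1-based inclusive and converted.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, ...)
}

#' Write and read probe-signal tables
#'
#' Tab-separated with header `Name Chr Position LRR BAF GType GC`;
#' positions are 1-based on disk and converted back to 0-based on read.
#'
#' @param signals probe-signal data.frame.
#' @param path file path.
#' @return `read_probe_signals()` returns the data.frame (0-based `pos`).
#' @export
write_probe_signals <- function(signals, path) {
  out <- data.frame(Name = signals$probe_id, Chr = signals$chrom,
                    Position = signals$pos + 1, LRR = signals$lrr,
                    BAF = signals$baf, GType = signals$genotype,
                    GC = signals$gc %||% NA)
  write_tsv(out, path)
  invisible(path)
}

#' @rdname write_probe_signals
#' @export
read_probe_signals <- function(path) {
  df <- read_tsv(path)
  need <- c("Name", "Chr", "Position", "LRR", "BAF", "GType")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing column(s) %s", path,
                          paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$Position) | !is.finite(df$LRR))
  if (length(bad)) stopf("%s: unparseable record at line %d", path,
                         bad[1] + 1L)
  data.frame(probe_id = as.character(df$Name), chrom = as.character(df$Chr),
             pos = df$Position - 1, lrr = df$LRR, baf = df$BAF,
             genotype = as.character(df$GType),
             gc = if ("GC" %in% names(df)) df$GC else NA_real_,
             stringsAsFactors = FALSE)
}

#' Write and read annotation tracks as BED
#'
#' BED is natively 0-based half-open; columns chrom, start, end, name,
#' score (biotype is carried in column 5's place as a text field).
#'
#' @param track an [annotation_track()].
#' @param path file path.
#' @param name track name on read.
#' @export
write_bed <- function(track, path) {
  out <- data.frame(track$chrom, format(track$start, scientific = FALSE,
                                        trim = TRUE),
                    format(track$end, scientific = FALSE, trim = TRUE),
                    track$gene_id, track$biotype)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path, name = "track") {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stopf("%s: BED needs >= 4 columns", path)
  annotation_track(df[[1]], as.numeric(df[[2]]), as.numeric(df[[3]]),
                   df[[4]],
                   biotype = if (ncol(df) >= 5) df[[5]] else "gene",
                   name = name)
}

#' Read gene footprints from a GTF file
#'
#' Uses `gene` feature rows when present, otherwise the per-gene span
#' (min start to max end over a gene's rows).  GTF is 1-based inclusive;
#' coordinates are converted to 0-based half-open.  `gene_id` and, when
#' present, `gene_biotype` are taken from the attributes column.
#'
#' @param path GTF file path.
#' @param name track name.
#' @return an [annotation_track()].
#' @export
read_gtf <- function(path, name = "gtf") {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          quote = "", stringsAsFactors = FALSE)
  if (ncol(df) < 9) stopf("%s: not a GTF file", path)
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, ' "([^"]+)"'), attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  gid <- get_attr(df[[9]], "gene_id")
  bty <- get_attr(df[[9]], "gene_biotype")
  if (any(is.na(gid))) stopf("%s: gene_id missing in attributes", path)
  use <- if (any(df[[3]] == "gene")) df[[3]] == "gene" else rep(TRUE, nrow(df))
  sub <- data.frame(chrom = df[[1]][use], start = df[[4]][use] - 1,
                    end = df[[5]][use], gene_id = gid[use],
                    biotype = ifelse(is.na(bty[use]), "gene", bty[use]),
                    stringsAsFactors = FALSE)
  span <- do.call(rbind, lapply(split(sub, sub$gene_id), function(g)
    data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
               gene_id = g$gene_id[1], biotype = g$biotype[1])))
  annotation_track(span$chrom, span$start, span$end, span$gene_id,
                   span$biotype, name = name)
}

#' Write and read SEG-style segment tables
#'
#' Tab-separated columns `Sample Chromosome Start End Num_Probes
#' Mean_LRR BAF_Dev Class`; coordinates are 1-based inclusive on disk and
#' 0-based half-open in memory.
#'
#' @param segments segment data.frame with a `sample_id` column.
#' @param path file path.
#' @export
write_seg <- function(segments, path) {
  out <- data.frame(Sample = segments$sample_id,
                    Chromosome = segments$chrom,
                    Start = format(segments$start + 1, scientific = FALSE,
                                   trim = TRUE),
                    End = format(segments$end, scientific = FALSE,
                                 trim = TRUE),
                    Num_Probes = segments$n_probes,
                    Mean_LRR = segments$mean_lrr,
                    BAF_Dev = segments$baf_dev,
                    Class = segments$class)
  write_tsv(out, path)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  df <- read_tsv(path)
  data.frame(sample_id = as.character(df$Sample),
             chrom = as.character(df$Chromosome),
             start = as.numeric(df$Start) - 1, end = as.numeric(df$End),
             n_probes = df$Num_Probes, mean_lrr = df$Mean_LRR,
             baf_dev = df$BAF_Dev, class = as.character(df$Class),
             length = as.numeric(df$End) - (as.numeric(df$Start) - 1),
             stringsAsFactors = FALSE)
}

#' Write and read truth sets
#'
#' One planted event per line; coordinates stay 0-based half-open (this
#' is an internal artifact, not an exchange format).
#'
#' @param truth a truth set from [plant_events()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- read_tsv(path)
  class(df) <- c("truth_set", "data.frame")
  df
}

#' Write Circos-format frequency tracks
#'
#' Plain `chrom start end value` text, one file per direction.
#'
#' @param freq a data.frame from [aggregate_frequencies()] (`gain` or
#'   `loss` element).
#' @param path file path.
#' @export
write_circos <- function(freq, path) {
  out <- data.frame(freq$chrom,
                    format(freq$start, scientific = FALSE, trim = TRUE),
                    format(freq$end, scientific = FALSE, trim = TRUE),
                    freq$freq)
  utils::write.table(out, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_circos
#' @export
read_circos <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = df[[1]], start = as.numeric(df[[2]]),
             end = as.numeric(df[[3]]), freq = as.numeric(df[[4]]),
             stringsAsFactors = FALSE)
}

#' Write and read qPCR Ct tables
#'
#' @param ct data.frame as produced by [simulate_qpcr()].
#' @param path file path.
#' @export
write_ct_table <- function(ct, path) {
  write_tsv(ct, path)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) read_tsv(path)
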