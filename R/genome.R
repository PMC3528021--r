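#' Genome model
#'
#' A minimal genome description: named chromosome lengths plus a flag for a
#' female genome (no Y chromosome).  All coordinates in this package are
#' 0-based half-open in memory; files use the native convention of each
#' format (BED 0-based half-open, tabular probe/segment files 1-based).
#'
#' @param lengths named numeric vector of chromosome lengths in bp.
#' @param female logical; if `TRUE` (default) the genome carries no Y
#'   chromosome and any `chrY` entry is rejected.
#' @return an object of class `genome_model`: a list with elements
#'   `lengths` and `female`.
#' @examples
#' g <- genome_model(c(chr1 = 1e7, chr2 = 5e6))
#' genome_length(g)
#' @export
genome_model <- function(lengths, female = TRUE) {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)) ||
      any(!nzchar(names(lengths)))) {
    stopf("chromosome names must be present and unique")
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stopf("all chromosome lengths must be positive and finite")
  }
  if (female && any(is_chrY(names(lengths)))) {
    stopf("a female genome cannot contain a Y chromosome")
  }
  structure(list(lengths = lengths, female = female),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d chromosome(s), %.3g bp total, %s\n",
              length(x$lengths), sum(x$lengths),
              if (x$female) "female (no chrY)" else "male"))
  invisible(x)
}

#' Total genome length
#'
#' @param genome a [genome_model()].
#' @param exclude_chrY drop chrY from the tally (the analysis genome is
#'   female, so chrY never contributes to compartment totals).
#' @return total length in bp.
#' @export
genome_length <- function(genome, exclude_chrY = TRUE) {
  len <- genome$lengths
  if (exclude_chrY) len <- len[!is_chrY(names(len))]
  sum(len)
}

#' Annotation track constructor
#'
#' A named set of genomic intervals with gene identifiers and biotype,
#' stored 0-based half-open.  Gene identifiers must be unique within a
#' track and every interval must satisfy `start < end`.
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param gene_id unique gene identifiers.
#' @param biotype biotype label(s), recycled (e.g. `"protein_coding"`,
#'   `"lincRNA"`).
#' @param name track name.
#' @param genome optional [genome_model()]; if given, intervals are checked
#'   against chromosome bounds.
#' @return a `data.frame` of class `annotation_track` with columns
#'   `chrom`, `start`, `end`, `gene_id`, `biotype` and attribute
#'   `track_name`.
#' @export
annotation_track <- function(chrom, start, end, gene_id,
                             biotype = "gene", name = "track",
                             genome = NULL) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   gene_id = as.character(gene_id),
                   biotype = rep_len(as.character(biotype), n),
                   stringsAsFactors = FALSE)
  if (n > 0) {
    if (any(df$start >= df$end)) stopf("every interval needs start < end")
    if (any(df$start < 0)) stopf("negative interval start")
    if (anyDuplicated(df$gene_id)) {
      stopf("gene identifiers must be unique within a track")
    }
    if (!is.null(genome)) {
      bad <- !(df$chrom %in% names(genome$lengths)) |
        df$end > genome$lengths[df$chrom]
      if (any(bad)) {
        stopf("interval(s) outside chromosome bounds: %s",
              paste(df$gene_id[bad], collapse = ", "))
      }
    }
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "track_name") <- name
  class(df) <- c("annotation_track", "data.frame")
  df
}

# Subset of a track on one chromosome as an IRanges.
track_iranges <- function(track, chrom) {
  sub <- track[track$chrom == chrom, , drop = FALSE]
  as_iranges0(sub$start, sub$end)
}

# Total merged footprint of a track in bp (overlapping intervals counted
# once), optionally excluding chrY.
track_footprint <- function(track, exclude_chrY = TRUE) {
  if (nrow(track) == 0) return(0)
  keep <- if (exclude_chrY) !is_chrY(track$chrom) else rep(TRUE, nrow(track))
  sub <- track[keep, , drop = FALSE]
  total <- 0
  for (chr in unique(sub$chrom)) {
    total <- total + sum(IRanges::width(IRanges::reduce(track_iranges(sub, chr))))
  }
  total
}
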