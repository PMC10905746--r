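#' Binned coverage tracks
#'
#' A `binned_track` stores per-bin fragment counts for one sample: a named
#' list of numeric vectors (one per chromosome) at a fixed `bin_size`. Bin
#' `i` (1-based) covers bases `[(i-1) * bin_size, i * bin_size)`. These
#' tracks stand in for aligned fragments; the pipeline never touches BAMs.
#'
#' @param counts named list of non-negative numeric vectors, one per
#'   chromosome.
#' @param bin_size bin width in bp.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(counts, bin_size) {
  stopifnot(is.list(counts), !is.null(names(counts)), bin_size > 0)
  for (v in counts) {
    if (any(!is.finite(v)) || any(v < 0))
      stop("binned_track: counts must be finite and non-negative")
  }
  structure(list(counts = counts, bin_size = as.numeric(bin_size)),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track: %d chromosome(s), bin_size %d bp, %.0f fragments\n",
              length(x$counts), as.integer(x$bin_size), track_total(x)))
  invisible(x)
}

#' Total fragment count of a track
#' @param track a `binned_track`.
#' @return Sum of all bin counts.
#' @export
track_total <- function(track) {
  sum(vapply(track$counts, sum, numeric(1)))
}

#' Sum binned tracks (replicate pooling)
#'
#' Pooling replicates for peak calling is the sum of their bin counts.
#'
#' @param tracks list of `binned_track`s with identical layout.
#' @return A `binned_track`.
#' @export
pool_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  base <- tracks[[1]]
  for (t in tracks[-1]) {
    stopifnot(identical(names(t$counts), names(base$counts)),
              t$bin_size == base$bin_size)
    base$counts <- Map(`+`, base$counts, t$counts)
  }
  base
}

#' Read and write bedGraph tracks
#'
#' Four-column bedGraph (`chrom start end value`), run-length encoded on
#' write so constant stretches collapse to one row. `read_bedgraph` expands
#' back to fixed-size bins and requires all record bounds to be multiples of
#' `bin_size`; files written by [write_bedgraph()] round-trip exactly.
#'
#' @param path file path.
#' @param bin_size bin width in bp used to expand records.
#' @param chrom_lengths named vector of chromosome lengths in bp (defines
#'   the number of bins; trailing unreported bins are zero).
#' @return `read_bedgraph` returns a `binned_track`.
#' @export
read_bedgraph <- function(path, bin_size, chrom_lengths) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "value"),
                         stringsAsFactors = FALSE, quote = "")
  counts <- lapply(chrom_lengths, function(len) numeric(ceiling(len / bin_size)))
  names(counts) <- names(chrom_lengths)
  if (nrow(x) > 0) {
    if (any(x$start %% bin_size != 0) || any(x$end %% bin_size != 0))
      stop("read_bedgraph: record bounds must be multiples of bin_size")
    for (ch in unique(x$chrom)) {
      if (!ch %in% names(counts))
        stop(sprintf("read_bedgraph: chromosome '%s' not in chrom_lengths", ch))
      xi <- x[x$chrom == ch, , drop = FALSE]
      for (j in seq_len(nrow(xi))) {
        b0 <- xi$start[j] / bin_size + 1
        b1 <- xi$end[j] / bin_size
        counts[[ch]][b0:b1] <- xi$value[j]
      }
    }
  }
  binned_track(counts, bin_size)
}

#' @rdname read_bedgraph
#' @param track a `binned_track` to write.
#' @export
write_bedgraph <- function(track, path) {
  bs <- track$bin_size
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(track$counts)) {
    v <- track$counts[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- c(0, ends[-length(ends)])
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%.0f\t%.0f\t%s", ch, starts[keep] * bs,
                         ends[keep] * bs, format(r$values[keep],
                                                 scientific = FALSE,
                                                 trim = TRUE)),
                 con)
    }
  }
  invisible(path)
}

sample_sheet_cols <- c("sample_id", "assay", "genotype", "timepoint",
                       "replicate", "primary_mapped_reads",
                       "spike_mapped_reads")

#' Validate a sample design table
#'
#' The sample sheet carries one row per sequencing library: `sample_id`,
#' `assay` (BRD4, H3K27ac, H3K4me2, H3K27me3, RUNX2, RNA), `genotype`
#' (WT, KO1, KO2), `timepoint` (D0, D3, D6), `replicate`,
#' `primary_mapped_reads` (> 0) and `spike_mapped_reads` (>= 0; `NA` for
#' assays without an exogenous spike channel).
#'
#' @param x data frame to validate.
#' @return `x`, invisibly modified to canonical column order.
#' @export
validate_sample_sheet <- function(x) {
  if (!all(sample_sheet_cols %in% names(x)))
    stop("sample sheet must contain columns: ",
         paste(sample_sheet_cols, collapse = ", "))
  stopifnot(
    !anyDuplicated(x$sample_id),
    all(x$assay %in% c("BRD4", "H3K27ac", "H3K4me2", "H3K27me3", "RUNX2", "RNA")),
    all(x$genotype %in% c("WT", "KO1", "KO2")),
    all(x$timepoint %in% c("D0", "D3", "D6")),
    all(x$primary_mapped_reads > 0),
    all(is.na(x$spike_mapped_reads) | x$spike_mapped_reads >= 0)
  )
  x[, c(sample_sheet_cols, setdiff(names(x), sample_sheet_cols)), drop = FALSE]
}

#' Read and write the sample sheet TSV
#' @param path file path.
#' @return `read_sample_sheet` returns a validated data frame.
#' @export
read_sample_sheet <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "")
  validate_sample_sheet(x)
}

#' @rdname read_sample_sheet
#' @param x sample sheet data frame.
#' @export
write_sample_sheet <- function(x, path) {
  utils::write.table(validate_sample_sheet(x), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write feature count tables
#'
#' TSV layout: BED-style `chrom`, `start`, `end`, `id` columns followed by
#' one numeric column per sample.
#'
#' @param path file path.
#' @return `read_count_table` returns a list with `features`
#'   (an `interval_set`) and `counts` (matrix, rownames = feature ids).
#' @export
read_count_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "",
                         check.names = FALSE)
  feats <- as_interval_set(x[, c("chrom", "start", "end", "id")])
  m <- as.matrix(x[, setdiff(names(x), c("chrom", "start", "end", "id")),
                   drop = FALSE])
  rownames(m) <- x$id
  list(features = feats, counts = m)
}

#' @rdname read_count_table
#' @param features `interval_set` (row order defines output order).
#' @param counts numeric matrix, one column per sample.
#' @export
write_count_table <- function(features, counts, path) {
  stopifnot(nrow(features) == nrow(counts))
  out <- cbind(
    data.frame(chrom = features$chrom, start = as.integer(features$start),
               end = as.integer(features$end),
               id = ifelse(is.na(features$id), ".", features$id),
               stringsAsFactors = FALSE),
    as.data.frame(counts)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
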