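#' Genomic interval sets
#'
#' An `interval_set` is a data frame of 0-based, half-open genomic intervals
#' (`chrom`, `start`, `end`, plus optional `id` and `strand`), kept sorted by
#' `(chrom, start, end)`. The half-open convention is the BED dialect: a base
#' at offset `b` is inside `[start, end)` iff `start <= b < end`, and two
#' intervals that merely abut (`a$end == b$start`) do not overlap.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer vector, 0-based inclusive start offsets.
#' @param end integer vector, exclusive end offsets; `start < end` required.
#' @param id optional character labels.
#' @param strand optional strand, one of `"+"`, `"-"`, `"."`.
#' @return A data frame with class `interval_set`, sorted by
#'   `(chrom, start, end)`.
#' @examples
#' interval_set("chr1", c(100, 0), c(200, 50))
#' @export
interval_set <- function(chrom, start, end, id = NULL, strand = NULL) {
  n <- length(chrom)
  if (is.null(id)) id <- rep(NA_character_, n)
  if (is.null(strand)) strand <- rep(".", n)
  x <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    id = as.character(id),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  as_interval_set(x)
}

#' Coerce a data frame to a sorted interval set
#'
#' Validates the interval invariants (`0 <= start < end`, non-empty `chrom`)
#' and sorts by `(chrom, start, end)`.
#'
#' @param x data frame with at least `chrom`, `start`, `end` columns.
#' @return An `interval_set`.
#' @export
as_interval_set <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (!"id" %in% names(x)) x$id <- rep(NA_character_, nrow(x))
  if (!"strand" %in% names(x)) x$strand <- rep(".", nrow(x))
  if (nrow(x) > 0) {
    if (any(is.na(x$chrom) | !nzchar(x$chrom)))
      stop("interval_set: chrom must be non-empty")
    if (any(x$start < 0) || any(x$start >= x$end))
      stop("interval_set: need 0 <= start < end")
    if (!all(x$strand %in% c("+", "-", ".")))
      stop("interval_set: strand must be one of '+', '-', '.'")
  }
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("interval_set", "data.frame")
  x
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("interval_set with %d intervals on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  NextMethod()
}

empty_interval_set <- function() {
  interval_set(character(0), numeric(0), numeric(0))
}

check_sorted <- function(x, what = "interval set") {
  stopifnot(is.data.frame(x))
  if (nrow(x) > 1) {
    o <- order(x$chrom, x$start, x$end)
    if (!identical(o, seq_len(nrow(x))))
      stop(sprintf("%s is not sorted by (chrom, start, end); use as_interval_set()",
                   what))
  }
  invisible(x)
}

## For each interval in `a`, does it overlap (>= 1 bp) any interval in `b`?
## Half-open: overlap iff b.start < a.end and b.end > a.start.
overlaps_any <- function(a, b) {
  if (nrow(a) == 0) return(logical(0))
  hit <- logical(nrow(a))
  if (nrow(b) == 0) return(hit)
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    if (length(bi) == 0) next
    bs <- b$start[bi]                  # sorted ascending within chrom
    ce <- cummax(b$end[bi])
    # number of b intervals with start < a.end (integer coords)
    k <- findInterval(a$end[ai] - 0.5, bs)
    ok <- k > 0
    ok[ok] <- ce[k[ok]] > a$start[ai][ok]
    hit[ai] <- ok
  }
  hit
}

#' Intersect two interval sets (report semantics)
#'
#' Returns the members of `a` that overlap at least 1 bp of any member of `b`
#' (bedtools `intersect -u` semantics). Order of `a` is preserved. Abutting
#' intervals do not overlap under the half-open convention.
#'
#' @param a,b sorted `interval_set` objects (unsorted input is an error).
#' @return The overlapping subset of `a`, an `interval_set`.
#' @examples
#' a <- interval_set("chr1", 100, 200)
#' b <- interval_set("chr1", 150, 250)
#' intersect_overlapping(a, b)
#' @export
intersect_overlapping <- function(a, b) {
  check_sorted(a, "intersect: set a")
  check_sorted(b, "intersect: set b")
  out <- a[overlaps_any(a, b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interval_set", "data.frame")
  out
}

#' Merge overlapping or near-adjacent intervals
#'
#' Fuses intervals on the same chromosome that overlap or lie within
#' `max_gap` bp of each other. Output intervals are disjoint and separated by
#' more than `max_gap`. Merging is idempotent.
#'
#' @param x a sorted `interval_set`.
#' @param max_gap non-negative gap (bp); intervals with
#'   `next$start - prev$end <= max_gap` are fused. The default 0 fuses
#'   overlapping and book-ended intervals.
#' @return An `interval_set` of disjoint intervals.
#' @export
merge_intervals <- function(x, max_gap = 0) {
  if (max_gap < 0) stop("merge_intervals: max_gap must be >= 0")
  check_sorted(x, "merge")
  if (nrow(x) == 0) return(empty_interval_set())
  res <- lapply(split(seq_len(nrow(x)), x$chrom), function(ix) {
    s <- x$start[ix]; e <- x$end[ix]
    prev_end <- c(-Inf, cummax(e)[-length(e)])
    grp <- cumsum(s - prev_end > max_gap)
    data.frame(
      chrom = x$chrom[ix][1],
      start = as.numeric(tapply(s, grp, min)),
      end = as.numeric(tapply(e, grp, max)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  as_interval_set(out)
}

#' Gene models with strand-aware TSS
#'
#' Builds a gene-model table from interval coordinates: the transcription
#' start site (TSS) is the `start` offset for `+` strand genes and `end - 1`
#' for `-` strand genes, so it always lies within `[start, end)`.
#'
#' @param chrom,start,end gene body coordinates (0-based half-open).
#' @param strand `"+"` or `"-"` per gene.
#' @param gene_id unique gene identifiers.
#' @return A data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `tss`, sorted by `(chrom, start, end)`.
#' @export
gene_model <- function(chrom, start, end, strand, gene_id) {
  stopifnot(all(strand %in% c("+", "-")), !anyDuplicated(gene_id))
  if (any(start < 0) || any(start >= end)) stop("gene_model: need 0 <= start < end")
  g <- data.frame(
    chrom = as.character(chrom), start = as.numeric(start),
    end = as.numeric(end), strand = as.character(strand),
    gene_id = as.character(gene_id),
    stringsAsFactors = FALSE
  )
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1)
  g <- g[order(g$chrom, g$start, g$end), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Closest gene per peak
#'
#' For each peak, finds the gene whose body minimizes the unsigned gap
#' (0 when overlapping; `gene$start - peak$end` or `peak$start - gene$end`
#' when disjoint). Ties are broken by smaller gene start, then gene id.
#' Peaks on a chromosome with no genes get `NA` gene and distance.
#'
#' @param peaks an `interval_set`.
#' @param genes a gene-model data frame from [gene_model()].
#' @return Data frame: peak coordinates plus `gene_id` and `distance` (bp).
#' @export
closest_distance <- function(peaks, genes) {
  check_sorted(peaks, "closest: peaks")
  n <- nrow(peaks)
  gene_id <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    gi <- which(genes$chrom == peaks$chrom[i])
    if (length(gi) == 0) next
    d <- pmax(0, pmax(genes$start[gi] - peaks$end[i],
                      peaks$start[i] - genes$end[gi]))
    o <- order(d, genes$start[gi], genes$gene_id[gi])[1]
    gene_id[i] <- genes$gene_id[gi][o]
    distance[i] <- d[o]
  }
  out <- as.data.frame(peaks)
  out$gene_id <- gene_id
  out$distance <- distance
  out
}

#' TSS windows
#'
#' One window `[tss - halfwidth, tss + halfwidth + 1)` per gene (symmetric
#' around the strand-aware TSS base), clipped at 0. The pipeline default
#' halfwidth is 500 bp, giving the TSS+/-500 promoter definition.
#'
#' @param genes gene-model data frame from [gene_model()].
#' @param halfwidth positive window half-width in bp.
#' @return An `interval_set` with `id` set to the gene id.
#' @export
tss_windows <- function(genes, halfwidth = 500) {
  if (halfwidth <= 0) stop("tss_windows: halfwidth must be > 0")
  interval_set(
    chrom = genes$chrom,
    start = pmax(0, genes$tss - halfwidth),
    end = genes$tss + halfwidth + 1,
    id = genes$gene_id
  )
}

#' Read and write BED files
#'
#' Tab-separated, headerless BED3 (`chrom start end`) or BED6
#' (`... name score strand`). Coordinates are kept in the BED 0-based
#' half-open convention; `write_bed` emits BED6 when any id or strand is set,
#' and files written by the package round-trip exactly.
#'
#' @param path file path.
#' @return `read_bed` returns an `interval_set`.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character", quote = "",
                         comment.char = "")
  if (ncol(x) < 3) stop("read_bed: fewer than 3 columns")
  out <- data.frame(
    chrom = x[[1]], start = as.numeric(x[[2]]), end = as.numeric(x[[3]]),
    stringsAsFactors = FALSE
  )
  if (ncol(x) >= 4) out$id <- ifelse(x[[4]] == ".", NA_character_, x[[4]])
  if (ncol(x) >= 6) out$strand <- x[[6]]
  as_interval_set(out)
}

#' @rdname read_bed
#' @param x an `interval_set` to write.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "interval_set"))
  if (all(is.na(x$id)) && all(x$strand == ".")) {
    lines <- sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start),
                     as.integer(x$end))
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", x$chrom, as.integer(x$start),
                     as.integer(x$end), ifelse(is.na(x$id), ".", x$id),
                     x$strand)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write a gene table
#'
#' TSV with header columns `chrom`, `start`, `end`, `strand`, `gene_id`
#' (0-based half-open gene bodies, one interval per gene).
#'
#' @param path file path.
#' @return `read_gene_table` returns a gene-model data frame with `tss`.
#' @export
read_gene_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "")
  need <- c("chrom", "start", "end", "strand", "gene_id")
  if (!all(need %in% names(x)))
    stop("read_gene_table: header must contain chrom/start/end/strand/gene_id")
  gene_model(x$chrom, x$start, x$end, x$strand, x$gene_id)
}

#' @rdname read_gene_table
#' @param genes gene-model data frame to write.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(
    genes[, c("chrom", "start", "end", "strand", "gene_id")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
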