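#' Exogenous-genome spike-in scaling factor
#'
#' Occupancy assays spiked with chromatin from a second genome at a fixed
#' ratio per cell can be calibrated against that channel: the factor
#' `((primary_reads / primary_genome_bp) / spike_reads) * 10000` shrinks when
#' the primary signal collapses globally (more of the fixed sequencing depth
#' goes to the spike), which per-library normalizations such as CPM cannot
#' see. Scaled coverage is `counts * factor`; the equivalent effective
#' library size for count-based tests is `1 / factor`.
#'
#' @param primary_reads mapped reads on the primary genome (> 0).
#' @param spike_reads mapped reads on the spike genome (> 0).
#' @param primary_genome_bp primary genome size in bp (default
#'   2,654,895,218, a standard mouse assembly total).
#' @return Positive scaling factor(s); vectorized over samples.
#' @examples
#' spike_scaling_factor(1e6, 100, primary_genome_bp = 1e6)  # 100
#' @export
spike_scaling_factor <- function(primary_reads, spike_reads,
                                 primary_genome_bp = 2654895218) {
  if (any(primary_reads <= 0)) stop("spike_scaling_factor: primary_reads must be > 0")
  if (any(primary_genome_bp <= 0)) stop("spike_scaling_factor: genome size must be > 0")
  if (any(spike_reads <= 0))
    stop("spike_scaling_factor: spike_reads must be > 0; calibration impossible")
  ((primary_reads / primary_genome_bp) / spike_reads) * 10000
}

## Per-region weighted bin sum for one chromosome vector.
region_bin_sum <- function(v, bin_size, start, end) {
  b0 <- floor(start / bin_size)
  b1 <- floor((end - 1) / bin_size)
  idx <- b0:b1
  lo <- pmax(start, idx * bin_size)
  hi <- pmin(end, (idx + 1) * bin_size)
  w <- (hi - lo) / bin_size
  inside <- idx + 1 <= length(v) & idx >= 0
  sum(v[idx[inside] + 1] * w[inside])
}

#' Count track signal in regions
#'
#' Per region, the sum of bin counts weighted by the fraction of each bin the
#' region covers (so a region covering half of a 100 bp bin with count 10
#' contributes 5). Regions extending beyond the track raise a warning and
#' count the missing part as 0.
#'
#' @param track a `binned_track`.
#' @param regions an `interval_set`.
#' @return Numeric vector of weighted counts, one per region (in region
#'   order).
#' @export
count_in_intervals <- function(track, regions) {
  n <- nrow(regions)
  out <- numeric(n)
  warned <- FALSE
  for (i in seq_len(n)) {
    ch <- regions$chrom[i]
    v <- track$counts[[ch]]
    if (is.null(v)) {
      warned <- TRUE
      next
    }
    if (regions$end[i] > length(v) * track$bin_size) warned <- TRUE
    out[i] <- region_bin_sum(v, track$bin_size, regions$start[i], regions$end[i])
  }
  if (warned) warning("count_in_intervals: region(s) beyond track extent; counted as 0")
  out
}

#' Count matrix over regions for several tracks
#'
#' @param tracks named list of `binned_track`s (names become column names).
#' @param regions an `interval_set`; `id` becomes rownames when present.
#' @return Numeric matrix, regions x samples.
#' @export
count_matrix <- function(tracks, regions) {
  m <- vapply(tracks, count_in_intervals, numeric(nrow(regions)),
              regions = regions)
  m <- matrix(m, nrow = nrow(regions),
              dimnames = list(regions$id, names(tracks)))
  m
}

#' RPKM normalization
#'
#' Reads per kilobase per million mapped reads:
#' `count / (length_kb * mapped_reads_millions)`, elementwise.
#'
#' @param counts matrix (features x samples) or vector.
#' @param lengths_bp feature lengths in bp.
#' @param mapped_reads per-sample total mapped reads (library sizes).
#' @return Matrix of RPKM values with the shape of `counts`.
#' @export
rpkm <- function(counts, lengths_bp, mapped_reads) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths_bp) == nrow(counts),
            length(mapped_reads) == ncol(counts))
  if (any(mapped_reads <= 0)) stop("rpkm: zero library size")
  sweep(counts / (lengths_bp / 1000), 2, mapped_reads / 1e6, `/`)
}

#' CPM normalization
#'
#' Counts per million: `count * 1e6 / column_sum`.
#'
#' @param counts matrix (features x samples).
#' @return Matrix of CPM values; every column sums to 1e6.
#' @export
cpm <- function(counts) {
  counts <- as.matrix(counts)
  cs <- colSums(counts)
  if (any(cs == 0)) stop("cpm: all-zero column")
  sweep(counts, 2, cs / 1e6, `/`)
}

## Centered running mean with truncated windows at the edges.
running_mean <- function(x, halfwidth) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(0, i - 1 - halfwidth)
  hi <- pmin(n, i + halfwidth)
  (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
}

#' Local-background Poisson broad-peak caller
#'
#' A transparent stand-in for broad peak calling on binned fragment counts:
#' each bin is tested against `lambda = max(lambda_genome, lambda_local)`,
#' where `lambda_genome` is the genome-wide mean bin count and
#' `lambda_local` the mean over a centered window (default 10 kb), with an
#' upper-tail Poisson p-value. Benjamini-Hochberg FDR is applied across all
#' bins genome-wide; maximal runs of significant bins become peaks, merged
#' within `merge_gap` and filtered to a minimum length.
#'
#' @param track a `binned_track` (one sample, or replicates pooled with
#'   [pool_tracks()]).
#' @param qvalue_cutoff BH-FDR cutoff for significant bins (default 0.1,
#'   the usual broad-peak cutoff).
#' @param merge_gap fuse peaks closer than this many bp (default 500).
#' @param min_len drop peaks shorter than this many bp (default 200).
#' @param local_window width of the local background window in bp
#'   (default 10000).
#' @return An `interval_set` of peaks.
#' @export
call_broad_peaks <- function(track, qvalue_cutoff = 0.1, merge_gap = 500,
                             min_len = 200, local_window = 10000) {
  bs <- track$bin_size
  allv <- unlist(track$counts, use.names = FALSE)
  if (length(allv) == 0 || sum(allv) == 0) return(empty_interval_set())
  lambda_genome <- mean(allv)
  hw <- max(1, round(local_window / bs / 2))
  pvals <- lapply(track$counts, function(v) {
    lam <- pmax(lambda_genome, running_mean(v, hw))
    stats::ppois(v - 1, lam, lower.tail = FALSE)
  })
  fdr <- stats::p.adjust(unlist(pvals, use.names = FALSE), method = "BH")
  nb <- vapply(track$counts, length, integer(1))
  offs <- c(0, cumsum(nb))
  peaks <- list()
  for (k in seq_along(track$counts)) {
    ch <- names(track$counts)[k]
    sig <- fdr[(offs[k] + 1):offs[k + 1]] <= qvalue_cutoff &
      track$counts[[k]] > 0
    if (!any(sig)) next
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- c(0, ends[-length(ends)])
    keep <- r$values
    peaks[[ch]] <- data.frame(chrom = ch, start = starts[keep] * bs,
                              end = ends[keep] * bs,
                              stringsAsFactors = FALSE)
  }
  if (length(peaks) == 0) return(empty_interval_set())
  out <- merge_intervals(as_interval_set(do.call(rbind, peaks)), merge_gap)
  out <- out[out$end - out$start >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interval_set", "data.frame")
  if (nrow(out) > 0)
    out$id <- sprintf("peak_%04d", seq_len(nrow(out)))
  out
}

#' Coverage metaprofile around region midpoints
#'
#' Per region, signal is summarized in `nbins` equal windows spanning
#' `[midpoint - flank, midpoint + flank)`; windows falling off a chromosome
#' end are zero-padded. Values are weighted bin counts per window times
#' `scale_factors` (for example a spike-in factor or `1e6 / library size`
#' for CPM units).
#'
#' @param track a `binned_track`.
#' @param regions an `interval_set`.
#' @param flank half-width of the profiled window in bp (> 0).
#' @param nbins number of profile bins.
#' @param scale_factors scalar or per-region multiplier applied to the
#'   profile (default 1).
#' @return List with `matrix` (regions x nbins) and `mean` (column means).
#' @export
coverage_profile <- function(track, regions, flank = 2000, nbins = 40,
                             scale_factors = 1) {
  stopifnot(flank > 0, nbins >= 1)
  w <- 2 * flank / nbins
  n <- nrow(regions)
  m <- matrix(0, n, nbins)
  for (i in seq_len(n)) {
    v <- track$counts[[regions$chrom[i]]]
    if (is.null(v)) next
    mid <- floor((regions$start[i] + regions$end[i]) / 2)
    lo <- mid - flank + (seq_len(nbins) - 1) * w
    hi <- lo + w
    tlen <- length(v) * track$bin_size
    for (j in seq_len(nbins)) {
      a <- max(0, lo[j]); b <- min(tlen, hi[j])
      if (b > a) m[i, j] <- region_bin_sum(v, track$bin_size, a, b)
    }
  }
  m <- m * scale_factors
  rownames(m) <- regions$id
  list(matrix = m, mean = colMeans(m))
}
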