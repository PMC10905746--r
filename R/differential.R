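#' Rescale counts to a common pseudo-library size
#'
#' Counts are multiplied by `L / lib_i` with `L` the geometric mean of the
#' (effective) library sizes and rounded to integers, so that all samples sit
#' on one depth scale before the exact test. For spike-calibrated occupancy
#' data the effective library size is `1 / spike_factor`; for expression data
#' it is the total mapped reads.
#'
#' @param counts matrix (features x samples) of non-negative integers.
#' @param lib_sizes positive per-sample (effective) library sizes.
#' @return List with `counts` (rescaled integer matrix) and `common` (the
#'   pseudo-library size).
#' @export
rescale_to_common <- function(counts, lib_sizes) {
  counts <- as.matrix(counts)
  stopifnot(length(lib_sizes) == ncol(counts), all(lib_sizes > 0))
  L <- exp(mean(log(lib_sizes)))
  list(counts = round(sweep(counts, 2, L / lib_sizes, `*`)), common = L)
}

#' Method-of-moments common NB dispersion
#'
#' After rescaling to a common pseudo-library size, the per-feature
#' dispersion is `phi_f = max(0, (s2 - m) / m^2)` with `m` the grand mean of
#' the rescaled counts and `s2` the pooled within-group sample variance
#' (variances are taken within genotype groups so treatment effects do not
#' inflate them). The common dispersion is the median of `phi_f` over
#' features with `m > min_mean`.
#'
#' @param counts matrix (features x samples).
#' @param lib_sizes per-sample effective library sizes.
#' @param groups factor/character of group labels; every group needs >= 2
#'   replicates.
#' @param min_mean mean-count filter for the median (default 5).
#' @return Common dispersion estimate `phi >= 0` (a single number).
#' @export
estimate_common_dispersion <- function(counts, lib_sizes, groups,
                                       min_mean = 5) {
  groups <- as.factor(groups)
  if (any(table(groups) < 2))
    stop("estimate_common_dispersion: every group needs >= 2 replicates")
  y <- rescale_to_common(counts, lib_sizes)$counts
  m <- rowMeans(y)
  ss <- 0
  df <- 0
  for (g in levels(groups)) {
    yg <- y[, groups == g, drop = FALSE]
    mg <- rowMeans(yg)
    ss <- ss + rowSums((yg - mg)^2)
    df <- df + ncol(yg) - 1
  }
  s2 <- ss / df
  phi_f <- pmax(0, (s2 - m) / m^2)
  keep <- m > min_mean
  if (!any(keep))
    stop("estimate_common_dispersion: no feature passes the mean filter")
  stats::median(phi_f[keep])
}

## Conditional law of the group-a sum given the total, on the rescaled
## scale: Y_a ~ NB(n_a * mu, phi / n_a), Y_b ~ NB(n_b * mu, phi / n_b).
## Returns the two-sided exact p (sum of conditional probabilities <= that
## of the observed split, the "minlike" rule).
nb_exact_p <- function(sum_a, sum_b, n_a, n_b, phi, max_enum = 1e6) {
  n <- sum_a + sum_b
  if (n == 0) return(1)
  if (n > max_enum)
    stop("nb_exact_test: total count exceeds the enumeration bound (",
         format(max_enum, scientific = FALSE),
         "); increase max_enum to force enumeration")
  mu <- n / (n_a + n_b)
  y <- 0:n
  if (phi == 0) {
    lp <- stats::dpois(y, n_a * mu, log = TRUE) +
      stats::dpois(n - y, n_b * mu, log = TRUE)
  } else {
    lp <- stats::dnbinom(y, size = n_a / phi, mu = n_a * mu, log = TRUE) +
      stats::dnbinom(n - y, size = n_b / phi, mu = n_b * mu, log = TRUE)
  }
  M <- max(lp)
  w <- exp(lp - M)
  p <- sum(w[lp <= lp[sum_a + 1] + 1e-10]) / sum(w)
  min(1, p)
}

#' Sum-conditional negative-binomial exact test
#'
#' Two-sided exact test for a difference in mean between two groups of NB
#' counts with common dispersion `phi`. Counts are rescaled to a common
#' pseudo-library size with [rescale_to_common()] and summed per group; the
#' group-A sum is then compared with its conditional law given the total
#' (group sums of n iid NB(mu, phi) variables are NB(n mu, phi/n)). The
#' p-value sums conditional probabilities no larger than the observed one,
#' so it is invariant to swapping the group labels and to uniform rescaling
#' of all library sizes. With `phi = 0` it reduces to the conditional
#' binomial exact test.
#'
#' @param counts_a,counts_b per-replicate counts in each group.
#' @param lib_sizes_a,lib_sizes_b effective library sizes (same order).
#' @param phi common NB dispersion (>= 0).
#' @param max_enum refuse to enumerate totals above this bound.
#' @return Two-sided p-value.
#' @export
nb_exact_test <- function(counts_a, counts_b, lib_sizes_a, lib_sizes_b,
                          phi, max_enum = 1e6) {
  stopifnot(phi >= 0)
  y <- rescale_to_common(matrix(c(counts_a, counts_b), nrow = 1),
                         c(lib_sizes_a, lib_sizes_b))$counts
  n_a <- length(counts_a)
  nb_exact_p(sum(y[1, seq_len(n_a)]), sum(y[1, -seq_len(n_a)]),
             n_a, length(counts_b), phi, max_enum)
}

#' Differential test over a count matrix
#'
#' Runs the NB exact test feature by feature and reports normalized group
#' means, `logFC = log2(mean_b / mean_a)` (with a small prior count of 0.5
#' on each mean so the fold change stays finite), p-values and BH FDR.
#'
#' @param counts matrix (features x samples); rownames are feature ids.
#' @param groups two-level factor aligned with columns; the first level is
#'   group A (the reference, e.g. WT). A character vector is taken in
#'   first-appearance order.
#' @param lib_sizes per-sample effective library sizes.
#' @param phi common dispersion; estimated with
#'   [estimate_common_dispersion()] when `NULL`.
#' @param max_enum enumeration bound passed to the exact test.
#' @return Data frame: `feature`, `mean_a`, `mean_b`, `logFC`, `pvalue`,
#'   `fdr`.
#' @export
nb_test_matrix <- function(counts, groups, lib_sizes, phi = NULL,
                           max_enum = 1e6) {
  counts <- as.matrix(counts)
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  stopifnot(nlevels(groups) == 2, length(groups) == ncol(counts))
  if (is.null(phi))
    phi <- estimate_common_dispersion(counts, lib_sizes, groups)
  y <- rescale_to_common(counts, lib_sizes)$counts
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])
  sa <- rowSums(y[, ia, drop = FALSE])
  sb <- rowSums(y[, ib, drop = FALSE])
  mean_a <- sa / length(ia)
  mean_b <- sb / length(ib)
  pv <- vapply(seq_len(nrow(y)), function(i) {
    nb_exact_p(sa[i], sb[i], length(ia), length(ib), phi, max_enum)
  }, numeric(1))
  data.frame(
    feature = if (!is.null(rownames(counts))) rownames(counts)
              else as.character(seq_len(nrow(counts))),
    mean_a = mean_a, mean_b = mean_b,
    logFC = log2((mean_b + 0.5) / (mean_a + 0.5)),
    pvalue = pv, fdr = bh_fdr(pv),
    stringsAsFactors = FALSE
  )
}

#' Median-of-ratios effective library sizes
#'
#' Composition-robust library sizes for expression testing: each sample's
#' size is the median ratio of its counts to the per-gene geometric-mean
#' reference, computed over genes with all-positive counts. When a large
#' fraction of the count mass shifts (for example many direct targets
#' losing expression in a knockout), raw total counts absorb part of the
#' effect into the normalization; the median ratio tracks the unchanged
#' majority of genes instead, which is what TMM-style normalization does
#' in standard differential-expression tools.
#'
#' @param counts matrix (genes x samples) of non-negative counts.
#' @return Positive per-sample effective library sizes (relative scale).
#' @export
median_ratio_lib_sizes <- function(counts) {
  counts <- as.matrix(counts)
  lg <- rowMeans(log(counts))
  use <- is.finite(lg)
  if (!any(use))
    stop("median_ratio_lib_sizes: no gene with all-positive counts")
  f <- apply(counts, 2, function(y) {
    exp(stats::median(log(y[use]) - lg[use]))
  })
  if (any(!is.finite(f) | f <= 0))
    stop("median_ratio_lib_sizes: degenerate size factor")
  f
}

#' Benjamini-Hochberg FDR
#'
#' Step-up BH adjustment with monotone enforcement (delegates to
#' `stats::p.adjust(method = "BH")`).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return Adjusted FDR values, same length.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Independent filtering of weak features
#'
#' Scans a grid of mean-normalized-count thresholds; for each threshold, BH
#' is applied only to features at or above it and the number of rejections
#' at `alpha` is recorded. The threshold maximizing rejections wins (ties go
#' to the smallest threshold, and 0 is always in the grid, so filtering can
#' never be forced). BH is then re-run on the surviving set; filtered-out
#' features get `NA` FDR.
#'
#' @param mean_counts per-feature mean normalized counts.
#' @param pvalues per-feature p-values.
#' @param grid candidate thresholds (0 is added if absent).
#' @param alpha FDR level used to count rejections (default 0.05).
#' @return List with `threshold`, `fdr` (NA below threshold),
#'   `n_rejected`, and the `grid` with rejection counts.
#' @export
independent_filter <- function(mean_counts, pvalues,
                               grid = c(0, 1, 2, 5, 10, 20, 50),
                               alpha = 0.05) {
  stopifnot(length(mean_counts) == length(pvalues), length(grid) >= 1)
  grid <- sort(unique(c(0, grid)))
  rej <- vapply(grid, function(th) {
    keep <- mean_counts >= th
    if (!any(keep)) return(0L)
    sum(bh_fdr(pvalues[keep]) < alpha)
  }, integer(1))
  th <- grid[which.max(rej)]          # first max = smallest threshold
  keep <- mean_counts >= th
  fdr <- rep(NA_real_, length(pvalues))
  fdr[keep] <- bh_fdr(pvalues[keep])
  list(threshold = th, fdr = fdr, n_rejected = rej[which.max(rej)],
       grid = data.frame(threshold = grid, rejections = rej))
}

#' Per-gene expression-change flags
#'
#' Combines two knockout-versus-wild-type tests with the wild-type
#' differentiation trajectory tests into the flag table that drives target
#' and temporal classification. A gene is `expressed` when its wild-type
#' RPKM is at least `rpkm_min`; `down`/`up` per KO line requires
#' `fdr < fdr_cut` and a fold change past `logfc_cut` in that direction
#' (default `logfc_cut = 0`, i.e. FDR alone decides); `down_in_both`
#' additionally requires the gene to be expressed. Trajectory flags mark
#' significant wild-type increases D0->D3, D0->D6 and D3->D6, and
#' `osteogenic` is their union. `severe_down_in_both`/`severe_up_in_both`
#' use `|logFC| >= severe_logfc` (default 1) in both lines.
#'
#' @param de_ko1,de_ko2 results from [nb_test_matrix()] with WT as group A
#'   and the KO line as group B, over the same gene universe.
#' @param traj named list of WT-only trajectory results `d0_d3`, `d0_d6`,
#'   `d3_d6` (earlier timepoint as group A); any may be `NULL`.
#' @param wt_rpkm per-gene wild-type mean RPKM, aligned with the universe.
#' @param rpkm_min expressed-gene cutoff (default 1).
#' @param fdr_cut significance cutoff (default 0.05).
#' @param logfc_cut extra |logFC| requirement for up/down calls (default 0).
#' @param severe_logfc |logFC| for the severe-misregulation flags.
#' @return Data frame of per-gene logical flags plus the per-line logFC/FDR.
#' @export
classify_expression_changes <- function(de_ko1, de_ko2, traj = NULL,
                                        wt_rpkm, rpkm_min = 1,
                                        fdr_cut = 0.05, logfc_cut = 0,
                                        severe_logfc = 1) {
  if (!identical(de_ko1$feature, de_ko2$feature))
    stop("classify_expression_changes: gene universes differ")
  stopifnot(length(wt_rpkm) == nrow(de_ko1))
  dn <- function(d) d$fdr < fdr_cut & d$logFC < 0 & -d$logFC >= logfc_cut
  up <- function(d) d$fdr < fdr_cut & d$logFC > 0 & d$logFC >= logfc_cut
  out <- data.frame(
    gene_id = de_ko1$feature,
    wt_rpkm = wt_rpkm,
    expressed = wt_rpkm >= rpkm_min,
    logFC_ko1 = de_ko1$logFC, fdr_ko1 = de_ko1$fdr,
    logFC_ko2 = de_ko2$logFC, fdr_ko2 = de_ko2$fdr,
    down_ko1 = dn(de_ko1), down_ko2 = dn(de_ko2),
    up_ko1 = up(de_ko1), up_ko2 = up(de_ko2),
    stringsAsFactors = FALSE
  )
  out$down_in_both <- out$expressed & out$down_ko1 & out$down_ko2
  out$up_in_both <- out$expressed & out$up_ko1 & out$up_ko2
  out$severe_down_in_both <- out$down_in_both &
    -de_ko1$logFC >= severe_logfc & -de_ko2$logFC >= severe_logfc
  out$severe_up_in_both <- out$up_in_both &
    de_ko1$logFC >= severe_logfc & de_ko2$logFC >= severe_logfc
  inc <- function(d) {
    if (is.null(d)) return(rep(FALSE, nrow(out)))
    if (!identical(d$feature, out$gene_id))
      stop("classify_expression_changes: trajectory gene universe differs")
    d$fdr < fdr_cut & d$logFC > 0 & d$logFC >= logfc_cut
  }
  out$increase_d0_d3 <- inc(traj$d0_d3)
  out$increase_d0_d6 <- inc(traj$d0_d6)
  out$increase_d3_d6 <- inc(traj$d3_d6)
  out$osteogenic <- out$increase_d0_d3 | out$increase_d0_d6 | out$increase_d3_d6
  out
}

#' Write a differential-result table
#'
#' TSV with columns `feature`, `mean_a`, `mean_b`, `logFC`, `pvalue`, `FDR`
#' (plus any extra flag columns present).
#'
#' @param x differential result data frame.
#' @param path file path.
#' @export
write_differential_table <- function(x, path) {
  names(x)[names(x) == "fdr"] <- "FDR"
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
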