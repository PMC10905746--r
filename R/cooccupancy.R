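#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact p by full hypergeometric enumeration: with row margin `a + b`,
#' the conditional law of cell `a` given all margins is hypergeometric, and
#' the two-sided p sums the probabilities of all outcomes no more likely
#' than the observed one (with a 1e-7 relative tie tolerance on the
#' discrete probabilities). The odds ratio is `ad / bc`, with the Haldane
#' correction (+0.5 on every cell) when any cell is zero.
#'
#' @param a,b,c,d non-negative cell counts, laid out as rows
#'   `(a, b)` / `(c, d)`.
#' @return List with `odds_ratio`, `p_value` and the `table`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("fisher_exact_2x2: negative cell")
  if (a + b + c + d == 0) stop("fisher_exact_2x2: empty table")
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(x, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
  or <- if (any(c(a, b, c, d) == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p_value = p,
       table = matrix(c(a, c, b, d), 2, 2,
                      dimnames = list(c("x", "not_x"), c("y", "not_y"))))
}

#' Co-occupancy Fisher test over an enhancer universe
#'
#' Builds the 2x2 table of (bound by factor A) x (bound by factor B) over
#' the members of a universe of regions -- by default all annotated
#' enhancers at the matching timepoint -- and tests association with the
#' exact hypergeometric enumeration of [fisher_exact_2x2()].
#'
#' @param bound_peaks `interval_set` of peaks for the first factor (e.g.
#'   retained BRD4 peaks).
#' @param partner_peaks `interval_set` for the second factor (e.g. RUNX2).
#' @param universe non-empty `interval_set` partitioned by overlap flags.
#' @return List with `odds_ratio`, `p_value`, `table`, and the per-member
#'   logical `bound` / `partner` flags.
#' @export
fisher_cooccupancy <- function(bound_peaks, partner_peaks, universe) {
  if (nrow(universe) == 0) stop("fisher_cooccupancy: empty universe")
  u <- as_interval_set(as.data.frame(universe))
  f1 <- overlaps_any(u, bound_peaks)
  f2 <- overlaps_any(u, partner_peaks)
  ft <- fisher_exact_2x2(sum(f1 & f2), sum(f1 & !f2),
                         sum(!f1 & f2), sum(!f1 & !f2))
  c(ft, list(bound = f1, partner = f2, universe = u))
}

#' Classify loss of factor occupancy in the knockout
#'
#' Per wild-type peak of a factor (e.g. RUNX2), flags `sig_loss` when the
#' NB exact test shows significant wild-type excess (`FDR <= fdr_cut`,
#' negative logFC toward the knockout) and `wt_specific` when the peak
#' overlaps no knockout-called peak; `lost` is their union. When a
#' misexpressed gene set is supplied, the closest such gene within
#' `max_dist` is reported (`near_misexpressed`).
#'
#' @param wt_peaks wild-type peak `interval_set` with unique ids.
#' @param ko_peaks knockout peak `interval_set` (empty set makes every WT
#'   peak `wt_specific`).
#' @param counts matrix peaks x samples of counts at `wt_peaks`.
#' @param samples sample sheet rows aligned with columns (genotype WT/KO).
#' @param effective_lib_sizes per-sample effective library sizes (defaults
#'   to column sums, i.e. per-library normalization, appropriate when the
#'   loss is local rather than global).
#' @param misexpressed_genes optional gene-model data frame restricted to
#'   misexpressed genes.
#' @param max_dist proximity cutoff in bp (default 50000).
#' @param fdr_cut significance cutoff (default 0.05).
#' @param phi common dispersion; estimated when `NULL`.
#' @return Data frame of per-peak flags, means, logFC and FDR.
#' @export
classify_factor_loss <- function(wt_peaks, ko_peaks, counts, samples,
                                 effective_lib_sizes = NULL,
                                 misexpressed_genes = NULL,
                                 max_dist = 50000, fdr_cut = 0.05,
                                 phi = NULL) {
  stopifnot(nrow(wt_peaks) == nrow(counts))
  if (any(is.na(counts))) stop("classify_factor_loss: missing counts for a peak")
  if (is.null(effective_lib_sizes)) effective_lib_sizes <- colSums(counts)
  wt <- samples$genotype == "WT"
  de <- nb_test_matrix(counts, factor(ifelse(wt, "WT", "KO"),
                                      levels = c("WT", "KO")),
                       effective_lib_sizes, phi = phi)
  sig_loss <- de$fdr <= fdr_cut & de$logFC < 0
  wt_specific <- !overlaps_any(wt_peaks, ko_peaks)
  out <- data.frame(
    chrom = wt_peaks$chrom, start = wt_peaks$start, end = wt_peaks$end,
    id = wt_peaks$id,
    mean_wt = de$mean_a, mean_ko = de$mean_b,
    logFC = de$logFC, fdr = de$fdr,
    sig_loss = sig_loss, wt_specific = wt_specific,
    lost = sig_loss | wt_specific,
    stringsAsFactors = FALSE
  )
  if (!is.null(misexpressed_genes) && nrow(misexpressed_genes) > 0) {
    cl <- closest_distance(wt_peaks, misexpressed_genes)
    out$nearest_misexpressed_gene <- cl$gene_id
    out$gene_distance <- cl$distance
    out$near_misexpressed <- !is.na(cl$distance) & cl$distance <= max_dist
  } else {
    out$nearest_misexpressed_gene <- NA_character_
    out$gene_distance <- NA_real_
    out$near_misexpressed <- FALSE
  }
  out
}

#' Per-class signal comparison by Student's t-test
#'
#' For each enhancer class, compares the per-enhancer signal (e.g. mean
#' RUNX2 RPKM) between two conditions with an unpaired, two-tailed
#' Student's t-test (pooled variance). Classes with fewer than two
#' enhancers or zero pooled variance report `NA` statistics.
#'
#' @param signal_a,signal_b per-enhancer signal in the two conditions
#'   (e.g. WT and KO), aligned.
#' @param classes class label per enhancer.
#' @return Data frame: `class`, `n`, `mean_a`, `mean_b`, `t`, `p_value`.
#' @export
class_signal_ttest <- function(signal_a, signal_b, classes) {
  stopifnot(length(signal_a) == length(signal_b),
            length(classes) == length(signal_a))
  res <- lapply(unique(classes), function(cl) {
    i <- which(classes == cl)
    xa <- signal_a[i]; xb <- signal_b[i]
    tt <- if (length(i) >= 2 && (stats::var(xa) > 0 || stats::var(xb) > 0)) {
      h <- stats::t.test(xa, xb, var.equal = TRUE)
      list(t = unname(h$statistic), p = h$p.value)
    } else {
      list(t = NA_real_, p = NA_real_)
    }
    data.frame(class = cl, n = length(i), mean_a = mean(xa),
               mean_b = mean(xb), t = tt$t, p_value = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
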