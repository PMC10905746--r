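#' Validate pooled peaks against replicates and knockout loss
#'
#' Applies the retention ladder for occupancy peaks called on pooled
#' wild-type replicates: (i) wild-type RPKM above `rpkm_min` (mean over WT
#' replicates), and (ii) either the peak is absent from the pooled knockout
#' peak set (`wt_only`) or it shows significant knockout loss in the
#' spike-calibrated NB exact test (`FDR < fdr_cut` with negative logFC).
#' Replicate support (the number of per-replicate peak sets overlapping the
#' pooled peak) is reported alongside.
#'
#' @param peaks pooled WT peaks, an `interval_set` with unique `id`s.
#' @param replicate_peaks list of per-replicate peak `interval_set`s.
#' @param ko_peaks pooled knockout peak `interval_set` (may be empty).
#' @param counts matrix peaks x samples of fragment counts covering every
#'   peak (missing peaks are an error).
#' @param samples sample sheet rows aligned with `counts` columns; the
#'   `genotype` column separates WT from KO.
#' @param effective_lib_sizes per-sample effective library sizes (for
#'   spike-calibrated data, `1 / spike_scaling_factor`).
#' @param rpkm_min RPKM retention cutoff (default 1).
#' @param fdr_cut knockout-loss significance cutoff (default 0.05).
#' @param phi common NB dispersion; estimated from `counts` when `NULL`.
#' @return A `validated_peaks` data frame: peak coordinates, `rpkm_wt`,
#'   `replicate_support`, `wt_only`, `ko_loss_logFC`, `ko_loss_fdr`,
#'   `retained`.
#' @export
validate_peaks <- function(peaks, replicate_peaks, ko_peaks, counts, samples,
                           effective_lib_sizes, rpkm_min = 1, fdr_cut = 0.05,
                           phi = NULL) {
  stopifnot(nrow(peaks) == nrow(counts))
  if (any(is.na(counts))) stop("validate_peaks: missing counts for a peak")
  wt <- samples$genotype == "WT"
  stopifnot(any(wt), any(!wt))
  lens <- peaks$end - peaks$start
  rpkm_wt <- rowMeans(rpkm(counts[, wt, drop = FALSE], lens,
                           samples$primary_mapped_reads[wt]))
  support <- rowSums(matrix(vapply(replicate_peaks,
                                   function(rp) overlaps_any(peaks, rp),
                                   logical(nrow(peaks))),
                            nrow = nrow(peaks)))
  wt_only <- !overlaps_any(peaks, ko_peaks)
  de <- nb_test_matrix(counts, factor(ifelse(wt, "WT", "KO"),
                                      levels = c("WT", "KO")),
                       effective_lib_sizes, phi = phi)
  loss <- de$fdr < fdr_cut & de$logFC < 0
  out <- data.frame(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end, id = peaks$id,
    rpkm_wt = rpkm_wt,
    replicate_support = as.integer(support),
    wt_only = wt_only,
    ko_loss_logFC = de$logFC, ko_loss_fdr = de$fdr,
    retained = rpkm_wt > rpkm_min & (wt_only | loss),
    stringsAsFactors = FALSE
  )
  class(out) <- c("validated_peaks", "data.frame")
  out
}

#' Promoter/enhancer annotation of validated peaks
#'
#' A peak overlapping any TSS window is a `promoter` (TSS takes precedence);
#' otherwise a peak overlapping an H3K27ac peak is an `enhancer`; peaks
#' overlapping neither stay unannotated (`NA`) and are excluded from
#' enhancer sets downstream.
#'
#' @param validated validated-peak table from [validate_peaks()].
#' @param k27ac_peaks H3K27ac peak `interval_set` for the matching
#'   timepoint.
#' @param tss `interval_set` of TSS windows from [tss_windows()].
#' @return `validated` with a `cis_class` column (`"promoter"`,
#'   `"enhancer"`, or `NA`).
#' @export
annotate_cis_class <- function(validated, k27ac_peaks, tss) {
  # overlaps_any needs sorted input; compute on a sorted copy, map back by id
  sorted <- as_interval_set(validated[, c("chrom", "start", "end", "id")])
  tss_hit <- overlaps_any(sorted, tss)[match(validated$id, sorted$id)]
  k27_hit <- overlaps_any(sorted, k27ac_peaks)[match(validated$id, sorted$id)]
  validated$cis_class <- ifelse(tss_hit, "promoter",
                                ifelse(k27_hit, "enhancer", NA_character_))
  validated
}

#' Super-enhancer calling by the rank-curve tangent rule
#'
#' Enhancers are scored by normalized signal density (normalized H3K27ac
#' count divided by enhancer length), sorted ascending, and both rank and
#' density are rescaled to `[0, 1]`. The cutoff is the tangent point of a
#' line of slope 1 touching the hockey-stick curve from below -- the rank
#' minimizing `y - x`, where the curve is furthest below the unit diagonal
#' and its slope crosses 1. Enhancers whose rescaled density exceeds the
#' curve height at that rank are flagged. The tangent-distance form of the
#' rule is robust to isolated outliers and plateaus that make pointwise
#' slope estimates noisy. A flat curve (all densities equal) yields zero
#' super-enhancers.
#'
#' @param enhancers `interval_set` of enhancers (>= 10 required).
#' @param norm_counts normalized signal per enhancer (same order), e.g.
#'   spike-scaled or CPM-scaled H3K27ac counts.
#' @return List with `flags` (logical per enhancer, input order), `curve`
#'   (data frame `id`, `rank`, `x`, `y`, `density`) and `cutoff_rank`
#'   (NA when nothing is flagged).
#' @export
call_super_enhancers <- function(enhancers, norm_counts) {
  n <- nrow(enhancers)
  if (n < 10) stop("call_super_enhancers: need >= 10 enhancers")
  stopifnot(length(norm_counts) == n)
  density <- norm_counts / (enhancers$end - enhancers$start)
  o <- order(density)
  d <- density[o]
  flags <- logical(n)
  x <- (seq_len(n) - 1) / (n - 1)
  rng <- max(d) - min(d)
  if (rng == 0) {
    curve <- data.frame(id = enhancers$id[o], rank = seq_len(n), x = x,
                        y = 0, density = d, stringsAsFactors = FALSE)
    return(list(flags = flags, curve = curve, cutoff_rank = NA_integer_))
  }
  y <- (d - min(d)) / rng
  cutoff <- which.min(y - x)
  flags[o[y > y[cutoff]]] <- TRUE
  if (!any(flags)) cutoff <- NA_integer_
  curve <- data.frame(id = enhancers$id[o], rank = seq_len(n), x = x, y = y,
                      density = d, stringsAsFactors = FALSE)
  list(flags = flags, curve = curve, cutoff_rank = cutoff)
}

#' Assign target genes within a distance cutoff
#'
#' Links every retained peak to every gene flagged down in both knockout
#' lines whose body lies within `max_dist` bp (unsigned gap; 0 when
#' overlapping). Peaks may hit several genes and genes several peaks.
#' Expanding `max_dist` never removes links.
#'
#' @param validated validated-peak table (only `retained` rows are linked).
#' @param genes gene-model data frame.
#' @param expr_flags flag table from [classify_expression_changes()].
#' @param max_dist maximum peak-gene gap in bp (default 50000).
#' @return Data frame: `peak_id`, `chrom`, `start`, `end`, `gene_id`,
#'   `distance`, `gene_down_in_both`, `gene_osteogenic`.
#' @export
assign_target_genes <- function(validated, genes, expr_flags,
                                max_dist = 50000) {
  vp <- validated[validated$retained, , drop = FALSE]
  down <- expr_flags$gene_id[expr_flags$down_in_both]
  g <- genes[genes$gene_id %in% down, , drop = FALSE]
  rows <- vector("list", nrow(vp))
  for (i in seq_len(nrow(vp))) {
    gi <- which(g$chrom == vp$chrom[i])
    if (length(gi) == 0) next
    d <- pmax(0, pmax(g$start[gi] - vp$end[i], vp$start[i] - g$end[gi]))
    hit <- which(d <= max_dist)
    if (length(hit) == 0) next
    rows[[i]] <- data.frame(
      peak_id = vp$id[i], chrom = vp$chrom[i], start = vp$start[i],
      end = vp$end[i], gene_id = g$gene_id[gi][hit], distance = d[hit],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(peak_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      gene_id = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  out$gene_down_in_both <- rep(TRUE, nrow(out))
  out$gene_osteogenic <-
    expr_flags$osteogenic[match(out$gene_id, expr_flags$gene_id)]
  rownames(out) <- NULL
  out
}

#' Temporal enhancer classes
#'
#' Classifies each (enhancer peak, linked gene) pair per timepoint:
#' a D0-bound enhancer whose linked affected gene shows no significant
#' wild-type increase in any of D0->D3, D0->D6, D3->D6 is a `stem`
#' enhancer; a D3-bound enhancer with an increasing linked gene is
#' `early_osteogenic`; a D6-bound enhancer with an increasing linked gene is
#' `late_osteogenic`. Links that contradict their timepoint (for example a
#' D0 enhancer whose gene is induced) and enhancers without any link are
#' `unclassified`. An enhancer bound at both D3 and D6 can be early in the
#' D3 table and late in the D6 table; the tables are kept separate.
#'
#' @param annotated_by_tp named list (`D0`, `D3`, `D6`) of annotated
#'   validated-peak tables from [annotate_cis_class()].
#' @param targets_by_tp named list of target tables from
#'   [assign_target_genes()] for the matching timepoints.
#' @param expr_flags_by_tp named list of flag tables from
#'   [classify_expression_changes()]; the trajectory columns must come from
#'   WT-only comparisons.
#' @return Named list of per-timepoint data frames: `peak_id`, `gene_id`,
#'   `temporal_class`.
#' @export
temporal_classify <- function(annotated_by_tp, targets_by_tp,
                              expr_flags_by_tp) {
  out <- list()
  for (tp in names(annotated_by_tp)) {
    ann <- annotated_by_tp[[tp]]
    enh <- ann[!is.na(ann$cis_class) & ann$cis_class == "enhancer" &
                 ann$retained, , drop = FALSE]
    tg <- targets_by_tp[[tp]]
    fl <- expr_flags_by_tp[[tp]]
    links <- tg[tg$peak_id %in% enh$id, , drop = FALSE]
    osteo <- fl$osteogenic[match(links$gene_id, fl$gene_id)]
    cls <- rep("unclassified", nrow(links))
    if (tp == "D0") cls[!osteo] <- "stem"
    if (tp == "D3") cls[osteo] <- "early_osteogenic"
    if (tp == "D6") cls[osteo] <- "late_osteogenic"
    res <- data.frame(peak_id = links$peak_id, gene_id = links$gene_id,
                      temporal_class = cls, stringsAsFactors = FALSE)
    orphan <- setdiff(enh$id, links$peak_id)
    if (length(orphan))
      res <- rbind(res, data.frame(peak_id = orphan, gene_id = NA_character_,
                                   temporal_class = "unclassified",
                                   stringsAsFactors = FALSE))
    res <- res[order(res$peak_id, res$gene_id), , drop = FALSE]
    rownames(res) <- NULL
    out[[tp]] <- res
  }
  out
}
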