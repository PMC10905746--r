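#' Pipeline configuration
#'
#' Flat key/value configuration with validated defaults mirroring the
#' analysis constants: peaks retained at RPKM > 1, significance at
#' FDR < 0.05, promoters as TSS +/- 500 bp, target genes within 50 kb,
#' broad peaks at q-value 0.1. Unknown keys are errors, which guards
#' against silent typos in thresholds.
#'
#' @param ... overrides for the defaults listed below.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    rpkm_min = 1,
    fdr = 0.05,
    logfc_cut = 0,
    tss_halfwidth = 500,
    target_max_dist = 50000,
    peak_qvalue = 0.1,
    peak_merge_gap = 500,
    peak_min_len = 200,
    peak_local_window = 10000,
    se_min_enhancers = 10,
    primary_genome_bp = 2654895218,
    profile_flank = 2000,
    profile_nbins = 40,
    verbose = FALSE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("pipeline_config: unknown option(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(
    cfg$rpkm_min >= 0, cfg$fdr > 0, cfg$fdr < 1, cfg$logfc_cut >= 0,
    cfg$tss_halfwidth > 0, cfg$target_max_dist >= 0,
    cfg$peak_qvalue > 0, cfg$peak_merge_gap >= 0, cfg$peak_min_len >= 0,
    cfg$peak_local_window > 0, cfg$primary_genome_bp > 0
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The file is a flat key/value document; keys mirror the arguments of
#' [pipeline_config()] and unknown keys are errors.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

plog <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbose)) message(sprintf(paste0("[calenh] ", fmt), ...))
}

parse_region_names <- function(x) {
  m <- regmatches(x, regexec("^(.+):([0-9]+)-([0-9]+)$", x))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) stop("cannot parse region name(s): ",
                     paste(utils::head(x[bad]), collapse = ", "))
  data.frame(chrom = vapply(m, `[`, "", 2),
             start = as.numeric(vapply(m, `[`, "", 3)),
             end = as.numeric(vapply(m, `[`, "", 4)),
             id = x, stringsAsFactors = FALSE)
}

#' Run the full analysis on an input bundle
#'
#' Executes the analysis ladder in order: broad-peak calling on pooled
#' wild-type replicates per timepoint, spike-calibrated peak validation
#' against the knockout, promoter/enhancer annotation against TSS windows
#' and H3K27ac peaks, super-enhancer calling on the H3K27ac enhancer
#' universe, differential expression and trajectory flags, 50 kb
#' target-gene assignment, temporal enhancer classes, RUNX2 co-occupancy
#' and knockout-loss statistics, per-class signal t-tests, coverage
#' metaprofiles, and motif enrichment at bound versus unbound enhancers.
#' The run is a pure function of its inputs: identical inputs give
#' bit-identical outputs.
#'
#' @param bundle input bundle from [simulate_bundle()] or [read_bundle()].
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, master tables (TSV), BED
#'   exports and a JSON summary are written there.
#' @return Nested list with per-timepoint `validated`, `annotated`,
#'   `enhancer_universe`, `super_enhancers`, `expression`, `targets`,
#'   `temporal`, plus `runx2`, `profiles`, `motif` and `summary`.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(), outdir = NULL) {
  tracks <- bundle$occupancy$tracks
  osamp <- bundle$occupancy$samples
  genes <- bundle$genome$genes
  tps <- c("D0", "D3", "D6")
  tssw <- tss_windows(genes, config$tss_halfwidth)

  validated <- list(); annotated <- list(); universe_by_tp <- list()
  se_by_tp <- list(); flags_by_tp <- list(); targets_by_tp <- list()
  de_by_tp <- list()

  # WT-only differentiation trajectory (shared across timepoints)
  ernam <- bundle$expression$samples
  ecounts <- bundle$expression$counts
  elib <- ernam$primary_mapped_reads          # RPKM denominators
  esize <- median_ratio_lib_sizes(ecounts)    # composition-robust offsets
  traj <- list()
  for (cmp in list(c("D0", "D3"), c("D0", "D6"), c("D3", "D6"))) {
    sel <- ernam$genotype == "WT" & ernam$timepoint %in% cmp
    traj[[paste0(tolower(cmp[1]), "_", tolower(cmp[2]))]] <- nb_test_matrix(
      ecounts[, sel, drop = FALSE],
      factor(ernam$timepoint[sel], levels = cmp),
      esize[sel])
  }
  plog(config, "trajectory tests: %d genes x 3 comparisons", nrow(ecounts))

  for (tp in tps) {
    sel <- osamp$assay == "BRD4" & osamp$timepoint == tp
    samp <- osamp[sel, , drop = FALSE]
    wt_ids <- samp$sample_id[samp$genotype == "WT"]
    ko_ids <- samp$sample_id[samp$genotype != "WT"]
    pooled_wt <- pool_tracks(tracks[wt_ids])
    peaks <- call_broad_peaks(pooled_wt, config$peak_qvalue,
                              config$peak_merge_gap, config$peak_min_len,
                              config$peak_local_window)
    rep_peaks <- lapply(tracks[wt_ids], call_broad_peaks,
                        qvalue_cutoff = config$peak_qvalue,
                        merge_gap = config$peak_merge_gap,
                        min_len = config$peak_min_len,
                        local_window = config$peak_local_window)
    ko_peaks <- call_broad_peaks(pool_tracks(tracks[ko_ids]),
                                 config$peak_qvalue, config$peak_merge_gap,
                                 config$peak_min_len, config$peak_local_window)
    counts <- count_matrix(tracks[samp$sample_id], peaks)
    factors <- spike_scaling_factor(samp$primary_mapped_reads,
                                    samp$spike_mapped_reads,
                                    config$primary_genome_bp)
    vp <- validate_peaks(peaks, rep_peaks, ko_peaks, counts, samp,
                         1 / factors, config$rpkm_min, config$fdr)
    plog(config, "%s: %d pooled peaks, %d retained", tp, nrow(peaks),
         sum(vp$retained))

    k27_ids <- osamp$sample_id[osamp$assay == "H3K27ac" &
                                 osamp$timepoint == tp]
    k27_pooled <- pool_tracks(tracks[k27_ids])
    k27_peaks <- call_broad_peaks(k27_pooled, config$peak_qvalue,
                                  config$peak_merge_gap, config$peak_min_len,
                                  config$peak_local_window)
    ann <- annotate_cis_class(vp, k27_peaks, tssw)

    universe <- k27_peaks[!overlaps_any(k27_peaks, tssw), , drop = FALSE]
    class(universe) <- c("interval_set", "data.frame")
    if (nrow(universe) > 0)
      universe$id <- sprintf("enh_%s_%04d", tp, seq_len(nrow(universe)))
    k27_norm <- count_in_intervals(k27_pooled, universe) *
      1e6 / track_total(k27_pooled)
    se <- if (nrow(universe) >= config$se_min_enhancers)
      call_super_enhancers(universe, k27_norm)
    else list(flags = logical(nrow(universe)), curve = NULL,
              cutoff_rank = NA_integer_)
    se$universe <- universe
    se$bound <- overlaps_any(universe,
                             as_interval_set(vp[vp$retained,
                                                c("chrom", "start", "end", "id")]))
    sorted_ann <- as_interval_set(ann[, c("chrom", "start", "end", "id")])
    se_hit <- overlaps_any(sorted_ann,
                           universe[se$flags, , drop = FALSE])[
                             match(ann$id, sorted_ann$id)]
    ann$super_enhancer <- !is.na(ann$cis_class) & ann$cis_class == "enhancer" &
      se_hit
    plog(config, "%s: %d enhancer universe members, %d super-enhancers",
         tp, nrow(universe), sum(se$flags))

    # expression: WT vs each KO line at this timepoint
    de <- list()
    for (ko in c("KO1", "KO2")) {
      s2 <- ernam$genotype %in% c("WT", ko) & ernam$timepoint == tp
      de[[ko]] <- nb_test_matrix(ecounts[, s2, drop = FALSE],
                                 factor(ernam$genotype[s2],
                                        levels = c("WT", ko)),
                                 esize[s2])
    }
    wt_sel <- ernam$genotype == "WT" & ernam$timepoint == tp
    wt_rpkm <- rowMeans(rpkm(ecounts[, wt_sel, drop = FALSE],
                             genes$end - genes$start, elib[wt_sel]))
    flags <- classify_expression_changes(de$KO1, de$KO2, traj, wt_rpkm,
                                         config$rpkm_min, config$fdr,
                                         config$logfc_cut)
    targets <- assign_target_genes(ann, genes, flags, config$target_max_dist)
    plog(config, "%s: %d down-in-both genes, %d target links", tp,
         sum(flags$down_in_both), nrow(targets))

    validated[[tp]] <- vp; annotated[[tp]] <- ann
    universe_by_tp[[tp]] <- universe; se_by_tp[[tp]] <- se
    flags_by_tp[[tp]] <- flags; targets_by_tp[[tp]] <- targets
    de_by_tp[[tp]] <- de
  }

  temporal <- temporal_classify(annotated, targets_by_tp, flags_by_tp)

  # RUNX2 co-occupancy and knockout loss (D0)
  rsel <- osamp$assay == "RUNX2"
  rsamp <- osamp[rsel, , drop = FALSE]
  runx2 <- NULL
  profiles <- NULL
  if (nrow(rsamp) > 0) {
    wt_ids <- rsamp$sample_id[rsamp$genotype == "WT"]
    ko_ids <- rsamp$sample_id[rsamp$genotype != "WT"]
    rx_wt_peaks <- call_broad_peaks(pool_tracks(tracks[wt_ids]),
                                    config$peak_qvalue, config$peak_merge_gap,
                                    config$peak_min_len,
                                    config$peak_local_window)
    rx_ko_peaks <- call_broad_peaks(pool_tracks(tracks[ko_ids]),
                                    config$peak_qvalue, config$peak_merge_gap,
                                    config$peak_min_len,
                                    config$peak_local_window)
    rcounts <- count_matrix(tracks[rsamp$sample_id], rx_wt_peaks)
    fl0 <- flags_by_tp$D0
    mis <- genes[genes$gene_id %in%
                   fl0$gene_id[fl0$down_in_both | fl0$up_in_both], ,
                 drop = FALSE]
    loss <- classify_factor_loss(rx_wt_peaks, rx_ko_peaks, rcounts, rsamp,
                                 effective_lib_sizes = rsamp$primary_mapped_reads,
                                 misexpressed_genes = mis,
                                 max_dist = config$target_max_dist,
                                 fdr_cut = config$fdr)
    universe <- universe_by_tp$D0
    ret_any <- as_interval_set(do.call(rbind, lapply(validated, function(v)
      v[v$retained, c("chrom", "start", "end", "id")])))
    fisher <- fisher_cooccupancy(ret_any, rx_wt_peaks, universe)

    # per-enhancer RUNX2 RPKM by temporal class (WT vs KO)
    ucounts <- count_matrix(tracks[rsamp$sample_id], universe)
    urpkm <- rpkm(ucounts, universe$end - universe$start,
                  rsamp$primary_mapped_reads)
    wt_mean <- rowMeans(urpkm[, rsamp$genotype == "WT", drop = FALSE])
    ko_mean <- rowMeans(urpkm[, rsamp$genotype != "WT", drop = FALSE])
    cls <- rep("unbound", nrow(universe))
    for (tp in tps) {
      tcl <- temporal[[tp]]
      want <- switch(tp, D0 = "stem", D3 = "early_osteogenic",
                     D6 = "late_osteogenic")
      ids <- unique(tcl$peak_id[tcl$temporal_class == want])
      pk <- annotated[[tp]]
      pk <- as_interval_set(pk[pk$id %in% ids,
                               c("chrom", "start", "end", "id")])
      hit <- overlaps_any(universe, pk)
      cls[hit] <- want
    }
    cls[cls == "unbound" & fisher$bound] <- "other_bound"
    ttests <- class_signal_ttest(wt_mean, ko_mean, cls)
    runx2 <- list(peaks_wt = rx_wt_peaks, peaks_ko = rx_ko_peaks,
                  loss = loss, fisher = fisher, class_ttests = ttests,
                  class = cls, rpkm_wt = wt_mean, rpkm_ko = ko_mean)
    plog(config, "RUNX2: %d WT peaks, %d lost; co-occupancy p = %.3g",
         nrow(rx_wt_peaks), sum(loss$lost), fisher$p_value)

    rx_pool <- pool_tracks(tracks[wt_ids])
    sc <- 1e6 / track_total(rx_pool)
    profiles <- list(
      bound = coverage_profile(rx_pool,
                               universe[fisher$bound, , drop = FALSE],
                               config$profile_flank, config$profile_nbins,
                               sc)$mean,
      unbound = coverage_profile(rx_pool,
                                 universe[!fisher$bound, , drop = FALSE],
                                 config$profile_flank, config$profile_nbins,
                                 sc)$mean
    )
  }

  # motif enrichment: bound vs unbound enhancer sequences
  motif_res <- NULL
  if (!is.null(bundle$sequences) && !is.null(bundle$motif)) {
    regions <- as_interval_set(parse_region_names(names(bundle$sequences)))
    ret_all <- do.call(rbind, lapply(validated, function(v)
      v[v$retained, c("chrom", "start", "end", "id")]))
    ret_all <- as_interval_set(ret_all)
    bound_flag <- overlaps_any(regions, ret_all)
    bnd <- bundle$sequences[regions$id[bound_flag]]
    ubd <- bundle$sequences[regions$id[!bound_flag]]
    if (length(bnd) > 0 && length(ubd) > 0) {
      motif_res <- motif_enrichment(bnd, ubd, bundle$motif)
      motif_res$n_bound <- length(bnd)
      motif_res$n_background <- length(ubd)
      plog(config, "motif: %.2f bound vs %.2f background, p = %.3g",
           motif_res$frac_bound, motif_res$frac_background,
           motif_res$p_value)
    }
  }

  summary <- list(
    parameters = unclass(config),
    per_timepoint = lapply(tps, function(tp) {
      ann <- annotated[[tp]]
      list(
        timepoint = tp,
        n_pooled_peaks = nrow(ann),
        n_retained = sum(ann$retained),
        n_promoter = sum(ann$retained & !is.na(ann$cis_class) &
                           ann$cis_class == "promoter"),
        n_enhancer = sum(ann$retained & !is.na(ann$cis_class) &
                           ann$cis_class == "enhancer"),
        n_enhancer_universe = nrow(universe_by_tp[[tp]]),
        n_super_enhancer = sum(se_by_tp[[tp]]$flags),
        se_frac_bound = {
          se <- se_by_tp[[tp]]
          if (any(se$bound)) mean(se$flags[se$bound]) else NA_real_
        },
        se_frac_unbound = {
          se <- se_by_tp[[tp]]
          if (any(!se$bound)) mean(se$flags[!se$bound]) else NA_real_
        },
        n_down_in_both = sum(flags_by_tp[[tp]]$down_in_both),
        n_target_links = nrow(targets_by_tp[[tp]])
      )
    }),
    cooccupancy = if (!is.null(runx2)) list(
      odds_ratio = runx2$fisher$odds_ratio,
      p_value = runx2$fisher$p_value,
      table = as.vector(runx2$fisher$table)
    ),
    motif = if (!is.null(motif_res)) list(
      frac_bound = motif_res$frac_bound,
      frac_background = motif_res$frac_background,
      odds_ratio = motif_res$odds_ratio,
      p_value = motif_res$p_value
    )
  )
  names(summary$per_timepoint) <- tps

  results <- list(validated = validated, annotated = annotated,
                  enhancer_universe = universe_by_tp,
                  super_enhancers = se_by_tp, expression = flags_by_tp,
                  differential = de_by_tp, trajectory = traj,
                  targets = targets_by_tp, temporal = temporal,
                  runx2 = runx2, profiles = profiles, motif = motif_res,
                  summary = summary)
  if (!is.null(outdir)) write_results(results, outdir)
  results
}

## Serialize the master tables, BED exports and JSON summary.
write_results <- function(results, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(outdir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  for (tp in names(results$annotated)) {
    wt(results$annotated[[tp]], sprintf("validated_peaks_%s.tsv", tp))
    wt(results$targets[[tp]], sprintf("targets_%s.tsv", tp))
    wt(results$temporal[[tp]], sprintf("temporal_%s.tsv", tp))
    wt(results$expression[[tp]], sprintf("expression_flags_%s.tsv", tp))
    ann <- results$annotated[[tp]]
    for (klass in c("promoter", "enhancer")) {
      sub <- ann[ann$retained & !is.na(ann$cis_class) &
                   ann$cis_class == klass, , drop = FALSE]
      if (nrow(sub))
        write_bed(as_interval_set(sub[, c("chrom", "start", "end", "id")]),
                  file.path(outdir, sprintf("%s_%s.bed", klass, tp)))
    }
    se <- results$super_enhancers[[tp]]
    if (!is.null(se$curve))
      wt(se$curve, sprintf("se_curve_%s.tsv", tp))
  }
  if (!is.null(results$runx2)) {
    wt(results$runx2$loss, "runx2_loss.tsv")
    wt(results$runx2$class_ttests, "runx2_class_ttests.tsv")
  }
  jsonlite::write_json(results$summary, file.path(outdir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, na = "null",
                       pretty = TRUE)
  invisible(outdir)
}

#' One-command demonstration run on synthetic data
#'
#' Simulates a bundle from a seed, writes it to disk, reads it back, runs
#' the full pipeline, scores the result against the planted truth and
#' writes a machine-readable metrics report. `pass` is `FALSE` when any
#' recovery metric falls below its regression floor (0.85 for retention,
#' annotation, targets and temporal classes; 0.8 Jaccard for
#' super-enhancers; co-occupancy and motif enrichment p below 1e-4). The
#' floors sit a little under the typical-seed recovery so they flag real
#' regressions rather than replicate-sampling noise.
#'
#' @param seed integer seed driving the whole run.
#' @param outdir output directory (bundle, result tables, metrics JSON).
#' @param config optional [pipeline_config()] override.
#' @param generator optional [generator_config()] override (its seed is
#'   replaced by `seed`).
#' @return List with `results`, `metrics`, `pass`, `outdir` (invisibly).
#' @export
pipeline_demo <- function(seed, outdir = tempfile("calenh_demo_"),
                          config = pipeline_config(),
                          generator = NULL) {
  gcfg <- if (is.null(generator)) generator_config(seed) else {
    generator$seed <- as.integer(seed)
    generator
  }
  bundle <- simulate_bundle(gcfg)
  bdir <- file.path(outdir, "bundle")
  write_bundle(bundle, bdir)
  bundle2 <- read_bundle(bdir)
  results <- run_pipeline(bundle2, config, file.path(outdir, "results"))
  metrics <- evaluate_against_truth(results, bundle2$genome)
  jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                       digits = NA, auto_unbox = TRUE, na = "null",
                       pretty = TRUE)
  floors <- c(
    unlist(lapply(metrics[c("D0", "D3", "D6")], function(m) c(
      m$retention$precision >= 0.85, m$retention$recall >= 0.85,
      m$cis_class$promoter$precision >= 0.85, m$cis_class$promoter$recall >= 0.85,
      m$cis_class$enhancer$precision >= 0.85, m$cis_class$enhancer$recall >= 0.85,
      m$targets$precision >= 0.85, m$targets$recall >= 0.85,
      m$temporal$precision >= 0.85, m$temporal$recall >= 0.85))),
    metrics$super_enhancer$jaccard >= 0.8,
    metrics$cooccupancy_p < 1e-4,
    metrics$motif_p < 1e-4
  )
  invisible(list(results = results, metrics = metrics,
                 pass = all(floors), outdir = outdir))
}
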