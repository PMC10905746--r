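#' Configuration for the synthetic-data generator
#'
#' Builds and validates the generator configuration. The defaults describe a
#' desk-scale two-chromosome genome (2 x 5 Mb, 100 bp bins) carrying 200
#' genes and 300 enhancers with planted ground truth: stem / early- / late-
#' osteogenic target enhancers on chr1 near their down-regulated genes
#' (within 50 kb), unbound decoy enhancers on chr2 far from any affected
#' gene, promoter-bound genes, a global knockout occupancy collapse visible
#' only through the exogenous spike-in channel, heavy-tailed acetylation
#' multipliers for planted super-enhancers, RUNX2 co-occupancy concentrated
#' on BRD4-bound enhancers, and a consensus motif planted preferentially in
#' bound enhancers. Replicate counts follow the study design (4 BRD4
#' CUT&Tag, 2 for other occupancy assays, 3 RNA).
#'
#' @param seed mandatory integer seed; every random draw flows from it.
#' @param ... overrides for any default listed below; unknown names error.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(seed, ...) {
  if (missing(seed)) stop("generator_config: seed is mandatory")
  cfg <- list(
    seed = as.integer(seed),
    chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
    bin_size = 100,
    gene_length = 8000,
    enhancer_length = 1000,
    n_stem = 51, n_early = 51, n_late = 48, n_decoy = 150,
    enhancers_per_gene = 3,
    n_promoter_bound = 30,
    n_flat = 150, n_low = 10,
    mu_bg = 2, phi = 0.1,
    brd4_enrichment = 20, brd4_promoter_enrichment = 15,
    k27_enhancer_enrichment = 15, k27_promoter_enrichment = 10,
    runx2_enrichment = 15,
    ko_loss_factor = 0.25, runx2_ko_factor = 0.25,
    spike_ratio = 0.1,
    depth_occupancy = 4e5,
    brd4_reps = 4, k27_reps = 2, runx2_reps = 2, rna_reps = 3,
    rna_mean_log = log(300), rna_sd_log = 0.7, rna_low_mu = 0.2,
    rna_lib_sigma = 0.1,
    down_logfc = 2, osteo_logfc = 2,
    runx2_bound_rate = 0.8, runx2_decoy_rate = 0.05,
    se_rate_bound = 0.18, se_rate_unbound = 0.03,
    se_boost = 8, se_sigma = 0.25,
    motif_rate_bound = 0.6, motif_rate_background = 0.1,
    motif_consensus = "AACCACAGCA",
    target_max_dist = 50000
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("generator_config: unknown option(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  rates <- c("runx2_bound_rate", "runx2_decoy_rate", "se_rate_bound",
             "se_rate_unbound", "motif_rate_bound", "motif_rate_background")
  stopifnot(
    all(unlist(cfg[rates]) >= 0), all(unlist(cfg[rates]) <= 1),
    cfg$phi >= 0, cfg$mu_bg > 0, cfg$bin_size > 0,
    cfg$ko_loss_factor > 0, cfg$spike_ratio > 0,
    all(cfg$chrom_lengths > 0)
  )
  class(cfg) <- "generator_config"
  cfg
}

#' Generate the toy genome with planted elements
#'
#' Places target genes and their enhancers in fixed-size loci on chr1: one
#' down-regulated gene per locus with up to `enhancers_per_gene` target
#' enhancers 10-40 kb downstream (always within the 50 kb target rule, and
#' loci far enough apart that no enhancer reaches a neighbouring gene).
#' Down-regulated genes are deliberately a minority of the transcriptome --
#' flat genes plus unbound decoy enhancers fill chr2, where no affected
#' gene lives, so every decoy is more than 50 kb from any affected gene and
#' total-count library normalization stays meaningful. A subset of target
#' genes additionally gets a promoter-bound element at its TSS. Infeasible
#' packings error with the violated capacity. Deterministic given
#' `config$seed`.
#'
#' @param config a `generator_config`.
#' @return List with `genes` (gene models plus a `program` column),
#'   `elements` (the truth table: coordinates, kind, class, per-timepoint
#'   bound flags, `runx2_bound`, `super_enhancer`, `k27_mult`,
#'   `linked_gene`, `gene_program`, `motif_planted`), and `config`.
#' @export
generate_genome <- function(config) {
  set.seed(config$seed)
  cl <- config$chrom_lengths
  n_t <- config$n_stem + config$n_early + config$n_late
  gene_len <- config$gene_length
  enh_len <- config$enhancer_length

  genes <- list(); elements <- list()
  epg <- config$enhancers_per_gene
  stopifnot(epg >= 1)
  class_names <- c("stem", "early_osteogenic", "late_osteogenic")
  class_n <- c(config$n_stem, config$n_early, config$n_late)
  class_prog <- c(stem = "down_flat", early_osteogenic = "down_osteo_d3",
                  late_osteogenic = "down_osteo_d6")
  n_genes_down <- sum(ceiling(class_n / epg))

  if (n_t > 0) {
    # one down-regulated gene per locus, its enhancers strung downstream
    locus_class <- sample(rep(class_names, ceiling(class_n / epg)))
    slot1 <- floor(cl[["chr1"]] / n_genes_down)
    need1 <- 2000 + gene_len + 10000 + (epg - 1) * 15000 + enh_len + 2000
    if (slot1 < need1)
      stop(sprintf("generate_genome: chr1 capacity violated: %d down-gene loci need %d bp each, have %d",
                   n_genes_down, need1, slot1))
    if (10000 + (epg - 1) * 15000 + enh_len > config$target_max_dist)
      stop("generate_genome: enhancers_per_gene too large for the distance rule")
    left <- stats::setNames(class_n, class_names)
    for (i in seq_len(n_genes_down)) {
      s0 <- (i - 1) * slot1
      gs <- s0 + 2000
      ge <- gs + gene_len
      gid <- sprintf("g%04d", i)
      cls_i <- locus_class[i]
      genes[[length(genes) + 1]] <- data.frame(
        chrom = "chr1", start = gs, end = ge,
        strand = sample(c("+", "-"), 1), gene_id = gid,
        program = unname(class_prog[cls_i]), stringsAsFactors = FALSE)
      k <- min(epg, left[[cls_i]])
      for (j in seq_len(k)) {
        es <- ge + 10000 + (j - 1) * 15000 + sample(-3000:3000, 1)
        elements[[length(elements) + 1]] <- data.frame(
          chrom = "chr1", start = es, end = es + enh_len, kind = "enhancer",
          class = cls_i, linked_gene = gid,
          gene_program = unname(class_prog[cls_i]), stringsAsFactors = FALSE)
      }
      left[[cls_i]] <- left[[cls_i]] - k
    }
  }

  if (config$n_flat > 0) {
    slot2 <- floor(cl[["chr2"]] / config$n_flat)
    per_slot <- ceiling(config$n_decoy / config$n_flat)
    need2 <- 20000 + per_slot * 3000 + 2000
    if (slot2 < max(need2, 2000 + gene_len + 2000))
      stop(sprintf("generate_genome: chr2 capacity violated: %d loci with %d decoys each need %d bp, have %d",
                   config$n_flat, per_slot, need2, slot2))
    low <- sample(config$n_flat, min(config$n_low, config$n_flat))
    placed <- 0
    for (i in seq_len(config$n_flat)) {
      s0 <- (i - 1) * slot2
      gs <- s0 + 2000
      gid <- sprintf("g%04d", n_genes_down + i)
      genes[[length(genes) + 1]] <- data.frame(
        chrom = "chr2", start = gs, end = gs + gene_len,
        strand = sample(c("+", "-"), 1), gene_id = gid,
        program = if (i %in% low) "low" else "flat", stringsAsFactors = FALSE)
      for (j in seq_len(per_slot)) {
        if (placed >= config$n_decoy) break
        es <- s0 + 20000 + (j - 1) * 3000
        elements[[length(elements) + 1]] <- data.frame(
          chrom = "chr2", start = es, end = es + enh_len, kind = "enhancer",
          class = "decoy", linked_gene = NA_character_,
          gene_program = NA_character_, stringsAsFactors = FALSE)
        placed <- placed + 1
      }
    }
  }

  gdf <- do.call(rbind, genes)
  gm <- gene_model(gdf$chrom, gdf$start, gdf$end, gdf$strand, gdf$gene_id)
  gm$program <- gdf$program[match(gm$gene_id, gdf$gene_id)]
  el <- if (length(elements)) do.call(rbind, elements) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               kind = character(0), class = character(0),
               linked_gene = character(0), gene_program = character(0),
               stringsAsFactors = FALSE)

  # promoter-bound elements at the TSS of a random subset of target genes
  if (config$n_promoter_bound > 0 && n_t > 0) {
    pick <- sample(seq_len(n_genes_down),
                   min(config$n_promoter_bound, n_genes_down))
    pg <- gm[match(sprintf("g%04d", pick), gm$gene_id), , drop = FALSE]
    el <- rbind(el, data.frame(
      chrom = pg$chrom, start = pmax(0, pg$tss - 500), end = pg$tss + 501,
      kind = "promoter", class = "promoter", linked_gene = pg$gene_id,
      gene_program = pg$program, stringsAsFactors = FALSE))
  }

  el <- el[order(el$chrom, el$start), , drop = FALSE]
  el$element_id <- sprintf("E%04d", seq_len(nrow(el)))
  el$bound_d0 <- el$class %in% c("stem", "promoter")
  el$bound_d3 <- el$class %in% c("early_osteogenic", "promoter")
  el$bound_d6 <- el$class %in% c("late_osteogenic", "promoter")
  is_enh <- el$kind == "enhancer"
  bound_enh <- is_enh & el$class != "decoy"
  el$runx2_bound <- rep(FALSE, nrow(el))
  el$runx2_bound[bound_enh] <-
    stats::rbinom(sum(bound_enh), 1, config$runx2_bound_rate) == 1
  decoy <- el$class == "decoy"
  el$runx2_bound[decoy] <-
    stats::rbinom(sum(decoy), 1, config$runx2_decoy_rate) == 1
  el$super_enhancer <- rep(FALSE, nrow(el))
  el$super_enhancer[bound_enh] <-
    stats::rbinom(sum(bound_enh), 1, config$se_rate_bound) == 1
  el$super_enhancer[decoy] <-
    stats::rbinom(sum(decoy), 1, config$se_rate_unbound) == 1
  el$k27_mult <- rep(1, nrow(el))
  el$k27_mult[is_enh] <- stats::rlnorm(sum(is_enh), 0, config$se_sigma) *
    ifelse(el$super_enhancer[is_enh], config$se_boost, 1)
  el$motif_planted <- rep(FALSE, nrow(el))
  el$motif_planted[is_enh] <- stats::rbinom(
    sum(is_enh), 1,
    ifelse(el$runx2_bound[is_enh], config$motif_rate_bound,
           config$motif_rate_background)) == 1
  rownames(el) <- NULL

  # constraint audit: targets within the rule, decoys outside it
  down <- gm[startsWith(gm$program, "down"), , drop = FALSE]
  tgt <- el[is_enh & el$class != "decoy", , drop = FALSE]
  gaps <- mapply(function(ch, s, e, g) {
    gi <- which(down$gene_id == g)
    max(0, down$start[gi] - e, s - down$end[gi])
  }, tgt$chrom, tgt$start, tgt$end, tgt$linked_gene)
  if (any(gaps > config$target_max_dist))
    stop("generate_genome: target enhancer placed beyond the distance rule")
  if (any(el$chrom[decoy] %in% down$chrom))
    stop("generate_genome: decoy enhancer shares a chromosome with affected genes")

  list(genes = gm, elements = el, config = config)
}

## Relative fragment-rate track (list of per-chrom vectors) for one assay
## condition: background mu_bg everywhere, element bins raised to
## mu_bg * enrichment. `enr` is a per-element enrichment vector.
rate_track <- function(genome, enr) {
  cfg <- genome$config
  bs <- cfg$bin_size
  r <- lapply(cfg$chrom_lengths, function(len) rep(cfg$mu_bg, ceiling(len / bs)))
  el <- genome$elements
  for (i in seq_len(nrow(el))) {
    if (enr[i] <= 1) next
    b0 <- floor(el$start[i] / bs) + 1
    b1 <- ceiling(el$end[i] / bs)
    ch <- el$chrom[i]
    r[[ch]][b0:b1] <- cfg$mu_bg * enr[i]
  }
  r
}

draw_track <- function(rates, scale, phi) {
  counts <- lapply(rates, function(v) {
    mu <- v * scale
    if (phi == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), size = 1 / phi, mu = mu)
  })
  counts
}

#' Simulate occupancy tracks with a spike-in channel
#'
#' Draws NB(mu, phi) bin counts for every occupancy library. BRD4 signal
#' follows the planted temporal classes (stem elements bound at D0, early
#' at D3, late at D6, promoters throughout). The knockout collapse is
#' simulated physically: knockout primary material is the wild-type rate
#' track scaled uniformly by `ko_loss_factor` while the spike material is
#' constant, and each library is sequenced to a fixed total depth, so reads
#' split between primary and spike in proportion to material. The primary
#' track then has the same shape as wild type (invisible to per-library
#' normalization) while the spike fraction rises -- only the spike scaling
#' factors reveal the loss. H3K27ac tracks carry the heavy-tailed
#' super-enhancer multipliers; knockout RUNX2 tracks lose signal only at
#' BRD4-bound elements. Deterministic given `config$seed`.
#'
#' @param genome output of [generate_genome()].
#' @return List with `tracks` (named list of `binned_track`) and `samples`
#'   (sample sheet with spike read counts for the calibrated assay).
#' @export
simulate_occupancy_counts <- function(genome) {
  cfg <- genome$config
  set.seed(cfg$seed + 1L)
  el <- genome$elements
  tracks <- list(); rows <- list()

  add_samples <- function(assay, genotype, tp, nrep, rates_wt, loss) {
    M_p_wt <- sum(vapply(rates_wt, sum, numeric(1)))
    spike <- assay == "BRD4"
    M_s <- if (spike) cfg$spike_ratio * M_p_wt else 0
    M_p <- M_p_wt * loss
    f <- M_p / (M_p + M_s)
    for (r in seq_len(nrep)) {
      id <- sprintf("%s_%s_%s_r%d", assay, genotype, tp, r)
      cnt <- draw_track(rates_wt, loss * cfg$depth_occupancy * f / M_p, cfg$phi)
      tracks[[id]] <<- binned_track(cnt, cfg$bin_size)
      prim <- max(1, track_total(tracks[[id]]))
      spk <- if (spike)
        max(1, stats::rpois(1, cfg$depth_occupancy * M_s / (M_p + M_s)))
      else NA_real_
      rows[[length(rows) + 1]] <<- data.frame(
        sample_id = id, assay = assay, genotype = genotype, timepoint = tp,
        replicate = r, primary_mapped_reads = prim, spike_mapped_reads = spk,
        stringsAsFactors = FALSE)
    }
  }

  for (tp in c("D0", "D3", "D6")) {
    bound <- el[[paste0("bound_", tolower(tp))]]
    enr <- ifelse(bound & el$kind == "promoter", cfg$brd4_promoter_enrichment,
                  ifelse(bound, cfg$brd4_enrichment, 1))
    rwt <- rate_track(genome, enr)
    add_samples("BRD4", "WT", tp, cfg$brd4_reps, rwt, 1)
    add_samples("BRD4", "KO2", tp, cfg$brd4_reps, rwt, cfg$ko_loss_factor)

    k27 <- ifelse(el$kind == "enhancer",
                  cfg$k27_enhancer_enrichment * el$k27_mult,
                  cfg$k27_promoter_enrichment)
    add_samples("H3K27ac", "WT", tp, cfg$k27_reps, rate_track(genome, k27), 1)
  }

  rx_wt <- ifelse(el$runx2_bound, cfg$runx2_enrichment, 1)
  brd4_any <- el$bound_d0 | el$bound_d3 | el$bound_d6
  rx_ko <- ifelse(el$runx2_bound & brd4_any,
                  cfg$runx2_enrichment * cfg$runx2_ko_factor, rx_wt)
  add_samples("RUNX2", "WT", "D0", cfg$runx2_reps, rate_track(genome, rx_wt), 1)
  # local loss: the KO rate track is its own shape, not a scaled WT track
  M_ko <- sum(vapply(rate_track(genome, rx_ko), sum, numeric(1)))
  for (r in seq_len(cfg$runx2_reps)) {
    id <- sprintf("RUNX2_KO2_D0_r%d", r)
    cnt <- draw_track(rate_track(genome, rx_ko), cfg$depth_occupancy / M_ko,
                      cfg$phi)
    tracks[[id]] <- binned_track(cnt, cfg$bin_size)
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = id, assay = "RUNX2", genotype = "KO2", timepoint = "D0",
      replicate = r, primary_mapped_reads = max(1, track_total(tracks[[id]])),
      spike_mapped_reads = NA_real_, stringsAsFactors = FALSE)
  }

  list(tracks = tracks, samples = validate_sample_sheet(do.call(rbind, rows)))
}

#' Simulate the expression count matrix
#'
#' NB counts for genes x (WT/KO1/KO2 x D0/D3/D6 x replicates). Genes with a
#' `down_*` program lose `2^-down_logfc` in both knockout lines at every
#' timepoint; `down_osteo_d3` genes are induced `2^osteo_logfc` in wild
#' type from D3 on, `down_osteo_d6` genes from D6; `flat` genes are
#' constant and `low` genes sit below the expressed-gene RPKM cutoff.
#' Deterministic given `config$seed`.
#'
#' @param genome output of [generate_genome()].
#' @return List with `counts` (genes x samples matrix) and `samples`.
#' @export
simulate_expression_counts <- function(genome) {
  cfg <- genome$config
  set.seed(cfg$seed + 2L)
  g <- genome$genes
  mu0 <- stats::rlnorm(nrow(g), cfg$rna_mean_log, cfg$rna_sd_log)
  mu0[g$program == "low"] <- cfg$rna_low_mu
  tp_mult <- function(tp) {
    m <- rep(1, nrow(g))
    if (tp %in% c("D3", "D6"))
      m[g$program == "down_osteo_d3"] <- 2^cfg$osteo_logfc
    if (tp == "D6")
      m[g$program == "down_osteo_d6"] <- 2^cfg$osteo_logfc
    m
  }
  cols <- list(); rows <- list()
  for (gt in c("WT", "KO1", "KO2")) {
    ko <- if (gt == "WT") rep(1, nrow(g)) else
      ifelse(startsWith(g$program, "down"), 2^(-cfg$down_logfc), 1)
    for (tp in c("D0", "D3", "D6")) {
      mu_base <- mu0 * tp_mult(tp) * ko
      for (r in seq_len(cfg$rna_reps)) {
        libf <- stats::rlnorm(1, 0, cfg$rna_lib_sigma)
        id <- sprintf("RNA_%s_%s_r%d", gt, tp, r)
        cols[[id]] <- stats::rnbinom(nrow(g), size = 1 / cfg$phi,
                                     mu = mu_base * libf)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = id, assay = "RNA", genotype = gt, timepoint = tp,
          replicate = r, primary_mapped_reads = max(1, sum(cols[[id]])),
          spike_mapped_reads = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- g$gene_id
  list(counts = counts, samples = validate_sample_sheet(do.call(rbind, rows)))
}

#' Simulate enhancer sequences with planted motifs
#'
#' I.i.d. uniform base composition per enhancer; elements flagged
#' `motif_planted` get one copy of the consensus inserted at a random
#' offset on a random strand. Sequence names encode the region
#' (`chrom:start-end`). Deterministic given `config$seed`.
#'
#' @param genome output of [generate_genome()].
#' @return Named character vector of enhancer sequences.
#' @export
simulate_sequences <- function(genome) {
  cfg <- genome$config
  set.seed(cfg$seed + 3L)
  el <- genome$elements[genome$elements$kind == "enhancer", , drop = FALSE]
  motif <- toupper(cfg$motif_consensus)
  w <- nchar(motif)
  seqs <- vapply(seq_len(nrow(el)), function(i) {
    len <- el$end[i] - el$start[i]
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    if (el$motif_planted[i]) {
      off <- sample.int(len - w + 1, 1)
      ins <- if (sample(c(TRUE, FALSE), 1)) motif else reverse_complement(motif)
      substr(s, off, off + w - 1) <- ins
    }
    s
  }, character(1))
  names(seqs) <- sprintf("%s:%d-%d", el$chrom, as.integer(el$start),
                         as.integer(el$end))
  seqs
}

#' Simulate the full input bundle
#'
#' Runs genome placement, occupancy, expression and sequence simulation in
#' order and returns everything the pipeline consumes, plus the planted
#' truth.
#'
#' @param config a `generator_config`.
#' @return List: `genome`, `occupancy`, `expression`, `sequences`, `motif`
#'   (the consensus-derived `pwm`), `config`.
#' @export
simulate_bundle <- function(config) {
  genome <- generate_genome(config)
  list(
    genome = genome,
    occupancy = simulate_occupancy_counts(genome),
    expression = simulate_expression_counts(genome),
    sequences = simulate_sequences(genome),
    motif = consensus_pwm(config$motif_consensus),
    config = config
  )
}

#' Write and read a bundle directory
#'
#' Serializes a simulated bundle to the plain-text formats the pipeline
#' reads: gene table TSV, truth JSON, element BED, per-sample bedGraph
#' tracks, occupancy and RNA sample sheets, RNA count TSV, enhancer FASTA
#' and PWM text. `read_bundle` restores the same structure; files written
#' by the package round-trip exactly.
#'
#' @param bundle output of [simulate_bundle()].
#' @param dir directory to create.
#' @return `write_bundle` returns `dir`; `read_bundle` returns a bundle
#'   list.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  g <- bundle$genome
  write_gene_table(g$genes, file.path(dir, "genes.tsv"))
  utils::write.table(g$genes[, c("gene_id", "program")],
                     file.path(dir, "gene_programs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(chrom = names(g$config$chrom_lengths),
               length = as.integer(g$config$chrom_lengths)),
    file.path(dir, "chrom_lengths.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(g$elements, file.path(dir, "truth.json"),
                       digits = NA, na = "null")
  be <- as_interval_set(data.frame(chrom = g$elements$chrom,
                                   start = g$elements$start,
                                   end = g$elements$end,
                                   id = g$elements$element_id,
                                   stringsAsFactors = FALSE))
  write_bed(be, file.path(dir, "elements.bed"))
  write_sample_sheet(bundle$occupancy$samples,
                     file.path(dir, "sample_sheet_occupancy.tsv"))
  for (id in names(bundle$occupancy$tracks))
    write_bedgraph(bundle$occupancy$tracks[[id]],
                   file.path(dir, "tracks", paste0(id, ".bedGraph")))
  write_sample_sheet(bundle$expression$samples,
                     file.path(dir, "sample_sheet_rna.tsv"))
  rc <- data.frame(gene_id = rownames(bundle$expression$counts),
                   bundle$expression$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(rc, file.path(dir, "rna_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_region_fasta(bundle$sequences, file.path(dir, "enhancers.fa"))
  write_pwm(bundle$motif, file.path(dir, "motif.pwm"))
  cfg_json <- unclass(bundle$config)
  cfg_json$chrom_lengths <- as.list(cfg_json$chrom_lengths)
  jsonlite::write_json(cfg_json, file.path(dir, "config.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  cfg_l <- jsonlite::read_json(file.path(dir, "config.json"),
                               simplifyVector = TRUE)
  chrom_lengths <- unlist(cfg_l$chrom_lengths)
  cfg_l$chrom_lengths <- NULL
  seed <- cfg_l$seed
  cfg_l$seed <- NULL
  cfg <- do.call(generator_config,
                 c(list(seed = seed, chrom_lengths = chrom_lengths), cfg_l))
  genes <- read_gene_table(file.path(dir, "genes.tsv"))
  prog <- utils::read.table(file.path(dir, "gene_programs.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  genes$program <- prog$program[match(genes$gene_id, prog$gene_id)]
  elements <- jsonlite::read_json(file.path(dir, "truth.json"),
                                  simplifyVector = TRUE)
  occ_samples <- read_sample_sheet(file.path(dir, "sample_sheet_occupancy.tsv"))
  tracks <- lapply(occ_samples$sample_id, function(id) {
    read_bedgraph(file.path(dir, "tracks", paste0(id, ".bedGraph")),
                  cfg$bin_size, cfg$chrom_lengths)
  })
  names(tracks) <- occ_samples$sample_id
  rna_samples <- read_sample_sheet(file.path(dir, "sample_sheet_rna.tsv"))
  rc <- utils::read.table(file.path(dir, "rna_counts.tsv"), header = TRUE,
                          sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(rc[, rna_samples$sample_id, drop = FALSE])
  rownames(counts) <- rc$gene_id
  list(
    genome = list(genes = genes, elements = as.data.frame(elements),
                  config = cfg),
    occupancy = list(tracks = tracks, samples = occ_samples),
    expression = list(counts = counts, samples = rna_samples),
    sequences = read_region_fasta(file.path(dir, "enhancers.fa")),
    motif = read_pwm(file.path(dir, "motif.pwm"), pseudocount = 0),
    config = cfg
  )
}

#' Precision, recall and Jaccard between label sets
#'
#' Set-based metrics with the 0/0 convention that empty prediction and
#' empty truth agree perfectly (all metrics 1).
#'
#' @param pred,truth character vectors of predicted and true labels.
#' @return List with `precision`, `recall`, `jaccard`, `tp`, `fp`, `fn`.
#' @export
precision_recall <- function(pred, truth) {
  pred <- unique(pred); truth <- unique(truth)
  tp <- length(intersect(pred, truth))
  fp <- length(setdiff(pred, truth))
  fn <- length(setdiff(truth, pred))
  list(
    precision = if (tp + fp == 0) 1 else tp / (tp + fp),
    recall = if (tp + fn == 0) 1 else tp / (tp + fn),
    jaccard = if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn),
    tp = tp, fp = fp, fn = fn
  )
}

## Map peaks to the truth elements they overlap; returns a character vector
## of element ids per peak (NA when none).
map_peaks_to_elements <- function(peaks, elements) {
  out <- rep(NA_character_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    j <- which(elements$chrom == peaks$chrom[i] &
                 elements$start < peaks$end[i] &
                 elements$end > peaks$start[i])
    if (length(j)) out[i] <- elements$element_id[j[1]]
  }
  out
}

## Geometric truth links: (bound element at tp) x (down gene within max_dist).
truth_target_links <- function(genome, tp, enhancer_only = FALSE) {
  el <- genome$elements
  bound <- el[[paste0("bound_", tolower(tp))]]
  if (enhancer_only) bound <- bound & el$kind == "enhancer"
  el <- el[bound, , drop = FALSE]
  g <- genome$genes
  down <- g[startsWith(g$program, "down"), , drop = FALSE]
  links <- list()
  for (i in seq_len(nrow(el))) {
    gi <- which(down$chrom == el$chrom[i])
    if (!length(gi)) next
    d <- pmax(0, pmax(down$start[gi] - el$end[i], el$start[i] - down$end[gi]))
    hit <- gi[d <= genome$config$target_max_dist]
    if (length(hit))
      links[[length(links) + 1]] <- data.frame(
        element_id = el$element_id[i], gene_id = down$gene_id[hit],
        gene_program = down$program[hit], stringsAsFactors = FALSE)
  }
  if (!length(links))
    return(data.frame(element_id = character(0), gene_id = character(0),
                      gene_program = character(0), stringsAsFactors = FALSE))
  do.call(rbind, links)
}

truth_temporal_links <- function(genome, tp) {
  tl <- truth_target_links(genome, tp, enhancer_only = TRUE)
  osteo <- tl$gene_program %in% c("down_osteo_d3", "down_osteo_d6")
  cls <- rep("unclassified", nrow(tl))
  if (tp == "D0") cls[!osteo] <- "stem"
  if (tp == "D3") cls[osteo] <- "early_osteogenic"
  if (tp == "D6") cls[osteo] <- "late_osteogenic"
  tl$temporal_class <- cls
  tl[tl$temporal_class != "unclassified", , drop = FALSE]
}

#' Score a pipeline run against the planted truth
#'
#' Computes per-stage precision/recall (and Jaccard where a single set is
#' compared): validated-peak retention per timepoint, promoter/enhancer
#' annotation, super-enhancer recovery, target-gene links against the
#' geometric truth, temporal classes, and RUNX2-loss flags; the
#' co-occupancy and motif p-values are carried through. Peaks are matched
#' to planted elements by coordinate overlap.
#'
#' @param results output of [run_pipeline()].
#' @param genome the truth-bearing genome from the simulated bundle.
#' @return Nested list of metrics, all in `[0, 1]` (plus raw counts).
#' @export
evaluate_against_truth <- function(results, genome) {
  el <- genome$elements
  out <- list()
  for (tp in c("D0", "D3", "D6")) {
    vp <- results$validated[[tp]]
    bound <- el[el[[paste0("bound_", tolower(tp))]], , drop = FALSE]
    ret <- vp[vp$retained, , drop = FALSE]
    mapped <- map_peaks_to_elements(ret, bound)
    retention <- list(
      precision = if (nrow(ret) == 0) 1 else mean(!is.na(mapped)),
      recall = if (nrow(bound) == 0) 1 else
        length(unique(mapped[!is.na(mapped)])) / nrow(bound),
      n_retained = nrow(ret), n_planted = nrow(bound)
    )
    ann <- results$annotated[[tp]]
    ann_ret <- ann[ann$retained & !is.na(ann$cis_class), , drop = FALSE]
    amap <- map_peaks_to_elements(ann_ret, bound)
    ok <- !is.na(amap)
    truth_kind <- bound$kind[match(amap[ok], bound$element_id)]
    pred_kind <- ifelse(ann_ret$cis_class[ok] == "promoter", "promoter",
                        "enhancer")
    cis <- list()
    for (k in c("promoter", "enhancer")) {
      tpos <- sum(pred_kind == k & truth_kind == k)
      cis[[k]] <- list(
        precision = if (sum(pred_kind == k) == 0) 1 else
          tpos / sum(pred_kind == k),
        recall = if (sum(truth_kind == k) == 0) 1 else
          tpos / sum(truth_kind == k)
      )
    }
    tg <- results$targets[[tp]]
    ret_map <- map_peaks_to_elements(ret, bound)
    key <- function(e, g) paste(e, g, sep = "|")
    pred_links <- key(ret_map[match(tg$peak_id, ret$id)], tg$gene_id)
    pred_links <- pred_links[!is.na(ret_map[match(tg$peak_id, ret$id)])]
    ttl <- truth_target_links(genome, tp)
    targets <- precision_recall(pred_links, key(ttl$element_id, ttl$gene_id))
    tc <- results$temporal[[tp]]
    tc <- tc[tc$temporal_class != "unclassified" & !is.na(tc$gene_id), ,
             drop = FALSE]
    emap <- map_peaks_to_elements(ret, el)
    pk <- paste(emap[match(tc$peak_id, ret$id)], tc$gene_id,
                tc$temporal_class, sep = "|")
    pk <- pk[!is.na(emap[match(tc$peak_id, ret$id)])]
    tt <- truth_temporal_links(genome, tp)
    temporal <- precision_recall(
      pk, paste(tt$element_id, tt$gene_id, tt$temporal_class, sep = "|"))
    out[[tp]] <- list(retention = retention, cis_class = cis,
                      targets = targets, temporal = temporal)
  }
  # super-enhancers (evaluated on the D0 enhancer universe)
  se_pred <- results$super_enhancers$D0
  enh_el <- el[el$kind == "enhancer", , drop = FALSE]
  se_map <- map_peaks_to_elements(se_pred$universe, enh_el)
  pred_se <- unique(se_map[se_pred$flags & !is.na(se_map)])
  truth_se <- enh_el$element_id[enh_el$super_enhancer]
  out$super_enhancer <- precision_recall(pred_se, truth_se)
  # RUNX2 loss
  rl <- results$runx2$loss
  lost_map <- map_peaks_to_elements(rl[rl$lost, , drop = FALSE], el)
  truth_lost <- el$element_id[el$runx2_bound &
                                (el$bound_d0 | el$bound_d3 | el$bound_d6)]
  out$runx2_loss <- precision_recall(unique(lost_map[!is.na(lost_map)]),
                                     truth_lost)
  out$cooccupancy_p <- results$runx2$fisher$p_value
  out$motif_p <- results$motif$p_value
  out
}
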