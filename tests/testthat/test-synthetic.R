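test_that("generator config validates and rejects unknown keys", {
  expect_error(generator_config(), "seed is mandatory")
  expect_error(generator_config(1, not_a_key = 2), "unknown option")
  cfg <- generator_config(5, n_decoy = 10)
  expect_equal(cfg$n_decoy, 10)
  expect_error(generator_config(1, se_rate_bound = 2))
})

test_that("genome placement honours the planted distance constraints", {
  g <- generate_genome(generator_config(3))
  el <- g$elements
  genes <- g$genes
  expect_equal(sum(el$kind == "enhancer"), 300)
  expect_equal(nrow(genes), 200)
  down <- genes[startsWith(genes$program, "down"), ]
  # every target enhancer within the rule of its linked gene
  tgt <- el[el$kind == "enhancer" & el$class != "decoy", ]
  for (i in seq_len(nrow(tgt))) {
    gi <- down[down$gene_id == tgt$linked_gene[i], ]
    gap <- max(0, gi$start - tgt$end[i], tgt$start[i] - gi$end)
    expect_lte(gap, 50000)
  }
  # every decoy beyond the rule from every affected gene
  dec <- el[el$class == "decoy", ]
  expect_false(any(dec$chrom %in% down$chrom))
  # element class counts match the requested configuration
  expect_equal(as.vector(table(el$class)[c("stem", "early_osteogenic",
                                           "late_osteogenic", "decoy")]),
               c(51, 51, 48, 150))
  # infeasible packing errors name the capacity
  expect_error(generate_genome(generator_config(1, chrom_lengths =
    c(chr1 = 1e5, chr2 = 5e6))), "chr1 capacity")
  # zero enhancers leaves genes only
  g0 <- generate_genome(generator_config(2, n_stem = 0, n_early = 0,
                                         n_late = 0, n_decoy = 0,
                                         n_promoter_bound = 0))
  expect_equal(sum(g0$elements$kind == "enhancer"), 0)
  expect_gt(nrow(g0$genes), 0)
})

test_that("simulation is deterministic under a fixed seed", {
  b1 <- simulate_bundle(generator_config(9, n_flat = 30, n_decoy = 30,
                                         n_stem = 9, n_early = 9, n_late = 9,
                                         chrom_lengths = c(chr1 = 1e6,
                                                           chr2 = 1e6)))
  b2 <- simulate_bundle(generator_config(9, n_flat = 30, n_decoy = 30,
                                         n_stem = 9, n_early = 9, n_late = 9,
                                         chrom_lengths = c(chr1 = 1e6,
                                                           chr2 = 1e6)))
  expect_identical(b1$genome$elements, b2$genome$elements)
  expect_identical(b1$occupancy$tracks, b2$occupancy$tracks)
  expect_identical(b1$expression$counts, b2$expression$counts)
  expect_identical(b1$sequences, b2$sequences)
  # a different seed gives different data
  b3 <- simulate_bundle(generator_config(10, n_flat = 30, n_decoy = 30,
                                         n_stem = 9, n_early = 9, n_late = 9,
                                         chrom_lengths = c(chr1 = 1e6,
                                                           chr2 = 1e6)))
  expect_false(identical(b1$expression$counts, b3$expression$counts))
})

test_that("occupancy totals match the sequencing-depth model", {
  b <- default_bundle(1)
  cfg <- b$config
  s <- b$occupancy$samples
  # primary + spike reads sum to the configured depth in expectation;
  # the knockout diverts depth into the spike channel
  wt <- s[s$assay == "BRD4" & s$genotype == "WT" & s$timepoint == "D0", ]
  ko <- s[s$assay == "BRD4" & s$genotype != "WT" & s$timepoint == "D0", ]
  expect_equal(mean(wt$primary_mapped_reads + wt$spike_mapped_reads),
               cfg$depth_occupancy, tolerance = 0.02)
  expect_gt(mean(ko$spike_mapped_reads), 2 * mean(wt$spike_mapped_reads))
  # spike factors reveal the planted global loss factor
  fw <- spike_scaling_factor(wt$primary_mapped_reads, wt$spike_mapped_reads)
  fk <- spike_scaling_factor(ko$primary_mapped_reads, ko$spike_mapped_reads)
  expect_equal(mean(fk) / mean(fw), cfg$ko_loss_factor, tolerance = 0.1)
  # raw depth alone does not: primary read counts stay comparable
  expect_gt(mean(ko$primary_mapped_reads) / mean(wt$primary_mapped_reads),
            0.6)
})

test_that("a loss factor of 1 leaves WT and KO element signal equal", {
  cfg <- generator_config(12, ko_loss_factor = 1, n_flat = 30, n_decoy = 30,
                          n_stem = 9, n_early = 9, n_late = 9,
                          chrom_lengths = c(chr1 = 1e6, chr2 = 1e6))
  g <- generate_genome(cfg)
  occ <- simulate_occupancy_counts(g)
  el <- g$elements[g$elements$bound_d0, ]
  regions <- as_interval_set(data.frame(
    chrom = el$chrom, start = el$start, end = el$end, id = el$element_id,
    stringsAsFactors = FALSE))
  s <- occ$samples
  wt_ids <- s$sample_id[s$assay == "BRD4" & s$genotype == "WT" &
                          s$timepoint == "D0"]
  ko_ids <- s$sample_id[s$assay == "BRD4" & s$genotype != "WT" &
                          s$timepoint == "D0"]
  mw <- mean(count_matrix(occ$tracks[wt_ids], regions))
  mk <- mean(count_matrix(occ$tracks[ko_ids], regions))
  expect_equal(mk / mw, 1, tolerance = 0.05)
})

test_that("expression simulation plants the configured effects", {
  b <- default_bundle(1)
  cfg <- b$config
  g <- b$genome$genes
  ec <- b$expression$counts
  es <- b$expression$samples
  grp_mean <- function(gt, tp) rowMeans(
    ec[, es$genotype == gt & es$timepoint == tp, drop = FALSE])
  down <- startsWith(g$program, "down")
  # knockout effect at D0 on the affected genes (median log2 ratio)
  lfc <- log2((grp_mean("KO2", "D0") + 0.5) / (grp_mean("WT", "D0") + 0.5))
  expect_equal(median(lfc[down]), -cfg$down_logfc, tolerance = 0.3)
  expect_equal(median(lfc[!down]), 0, tolerance = 0.3)
  # osteogenic induction in wild type
  lfc_traj <- log2((grp_mean("WT", "D3") + 0.5) / (grp_mean("WT", "D0") + 0.5))
  d3 <- g$program == "down_osteo_d3"
  expect_equal(median(lfc_traj[d3]), cfg$osteo_logfc, tolerance = 0.3)
  # low-program genes sit under the expressed cutoff
  wt_sel <- es$genotype == "WT" & es$timepoint == "D0"
  wr <- rowMeans(rpkm(ec[, wt_sel], g$end - g$start,
                      es$primary_mapped_reads[wt_sel]))
  expect_true(all(wr[g$program == "low"] < 1))
})

test_that("sequence simulation plants motifs at the configured rates", {
  cfg1 <- generator_config(14, motif_rate_bound = 1, motif_rate_background = 1)
  g1 <- generate_genome(cfg1)
  seqs1 <- simulate_sequences(g1)
  motif <- consensus_pwm(cfg1$motif_consensus)
  hits1 <- vapply(seqs1, function(s) nrow(scan_pwm(s, motif)) > 0, logical(1))
  expect_true(all(hits1))
  # rate 0: only scan false positives remain (expected ~0.2% of regions)
  cfg0 <- generator_config(14, motif_rate_bound = 0, motif_rate_background = 0)
  seqs0 <- simulate_sequences(generate_genome(cfg0))
  hits0 <- vapply(seqs0, function(s) nrow(scan_pwm(s, motif)) > 0, logical(1))
  expect_lte(sum(hits0), 4)
  # determinism by seed
  expect_identical(seqs0, simulate_sequences(generate_genome(cfg0)))
})

test_that("bundles round-trip through their plain-text formats", {
  b <- simulate_bundle(generator_config(15, n_flat = 20, n_decoy = 20,
                                        n_stem = 6, n_early = 6, n_late = 6,
                                        brd4_reps = 2, rna_reps = 2,
                                        chrom_lengths = c(chr1 = 1e6,
                                                          chr2 = 1e6)))
  d <- tempfile("bundle_")
  write_bundle(b, d)
  b2 <- read_bundle(d)
  expect_equal(b2$genome$genes, b$genome$genes)
  el2 <- b2$genome$elements
  expect_equal(el2[order(el2$element_id), names(b$genome$elements)],
               b$genome$elements[order(b$genome$elements$element_id), ],
               ignore_attr = TRUE)
  for (id in names(b$occupancy$tracks))
    expect_equal(b2$occupancy$tracks[[id]]$counts,
                 lapply(b$occupancy$tracks[[id]]$counts, as.numeric))
  expect_equal(b2$expression$counts, b$expression$counts)
  expect_equal(b2$sequences, b$sequences)
  expect_equal(b2$motif$probs, b$motif$probs, tolerance = 1e-5)
  unlink(d, recursive = TRUE)
})

test_that("precision_recall handles edges and stays in [0, 1]", {
  p <- precision_recall(c("a", "b"), c("a", "b"))
  expect_equal(c(p$precision, p$recall, p$jaccard), c(1, 1, 1))
  p0 <- precision_recall(character(0), character(0))
  expect_equal(c(p0$precision, p0$recall, p0$jaccard), c(1, 1, 1))
  pd <- precision_recall("a", "b")
  expect_equal(c(pd$precision, pd$recall, pd$jaccard), c(0, 0, 0))
  set.seed(16)
  for (rep in 1:20) {
    pr <- precision_recall(sample(letters, sample(0:10, 1)),
                           sample(letters, sample(0:10, 1)))
    expect_true(all(unlist(pr[1:3]) >= 0 & unlist(pr[1:3]) <= 1))
  }
})
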