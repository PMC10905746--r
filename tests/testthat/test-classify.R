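# lib of 1e9 makes RPKM = counts / 1000 for 1 kb peaks
make_brd4_samples <- function(n_wt = 2, n_ko = 2, lib = 1e9) {
  data.frame(
    sample_id = c(sprintf("wt%d", seq_len(n_wt)), sprintf("ko%d", seq_len(n_ko))),
    assay = "BRD4",
    genotype = rep(c("WT", "KO2"), c(n_wt, n_ko)),
    timepoint = "D0",
    replicate = c(seq_len(n_wt), seq_len(n_ko)),
    primary_mapped_reads = lib,
    spike_mapped_reads = NA_real_,
    stringsAsFactors = FALSE
  )
}

test_that("validate_peaks applies the retention ladder", {
  peaks <- interval_set("chr1", c(1000, 5000, 9000), c(2000, 6000, 10000),
                        id = c("p1", "p2", "p3"))
  samples <- make_brd4_samples()
  # p1: strong WT signal lost in KO; p2: weak RPKM; p3: unchanged
  counts <- rbind(c(5000, 5200, 1200, 1300),
                  c(700, 750, 180, 190),
                  c(3000, 3100, 3050, 2950))
  # per-kb per-million: p2 has RPKM ~0.7 < 1
  vp <- validate_peaks(peaks, replicate_peaks = list(peaks), ko_peaks = peaks,
                       counts = counts, samples = samples,
                       effective_lib_sizes = rep(1e6, 4), rpkm_min = 1,
                       phi = 0.05)
  expect_false(vp$retained[2])   # RPKM gate
  expect_true(vp$retained[1])    # significant KO loss
  expect_false(vp$retained[3])   # neither wt-only nor lost
  expect_true(all(vp$retained == (vp$rpkm_wt > 1 &
                                    (vp$wt_only | vp$ko_loss_fdr < 0.05))))
  # wt_only branch retains even without differential power
  vp2 <- validate_peaks(peaks[1, ], list(peaks), ko_peaks = empty_interval_set(),
                        counts = matrix(c(5000, 5200, 5000, 5100), 1),
                        samples = samples, effective_lib_sizes = rep(1e6, 4),
                        phi = 0.05)
  expect_true(vp2$wt_only && vp2$retained)
  expect_error(validate_peaks(peaks, list(peaks), peaks,
                              matrix(NA_real_, 3, 4), samples, rep(1e6, 4)),
               "missing counts")
})

test_that("cis-class annotation is exclusive with promoter precedence", {
  tssw <- interval_set("chr1", 9500, 10501, id = "g1")
  k27 <- interval_set("chr1", c(9000, 30000), c(11000, 32000))
  vp <- data.frame(
    chrom = "chr1",
    start = c(10000, 30500, 50000, 9400),
    end = c(10400, 30900, 50400, 9800),
    id = c("both", "k27only", "neither", "tssonly"),
    retained = TRUE, stringsAsFactors = FALSE
  )
  ann <- annotate_cis_class(vp, k27, tssw)
  expect_equal(ann$cis_class[ann$id == "both"], "promoter")
  expect_equal(ann$cis_class[ann$id == "k27only"], "enhancer")
  expect_equal(ann$cis_class[ann$id == "tssonly"], "promoter")
  expect_true(is.na(ann$cis_class[ann$id == "neither"]))
  # random layouts: the three outcomes are mutually exclusive and exhaustive
  set.seed(55)
  for (rep in 1:10) {
    vpr <- as.data.frame(random_interval_set(40))
    vpr$retained <- TRUE
    k27r <- random_interval_set(15)
    tssr <- random_interval_set(15)
    a <- annotate_cis_class(vpr, k27r, tssr)
    srt <- as_interval_set(vpr[, c("chrom", "start", "end", "id")])
    t_hit <- calenh:::overlaps_any(srt, tssr)[match(vpr$id, srt$id)]
    k_hit <- calenh:::overlaps_any(srt, k27r)[match(vpr$id, srt$id)]
    expect_equal(a$cis_class, ifelse(t_hit, "promoter",
                                     ifelse(k_hit, "enhancer", NA)))
  }
})

test_that("super-enhancer tangent rule isolates extreme densities", {
  enh <- interval_set("chr1", (0:99) * 2000, (0:99) * 2000 + 1000,
                      id = sprintf("e%02d", 0:99))
  counts <- rep(10, 100); counts[42] <- 1000   # one at 100x the others
  se <- call_super_enhancers(enh, counts)
  expect_equal(which(se$flags), 42)
  expect_equal(sum(se$flags), 1)
  # degenerate flat curve: nothing flagged
  se0 <- call_super_enhancers(enh, rep(7, 100))
  expect_equal(sum(se0$flags), 0)
  expect_true(is.na(se0$cutoff_rank))
  expect_error(call_super_enhancers(enh[1:5, ], rep(1, 5)), ">= 10")
})

test_that("planted heavy-tail super-enhancers are recovered", {
  set.seed(77)
  n <- 300
  enh <- interval_set("chr1", (0:(n - 1)) * 3000, (0:(n - 1)) * 3000 + 1000,
                      id = sprintf("e%03d", seq_len(n)))
  dens <- rlnorm(n, 0, 1.5)
  planted <- order(dens, decreasing = TRUE)[1:30]  # top decile boosted
  dens[planted] <- dens[planted] * 10
  se <- call_super_enhancers(enh, dens * 1000)
  pr <- precision_recall(enh$id[se$flags], enh$id[planted])
  expect_gte(pr$jaccard, 0.8)
})

test_that("target assignment respects the distance boundary and brute force", {
  genes <- gene_model("chr1", c(100000, 300000), c(110000, 310000),
                      c("+", "+"), c("gNear", "gFar"))
  flags <- data.frame(gene_id = c("gNear", "gFar"),
                      down_in_both = c(TRUE, TRUE),
                      osteogenic = c(FALSE, FALSE), stringsAsFactors = FALSE)
  vp <- data.frame(chrom = "chr1",
                   start = c(50000, 48000), end = c(51000, 49000),
                   id = c("in49", "out51"), retained = TRUE,
                   stringsAsFactors = FALSE)
  # gaps to gNear: 100000-51000 = 49 kb (in), 100000-49000 = 51 kb (out)
  tg <- assign_target_genes(vp, genes, flags, 50000)
  expect_equal(tg$peak_id, "in49")
  expect_equal(tg$distance, 49000)
  # monotone in max_dist: widening never removes links
  tg2 <- assign_target_genes(vp, genes, flags, 60000)
  expect_true(all(paste(tg$peak_id, tg$gene_id) %in%
                    paste(tg2$peak_id, tg2$gene_id)))
  # random layouts match the all-pairs filter
  set.seed(88)
  for (rep in 1:10) {
    ng <- 15
    gs <- sample.int(500000, ng)
    genes_r <- gene_model("chr1", gs, gs + 5000,
                          sample(c("+", "-"), ng, TRUE),
                          sprintf("g%02d", seq_len(ng)))
    down <- sample(c(TRUE, FALSE), ng, TRUE)
    flags_r <- data.frame(gene_id = genes_r$gene_id, down_in_both = down,
                          osteogenic = FALSE, stringsAsFactors = FALSE)
    vpr <- as.data.frame(random_interval_set(20, chroms = "chr1",
                                             max_pos = 500000))
    vpr$retained <- TRUE
    tg_r <- assign_target_genes(vpr, genes_r, flags_r, 30000)
    expected <- character(0)
    for (i in seq_len(nrow(vpr))) for (j in seq_len(ng)) {
      gap <- max(0, genes_r$start[j] - vpr$end[i],
                 vpr$start[i] - genes_r$end[j])
      if (down[j] && gap <= 30000)
        expected <- c(expected, paste(vpr$id[i], genes_r$gene_id[j]))
    }
    expect_setequal(paste(tg_r$peak_id, tg_r$gene_id), expected)
  }
})

test_that("temporal classes follow binding timepoint and trajectory flags", {
  ann <- function(ids) data.frame(
    chrom = "chr1", start = seq_along(ids) * 1000,
    end = seq_along(ids) * 1000 + 500, id = ids,
    retained = TRUE, cis_class = "enhancer", stringsAsFactors = FALSE)
  tg <- function(pid, gid) data.frame(
    peak_id = pid, chrom = "chr1", start = 0, end = 1, gene_id = gid,
    distance = 0, gene_down_in_both = TRUE, gene_osteogenic = NA,
    stringsAsFactors = FALSE)
  fl <- data.frame(gene_id = c("gflat", "gosteo"),
                   osteogenic = c(FALSE, TRUE), stringsAsFactors = FALSE)
  out <- temporal_classify(
    list(D0 = ann(c("a", "b", "orphan")), D3 = ann("c"), D6 = ann("d")),
    list(D0 = rbind(tg("a", "gflat"), tg("b", "gosteo")),
         D3 = tg("c", "gosteo"), D6 = tg("d", "gosteo")),
    list(D0 = fl, D3 = fl, D6 = fl))
  expect_equal(out$D0$temporal_class[out$D0$peak_id == "a"], "stem")
  # a D0 enhancer whose gene is induced stays unclassified
  expect_equal(out$D0$temporal_class[out$D0$peak_id == "b"], "unclassified")
  expect_equal(out$D0$temporal_class[out$D0$peak_id == "orphan"],
               "unclassified")
  expect_equal(out$D3$temporal_class, "early_osteogenic")
  expect_equal(out$D6$temporal_class, "late_osteogenic")
})
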