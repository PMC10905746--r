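test_that("intersect follows half-open overlap semantics", {
  a <- interval_set("chr1", 100, 200)
  b <- interval_set("chr1", 150, 250)
  expect_equal(nrow(intersect_overlapping(a, b)), 1)
  # abutting intervals do not overlap
  b2 <- interval_set("chr1", 200, 300)
  expect_equal(nrow(intersect_overlapping(a, b2)), 0)
  # result is a subset of a, order preserved
  a3 <- interval_set("chr1", c(0, 500, 900), c(100, 600, 1000))
  b3 <- interval_set("chr1", c(50, 950), c(60, 960))
  r <- intersect_overlapping(a3, b3)
  expect_equal(r$start, c(0, 900))
  expect_error(intersect_overlapping(a3[c(3, 1, 2), ], b3), "not sorted")
})

test_that("interval_set validates invariants", {
  expect_error(interval_set("chr1", 10, 10), "start < end")
  expect_error(interval_set("chr1", -1, 10), "start < end")
  expect_error(interval_set("", 0, 10), "non-empty")
  x <- interval_set(c("chr2", "chr1"), c(5, 9), c(10, 20))
  expect_equal(x$chrom, c("chr1", "chr2"))
})

test_that("merge fuses overlapping and within-gap intervals", {
  x <- interval_set("chr1", c(0, 5), c(10, 20))
  m <- merge_intervals(x, 0)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 20))
  # gap 2 > max_gap 1 stays split
  y <- interval_set("chr1", c(0, 12), c(10, 20))
  expect_equal(nrow(merge_intervals(y, 1)), 2)
  expect_equal(nrow(merge_intervals(y, 2)), 1)
  expect_error(merge_intervals(y, -1), "max_gap")
})

test_that("interval operations agree with quadratic brute-force oracles", {
  set.seed(421)
  for (rep in 1:30) {
    a <- random_interval_set(sample(5:60, 1))
    b <- random_interval_set(sample(5:60, 1))
    expect_equal(as.data.frame(intersect_overlapping(a, b)),
                 as.data.frame(brute_intersect(a, b)))
    gap <- sample(0:50, 1)
    m1 <- merge_intervals(a, gap)
    m2 <- brute_merge(a, gap)
    expect_equal(m1$start, m2$start)
    expect_equal(m1$end, m2$end)
    # merge is idempotent and conserves coverage bounds
    expect_equal(as.data.frame(merge_intervals(m1, gap))[, 1:3],
                 as.data.frame(m1)[, 1:3])
    expect_gte(sum(m1$end - m1$start), max(a$end - a$start))
    expect_lte(sum(m1$end - m1$start), sum(a$end - a$start))
  }
})

test_that("interval operations agree with GenomicRanges", {
  skip_if_not_installed("GenomicRanges")
  set.seed(99)
  for (rep in 1:5) {
    a <- random_interval_set(40)
    b <- random_interval_set(40)
    gr <- function(x) GenomicRanges::GRanges(
      x$chrom, IRanges::IRanges(x$start + 1, x$end))
    hit <- GenomicRanges::countOverlaps(gr(a), gr(b)) > 0
    expect_equal(intersect_overlapping(a, b)$id, a$id[hit])
    mr <- GenomicRanges::reduce(gr(a))
    m <- merge_intervals(a, 0)
    expect_equal(m$start, GenomicRanges::start(mr) - 1)
    expect_equal(m$end, GenomicRanges::end(mr))
  }
})

test_that("closest_distance finds the gene minimizing the unsigned gap", {
  g <- toy_genes()
  # peak inside a gene body
  p1 <- interval_set("chr1", 12000, 12100)
  r1 <- closest_distance(p1, g)
  expect_equal(r1$distance, 0)
  expect_equal(r1$gene_id, "gB")
  # disjoint gap arithmetic: 10000 - 9100 = 900
  p2 <- interval_set("chr1", 9000, 9100)
  expect_equal(closest_distance(p2, g)$distance, 900)
  # chromosome with no genes reports missing, not an error
  p3 <- interval_set("chrX", 0, 100)
  r3 <- closest_distance(p3, g)
  expect_true(is.na(r3$distance) && is.na(r3$gene_id))
})

test_that("closest_distance matches the exhaustive scan and is translation invariant", {
  set.seed(7)
  for (rep in 1:20) {
    ng <- sample(3:20, 1)
    gs <- sample.int(50000, ng)
    genes <- gene_model("chr1", gs, gs + sample(500:3000, ng, replace = TRUE),
                        sample(c("+", "-"), ng, replace = TRUE),
                        sprintf("g%02d", seq_len(ng)))
    peaks <- random_interval_set(15, chroms = "chr1", max_pos = 60000)
    r <- closest_distance(peaks, genes)
    o <- brute_closest(peaks, genes)
    expect_equal(r$gene_id, o[, 1])
    expect_equal(r$distance, as.numeric(o[, 2]))
    # translating the whole chromosome preserves distances
    shift <- 1000
    genes2 <- gene_model("chr1", genes$start + shift, genes$end + shift,
                         genes$strand, genes$gene_id)
    peaks2 <- as_interval_set(transform(as.data.frame(peaks),
                                        start = start + shift,
                                        end = end + shift))
    expect_equal(closest_distance(peaks2, genes2)$distance, r$distance)
  }
})

test_that("tss_windows is strand-aware and clipped at zero", {
  g <- gene_model("chr1", c(10000, 10000, 100), c(20000, 20000, 900),
                  c("+", "-", "+"), c("gp", "gm", "gz"))
  w <- tss_windows(g, 500)
  wp <- w[w$id == "gp", ]
  expect_equal(c(wp$start, wp$end), c(9500, 10501))
  wm <- w[w$id == "gm", ]
  # minus-strand TSS is end - 1 = 19999
  expect_equal(c(wm$start, wm$end), c(19499, 20500))
  wz <- w[w$id == "gz", ]
  expect_equal(wz$start, 0)
  expect_error(tss_windows(g, 0), "halfwidth")
})

test_that("BED and gene tables round-trip exactly", {
  x <- random_interval_set(25)
  f <- tempfile(fileext = ".bed")
  write_bed(x, f)
  y <- read_bed(f)
  expect_equal(as.data.frame(y), as.data.frame(x))
  # BED3 path
  x3 <- interval_set(c("chr1", "chr2"), c(0, 10), c(5, 20))
  write_bed(x3, f)
  expect_equal(as.data.frame(read_bed(f))[, 1:3], as.data.frame(x3)[, 1:3])
  g <- toy_genes()
  fg <- tempfile(fileext = ".tsv")
  write_gene_table(g, fg)
  expect_equal(read_gene_table(fg), g)
})
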