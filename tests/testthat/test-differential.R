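test_that("common dispersion estimator recovers simulation truth", {
  groups <- rep(c("A", "B"), each = 4)
  # Poisson counts carry no extra-Poisson variance
  set.seed(201)
  cp <- matrix(rpois(2000 * 8, 60), 2000, 8)
  expect_lt(abs(estimate_common_dispersion(cp, rep(1, 8), groups)), 0.02)
  # NB at phi = 0.2 lands in a sane band
  set.seed(202)
  cn <- matrix(rnbinom(2000 * 8, size = 5, mu = 60), 2000, 8)
  phi <- estimate_common_dispersion(cn, rep(1, 8), groups)
  expect_gte(phi, 0.1); expect_lte(phi, 0.3)
  # constant replicates have zero variance
  cc <- matrix(rep(c(10, 20), each = 4), 3, 8, byrow = TRUE)
  expect_equal(estimate_common_dispersion(cc, rep(1, 8), groups), 0)
  expect_error(estimate_common_dispersion(cp[, 1:2, drop = FALSE], c(1, 1),
                                          c("A", "B")), ">= 2 replicates")
  expect_error(estimate_common_dispersion(matrix(0, 5, 8), rep(1, 8), groups),
               "mean filter")
})

test_that("NB exact test is exact, symmetric and scale invariant", {
  # perfectly balanced groups: the observed split is the conditional mode
  expect_equal(nb_exact_test(c(10, 10), c(10, 10), rep(1, 2), rep(1, 2), 0.1), 1)
  # phi = 0 reduces to the conditional binomial exact test
  set.seed(203)
  for (rep in 1:30) {
    ya <- rpois(3, 25); yb <- rpois(4, 40)
    p <- nb_exact_test(ya, yb, rep(1, 3), rep(1, 4), 0)
    n <- sum(ya) + sum(yb)
    pr <- dbinom(0:n, n, 3 / 7)
    p_oracle <- sum(pr[pr <= pr[sum(ya) + 1] * (1 + 1e-10)])
    expect_equal(p, p_oracle, tolerance = 1e-12)
  }
  # label swap and uniform library rescaling leave p unchanged
  set.seed(204)
  for (rep in 1:20) {
    ya <- rnbinom(4, size = 10, mu = 50); yb <- rnbinom(4, size = 10, mu = 90)
    la <- runif(4, 0.5, 2); lb <- runif(4, 0.5, 2)
    p1 <- nb_exact_test(ya, yb, la, lb, 0.1)
    expect_equal(nb_exact_test(yb, ya, lb, la, 0.1), p1)
    expect_equal(nb_exact_test(ya, yb, 3 * la, 3 * lb, 0.1), p1)
  }
  expect_error(nb_exact_test(2e6, 1, 1, 1, 0.1), "enumeration bound")
})

test_that("NB exact test power rises monotonically with effect size", {
  set.seed(205)
  power_at <- function(lfc) {
    mu_b <- 50 * 2^lfc
    mean(replicate(150, {
      nb_exact_test(rnbinom(4, size = 10, mu = 50),
                    rnbinom(4, size = 10, mu = mu_b),
                    rep(1, 4), rep(1, 4), 0.1) < 0.05
    }))
  }
  pw <- vapply(c(0.5, 1, 2), power_at, numeric(1))
  expect_true(all(diff(pw) > 0))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(206)
  for (rep in 1:20) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
})

test_that("independent filtering only helps and is deterministic", {
  # all features high count: no reason to filter
  set.seed(207)
  p <- runif(100)
  mc <- runif(100, 50, 100)
  f <- independent_filter(mc, p)
  expect_equal(f$threshold, 0)
  # planted mixture: low-count features are pure null, high-count are signal
  mc2 <- c(runif(300, 0, 1), runif(200, 50, 100))
  p2 <- c(runif(300), rbeta(200, 0.05, 1))
  f2 <- independent_filter(mc2, p2, grid = c(0, 2, 5, 10))
  unfiltered <- sum(bh_fdr(p2) < 0.05)
  expect_gte(f2$n_rejected, unfiltered)
  expect_true(all(is.na(f2$fdr[mc2 < f2$threshold])))
  # same input, same output
  expect_identical(f2, independent_filter(mc2, p2, grid = c(0, 2, 5, 10)))
})

test_that("expression-change flags implement the gating rules", {
  de <- function(lfc, fdr) data.frame(
    feature = c("g1", "g2", "g3"), mean_a = 100, mean_b = 50,
    logFC = lfc, pvalue = fdr, fdr = fdr, stringsAsFactors = FALSE)
  # g1 down in KO1 only; g2 down in both; g3 not expressed
  ko1 <- de(c(-2, -2, -2), c(0.01, 0.01, 0.01))
  ko2 <- de(c(-2, -2, -2), c(0.50, 0.01, 0.01))
  fl <- classify_expression_changes(ko1, ko2, NULL, wt_rpkm = c(5, 5, 0.5))
  expect_equal(fl$down_in_both, c(FALSE, TRUE, FALSE))
  expect_false(fl$expressed[3])
  expect_equal(fl$severe_down_in_both, c(FALSE, TRUE, FALSE))
  expect_error(
    classify_expression_changes(ko1, ko2[c(2, 1, 3), ], NULL, c(5, 5, 5)),
    "universes differ")
})

test_that("planted down-in-both genes are recovered at the stated effect size", {
  set.seed(208)
  ng <- 400
  down <- seq_len(120)
  mu <- rlnorm(ng, log(250), 0.6)
  sim_geno <- function(effect) {
    matrix(rnbinom(ng * 4, size = 10, mu = mu * effect), ng, 4)
  }
  eff <- rep(1, ng); eff[down] <- 2^-1.5
  wt <- sim_geno(1); ko1 <- sim_geno(eff); ko2 <- sim_geno(eff)
  run <- function(ko) nb_test_matrix(cbind(wt, ko),
                                     rep(c("WT", "KO"), each = 4),
                                     rep(1, 8), phi = 0.1)
  fl <- classify_expression_changes(run(ko1), run(ko2), NULL,
                                    wt_rpkm = rep(10, ng))
  recovered <- mean(fl$down_in_both[down])
  expect_gte(recovered, 0.95)
  # false positives stay rare among true nulls
  expect_lte(mean(fl$down_in_both[-down]), 0.02)
})

test_that("median-of-ratios sizes track depth, not composition", {
  set.seed(209)
  mu <- rlnorm(300, log(200), 0.5)
  # pure depth differences are recovered
  depth <- c(1, 1.6, 0.7, 1.2)
  y <- sapply(depth, function(d) rnbinom(300, size = 10, mu = mu * d))
  sz <- median_ratio_lib_sizes(y)
  expect_equal(unname(sz / sz[1]), depth / depth[1], tolerance = 0.07)
  # with a quarter of genes losing 4x in half the samples, the median-ratio
  # group offset stays closer to pure depth than total counts do (tight
  # dispersion so the contaminated tail is well separated from the bulk)
  eff <- rep(1, 300); eff[1:75] <- 0.25
  y2 <- cbind(sapply(c(1, 1), function(d) rnbinom(300, size = 50, mu = mu)),
              sapply(c(1, 1), function(d) rnbinom(300, size = 50,
                                                  mu = mu * eff)))
  szc <- median_ratio_lib_sizes(y2)
  ratio_med <- mean(szc[3:4]) / mean(szc[1:2])
  ratio_tot <- mean(colSums(y2)[3:4]) / mean(colSums(y2)[1:2])
  expect_lt(abs(ratio_med - 1), abs(ratio_tot - 1))
})
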