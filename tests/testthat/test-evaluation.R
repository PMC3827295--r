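test_that("an exact competitive hyperbola fits with slope -1 and R^2 1", {
  sc <- 10^(2:6)
  f <- fit_titration(sc, 1e5 / sc)
  expect_equal(f$slope, -1)
  expect_equal(f$intercept, 5)
  expect_equal(f$r2, 1)
  expect_equal(f$n_points, 5L)
})

test_that("fewer than three titration points yield a no-fit result", {
  f <- fit_titration(c(1e3, 1e4), c(10, 1))
  expect_equal(f$status, "insufficient_points")
  expect_true(is.na(f$slope))
  # non-finite / non-positive ratios do not count as points
  f2 <- fit_titration(c(1e3, 1e4, 1e5), c(10, 0, NA))
  expect_equal(f2$status, "insufficient_points")
})

test_that("Poisson-sampled 12-point three-fold ladders average slope near -1", {
  copies <- design_samples(10, 3, 1e4, seed = 3)[, "A", drop = FALSE]
  sim <- simulate_study_counts(copies, ladder = 6e7 / 3^(0:11),
                               reads_per_library = 5e4, seed = 4)
  sl <- titration_slopes(replicate_estimates(sim$counts, sim$mix))
  expect_gte(nrow(sl), 8L)
  expect_lt(abs(mean(sl$slope) + 1), 0.05)
})

test_that("expected Poisson CV is 1/sqrt(n)", {
  expect_equal(expected_cv_poisson(100), 0.10)
  expect_equal(expected_cv_poisson(1e4), 0.01)
  expect_equal(expected_cv_poisson(1), 1.0)
  expect_error(expected_cv_poisson(0), "> 0")
})

test_that("mixture expectations follow 0.75A + 0.25B and 0.25A + 0.75B", {
  expect_equal(expected_mixture(1000, 200, 0.75), 800)
  expect_equal(expected_mixture(1000, 200, 0.25), 400)
  expect_equal(expected_mixture(123, 456, 1.0), 123)
})

test_that("rank AUC handles separation, the null, and monotone transforms", {
  expect_equal(auc_rank(1:10, 11:20)$auc, 1.0)
  set.seed(5)
  x <- rnorm(400); y <- rnorm(400)
  a0 <- auc_rank(x, y)
  expect_equal(a0$auc, 0.5, tolerance = 0.06)
  # monotone invariance
  shift <- function(v) exp(v / 3)
  expect_equal(auc_rank(shift(x), shift(y))$auc, a0$auc)
  expect_true(is.na(auc_rank(numeric(0), y)$auc))
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  ctrl <- rnorm(150); tst <- rnorm(120, mean = 0.8)
  mine <- auc_rank(ctrl, tst)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(0, 150), rep(1, 120)),
    predictor = c(ctrl, tst), quiet = TRUE, direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("fold-change comparisons land in the printed ratio bins", {
  # ERCC-style design: 3 genes per subgroup ratio, samples A-D
  ratios <- rep(c(0.5, 1.0, 4.0), each = 3)
  genes <- sprintf("g%02d", seq_along(ratios))
  a <- rep(1000, length(ratios))
  truth <- cbind(A = a, B = a * ratios,
                 C = expected_mixture(a, a * ratios, 0.75),
                 D = expected_mixture(a, a * ratios, 0.25))
  rownames(truth) <- genes
  long <- data.frame(sample = rep(colnames(truth), each = nrow(truth)),
                     gene_id = rep(genes, 4), expected = as.vector(truth))
  meas <- data.frame(sample = long$sample, gene_id = long$gene_id,
                     value = long$expected)  # perfect measurements
  roc <- roc_fold_change(meas, long)
  b <- roc$bins
  # expected ratio 2.0 (A vs B at 0.5x) sits in the [1.75, 2.49] bin
  expect_gt(b$n_tests[b$bin_label == "2.0"], 0)
  # controls: 1.0x subgroup pairs
  expect_equal(unique(b$n_controls), 3 * 6)
  # perfect data separate perfectly in every populated bin
  expect_true(all(b$auc[b$n_tests > 0] == 1))
})

test_that("null scores give chance-level AUC in every bin", {
  ratios <- rep(c(0.5, 1.0, 4.0), each = 10)
  genes <- sprintf("g%02d", seq_along(ratios))
  a <- rep(1000, length(ratios))
  truth <- cbind(A = a, B = a * ratios,
                 C = expected_mixture(a, a * ratios, 0.75),
                 D = expected_mixture(a, a * ratios, 0.25))
  rownames(truth) <- genes
  long <- data.frame(sample = rep(colnames(truth), each = nrow(truth)),
                     gene_id = rep(genes, 4), expected = as.vector(truth))
  set.seed(8)
  meas <- data.frame(sample = long$sample, gene_id = long$gene_id,
                     value = 10^rnorm(nrow(long), 3, 0.3))  # no signal
  roc <- roc_fold_change(meas, long)
  pop <- roc$bins[roc$bins$n_tests >= 10, ]
  expect_true(all(abs(pop$auc - 0.5) < 0.25))
})

test_that("Bland-Altman summaries are exact for shifts and track offset spread", {
  x <- log10(10^runif(20, 2, 6))
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa, c(0, 0))
  ba3 <- bland_altman(x, x + 0.3)
  expect_equal(ba3$mean_diff, 0.3)
  expect_equal(ba3$loa, c(0.3, 0.3))
  set.seed(9)
  offs <- rnorm(500, 0, 0.2)
  ba <- bland_altman(rep(3, 500), 3 + offs)
  expect_lt(abs(ba$sd_diff - 0.2), 0.02)
  expect_lt(abs(diff(ba$loa) - 2 * 1.96 * 0.2), 0.08)
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("cross-platform bias correction cancels shared per-gene offsets exactly", {
  set.seed(10)
  genes <- sprintf("g%02d", 1:30)
  ref_ab <- data.frame(gene_id = genes, A = rnorm(30, 3), B = rnorm(30, 3))
  off <- rnorm(30, 0, 0.8)
  other_ab <- data.frame(gene_id = genes, A = ref_ab$A + off, B = ref_ab$B + off)
  ref_cd <- data.frame(gene_id = genes, C = rnorm(30, 3), D = rnorm(30, 3))
  other_cd <- data.frame(gene_id = genes, C = ref_cd$C + off, D = ref_cd$D + off)
  res <- platform_bias_correction(ref_ab, other_ab, other_cd)
  expect_equal(res$corrected$C, ref_cd$C)
  expect_equal(res$corrected$D, ref_cd$D)
  expect_length(res$uncorrected_genes, 0)
  # zero offsets: identity
  res0 <- platform_bias_correction(ref_ab, ref_ab, other_cd)
  expect_equal(res0$corrected, other_cd)
  # sample-specific (A != B) bias leaves residual error for those genes
  biased <- other_ab
  biased$A[1:3] <- biased$A[1:3] + 1.0   # bias differs between A and B
  res_b <- platform_bias_correction(ref_ab, biased, other_cd)
  resid <- abs(res_b$corrected$C - ref_cd$C)
  expect_true(all(resid[1:3] > 0.4))
  expect_true(all(resid[-(1:3)] < 1e-9))
  # missing gene is flagged, not silently corrected
  res_m <- platform_bias_correction(ref_ab[-1, ], other_ab[-1, ], other_cd)
  expect_equal(res_m$uncorrected_genes, genes[1])
  expect_true(is.na(res_m$corrected$C[1]))
})

test_that("read budgets reproduce the worked two-target example", {
  b <- read_budget(c(1e6, 1), min_reads = 15)
  expect_equal(b$traditional_reads, 15000015)
  # n equimolar targets need exactly 15 n reads either way
  eq <- read_budget(rep(100, 7), min_reads = 15, fractions = rep(1 / 7, 7))
  expect_equal(eq$traditional_reads, 105)
  expect_equal(eq$competitive_reads, 105)
  expect_equal(eq$fold_reduction, 1)
  expect_error(read_budget(numeric(0)), "empty")
  expect_error(read_budget(c(1, -1)), "> 0")
})

test_that("plateau normalization collapses a 1e6-fold range to ~1e3-fold", {
  pcr <- simulate_competitive_pcr(c(1e8, 1e2), c(1e5, 1e5), jitter_log10 = 0)
  expect_equal(pcr$nt_fraction[1], 1e8 / (1e8 + 1e5))
  expect_equal(pcr$nt_fraction[2], 1e2 / (1e2 + 1e5))
  reduction <- (1e8 / 1e2) / (pcr$nt_fraction[1] / pcr$nt_fraction[2])
  expect_equal(reduction, 1000, tolerance = 1e-3)
})

test_that("read-budget fold reduction grows with dynamic range", {
  frac <- c(0.5, 0.5)
  prev <- 0
  for (decades in 2:6) {
    b <- read_budget(c(10^decades, 1), fractions = frac)
    expect_gte(b$fold_reduction, prev)
    prev <- b$fold_reduction
  }
})

test_that("the exact Poisson test meets the 15-read benchmark and is conservative", {
  p <- detection_power(15, 2, 0.05)
  expect_lte(p$type1, 0.05)
  expect_lte(p$type2, 0.20)
  # Monte-Carlo oracle for the same rejection region
  set.seed(11)
  x0 <- rpois(2e5, 15); x1 <- rpois(2e5, 30)
  mc_t1 <- mean(x0 <= p$reject_low | x0 >= p$reject_high)
  mc_t2 <- mean(x1 > p$reject_low & x1 < p$reject_high)
  expect_equal(p$type1, mc_t1, tolerance = 0.005)
  expect_equal(p$type2, mc_t2, tolerance = 0.005)
})

test_that("Poisson test edge behaviour: null fold, large counts, conservativeness", {
  p1 <- detection_power(15, 1, 0.05)
  expect_equal(p1$type2, 1 - p1$type1)
  expect_lt(detection_power(1500, 2, 0.05)$type2, 1e-6)
  # type1 <= alpha for a grid of null means; type2 non-increasing in the mean
  prev_t2 <- Inf
  for (lam in c(5, 15, 50, 200)) {
    p <- detection_power(lam, 2, 0.05)
    expect_lte(p$type1, 0.05)
    expect_lte(p$type2, prev_t2)
    prev_t2 <- p$type2
  }
})
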