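test_that("the competitive estimator multiplies the NT:IS ratio by the IS input", {
  expect_equal(estimate_concentration(100, 100, 1000)$nc, 1000)
  expect_equal(estimate_concentration(300, 100, 1e4)$nc, 3e4)
  und <- estimate_concentration(10, 0, 1e3)
  expect_true(is.na(und$nc))
  expect_equal(und$flag, "undefined_is_zero")
  bel <- estimate_concentration(0, 50, 1e3)
  expect_equal(bel$flag, "below_detection")
  expect_equal(bel$detection_bound, 20)
  expect_error(estimate_concentration(1, 1, 0), "sc must be")
})

test_that("NC is equivariant in SC and invariant to read depth (core property)", {
  set.seed(31)
  for (rep_i in 1:5) {
    nt <- sample(10:5000, 20); is_ <- sample(10:5000, 20)
    sc <- 10^runif(20, 2, 6)
    base <- estimate_concentration(nt, is_, sc)$nc
    k <- 10^runif(1, -2, 2)
    expect_equal(estimate_concentration(nt, is_, sc * k)$nc, base * k)
    m <- sample(2:50, 1)  # deeper sequencing scales both counts
    expect_equal(estimate_concentration(nt * m, is_ * m, sc)$nc, base)
  }
})

make_clean_estimates <- function(n_genes = 30, n_reps = 6, seed = 50) {
  set.seed(seed)
  true_nc <- 10^runif(n_genes, 3, 5)
  ladder <- 1e6 / 3^(0:(n_reps - 1))
  grid <- expand.grid(gene = seq_len(n_genes), i = seq_len(n_reps))
  is_count <- rep(20000L, nrow(grid))
  nt_count <- as.integer(round(is_count * true_nc[grid$gene] / ladder[grid$i]))
  counts <- data.frame(sample = "A", dilution_index = grid$i,
                       gene_id = sprintf("g%02d", grid$gene),
                       nt_count = nt_count, is_count = is_count)
  mix <- data.frame(dilution_index = rep(seq_len(n_reps), each = n_genes),
                    gene_id = rep(sprintf("g%02d", seq_len(n_genes)), n_reps),
                    sc = rep(ladder, each = n_genes))
  list(counts = count_table(counts), mix = is_mix(mix),
       true_nc = setNames(true_nc, sprintf("g%02d", seq_len(n_genes))))
}

test_that("pipetting correction recovers an injected replicate offset", {
  cl <- make_clean_estimates()
  est <- replicate_estimates(cl$counts, cl$mix)
  # inject +0.3 log10 into every gene of replicate 3
  est$nc_raw[est$dilution_index == 3] <- est$nc_raw[est$dilution_index == 3] * 10^0.3
  corrected <- correct_pipetting(est)
  off <- attr(corrected, "offsets")
  expect_equal(off$offset_log10[off$dilution_index == 3], 0.3, tolerance = 0.02)
  expect_equal(max(abs(off$offset_log10[off$dilution_index != 3])), 0, tolerance = 0.02)
  clean <- replicate_estimates(cl$counts, cl$mix)
  expect_equal(log10(corrected$nc_corrected[est$dilution_index == 3]),
               log10(clean$nc_raw[est$dilution_index == 3]), tolerance = 0.02)
})

test_that("perfectly consistent replicates are a fixed point of the correction", {
  cl <- make_clean_estimates()
  est <- replicate_estimates(cl$counts, cl$mix)
  corrected <- correct_pipetting(est)
  # rounding NT counts to integers leaves only sub-0.01 log10 wobble
  expect_equal(log10(corrected$nc_corrected), log10(est$nc_raw), tolerance = 0.005)
})

test_that("single-replicate input passes through unchanged with a warning", {
  cl <- make_clean_estimates(n_reps = 1)
  est <- replicate_estimates(cl$counts, cl$mix)
  expect_warning(out <- correct_pipetting(est), "fewer than 2 dilution replicates")
  expect_equal(out$nc_corrected, est$nc_raw)
})

test_that("the count filter drops replicates below 15 reads on either side", {
  counts <- count_table(data.frame(sample = "A", dilution_index = 1:2,
                                   gene_id = "g1",
                                   nt_count = c(15L, 14L), is_count = c(15L, 200L)))
  mix <- is_mix(data.frame(dilution_index = 1:2, gene_id = "g1", sc = c(1e4, 1e3)))
  q <- quantify(counts, mix, pipetting_correction = FALSE)
  expect_equal(q$summary$n_valid, 1L)
  expect_equal(q$summary$status, "ok")
  expect_equal(q$summary$nc_median, 1e4)  # only the (15, 15) replicate survives
})

test_that("dispersion at or above 1.00 log10 invalidates the gene", {
  vals <- c(3.0, 3.1, 5.6)
  expect_gte(sd(vals), 1.00)  # the dispersion statistic that triggers the filter
  counts <- count_table(data.frame(sample = "A", dilution_index = 1:3,
                                   gene_id = "g1", nt_count = 1000L,
                                   is_count = 1000L))
  mix <- is_mix(data.frame(dilution_index = 1:3, gene_id = "g1", sc = 10^vals))
  q <- quantify(counts, mix, pipetting_correction = FALSE)
  expect_equal(q$summary$status, "high_cv")
  expect_true(is.na(q$summary$nc_median))
})

test_that("identical replicates summarize to themselves with zero dispersion", {
  counts <- count_table(data.frame(sample = "A", dilution_index = 1:3,
                                   gene_id = "g1", nt_count = 100L, is_count = 100L))
  mix <- is_mix(data.frame(dilution_index = 1:3, gene_id = "g1", sc = 1e4))
  for (s in c("median", "average", "least_squares", "weighted_least_squares")) {
    q <- quantify(counts, mix, qc = qc_params(summarizer = s),
                  pipetting_correction = FALSE)
    expect_equal(q$summary$nc_median, 1e4)
    expect_equal(q$summary$cv_log10, 0)
  }
})

test_that("least-squares summarizers reduce to (weighted) geometric means", {
  counts <- count_table(data.frame(sample = "A", dilution_index = 1:3,
                                   gene_id = "g1",
                                   nt_count = c(100L, 400L, 900L),
                                   is_count = c(100L, 100L, 100L)))
  mix <- is_mix(data.frame(dilution_index = 1:3, gene_id = "g1", sc = 1e4))
  nc <- c(1e4, 4e4, 9e4)
  q <- quantify(counts, mix, qc = qc_params(summarizer = "least_squares"),
                pipetting_correction = FALSE)
  expect_equal(q$summary$nc_median, 10^mean(log10(nc)))
  qw <- quantify(counts, mix, qc = qc_params(summarizer = "weighted_least_squares"),
                 pipetting_correction = FALSE)
  w <- 1 / ((1 / c(100, 400, 900) + 1 / 100) / log(10)^2)
  expect_equal(qw$summary$nc_median, 10^(sum(w * log10(nc)) / sum(w)))
})

test_that("zero surviving replicates is reported, never summarized", {
  counts <- count_table(data.frame(sample = "A", dilution_index = 1:2,
                                   gene_id = "g1", nt_count = c(3L, 0L),
                                   is_count = c(2L, 500L)))
  mix <- is_mix(data.frame(dilution_index = 1:2, gene_id = "g1", sc = c(1e4, 1e3)))
  q <- quantify(counts, mix, pipetting_correction = FALSE)
  expect_equal(q$summary$status, "no_valid_replicates")
  expect_equal(q$summary$n_valid, 0L)
})

test_that("noise-free data make every QC combination perfect; retention picks best", {
  cl <- make_clean_estimates(n_genes = 10, n_reps = 4)
  expected <- data.frame(sample = "A", gene_id = names(cl$true_nc),
                         expected = cl$true_nc)
  res <- optimize_summarization(cl$counts, cl$mix, expected,
                                summarizers = c("average", "median"),
                                min_counts = c(5L, 15L), max_cv_log10 = 1.0)
  expect_true(all(res$grid$r2 > 0.999))
  expect_equal(res$best$n_retained, max(res$grid$n_retained))
})

test_that("grid of one returns that combination with its objective", {
  cl <- make_clean_estimates(n_genes = 6, n_reps = 4)
  expected <- data.frame(sample = "A", gene_id = names(cl$true_nc),
                         expected = cl$true_nc)
  res <- optimize_summarization(cl$counts, cl$mix, expected,
                                summarizers = "median", min_counts = 15L,
                                max_cv_log10 = 1.0)
  expect_equal(nrow(res$grid), 1L)
  expect_equal(res$best$summarizer, "median")
  expect_true(res$grid$pareto)
})

test_that("median/15/1.00 sits on or near the Pareto front under Poisson noise", {
  sim <- simulate_endogenous_study(seed = 77, n_genes = 40,
                                   reads_per_library = 3e4,
                                   is_calibration_log10 = 0)
  truth <- sim$truth$copies
  expected <- data.frame(sample = rep(colnames(truth), each = nrow(truth)),
                         gene_id = rep(rownames(truth), ncol(truth)),
                         expected = as.vector(truth))
  res <- optimize_summarization(sim$counts, sim$mix, expected,
                                summarizers = c("average", "median"),
                                min_counts = c(5L, 15L),
                                max_cv_log10 = c(0.5, 1.0))
  g <- res$grid
  ref <- g[g$summarizer == "median" & g$min_counts == 15 & g$max_cv_log10 == 1.0, ]
  rivals <- g[g$n_retained >= ref$n_retained, ]
  expect_gte(ref$r2, max(rivals$r2) - 0.01)
})
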