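#' Fit a competitive titration line
#'
#' As internal-standard input SC rises, the NT:IS read ratio must fall in
#' direct proportion: ordinary least squares of log10(ratio) on log10(SC)
#' should give a slope near -1 with the 95% prediction interval from the
#' standard linear-regression formula. At least three titration points are
#' required; fewer yield a no-fit result rather than an error.
#'
#' @param sc IS copies loaded at each titration point.
#' @param ratio measured NT:IS read ratio at each point (must be finite
#'   and > 0 to enter the fit).
#' @param gene_id optional label carried on the result.
#' @return object of class `titration_fit`: `slope`, `intercept`, `r2`,
#'   `pi95` (per-point prediction half-widths), `n_points`, `status`
#'   (`ok`/`insufficient_points`), and the underlying `model`.
#' @examples
#' f <- fit_titration(10^(2:6), 1e5 / 10^(2:6))
#' coef(f)  # slope -1, intercept 5
#' @export
fit_titration <- function(sc, ratio, gene_id = NA_character_) {
  keep <- is.finite(sc) & is.finite(ratio) & sc > 0 & ratio > 0
  if (sum(keep) < 3L)
    return(structure(list(gene_id = gene_id, slope = NA_real_,
                          intercept = NA_real_, r2 = NA_real_,
                          pi95 = NA_real_, n_points = sum(keep),
                          status = "insufficient_points", model = NULL),
                     class = "titration_fit"))
  d <- data.frame(x = log10(sc[keep]), y = log10(ratio[keep]))
  fit <- lm(y ~ x, data = d)
  # predict() notes that intervals at the fitted points refer to future
  # responses -- which is the intended use here
  pi <- suppressWarnings(predict(fit, interval = "prediction", level = 0.95))
  structure(list(gene_id = gene_id,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 # noise-free titrations fit exactly; the perfect-fit note
                 # from summary.lm is expected there
                 r2 = suppressWarnings(summary(fit)$r.squared),
                 pi95 = unname((pi[, "upr"] - pi[, "lwr"]) / 2),
                 n_points = nrow(d),
                 status = "ok", model = fit),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("Titration fit (%s): no fit (%d points; need >= 3)\n",
                x$gene_id, x$n_points))
  } else {
    cat(sprintf("Titration fit (%s): slope %.3f, intercept %.3f, R^2 %.4f, n = %d\n",
                x$gene_id, x$slope, x$intercept, x$r2, x$n_points))
  }
  invisible(x)
}

#' @export
coef.titration_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Per-assay titration slopes for a whole study
#'
#' Fits [fit_titration()] per (sample, gene) on the replicate table,
#' using only replicates with both counts at or above `min_counts`.
#'
#' @param estimates output of [replicate_estimates()].
#' @param min_counts count filter for points entering each fit (default 15).
#' @return data.frame with `sample`, `gene_id`, `slope`, `r2`, `n_points`.
#' @export
titration_slopes <- function(estimates, min_counts = 15L) {
  e <- estimates[estimates$nt_count >= min_counts &
                 estimates$is_count >= min_counts, , drop = FALSE]
  sp <- split(seq_len(nrow(e)), list(e$sample, e$gene_id), drop = TRUE)
  rows <- lapply(sp, function(ix) {
    d <- e[ix, , drop = FALSE]
    f <- fit_titration(d$sc, d$nt_count / d$is_count, d$gene_id[1])
    data.frame(sample = d$sample[1], gene_id = d$gene_id[1],
               slope = f$slope, r2 = f$r2, n_points = f$n_points)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[!is.na(out$slope), , drop = FALSE]
}

#' Expected coefficient of variation under Poisson sampling
#'
#' Sampling n molecule copies (or reads) at random is Poisson, so the
#' expected CV is 1 / sqrt(n): 10% at 100 copies, ~25.8% at 15.
#'
#' @param copies counts sampled (> 0).
#' @return CV as a fraction.
#' @export
expected_cv_poisson <- function(copies) {
  if (any(copies <= 0)) stopf("copies must be > 0")
  1 / sqrt(copies)
}

#' Expected abundance in a known two-sample mixture
#'
#' Samples C and D are 3:1 and 1:3 mixtures of A and B, so
#' expected C = 0.75 A + 0.25 B and expected D = 0.25 A + 0.75 B.
#'
#' @param a,b component abundances (copies).
#' @param weight_a mixing fraction of `a` in `[0, 1]`.
#' @return mixture abundance.
#' @export
expected_mixture <- function(a, b, weight_a) {
  stopifnot(all(weight_a >= 0 & weight_a <= 1))
  weight_a * a + (1 - weight_a) * b
}

#' Rank-statistic AUC with Hanley-McNeil confidence interval
#'
#' AUC is the Mann-Whitney probability that a random test score exceeds a
#' random control score (ties count half); the 95% CI uses the
#' Hanley-McNeil normal approximation. Invariant to monotone transforms of
#' the scores.
#'
#' @param controls,tests numeric score vectors.
#' @return list with `auc`, `ci95` (length 2), `n_controls`, `n_tests`.
#' @export
auc_rank <- function(controls, tests) {
  n1 <- length(controls); n2 <- length(tests)
  if (n1 == 0L || n2 == 0L)
    return(list(auc = NA_real_, ci95 = c(NA_real_, NA_real_),
                n_controls = n1, n_tests = n2))
  r <- rank(c(controls, tests))
  u <- sum(r[(n1 + 1):(n1 + n2)]) - n2 * (n2 + 1) / 2
  auc <- u / (n1 * n2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n2 - 1) * (q1 - auc^2) +
                (n1 - 1) * (q2 - auc^2)) / (n1 * n2))
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * qnorm(0.975) * se))
  list(auc = auc, ci95 = ci, n_controls = n1, n_tests = n2)
}

FOLD_CHANGE_BINS <- data.frame(
  bin_label = c("1.1", "1.25", "1.5", "2.0", ">=4.0"),
  low = c(1.05, 1.175, 1.375, 1.75, 2.5),
  high = c(1.174, 1.374, 1.74, 2.49, 10.0))

#' ROC accuracy to detect known fold changes
#'
#' Every unordered sample pair is compared per gene: the score is the
#' measured abundance ratio oriented by the expected direction. Pairs whose
#' expected ratio is exactly 1 are controls; pairs whose expected ratio
#' falls in a fold-change bin ([1.05-1.174], [1.175-1.374], [1.375-1.74],
#' [1.75-2.49], [2.5-10.0]) are that bin's tests. AUC per bin by the rank
#' statistic with Hanley-McNeil 95% CI.
#'
#' @param measured data.frame with `sample`, `gene_id`, `value` (measured
#'   copies; non-positive or missing values are excluded pairwise).
#' @param expected data.frame with `sample`, `gene_id`, `expected` (known
#'   copies defining the true ratios).
#' @return object of class `fold_change_roc`: data.frame `bins` with
#'   per-bin `auc`, `ci_lo`, `ci_hi`, `n_controls`, `n_tests`, plus the
#'   score vectors in attribute `"scores"`.
#' @export
roc_fold_change <- function(measured, expected) {
  m <- merge(measured, expected, by = c("sample", "gene_id"))
  m <- m[is.finite(m$value) & m$value > 0 & is.finite(m$expected) & m$expected > 0, ]
  samples <- sort(unique(m$sample))
  if (length(samples) < 2L) stopf("need at least 2 samples with measurements")
  ctrl <- numeric(0)
  test_scores <- vector("list", nrow(FOLD_CHANGE_BINS))
  for (i in seq_along(samples)) for (j in seq_along(samples)) {
    if (i >= j) next
    a <- m[m$sample == samples[i], ]
    b <- m[m$sample == samples[j], ]
    p <- merge(a, b, by = "gene_id", suffixes = c(".a", ".b"))
    if (!nrow(p)) next
    exp_ratio <- p$expected.a / p$expected.b
    meas_ratio <- p$value.a / p$value.b
    flip <- exp_ratio < 1
    exp_ratio[flip] <- 1 / exp_ratio[flip]
    meas_ratio[flip] <- 1 / meas_ratio[flip]
    is_ctrl <- abs(exp_ratio - 1) < 1e-9
    ctrl <- c(ctrl, meas_ratio[is_ctrl])
    for (k in seq_len(nrow(FOLD_CHANGE_BINS))) {
      inbin <- !is_ctrl & exp_ratio >= FOLD_CHANGE_BINS$low[k] &
        exp_ratio <= FOLD_CHANGE_BINS$high[k]
      if (any(inbin))
        test_scores[[k]] <- c(test_scores[[k]], meas_ratio[inbin])
    }
  }
  bins <- FOLD_CHANGE_BINS
  bins$auc <- bins$ci_lo <- bins$ci_hi <- NA_real_
  bins$n_controls <- length(ctrl)
  bins$n_tests <- vapply(test_scores, length, integer(1))
  for (k in seq_len(nrow(bins))) {
    a <- auc_rank(ctrl, test_scores[[k]])
    bins$auc[k] <- a$auc
    bins$ci_lo[k] <- a$ci95[1]
    bins$ci_hi[k] <- a$ci95[2]
  }
  structure(list(bins = bins),
            scores = list(controls = ctrl, tests = test_scores),
            class = "fold_change_roc")
}

#' @export
print.fold_change_roc <- function(x, ...) {
  cat("Fold-change detection (ROC AUC vs expected-ratio-1 controls):\n")
  b <- x$bins
  for (k in seq_len(nrow(b)))
    cat(sprintf("  %5s-fold [%.3f-%.3f]: AUC %s (95%% CI %s-%s; controls %d, tests %d)\n",
                b$bin_label[k], b$low[k], b$high[k],
                ifelse(is.na(b$auc[k]), "NA", sprintf("%.3f", b$auc[k])),
                ifelse(is.na(b$ci_lo[k]), "NA", sprintf("%.3f", b$ci_lo[k])),
                ifelse(is.na(b$ci_hi[k]), "NA", sprintf("%.3f", b$ci_hi[k])),
                b$n_controls[k], b$n_tests[k]))
  invisible(x)
}

#' Bland-Altman agreement on the log10 scale
#'
#' @param x,y paired log10 measurements.
#' @return object of class `bland_altman`: `mean_diff`, `sd_diff`, `loa`
#'   (limits of agreement, mean +- 1.96 SD), `n`.
#' @export
bland_altman <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 2L) stopf("need at least 2 finite pairs")
  d <- y[keep] - x[keep]
  md <- mean(d); s <- sd(d)
  structure(list(mean_diff = md, sd_diff = s,
                 loa = md + c(-1.96, 1.96) * s, n = sum(keep)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (log10): mean diff %.4f, LoA [%.4f, %.4f], n = %d\n",
              x$mean_diff, x$loa[1], x$loa[2], x$n))
  invisible(x)
}

#' Correct cross-platform systematic bias using samples A and B
#'
#' Most cross-platform disagreement per gene is a systematic offset. The
#' per-gene offset is the mean log10 difference (other - reference) over
#' samples A and B; it is subtracted from the other platform's C and D
#' measurements. Genes missing from A or B on either platform are left
#' uncorrected and flagged.
#'
#' @param ref_ab,other_ab data.frames with `gene_id` and log10 columns
#'   `A`, `B` for the reference and other platform.
#' @param other_cd data.frame with `gene_id` and log10 measurement columns
#'   (e.g. `C`, `D`) from the other platform.
#' @return list with `corrected` (same shape as `other_cd`), `offsets`
#'   (per-gene log10 offsets) and `uncorrected_genes`.
#' @export
platform_bias_correction <- function(ref_ab, other_ab, other_cd) {
  m <- merge(ref_ab, other_ab, by = "gene_id", suffixes = c(".ref", ".oth"))
  off <- data.frame(gene_id = m$gene_id,
                    offset_log10 = rowMeans(cbind(m$A.oth - m$A.ref,
                                                  m$B.oth - m$B.ref)))
  off <- off[is.finite(off$offset_log10), ]
  corrected <- other_cd
  hit <- match(other_cd$gene_id, off$gene_id)
  val_cols <- setdiff(names(other_cd), "gene_id")
  for (col in val_cols)
    corrected[[col]] <- other_cd[[col]] - off$offset_log10[hit]
  list(corrected = corrected, offsets = off,
       uncorrected_genes = other_cd$gene_id[is.na(hit)])
}

#' Sequencing read budgets: traditional vs competitive
#'
#' For traditional library preparation, read shares mirror input copies,
#' so observing the rarest target `min_reads` times requires
#' `ceil(min_reads * sum(copies) / min(copies))` total reads (two targets
#' over a 10^6-fold range need 15,000,015 reads at the 15-read benchmark).
#' For competitive plateau-normalized libraries the budget is determined
#' by the smallest realized read fraction: `ceil(min_reads /
#' min(fractions))`.
#'
#' @param copies per-target input copies (> 0).
#' @param min_reads minimum reads per target (default 15).
#' @param fractions realized post-normalization per-target read fractions
#'   (optional; enables the competitive budget).
#' @return object of class `read_budget`: `traditional_reads`,
#'   `competitive_reads`, `fold_reduction`, `min_reads`, `n_targets`.
#' @examples
#' read_budget(c(1e6, 1))$traditional_reads  # 15000015
#' @export
read_budget <- function(copies, min_reads = 15L, fractions = NULL) {
  if (length(copies) == 0L) stopf("empty copies list")
  if (any(copies <= 0)) stopf("all copies must be > 0")
  if (min_reads < 1L) stopf("min_reads must be >= 1")
  trad <- ceiling(min_reads * sum(copies) / min(copies))
  comp <- NA_real_
  if (!is.null(fractions)) {
    if (any(fractions <= 0)) stopf("all read fractions must be > 0")
    comp <- ceiling(min_reads / min(fractions))
  }
  structure(list(traditional_reads = trad, competitive_reads = comp,
                 fold_reduction = if (is.na(comp)) NA_real_ else trad / comp,
                 min_reads = min_reads, n_targets = length(copies)),
            class = "read_budget")
}

#' @export
print.read_budget <- function(x, ...) {
  cat(sprintf("Read budget (%d targets, >= %d reads each):\n",
              x$n_targets, x$min_reads))
  cat(sprintf("  traditional: %s reads\n",
              format(x$traditional_reads, big.mark = ",", scientific = FALSE)))
  if (!is.na(x$competitive_reads))
    cat(sprintf("  competitive: %s reads (%.0f-fold reduction)\n",
                format(x$competitive_reads, big.mark = ",", scientific = FALSE),
                x$fold_reduction))
  invisible(x)
}

#' Study-level read budget from a binned count table
#'
#' From realized study counts, each target-sample cell's best read share is
#' its largest NT read fraction over that sample's dilution libraries.
#' Because libraries are pooled at a chosen stoichiometry, each sample's
#' pool is sized independently by its own worst target
#' (`min_reads / min best share`), and the competitive budget is the sum of
#' the per-sample requirements. The traditional budget uses the measured
#' copies (`nc` values) of the same cells.
#'
#' @param counts a [count_table()] for the study.
#' @param nc data.frame with `sample`, `gene_id`, `value` (measured copies
#'   per cell; e.g. the `ok` rows of [quantify()]'s summary).
#' @param min_reads minimum reads per target (default 15).
#' @return a [read_budget()] object; per-sample requirements are attached
#'   as attribute `"per_sample"`.
#' @export
study_read_budget <- function(counts, nc, min_reads = 15L) {
  counts <- count_table(counts)
  lib_key <- paste(counts$sample, counts$dilution_index)
  lib_tot <- tapply(counts$nt_count + counts$is_count, lib_key, sum)
  share <- counts$nt_count / as.numeric(lib_tot[lib_key])
  cell_key <- paste(counts$sample, counts$gene_id)
  best_share <- tapply(share, cell_key, max)
  measured <- is.finite(nc$value) & nc$value > 0
  keep <- paste(nc$sample, nc$gene_id)[measured]
  best_share <- best_share[names(best_share) %in% keep]
  best_share <- best_share[best_share > 0]
  cell_sample <- sub(" .*$", "", names(best_share))
  per_sample <- tapply(best_share, cell_sample,
                       function(s) ceiling(min_reads / min(s)))
  out <- read_budget(nc$value[measured], min_reads = min_reads)
  out$competitive_reads <- sum(per_sample)
  out$fold_reduction <- out$traditional_reads / out$competitive_reads
  attr(out, "per_sample") <- per_sample
  out
}

#' Exact Poisson detection power at a read-count benchmark
#'
#' One-sample exact two-sided Poisson test of an observed read count
#' against a known reference mean (the IS-anchored expectation): the
#' rejection region takes the largest lower tail and smallest upper tail
#' each with probability at most alpha/2 under the null. Both error rates
#' are exact tail sums, no simulation. At the 15-read benchmark a 2-fold
#' change is detected with type I error below 0.05 and type II error
#' below 0.20.
#'
#' @param null_mean_reads null mean read count (>= 1).
#' @param fold fold change defining the alternative mean (> 0).
#' @param alpha nominal two-sided level in (0, 1).
#' @return object of class `detection_power`: `type1`, `type2`,
#'   `reject_low`, `reject_high` (reject when X <= low or X >= high),
#'   `null_mean`, `alt_mean`, `alpha`.
#' @examples
#' detection_power(15, 2)  # type1 ~0.037, type2 ~0.115
#' @export
detection_power <- function(null_mean_reads, fold = 2, alpha = 0.05) {
  stopifnot(null_mean_reads >= 1, fold > 0, alpha > 0, alpha < 1)
  lam0 <- null_mean_reads
  lam1 <- fold * null_mean_reads
  # largest lo with P(X <= lo) <= alpha/2 (lo = -1: no lower rejection)
  lo <- -1L
  while (ppois(lo + 1L, lam0) <= alpha / 2) lo <- lo + 1L
  # smallest hi with P(X >= hi) <= alpha/2
  hi <- as.integer(ceiling(lam0))
  while (ppois(hi - 1L, lam0, lower.tail = FALSE) > alpha / 2) hi <- hi + 1L
  p_lo0 <- if (lo >= 0L) ppois(lo, lam0) else 0
  p_hi0 <- ppois(hi - 1L, lam0, lower.tail = FALSE)
  p_lo1 <- if (lo >= 0L) ppois(lo, lam1) else 0
  p_hi1 <- ppois(hi - 1L, lam1, lower.tail = FALSE)
  structure(list(type1 = p_lo0 + p_hi0,
                 type2 = 1 - (p_lo1 + p_hi1),
                 reject_low = lo, reject_high = hi,
                 null_mean = lam0, alt_mean = lam1, alpha = alpha),
            class = "detection_power")
}

#' @export
print.detection_power <- function(x, ...) {
  cat(sprintf("Exact Poisson test, null mean %.4g reads, alternative %.4g (alpha %.3g):\n",
              x$null_mean, x$alt_mean, x$alpha))
  cat(sprintf("  reject when X <= %d or X >= %d\n", x$reject_low, x$reject_high))
  cat(sprintf("  type I error: %.4f   type II error: %.4f (power %.4f)\n",
              x$type1, x$type2, 1 - x$type2))
  invisible(x)
}
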