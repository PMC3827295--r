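#' Estimate native copies from one replicate's counts
#'
#' The competitive estimator: native copies per library preparation are the
#' NT:IS read ratio times the known internal-standard input,
#' NC_i = (NT_i / IS_i) * SC_i. Degenerate counts are flagged rather than
#' raised: `is_count == 0` gives an undefined estimate and `nt_count == 0`
#' a below-detection bound of SC_i / IS_i copies.
#'
#' @param nt_count,is_count non-negative integer read counts (vectorized).
#' @param sc known IS copies loaded (SC_i), > 0.
#' @return data.frame with `nc` (NA when flagged), `flag`
#'   (`ok`/`undefined_is_zero`/`below_detection`) and `detection_bound`
#'   (copies; NA unless below detection).
#' @examples
#' estimate_concentration(300, 100, 1e4)  # 3e4 copies
#' @export
estimate_concentration <- function(nt_count, is_count, sc) {
  if (any(sc <= 0)) stopf("sc must be > 0")
  n <- max(length(nt_count), length(is_count), length(sc))
  nt_count <- rep_len(nt_count, n); is_count <- rep_len(is_count, n)
  sc <- rep_len(sc, n)
  nc <- ifelse(is_count > 0, nt_count / is_count * sc, NA_real_)
  flag <- rep("ok", n)
  flag[is_count == 0] <- "undefined_is_zero"
  below <- is_count > 0 & nt_count == 0
  flag[below] <- "below_detection"
  nc[below] <- NA_real_
  data.frame(nc = nc, flag = flag,
             detection_bound = ifelse(below, sc / is_count, NA_real_))
}

#' Per-replicate estimates for a whole count table
#'
#' Joins a count table with the IS mix table and applies
#' [estimate_concentration()] to every (sample, dilution, gene) record.
#'
#' @param counts a [count_table()].
#' @param mix an [is_mix()] table.
#' @return data.frame of replicate estimates with columns `sample`,
#'   `gene_id`, `dilution_index`, `nt_count`, `is_count`, `sc`, `nc_raw`,
#'   `nc_corrected` (initially equal to `nc_raw`), `flag`.
#' @export
replicate_estimates <- function(counts, mix) {
  counts <- count_table(counts)
  mix <- is_mix(mix)
  m <- merge(counts, mix, by = c("dilution_index", "gene_id"))
  if (nrow(m) < nrow(counts))
    warnf("%d count record(s) had no matching IS mix entry and were dropped",
          nrow(counts) - nrow(m))
  est <- estimate_concentration(m$nt_count, m$is_count, m$sc)
  out <- data.frame(sample = m$sample, gene_id = m$gene_id,
                    dilution_index = m$dilution_index,
                    nt_count = m$nt_count, is_count = m$is_count, sc = m$sc,
                    nc_raw = est$nc, nc_corrected = est$nc, flag = est$flag)
  out[order(out$sample, out$gene_id, out$dilution_index), , drop = FALSE]
}

#' Correct systematic per-replicate pipetting offsets
#'
#' A pipetting error in loading sample or IS mixture shifts every gene's
#' NC_i of that dilution replicate by a common factor. Per sample, each
#' replicate's offset is the median over genes of
#' log10(NC_i) - log10(cross-replicate median NC for that gene), using only
#' genes with valid estimates in at least `min_replicates` replicates; the
#' offset is subtracted on the log10 scale. With no multi-replicate genes
#' the correction is skipped with a warning.
#'
#' @param estimates output of [replicate_estimates()].
#' @param min_replicates minimum valid replicates for a gene to inform the
#'   offsets (default 3).
#' @return `estimates` with `nc_corrected` filled in; per-(sample,
#'   replicate) offsets are attached as attribute `"offsets"`.
#' @export
correct_pipetting <- function(estimates, min_replicates = 3L) {
  est <- estimates
  est$nc_corrected <- est$nc_raw
  offsets <- NULL
  for (s in unique(est$sample)) {
    rows <- which(est$sample == s)
    e <- est[rows, , drop = FALSE]
    if (length(unique(e$dilution_index)) < 2L) {
      warnf("sample %s: fewer than 2 dilution replicates; pipetting correction skipped", s)
      next
    }
    valid <- is.finite(e$nc_raw) & e$nc_raw > 0
    reps_per_gene <- tapply(valid, e$gene_id, sum)
    ref_genes <- names(reps_per_gene)[reps_per_gene >= min_replicates]
    if (length(ref_genes) == 0L) {
      warnf("sample %s: no gene has >= %d valid replicates; pipetting correction skipped",
            s, min_replicates)
      next
    }
    use <- valid & e$gene_id %in% ref_genes
    gene_med <- tapply(log10(e$nc_raw[use]), e$gene_id[use], median)
    dev <- log10(e$nc_raw[use]) - gene_med[e$gene_id[use]]
    off <- tapply(dev, e$dilution_index[use], median)
    off_all <- off[as.character(e$dilution_index)]
    off_all[is.na(off_all)] <- 0
    est$nc_corrected[rows] <- 10^(log10(e$nc_raw) - off_all)
    offsets <- rbind(offsets,
                     data.frame(sample = s,
                                dilution_index = as.integer(names(off)),
                                offset_log10 = as.numeric(off)))
  }
  attr(est, "offsets") <- offsets
  est
}

#' Quality-control parameters for gene summarization
#'
#' Defaults are the empirically selected combination: the median of
#' replicate NC_i values that have at least 15 sequencing counts for both
#' NT_i and IS_i, with inter-replicate dispersion of log10(NC_i) below
#' 1.00 (a 10-fold spread).
#'
#' @param min_counts minimum reads for both NT_i and IS_i (default 15).
#' @param max_cv_log10 maximum SD of log10(NC_i) across surviving
#'   replicates (default 1.00).
#' @param summarizer one of `"median"`, `"average"`, `"least_squares"`,
#'   `"weighted_least_squares"`. The least-squares variants fit the
#'   titration log10(NT:IS) against log10(SC) with slope fixed at -1 and
#'   report the intercept-implied NC, unweighted or inverse-variance
#'   weighted (Poisson counting variance).
#' @return a `qc_params` list.
#' @export
qc_params <- function(min_counts = 15L, max_cv_log10 = 1.00,
                      summarizer = c("median", "average", "least_squares",
                                     "weighted_least_squares")) {
  if (min_counts < 1L) stopf("min_counts must be >= 1")
  if (max_cv_log10 <= 0) stopf("max_cv_log10 must be > 0")
  structure(list(min_counts = as.integer(min_counts),
                 max_cv_log10 = max_cv_log10,
                 summarizer = match.arg(summarizer)),
            class = "qc_params")
}

## one (sample, gene): apply QC and summarize surviving replicates
summarize_one <- function(nt, is_, sc, nc, qc) {
  keep <- nt >= qc$min_counts & is_ >= qc$min_counts & is.finite(nc) & nc > 0
  if (!any(keep))
    return(list(nc_median = NA_real_, n_valid = 0L, cv_log10 = NA_real_,
                status = "no_valid_replicates"))
  lnc <- log10(nc[keep])
  cv <- if (length(lnc) >= 2L) sd(lnc) else 0
  if (cv >= qc$max_cv_log10)
    return(list(nc_median = NA_real_, n_valid = sum(keep), cv_log10 = cv,
                status = "high_cv"))
  value <- switch(qc$summarizer,
    median = median(nc[keep]),
    average = mean(nc[keep]),
    least_squares = 10^mean(lnc),
    weighted_least_squares = {
      w <- 1 / ((1 / nt[keep] + 1 / is_[keep]) / log(10)^2)
      10^(sum(w * lnc) / sum(w))
    })
  list(nc_median = value, n_valid = sum(keep), cv_log10 = cv, status = "ok")
}

#' Summarize replicate estimates into per-gene concentrations
#'
#' Replicates failing the count filter are dropped; survivors must have
#' log10 dispersion below `max_cv_log10` (checked when at least two
#' survive), and the remaining corrected NC_i values are summarized
#' (median by default). Invalid genes are reported with a reason, never
#' silently dropped.
#'
#' @param estimates output of [replicate_estimates()] or
#'   [correct_pipetting()].
#' @param qc a [qc_params()] list.
#' @return data.frame with one row per (sample, gene): `nc_median`,
#'   `n_valid`, `cv_log10`, `status` (`ok`/`high_cv`/`no_valid_replicates`).
#' @export
summarize_genes <- function(estimates, qc = qc_params()) {
  sp <- split(seq_len(nrow(estimates)),
              list(estimates$sample, estimates$gene_id), drop = TRUE)
  rows <- lapply(sp, function(ix) {
    e <- estimates[ix, , drop = FALSE]
    s <- summarize_one(e$nt_count, e$is_count, e$sc, e$nc_corrected, qc)
    data.frame(sample = e$sample[1], gene_id = e$gene_id[1],
               nc_median = s$nc_median, n_valid = s$n_valid,
               cv_log10 = s$cv_log10, status = s$status)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample, out$gene_id), , drop = FALSE]
}

#' Quantify a binned study end to end
#'
#' Convenience wrapper: replicate estimates, pipetting correction, and
#' QC-filtered per-gene summaries.
#'
#' @inheritParams replicate_estimates
#' @inheritParams summarize_genes
#' @param pipetting_correction apply [correct_pipetting()] (default TRUE).
#' @return object of class `campseq_quant`: list with `replicates`,
#'   `summary`, `qc`, `offsets`.
#' @export
quantify <- function(counts, mix, qc = qc_params(), pipetting_correction = TRUE) {
  est <- replicate_estimates(counts, mix)
  if (pipetting_correction) est <- correct_pipetting(est)
  structure(list(replicates = est,
                 summary = summarize_genes(est, qc),
                 qc = qc,
                 offsets = attr(est, "offsets")),
            class = "campseq_quant")
}

#' @export
print.campseq_quant <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Competitive amplicon quantification: %d samples, %d genes\n",
              length(unique(s$sample)), length(unique(s$gene_id))))
  cat(sprintf("  valid (sample, gene) cells: %d of %d  [%s]\n",
              sum(s$status == "ok"), nrow(s),
              paste(sprintf("%s: %d", names(table(s$status)), table(s$status)),
                    collapse = ", ")))
  cat(sprintf("  QC: min counts %d, max log10 CV %.2f, summarizer %s\n",
              x$qc$min_counts, x$qc$max_cv_log10, x$qc$summarizer))
  invisible(x)
}

#' Grid search over summarization methods and QC parameters
#'
#' Evaluates every combination of summarizer, count filter, and CV filter
#' against reference values (simulation truth or a titration-implied
#' expectation), scoring each by the R^2 of log10 measured vs log10
#' expected over retained (sample, gene) cells and by the number of cells
#' retained. Because the two objectives trade off, the full grid is
#' returned with a Pareto-front flag; `best` maximizes R^2 subject to a
#' floor on retention.
#'
#' @inheritParams replicate_estimates
#' @param expected data.frame with `sample`, `gene_id`, `expected` (copies).
#' @param summarizers,min_counts,max_cv_log10 grid axes.
#' @param retention_floor minimum retained cells for `best`, as a fraction
#'   of the maximum retention achieved over the grid (default 0.5).
#' @return list with `grid` (data.frame incl. `r2`, `n_retained`,
#'   `pareto`) and `best` (one row).
#' @export
optimize_summarization <- function(counts, mix, expected,
                                   summarizers = c("average", "median",
                                                   "least_squares",
                                                   "weighted_least_squares"),
                                   min_counts = c(5L, 15L, 30L),
                                   max_cv_log10 = c(0.5, 1.0, 2.0),
                                   retention_floor = 0.5) {
  grid <- expand.grid(summarizer = summarizers, min_counts = min_counts,
                      max_cv_log10 = max_cv_log10, stringsAsFactors = FALSE)
  if (nrow(grid) == 0L) stopf("empty parameter grid")
  est <- correct_pipetting(replicate_estimates(counts, mix))
  grid$r2 <- NA_real_
  grid$n_retained <- 0L
  for (k in seq_len(nrow(grid))) {
    qc <- qc_params(grid$min_counts[k], grid$max_cv_log10[k], grid$summarizer[k])
    s <- summarize_genes(est, qc)
    m <- merge(s[s$status == "ok", ], expected, by = c("sample", "gene_id"))
    m <- m[is.finite(m$nc_median) & m$nc_median > 0 & m$expected > 0, ]
    grid$n_retained[k] <- nrow(m)
    if (nrow(m) >= 3L)
      grid$r2[k] <- summary(lm(log10(nc_median) ~ log10(expected), data = m))$r.squared
  }
  # Pareto front over (r2 up, n_retained up)
  grid$pareto <- vapply(seq_len(nrow(grid)), function(k) {
    !any(grid$r2 > grid$r2[k] + 1e-12 & grid$n_retained >= grid$n_retained[k] |
           grid$r2 >= grid$r2[k] & grid$n_retained > grid$n_retained[k],
         na.rm = TRUE)
  }, logical(1))
  floor_n <- retention_floor * max(grid$n_retained)
  eligible <- which(grid$n_retained >= floor_n & is.finite(grid$r2))
  best <- if (length(eligible)) grid[eligible[which.max(grid$r2[eligible])], ]
          else grid[which.max(grid$n_retained), ]
  list(grid = grid, best = best)
}
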