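#' Run the simulate -> bin -> quantify -> evaluate pipeline
#'
#' End-to-end orchestration over the package stages: build a panel and
#' copy-number design, simulate binned counts (and optionally a FASTQ
#' library, which is then re-binned from the raw reads), quantify with QC,
#' and fit per-assay titrations. All randomness flows from the single
#' `seed` (stage seeds are derived by fixed offsets), so reruns with the
#' same seed are byte-identical. Every stage writes its artifact CSV under
#' `out_dir` and logs record counts.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer master seed.
#' @param n_genes panel size.
#' @param samples sample names.
#' @param ladder nominal IS copies per dilution (strictly decreasing).
#' @param reads_per_library reads per simulated library.
#' @param abundance_log10_range,min_copies copy-number design (see
#'   [design_samples()]).
#' @param error_rate per-base substitution rate for FASTQ emission.
#' @param from_fastq if `TRUE` (default), counts are obtained by emitting
#'   a FASTQ library and re-binning it; otherwise the simulated counts are
#'   used directly (faster for large designs).
#' @param qc a [qc_params()] list.
#' @param quiet suppress per-stage logging.
#' @return invisibly, a list with `paths` of written artifacts, the
#'   binning `report` (when `from_fastq`), the `quant` object and the
#'   titration slope table.
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_genes = 10L,
                         samples = c("A", "B"),
                         ladder = c(1e5, 1e4, 1e3),
                         reads_per_library = 2e4,
                         abundance_log10_range = 3, min_copies = 100,
                         error_rate = 0, from_fastq = TRUE,
                         qc = qc_params(), quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  libs <- expand.grid(sample = samples, dilution_index = seq_along(ladder),
                      stringsAsFactors = FALSE)
  panel <- build_panel(n_genes, libs, seed = seed + 10L)
  copies <- design_samples(n_genes, abundance_log10_range, min_copies,
                           seed = seed + 20L)
  copies <- copies[, samples, drop = FALSE]
  sim <- simulate_study_counts(copies, ladder,
                               reads_per_library = reads_per_library,
                               replicate_noise_log10 = 0.05,
                               pipetting_log10 = 0.05, seed = seed + 30L)
  paths <- c(panel = file.path(out_dir, "panel.csv"),
             mix = file.path(out_dir, "is_mix.csv"),
             counts = file.path(out_dir, "counts.csv"),
             replicates = file.path(out_dir, "replicate_estimates.csv"),
             summary = file.path(out_dir, "gene_summary.csv"),
             titration = file.path(out_dir, "titration_slopes.csv"))
  write_panel(panel, paths["panel"])
  write_is_mix(sim$mix, paths["mix"])
  say("simulate: %d genes x %d libraries, %d reads each",
      n_genes, nrow(libs), reads_per_library)

  report <- NULL
  if (from_fastq) {
    paths["fastq"] <- file.path(out_dir, "library.fastq")
    paths["manifest"] <- file.path(out_dir, "manifest.csv")
    emit_fastq(sim$counts, panel, paths["fastq"], error_rate = error_rate,
               seed = seed + 40L, manifest_path = paths["manifest"])
    binned <- bin_reads(paths["fastq"], panel)
    counts <- binned$counts
    report <- binned$report
    say("bin: %d/%d reads assigned (%d ambiguous, %d no_gene, %d conflicts)",
        report["assigned"], report["accepted"], report["ambiguous"],
        report["no_gene"], report["barcode_conflict"])
  } else {
    counts <- sim$counts
  }
  write_count_table(counts, paths["counts"])

  quant <- quantify(counts, sim$mix, qc = qc)
  write.csv(quant$replicates, paths["replicates"], row.names = FALSE)
  write.csv(quant$summary, paths["summary"], row.names = FALSE)
  say("quantify: %d of %d (sample, gene) cells valid",
      sum(quant$summary$status == "ok"), nrow(quant$summary))

  slopes <- titration_slopes(quant$replicates)
  write.csv(slopes, paths["titration"], row.names = FALSE)
  if (nrow(slopes))
    say("evaluate: mean titration slope %.3f over %d fits",
        mean(slopes$slope), nrow(slopes))
  invisible(list(paths = paths, report = report, quant = quant,
                 slopes = slopes, truth = sim$truth))
}
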