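#' Build a random assay panel
#'
#' Generates `n_genes` random 101-nt NT amplicons whose 60-nt central
#' windows are pairwise at Hamming distance >= 15 (so allele calling at a
#' mismatch cap of 5 can never cross genes), derives each IS by exactly six
#' substitutions at random central-window positions, and assigns unique
#' 4-nt forward and reverse barcode indices to every library.
#'
#' @param n_genes number of assays (>= 1).
#' @param libraries data.frame with `sample`, `dilution_index`, one row per
#'   sequencing library.
#' @param seed integer seed; panels are reproducible given the seed.
#' @param gene_ids optional gene identifiers (default `GENE001`, ...).
#' @param fwd_primer_len,rev_primer_len primer lengths flanking the
#'   amplicon.
#' @param central_offset 0-based start of the 60-nt window (default 20,
#'   centered).
#' @param min_pairwise_dist minimum central-window Hamming distance
#'   between genes (default 15).
#' @return an [assay_panel()].
#' @export
build_panel <- function(n_genes, libraries, seed = 1L, gene_ids = NULL,
                        fwd_primer_len = 20L, rev_primer_len = 21L,
                        central_offset = 20L, min_pairwise_dist = 15L) {
  stopifnot(n_genes >= 1)
  set.seed(seed)
  if (is.null(gene_ids)) gene_ids <- sprintf("GENE%03d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  windows <- matrix(NA_integer_, nrow = 0, ncol = WINDOW_LEN)
  nt_seqs <- character(n_genes)
  tries <- 0L
  base_codes <- utf8ToInt(paste(DNA_BASES, collapse = ""))
  for (g in seq_len(n_genes)) {
    repeat {
      tries <- tries + 1L
      if (tries > 50L * n_genes)
        stopf("cannot satisfy the pairwise window distance at n_genes = %d", n_genes)
      amp <- sample(base_codes, AMPLICON_LEN, replace = TRUE)
      w <- amp[(central_offset + 1L):(central_offset + WINDOW_LEN)]
      if (nrow(windows) == 0L ||
          all(rowSums(windows != matrix(w, nrow(windows), WINDOW_LEN,
                                        byrow = TRUE)) >= min_pairwise_dist)) {
        windows <- rbind(windows, w)
        nt_seqs[g] <- intToUtf8(amp)
        break
      }
    }
  }
  is_seqs <- vapply(nt_seqs, function(nt) {
    pos <- sort(sample.int(WINDOW_LEN, N_DIAGNOSTIC)) + central_offset  # 1-based
    chars <- strsplit(nt, "")[[1]]
    for (p in pos)
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)

  n_lib <- nrow(libraries)
  if (2L * n_lib > 4^INDEX_LEN)
    stopf("too many libraries for unique 4-nt indices")
  all_idx <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES, DNA_BASES),
                   1, paste, collapse = "")
  picks <- sample(all_idx, 2L * n_lib)
  assays <- data.frame(gene_id = gene_ids, nt_sequence = nt_seqs,
                       is_sequence = is_seqs,
                       fwd_primer_len = fwd_primer_len,
                       rev_primer_len = rev_primer_len,
                       central_offset = central_offset)
  barcodes <- data.frame(fwd_index = picks[seq_len(n_lib)],
                         rev_index = picks[n_lib + seq_len(n_lib)],
                         sample = as.character(libraries$sample),
                         dilution_index = as.integer(libraries$dilution_index))
  assay_panel(assays, barcodes)
}

#' Design per-sample true copy numbers (samples A-D)
#'
#' Sample A abundances are log-uniform over `abundance_log10_range` decades
#' above `min_copies`. Sample B is A scaled per gene: by an assigned
#' subgroup ratio (the ERCC design uses 0.5x / 0.67x / 1.0x / 4.0x
#' subgroups) when `subgroup_ratios` is given, otherwise by a lognormal
#' fold (`b_fold_sd_log10`) emulating two unrelated tissues. Samples C and
#' D are the 3:1 and 1:3 mixtures 0.75A + 0.25B and 0.25A + 0.75B.
#'
#' @param n_genes number of genes.
#' @param abundance_log10_range decades spanned by sample A.
#' @param min_copies lowest sample-A abundance (copies per library prep).
#' @param subgroup_ratios optional per-gene B:A ratios (recycled).
#' @param b_fold_sd_log10 SD of the lognormal B:A fold when no subgroup
#'   ratios are given (default 1).
#' @param seed integer seed.
#' @param gene_ids optional row names.
#' @return matrix genes x samples (`A`, `B`, `C`, `D`) of true copies, with
#'   the per-gene B:A ratio in attribute `"ratio"`.
#' @export
design_samples <- function(n_genes, abundance_log10_range = 6,
                           min_copies = 15, subgroup_ratios = NULL,
                           b_fold_sd_log10 = 1, seed = 1L, gene_ids = NULL) {
  set.seed(seed)
  a <- min_copies * 10^runif(n_genes, 0, abundance_log10_range)
  ratio <- if (!is.null(subgroup_ratios)) rep_len(subgroup_ratios, n_genes)
           else 10^rnorm(n_genes, 0, b_fold_sd_log10)
  b <- a * ratio
  out <- cbind(A = a, B = b,
               C = expected_mixture(a, b, 0.75),
               D = expected_mixture(a, b, 0.25))
  rownames(out) <- gene_ids %||% sprintf("GENE%03d", seq_len(n_genes))
  attr(out, "ratio") <- ratio
  out
}

#' Competitive-PCR plateau model
#'
#' Every gene's NT + IS amplicon pool converges to the same plateau
#' concentration (optionally jittered by a lognormal factor modelling
#' unequal primer efficiency), while the NT fraction remains exactly
#' nt / (nt + sc): competition never distorts the within-gene ratio. This
#' is the normalization that compresses the read dynamic range.
#'
#' @param nt_copies,sc_copies input NT and IS copies (> 0, vectorized).
#' @param plateau_copies endpoint amplicon copies per gene (default 1e9).
#' @param jitter_log10 SD of the lognormal plateau jitter (default 0.1;
#'   0 for the deterministic model).
#' @param efficiency per-gene relative primer efficiency scaling the
#'   plateau (default 1).
#' @return data.frame with `total_amplicons` and `nt_fraction`.
#' @examples
#' simulate_competitive_pcr(1e8, 1e5, jitter_log10 = 0)$nt_fraction
#' @export
simulate_competitive_pcr <- function(nt_copies, sc_copies,
                                     plateau_copies = 1e9,
                                     jitter_log10 = 0.1, efficiency = 1) {
  stopifnot(all(nt_copies > 0), all(sc_copies > 0))
  n <- max(length(nt_copies), length(sc_copies))
  nt_copies <- rep_len(nt_copies, n); sc_copies <- rep_len(sc_copies, n)
  jit <- if (jitter_log10 > 0) 10^rnorm(n, 0, jitter_log10) else 1
  data.frame(total_amplicons = plateau_copies * rep_len(efficiency, n) * jit,
             nt_fraction = nt_copies / (nt_copies + sc_copies))
}

#' Multinomial read sampling over library cells
#'
#' Draws `reads` sequencing reads over (gene, allele) cells in proportion
#' to their amplicon mass. Marginals of rare cells are Poisson to good
#' approximation, which is what makes 1/sqrt(n) the expected CV.
#'
#' @param fractions non-negative cell masses (normalized internally).
#' @param reads total reads in the library (> 0).
#' @return integer vector of counts, same length as `fractions`.
#' @export
sample_reads <- function(fractions, reads) {
  stopifnot(reads > 0, all(fractions >= 0), sum(fractions) > 0)
  as.integer(rmultinom(1L, reads, fractions))
}

## One library: copies + true IS -> (nt_count, is_count) per gene.
simulate_library_counts <- function(nt_copies, sc_true, reads,
                                    plateau_copies = 1e9, jitter_log10 = 0.1,
                                    rep_noise_log10 = 0, efficiency = 1) {
  G <- length(nt_copies)
  ratio <- nt_copies / sc_true
  if (any(rep_noise_log10 > 0))
    ratio <- ratio * 10^rnorm(G, 0, rep_len(rep_noise_log10, G))
  pcr <- simulate_competitive_pcr(nt_copies, sc_true, plateau_copies,
                                  jitter_log10, efficiency)
  tot <- pcr$total_amplicons
  mass_nt <- tot * ratio / (1 + ratio)
  mass_is <- tot / (1 + ratio)
  counts <- sample_reads(c(mass_nt, mass_is), reads)
  list(nt_count = counts[seq_len(G)], is_count = counts[G + seq_len(G)])
}

#' Simulate binned study counts from a copy-number design
#'
#' The core generator behind the study presets: for every (sample,
#' dilution) library it computes each gene's true loaded IS copies
#' (nominal ladder value times a fixed per-gene calibration factor times a
#' per-library pipetting factor), applies per-replicate lognormal
#' technical noise to the NT:IS ratio, pushes the pools through the
#' competitive-PCR plateau model, and multinomially samples reads.
#'
#' @param copies matrix genes x samples of true NT copies (rownames are
#'   gene ids).
#' @param ladder nominal IS copies per gene at each dilution index
#'   (strictly decreasing).
#' @param reads_per_library total reads per library (default 1e5).
#' @param plateau_copies,plateau_jitter_log10 plateau model parameters.
#' @param efficiency per-gene relative primer efficiency (default 1; near
#'   zero emulates failed assays).
#' @param is_calibration_log10 SD of the fixed per-gene lognormal error of
#'   true vs nominal IS concentration (default 0).
#' @param replicate_noise_log10 per-gene SD of the per-replicate lognormal
#'   ratio noise (default 0).
#' @param pipetting_log10 SD of the per-library lognormal pipetting factor
#'   (default 0).
#' @param seed integer seed.
#' @return list with `counts` (a [count_table()]), `mix` (nominal
#'   [is_mix()]), and `truth` (list: `copies`, `calibration` per-gene
#'   factors, `efficiency`, `ladder`).
#' @export
simulate_study_counts <- function(copies, ladder, reads_per_library = 1e5,
                                  plateau_copies = 1e9,
                                  plateau_jitter_log10 = 0.1,
                                  efficiency = 1,
                                  is_calibration_log10 = 0,
                                  replicate_noise_log10 = 0,
                                  pipetting_log10 = 0,
                                  seed = 1L) {
  if (any(diff(ladder) >= 0)) stopf("IS ladder must be strictly decreasing")
  set.seed(seed)
  genes <- rownames(copies)
  G <- length(genes)
  efficiency <- rep_len(efficiency, G)
  rep_noise <- rep_len(replicate_noise_log10, G)
  cal <- if (is_calibration_log10 > 0) 10^rnorm(G, 0, is_calibration_log10)
         else rep(1, G)
  samples <- colnames(copies)
  rows <- vector("list", length(samples) * length(ladder))
  k <- 0L
  for (s in samples) for (i in seq_along(ladder)) {
    pip <- if (pipetting_log10 > 0) 10^rnorm(1, 0, pipetting_log10) else 1
    sc_true <- ladder[i] * cal * pip
    lib <- simulate_library_counts(copies[, s], sc_true, reads_per_library,
                                   plateau_copies, plateau_jitter_log10,
                                   rep_noise, efficiency)
    k <- k + 1L
    rows[[k]] <- data.frame(sample = s, dilution_index = i, gene_id = genes,
                            nt_count = lib$nt_count, is_count = lib$is_count)
  }
  counts <- count_table(do.call(rbind, rows))
  mix <- is_mix(data.frame(dilution_index = rep(seq_along(ladder), each = G),
                           gene_id = rep(genes, times = length(ladder)),
                           sc = rep(ladder, each = G)))
  list(counts = counts, mix = mix,
       truth = list(copies = copies, calibration = cal,
                    efficiency = efficiency, ladder = ladder))
}

#' Synthetic study presets mirroring the three reference designs
#'
#' Three ready-made study generators whose defaults are the reference
#' study conditions:
#'
#' * `simulate_gdna_study()`: 150 endogenous assays cross-titrated against
#'   a constant 1e5 genomic copies over a 10-point 3-fold IS ladder
#'   (2e7 down to ~1e3 copies). 26 assays amplify too weakly to yield
#'   countable reads and 1 assay carries unacceptable analytical
#'   variation, so 123 of 150 pass QC.
#' * `simulate_endogenous_study()`: 123 working assays measured in cDNA
#'   samples A-D over a 12-point 3-fold ladder (6e7 down to ~3.4e2), with
#'   sample-A abundances log-uniform over ~7.8 decades from 30 copies and
#'   B an unrelated tissue (lognormal fold, SD 1 log10).
#' * `simulate_ercc_study()`: 28 ERCC-style assays in four subgroups with
#'   B:A ratios 0.5 / 0.67 / 1.0 / 4.0, sample-A abundances log-uniform
#'   over the ~2.7e6-fold ERCC range, IS ladder 1e6 / 1e5 / 1e4 / 1e3 /
#'   300 copies, with one low-efficiency and one non-titrating assay (26
#'   working). ERCC IS mixes carry a fixed per-assay calibration error
#'   (SD 0.45 log10) reflecting their multi-step preparation; endogenous
#'   IS are cross-calibrated against gDNA and carry only 0.05 log10.
#'
#' All presets share per-replicate technical noise of 0.08 log10 (~20%
#' CV) and a small per-library pipetting factor (SD 0.05 log10).
#'
#' @param seed integer seed.
#' @param n_genes,n_assays panel size.
#' @param reads_per_library total reads per library.
#' @param n_low_efficiency,n_high_cv counts of failed-assay types in the
#'   gDNA design.
#' @param replicate_noise_log10,pipetting_log10,is_calibration_log10
#'   noise levels (see [simulate_study_counts()]); set to 0 for pure
#'   Poisson sampling conditions.
#' @param abundance_log10_range,min_copies sample-A abundance design.
#' @param ... passed through to [simulate_study_counts()].
#' @return as [simulate_study_counts()], plus `design` notes in `truth`.
#' @export
simulate_gdna_study <- function(seed = 1L, n_genes = 150L,
                                n_low_efficiency = 26L, n_high_cv = 1L,
                                reads_per_library = 1e5,
                                replicate_noise_log10 = 0.08,
                                pipetting_log10 = 0.05, ...) {
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  copies <- matrix(1e5, n_genes, 1, dimnames = list(genes, "gDNA"))
  efficiency <- rep(1, n_genes)
  rep_noise <- rep(replicate_noise_log10, n_genes)
  set.seed(seed + 1000L)
  fail_lo <- sample.int(n_genes, n_low_efficiency)
  fail_cv <- sample(setdiff(seq_len(n_genes), fail_lo), n_high_cv)
  efficiency[fail_lo] <- 1e-4   # too few reads: low primer efficiency
  rep_noise[fail_cv] <- 2.0     # unacceptable analytical variation
  out <- simulate_study_counts(copies, ladder = 2e7 / 3^(0:9),
                               reads_per_library = reads_per_library,
                               efficiency = efficiency,
                               replicate_noise_log10 = rep_noise,
                               pipetting_log10 = pipetting_log10,
                               seed = seed, ...)
  out$truth$failed_low_efficiency <- genes[fail_lo]
  out$truth$failed_high_cv <- genes[fail_cv]
  out
}

#' @rdname simulate_gdna_study
#' @export
simulate_endogenous_study <- function(seed = 1L, n_genes = 123L,
                                      abundance_log10_range = log10(6.2e7),
                                      min_copies = 30,
                                      reads_per_library = 1e5,
                                      replicate_noise_log10 = 0.08,
                                      pipetting_log10 = 0.05,
                                      is_calibration_log10 = 0.05, ...) {
  copies <- design_samples(n_genes, abundance_log10_range, min_copies,
                           subgroup_ratios = NULL, b_fold_sd_log10 = 1,
                           seed = seed + 2000L)
  out <- simulate_study_counts(copies, ladder = 6e7 / 3^(0:11),
                               reads_per_library = reads_per_library,
                               is_calibration_log10 = is_calibration_log10,
                               replicate_noise_log10 = replicate_noise_log10,
                               pipetting_log10 = pipetting_log10,
                               seed = seed, ...)
  out$truth$ratio <- attr(copies, "ratio")
  out
}

#' @rdname simulate_gdna_study
#' @export
simulate_ercc_study <- function(seed = 1L, n_assays = 28L,
                                abundance_log10_range = log10(2.7e6),
                                min_copies = 15,
                                reads_per_library = 1e5,
                                replicate_noise_log10 = 0.08,
                                pipetting_log10 = 0.05,
                                is_calibration_log10 = 0.45, ...) {
  genes <- sprintf("ERCC-%03d", seq_len(n_assays))
  subgroups <- rep(c(0.5, 0.67, 1.0, 4.0),
                   each = ceiling(n_assays / 4))[seq_len(n_assays)]
  copies <- design_samples(n_assays, abundance_log10_range, min_copies,
                           subgroup_ratios = subgroups,
                           seed = seed + 3000L, gene_ids = genes)
  efficiency <- rep(1, n_assays)
  rep_noise <- rep(replicate_noise_log10, n_assays)
  fail_lo <- 7L    # low PCR efficiency: too few reads for NT and IS
  fail_cv <- 14L   # fails to titrate NT:IS
  efficiency[fail_lo] <- 1e-4
  rep_noise[fail_cv] <- 2.0
  out <- simulate_study_counts(copies, ladder = c(1e6, 1e5, 1e4, 1e3, 300),
                               reads_per_library = reads_per_library,
                               efficiency = efficiency,
                               is_calibration_log10 = is_calibration_log10,
                               replicate_noise_log10 = rep_noise,
                               pipetting_log10 = pipetting_log10,
                               seed = seed, ...)
  out$truth$subgroup_ratio <- setNames(subgroups, genes)
  out$truth$failed <- genes[c(fail_lo, fail_cv)]
  out
}
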