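#' Emit a simulated FASTQ library with ground truth
#'
#' Expands a count table into 151-nt reads laid out per the panel's read
#' layout (14-nt forward tag with 4-nt index, 11-nt spacer, 101-nt NT or
#' IS amplicon, 11-nt spacer, 14-nt reverse tag), optionally injecting
#' uniform substitution errors, and writes a FASTQ file plus a manifest
#' recording every read's true (sample, dilution, gene, allele). With
#' `error_rate = 0`, [bin_reads()] on the output recovers the counts
#' exactly.
#'
#' Indels are deliberately not modelled: allele calling is Hamming-based
#' over a fixed-length window, and the competitive design carries no
#' length variation.
#'
#' @param counts a [count_table()] consistent with the panel.
#' @param panel an [assay_panel()].
#' @param path output FASTQ path.
#' @param error_rate per-base substitution probability in `[0, 0.05]`.
#' @param seed integer seed (read order and errors are deterministic
#'   given the seed).
#' @param manifest_path optional CSV path for the ground-truth manifest.
#' @return data.frame manifest (`read_id`, `sample`, `dilution_index`,
#'   `gene_id`, `allele`), invisibly.
#' @export
emit_fastq <- function(counts, panel, path, error_rate = 0, seed = 1L,
                       manifest_path = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 0.05)
  counts <- count_table(counts)
  b <- panel$barcodes
  a <- panel$assays
  lib_key <- paste(b$sample, b$dilution_index)
  lib_of <- match(paste(counts$sample, counts$dilution_index), lib_key)
  if (anyNA(lib_of))
    stopf("count table references libraries absent from the barcode table")
  gene_of <- match(counts$gene_id, a$gene_id)
  if (anyNA(gene_of))
    stopf("count table references genes absent from the panel")
  set.seed(seed)
  lay <- panel$layout
  fwd_tags <- paste0(b$fwd_index, lay$fwd_tag_pad)
  rev_tags <- paste0(lay$rev_tag_pad, b$rev_index)

  n_per_row <- counts$nt_count + counts$is_count
  rows <- rep(seq_len(nrow(counts)), n_per_row)
  allele <- unlist(mapply(function(nt, is_) c(rep("NT", nt), rep("IS", is_)),
                          counts$nt_count, counts$is_count, SIMPLIFY = FALSE))
  if (length(rows) == 0L) stopf("count table holds zero reads")
  amp <- ifelse(allele == "NT", a$nt_sequence[gene_of[rows]],
                a$is_sequence[gene_of[rows]])
  seqs <- paste0(fwd_tags[lib_of[rows]], lay$fwd_spacer, amp,
                 lay$rev_spacer, rev_tags[lib_of[rows]])
  # shuffle so library/gene order carries no information
  ord <- sample.int(length(seqs))
  seqs <- seqs[ord]; rows <- rows[ord]; allele <- allele[ord]
  if (error_rate > 0) seqs <- inject_substitutions(seqs, error_rate)
  ids <- sprintf("read%07d", seq_along(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                             strrep("I", nchar(seqs)))), path)
  manifest <- data.frame(read_id = ids,
                         sample = counts$sample[rows],
                         dilution_index = counts$dilution_index[rows],
                         gene_id = counts$gene_id[rows],
                         allele = allele)
  if (!is.null(manifest_path))
    write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

## uniform per-base substitutions; only reads drawing >= 1 error are touched
inject_substitutions <- function(seqs, rate) {
  len <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), len, rate)
  for (i in which(n_err > 0L)) {
    chars <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(len[i], n_err[i])
    chars[pos] <- vapply(chars[pos],
                         function(ch) sample(setdiff(DNA_BASES, ch), 1L),
                         character(1))
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}
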