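# Shared fixtures, all generated in code.

two_lib_frame <- function(samples = c("A", "B"), n_dilutions = 2L) {
  expand.grid(sample = samples, dilution_index = seq_len(n_dilutions),
              stringsAsFactors = FALSE)
}

# deterministic hand-built 2-gene panel with known diagnostic positions
manual_panel <- function() {
  set.seed(1234)
  mk <- function() paste(sample(c("A", "C", "G", "T"), 101, replace = TRUE),
                         collapse = "")
  nt1 <- mk(); nt2 <- mk()
  flip <- function(nt, pos_in_window) {          # pos 0-based within window
    chars <- strsplit(nt, "")[[1]]
    for (p in pos_in_window + 21L)               # offset 20, 1-based
      chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
    paste(chars, collapse = "")
  }
  d1 <- c(0L, 10L, 20L, 30L, 40L, 59L)
  d2 <- c(5L, 15L, 25L, 35L, 45L, 55L)
  assays <- data.frame(
    gene_id = c("g1", "g2"),
    nt_sequence = c(nt1, nt2),
    is_sequence = c(flip(nt1, d1), flip(nt2, d2)),
    fwd_primer_len = 20L, rev_primer_len = 21L, central_offset = 20L)
  barcodes <- data.frame(fwd_index = c("AAAA", "CCCC"),
                         rev_index = c("GGGG", "TTTT"),
                         sample = c("S1", "S1"), dilution_index = 1:2)
  list(panel = assay_panel(assays, barcodes), diag = list(g1 = d1, g2 = d2))
}

# FASTQ writer for hand-built records
write_fastq_records <- function(path, ids, seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

# compose a valid read for gene g / allele of a panel library
compose_read <- function(panel, lib_row, gene_row, allele = "NT") {
  b <- panel$barcodes[lib_row, ]
  a <- panel$assays[gene_row, ]
  amp <- if (allele == "NT") a$nt_sequence else a$is_sequence
  lay <- panel$layout
  paste0(b$fwd_index, lay$fwd_tag_pad, lay$fwd_spacer, amp,
         lay$rev_spacer, lay$rev_tag_pad, b$rev_index)
}
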