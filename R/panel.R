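#' Assay panels for competitive amplicon sequencing
#'
#' An assay panel holds, for every gene, the 101-nt native-target (NT) and
#' internal-standard (IS) amplicon sequences together with the dual 4-nt
#' barcode table that maps index pairs to sequencing libraries
#' (sample x IS-dilution replicate). NT and IS are identical at the priming
#' sites and differ at exactly six diagnostic positions, all inside the
#' 60-nt central window used for allele calling.
#'
#' All sequence coordinates are 0-based; `central_offset` is the 0-based
#' start of the 60-nt window within the amplicon (default 20, centering the
#' window), and diagnostic positions are 0-based within that window.
#'
#' @param assays data.frame with columns `gene_id`, `nt_sequence`,
#'   `is_sequence`, `fwd_primer_len`, `rev_primer_len`, `central_offset`.
#' @param barcodes data.frame with columns `fwd_index`, `rev_index`,
#'   `sample`, `dilution_index`; one row per sequencing library.
#' @param layout read layout constants used for FASTQ emission and tag
#'   export; see [default_read_layout()].
#' @return An object of class `assay_panel` with elements `assays`
#'   (including a `diagnostic` list-column of 0-based positions), `barcodes`
#'   and `layout`.
#' @examples
#' pan <- build_panel(2, libraries = data.frame(sample = "A", dilution_index = 1:2),
#'                    seed = 1)
#' pan$assays$diagnostic[[1]]
#' @export
assay_panel <- function(assays, barcodes, layout = default_read_layout()) {
  required <- c("gene_id", "nt_sequence", "is_sequence",
                "fwd_primer_len", "rev_primer_len", "central_offset")
  missing_cols <- setdiff(required, names(assays))
  if (length(missing_cols))
    stopf("panel assay table lacks columns: %s", paste(missing_cols, collapse = ", "))
  assays <- as.data.frame(assays)[required]
  assays$gene_id <- as.character(assays$gene_id)
  if (anyDuplicated(assays$gene_id))
    stopf("duplicate gene_id in panel: %s",
          paste(unique(assays$gene_id[duplicated(assays$gene_id)]), collapse = ", "))
  assays$diagnostic <- vector("list", nrow(assays))
  for (k in seq_len(nrow(assays))) {
    assays$diagnostic[[k]] <- validate_assay(
      assays$gene_id[k], assays$nt_sequence[k], assays$is_sequence[k],
      assays$central_offset[k])
  }
  barcodes <- validate_barcodes(barcodes)
  structure(list(assays = assays, barcodes = barcodes, layout = layout),
            class = "assay_panel")
}

#' @export
print.assay_panel <- function(x, ...) {
  cat(sprintf("Assay panel: %d assays, %d libraries (%d samples)\n",
              nrow(x$assays), nrow(x$barcodes),
              length(unique(x$barcodes$sample))))
  invisible(x)
}

## Checks one NT/IS amplicon pair and returns the 0-based diagnostic
## positions (within the central window) forced by the sequence difference.
validate_assay <- function(gene_id, nt, is, central_offset) {
  for (s in c(nt, is)) {
    if (nchar(s) != AMPLICON_LEN)
      stopf("assay %s: amplicon length %d, expected %d", gene_id, nchar(s), AMPLICON_LEN)
    if (grepl("[^ACGT]", s))
      stopf("assay %s: non-ACGT characters in amplicon sequence", gene_id)
  }
  if (central_offset < 0 || central_offset + WINDOW_LEN > AMPLICON_LEN)
    stopf("assay %s: central window [%d, %d) outside the %d-nt amplicon",
          gene_id, central_offset, central_offset + WINDOW_LEN, AMPLICON_LEN)
  diff_pos <- which(charToRaw(nt) != charToRaw(is))  # 1-based in amplicon
  if (length(diff_pos) == 0L)
    stopf("assay %s: zero diagnostic positions (NT == IS)", gene_id)
  if (length(diff_pos) != N_DIAGNOSTIC)
    stopf("assay %s: NT/IS Hamming distance %d, expected %d",
          gene_id, length(diff_pos), N_DIAGNOSTIC)
  in_window <- diff_pos > central_offset & diff_pos <= central_offset + WINDOW_LEN
  if (!all(in_window))
    stopf("assay %s: diagnostic substitutions outside the central window", gene_id)
  sort(diff_pos - 1L - as.integer(central_offset))  # 0-based within window
}

validate_barcodes <- function(barcodes) {
  required <- c("fwd_index", "rev_index", "sample", "dilution_index")
  missing_cols <- setdiff(required, names(barcodes))
  if (length(missing_cols))
    stopf("barcode table lacks columns: %s", paste(missing_cols, collapse = ", "))
  barcodes <- as.data.frame(barcodes)[required]
  barcodes$sample <- as.character(barcodes$sample)
  barcodes$dilution_index <- as.integer(barcodes$dilution_index)
  for (col in c("fwd_index", "rev_index")) {
    idx <- barcodes[[col]]
    if (any(nchar(idx) != INDEX_LEN) || any(grepl("[^ACGT]", idx)))
      stopf("%s entries must be 4-nt ACGT strings", col)
    if (anyDuplicated(idx))
      stopf("%s entries must be unique across libraries", col)
  }
  lib <- paste(barcodes$sample, barcodes$dilution_index)
  if (anyDuplicated(lib))
    stopf("duplicate (sample, dilution_index) in barcode table")
  barcodes
}

#' Read layout constants for simulated/parsed reads
#'
#' Reads are laid out as a 14-nt forward tag (4-nt sample index + 10-nt
#' fixed adapter pad), an 11-nt spacer, the 101-nt amplicon, an 11-nt
#' spacer, and a 14-nt reverse tag (10-nt pad + 4-nt index), for a total of
#' 151 nt, satisfying the strict >150-nt length filter. The 60-nt
#' diagnostic window of a default assay therefore starts at offset 31 of
#' the 123-nt central region.
#'
#' @param fwd_tag_pad,rev_tag_pad 10-nt constant pads completing the tags.
#' @param fwd_spacer,rev_spacer 11-nt constant spacers flanking the amplicon.
#' @return list of layout constants.
#' @export
default_read_layout <- function(fwd_tag_pad = "ACGTACGTAC",
                                rev_tag_pad = "TGCATGCATG",
                                fwd_spacer = "GATCGATCGAT",
                                rev_spacer = "CTAGCTAGCTA") {
  stopifnot(nchar(fwd_tag_pad) == 10L, nchar(rev_tag_pad) == 10L,
            nchar(fwd_spacer) == 11L, nchar(rev_spacer) == 11L)
  list(fwd_tag_pad = fwd_tag_pad, rev_tag_pad = rev_tag_pad,
       fwd_spacer = fwd_spacer, rev_spacer = rev_spacer)
}

central_window <- function(seq, offset) substr(seq, offset + 1L, offset + WINDOW_LEN)

## Central-window offset within the parsed central region of a read.
window_offset_in_central <- function(panel) {
  nchar(panel$layout$fwd_spacer) + panel$assays$central_offset[1]
}

#' Write / load an assay panel as a delimited table
#'
#' One comma-delimited file with an `[assays]` section and a `[barcodes]`
#' section. Diagnostic positions are not stored: they are re-derived from
#' the NT/IS sequence difference on load, so a round trip validates the
#' panel.
#'
#' @param panel an [assay_panel()].
#' @param path file path.
#' @return `load_panel` returns a validated `assay_panel`.
#' @export
write_panel <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# campseq panel v1", con)
  writeLines(sprintf("# layout,%s,%s,%s,%s",
                     panel$layout$fwd_tag_pad, panel$layout$rev_tag_pad,
                     panel$layout$fwd_spacer, panel$layout$rev_spacer), con)
  writeLines("[assays]", con)
  acols <- c("gene_id", "nt_sequence", "is_sequence",
             "fwd_primer_len", "rev_primer_len", "central_offset")
  write.csv(panel$assays[acols], con, row.names = FALSE, quote = FALSE)
  writeLines("[barcodes]", con)
  write.csv(panel$barcodes, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
load_panel <- function(path) {
  lines <- readLines(path)
  layout <- default_read_layout()
  lay_line <- grep("^# layout,", lines, value = TRUE)
  if (length(lay_line) == 1L) {
    parts <- strsplit(sub("^# layout,", "", lay_line), ",")[[1]]
    layout <- default_read_layout(parts[1], parts[2], parts[3], parts[4])
  }
  a_start <- match("[assays]", lines)
  b_start <- match("[barcodes]", lines)
  if (is.na(a_start) || is.na(b_start) || b_start < a_start)
    stopf("panel file must contain an [assays] then a [barcodes] section")
  assays <- read.csv(textConnection(lines[(a_start + 1L):(b_start - 1L)]),
                     colClasses = c(gene_id = "character"))
  barcodes <- read.csv(textConnection(lines[(b_start + 1L):length(lines)]),
                       colClasses = c(sample = "character"))
  assay_panel(assays, barcodes, layout)
}

#' Export panel reference sequences as FASTA databases
#'
#' The `subject` database holds, per gene, the NT and IS 60-nt central
#' windows (two records per assay, named `<gene>|NT` and `<gene>|IS`); the
#' `barcode` database holds every 14-nt forward and reverse tag.
#'
#' @param panel an [assay_panel()].
#' @param kind `"subject"` or `"barcode"`.
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
export_reference_fasta <- function(panel, kind = c("subject", "barcode"), path) {
  kind <- match.arg(kind)
  if (nrow(panel$assays) == 0L) stopf("cannot export an empty panel")
  if (kind == "subject") {
    a <- panel$assays
    seqs <- c(central_window(a$nt_sequence, a$central_offset),
              central_window(a$is_sequence, a$central_offset))
    names(seqs) <- c(paste0(a$gene_id, "|NT"), paste0(a$gene_id, "|IS"))
    ord <- order(rep(seq_len(nrow(a)), 2L))  # interleave NT/IS per gene
    seqs <- seqs[ord]
  } else {
    b <- panel$barcodes
    lib <- paste0(b$sample, ".", b$dilution_index)
    seqs <- c(paste0(b$fwd_index, panel$layout$fwd_tag_pad),
              paste0(panel$layout$rev_tag_pad, b$rev_index))
    names(seqs) <- c(paste0(lib, "|fwd"), paste0(lib, "|rev"))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
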