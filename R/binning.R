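#' Demultiplex parsed reads by dual 4-nt barcodes
#'
#' The forward index occupies the first 4 bases of the 14-nt forward tag
#' and the reverse index the last 4 bases of the reverse tag. Both indices
#' are matched exactly; a read is assigned only when both map to the same
#' library (sample, dilution index). Failures are reason-coded, never
#' errors: `fwd_unknown`, `rev_unknown`, or `conflict` when the two indices
#' name different libraries (dual indexing guards against false
#' barcoding).
#'
#' @param fwd_tag,rev_tag character vectors of 14-nt tags from
#'   [parse_reads()].
#' @param panel an [assay_panel()].
#' @return data.frame with `sample`, `dilution_index` (NA when unassigned)
#'   and `reason` (`ok`/`fwd_unknown`/`rev_unknown`/`conflict`).
#' @export
demultiplex <- function(fwd_tag, rev_tag, panel) {
  b <- panel$barcodes
  fwd_idx <- substr(fwd_tag, 1L, INDEX_LEN)
  rev_idx <- substr(rev_tag, TAG_LEN - INDEX_LEN + 1L, TAG_LEN)
  f <- match(fwd_idx, b$fwd_index)
  r <- match(rev_idx, b$rev_index)
  reason <- rep("ok", length(fwd_tag))
  reason[!is.na(f) & !is.na(r) & f != r] <- "conflict"
  reason[is.na(r)] <- "rev_unknown"
  reason[is.na(f)] <- "fwd_unknown"
  ok <- reason == "ok"
  out <- data.frame(sample = NA_character_,
                    dilution_index = NA_integer_,
                    reason = reason)
  if (any(ok)) {
    out$sample[ok] <- b$sample[f[ok]]
    out$dilution_index[ok] <- b$dilution_index[f[ok]]
  }
  out
}

## integer matrix (n x width) of character codes for equal-length strings
char_matrix <- function(s, width) {
  matrix(vapply(s, function(x) utf8ToInt(x)[seq_len(width)],
                integer(width)),
         ncol = width, byrow = TRUE)
}

#' Call each 60-nt read window as NT or IS of a panel gene
#'
#' The gene is the assay whose NT or IS reference window has minimal
#' Hamming distance to the read window, accepted only when that distance is
#' at most `max_mismatch` (otherwise `no_gene`). The NT/IS decision then
#' rests solely on the six diagnostic positions: the read is called NT when
#' at least `diag_min_match` of the six bases match NT's diagnostic bases
#' and more match NT than IS (symmetrically for IS); split evidence yields
#' `ambiguous`. Ties are resolved deterministically (first assay in panel
#' order), never randomly.
#'
#' @param windows character vector of 60-nt windows (NA allowed).
#' @param panel an [assay_panel()].
#' @param max_mismatch maximum Hamming distance over the full window
#'   (default 5).
#' @param diag_min_match minimum diagnostic-base matches required for an
#'   NT or IS call (default 4 of 6).
#' @return data.frame with `gene_id` (NA for `no_gene`), `allele`
#'   (`NT`/`IS`/`ambiguous`/`no_gene`) and `mismatches` (minimal Hamming
#'   distance; NA for `no_gene` without a candidate).
#' @export
call_allele <- function(windows, panel, max_mismatch = 5L, diag_min_match = 4L) {
  a <- panel$assays
  nt_w <- central_window(a$nt_sequence, a$central_offset)
  is_w <- central_window(a$is_sequence, a$central_offset)
  n <- length(windows)
  gene <- rep(NA_character_, n)
  allele <- rep("no_gene", n)
  mm <- rep(NA_integer_, n)

  valid <- !is.na(windows) & nchar(windows) == WINDOW_LEN
  # fast path: exact matches against either allele window
  ex_nt <- match(windows, nt_w)
  ex_is <- match(windows, is_w)
  hit_nt <- valid & !is.na(ex_nt)
  hit_is <- valid & !is.na(ex_is) & !hit_nt
  gene[hit_nt] <- a$gene_id[ex_nt[hit_nt]]
  allele[hit_nt] <- "NT"
  mm[hit_nt] <- 0L
  gene[hit_is] <- a$gene_id[ex_is[hit_is]]
  allele[hit_is] <- "IS"
  mm[hit_is] <- 0L

  rest <- which(valid & !hit_nt & !hit_is)
  if (length(rest)) {
    rm_ <- char_matrix(windows[rest], WINDOW_LEN)
    ref <- char_matrix(c(nt_w, is_w), WINDOW_LEN)
    G <- nrow(a)
    d <- matrix(0L, nrow = length(rest), ncol = 2L * G)
    for (j in seq_len(2L * G))
      d[, j] <- as.integer(rowSums(rm_ != matrix(ref[j, ], nrow = length(rest),
                                                 ncol = WINDOW_LEN, byrow = TRUE)))
    d_gene <- pmin(d[, seq_len(G), drop = FALSE],
                   d[, G + seq_len(G), drop = FALSE])
    best <- max.col(-d_gene, ties.method = "first")
    dmin <- d_gene[cbind(seq_along(rest), best)]
    accept <- dmin <= max_mismatch
    for (k in which(accept)) {
      i <- rest[k]
      g <- best[k]
      pos <- a$diagnostic[[g]] + 1L  # 1-based within window
      wb <- utf8ToInt(windows[i])[pos]
      n_nt <- sum(wb == utf8ToInt(nt_w[g])[pos])
      n_is <- sum(wb == utf8ToInt(is_w[g])[pos])
      gene[i] <- a$gene_id[g]
      mm[i] <- dmin[k]
      allele[i] <- if (n_nt >= diag_min_match && n_nt > n_is) "NT"
        else if (n_is >= diag_min_match && n_is > n_nt) "IS"
        else "ambiguous"
    }
    mm[rest[!accept]] <- dmin[!accept]
  }
  data.frame(gene_id = gene, allele = allele, mismatches = mm)
}

#' Bin a FASTQ library into a count table
#'
#' Full binning pipeline: parse reads, demultiplex by dual barcodes,
#' extract the 60-nt diagnostic window, call NT/IS, and aggregate counts
#' over every (sample, dilution index, gene) of the panel. Reads that fail
#' barcode consistency, gene assignment, or whose diagnostic evidence is
#' split are excluded from the counts (never fractionally assigned) and
#' tallied in the report.
#'
#' @param fastq FASTQ path or [read_fastq()] result.
#' @param panel an [assay_panel()].
#' @inheritParams call_allele
#' @return list with `counts` (a [count_table()] over the full panel grid)
#'   and `report` (named tallies: `total_records`, `malformed`,
#'   `rejected_short`, `accepted`, `assigned`, `fwd_unknown`,
#'   `rev_unknown`, `barcode_conflict`, `no_gene`, `ambiguous`).
#' @export
bin_reads <- function(fastq, panel, max_mismatch = 5L, diag_min_match = 4L) {
  pr <- parse_reads(fastq)
  p <- pr$parsed
  dm <- demultiplex(p$fwd_tag, p$rev_tag, panel)
  win <- extract_central_window(p$central, window_offset_in_central(panel))
  in_lib <- dm$reason == "ok"
  call <- call_allele(win[in_lib], panel, max_mismatch, diag_min_match)

  b <- panel$barcodes
  genes <- panel$assays$gene_id
  grid <- data.frame(sample = rep(b$sample, each = length(genes)),
                     dilution_index = rep(b$dilution_index, each = length(genes)),
                     gene_id = rep(genes, times = nrow(b)),
                     nt_count = 0L, is_count = 0L)
  key <- paste(grid$sample, grid$dilution_index, grid$gene_id)
  counted <- call$allele %in% c("NT", "IS")
  if (any(counted)) {
    lib_s <- dm$sample[in_lib][counted]
    lib_i <- dm$dilution_index[in_lib][counted]
    ckey <- paste(lib_s, lib_i, call$gene_id[counted])
    is_nt <- call$allele[counted] == "NT"
    tab_nt <- table(factor(ckey[is_nt], levels = key))
    tab_is <- table(factor(ckey[!is_nt], levels = key))
    grid$nt_count <- as.integer(tab_nt)
    grid$is_count <- as.integer(tab_is)
  }
  report <- c(total_records = pr$n_total,
              malformed = pr$n_malformed,
              rejected_short = pr$n_rejected_short,
              accepted = pr$n_accepted,
              assigned = sum(counted),
              fwd_unknown = sum(dm$reason == "fwd_unknown"),
              rev_unknown = sum(dm$reason == "rev_unknown"),
              barcode_conflict = sum(dm$reason == "conflict"),
              no_gene = sum(call$allele == "no_gene"),
              ambiguous = sum(call$allele == "ambiguous"))
  list(counts = count_table(grid), report = report)
}
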