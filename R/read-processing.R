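#' Read a FASTQ file record by record
#'
#' Tolerant 4-line-record reader: records whose sequence and quality
#' strings differ in length, or whose header/separator lines are malformed,
#' are skipped and tallied rather than aborting the run. Gzipped input is
#' handled transparently.
#'
#' @param path FASTQ file (optionally gzipped).
#' @return list with `records` (data.frame `read_id`, `seq`, `qual`) and
#'   `n_malformed`.
#' @export
read_fastq <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n_malformed <- 0L
  n <- length(lines)
  n_full <- n %/% 4L
  if (n %% 4L != 0L) n_malformed <- n_malformed + 1L  # trailing partial record
  if (n_full == 0L)
    return(list(records = data.frame(read_id = character(), seq = character(),
                                     qual = character()),
                n_malformed = n_malformed))
  idx <- seq_len(n_full)
  hdr <- lines[(idx - 1L) * 4L + 1L]
  seq <- lines[(idx - 1L) * 4L + 2L]
  sep <- lines[(idx - 1L) * 4L + 3L]
  qual <- lines[(idx - 1L) * 4L + 4L]
  ok <- startsWith(hdr, "@") & startsWith(sep, "+") & nchar(seq) == nchar(qual)
  n_malformed <- n_malformed + sum(!ok)
  list(records = data.frame(read_id = sub("^@", "", sub("\\s.*$", "", hdr[ok])),
                            seq = seq[ok], qual = qual[ok]),
       n_malformed = n_malformed)
}

#' Parse amplicon reads into barcode and central regions
#'
#' Reads strictly longer than 150 nt are accepted and split by pure string
#' slicing into the first 14 bases (forward tag), the last 14 bases
#' (reverse tag) and the interior central region; shorter reads are
#' rejected and counted. Base qualities are carried through unused:
#' classification downstream is purely sequence-based.
#'
#' @param fastq path to a FASTQ file, or the result of [read_fastq()].
#' @param min_length reads must be strictly longer than this (default 150).
#' @return list with `parsed` (data.frame `read_id`, `fwd_tag`, `central`,
#'   `rev_tag`), and tallies `n_total`, `n_accepted`, `n_rejected_short`,
#'   `n_malformed`.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", strrep("A", 151), "+", strrep("I", 151)), fq)
#' parse_reads(fq)$parsed$fwd_tag
#' @export
parse_reads <- function(fastq, min_length = 150L) {
  if (is.character(fastq)) fastq <- read_fastq(fastq)
  rec <- fastq$records
  len <- nchar(rec$seq)
  keep <- len > min_length
  acc <- rec[keep, , drop = FALSE]
  alen <- len[keep]
  parsed <- data.frame(
    read_id = acc$read_id,
    fwd_tag = substr(acc$seq, 1L, TAG_LEN),
    central = substr(acc$seq, TAG_LEN + 1L, alen - TAG_LEN),
    rev_tag = substr(acc$seq, alen - TAG_LEN + 1L, alen))
  list(parsed = parsed,
       n_total = nrow(rec) + fastq$n_malformed,
       n_accepted = nrow(acc),
       n_rejected_short = sum(!keep),
       n_malformed = fastq$n_malformed)
}

#' Extract the 60-nt diagnostic window from a central read region
#'
#' @param central character vector of central regions (between the two
#'   14-nt tags).
#' @param expected_offset 0-based offset of the window within the central
#'   region (31 for the default read layout).
#' @return character vector of 60-nt windows; `NA` marks centrals too short
#'   to contain the window (unclassifiable, not an error).
#' @export
extract_central_window <- function(central, expected_offset) {
  out <- substr(central, expected_offset + 1L, expected_offset + WINDOW_LEN)
  out[nchar(out) < WINDOW_LEN] <- NA_character_
  out
}

#' Write the three parsed-region FASTQ files
#'
#' Mirrors the three-way split of the original processing into
#' `query-barcode.fastq`, `query-revbarcode.fastq` and
#' `query-subject.fastq` (forward tag, reverse tag, central region).
#'
#' @param parsed result of [parse_reads()].
#' @param dir output directory.
#' @return named character vector of the three paths, invisibly.
#' @export
write_region_fastq <- function(parsed, dir) {
  p <- parsed$parsed
  paths <- c(barcode = file.path(dir, "query-barcode.fastq"),
             revbarcode = file.path(dir, "query-revbarcode.fastq"),
             subject = file.path(dir, "query-subject.fastq"))
  regions <- list(p$fwd_tag, p$rev_tag, p$central)
  for (k in 1:3) {
    s <- regions[[k]]
    writeLines(as.vector(rbind(paste0("@", p$read_id), s, "+",
                               strrep("I", nchar(s)))), paths[k])
  }
  invisible(paths)
}
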