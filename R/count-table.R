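#' Binned count tables and internal-standard mix tables
#'
#' A count table records, per sequencing library (sample x IS-dilution
#' replicate `i`) and gene, the number of reads called native target
#' (`nt_count`, NT_i in the estimator) and internal standard
#' (`is_count`, IS_i). The on-disk dialect is comma-delimited with header
#' `sample,dilution_index,gene,nt_count,is_count`.
#'
#' @param x data.frame with columns `sample`, `dilution_index`, `gene_id`,
#'   `nt_count`, `is_count`.
#' @return a validated `count_table` (a classed data.frame).
#' @export
count_table <- function(x) {
  required <- c("sample", "dilution_index", "gene_id", "nt_count", "is_count")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stopf("count table lacks columns: %s", paste(missing_cols, collapse = ", "))
  x <- as.data.frame(x)[required]
  x$sample <- as.character(x$sample)
  x$gene_id <- as.character(x$gene_id)
  x$dilution_index <- as.integer(x$dilution_index)
  for (col in c("nt_count", "is_count")) {
    v <- x[[col]]
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
      stopf("%s must be non-negative integers", col)
    x[[col]] <- as.integer(round(v))
  }
  key <- paste(x$sample, x$dilution_index, x$gene_id)
  if (anyDuplicated(key))
    stopf("duplicate (sample, dilution_index, gene) records in count table")
  rownames(x) <- NULL
  class(x) <- c("count_table", "data.frame")
  x
}

#' @param counts a [count_table()].
#' @param path CSV path.
#' @param panel optional [assay_panel()]; genes absent from it are flagged
#'   with a warning on read.
#' @rdname count_table
#' @export
write_count_table <- function(counts, path) {
  counts <- count_table(counts)
  out <- data.frame(sample = counts$sample,
                    dilution_index = counts$dilution_index,
                    gene = counts$gene_id,
                    nt_count = counts$nt_count,
                    is_count = counts$is_count)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname count_table
#' @export
read_count_table <- function(path, panel = NULL) {
  x <- read.csv(path, colClasses = c(sample = "character", gene = "character"))
  required <- c("sample", "dilution_index", "gene", "nt_count", "is_count")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stopf("count table %s lacks columns: %s", path,
          paste(missing_cols, collapse = ", "))
  names(x)[names(x) == "gene"] <- "gene_id"
  counts <- count_table(x)
  if (!is.null(panel)) {
    unknown <- setdiff(counts$gene_id, panel$assays$gene_id)
    if (length(unknown))
      warnf("count table contains %d gene(s) absent from the panel: %s",
            length(unknown), paste(head(unknown, 5L), collapse = ", "))
  }
  counts
}

#' Internal-standard mix tables
#'
#' Maps each (dilution index, gene) to SC_i, the known copies of that
#' gene's internal standard loaded into one library preparation. CSV
#' dialect: `dilution_index,gene,sc`.
#'
#' @param x data.frame with columns `dilution_index`, `gene_id`, `sc`.
#' @export
is_mix <- function(x) {
  required <- c("dilution_index", "gene_id", "sc")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stopf("IS mix table lacks columns: %s", paste(missing_cols, collapse = ", "))
  x <- as.data.frame(x)[required]
  x$gene_id <- as.character(x$gene_id)
  x$dilution_index <- as.integer(x$dilution_index)
  if (any(!is.finite(x$sc)) || any(x$sc <= 0))
    stopf("all SC values must be finite and > 0")
  if (anyDuplicated(paste(x$dilution_index, x$gene_id)))
    stopf("duplicate (dilution_index, gene) in IS mix table")
  rownames(x) <- NULL
  class(x) <- c("is_mix", "data.frame")
  x
}

#' @param mix an [is_mix()] table.
#' @param path CSV path.
#' @rdname is_mix
#' @export
write_is_mix <- function(mix, path) {
  mix <- is_mix(mix)
  out <- data.frame(dilution_index = mix$dilution_index,
                    gene = mix$gene_id, sc = mix$sc)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname is_mix
#' @export
read_is_mix <- function(path) {
  x <- read.csv(path, colClasses = c(gene = "character"))
  names(x)[names(x) == "gene"] <- "gene_id"
  is_mix(x)
}
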