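# Readers and writers for the pipeline's plain-text interchange formats:
# TSV read tables / labels / GRE maps, FASTA barcode sets, MatrixMarket
# count matrices with cells/features sidecars, and enrichment tables.

read_tsv_checked <- function(path, required) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0)
    stop_validation(path, " lacks required column(s): ",
                    paste(missing, collapse = ", "))
  x
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write pipeline tables
#'
#' Plain TSV formats: read tables (`cell_barcode`, `umi`, `sequence`),
#' cell labels (`cell_barcode`, `cell_type`) and GRE-barcode maps
#' (`gre_id`, `slot`, `barcode`).
#'
#' @param path File path.
#' @param x Object to write.
#' @return Readers return data frames; writers return the path,
#'   invisibly.
#' @export
read_reads <- function(path) {
  read_tsv_checked(path, c("cell_barcode", "umi", "sequence"))
}

#' @rdname read_reads
#' @export
write_reads <- function(x, path) write_tsv(x, path)

#' @rdname read_reads
#' @export
read_labels <- function(path) {
  read_tsv_checked(path, c("cell_barcode", "cell_type"))
}

#' @rdname read_reads
#' @export
write_labels <- function(x, path) write_tsv(x, path)

#' @rdname read_reads
#' @export
read_gre_map <- function(path) {
  x <- read_tsv_checked(path, c("gre_id", "barcode"))
  if (is.null(x$slot))
    x$slot <- stats::ave(seq_len(nrow(x)), x$gre_id, FUN = seq_along)
  class(x) <- c("gre_barcode_map", "data.frame")
  x
}

#' @rdname read_reads
#' @export
write_gre_map <- function(x, path) write_tsv(x, path)

#' Read and write barcode sets
#'
#' TSV (`barcode_id`, `sequence`) or FASTA (barcode id as header).
#' Metadata (`min_distance`, `metric`) travels in a `# pesca:` comment
#' line in TSV and is re-declared on read (defaulting to 3 /
#' levenshtein when absent); use [validate_barcode_set()] to verify.
#'
#' @param set A [barcode_set()].
#' @param path File path.
#' @return Readers return a [barcode_set()]; writers the path,
#'   invisibly.
#' @export
write_barcodes_tsv <- function(set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pesca:barcode_set min_distance=%d metric=%s",
                     set$min_distance, set$metric), con)
  writeLines("barcode_id\tsequence", con)
  writeLines(sprintf("bc%04d\t%s", seq_along(set$barcodes),
                     set$barcodes), con)
  invisible(path)
}

#' @rdname write_barcodes_tsv
#' @export
read_barcodes_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  min_d <- 3L
  metric <- "levenshtein"
  if (startsWith(first, "# pesca:barcode_set")) {
    min_d <- as.integer(sub(".*min_distance=(\\d+).*", "\\1", first))
    metric <- sub(".*metric=(\\S+).*", "\\1", first)
  }
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         comment.char = "#", stringsAsFactors = FALSE)
  barcode_set(x$sequence, min_distance = min_d, metric = metric)
}

#' @rdname write_barcodes_tsv
#' @export
write_barcodes_fasta <- function(set, path) {
  seqs <- Biostrings::DNAStringSet(set$barcodes)
  names(seqs) <- sprintf("bc%04d", seq_along(set$barcodes))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_barcodes_tsv
#' @export
read_barcodes_fasta <- function(path, min_distance = 3L,
                                metric = "levenshtein") {
  seqs <- Biostrings::readDNAStringSet(path)
  barcode_set(as.character(seqs), min_distance = min_distance,
              metric = metric)
}

#' Write and read sparse count matrices (MatrixMarket + sidecars)
#'
#' Writes `matrix.mtx` with `cells.tsv` and `features.tsv` sidecars
#' into a directory, and reads them back.
#'
#' @param counts Sparse cell x feature matrix.
#' @param dir Directory path (created if needed).
#' @return `read_counts_mtx()` returns the sparse matrix with
#'   dimnames; `write_counts_mtx()` the directory, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "cells.tsv"))
  writeLines(colnames(counts), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(readLines(file.path(dir, "cells.tsv")),
                      readLines(file.path(dir, "features.tsv")))
  m
}

#' Write a simulated screen to a directory
#'
#' Writes `reads.tsv`, `labels.tsv`, `gre_map.tsv`, `barcodes.tsv`, the
#' true cell x barcode counts (MTX under `true_counts/`) and the truth
#' parameters as JSON.
#'
#' @param screen A `pesca_screen` from [simulate_screen()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_screen <- function(screen, dir) {
  stopifnot(inherits(screen, "pesca_screen"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_reads(screen$reads, file.path(dir, "reads.tsv"))
  write_labels(screen$labels, file.path(dir, "labels.tsv"))
  write_gre_map(screen$map, file.path(dir, "gre_map.tsv"))
  write_barcodes_tsv(screen$barcode_set, file.path(dir, "barcodes.tsv"))
  write_counts_mtx(screen$true_counts, file.path(dir, "true_counts"))
  truth <- screen$truth
  truth$cell_type_proportions <- as.list(truth$cell_type_proportions)
  truth$true_fold <- as.list(truth$true_fold)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write an enrichment table as TSV
#'
#' @param x The data frame from [nb_lrt_test()] (or
#'   `pesca_enrichment$table`).
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_enrichment <- function(x, path) {
  if (inherits(x, "pesca_enrichment")) x <- x$table
  write_tsv(x, path)
}
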