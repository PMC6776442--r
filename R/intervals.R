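#' Validate a table of genomic intervals
#'
#' Intervals follow the BED convention: 0-based, half-open
#' (`start` inclusive, `end` exclusive).
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end` and
#'   optionally `id`.
#' @param chrom_sizes Optional named vector of chromosome lengths; when
#'   supplied, intervals must lie within bounds.
#' @return The validated data frame (invisibly usable), with an `id`
#'   column added when absent.
#' @export
validate_intervals <- function(intervals, chrom_sizes = NULL) {
  req <- c("chrom", "start", "end")
  if (!is.data.frame(intervals) || !all(req %in% names(intervals)))
    stop_validation("intervals must be a data frame with columns ",
                    paste(req, collapse = ", "))
  if (any(is.na(intervals$start)) || any(is.na(intervals$end)))
    stop_validation("interval coordinates contain NA")
  if (any(intervals$end <= intervals$start))
    stop_validation("intervals with end <= start found")
  if (any(intervals$start < 0))
    stop_validation("negative interval start found")
  if (!is.null(chrom_sizes)) {
    missing <- setdiff(unique(intervals$chrom), names(chrom_sizes))
    if (length(missing) > 0)
      stop_validation("chrom_sizes missing chromosomes: ",
                      paste(missing, collapse = ", "))
    if (any(intervals$end > chrom_sizes[intervals$chrom]))
      stop_validation("interval exceeds chromosome bounds")
  }
  if (is.null(intervals$id))
    intervals$id <- sprintf("iv%06d", seq_len(nrow(intervals)))
  intervals
}

iv_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end))
}

granges_to_iv <- function(gr, ids = NULL) {
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  out$id <- ids %||% sprintf("iv%06d", seq_len(nrow(out)))
  out
}

#' Merge overlapping intervals into a non-redundant reference list
#'
#' Combines peak intervals that overlap on the same chromosome into
#' their union, the standard step that builds an aggregated reference
#' peak list from per-sample peak calls. Intervals that merely abut
#' (one's `end` equals the other's `start` in half-open coordinates) are
#' kept separate. Output is sorted by chromosome then start.
#'
#' @param intervals BED-like data frame (see [validate_intervals()]).
#' @return Data frame of merged intervals with fresh ids and an
#'   `n_merged` column counting constituent inputs.
#' @examples
#' merge_intervals(data.frame(chrom = "chr1", start = c(0, 50),
#'                            end = c(100, 150)))
#' @export
merge_intervals <- function(intervals) {
  intervals <- validate_intervals(intervals)
  gr <- iv_to_granges(intervals)
  red <- GenomicRanges::reduce(GenomicRanges::sort(gr), min.gapwidth = 0L,
                               with.revmap = TRUE)
  out <- granges_to_iv(red)
  out$id <- sprintf("merged%06d", seq_len(nrow(out)))
  out$n_merged <- lengths(S4Vectors::mcols(red)$revmap)
  out
}

#' Distal control intervals for conservation calibration
#'
#' For each peak, places a same-length control interval a fixed distance
#' downstream (`start + offset_bp`); if that would overrun the
#' chromosome end, the control is mirrored upstream
#' (`start - offset_bp`). Peaks admitting neither placement are dropped
#' and reported in the `dropped` attribute.
#'
#' @param peaks BED-like data frame.
#' @param offset_bp Shift distance in bases (default 100000).
#' @param chrom_sizes Named vector of chromosome lengths covering all
#'   peak chromosomes.
#' @return Data frame of control intervals (ids suffixed `_ctrl`), with
#'   attribute `dropped` holding the ids of peaks without a valid
#'   placement.
#' @export
distal_controls <- function(peaks, offset_bp = 100000L, chrom_sizes) {
  peaks <- validate_intervals(peaks, chrom_sizes)
  offset_bp <- assert_count(offset_bp, "offset_bp")
  len <- peaks$end - peaks$start
  size <- chrom_sizes[peaks$chrom]
  right_ok <- peaks$end + offset_bp <= size
  left_ok <- peaks$start - offset_bp >= 0
  use_right <- right_ok
  use_left <- !right_ok & left_ok
  keep <- use_right | use_left
  shift <- ifelse(use_right, offset_bp, -offset_bp)
  ids <- peaks$id[keep]
  out <- data.frame(chrom = peaks$chrom[keep],
                    start = peaks$start[keep] + shift[keep],
                    end = peaks$end[keep] + shift[keep],
                    id = if (length(ids)) paste0(ids, "_ctrl")
                         else character(0),
                    source_id = ids,
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- peaks$id[!keep]
  out
}

#' Read / write BED files
#'
#' Thin wrappers over tab-separated BED3/BED6. `write_bed()` writes
#' `chrom`, `start`, `end` and, when present, `id`, `score`, `strand`.
#'
#' @param path File path.
#' @param x BED-like data frame.
#' @return `read_bed()` returns a data frame with columns `chrom`,
#'   `start`, `end` and, if present in the file, `id`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  names(x) <- c("chrom", "start", "end", "id", "score",
                "strand")[seq_len(ncol(x))]
  validate_intervals(x)
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "id", "score", "strand"),
                    names(x))
  utils::write.table(x[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
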