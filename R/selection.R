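#' Construct a peak table
#'
#' Couples peak intervals with a peaks x cell-type matrix of mean ATAC
#' signal and a per-peak mean conservation score (phyloP-style).
#'
#' @param intervals BED-like data frame (see [validate_intervals()]).
#' @param signal Non-negative numeric matrix, one row per interval, one
#'   named column per cell type.
#' @param conservation Numeric vector of per-interval mean conservation
#'   scores, or `NULL` when not yet attached.
#' @return An object of class `peak_table`.
#' @export
peak_table <- function(intervals, signal, conservation = NULL) {
  intervals <- validate_intervals(intervals)
  signal <- as.matrix(signal)
  if (nrow(signal) != nrow(intervals))
    stop_validation("signal row count (", nrow(signal),
                    ") != interval count (", nrow(intervals), ")")
  if (is.null(colnames(signal)))
    stop_validation("signal matrix must have cell-type column names")
  if (any(signal < 0)) stop_validation("negative ATAC signal")
  if (!is.null(conservation) && length(conservation) != nrow(intervals))
    stop_validation("conservation length != interval count")
  rownames(signal) <- intervals$id
  structure(list(intervals = intervals, signal = signal,
                 conservation = conservation),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("peak_table: %d intervals x %d cell types (%s)%s\n",
              nrow(x$intervals), ncol(x$signal),
              paste(colnames(x$signal), collapse = ", "),
              if (is.null(x$conservation)) "" else ", with conservation"))
  invisible(x)
}

#' Nearest-rank percentile of a score distribution
#'
#' Returns the `ceiling(p/100 * n)`-th order statistic. Used to derive
#' the minimum conservation cutoff from the distal-control score
#' distribution.
#'
#' @param control_scores Non-empty numeric vector.
#' @param percentile Percentile in (0, 100) (default 95).
#' @return A single numeric threshold.
#' @examples
#' conservation_threshold(1:100, 95)  # 95
#' @export
conservation_threshold <- function(control_scores, percentile = 95) {
  if (length(control_scores) == 0L || all(is.na(control_scores)))
    stop_validation("empty control score distribution")
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 100)
    stop_validation("percentile must be in (0, 100)")
  x <- sort(control_scores[!is.na(control_scores)])
  x[ceiling(percentile / 100 * length(x))]
}

#' Filter a peak table to conserved peaks
#'
#' Retains peaks whose mean conservation score is greater than or equal
#' to the threshold (ties at the threshold retained).
#'
#' @param peaks A [peak_table()] with conservation populated.
#' @param threshold Minimum conservation score.
#' @return A `peak_table` restricted to the retained rows.
#' @export
filter_conserved <- function(peaks, threshold) {
  stopifnot(inherits(peaks, "peak_table"))
  if (is.null(peaks$conservation) || any(is.na(peaks$conservation)))
    stop_validation("conservation scores missing")
  keep <- peaks$conservation >= threshold
  peak_table(peaks$intervals[keep, , drop = FALSE],
             peaks$signal[keep, , drop = FALSE],
             peaks$conservation[keep])
}

#' Scale per-cell-type ATAC signal to a common library size
#'
#' Rescales each cell-type column so its total equals `scale`
#' (default 1e7), removing per-population sequencing-depth differences
#' before fold-enrichment scoring.
#'
#' @param signal Non-negative matrix, one column per cell type.
#' @param scale Target column total (default 1e7).
#' @return The rescaled matrix.
#' @export
normalize_signal <- function(signal, scale = 1e7) {
  signal <- as.matrix(signal)
  if (any(signal < 0)) stop_validation("negative ATAC signal")
  scale <- assert_positive(scale, "scale")
  totals <- colSums(signal)
  if (any(totals <= 0))
    stop_validation("zero-total cell-type column(s): ",
                    paste(colnames(signal)[totals <= 0], collapse = ", "))
  sweep(signal, 2L, totals / scale, "/")
}

#' Cell-type specificity score from normalized ATAC signal
#'
#' For each peak, the pseudocounted ratio of target-cell-type signal to
#' the mean signal across all other cell types:
#' `(s_target + c) / (mean(s_other) + c)`.
#'
#' @param norm_signal Normalized signal matrix (see
#'   [normalize_signal()]).
#' @param target Target cell-type column name.
#' @param pseudocount Additive constant `c` (default 0.5).
#' @return Numeric vector of per-peak enrichment scores.
#' @examples
#' m <- cbind(SST = 10, PV = 2, VIP = 4)
#' atac_enrichment(m, "SST")  # (10 + 0.5) / (3 + 0.5) = 3
#' @export
atac_enrichment <- function(norm_signal, target, pseudocount = 0.5) {
  norm_signal <- as.matrix(norm_signal)
  if (!target %in% colnames(norm_signal))
    stop_validation("unknown target cell type: ", target)
  if (ncol(norm_signal) < 2L)
    stop_validation("at least two cell types required")
  pseudocount <- assert_positive(pseudocount, "pseudocount")
  others <- setdiff(colnames(norm_signal), target)
  rest <- rowMeans(norm_signal[, others, drop = FALSE])
  unname((norm_signal[, target] + pseudocount) / (rest + pseudocount))
}

#' Select the top-k most cell-type-specific peaks
#'
#' Ranks peaks by descending enrichment score; ties are broken by higher
#' target-cell-type signal, then by input order, so the ranking is
#' deterministic.
#'
#' @param peaks A [peak_table()].
#' @param scores Per-peak enrichment scores (same order as the table).
#' @param k Panel size.
#' @param target Target cell-type column used for tie-breaking.
#' @return Data frame with `rank`, the interval columns, `score`,
#'   `conservation` (if present) and the per-type signal columns.
#' @export
select_panel <- function(peaks, scores, k, target) {
  stopifnot(inherits(peaks, "peak_table"))
  n <- nrow(peaks$intervals)
  if (length(scores) != n)
    stop_validation("scores length != peak count")
  k <- assert_count(k, "k")
  if (k > n) stop_validation("k (", k, ") exceeds available peaks (", n, ")")
  tie <- if (target %in% colnames(peaks$signal))
    peaks$signal[, target] else rep(0, n)
  ord <- order(-scores, -tie, seq_len(n))[seq_len(k)]
  out <- cbind(rank = seq_len(k),
               peaks$intervals[ord, , drop = FALSE],
               score = scores[ord])
  if (!is.null(peaks$conservation))
    out$conservation <- peaks$conservation[ord]
  out <- cbind(out, peaks$signal[ord, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' GRE panel selection pipeline
#'
#' End-to-end selection of a conserved, cell-type-specific GRE panel:
#' derive the conservation cutoff from the distal-control score
#' distribution (nearest-rank percentile), drop non-conserved peaks,
#' scale each cell-type signal column to a common total, score peaks by
#' pseudocounted target-vs-rest signal ratio, and return the top `k`.
#'
#' @param peaks A [peak_table()] with conservation scores.
#' @param control_scores Conservation scores of distal control
#'   sequences (see [distal_controls()]).
#' @param target Target cell-type column name.
#' @param k Panel size (default 287).
#' @param conservation_percentile Control-distribution percentile used
#'   as the conservation cutoff (default 95).
#' @param signal_scale Per-column signal total after normalization
#'   (default 1e7).
#' @param atac_pseudocount Pseudocount for the signal ratio
#'   (default 0.5).
#' @return The [select_panel()] data frame, with attributes
#'   `conservation_cutoff` and `n_conserved`.
#' @export
select_gres <- function(peaks, control_scores, target, k = 287L,
                        conservation_percentile = 95,
                        signal_scale = 1e7, atac_pseudocount = 0.5) {
  cutoff <- conservation_threshold(control_scores, conservation_percentile)
  conserved <- filter_conserved(peaks, cutoff)
  norm <- normalize_signal(conserved$signal, signal_scale)
  scores <- atac_enrichment(norm, target, atac_pseudocount)
  if (k > nrow(conserved$intervals))
    stop_validation("panel size k (", k, ") exceeds the ",
                    nrow(conserved$intervals), " conserved peaks")
  panel <- select_panel(conserved, scores, k, target)
  attr(panel, "conservation_cutoff") <- cutoff
  attr(panel, "n_conserved") <- nrow(conserved$intervals)
  panel
}
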