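#' Mismatch-tolerant assignment of observed sequences to barcodes
#'
#' Computes the Hamming distance from each observed fixed-length
#' sequence to every barcode in the set and applies the assignment
#' policy: a sequence is `assigned` iff exactly one barcode lies within
#' `max_mismatch` and no second barcode lies within
#' `uniqueness_radius`; it is `ambiguous` when two or more barcodes lie
#' within the uniqueness radius; otherwise `unassigned`. For a set with
#' pairwise distance >= 3 and `max_mismatch = 1`, ties at the mismatch
#' cap are impossible; this is asserted, not assumed.
#'
#' @param sequences Character vector of observed barcode-region
#'   sequences, already trimmed to the barcode length.
#' @param set A [barcode_set()].
#' @param max_mismatch Maximum Hamming distance for assignment
#'   (default 1).
#' @param uniqueness_radius Radius within which a second barcode makes
#'   the read ambiguous (default 2). Must be >= `max_mismatch`.
#' @return Data frame with one row per sequence: `sequence`, `status`
#'   (`"assigned"`, `"ambiguous"`, `"unassigned"`), `barcode` (NA unless
#'   assigned) and `distance` (Hamming distance to the closest barcode).
#' @examples
#' bs <- barcode_set(c("AAAAA", "CCCCC", "GGGGG"))
#' match_barcode(c("AAAAA", "AAAAC", "AACCC"), bs)
#' @export
match_barcode <- function(sequences, set, max_mismatch = 1L,
                          uniqueness_radius = 2L) {
  stopifnot(inherits(set, "barcode_set"))
  max_mismatch <- assert_count(max_mismatch, "max_mismatch", min = 0L)
  uniqueness_radius <- assert_count(uniqueness_radius,
                                    "uniqueness_radius", min = 0L)
  if (max_mismatch > uniqueness_radius)
    stop_validation("max_mismatch must be <= uniqueness_radius")
  sequences <- as.character(sequences)
  if (any(nchar(sequences) != set$length))
    stop_validation("sequences must be trimmed to the barcode length (",
                    set$length, ")")
  m <- hamming_match_cpp(sequences, set$barcodes, uniqueness_radius)
  # when the set's pairwise distance exceeds 2 * max_mismatch, a tie at
  # <= max_mismatch would prove the distance guarantee broken; assert
  # rather than assume (for larger max_mismatch ties are legitimate and
  # fall under the ambiguity rule)
  if (set$min_distance > 2L * max_mismatch) {
    tie <- m$best_dist <= max_mismatch & m$second_dist <= max_mismatch
    if (any(tie))
      stop_validation("two barcodes within max_mismatch of one ",
                      "sequence; the barcode set violates its distance ",
                      "guarantee")
  }
  assigned <- m$best_dist <= max_mismatch & m$n_within_radius == 1L
  ambiguous <- m$n_within_radius >= 2L
  status <- ifelse(assigned, "assigned",
                   ifelse(ambiguous, "ambiguous", "unassigned"))
  data.frame(sequence = sequences, status = status,
             barcode = ifelse(assigned, set$barcodes[m$best_idx],
                              NA_character_),
             distance = m$best_dist, stringsAsFactors = FALSE)
}

#' UMI-deduplicated cell x barcode counts from a read table
#'
#' Assigns every read's viral sequence to a barcode under the mismatch
#' policy of [match_barcode()], collapses duplicate
#' (cell, UMI, barcode) combinations to single molecules, and returns a
#' sparse cell x barcode UMI count matrix together with a QC report.
#'
#' @param reads Data frame with columns `cell_barcode`, `umi`,
#'   `sequence`.
#' @param set A [barcode_set()].
#' @param max_mismatch,uniqueness_radius Assignment policy (see
#'   [match_barcode()]).
#' @param cell_whitelist Optional character vector; reads from other
#'   cells are dropped (counted in QC). `NULL` retains all observed
#'   cells.
#' @param prefix,suffix Optional fixed flanking sequences; when
#'   supplied, each read must start/end with them and the barcode
#'   region in between is extracted before matching. Reads whose
#'   trimmed region is not the barcode length are rejected.
#' @return A list of class `pesca_counts`: `counts` (sparse dgCMatrix,
#'   cells x barcodes), `qc` (list with read/molecule tallies, the
#'   fraction of viral reads not uniquely assignable, and rejected-read
#'   counts).
#' @export
count_umis <- function(reads, set, max_mismatch = 1L,
                       uniqueness_radius = 2L, cell_whitelist = NULL,
                       prefix = "", suffix = "") {
  stopifnot(inherits(set, "barcode_set"))
  req <- c("cell_barcode", "umi", "sequence")
  if (!is.data.frame(reads) || !all(req %in% names(reads)))
    stop_validation("reads must have columns ", paste(req, collapse = ", "))
  n_total <- nrow(reads)
  if (n_total == 0L) {
    warning("empty read table; returning empty matrix")
    return(structure(list(
      counts = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                    x = numeric(0), dims = c(0L, length(set)),
                                    dimnames = list(NULL, set$barcodes)),
      qc = list(n_reads = 0L, n_assigned = 0L, n_ambiguous = 0L,
                n_unassigned = 0L, n_rejected = 0L, n_off_whitelist = 0L,
                frac_not_unique = NA_real_, n_molecules = 0L)),
      class = "pesca_counts"))
  }

  n_off <- 0L
  if (!is.null(cell_whitelist)) {
    keep <- reads$cell_barcode %in% cell_whitelist
    n_off <- sum(!keep)
    reads <- reads[keep, , drop = FALSE]
  }

  seqs <- as.character(reads$sequence)
  if (nzchar(prefix) || nzchar(suffix)) {
    ok <- (!nzchar(prefix) | startsWith(seqs, prefix)) &
      (!nzchar(suffix) | endsWith(seqs, suffix))
    seqs <- substr(seqs, nchar(prefix) + 1L, nchar(seqs) - nchar(suffix))
  } else ok <- rep(TRUE, length(seqs))
  ok <- ok & nchar(seqs) == set$length
  n_rejected <- sum(!ok)
  reads <- reads[ok, , drop = FALSE]
  seqs <- seqs[ok]

  uniq <- unique(seqs)
  hit <- match_barcode(uniq, set, max_mismatch, uniqueness_radius)
  idx <- match(seqs, uniq)
  status <- hit$status[idx]
  barcode <- hit$barcode[idx]

  n_assigned <- sum(status == "assigned")
  n_ambiguous <- sum(status == "ambiguous")
  n_unassigned <- sum(status == "unassigned")
  frac_not_unique <- (n_ambiguous + n_unassigned) / max(1L, nrow(reads))

  keep <- status == "assigned"
  trip <- unique(data.frame(cell = reads$cell_barcode[keep],
                            umi = reads$umi[keep],
                            barcode = barcode[keep],
                            stringsAsFactors = FALSE))
  cells <- sort(unique(reads$cell_barcode))
  counts <- Matrix::sparseMatrix(
    i = match(trip$cell, cells), j = match(trip$barcode, set$barcodes),
    x = 1, dims = c(length(cells), length(set)),
    dimnames = list(cells, set$barcodes))

  structure(list(counts = counts,
                 qc = list(n_reads = n_total, n_assigned = n_assigned,
                           n_ambiguous = n_ambiguous,
                           n_unassigned = n_unassigned,
                           n_rejected = n_rejected,
                           n_off_whitelist = n_off,
                           frac_not_unique = frac_not_unique,
                           n_molecules = nrow(trip))),
            class = "pesca_counts")
}

#' @export
print.pesca_counts <- function(x, ...) {
  q <- x$qc
  cat(sprintf(paste0(
    "pesca_counts: %d cells x %d barcodes, %d molecules\n",
    "  reads: %d total, %d assigned, %d ambiguous, %d unassigned, ",
    "%d rejected\n  not uniquely assignable: %.2f%%\n"),
    nrow(x$counts), ncol(x$counts), q$n_molecules, q$n_reads,
    q$n_assigned, q$n_ambiguous, q$n_unassigned, q$n_rejected,
    100 * q$frac_not_unique))
  invisible(x)
}

#' Aggregate barcode counts to GRE counts
#'
#' Sums, per cell, the UMI counts of the barcodes paired with each GRE,
#' giving the per-cell GRE expression used by the enrichment tests.
#' Matrix columns absent from the map are dropped with a warning; total
#' counts are conserved up to dropped barcodes.
#'
#' @param counts Cell x barcode matrix (sparse or dense), columns named
#'   by barcode sequence.
#' @param map A `gre_barcode_map` from [assign_barcodes()].
#' @return Sparse cell x GRE count matrix.
#' @export
aggregate_gre <- function(counts, map) {
  if (!all(c("gre_id", "barcode") %in% names(map)))
    stop_validation("map must have columns gre_id, barcode")
  counts <- methods::as(methods::as(counts, "CsparseMatrix"),
                        "generalMatrix")
  unmapped <- setdiff(colnames(counts), map$barcode)
  if (length(unmapped) > 0) {
    warning(length(unmapped), " barcode column(s) absent from the map ",
            "were dropped")
    counts <- counts[, colnames(counts) %in% map$barcode, drop = FALSE]
  }
  gres <- unique(map$gre_id)
  grp <- factor(map$gre_id[match(colnames(counts), map$barcode)],
                levels = gres)
  agg <- Matrix::sparseMatrix(i = seq_along(grp), j = as.integer(grp),
                              x = 1, dims = c(length(grp), length(gres)),
                              dimnames = list(colnames(counts), gres))
  out <- counts %*% agg
  methods::as(out, "CsparseMatrix")
}

#' Library complexity report
#'
#' Fraction of designed barcodes and of GREs detected (>= 1 count) in a
#' counts matrix, with abundance histograms binned by total counts per
#' feature on a log10 grid.
#'
#' @param counts Cell x barcode matrix, columns named by barcode.
#' @param set A [barcode_set()] defining the designed barcodes.
#' @param map A `gre_barcode_map`.
#' @return A list with `n_barcodes_detected`, `frac_barcodes_detected`,
#'   `n_gres_detected`, `frac_gres_detected`, and `barcode_hist` /
#'   `gre_hist` tables of features per abundance bin.
#' @export
library_complexity <- function(counts, set, map) {
  stopifnot(inherits(set, "barcode_set"))
  bc_tot <- structure(numeric(length(set)), names = set$barcodes)
  present <- intersect(colnames(counts), set$barcodes)
  bc_tot[present] <- Matrix::colSums(counts[, present, drop = FALSE])
  gres <- unique(map$gre_id)
  gre_tot <- vapply(split(bc_tot[map$barcode], map$gre_id)[gres], sum,
                    numeric(1))
  bin <- function(tot) {
    brk <- c(-0.5, 0.5, 10^seq(1, ceiling(log10(max(tot, 10))), by = 1))
    table(cut(tot, breaks = unique(brk), include.lowest = TRUE))
  }
  list(n_barcodes_detected = sum(bc_tot > 0),
       frac_barcodes_detected = mean(bc_tot > 0),
       n_gres_detected = sum(gre_tot > 0),
       frac_gres_detected = mean(gre_tot > 0),
       barcode_hist = bin(bc_tot), gre_hist = bin(gre_tot))
}
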