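#' Ground-truth parameters for a synthetic PESCA screen
#'
#' Defines the generative conditions of a simulated enhancer screen:
#' library geometry (GREs x barcodes per GRE), cell-type composition
#' with one designated target type, per-GRE true target enrichment,
#' viral capture depth and infection rate, count overdispersion, and
#' the per-base sequencing error rate on the viral barcode.
#'
#' Defaults mirror a screen of 287 GREs x 3 barcodes read out at an
#' average of 15.6 unique viral transcripts per nucleus with viral
#' transcripts detected in 86% of cells, across ten cortical cell types
#' of which the somatostatin (Sst) interneuron target comprises ~5%.
#'
#' @param n_gres Number of GREs in the library (default 287).
#' @param barcodes_per_gre Barcodes per GRE (default 3).
#' @param cell_type_proportions Named numeric vector of cell-type
#'   fractions summing to 1. The default emulates cortical composition
#'   (excitatory neurons, interneuron classes, glia).
#' @param target_type Name of the target cell type; must be one of the
#'   proportion names (default `"Sst"`).
#' @param true_fold Named numeric vector giving, for specific GREs, the
#'   true ratio of expected viral expression in target vs non-target
#'   cells; unnamed GREs default to 1. Names must be GRE ids
#'   (`"GRE001"`, ...). A scalar 1 (default) means no enriched GREs.
#' @param mean_viral_umis_per_cell Mean unique viral transcripts per
#'   infected cell (default 15.6).
#' @param infection_fraction Fraction of cells carrying viral
#'   transcripts, in (0, 1] (default 0.86).
#' @param nb_dispersion Negative-binomial dispersion (1/size) of the
#'   per-cell total viral UMI count (default 0.3; the screen this
#'   emulates does not constrain it).
#' @param barcode_error_rate Per-base substitution probability on each
#'   read's barcode sequence, in `[0, 0.25)` (default 0.005).
#' @param reads_per_umi Reads emitted per UMI (default 1; larger values
#'   exercise UMI deduplication).
#' @param barcode_length Viral barcode length (default 10).
#' @param seed Integer seed; identical seeds give byte-identical screens.
#' @return An object of class `screen_truth`.
#' @export
screen_truth <- function(n_gres = 287L, barcodes_per_gre = 3L,
                         cell_type_proportions = NULL,
                         target_type = "Sst",
                         true_fold = 1,
                         mean_viral_umis_per_cell = 15.6,
                         infection_fraction = 0.86,
                         nb_dispersion = 0.3,
                         barcode_error_rate = 0.005,
                         reads_per_umi = 1L,
                         barcode_length = 10L,
                         seed = 1L) {
  n_gres <- assert_count(n_gres, "n_gres")
  barcodes_per_gre <- assert_count(barcodes_per_gre, "barcodes_per_gre")
  if (is.null(cell_type_proportions))
    cell_type_proportions <- c(Exc = 0.50, Pv = 0.07, Sst = 0.05,
                               Vip = 0.07, Npy = 0.03, Astro = 0.10,
                               Olig = 0.08, OPC = 0.03, Micro = 0.04,
                               Vasc = 0.03)
  if (is.null(names(cell_type_proportions)) ||
      any(cell_type_proportions < 0))
    stop_validation("cell_type_proportions must be a named non-negative ",
                    "vector")
  if (abs(sum(cell_type_proportions) - 1) > 1e-9)
    stop_validation("cell_type_proportions must sum to 1")
  if (!target_type %in% names(cell_type_proportions))
    stop_validation("target_type '", target_type,
                    "' not among cell types")
  infection_fraction <- assert_fraction(infection_fraction,
                                        "infection_fraction")
  barcode_error_rate <- assert_fraction(barcode_error_rate,
                                        "barcode_error_rate",
                                        lo = 0, hi = 0.25,
                                        lo_open = FALSE, hi_open = TRUE)
  mean_viral_umis_per_cell <- assert_positive(mean_viral_umis_per_cell,
                                              "mean_viral_umis_per_cell")
  nb_dispersion <- assert_positive(nb_dispersion, "nb_dispersion")
  reads_per_umi <- assert_count(reads_per_umi, "reads_per_umi")

  gre_ids <- sprintf("GRE%03d", seq_len(n_gres))
  fold <- rep(1, n_gres)
  names(fold) <- gre_ids
  if (!is.null(names(true_fold))) {
    unknown <- setdiff(names(true_fold), gre_ids)
    if (length(unknown) > 0)
      stop_validation("true_fold names not in GRE ids: ",
                      paste(unknown, collapse = ", "))
    fold[names(true_fold)] <- true_fold
  } else if (length(true_fold) == n_gres) {
    fold[] <- true_fold
  } else if (!identical(as.numeric(true_fold), 1)) {
    stop_validation("true_fold must be 1, a named vector, or length n_gres")
  }
  if (any(fold <= 0)) stop_validation("true_fold values must be > 0")

  structure(list(n_gres = n_gres, barcodes_per_gre = barcodes_per_gre,
                 gre_ids = gre_ids,
                 cell_type_proportions = cell_type_proportions,
                 target_type = target_type, true_fold = fold,
                 mean_viral_umis_per_cell = mean_viral_umis_per_cell,
                 infection_fraction = infection_fraction,
                 nb_dispersion = nb_dispersion,
                 barcode_error_rate = barcode_error_rate,
                 reads_per_umi = reads_per_umi,
                 barcode_length = as.integer(barcode_length),
                 seed = as.integer(seed)),
            class = "screen_truth")
}

#' @export
print.screen_truth <- function(x, ...) {
  hits <- sum(x$true_fold != 1)
  cat(sprintf(paste0(
    "screen_truth: %d GREs x %d barcodes, %d cell types ",
    "(target %s = %.1f%%)\n  %d enriched GRE(s); %.1f viral UMIs/cell, ",
    "%.0f%% infected, error rate %.3g, seed %d\n"),
    x$n_gres, x$barcodes_per_gre, length(x$cell_type_proportions),
    x$target_type, 100 * x$cell_type_proportions[[x$target_type]],
    hits, x$mean_viral_umis_per_cell, 100 * x$infection_fraction,
    x$barcode_error_rate, x$seed))
  invisible(x)
}

#' Simulate a peak/conservation fixture for GRE selection
#'
#' Generates BED-like intervals on a toy genome, a peaks x cell-type
#' ATAC signal matrix in which `n_specific` designated peaks carry
#' elevated signal in the first (target) cell type, per-peak
#' conservation scores, and a matching distal-control conservation
#' distribution. Designated specific peaks are drawn conserved (above
#' the control distribution's 95th percentile) so the full selection
#' pipeline can recover them; a further random subset of background
#' peaks is conserved but not cell-type-specific.
#'
#' @param n_peaks Number of peaks.
#' @param n_celltypes Number of cell types (>= 2; the first is the
#'   target). Three cell types are named SST/PV/VIP.
#' @param n_specific Number of target-specific peaks (<= `n_peaks`).
#' @param seed Integer seed.
#' @param specific_boost Multiplicative target-signal boost applied to
#'   specific peaks (default 6).
#' @return A list with `peaks` (a [peak_table()]), `control_scores`
#'   (numeric), `target` (cell-type name) and `truth` (data frame with
#'   per-peak `specific` and `conserved` flags).
#' @export
simulate_peak_fixture <- function(n_peaks, n_celltypes = 3L, n_specific,
                                  seed = 1L, specific_boost = 6) {
  n_peaks <- assert_count(n_peaks, "n_peaks")
  n_celltypes <- assert_count(n_celltypes, "n_celltypes", min = 2L)
  n_specific <- assert_count(n_specific, "n_specific", min = 0L)
  if (n_specific > n_peaks)
    stop_validation("n_specific exceeds n_peaks")
  types <- if (n_celltypes == 3L) c("SST", "PV", "VIP") else
    paste0("CT", seq_len(n_celltypes))
  with_seed(seed, {
    chrom <- sample(c("chr1", "chr2"), n_peaks, replace = TRUE)
    start <- sample.int(1e7, n_peaks, replace = TRUE) * 10L
    width <- sample(200:1000, n_peaks, replace = TRUE)
    intervals <- data.frame(chrom = chrom, start = start,
                            end = start + width,
                            id = sprintf("peak%05d", seq_len(n_peaks)),
                            stringsAsFactors = FALSE)
    signal <- matrix(stats::rgamma(n_peaks * n_celltypes, shape = 4,
                                   scale = 25),
                     nrow = n_peaks, ncol = n_celltypes,
                     dimnames = list(intervals$id, types))
    specific <- rep(FALSE, n_peaks)
    if (n_specific > 0) {
      specific[sample.int(n_peaks, n_specific)] <- TRUE
      signal[specific, 1L] <- signal[specific, 1L] * specific_boost
    }
    control_scores <- stats::rnorm(n_peaks, mean = 0, sd = 0.25)
    cut95 <- conservation_threshold(control_scores, 95)
    conserved <- specific | (stats::runif(n_peaks) < 0.2)
    conservation <- stats::rnorm(n_peaks, mean = 0, sd = 0.25)
    conservation[conserved] <- cut95 + 0.05 +
      abs(stats::rnorm(sum(conserved), sd = 0.3))
    list(peaks = peak_table(intervals, signal, conservation),
         control_scores = control_scores, target = types[1L],
         truth = data.frame(id = intervals$id, specific = specific,
                            conserved = conserved,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a full PESCA screen with known ground truth
#'
#' Generates everything the quantification and enrichment stages
#' consume: a barcode set and GRE-barcode map (via [design_barcodes()]
#' and [assign_barcodes()]), per-cell type labels, and a read table of
#' (cell barcode, UMI, observed viral barcode sequence).
#'
#' Per cell: the type is drawn from the truth's proportions; with
#' probability `infection_fraction` the cell is infected and its total
#' unique viral transcript count is negative-binomially distributed
#' around `mean_viral_umis_per_cell`; UMIs are allocated to GRE-barcodes
#' multinomially, with weights proportional to `true_fold` in
#' target-type cells and uniform otherwise; each UMI is emitted as
#' `reads_per_umi` reads whose barcode sequence carries i.i.d. per-base
#' substitution errors. UMI tags are unique within a cell by
#' construction, so with a zero error rate deconvolution recovers the
#' generator's counts exactly.
#'
#' @param truth A [screen_truth()].
#' @param n_cells Number of cells to simulate.
#' @return An object of class `pesca_screen`: a list with `reads`,
#'   `labels`, `map`, `barcode_set`, `true_counts` (sparse cell x
#'   barcode UMI matrix), `truth` and `n_cells`.
#' @examples
#' scr <- simulate_screen(screen_truth(n_gres = 20, seed = 1), n_cells = 200)
#' scr
#' @export
simulate_screen <- function(truth, n_cells) {
  stopifnot(inherits(truth, "screen_truth"))
  n_cells <- assert_count(n_cells, "n_cells")
  n_bc <- truth$n_gres * truth$barcodes_per_gre
  set <- design_barcodes(truth$barcode_length, 3L, n_bc,
                         metric = "levenshtein",
                         seed = derive_seed(truth$seed, 1L))
  map <- assign_barcodes(truth$gre_ids, set,
                         per_gre = truth$barcodes_per_gre,
                         seed = derive_seed(truth$seed, 2L))
  # barcode weights: uniform for non-target cells, scaled by the GRE's
  # true_fold for target cells (multinomial within the cell's UMI total)
  ord <- order(match(map$gre_id, truth$gre_ids), map$slot)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  barcodes <- map$barcode
  w_target <- rep(truth$true_fold, each = truth$barcodes_per_gre)

  with_seed(derive_seed(truth$seed, 3L), {
    cell_id <- sprintf("cell%06d", seq_len(n_cells))
    type <- sample(names(truth$cell_type_proportions), n_cells,
                   replace = TRUE, prob = truth$cell_type_proportions)
    infected <- stats::runif(n_cells) < truth$infection_fraction
    totals <- integer(n_cells)
    totals[infected] <- stats::rnbinom(
      sum(infected), mu = truth$mean_viral_umis_per_cell,
      size = 1 / truth$nb_dispersion)
    is_target <- type == truth$target_type

    alloc <- function(cells) {
      tot <- totals[cells]
      n_umi <- sum(tot)
      if (n_umi == 0)
        return(data.frame(cell = integer(0), bc = integer(0)))
      prob <- if (is_target[cells[1L]]) w_target else rep(1, n_bc)
      data.frame(cell = rep(cells, tot),
                 bc = sample.int(n_bc, n_umi, replace = TRUE,
                                 prob = prob))
    }
    tcells <- which(is_target & totals > 0)
    ncells <- which(!is_target & totals > 0)
    umis <- rbind(if (length(tcells)) alloc(tcells),
                  if (length(ncells)) alloc(ncells))
    umis <- umis[order(umis$cell), , drop = FALSE]

    true_counts <- Matrix::sparseMatrix(
      i = umis$cell, j = umis$bc, x = 1,
      dims = c(n_cells, n_bc),
      dimnames = list(cell_id, barcodes))

    # deterministic per-cell UMI tags (base-4 encoding of molecule index)
    within_idx <- sequence(tabulate(umis$cell, nbins = n_cells))
    umi_tag <- int2dna(within_idx - 1L, 8L)

    # emit reads, duplicating per UMI, with per-base substitution errors
    rep_idx <- rep(seq_len(nrow(umis)), each = truth$reads_per_umi)
    bc_chars <- do.call(rbind, strsplit(barcodes, ""))
    read_mat <- bc_chars[umis$bc[rep_idx], , drop = FALSE]
    if (truth$barcode_error_rate > 0 && nrow(read_mat) > 0) {
      hit <- which(stats::runif(base::length(read_mat)) <
                     truth$barcode_error_rate)
      if (base::length(hit) > 0) {
        code <- match(read_mat[hit], c("A", "C", "G", "T"))
        shift <- sample.int(3L, base::length(hit), replace = TRUE)
        read_mat[hit] <- c("A", "C", "G", "T")[((code - 1L + shift) %% 4L)
                                               + 1L]
      }
    }
    seqs <- do.call(paste0, split(read_mat, col(read_mat)))
    reads <- data.frame(cell_barcode = cell_id[umis$cell[rep_idx]],
                        umi = umi_tag[rep_idx],
                        sequence = seqs, stringsAsFactors = FALSE)
    labels <- data.frame(cell_barcode = cell_id, cell_type = type,
                         stringsAsFactors = FALSE)
    structure(list(reads = reads, labels = labels, map = map,
                   barcode_set = set, true_counts = true_counts,
                   truth = truth, n_cells = n_cells),
              class = "pesca_screen")
  })
}

#' @export
print.pesca_screen <- function(x, ...) {
  cat(sprintf(paste0(
    "pesca_screen: %d cells, %d reads, %d GREs x %d barcodes\n",
    "  mean viral UMIs/cell (infected): %.2f; cells with >=1 UMI: %.1f%%\n"),
    x$n_cells, nrow(x$reads), x$truth$n_gres, x$truth$barcodes_per_gre,
    mean(Matrix::rowSums(x$true_counts)[
      Matrix::rowSums(x$true_counts) > 0]),
    100 * mean(Matrix::rowSums(x$true_counts) > 0)))
  invisible(x)
}
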