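#' Full enrichment analysis of a deconvolved screen
#'
#' The top-level analysis of a PESCA screen: per-barcode pseudocounted
#' fold-enrichment toward the target cell type, pairwise consistency of
#' the barcode triplets with a shuffle null, aggregation of barcodes to
#' GREs, and the negative-binomial likelihood-ratio test with BH-FDR
#' control on the GRE counts.
#'
#' Fold-enrichment is computed on per-cell expression at the scale
#' selected by `expr_scale`: `"relative"` (linear counts per
#' `normalize_scale`; default — the ratio-of-means estimator is then a
#' consistent estimate of the underlying expression fold and the
#' pseudocount is negligible), `"lognorm"` (`ln(1 + x)` of the same,
#' the display scale of droplet data) or `"raw"` (plain counts). The NB
#' test always runs on raw counts with size-factor offsets.
#'
#' @param counts Cell x barcode UMI count matrix (e.g.
#'   `count_umis()$counts`).
#' @param map A `gre_barcode_map` from [assign_barcodes()].
#' @param labels Cell labels (data frame `cell_barcode`, `cell_type`,
#'   or named vector).
#' @param target Target cell-type name.
#' @param expr_pseudocount Pseudocount for fold-enrichment
#'   (default 0.01).
#' @param normalize_scale Per-cell scale for relative expression
#'   (default 10000).
#' @param expr_scale Expression scale for fold estimates (see above).
#' @param fdr_threshold BH q threshold for calling enrichment
#'   (default 0.01).
#' @param n_shuffles Shuffle-null permutations (default 1000).
#' @param seed Integer seed for the shuffle null.
#' @param size_factors Size-factor method for the NB test (see
#'   [nb_lrt_test()]).
#' @return An object of class `pesca_enrichment`: list with
#'   `barcode_fold` (per-barcode enrichment data frame), `consistency`
#'   (pairwise slot correlations), `null` (shuffle-null summary),
#'   `gre_counts` (sparse cell x GRE matrix), `table` (the
#'   [nb_lrt_test()] data frame) and the call parameters.
#' @examples
#' scr <- simulate_screen(screen_truth(n_gres = 12, seed = 1,
#'                                     true_fold = c(GRE001 = 8)), 600)
#' fit <- enrich_screen(scr$true_counts, scr$map, scr$labels, "Sst",
#'                      n_shuffles = 100)
#' summary(fit)
#' @export
enrich_screen <- function(counts, map, labels, target,
                          expr_pseudocount = 0.01,
                          normalize_scale = 1e4,
                          expr_scale = c("relative", "lognorm", "raw"),
                          fdr_threshold = 0.01, n_shuffles = 1000L,
                          seed = 1L, size_factors = "total") {
  expr_scale <- match.arg(expr_scale)
  expr <- switch(expr_scale,
    relative = normalize_expression(counts, normalize_scale,
                                    log1p = FALSE),
    lognorm = normalize_expression(counts, normalize_scale,
                                   log1p = TRUE),
    raw = as.matrix(counts))
  lab_expr <- labels_subset(labels, rownames(expr))
  barcode_fold <- expression_enrichment(expr, lab_expr, target,
                                        expr_pseudocount)
  consistency <- barcode_consistency(barcode_fold, map)
  null <- shuffle_null(barcode_fold, map, n_shuffles = n_shuffles,
                       seed = seed)
  gre_counts <- aggregate_gre(counts, map)
  table <- nb_lrt_test(gre_counts, labels, target,
                       size_factors = size_factors,
                       fdr_threshold = fdr_threshold,
                       pseudocount = expr_pseudocount,
                       normalize_scale = normalize_scale)
  structure(list(barcode_fold = barcode_fold, consistency = consistency,
                 null = null, gre_counts = gre_counts, table = table,
                 target = target, fdr_threshold = fdr_threshold,
                 expr_scale = expr_scale,
                 expr_pseudocount = expr_pseudocount),
            class = "pesca_enrichment")
}

#' @export
print.pesca_enrichment <- function(x, ...) {
  cat(sprintf(paste0(
    "pesca_enrichment: %d GREs x %d cells, target '%s'\n",
    "  barcode-slot consistency: mean pairwise r = %.3f ",
    "(shuffle null %.3f +/- %.3f)\n",
    "  enriched GREs (q < %g, fold > 1): %d\n"),
    ncol(x$gre_counts), nrow(x$gre_counts), x$target,
    mean(x$consistency$r, na.rm = TRUE), x$null$mean, x$null$sd,
    x$fdr_threshold, sum(x$table$enriched, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.pesca_enrichment <- function(object, n = 10L, ...) {
  tab <- object$table[order(object$table$q, -object$table$fold), ]
  cat(sprintf("Top %d GREs by q-value (target '%s'):\n", n,
              object$target))
  print(utils::head(
    tab[, c("feature", "fold", "log2_fold", "lrt_stat", "p", "q",
            "enriched")], n),
    row.names = FALSE, digits = 3)
  invisible(tab)
}

#' @export
coef.pesca_enrichment <- function(object, ...) {
  stats::setNames(object$table$log2_fold, object$table$feature)
}

#' Ranked enrichment plot of a screen analysis
#'
#' GREs ranked by log2 target-cell fold-enrichment, with
#' significantly enriched GREs (BH q below the threshold and fold > 1)
#' highlighted.
#'
#' @param x A `pesca_enrichment` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pesca_enrichment <- function(x, ...) {
  tab <- x$table[order(-x$table$log2_fold), ]
  col <- ifelse(!is.na(tab$enriched) & tab$enriched, "dodgerblue3",
                "grey60")
  graphics::plot(seq_len(nrow(tab)), tab$log2_fold, pch = 16, col = col,
                 xlab = "GRE rank", ylab = "log2 fold-enrichment", ...)
  graphics::abline(h = 0, lty = 2, col = "grey40")
  graphics::legend("topright", pch = 16,
                   col = c("dodgerblue3", "grey60"),
                   legend = c(sprintf("q < %g", x$fdr_threshold),
                              "not significant"), bty = "n")
  invisible(x)
}
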