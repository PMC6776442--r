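#' Per-cell normalization of UMI counts
#'
#' Scales each cell's counts to a common library size and (optionally)
#' log-transforms: `log1p = TRUE` gives `ln(1 + count / total * scale)`,
#' the standard log-normalization of droplet single-cell data;
#' `log1p = FALSE` gives linear relative expression
#' (`count / total * scale`), the scale on which ratio-of-means
#' fold-change estimates are consistent. Cell totals are computed over
#' the full column set supplied; cells with zero total are excluded and
#' reported in the `excluded_cells` attribute.
#'
#' @param counts Cell x feature matrix of non-negative counts (sparse
#'   or dense).
#' @param scale Target per-cell total (default 10000).
#' @param log1p Apply `ln(1 + x)` after scaling (default `TRUE`).
#' @return Numeric matrix of normalized expression (zero-total cells
#'   removed), with attribute `excluded_cells`.
#' @export
normalize_expression <- function(counts, scale = 1e4, log1p = TRUE) {
  if (any(counts < 0)) stop_validation("negative counts")
  scale <- assert_positive(scale, "scale")
  totals <- Matrix::rowSums(counts)
  excluded <- rownames(counts)[totals == 0] %||% character(0)
  keep <- totals > 0
  x <- counts[keep, , drop = FALSE] / totals[keep] * scale
  x <- as.matrix(x)
  if (log1p) x <- log1p(x)
  attr(x, "excluded_cells") <- excluded
  x
}

#' Pseudocounted target-cell fold-enrichment per feature
#'
#' For each feature (barcode or GRE), the ratio of its mean expression
#' in target-type cells to its mean expression in all other cells, each
#' mean stabilized by a small pseudocount:
#' `(mean_target + c) / (mean_rest + c)`.
#'
#' @param mat Cell x feature expression matrix (rows must be labelled
#'   cells).
#' @param labels Data frame with columns `cell_barcode`, `cell_type`,
#'   or a named character vector of cell types.
#' @param target Target cell-type name.
#' @param pseudocount Additive constant `c` (default 0.01).
#' @return Data frame with `feature`, `mean_target`, `mean_rest`,
#'   `fold`, `log2_fold`, `n_cells_detected`.
#' @examples
#' m <- matrix(c(0.09, 0.09, 0, 0), 4, 1,
#'             dimnames = list(paste0("c", 1:4), "f1"))
#' lab <- data.frame(cell_barcode = paste0("c", 1:4),
#'                   cell_type = c("Sst", "Sst", "Exc", "Exc"))
#' expression_enrichment(m, lab, "Sst")$fold  # (0.09+0.01)/(0+0.01) = 10
#' @export
expression_enrichment <- function(mat, labels, target,
                                  pseudocount = 0.01) {
  lab <- as_label_vector(labels, rownames(mat))
  if (!target %in% lab)
    stop_validation("no cells labelled as target type '", target, "'")
  if (all(lab == target))
    stop_validation("no non-target cells")
  pseudocount <- assert_positive(pseudocount, "pseudocount")
  is_t <- lab == target
  mean_t <- Matrix::colMeans(mat[is_t, , drop = FALSE])
  mean_r <- Matrix::colMeans(mat[!is_t, , drop = FALSE])
  fold <- (mean_t + pseudocount) / (mean_r + pseudocount)
  data.frame(feature = colnames(mat) %||%
               sprintf("f%04d", seq_along(mean_t)),
             mean_target = as.numeric(mean_t),
             mean_rest = as.numeric(mean_r),
             fold = as.numeric(fold), log2_fold = log2(as.numeric(fold)),
             n_cells_detected = as.numeric(Matrix::colSums(mat > 0)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Accept labels as a data frame (cell_barcode, cell_type) or named
# vector, aligned to the matrix rows.
as_label_vector <- function(labels, cell_ids) {
  if (is.data.frame(labels)) {
    if (!all(c("cell_barcode", "cell_type") %in% names(labels)))
      stop_validation("labels must have columns cell_barcode, cell_type")
    v <- stats::setNames(as.character(labels$cell_type),
                         labels$cell_barcode)
  } else v <- labels
  if (is.null(cell_ids)) {
    if (length(v) == 0) stop_validation("no labels supplied")
    return(unname(v))
  }
  if (!all(cell_ids %in% names(v)))
    stop_validation("labels missing for some cells")
  unname(v[cell_ids])
}

#' Pairwise consistency of barcode-triplet enrichment
#'
#' Arranges per-barcode log2 fold-enrichment values into one vector per
#' barcode slot (each of length = number of GREs, ordered by GRE) and
#' returns every pairwise Pearson correlation between slots, the
#' consistency check that barcodes paired with the same GRE report the
#' same enrichment.
#'
#' @param fold Named numeric vector of per-barcode fold-enrichment
#'   (names are barcode sequences), or the data frame from
#'   [expression_enrichment()] on the barcode-level matrix.
#' @param map A `gre_barcode_map`.
#' @param log2 Correlate `log2(fold)` (default `TRUE`).
#' @return Data frame with one row per slot pair: `slot_i`, `slot_j`,
#'   `r`, `p` (two-sided), `n`. Zero-variance slots give `NA` with a
#'   warning.
#' @export
barcode_consistency <- function(fold, map, log2 = TRUE) {
  M <- slot_matrix(fold, map, log2 = log2)
  k <- ncol(M)
  pairs <- utils::combn(k, 2L)
  out <- data.frame(slot_i = pairs[1L, ], slot_j = pairs[2L, ],
                    r = NA_real_, p = NA_real_, n = nrow(M))
  for (idx in seq_len(ncol(pairs))) {
    a <- M[, pairs[1L, idx]]
    b <- M[, pairs[2L, idx]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("zero-variance slot vector; correlation undefined")
      next
    }
    ct <- stats::cor.test(a, b)
    out$r[idx] <- unname(ct$estimate)
    out$p[idx] <- ct$p.value
  }
  out
}

# GREs x slots matrix of (log2) per-barcode enrichment values.
slot_matrix <- function(fold, map, log2 = TRUE) {
  if (is.data.frame(fold))
    fold <- stats::setNames(fold$fold, fold$feature)
  if (is.null(names(fold)))
    stop_validation("fold must be named by barcode sequence")
  if (!all(map$barcode %in% names(fold)))
    stop_validation("fold values missing for some mapped barcodes")
  slots <- sort(unique(map$slot))
  gres <- unique(map$gre_id)
  per <- table(map$gre_id)
  if (length(unique(per)) != 1L)
    stop_validation("every GRE must have the same number of barcodes")
  M <- matrix(NA_real_, nrow = length(gres), ncol = length(slots),
              dimnames = list(gres, paste0("slot", slots)))
  for (s in seq_along(slots)) {
    sub <- map[map$slot == slots[s], ]
    M[sub$gre_id, s] <- fold[sub$barcode]
  }
  if (log2) M <- base::log2(M)
  M
}

#' Shuffle null for barcode-triplet consistency
#'
#' Permutes the assignment of enrichment values to GRE-by-slot
#' positions uniformly at random and recomputes the mean pairwise
#' Pearson correlation between slots, `n_shuffles` times. Under the
#' null of no GRE-level structure the mean correlation is 0.
#'
#' @inheritParams barcode_consistency
#' @param n_shuffles Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A list with `null_r` (mean pairwise r per shuffle), `mean`,
#'   `sd`, and `n_shuffles`.
#' @export
shuffle_null <- function(fold, map, n_shuffles = 1000L, seed = 1L,
                         log2 = TRUE) {
  M <- slot_matrix(fold, map, log2 = log2)
  n_shuffles <- assert_count(n_shuffles, "n_shuffles")
  vals <- as.vector(M)
  k <- ncol(M)
  pairs <- utils::combn(k, 2L)
  with_seed(seed, {
    null_r <- vapply(seq_len(n_shuffles), function(i) {
      P <- matrix(sample(vals), nrow = nrow(M), ncol = k)
      mean(vapply(seq_len(ncol(pairs)), function(j)
        stats::cor(P[, pairs[1L, j]], P[, pairs[2L, j]]), numeric(1)))
    }, numeric(1))
    list(null_r = null_r, mean = mean(null_r), sd = stats::sd(null_r),
         n_shuffles = n_shuffles)
  })
}

#' Negative-binomial likelihood-ratio test of target-cell enrichment
#'
#' Per feature, fits a negative-binomial GLM with log link and log
#' size-factor offset under the full model
#' `count ~ 1 + is_target` and the reduced model `count ~ 1`, and
#' compares them by likelihood ratio against chi-squared with one
#' degree of freedom. The per-feature dispersion is estimated by
#' maximum likelihood on the full model (method-of-moments fallback;
#' near-Poisson features fall back to a large size), and the reduced
#' model reuses it so the test is nested. P-values are
#' Benjamini-Hochberg corrected across features; features that fail to
#' converge get `p = NA` and are excluded from the BH denominator.
#'
#' @param counts Cell x feature matrix of integer UMI counts.
#' @param labels Cell labels (see [expression_enrichment()]).
#' @param target Target cell-type name.
#' @param size_factors `"total"` (per-cell totals, geometric-mean
#'   centred; default), `"ratio"` (median-of-ratios), or a numeric
#'   vector. Cells with non-positive size factor are dropped.
#' @param fdr_threshold Significance threshold on BH q (default 0.01).
#' @param pseudocount Pseudocount passed to the fold-enrichment
#'   estimate reported alongside the test (default 0.01); the fold is
#'   computed on linear relative expression (see
#'   [normalize_expression()] with `log1p = FALSE`).
#' @param normalize_scale Scale for the relative-expression fold
#'   (default 10000).
#' @return Data frame (one row per feature): `feature`, `mean_target`,
#'   `mean_rest`, `fold`, `log2_fold`, `lrt_stat`, `p`, `q`,
#'   `n_cells_detected`, `enriched` (q below threshold and fold > 1).
#' @export
nb_lrt_test <- function(counts, labels, target, size_factors = "total",
                        fdr_threshold = 0.01, pseudocount = 0.01,
                        normalize_scale = 1e4) {
  if (any(counts < 0)) stop_validation("negative counts")
  dense <- as.matrix(counts)
  if (any(dense != floor(dense)))
    stop_validation("counts must be integers")
  lab <- as_label_vector(labels, rownames(dense))
  if (!target %in% lab)
    stop_validation("no cells labelled as target type '", target, "'")

  sf <- compute_size_factors(dense, size_factors)
  keep <- sf > 0 & !is.na(sf)
  dense <- dense[keep, , drop = FALSE]
  lab <- lab[keep]
  sf <- sf[keep]
  is_t <- lab == target
  res <- vapply(seq_len(ncol(dense)), function(j) {
    nb_lrt_one(dense[, j], is_t, sf)
  }, numeric(2))
  lrt_stat <- res[1L, ]
  p <- res[2L, ]
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")

  rel <- normalize_expression(counts, scale = normalize_scale,
                              log1p = FALSE)
  enr <- expression_enrichment(rel,
                               labels_subset(labels, rownames(rel)),
                               target, pseudocount)
  out <- enr[match(colnames(dense), enr$feature), , drop = FALSE]
  out$lrt_stat <- lrt_stat
  out$p <- p
  out$q <- q
  out$enriched <- !is.na(q) & q < fdr_threshold & out$fold > 1
  rownames(out) <- NULL
  out
}

labels_subset <- function(labels, cell_ids) {
  if (is.data.frame(labels))
    labels[labels$cell_barcode %in% cell_ids, , drop = FALSE]
  else labels[names(labels) %in% cell_ids]
}

compute_size_factors <- function(counts, size_factors) {
  if (is.numeric(size_factors)) {
    if (length(size_factors) != nrow(counts))
      stop_validation("size_factors length != cell count")
    return(size_factors)
  }
  totals <- rowSums(counts)
  if (identical(size_factors, "total")) {
    pos <- totals > 0
    gm <- exp(mean(log(totals[pos])))
    return(totals / gm)
  }
  if (identical(size_factors, "ratio")) {
    # median-of-ratios over features with positive geometric mean
    logc <- log(counts)
    logc[!is.finite(logc)] <- NA
    ref <- colMeans(logc, na.rm = TRUE)
    use <- is.finite(ref)
    sf <- apply(counts[, use, drop = FALSE], 1L, function(y) {
      r <- log(y[y > 0]) - ref[use][y > 0]
      if (length(r) == 0) return(0)
      exp(stats::median(r))
    })
    return(sf)
  }
  stop_validation("size_factors must be 'total', 'ratio', or numeric")
}

# ML of the scalar group mean m in mu_i = s_i * m for fixed NB size
# theta. The score equation sum(y)/m = sum((y + theta) s / (theta + s m))
# is solved by fixed-point iteration from the Poisson closed form
# m0 = sum(y) / sum(s). Returns NA on non-convergence.
nb_fit_mean <- function(y, s, theta, iter = 100L, tol = 1e-9) {
  sy <- sum(y)
  if (sy == 0) return(0)
  m <- sy / sum(s)
  if (!is.finite(theta) || theta >= 1e8) return(m)  # Poisson limit: exact
  for (i in seq_len(iter)) {
    m_new <- sy / sum((y + theta) * s / (theta + s * m))
    if (abs(m_new - m) <= tol * m) return(m_new)
    m <- m_new
  }
  NA_real_
}

# LRT for one feature; returns c(stat, p). All-zero features carry no
# information (p = 1); non-convergence returns NA. Dispersion is the
# per-feature profile ML given the full-model means (MoM fallback),
# shared by the reduced model so the models are nested.
nb_lrt_one <- function(y, is_t, s) {
  if (all(y == 0)) return(c(0, 1))
  fit <- tryCatch({
    yt <- y[is_t]; st <- s[is_t]
    yr <- y[!is_t]; sr <- s[!is_t]
    mu_of <- function(mt, mr) {
      mu <- numeric(length(y))
      mu[is_t] <- st * mt
      mu[!is_t] <- sr * mr
      mu
    }
    # Poisson start, then two rounds of (theta | mu), (mu | theta)
    mt <- sum(yt) / sum(st)
    mr <- sum(yr) / sum(sr)
    theta <- NA_real_
    for (round in 1:2) {
      theta <- est_theta(y, mu_of(mt, mr))
      mt <- nb_fit_mean(yt, st, theta)
      mr <- nb_fit_mean(yr, sr, theta)
      if (is.na(mt) || is.na(mr)) return(c(NA_real_, NA_real_))
    }
    m0 <- nb_fit_mean(y, s, theta)
    if (is.na(m0)) return(c(NA_real_, NA_real_))
    ll_f <- sum(stats::dnbinom(y, size = theta, mu = mu_of(mt, mr),
                               log = TRUE))
    ll_r <- sum(stats::dnbinom(y, size = theta, mu = s * m0,
                               log = TRUE))
    stat <- max(0, 2 * (ll_f - ll_r))
    c(stat, stats::pchisq(stat, df = 1L, lower.tail = FALSE))
  }, error = function(e) c(NA_real_, NA_real_))
  fit
}

# Per-feature NB size (theta) by profile ML given fitted means
# (1-D likelihood maximization over log theta); falls back to method
# of moments, then to a large size (Poisson limit) when not
# overdispersed.
est_theta <- function(y, mu, max_theta = 1e8) {
  mom <- {
    num <- sum(mu^2)
    den <- sum((y - mu)^2 - mu)
    if (den > 0) num / den else max_theta
  }
  th <- tryCatch({
    nll <- function(lt) -sum(stats::dnbinom(y, size = exp(lt), mu = mu,
                                            log = TRUE))
    opt <- stats::optimize(nll, c(log(1e-3), log(max_theta)))
    # boundary solutions mean no interior optimum; use the limit
    if (opt$minimum >= log(max_theta) - 1e-3) max_theta
    else exp(opt$minimum)
  }, error = function(e) mom)
  if (!is.finite(th) || th <= 0) th <- mom
  min(th, max_theta)
}

#' Binomial-thinning power analysis
#'
#' Emulates reduced sequencing depth by replacing every count `c` with
#' a `Binomial(c, p)` draw and rerunning the enrichment test, for each
#' thinning probability and replicate. Reports per-feature q-values and
#' folds per (probability, replicate), plus the detection rate
#' (fraction of replicates with q below threshold).
#'
#' @inheritParams nb_lrt_test
#' @param probabilities Thinning probabilities in (0, 1]
#'   (default `c(0.5, 0.25, 0.125, 0.0625)`).
#' @param replicates Replicates per probability (default 10).
#' @param seed Integer seed.
#' @return A list of class `pesca_subsample`: `report` (long data
#'   frame: `feature`, `probability`, `replicate`, `fold`, `q`,
#'   `detected`), `detection` (feature x probability detection-rate
#'   matrix) and `totals` (total thinned counts per probability and
#'   replicate, a direct check of the thinning mean).
#' @export
subsample_power <- function(counts, labels, target,
                            probabilities = c(0.5, 0.25, 0.125, 0.0625),
                            replicates = 10L, seed = 1L,
                            fdr_threshold = 0.01,
                            size_factors = "total") {
  for (p in probabilities)
    assert_fraction(p, "probabilities", lo = 0, hi = 1)
  replicates <- assert_count(replicates, "replicates")
  dense <- as.matrix(counts)
  if (any(dense < 0) || any(dense != floor(dense)))
    stop_validation("counts must be non-negative integers")
  rows <- list()
  totals_list <- list()
  for (pi in seq_along(probabilities)) {
    p <- probabilities[pi]
    for (rep_i in seq_len(replicates)) {
      thinned <- with_seed(derive_seed(seed, pi * 1000L + rep_i), {
        m <- dense
        m[] <- stats::rbinom(length(m), size = as.integer(m), prob = p)
        m
      })
      dimnames(thinned) <- dimnames(dense)
      tab <- nb_lrt_test(thinned, labels, target,
                         size_factors = size_factors,
                         fdr_threshold = fdr_threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = tab$feature, probability = p, replicate = rep_i,
        fold = tab$fold, q = tab$q,
        detected = !is.na(tab$q) & tab$q < fdr_threshold,
        stringsAsFactors = FALSE)
      totals_list[[length(totals_list) + 1L]] <- data.frame(
        probability = p, replicate = rep_i,
        total_counts = sum(thinned))
    }
  }
  report <- do.call(rbind, rows)
  totals <- do.call(rbind, totals_list)
  det <- tapply(report$detected,
                list(report$feature, report$probability), mean)
  structure(list(report = report, detection = det, totals = totals,
                 probabilities = probabilities, replicates = replicates,
                 fdr_threshold = fdr_threshold),
            class = "pesca_subsample")
}

#' @export
print.pesca_subsample <- function(x, ...) {
  cat(sprintf(paste0(
    "pesca_subsample: %d features x %d probabilities x %d replicates\n",
    "  mean detection rate (q < %g) by thinning probability:\n"),
    nrow(x$detection), length(x$probabilities), x$replicates,
    x$fdr_threshold))
  print(round(colMeans(x$detection, na.rm = TRUE), 3))
  invisible(x)
}
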