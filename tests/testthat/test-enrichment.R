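lab_df <- function(ids, types) {
  data.frame(cell_barcode = ids, cell_type = types,
             stringsAsFactors = FALSE)
}

test_that("expression normalization matches the direct formula", {
  set.seed(71)
  m <- matrix(rpois(200, 2), 20, 10,
              dimnames = list(sprintf("c%02d", 1:20),
                              sprintf("f%02d", 1:10)))
  m[3, ] <- 0  # zero-total cell
  x <- normalize_expression(m, scale = 1e4)
  expect_identical(attr(x, "excluded_cells"), "c03")
  keep <- rownames(m)[rowSums(m) > 0]
  ref <- log(1 + m[keep, ] / rowSums(m)[keep] * 1e4)
  expect_equal(x, ref, ignore_attr = TRUE)
  expect_true(all(x[m[keep, ] == 0] == 0))
  lin <- normalize_expression(m, scale = 1e4, log1p = FALSE)
  expect_equal(lin, m[keep, ] / rowSums(m)[keep] * 1e4,
               ignore_attr = TRUE)
  expect_error(normalize_expression(m - 5),
               class = "pesca_validation_error")
})

test_that("fold-enrichment implements the pseudocounted ratio of means", {
  m <- matrix(c(0.09, 0.09, 0, 0), 4, 1,
              dimnames = list(paste0("c", 1:4), "f1"))
  lab <- lab_df(paste0("c", 1:4), c("Sst", "Sst", "Exc", "Exc"))
  out <- expression_enrichment(m, lab, "Sst")
  expect_equal(out$fold, 10)
  expect_equal(out$log2_fold, log2(10))
  # identical means give exactly 1
  m2 <- matrix(c(3, 3, 3, 3), 4, 1,
               dimnames = list(paste0("c", 1:4), "f1"))
  expect_equal(expression_enrichment(m2, lab, "Sst")$fold, 1)
  expect_error(expression_enrichment(m, lab, "Npy"),
               class = "pesca_validation_error")
  # matches direct evaluation on random data
  set.seed(72)
  r <- matrix(runif(60), 12, 5,
              dimnames = list(paste0("c", 1:12), paste0("f", 1:5)))
  labs <- lab_df(paste0("c", 1:12), rep(c("Sst", "Exc", "Pv"), 4))
  got <- expression_enrichment(r, labs, "Sst", pseudocount = 0.01)
  is_t <- labs$cell_type == "Sst"
  ref <- (colMeans(r[is_t, ]) + 0.01) / (colMeans(r[!is_t, ]) + 0.01)
  expect_equal(got$fold, unname(ref))
})

test_that("barcode consistency equals the textbook Pearson formula", {
  set.seed(73)
  g <- 30
  map <- data.frame(gre_id = rep(sprintf("g%02d", 1:g), each = 3),
                    slot = rep(1:3, g),
                    barcode = random_dna(3 * g, 10))
  base <- runif(g, 0.5, 8)
  fold <- rep(base, each = 3) * exp(rnorm(3 * g, 0, 0.2))
  names(fold) <- map$barcode
  cons <- barcode_consistency(fold, map)
  expect_identical(nrow(cons), 3L)
  M <- sapply(1:3, function(s)
    log2(fold[map$barcode[map$slot == s]]))
  expect_equal(cons$r[1], oracle_pearson(M[, 1], M[, 2]))
  expect_equal(cons$r[3], oracle_pearson(M[, 2], M[, 3]))
  expect_equal(cons$p[1], cor.test(M[, 1], M[, 2])$p.value)
  # identical vectors give r = 1; a negated pair gives r = -1
  f2 <- rep(base, each = 3)
  names(f2) <- map$barcode
  expect_equal(barcode_consistency(f2, map)$r, rep(1, 3))
  M3 <- cbind(base, -base + 2 * mean(base))
  expect_equal(oracle_pearson(M3[, 1], M3[, 2]), -1)
})

test_that("zero-variance slots are reported as undefined", {
  map <- data.frame(gre_id = rep(c("g1", "g2"), each = 2),
                    slot = rep(1:2, 2),
                    barcode = c("AAAA", "CCCC", "GGGG", "TTTT"))
  fold <- c(AAAA = 1, CCCC = 2, GGGG = 1, TTTT = 3)
  expect_warning(cons <- barcode_consistency(fold, map), "zero-variance")
  expect_true(is.na(cons$r[1]))
})

test_that("the shuffle null is centred at zero with the expected spread", {
  scr <- tiny_screen(n_gres = 100, n_cells = 4000, seed = 75,
                     true_fold = stats::setNames(
                       rep(c(4, 6, 8, 10), 5), sprintf("GRE%03d", 1:20)))
  rel <- normalize_expression(scr$true_counts, log1p = FALSE)
  lab <- scr$labels[scr$labels$cell_barcode %in% rownames(rel), ]
  enr <- expression_enrichment(rel, lab, "Sst")
  null <- shuffle_null(enr, scr$map, n_shuffles = 1000, seed = 9)
  expect_lt(abs(null$mean), 0.02)
  # observed consistency exceeds the null's 99th percentile
  obs <- mean(barcode_consistency(enr, scr$map)$r)
  expect_gt(obs, quantile(null$null_r, 0.99))
  # spread of a single-pair null matches ~1/sqrt(G - 1)
  map2 <- scr$map[scr$map$slot <= 2, ]
  null2 <- shuffle_null(enr, map2, n_shuffles = 1000, seed = 10)
  expect_lt(abs(null2$sd - 1 / sqrt(99)) / (1 / sqrt(99)), 0.25)
  # reproducible under seed
  null_b <- shuffle_null(enr, scr$map, n_shuffles = 50, seed = 9)
  expect_identical(null_b$null_r[1:50], null$null_r[1:50])
})

test_that("the NB LRT statistic matches a brute-force likelihood search", {
  y <- c(3, 4, 5, 0, 1, 0, 2, 0, 1, 0)
  is_t <- c(TRUE, TRUE, TRUE, rep(FALSE, 7))
  sf <- c(1, 1.2, 0.8, 1, 1, 1.1, 0.9, 1, 1.3, 0.7)
  m <- matrix(y, ncol = 1, dimnames = list(paste0("c", 1:10), "f1"))
  lab <- lab_df(paste0("c", 1:10), ifelse(is_t, "Sst", "Exc"))
  tab <- nb_lrt_test(m, lab, "Sst", size_factors = sf)
  ref <- oracle_nb_lrt(y, is_t, sf)
  expect_equal(tab$lrt_stat, ref, tolerance = 1e-3)
  expect_equal(tab$p, pchisq(ref, 1, lower.tail = FALSE),
               tolerance = 1e-3)
})

test_that("degenerate features are handled: all-zero gives p = 1", {
  m <- cbind(f1 = rep(0L, 8), f2 = c(5L, 6L, 0L, 1L, 0L, 2L, 1L, 0L))
  rownames(m) <- paste0("c", 1:8)
  lab <- lab_df(paste0("c", 1:8), rep(c("Sst", "Exc"), each = 4))
  tab <- nb_lrt_test(m, lab, "Sst")
  expect_equal(tab$p[tab$feature == "f1"], 1)
  expect_false(tab$enriched[tab$feature == "f1"])
  expect_error(nb_lrt_test(m + 0.5, lab, "Sst"),
               class = "pesca_validation_error")
})

test_that("permuted labels give calibrated type-I error and uniform p", {
  scr <- tiny_screen(n_cells = 1500, n_gres = 287, seed = 77)
  gre <- aggregate_gre(scr$true_counts, scr$map)
  fracs <- numeric(5)
  ps <- c()
  for (s in 1:5) {
    set.seed(100 + s)
    lab <- scr$labels
    lab$cell_type <- sample(lab$cell_type)
    tab <- nb_lrt_test(gre, lab, "Sst")
    fracs[s] <- mean(tab$p < 0.05, na.rm = TRUE)
    ps <- c(ps, tab$p)
  }
  # one 287-feature permutation has binomial sd ~0.013 on the fraction,
  # so the 0.05 +/- 0.02 calibration band is asserted on the mean of 5
  expect_gte(mean(fracs), 0.03)
  expect_lte(mean(fracs), 0.07)
  expect_gt(ks.test(ps, "punif")$p.value, 1e-3)
})

test_that("BH adjustment is monotone and bounded below by p", {
  scr <- tiny_screen(n_gres = 40, n_cells = 800, seed = 79,
                     true_fold = c(GRE005 = 8))
  gre <- aggregate_gre(scr$true_counts, scr$map)
  tab <- nb_lrt_test(gre, scr$labels, "Sst")
  ok <- !is.na(tab$p)
  expect_true(all(tab$q[ok] >= tab$p[ok]))
  ord <- order(tab$p[ok])
  expect_true(all(diff(tab$q[ok][ord]) >= -1e-12))
  expect_equal(tab$q[ok], p.adjust(tab$p[ok], "BH"))
})

test_that("estimated fold is monotone in the generated true fold", {
  folds <- c(1, 2, 4, 8)
  est <- matrix(NA_real_, 3, length(folds))
  for (s in 1:3) for (k in seq_along(folds)) {
    tr <- screen_truth(seed = 300 + 10 * s + k,
                       true_fold = c(GRE050 = folds[k]))
    scr <- simulate_screen(tr, 10000)
    gre <- aggregate_gre(scr$true_counts, scr$map)
    rel <- normalize_expression(gre, log1p = FALSE)
    lab <- scr$labels[scr$labels$cell_barcode %in% rownames(rel), ]
    enr <- expression_enrichment(rel, lab, "Sst")
    est[s, k] <- enr$fold[enr$feature == "GRE050"]
  }
  expect_true(all(diff(colMeans(est)) > 0))
  expect_lt(abs(colMeans(est)[1] - 1), 0.2)
})

test_that("binomial thinning: identity at p = 1, mean scaling, monotone power", {
  scr <- tiny_screen(n_gres = 30, n_cells = 1200, seed = 81,
                     true_fold = c(GRE003 = 8, GRE011 = 8))
  gre <- as.matrix(aggregate_gre(scr$true_counts, scr$map))
  tab0 <- nb_lrt_test(gre, scr$labels, "Sst")
  sub1 <- subsample_power(gre, scr$labels, "Sst", probabilities = 1,
                          replicates = 1, seed = 5)
  expect_equal(stats::setNames(sub1$report$q, sub1$report$feature),
               stats::setNames(tab0$q, tab0$feature))
  # thinned totals stay within 3 binomial sd of p * total
  p <- 0.25
  sub2 <- subsample_power(gre, scr$labels, "Sst", probabilities = p,
                          replicates = 3, seed = 7)
  tot <- sum(gre)
  expect_true(all(abs(sub2$totals$total_counts - p * tot)
                  <= 3 * sqrt(tot * p * (1 - p))))
  # detection of true hits is non-increasing as thinning gets severe
  sub <- subsample_power(gre, scr$labels, "Sst",
                         probabilities = c(1, 0.25, 0.0625, 0.015625),
                         replicates = 4, seed = 11)
  det <- sub$detection[c("GRE003", "GRE011"),
                       c("1", "0.25", "0.0625", "0.015625")]
  for (g in 1:2) expect_true(all(diff(as.numeric(det[g, ])) <= 1e-9))
  expect_error(subsample_power(gre, scr$labels, "Sst",
                               probabilities = 1.5),
               class = "pesca_validation_error")
})
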