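policy_set <- function() {
  # distance-3 set built once for the policy tests
  design_barcodes(10, 3, n_required = 40, seed = 13)
}

test_that("barcode matching applies the mismatch/uniqueness policy", {
  bs <- policy_set()
  b1 <- bs$barcodes[1]
  # exact match
  expect_identical(match_barcode(b1, bs)$status, "assigned")
  expect_identical(match_barcode(b1, bs)$barcode, b1)
  # one substitution anywhere still assigns to the same barcode unless a
  # second barcode sits within the uniqueness radius
  for (pos in c(1L, 5L, 10L)) {
    mutated <- b1
    substr(mutated, pos, pos) <- chartr("ACGT", "CAAA",
                                        substr(b1, pos, pos))
    m <- match_barcode(mutated, bs)
    expect_true(m$status %in% c("assigned", "ambiguous"))
    if (m$status == "assigned") expect_identical(m$barcode, b1)
    expect_identical(m$distance, 1L)
  }
  # two substitutions: never assigned under max_mismatch = 1
  mutated <- b1
  substr(mutated, 1, 2) <- chartr("ACGT", "CAAA", substr(b1, 1, 2))
  expect_true(match_barcode(mutated, bs)$status
              %in% c("ambiguous", "unassigned"))
  expect_error(match_barcode("ACGT", bs),
               class = "pesca_validation_error")
  expect_error(match_barcode(b1, bs, max_mismatch = 3,
                             uniqueness_radius = 2),
               class = "pesca_validation_error")
})

test_that("a midpoint between two barcodes is ambiguous", {
  # construct two barcodes at Hamming distance 4 and a sequence at
  # distance 2 from both
  a <- "AAAAAAAAAA"
  b <- "CCCCAAAAAA"
  mid <- "CCAAAAAAAA"  # Hamming 2 to both
  bs <- barcode_set(c(a, b), min_distance = 3)
  m <- match_barcode(mid, bs, max_mismatch = 1, uniqueness_radius = 2)
  expect_identical(m$status, "ambiguous")
})

test_that("one-mismatch assignment is verified by an exhaustive scan", {
  bs <- policy_set()
  set.seed(14)
  for (i in sample(seq_along(bs$barcodes), 5)) {
    b <- bs$barcodes[i]
    mutated <- b
    substr(mutated, 4, 4) <- chartr("ACGT", "GGTC", substr(b, 4, 4))
    d <- sapply(bs$barcodes,
                function(x) sum(strsplit(x, "")[[1]] !=
                                  strsplit(mutated, "")[[1]]))
    m <- match_barcode(mutated, bs)
    if (sum(d <= 2) == 1) {
      expect_identical(m$status, "assigned")
      expect_identical(m$barcode, b)
    } else {
      expect_identical(m$status, "ambiguous")
    }
  }
})

test_that("UMI deduplication collapses on the (cell, umi, barcode) key", {
  bs <- barcode_set(c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG"))
  reads <- data.frame(
    cell_barcode = c("c1", "c1", "c1", "c1", "c2"),
    umi = c("u1", "u1", "u1", "u2", "u1"),
    sequence = c("AAAAAAAAAA", "AAAAAAAAAA", "CCCCCCCCCC",
                 "AAAAAAAAAA", "AAAAAAAAAA"))
  res <- count_umis(reads, bs)
  expect_identical(sum(res$counts), 4)  # u1 dup collapsed
  expect_identical(unname(res$counts["c1", "AAAAAAAAAA"]), 2)
  # same cell+umi but different barcode: two distinct molecules
  expect_identical(unname(res$counts["c1", "CCCCCCCCCC"]), 1)
  expect_identical(res$qc$n_molecules, 4L)
})

test_that("empty and malformed inputs are handled", {
  bs <- barcode_set(c("AAAAAAAAAA", "CCCCCCCCCC"))
  expect_warning(res <- count_umis(
    data.frame(cell_barcode = character(0), umi = character(0),
               sequence = character(0)), bs), "empty")
  expect_identical(dim(res$counts), c(0L, 2L))
  expect_error(count_umis(data.frame(x = 1), bs),
               class = "pesca_validation_error")
})

test_that("flank trimming and length rejection are counted in QC", {
  bs <- barcode_set(c("AAAAAAAAAA", "CCCCCCCCCC"))
  reads <- data.frame(cell_barcode = c("c1", "c1", "c2"),
                      umi = c("u1", "u2", "u3"),
                      sequence = c("GGAAAAAAAAAATT", "GGCCCCCCCCCCTT",
                                   "GGAAAAAAAATT"))
  res <- count_umis(reads, bs, prefix = "GG", suffix = "TT")
  expect_identical(sum(res$counts), 2)
  expect_identical(res$qc$n_rejected, 1L)
})

test_that("cell whitelist restricts and reports dropped reads", {
  scr <- tiny_screen(n_gres = 10, n_cells = 50, seed = 51)
  wl <- unique(scr$reads$cell_barcode)[1:10]
  res <- count_umis(scr$reads, scr$barcode_set, cell_whitelist = wl)
  expect_true(all(rownames(res$counts) %in% wl))
  expect_identical(res$qc$n_off_whitelist,
                   sum(!scr$reads$cell_barcode %in% wl))
})

test_that("error-free simulation round-trips exactly through deconvolution", {
  scr <- tiny_screen(n_gres = 30, n_cells = 500, seed = 53)
  res <- count_umis(scr$reads, scr$barcode_set)
  truth <- scr$true_counts[Matrix::rowSums(scr$true_counts) > 0, ,
                           drop = FALSE]
  expect_identical(dim(res$counts), dim(truth))
  expect_true(all(res$counts[rownames(truth), colnames(truth)] == truth))
  expect_identical(res$qc$n_ambiguous + res$qc$n_unassigned, 0L)
})

test_that("raising max_mismatch never decreases assigned reads", {
  tr <- screen_truth(n_gres = 25, seed = 57, barcode_error_rate = 0.05)
  scr <- simulate_screen(tr, 300)
  a0 <- count_umis(scr$reads, scr$barcode_set, max_mismatch = 0,
                   uniqueness_radius = 2)$qc$n_assigned
  a1 <- count_umis(scr$reads, scr$barcode_set, max_mismatch = 1,
                   uniqueness_radius = 2)$qc$n_assigned
  a2 <- count_umis(scr$reads, scr$barcode_set, max_mismatch = 2,
                   uniqueness_radius = 2)$qc$n_assigned
  expect_lte(a0, a1)
  expect_lte(a1, a2)
})

test_that("mis-assignment stays below 1% at the error-rate bound", {
  # error rate at (min_dist - 1) / (2 L) = 0.1 per base
  mis <- sapply(1:5, function(s) {
    tr <- screen_truth(n_gres = 50, seed = s, barcode_error_rate = 0.1)
    scr <- simulate_screen(tr, 400)
    res <- count_umis(scr$reads, scr$barcode_set)
    tc <- scr$true_counts[rownames(res$counts), colnames(res$counts)]
    sum(pmax(res$counts - tc, 0)) / sum(res$counts)
  })
  expect_true(all(mis < 0.01))
})

test_that("GRE aggregation sums barcode columns and conserves counts", {
  bs <- barcode_set(c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG",
                      "TTTTTTTTTT", "AACCGGTTAA", "GGTTAACCGG"))
  map <- data.frame(gre_id = rep(c("g1", "g2"), each = 3),
                    slot = rep(1:3, 2), barcode = bs$barcodes)
  m <- matrix(c(2, 0, 1, 0, 0, 0,
                0, 0, 0, 0, 0, 0,
                1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("c1", "c2", "c3"), bs$barcodes))
  g <- aggregate_gre(m, map)
  expect_equal(unname(g["c1", "g1"]), 3)
  expect_equal(unname(as.matrix(g)["c2", ]), c(g1 = 0, g2 = 0),
               ignore_attr = TRUE)
  expect_equal(sum(g), sum(m))
  # random matrices conserve totals
  scr <- tiny_screen(n_gres = 15, n_cells = 200, seed = 59)
  res <- count_umis(scr$reads, scr$barcode_set)
  g2 <- aggregate_gre(res$counts, scr$map)
  expect_equal(sum(g2), sum(res$counts))
  bc_tot <- Matrix::colSums(res$counts)
  gre_tot <- tapply(bc_tot[scr$map$barcode], scr$map$gre_id, sum)
  expect_equal(unname(Matrix::colSums(g2)[names(gre_tot)]),
               unname(as.numeric(gre_tot)))
})

test_that("unmapped barcode columns are dropped with a warning", {
  bs <- barcode_set(c("AAAAAAAAAA", "CCCCCCCCCC"))
  map <- data.frame(gre_id = "g1", slot = 1, barcode = "AAAAAAAAAA")
  m <- matrix(1:4, 2, dimnames = list(c("c1", "c2"), bs$barcodes))
  expect_warning(g <- aggregate_gre(m, map), "dropped")
  expect_identical(colnames(g), "g1")
  expect_equal(sum(g), sum(m[, "AAAAAAAAAA"]))
})

test_that("library complexity reports detection fractions", {
  scr <- tiny_screen(n_gres = 20, n_cells = 400, seed = 61)
  res <- count_umis(scr$reads, scr$barcode_set)
  rep <- library_complexity(res$counts, scr$barcode_set, scr$map)
  nz <- sum(Matrix::colSums(res$counts) > 0)
  expect_identical(rep$n_barcodes_detected, nz)
  expect_equal(rep$frac_barcodes_detected, nz / 60)
  # zero out half the barcodes
  half <- res$counts
  half[, 1:30] <- 0
  rep2 <- library_complexity(half, scr$barcode_set, scr$map)
  expect_equal(rep2$frac_barcodes_detected,
               sum(Matrix::colSums(half) > 0) / 60)
  full <- matrix(1, 2, 60, dimnames = list(c("a", "b"),
                                           scr$barcode_set$barcodes))
  rep3 <- library_complexity(full, scr$barcode_set, scr$map)
  expect_equal(rep3$frac_barcodes_detected, 1)
  expect_equal(rep3$frac_gres_detected, 1)
})
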