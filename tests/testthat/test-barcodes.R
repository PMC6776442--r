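test_that("edit distance matches hand-worked examples", {
  expect_identical(edit_distance("ACGTACGTAC", "ACGTACGTAC"), 0L)
  expect_identical(edit_distance("ACGT", "AGGT"), 1L)
  # one deletion + frame shift: seqlev forgives the boundary overhang
  expect_identical(edit_distance("AACGTACGTA", "ACGTACGTAC"), 2L)
  expect_identical(edit_distance("AACGTACGTA", "ACGTACGTAC",
                                 metric = "sequence_levenshtein"), 1L)
  expect_error(edit_distance("ACGN", "ACGT"), class = "pesca_validation_error")
})

test_that("both metrics agree with recursive oracles on random pairs", {
  set.seed(11)
  for (len in c(4L, 7L)) {
    a <- random_dna(100, len)
    b <- random_dna(100, len)
    expect_equal(edit_distance(a, b),
                     mapply(oracle_lev, a, b, USE.NAMES = FALSE))
    expect_equal(edit_distance(a, b, metric = "sequence_levenshtein"),
                     mapply(oracle_seqlev, a, b, USE.NAMES = FALSE))
  }
})

test_that("metric axioms hold and seqlev is bounded by levenshtein", {
  set.seed(12)
  a <- random_dna(60, 8)
  b <- random_dna(60, 8)
  c_ <- random_dna(60, 8)
  dab <- edit_distance(a, b)
  expect_identical(dab, edit_distance(b, a))
  expect_true(all(edit_distance(a, a) == 0L))
  expect_true(all(dab + edit_distance(b, c_) >= edit_distance(a, c_)))
  expect_true(all(edit_distance(a, b, metric = "sequence_levenshtein")
                  <= dab))
})

test_that("greedy design equals an exhaustive greedy oracle on 4-mers", {
  all4 <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 4),
                                      stringsAsFactors = FALSE))
  set.seed(5)
  cand <- sample(all4)
  got <- tryCatch(
    design_barcodes(4, 3, n_required = 10000, candidates = cand),
    pesca_capacity_error = function(e) e)
  expect_s3_class(got, "pesca_capacity_error")
  # oracle: same scan order, recursive-oracle distances
  accepted <- character(0)
  for (x in cand) {
    if (all(vapply(accepted, function(y) oracle_lev(x, y), numeric(1))
            >= 3))
      accepted <- c(accepted, x)
  }
  # the capacity error reports the achieved count; rebuild the set with
  # the oracle size to compare membership
  got_set <- design_barcodes(4, 3, n_required = length(accepted),
                             candidates = cand)
  expect_identical(got_set$barcodes, accepted)
})

test_that("impossible constraints raise a capacity error", {
  expect_error(design_barcodes(2, 5, n_required = 2, seed = 1),
               class = "pesca_capacity_error")
  err <- tryCatch(design_barcodes(2, 5, n_required = 2, seed = 1),
                  error = function(e) e)
  expect_match(conditionMessage(err), "1 of 2")
})

test_that("designed sets pass exhaustive validation for both metrics", {
  for (metric in c("levenshtein", "sequence_levenshtein")) {
    bs <- design_barcodes(7, 3, n_required = 60, metric = metric,
                          seed = 3)
    expect_gte(length(bs), 60)
    rep <- validate_barcode_set(bs)
    expect_true(rep$valid)
    expect_identical(nrow(rep$violations), 0L)
  }
})

test_that("validation pinpoints a planted near-duplicate", {
  bs <- design_barcodes(8, 3, n_required = 30, seed = 9)
  b1 <- bs$barcodes[1]
  planted <- paste0(chartr("ACGT", "CAAA", substr(b1, 1, 1)),
                    substr(b1, 2, nchar(b1)))
  bad <- barcode_set(c(bs$barcodes, planted), min_distance = 3)
  rep <- validate_barcode_set(bad)
  expect_false(rep$valid)
  expect_identical(nrow(rep$violations), 1L)
  expect_setequal(unlist(rep$violations[1, 1:2]),
                  c(bs$barcodes[1], planted))
  expect_identical(rep$violations$distance, 1L)
})

test_that("validation report agrees with oracle pair enumeration", {
  set.seed(21)
  bcs <- unique(random_dna(25, 4))
  set <- barcode_set(bcs, min_distance = 3)
  rep <- validate_barcode_set(set)
  n_bad <- 0L
  for (i in seq_along(bcs)) for (j in seq_along(bcs)) {
    if (i < j && oracle_lev(bcs[i], bcs[j]) < 3) n_bad <- n_bad + 1L
  }
  expect_identical(nrow(rep$violations), n_bad)
})

test_that("barcode assignment gives each GRE its own barcodes", {
  bs <- design_barcodes(8, 3, n_required = 40, seed = 2)
  map <- assign_barcodes(paste0("GRE", 1:12), bs, per_gre = 3, seed = 4)
  expect_identical(nrow(map), 36L)
  expect_true(all(table(map$gre_id) == 3))
  expect_false(anyDuplicated(map$barcode) > 0)
  expect_true(all(map$barcode %in% bs$barcodes))
  one <- assign_barcodes("GRE1", bs, per_gre = 1, seed = 1)
  expect_identical(nrow(one), 1L)
  expect_error(assign_barcodes(paste0("G", 1:20), bs, per_gre = 3),
               class = "pesca_capacity_error")
})

test_that("design and assignment are reproducible under a seed", {
  a <- design_barcodes(8, 3, n_required = 30, seed = 7)
  b <- design_barcodes(8, 3, n_required = 30, seed = 7)
  expect_identical(a$barcodes, b$barcodes)
  expect_false(identical(
    a$barcodes, design_barcodes(8, 3, n_required = 30, seed = 8)$barcodes))
  m1 <- assign_barcodes(paste0("G", 1:5), a, seed = 3)
  m2 <- assign_barcodes(paste0("G", 1:5), a, seed = 3)
  expect_identical(m1, m2)
})

test_that("barcode sets round-trip through TSV and FASTA", {
  bs <- design_barcodes(6, 3, n_required = 15, seed = 1,
                        metric = "sequence_levenshtein")
  tsv <- tempfile(fileext = ".tsv")
  write_barcodes_tsv(bs, tsv)
  back <- read_barcodes_tsv(tsv)
  expect_identical(back$barcodes, bs$barcodes)
  expect_identical(back$metric, "sequence_levenshtein")
  fa <- tempfile(fileext = ".fasta")
  write_barcodes_fasta(bs, fa)
  expect_identical(read_barcodes_fasta(fa)$barcodes, bs$barcodes)
})
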