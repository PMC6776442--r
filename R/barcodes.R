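#' Edit distance between DNA barcodes
#'
#' Computes the unit-cost Levenshtein distance (insertions, deletions,
#' substitutions) or the sequence-Levenshtein distance between pairs of
#' DNA sequences. The sequence-Levenshtein variant minimises over the
#' final row and column of the dynamic-programming table, which models
#' fixed-length reads where an indel shifts the read frame at the
#' sequence end; it is never larger than the plain Levenshtein distance.
#'
#' @param a,b Character vectors of DNA sequences (A/C/G/T only).
#'   Recycled to a common length.
#' @param metric `"levenshtein"` (default) or `"sequence_levenshtein"`.
#' @return Integer vector of distances.
#' @examples
#' edit_distance("ACGT", "AGGT")                      # 1
#' edit_distance("AACGTACGTA", "ACGTACGTAC")          # shifted frame
#' @export
edit_distance <- function(a, b,
                          metric = c("levenshtein", "sequence_levenshtein")) {
  metric <- match.arg(metric)
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  check_dna(c(a, b))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  edit_dist_cpp(a, b, metric_code(metric))
}

metric_code <- function(metric) {
  if (identical(metric, "levenshtein")) 0L else 1L
}

check_dna <- function(x) {
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop_validation("sequences contain non-ACGT characters: ",
                    paste(utils::head(x[bad], 3L), collapse = ", "))
  invisible(x)
}

# Map 0-based integer indices to DNA strings of length L (base-4 digits,
# most significant first; 0=A, 1=C, 2=G, 3=T).
int2dna <- function(idx, L) {
  alphabet <- c("A", "C", "G", "T")
  out <- matrix("", nrow = length(idx), ncol = L)
  v <- as.numeric(idx)
  for (k in L:1) {
    out[, k] <- alphabet[(v %% 4) + 1]
    v <- v %/% 4
  }
  do.call(paste0, split(out, col(out)))
}

has_homopolymer <- function(x, run) {
  pat <- paste0("([ACGT])\\1{", run - 1L, ",}")
  grepl(pat, x)
}

#' Construct a barcode set
#'
#' Bundles a vector of fixed-length DNA barcodes with the minimum
#' pairwise distance they are declared to satisfy and the metric under
#' which that guarantee holds. Use [validate_barcode_set()] to verify the
#' guarantee exhaustively.
#'
#' @param barcodes Character vector of same-length A/C/G/T sequences.
#' @param min_distance Declared minimum pairwise distance (default 3).
#' @param metric Distance metric of the guarantee.
#' @return An object of class `barcode_set`.
#' @export
barcode_set <- function(barcodes, min_distance = 3L,
                        metric = c("levenshtein", "sequence_levenshtein")) {
  metric <- match.arg(metric)
  barcodes <- toupper(as.character(barcodes))
  check_dna(barcodes)
  L <- unique(nchar(barcodes))
  if (length(L) != 1L)
    stop_validation("all barcodes in a set must have the same length")
  if (anyDuplicated(barcodes))
    stop_validation("barcode set contains duplicated sequences")
  structure(list(barcodes = barcodes, length = L,
                 min_distance = as.integer(min_distance), metric = metric),
            class = "barcode_set")
}

#' @export
print.barcode_set <- function(x, ...) {
  cat(sprintf("barcode_set: %d barcodes of length %d (pairwise %s >= %d)\n",
              length(x$barcodes), x$length, x$metric, x$min_distance))
  invisible(x)
}

#' @export
length.barcode_set <- function(x) length(x$barcodes)

#' Design a DNA barcode set with a minimum pairwise edit distance
#'
#' Greedy closure over a seeded random enumeration of the candidate
#' sequence space: candidates are visited in a reproducible shuffled
#' order and accepted when they are at distance >= `min_dist` from every
#' barcode accepted so far. The construction guarantees the pairwise
#' distance constraint by design; set sizes depend on the visiting order
#' and are not maximal.
#'
#' @param length Barcode length in bases (default 10).
#' @param min_dist Minimum pairwise distance (default 3, tolerating one
#'   sequencing error under Hamming decoding with a uniqueness radius
#'   of 2).
#' @param n_required Number of barcodes needed; generation stops once
#'   reached.
#' @param metric Distance metric, as in [edit_distance()].
#' @param seed Integer seed controlling the candidate order.
#' @param max_homopolymer Optional maximum homopolymer run; candidates
#'   with a longer run are skipped. `Inf` (default) disables the filter.
#' @param candidates Optional explicit candidate vector; when supplied it
#'   is scanned in the given order and no enumeration or shuffling is
#'   performed (useful for exhaustive small-alphabet checks).
#' @return A [barcode_set()] with at least `n_required` barcodes.
#'   Throws a capacity error naming the count achieved when the
#'   candidate space is exhausted first.
#' @examples
#' bs <- design_barcodes(length = 6, min_dist = 3, n_required = 20, seed = 1)
#' validate_barcode_set(bs)$valid
#' @export
design_barcodes <- function(length = 10L, min_dist = 3L, n_required,
                            metric = c("levenshtein",
                                       "sequence_levenshtein"),
                            seed = 1L, max_homopolymer = Inf,
                            candidates = NULL) {
  metric <- match.arg(metric)
  length <- assert_count(length, "length")
  min_dist <- assert_count(min_dist, "min_dist")
  n_required <- assert_count(n_required, "n_required")
  mcode <- metric_code(metric)
  accepted <- character(0)

  scan <- function(cands) {
    if (is.finite(max_homopolymer))
      cands <- cands[!has_homopolymer(cands, max_homopolymer + 1L)]
    for (cand in cands) {
      if (min_dist_ok_cpp(cand, accepted, min_dist, mcode)) {
        accepted[base::length(accepted) + 1L] <<- cand
        if (base::length(accepted) >= n_required) return(TRUE)
      }
    }
    FALSE
  }

  if (!is.null(candidates)) {
    candidates <- toupper(as.character(candidates))
    check_dna(candidates)
    done <- scan(candidates)
  } else {
    space <- 4^length
    done <- with_seed(seed, {
      if (space <= 2^22) {
        # Full seeded permutation of the candidate space, scanned in chunks.
        ord <- sample.int(space) - 1
        ok <- FALSE
        for (from in seq(1, space, by = 65536L)) {
          to <- min(from + 65535L, space)
          if (scan(int2dna(ord[from:to], length))) { ok <- TRUE; break }
        }
        ok
      } else {
        # Space too large to permute: stream random candidates, skipping
        # revisits, and stop after a bounded number of fresh draws.
        seen <- new.env(hash = TRUE, size = 4L * n_required)
        budget <- max(200L * n_required, 200000L)
        drawn <- 0L
        ok <- FALSE
        while (drawn < budget && !ok) {
          idx <- unique(floor(stats::runif(16384L) * space))
          keys <- sprintf("%.0f", idx)
          fresh <- !vapply(keys, exists, logical(1), envir = seen,
                           inherits = FALSE)
          for (k in keys[fresh]) assign(k, TRUE, envir = seen)
          drawn <- drawn + sum(fresh)
          ok <- scan(int2dna(idx[fresh], length))
        }
        ok
      }
    })
  }

  if (!done)
    stop_capacity("candidate space exhausted: only ",
                  base::length(accepted), " of ", n_required,
                  " barcodes found (length=", length,
                  ", min_dist=", min_dist, ", metric=", metric, ")")
  barcode_set(accepted, min_distance = min_dist, metric = metric)
}

#' Exhaustively validate the pairwise distance guarantee of a barcode set
#'
#' Checks every pair of barcodes (O(n^2)) against the set's declared
#' minimum distance and metric.
#'
#' @param set A [barcode_set()].
#' @return A list with `valid` (logical), `violations` (data frame with
#'   columns `barcode_i`, `barcode_j`, `distance` for every violating
#'   pair; zero rows when valid), `n_pairs_checked`, `min_distance`,
#'   and `metric`.
#' @export
validate_barcode_set <- function(set) {
  stopifnot(inherits(set, "barcode_set"))
  v <- pairwise_violations_cpp(set$barcodes, set$min_distance,
                               metric_code(set$metric))
  violations <- data.frame(barcode_i = set$barcodes[v$i],
                           barcode_j = set$barcodes[v$j],
                           distance = v$distance,
                           stringsAsFactors = FALSE)
  n <- length(set$barcodes)
  list(valid = nrow(violations) == 0L, violations = violations,
       n_pairs_checked = n * (n - 1) / 2,
       min_distance = set$min_distance, metric = set$metric)
}

#' Pair GREs with barcodes
#'
#' Randomly assigns `per_gre` unique barcodes to every GRE in a panel,
#' without replacement across the whole map, so no barcode serves two
#' GREs.
#'
#' @param gre_ids Character vector of GRE identifiers.
#' @param set A [barcode_set()] with at least
#'   `length(gre_ids) * per_gre` barcodes.
#' @param per_gre Barcodes per GRE (default 3).
#' @param seed Integer seed for the assignment.
#' @return A `gre_barcode_map` data frame with columns `gre_id`, `slot`
#'   (1..`per_gre`), and `barcode`.
#' @examples
#' bs <- design_barcodes(length = 8, min_dist = 3, n_required = 12, seed = 1)
#' assign_barcodes(paste0("GRE", 1:4), bs, per_gre = 3, seed = 1)
#' @export
assign_barcodes <- function(gre_ids, set, per_gre = 3L, seed = 1L) {
  stopifnot(inherits(set, "barcode_set"))
  gre_ids <- as.character(gre_ids)
  if (anyDuplicated(gre_ids)) stop_validation("duplicated GRE ids")
  per_gre <- assert_count(per_gre, "per_gre")
  need <- length(gre_ids) * per_gre
  if (length(set$barcodes) < need)
    stop_capacity("barcode set has ", length(set$barcodes),
                  " barcodes but ", need, " are required")
  chosen <- with_seed(seed, sample(set$barcodes, need, replace = FALSE))
  map <- data.frame(gre_id = rep(gre_ids, each = per_gre),
                    slot = rep(seq_len(per_gre), times = length(gre_ids)),
                    barcode = chosen, stringsAsFactors = FALSE)
  class(map) <- c("gre_barcode_map", "data.frame")
  map
}
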