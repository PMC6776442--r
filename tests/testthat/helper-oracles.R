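# Independent oracles used to check the package's implementations.
# These deliberately use naive formulations (memoized recursion,
# brute-force masks, direct formula evaluation) rather than the code
# paths under test.

# Levenshtein distance by memoized recursion on string prefixes.
oracle_lev <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- min(rec(i - 1, j) + 1, rec(i, j - 1) + 1,
             rec(i - 1, j - 1) + as.integer(av[i] != bv[j]))
    memo[[key]] <- v
    v
  }
  rec(length(av), length(bv))
}

# Sequence-Levenshtein via its prefix characterisation: the minimum
# Levenshtein distance after truncating either string at any point.
oracle_seqlev <- function(a, b) {
  n <- nchar(a)
  m <- nchar(b)
  d <- oracle_lev(a, b)
  for (i in 0:n) d <- min(d, oracle_lev(substr(a, 1, i), b))
  for (j in 0:m) d <- min(d, oracle_lev(a, substr(b, 1, j)))
  d
}

# Random DNA strings.
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

# Per-base boolean coverage mask of a set of half-open intervals.
coverage_mask <- function(intervals, chrom, len) {
  mask <- logical(len)
  sub <- intervals[intervals$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    lo <- sub$start[i] + 1L
    hi <- sub$end[i]
    if (hi >= lo) mask[lo:hi] <- TRUE
  }
  mask
}

# Direct NB log-likelihood for the two-group model with size-factor
# offsets, maximized by plain numeric search; independent of the
# package's fitting routine.
oracle_nb_lrt <- function(y, is_t, sf) {
  ll <- function(m_t, m_r, theta) {
    mu <- ifelse(is_t, sf * m_t, sf * m_r)
    sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
  }
  prof_full <- function(ltheta) {
    th <- exp(ltheta)
    o <- optim(log(c(mean(y[is_t]) + 0.1, mean(y[!is_t]) + 0.1)),
               function(lm) -ll(exp(lm[1]), exp(lm[2]), th),
               method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
    -o$value
  }
  # profile theta on a fine grid, then the reduced model at that theta
  grid <- seq(log(0.01), log(1e6), length.out = 240)
  lls <- vapply(grid, prof_full, numeric(1))
  th <- exp(grid[which.max(lls)])
  ll_f <- max(lls)
  o_r <- optimize(function(lm) -ll(exp(lm), exp(lm), th),
                  c(-20, 10), tol = 1e-12)
  ll_r <- -o_r$objective
  max(0, 2 * (ll_f - ll_r))
}

# Textbook Pearson correlation from the covariance formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sd(x) * sd(y))
}

# Small error-free screen reused by several tests.
tiny_screen <- function(n_gres = 20, n_cells = 300, seed = 42, ...) {
  simulate_screen(screen_truth(n_gres = n_gres, seed = seed,
                               barcode_error_rate = 0, ...), n_cells)
}
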