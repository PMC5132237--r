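# Independent oracles used across the suite. These re-derive results by
# direct, brute-force routes so they stay independent of the package's own
# computational paths.

# Natural cubic smoothing spline by dense direct linear algebra:
# f = (I + lambda * K)^{-1} y with K = Q R^{-1} Q' assembled from the
# textbook band formulas, lambda = (n / tr(K)) * 256^(3*spar - 1) on
# unit-rescaled abscissae.
oracle_spline <- function(x, y, spar) {
  n <- length(x)
  xs <- (x - x[1]) / (x[n] - x[1])
  h <- diff(xs)
  Q <- matrix(0, n, n - 2)
  R <- matrix(0, n - 2, n - 2)
  for (j in 2:(n - 1)) {
    i <- j - 1
    Q[j - 1, i] <- 1 / h[j - 1]
    Q[j, i] <- -1 / h[j - 1] - 1 / h[j]
    Q[j + 1, i] <- 1 / h[j]
    R[i, i] <- (h[j - 1] + h[j]) / 3
    if (i > 1) R[i, i - 1] <- R[i - 1, i] <- h[j - 1] / 6
  }
  K <- Q %*% solve(R) %*% t(Q)
  lambda <- (n / sum(diag(K))) * 256^(3 * spar - 1)
  as.numeric(solve(diag(n) + lambda * K, y))
}

# Exhaustive elbow search: distance of every interior point to the chord,
# points on the sagging (below-chord) side only.
oracle_sep <- function(ages, durations, epsilon = 0.02) {
  m <- length(durations)
  if (diff(range(durations)) == 0) return(NA_integer_)
  x <- (ages - min(ages)) / diff(range(ages))
  y <- (durations - min(durations)) / diff(range(durations))
  a <- c(x[1], y[1]); b <- c(x[m], y[m])
  best_age <- NA_integer_; best_d <- epsilon
  for (i in 2:(m - 1)) {
    # perpendicular distance, signed so the sag side is positive
    d <- ((x[i] - a[1]) * (b[2] - a[2]) - (y[i] - a[2]) * (b[1] - a[1])) /
      sqrt(sum((b - a)^2))
    if (d > best_d + 1e-12) {
      best_d <- d
      best_age <- ages[i]
    }
  }
  best_age
}

# Exact two-sided Mann-Whitney p by bitmask enumeration over group
# assignments, using the rank-sum route (mid-ranks for ties) rather than
# pairwise counting.
oracle_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_of <- function(members) sum(rk[members]) - n * (n + 1) / 2
  u_obs <- u_of(seq_len(n))
  centre <- n * m / 2
  total <- 0L; extreme <- 0L
  for (mask in 0:(2^(n + m) - 1)) {
    members <- which(bitwAnd(bitwShiftL(1L, 0:(n + m - 1)), mask) != 0L)
    if (length(members) != n) next
    total <- total + 1L
    if (abs(u_of(members) - centre) >= abs(u_obs - centre) - 1e-9)
      extreme <- extreme + 1L
  }
  extreme / total
}

# Two-group log-rank chi-square from an explicit life table.
oracle_logrank_chisq <- function(ta, tb) {
  times <- sort(unique(c(ta, tb)))
  oa <- 0; ea <- 0; v <- 0
  for (t in times) {
    na <- sum(ta >= t); nb <- sum(tb >= t); nn <- na + nb
    da <- sum(ta == t); db <- sum(tb == t); dd <- da + db
    if (nn < 1 || dd == 0) next
    oa <- oa + da
    ea <- ea + dd * na / nn
    if (nn > 1)
      v <- v + dd * (na / nn) * (nb / nn) * (nn - dd) / (nn - 1)
  }
  (oa - ea)^2 / v
}

# Curated life-history tables of the two published cohorts (119 and 106
# cells). They are not redistributed with the package; analyses that need
# them look here and report their absence.
reference_dataset <- function(which = 1) {
  base <- system.file("extdata", "reference", package = "cellspan")
  sizes <- file.path(base, sprintf("dataset%d_sizes.csv", which))
  times <- file.path(base, sprintf("dataset%d_times.csv", which))
  fluor <- file.path(base, sprintf("dataset%d_fluor.csv", which))
  if (base == "" || !file.exists(sizes) || !file.exists(times)) return(NULL)
  read_life_history_tables(sizes, times,
                           fluor_table = if (file.exists(fluor)) fluor,
                           name = sprintf("dataset %d", which))
}

fail_no_reference_data <- function(which = 1) {
  fail(sprintf(paste(
    "the curated %d-cell life-history tables are not redistributed with",
    "this package (expected under inst/extdata/reference/); the printed",
    "statistic cannot be recomputed without them"),
    if (which == 1) 119L else 106L))
}

# Small deterministic cohort used by several unit tests.
make_test_cells <- function() {
  list(
    cell_life_history("A", c(20, 24, 30), c(0, 1.5, 3.1)),
    cell_life_history("B", c(15, 16.2, 18, 21, 26, 34),
                      c(0, 1.4, 2.9, 4.5, 7.0, 11.0)),
    cell_life_history("C", c(18, 19, 21, 24), c(0, 1.6, 3.2, 5.1)))
}
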