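# Inferential toolkit: exact r x c Fisher test by full enumeration with a
# seeded Monte-Carlo fallback, sample odds ratios with zero-cell semantics,
# seeded two-sample permutation test, Pearson correlation.

log_table_prob <- function(tab, lrow, lcol, ln) {
  # hypergeometric probability of a table given fixed margins
  lrow + lcol - ln - sum(lgamma(tab + 1))
}

enumerate_margin_tables <- function(rows, cols, visit, budget) {
  # depth-first enumeration of all non-negative integer tables with the given
  # margins; visit(tab) is called for each; returns count or -1 if budget hit
  r <- length(rows); c <- length(cols)
  tab <- matrix(0L, r, c)
  count <- 0L
  rec <- function(i, j, row_rem, col_rem) {
    if (count < 0L) return()
    if (i == r) {
      # last row forced by column remainders
      if (any(col_rem < 0L)) return()
      tab[r, ] <<- col_rem
      count <<- count + 1L
      if (count > budget) { count <<- -1L; return() }
      visit(tab)
      return()
    }
    if (j == c) {
      # last cell of the row is forced by the row remainder
      if (row_rem > col_rem[c]) return()
      tab[i, c] <<- row_rem
      cr <- col_rem; cr[c] <- cr[c] - row_rem
      rec(i + 1L, 1L, rows[i + 1L], cr)
      return()
    }
    # upper bound: can't exceed row or column remainder; lower bound: must be
    # able to place the rest of the row in the remaining columns
    hi <- min(row_rem, col_rem[j])
    rest <- if (j < c) sum(col_rem[(j + 1L):c]) else 0L
    lo <- max(0L, row_rem - rest)
    if (hi < lo) return()
    for (v in lo:hi) {
      tab[i, j] <<- v
      cr <- col_rem; cr[j] <- cr[j] - v
      rec(i, j + 1L, row_rem - v, cr)
      if (count < 0L) return()
    }
  }
  rec(1L, 1L, rows[1L], as.integer(cols))
  count
}

#' Exact r x c Fisher test for count data
#'
#' Two-sided exact test of independence in an r x c contingency table. The
#' p-value is the total null (multivariate hypergeometric, fixed margins)
#' probability of all tables whose probability does not exceed that of the
#' observed table (the probability-ordering criterion, matching the
#' conventional two-sided Fisher test). Full enumeration is used when the
#' number of margin-consistent tables is within `budget`; otherwise a seeded
#' Monte-Carlo estimate over `mc_reps` Patefield-sampled tables is returned
#' with its standard error.
#'
#' @param table matrix of non-negative integer counts, r, c >= 2.
#' @param budget maximum number of tables to enumerate, default 2e5.
#' @param mc_reps Monte-Carlo replications for large problems, default 1e5.
#' @param seed RNG seed for the Monte-Carlo path.
#' @return list with `p_value`, `method` (`"exact"` or `"monte-carlo"`), and
#'   `mc_se` (`NA` for exact).
#' @export
fisher_exact_rxc <- function(table, budget = 2e5, mc_reps = 1e5, seed = 1L) {
  tab <- as.matrix(table)
  storage.mode(tab) <- "integer"
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need an r x c table with r, c >= 2")
  if (any(tab < 0L)) stop("counts must be non-negative")
  rows <- rowSums(tab); cols <- colSums(tab)
  if (any(rows == 0L) || any(cols == 0L))
    stop("degenerate margin: all-zero row or column")
  n <- sum(tab)
  lrow <- sum(lgamma(rows + 1)); lcol <- sum(lgamma(cols + 1)); ln <- lgamma(n + 1)
  lp_obs <- log_table_prob(tab, lrow, lcol, ln)
  tol <- 1e-7  # relative tolerance absorbing floating-point ties
  acc <- 0
  res <- enumerate_margin_tables(rows, cols, function(t2) {
    lp <- log_table_prob(t2, lrow, lcol, ln)
    if (lp <= lp_obs + tol) acc <<- acc + exp(lp)
  }, budget = budget)
  if (res >= 0L)
    return(list(p_value = min(1, acc), method = "exact", mc_se = NA_real_,
                n_tables = res))
  # Monte Carlo over Patefield-sampled margin-fixed tables
  set.seed(seed)
  sims <- stats::r2dtable(mc_reps, rows, cols)
  hits <- vapply(sims, function(t2)
    log_table_prob(t2, lrow, lcol, ln) <= lp_obs + tol, logical(1))
  p <- (sum(hits) + 1) / (mc_reps + 1)
  list(p_value = p, method = "monte-carlo",
       mc_se = sqrt(p * (1 - p) / mc_reps), n_tables = NA_integer_)
}

#' Sample odds ratio of a 2 x 2 table
#'
#' Plain cross-product ratio `(a*d)/(b*c)` with no continuity correction.
#' Zero cells give the conventional markers: 0 when the numerator is zero and
#' the denominator positive, `Inf` in the opposite case, `NaN` when both are
#' zero. The `orientation` argument flips the ratio (`"reciprocal"` returns
#' `(b*c)/(a*d)`), since published tables sometimes mix event-odds and
#' complement-odds orientations for the same comparison.
#'
#' @param a,b,c,d cell counts: rows are groups, columns are outcomes, so
#'   `a/b` are outcome-1/outcome-2 counts in group 1 and `c/d` in group 2.
#' @param orientation `"standard"` or `"reciprocal"`.
#' @return numeric odds ratio (possibly 0, `Inf`, or `NaN`).
#' @export
odds_ratio_2x2 <- function(a, b, c, d, orientation = c("standard", "reciprocal")) {
  orientation <- match.arg(orientation)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  num <- a * d; den <- b * c
  or <- if (num == 0 && den == 0) NaN
        else if (den == 0) Inf
        else num / den
  if (orientation == "reciprocal") {
    or <- if (num == 0 && den == 0) NaN else if (num == 0) Inf else den / num
  }
  or
}

#' Two-sample permutation test on the difference in means
#'
#' Tests whether `x` and `y` come from the same distribution by permuting
#' group labels. When the number of distinct assignments `choose(n, nx)` is
#' within `exact_budget`, all assignments are enumerated and the two-sided
#' p-value is the exact proportion with `|mean(x*) - mean(y*)|` at least the
#' observed value. Otherwise a seeded Monte-Carlo estimate over `reps` random
#' permutations is reported with the add-one correction `(b + 1)/(reps + 1)`.
#'
#' @param x,y numeric samples.
#' @param reps Monte-Carlo replications, default 1e4.
#' @param seed RNG seed for the Monte-Carlo path.
#' @param exact_budget maximum number of assignments to enumerate, default 5e4.
#' @return list with `p_value`, `method`, `statistic` (observed mean
#'   difference), and `mc_se` (`NA` for exact).
#' @export
permutation_test_two_sample <- function(x, y, reps = 1e4, seed = 1L,
                                        exact_budget = 5e4) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  z <- c(x, y); nx <- length(x); n <- length(z)
  obs <- mean(x) - mean(y)
  if (all(z == z[1]))
    return(list(p_value = 1, method = "degenerate", statistic = obs,
                mc_se = NA_real_))
  eps <- 1e-12 * max(1, abs(obs))
  if (choose(n, nx) <= exact_budget) {
    idx <- utils::combn(n, nx)
    diffs <- apply(idx, 2L, function(i) mean(z[i]) - mean(z[-i]))
    p <- mean(abs(diffs) >= abs(obs) - eps)
    return(list(p_value = p, method = "exact", statistic = obs,
                mc_se = NA_real_))
  }
  set.seed(seed)
  b <- 0L
  for (r in seq_len(reps)) {
    i <- sample.int(n, nx)
    if (abs(mean(z[i]) - mean(z[-i])) >= abs(obs) - eps) b <- b + 1L
  }
  p <- (b + 1) / (reps + 1)
  list(p_value = p, method = "monte-carlo", statistic = obs,
       mc_se = sqrt(p * (1 - p) / reps))
}

#' Pearson correlation with two-sided t-based p-value
#'
#' @param x,y paired numeric vectors, n >= 3, nonzero variances.
#' @return list with `r` and `p_value`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) return(list(r = sign(r), p_value = 0))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(-abs(tstat), df = n - 2))
}
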