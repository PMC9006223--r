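# Multi-dataset statistical comparison of algorithms by average Friedman
# ranks: Friedman chi-square with the Iman-Davenport F correction, Holm
# step-down comparison of the best-ranked algorithm against the rest, and
# the Nemenyi critical difference for all-pairs comparison.

#' Friedman test with Iman-Davenport correction
#'
#' `chi2_F = 12 N / (k (k + 1)) * (sum R_j^2 - k (k + 1)^2 / 4)` over the
#' average ranks `R_j` of `k` algorithms on `N` datasets, and the less
#' conservative Iman-Davenport statistic
#' `F = (N - 1) chi2_F / (N (k - 1) - chi2_F)`, referred to the F
#' distribution with `(k - 1, (k - 1)(N - 1))` degrees of freedom.
#'
#' @param table a `rank_table` from [build_rank_table()].
#' @return a list with `chi2`, `F`, `p_value`, `df1`, `df2`, `k`, `N`.
#' @export
friedman_imandavenport <- function(table) {
  stopifnot(inherits(table, "rank_table"))
  k <- length(table$algorithms)
  N <- length(table$datasets)
  if (k < 2 || N < 2) stop("need at least 2 algorithms and 2 datasets")
  R <- table$avg_ranks
  chi2 <- 12 * N / (k * (k + 1)) * (sum(R^2) - k * (k + 1)^2 / 4)
  denom <- N * (k - 1) - chi2
  if (denom <= .Machine$double.eps^0.5) {
    stop("Iman-Davenport F undefined: ranks perfectly consistent")
  }
  Fstat <- (N - 1) * chi2 / denom
  df1 <- k - 1
  df2 <- (k - 1) * (N - 1)
  list(chi2 = chi2, F = Fstat,
       p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, k = k, N = N)
}

#' Holm step-down comparison against the best-ranked algorithm
#'
#' The algorithm with the lowest average rank is compared with each other
#' algorithm through `z = (R_i - R_j) / sqrt(k (k + 1) / (6 N))`, two-sided
#' normal p-values.  The p-values are sorted ascending and compared in turn
#' with `alpha / (k - 1)`, `alpha / (k - 2)`, ...; at the first failure all
#' remaining hypotheses are retained.
#'
#' @param table a `rank_table`.
#' @param alpha family-wise significance level.
#' @return a list with `best` (algorithm name), `comparisons` (data.frame
#'   with `algorithm`, `z`, `p`, `threshold`, `reject`, sorted by p), and
#'   `alpha`.
#' @export
holm_test <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "rank_table"))
  k <- length(table$algorithms)
  N <- length(table$datasets)
  R <- table$avg_ranks
  best <- which.min(R)
  se <- sqrt(k * (k + 1) / (6 * N))
  others <- setdiff(seq_len(k), best)
  z <- (R[others] - R[best]) / se
  p <- 2 * stats::pnorm(-abs(z))
  ord <- order(p)
  others <- others[ord]; z <- z[ord]; p <- p[ord]
  m <- k - 1
  thresholds <- alpha / (m - seq_len(m) + 1)   # alpha/(k-1), alpha/(k-2), ...
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[i] < thresholds[i]) reject[i] <- TRUE else break
  }
  list(
    best = table$algorithms[best],
    comparisons = data.frame(
      algorithm = table$algorithms[others],
      z = unname(z), p = unname(p),
      threshold = thresholds, reject = reject
    ),
    alpha = alpha
  )
}

# Two-tailed Nemenyi critical values q_alpha (Studentized range / sqrt(2))
# for k = 2..10, as tabulated in Demsar (2006), JMLR 7:1-30, Table 5.
nemenyi_q <- list(
  "0.05" = c(1.960, 2.343, 2.569, 2.728, 2.850, 2.949, 3.031, 3.102, 3.164),
  "0.1"  = c(1.645, 2.052, 2.291, 2.459, 2.589, 2.693, 2.780, 2.855, 2.920)
)

#' Nemenyi critical difference
#'
#' `CD = q_alpha * sqrt(k (k + 1) / (6 N))`: two algorithms differ
#' significantly when their average ranks differ by at least CD.
#'
#' @param k number of algorithms (2..10, the tabulated range of `q_alpha`).
#' @param N number of datasets (>= 2).
#' @param alpha 0.05 or 0.10.
#' @return the critical difference.
#' @export
nemenyi_cd <- function(k, N, alpha = 0.05) {
  if (k < 2 || k > 10) stop("k outside the tabulated range 2..10")
  if (N < 2) stop("N must be >= 2")
  key <- as.character(alpha)
  if (!key %in% names(nemenyi_q)) stop("alpha must be 0.05 or 0.1")
  nemenyi_q[[key]][k - 1] * sqrt(k * (k + 1) / (6 * N))
}

#' Full multi-dataset comparison
#'
#' Convenience wrapper running [friedman_imandavenport()], [holm_test()] and
#' [nemenyi_cd()] on one rank table; the returned object carries everything
#' needed to draw a critical-difference diagram (average ranks plus CD).
#'
#' @param table a `rank_table`.
#' @param alpha significance level.
#' @return a list with `avg_ranks`, `friedman`, `holm`, `cd`, `alpha`.
#' @export
compare_algorithms <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "rank_table"))
  k <- length(table$algorithms)
  N <- length(table$datasets)
  fr <- tryCatch(friedman_imandavenport(table),
                 error = function(e) list(chi2 = NA, F = NA, p_value = NA,
                                          error = conditionMessage(e)))
  list(
    avg_ranks = as.list(table$avg_ranks),
    friedman = fr,
    holm = holm_test(table, alpha),
    cd = if (k >= 2 && k <= 10) nemenyi_cd(k, N, alpha) else NA,
    alpha = alpha
  )
}
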