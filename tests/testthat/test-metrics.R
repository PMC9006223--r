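# Closed-form checks and invariances of the evaluation metrics.

test_that("G-Mean matches its closed form and conventions", {
  expect_equal(g_mean(confusion_counts(50, 50, 0, 0)), 1)
  expect_equal(g_mean(confusion_counts(40, 0, 40, 0)), 0)   # specificity 0
  expect_equal(g_mean(confusion_counts(30, 20, 20, 10)), sqrt(0.75 * 0.5))
})

test_that("Cohen's kappa matches its closed form", {
  expect_equal(cohen_kappa(confusion_counts(25, 25, 0, 0)), 1)
  # counts equal to marginal products: chance-level agreement
  expect_equal(cohen_kappa(confusion_counts(16, 24, 16, 24)), 0)
  expect_equal(cohen_kappa(confusion_counts(20, 15, 10, 5)), 0.4)
})

test_that("reduction is the eliminated fraction", {
  expect_equal(reduction(10, 10), 0)
  expect_equal(reduction(0, 10), 1)
  expect_equal(reduction(250, 1138), 1 - 250 / 1138)
  expect_error(reduction(11, 10), "m must")
})

test_that("mutual information and SU match direct summation", {
  # joint frequencies [[0.4, 0.1], [0.1, 0.4]] realized over 100 samples
  x <- rep(c(0, 0, 1, 1), times = c(40, 10, 10, 40))
  y <- rep(c(0, 1, 0, 1), times = c(40, 10, 10, 40))
  mi_expected <- 0.8 * log2(1.6) + 0.2 * log2(0.4)
  expect_equal(mutual_information(x, y), mi_expected, tolerance = 1e-12)
  # H(X) = H(Y) = 1 bit, so SU = MI here
  expect_equal(symmetric_uncertainty(x, y), mi_expected, tolerance = 1e-12)

  expect_equal(symmetric_uncertainty(y, y), 1)
  xi <- rep(c(0, 1), each = 20)
  yi <- rep(c(0, 1), times = 20)
  expect_equal(mutual_information(xi, yi), 0)
  expect_equal(symmetric_uncertainty(xi, yi), 0)
  expect_equal(symmetric_uncertainty(rep(1, 5), rep(2, 5)), 0)
  expect_error(mutual_information(1:3, 1:4), "length")
})

test_that("information metrics are symmetric and permutation-invariant", {
  set.seed(21)
  for (rep in 1:10) {
    x <- rbinom(50, 3, 0.4)
    y <- rbinom(50, 1, 0.5)
    expect_equal(mutual_information(x, y), mutual_information(y, x))
    p <- sample.int(50)
    expect_equal(mutual_information(x[p], y[p]), mutual_information(x, y))
    expect_equal(symmetric_uncertainty(x[p], y[p]),
                 symmetric_uncertainty(x, y))
    # MI(x, x) recovers the entropy of x
    tab <- table(x) / 50
    expect_equal(mutual_information(x, x), -sum(tab * log2(tab)))
  }
})

test_that("MI redundancy is the mean over unordered pairs", {
  f <- rep(c(0, 1), each = 20)
  expect_equal(mi_redundancy(cbind(f)), 0)
  expect_equal(mi_redundancy(cbind(f, f)), 1)      # identical balanced pair
  ind <- cbind(rep(c(0, 1), each = 4),
               rep(rep(c(0, 1), each = 2), 2),
               rep(c(0, 1), 4))                    # mutually independent
  expect_equal(mi_redundancy(ind), 0)
  # feature-order invariance
  set.seed(22)
  m <- matrix(rbinom(200, 2, 0.5), 50, 4)
  expect_equal(mi_redundancy(m[, c(3, 1, 4, 2)]), mi_redundancy(m))
})

test_that("AcRed averages absolute pairwise correlations", {
  set.seed(23)
  f <- rnorm(40)
  expect_equal(ac_red(cbind(f, f)), 1)
  expect_equal(ac_red(cbind(f, -2 * f)), 1)
  expect_equal(ac_red(cbind(f)), 0)
  # against an independent pairwise computation
  for (rep in 1:10) {
    m <- matrix(rpois(160, 2), 40, 4)
    expected <- mean(abs(cor(m)[upper.tri(diag(4))]))
    expect_equal(ac_red(m), expected)
    expect_equal(ac_red(m[, 4:1]), expected)
  }
  # zero-variance column contributes 0 per pair
  m2 <- cbind(f, rep(3, 40))
  expect_equal(ac_red(m2), 0)
})

test_that("coefficient of variation uses the population sd and scales out", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), 0.5)
  v <- c(1.5, 2, 8, 3)
  expect_equal(coefficient_of_variation(7 * v), coefficient_of_variation(v))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("metrics_report bundles the per-selection metrics", {
  set.seed(24)
  x <- matrix(rpois(100, 1), 20, 5)
  truth <- rep(c(0, 1), 10)
  pred <- truth
  rep0 <- metrics_report(truth, pred, c(1, 3), x)
  expect_equal(rep0$g_mean, 1)
  expect_equal(rep0$kappa, 1)
  expect_equal(rep0$reduction, 1 - 2 / 5)
  expect_equal(rep0$m, 2)
  expect_equal(rep0$ac_red, ac_red(x[, c(1, 3)]))
})
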