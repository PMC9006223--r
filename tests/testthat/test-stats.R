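# Friedman / Iman-Davenport, Holm step-down and Nemenyi critical difference.

# rank_table with prescribed per-dataset ranks (fed as negated values so
# that smaller rank = better value).
rank_fixture <- function(ranks) {
  build_rank_table(-ranks)
}

test_that("the k=3, N=4 worked table gives chi2 = 6.5 and F = 13", {
  ranks <- cbind(A = c(1, 1, 1, 2), B = c(2, 2, 2, 1), C = c(3, 3, 3, 3))
  rownames(ranks) <- paste0("D", 1:4)
  rt <- rank_fixture(ranks)
  expect_equal(unname(rt$avg_ranks), c(1.25, 1.75, 3))
  fr <- friedman_imandavenport(rt)
  expect_equal(fr$chi2, 6.5)
  expect_equal(fr$F, 13)
  expect_equal(fr$df1, 2)
  expect_equal(fr$df2, 6)
})

test_that("all-tied algorithms give chi2 = 0; perfect consistency signals", {
  tied <- matrix(rep(c(1.5, 1.5), 4), 4, 2,
                 dimnames = list(paste0("D", 1:4), c("A", "B")))
  rt <- build_rank_table(-tied)
  expect_equal(friedman_imandavenport(rt)$chi2, 0, tolerance = 1e-12)

  consistent <- cbind(A = rep(1, 4), B = rep(2, 4))
  rownames(consistent) <- paste0("D", 1:4)
  expect_error(friedman_imandavenport(rank_fixture(consistent)),
               "undefined")
})

test_that("the Friedman statistic ignores dataset relabeling", {
  set.seed(81)
  m <- matrix(runif(4 * 10), 10, 4,
              dimnames = list(paste0("D", 1:10), paste0("A", 1:4)))
  f1 <- friedman_imandavenport(build_rank_table(m))$chi2
  perm <- m[sample(10), , drop = FALSE]
  f2 <- friedman_imandavenport(build_rank_table(perm))$chi2
  expect_equal(f1, f2)
})

test_that("Holm z follows (R_i - R_j) / sqrt(k(k+1)/(6N))", {
  # k = 5, N = 24, rank difference 1.0 -> z = 2.191; rank table assembled
  # directly with average ranks (2, 3, 3, 3, 4)
  avg <- c(A1 = 2, A2 = 3, A3 = 3, A4 = 3, A5 = 4)
  rt <- structure(
    list(values = NULL, ranks = NULL, avg_ranks = avg,
         algorithms = names(avg), datasets = paste0("D", 1:24)),
    class = "rank_table"
  )
  ht <- holm_test(rt)
  se <- sqrt(5 * 6 / (6 * 24))
  worst <- ht$comparisons[ht$comparisons$algorithm == "A5", ]
  expect_equal(worst$z, 2 / se)
  mid <- ht$comparisons[ht$comparisons$algorithm == "A2", ]
  expect_equal(mid$z, 1 / se)
  expect_equal(1 / se, 2.19089, tolerance = 1e-4)
})

test_that("Holm rejections are a step-down prefix, monotone in alpha", {
  set.seed(82)
  for (rep in 1:10) {
    m <- matrix(runif(4 * 8), 8, 4,
                dimnames = list(paste0("D", 1:8), paste0("A", 1:4)))
    rt <- build_rank_table(m)
    prev_rejected <- -1
    for (alpha in c(0.01, 0.05, 0.1, 0.5)) {
      ht <- holm_test(rt, alpha)
      rej <- ht$comparisons$reject
      # prefix property: no rejection after the first retention
      if (any(!rej)) {
        expect_false(any(rej[seq(which.min(rej), length(rej))]))
      }
      expect_gte(sum(rej), prev_rejected)
      prev_rejected <- sum(rej)
    }
  }
  # equal average ranks -> z = 0, p = 1, never rejected
  eq <- matrix(rep(c(0.3, 0.3), 6), 6, 2,
               dimnames = list(paste0("D", 1:6), c("A", "B")))
  ht <- holm_test(build_rank_table(eq))
  expect_equal(ht$comparisons$z, 0)
  expect_equal(ht$comparisons$p, 1)
  expect_false(any(ht$comparisons$reject))
})

test_that("Nemenyi CD matches the closed form and shrinks with N", {
  expect_equal(nemenyi_cd(2, 24, 0.05), 1.96 * sqrt(2 * 3 / (6 * 24)))
  expect_equal(nemenyi_cd(2, 24, 0.05), 0.4001, tolerance = 1e-4)
  cds <- vapply(c(5, 10, 20, 50), function(N) nemenyi_cd(4, N), numeric(1))
  expect_true(all(diff(cds) < 0))
  expect_error(nemenyi_cd(11, 10), "tabulated")
  expect_error(nemenyi_cd(3, 10, alpha = 0.01), "alpha")
})

test_that("at k = 2 the Nemenyi criterion agrees with the Holm z-test", {
  set.seed(83)
  for (rep in 1:20) {
    m <- matrix(runif(2 * 12), 12, 2,
                dimnames = list(paste0("D", 1:12), c("A", "B")))
    rt <- build_rank_table(m)
    ht <- holm_test(rt, alpha = 0.05)
    cd <- nemenyi_cd(2, 12, 0.05)
    gap <- abs(diff(rt$avg_ranks))
    expect_equal(ht$comparisons$reject[1], unname(gap >= cd))
  }
})

test_that("compare_algorithms bundles ranks, tests and CD", {
  set.seed(84)
  m <- matrix(runif(3 * 10), 10, 3,
              dimnames = list(paste0("D", 1:10), c("A", "B", "C")))
  rt <- build_rank_table(m)
  cmp <- compare_algorithms(rt)
  expect_named(cmp, c("avg_ranks", "friedman", "holm", "cd", "alpha"))
  expect_equal(cmp$cd, nemenyi_cd(3, 10, 0.05))
})
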