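# Co-selection graph construction and the two subset-extraction strategies.

test_that("record_selection applies the (weighted) increment rule", {
  g <- selection_graph(3)
  g <- record_selection(g, c(1, 2), 1)
  expect_equal(g$v, c(1, 1, 0))
  expect_equal(g$e[1, 2], 1)
  expect_equal(g$e[1, 3], 0)

  g <- record_selection(g, c(2, 3), 1)
  expect_equal(g$v, c(1, 2, 1))
  expect_equal(g$e[1, 2], 1)
  expect_equal(g$e[2, 3], 1)
  expect_equal(g$e[1, 3], 0)

  g2 <- record_selection(selection_graph(3), c(1, 3), 0.7)
  expect_equal(g2$v, c(0.7, 0, 0.7))
  expect_equal(g2$e[1, 3], 0.7)
  expect_true(isSymmetric(g2$e))
  expect_equal(diag(g2$e), rep(0, 3))

  expect_error(record_selection(selection_graph(3), c(1, 4), 1), "range")
  expect_error(record_selection(selection_graph(3), 1, -0.1), "nonnegative")
})

test_that("recording rounds commutes and preserves mass/edge bounds", {
  rounds <- list(list(s = c(1, 3, 5), w = 1.2), list(s = c(2, 3), w = 0.5),
                 list(s = c(1, 2, 3, 4), w = 2), list(s = 5, w = 0.3))
  build <- function(ord) {
    g <- selection_graph(5)
    for (r in rounds[ord]) g <- record_selection(g, r$s, r$w)
    g
  }
  g <- build(1:4)
  expect_equal(g, build(c(3, 1, 4, 2)))
  expect_equal(sum(g$v), sum(vapply(rounds, function(r) r$w * length(r$s),
                                    numeric(1))))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_lte(g$e[i, j], min(g$v[i], g$v[j]) + 1e-12)
  }
})

test_that("select_threshold matches the hand-derived cases", {
  g <- selection_graph(3)
  g$v <- c(3, 2, 1)
  g$e[1, 2] <- g$e[2, 1] <- 2
  g$e[2, 3] <- g$e[3, 2] <- 1
  expect_equal(select_threshold(g, 2, 1), c(1L, 2L))
  expect_equal(select_threshold(g, 0, 0), 1:3)

  g2 <- selection_graph(3)
  g2$v <- c(2, 2, 5)
  expect_equal(select_threshold(g2, 1, 1), 3L)
})

test_that("select_chain follows the strongest admissible edges", {
  g <- selection_graph(3)
  g$v <- c(5, 3, 4)
  g$e[1, 3] <- g$e[3, 1] <- 4
  g$e[1, 2] <- g$e[2, 1] <- 1
  g$e[2, 3] <- g$e[3, 2] <- 2
  expect_equal(select_chain(g, 0, 2), c(1L, 3L, 2L))
  expect_equal(select_chain(g, 0, 5), 1L)          # no edge admissible
  expect_equal(select_chain(g, 4, 2), c(1L, 3L))   # vertex 2 filtered out
  expect_error(select_chain(g, 6, 0), "vertex threshold")
})

test_that("both strategies match the straight-line oracle on random graphs", {
  set.seed(11)
  for (rep in 1:60) {
    g <- random_graph(sample(2:7, 1))
    for (r in seq_len(nrow(op <- oracle_pairs(g)))) {
      tv <- op$tau_v[r]; te <- op$tau_e[r]
      expect_identical(select_threshold(g, tv, te),
                       as.integer(oracle_select_threshold(g$v, g$e, tv, te)))
      oc <- oracle_select_chain(g$v, g$e, tv, te)
      if (is.null(oc)) {
        expect_error(select_chain(g, tv, te))
      } else {
        expect_identical(select_chain(g, tv, te), as.integer(oc))
      }
    }
  }
})

test_that("tau_e = 0 reduces to a plain vote threshold, monotone in tau_v", {
  set.seed(12)
  for (rep in 1:25) {
    g <- random_graph(6)
    prev <- NULL
    for (tv in sort(unique(c(0, g$v)))) {
      s <- select_threshold(g, tv, 0)
      expect_identical(s, which(g$v >= tv))
      if (!is.null(prev)) expect_true(all(s %in% prev))
      prev <- s
    }
  }
})

test_that("chain output is closed: strong links, max-vertex start", {
  set.seed(13)
  for (rep in 1:25) {
    g <- random_graph(6)
    for (te in sort(unique(c(0, g$e[upper.tri(g$e)])))) {
      ch <- select_chain(g, 0, te)
      expect_equal(g$v[ch[1]], max(g$v))
      if (length(ch) > 1) {
        for (i in seq_len(length(ch) - 1)) {
          expect_gte(g$e[ch[i], ch[i + 1]], te)
        }
      }
    }
  }
})

test_that("grid_thresholds enumerates distinct values and caps long lists", {
  g <- selection_graph(2)
  g$v <- c(1, 2)
  g$e[1, 2] <- g$e[2, 1] <- 1
  gr <- grid_thresholds(g, 100)
  expect_equal(nrow(gr), 6)
  expect_equal(sort(unique(gr$tau_v)), c(0, 1, 2))
  expect_equal(sort(unique(gr$tau_e)), c(0, 1))

  g2 <- selection_graph(3)
  g2$v <- c(3, 3, 3)
  gr2 <- grid_thresholds(g2, 100)
  expect_equal(sort(unique(gr2$tau_v)), c(0, 3))

  # many distinct edge values get replaced by equally spaced candidates
  M <- 50
  g3 <- selection_graph(M)
  g3$v <- rep(1, M)
  vals <- seq_len(M * (M - 1) / 2)
  g3$e[upper.tri(g3$e)] <- vals
  g3$e <- g3$e + t(g3$e)
  gr3 <- grid_thresholds(g3, 20)
  ec <- sort(unique(gr3$tau_e))
  expect_length(ec, 20)
  expect_equal(ec, seq(0, max(vals), length.out = 20))
})

test_that("graph JSON serialization round-trips bit-exactly", {
  g <- selection_graph(4)
  g <- record_selection(g, c(1, 2, 4), log(2))     # irrational weight
  g <- record_selection(g, c(2, 3), 1 / 3)
  path <- tempfile(fileext = ".json")
  write_graph(g, path)
  g2 <- read_graph(path)
  expect_identical(g2$M, g$M)
  expect_identical(g2$v, g$v)
  expect_identical(g2$e, g$e)
})
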