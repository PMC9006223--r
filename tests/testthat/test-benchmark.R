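# Repeated double cross-validation harness and rank tables.

small_protocol <- function(classifier = "dt", rounds = 2, seed = 71) {
  protocol_config(external_rounds = rounds, inner_folds = 3,
                  classifier = classifier, seed = seed)
}

test_that("perfectly separable data scores external G-Mean 1 everywhere", {
  spec <- synth_spec(n_samples = 80, n_relevant = 2, copies_per_relevant = 0,
                     n_irrelevant = 6, flip_noise = 0, label_noise = 0,
                     p1 = 1, p0 = 0, seed = 71)
  sim <- simulate_fragments(spec)
  rec <- double_cv(sim$data, variants = c("mT", "T"),
                   protocol = small_protocol(), rounds = 3)
  expect_true(all(rec$g_mean == 1))
})

test_that("build and validation partitions are disjoint and exhaustive", {
  sim <- simulate_fragments(synth_spec(n_samples = 90, n_relevant = 2,
                                       n_irrelevant = 8, seed = 72))
  rec <- double_cv(sim$data, variants = c("mT", "T"),
                   protocol = small_protocol(seed = 72), rounds = 3)
  splits <- attr(rec, "splits")
  expect_length(splits, 2)
  for (s in splits) {
    expect_length(intersect(s$build, s$val), 0)
    expect_equal(sort(c(s$build, s$val)), 1:90)
  }
  # variants within a round share the split: one splits entry per round
  expect_equal(nrow(rec), 2 * 2)
})

test_that("the harness reproduces itself bit-for-bit under one seed", {
  sim <- simulate_fragments(synth_spec(n_samples = 70, n_relevant = 2,
                                       n_irrelevant = 6, seed = 73))
  r1 <- double_cv(sim$data, variants = "mT", protocol = small_protocol(seed = 73),
                  rounds = 3)
  r2 <- double_cv(sim$data, variants = "mT", protocol = small_protocol(seed = 73),
                  rounds = 3)
  attr(r1, "splits") <- attr(r2, "splits") <- NULL
  expect_identical(r1, r2)
})

test_that("no information leaks from the validation portion", {
  # on label-free noise the external G-Mean must sit at (or below) the
  # chance level; selection or tuning that saw the validation labels would
  # inflate it
  gms <- vapply(1:15, function(s) {
    spec <- synth_spec(n_samples = 60, n_relevant = 0,
                       copies_per_relevant = 0, n_irrelevant = 8,
                       label_noise = 0, seed = 700 + s)
    sim <- simulate_fragments(spec)
    rec <- double_cv(sim$data, variants = "mT",
                     protocol = small_protocol(rounds = 1, seed = 700 + s),
                     rounds = 3)
    mean(rec$g_mean)
  }, numeric(1))
  se <- stats::sd(gms) / sqrt(length(gms))
  expect_lte(mean(gms), 0.5 + 3 * se)
})

test_that("rank tables rank best = 1 with average-rank ties", {
  vals <- matrix(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4), 3, 2,
                 dimnames = list(paste0("D", 1:3), c("A", "B")))
  rt <- build_rank_table(vals)
  expect_equal(unname(rt$avg_ranks), c(1, 2))

  tie <- matrix(c(0.5, 0.5), 1, 2,
                dimnames = list("D1", c("A", "B")))
  expect_equal(unname(build_rank_table(tie)$avg_ranks), c(1.5, 1.5))

  # random matrices against an independent sort-based oracle
  set.seed(74)
  for (rep in 1:10) {
    m <- matrix(runif(5 * 24), 24, 5)
    rt <- build_rank_table(m)
    for (d in 1:24) {
      oracle <- match(seq_len(5), order(-m[d, ]))
      expect_equal(unname(rt$ranks[d, ]), oracle)
    }
    expect_equal(unname(rowSums(rt$ranks)), rep(15, 24))  # k(k+1)/2
  }
})

test_that("rank tables aggregate run records and flag missing cells", {
  rec <- data.frame(
    dataset = rep(c("a", "b"), each = 4),
    variant = rep(c("mT", "T"), 4),
    g_mean = c(0.9, 0.5, 0.8, 0.6, 0.4, 0.7, 0.5, 0.9)
  )
  rt <- build_rank_table(rec)
  expect_equal(unname(rt$values["a", c("mT", "T")]), c(0.85, 0.55))
  expect_equal(unname(rt$ranks["a", c("mT", "T")]), c(1, 2))
  expect_equal(unname(rt$ranks["b", c("mT", "T")]), c(2, 1))
  expect_error(build_rank_table(rec[rec$variant == "mT" | rec$dataset == "a", ]),
               "missing")
  # redundancy metrics rank low values best
  rt_min <- build_rank_table(rec, minimize = TRUE)
  expect_equal(unname(rt_min$ranks["a", c("mT", "T")]), c(2, 1))
})

test_that("the svm and rf grids carry the documented combinations", {
  expect_equal(nrow(default_hyper_grid("svm")), 21)
  expect_equal(sum(default_hyper_grid("svm")$kernel == "linear"), 3)
  expect_equal(default_hyper_grid("rf")$ntree, 100L)
  expect_equal(nrow(default_hyper_grid("dt")), 4)
})
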