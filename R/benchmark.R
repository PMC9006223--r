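# Repeated double cross-validation: outer rounds of stratified random
# build/validation splits, with feature selection and inner k-fold
# hyperparameter tuning confined to the build portion, and all metrics
# measured on the untouched validation portion.

#' Default hyperparameter grid for a classifier family
#'
#' dt: pruning on/off x committee size {1, 10} (4 combinations).
#' rf: fixed 100 fully grown trees (1 combination).
#' svm: linear kernel with C in \{0.1, 1, 10\} plus Gaussian kernel with the
#' same C values crossed with gamma in \{1e-4, 1e-3, 1e-2, 0.1, 1, 10\}
#' (21 combinations).
#'
#' @param family `"dt"`, `"rf"` or `"svm"`.
#' @return a data.frame, one row per hyperparameter combination.
#' @export
default_hyper_grid <- function(family = c("dt", "rf", "svm")) {
  family <- match.arg(family)
  switch(family,
    dt = expand.grid(prune = c(TRUE, FALSE), trials = c(1L, 10L),
                     KEEP.OUT.ATTRS = FALSE),
    rf = data.frame(ntree = 100L),
    svm = rbind(
      data.frame(kernel = "linear", cost = c(0.1, 1, 10), gamma = NA_real_),
      expand.grid(kernel = "radial", cost = c(0.1, 1, 10),
                  gamma = c(1e-4, 1e-3, 1e-2, 0.1, 1, 10),
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    )
  )
}

#' Double cross-validation protocol configuration
#'
#' @param external_rounds outer build/validation rounds (default 5).
#' @param inner_folds folds of the inner hyperparameter-tuning CV
#'   (default 10).
#' @param split_fraction fraction of samples in the build portion.
#' @param classifier classifier family evaluated externally
#'   (`"dt"`, `"rf"`, `"svm"`).
#' @param hyper_grid data.frame of hyperparameter combinations
#'   (defaults to [default_hyper_grid()] for the family).
#' @param seed integer seed for splits and folds.
#' @return an object of class `protocol_config`.
#' @export
protocol_config <- function(external_rounds = 5L, inner_folds = 10L,
                            split_fraction = 0.5,
                            classifier = c("dt", "rf", "svm"),
                            hyper_grid = NULL, seed = 1L) {
  classifier <- match.arg(classifier)
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must be in (0, 1)")
  }
  structure(
    list(external_rounds = as.integer(external_rounds),
         inner_folds = as.integer(inner_folds),
         split_fraction = split_fraction,
         classifier = classifier,
         hyper_grid = hyper_grid %||% default_hyper_grid(classifier),
         seed = as.integer(seed)),
    class = "protocol_config"
  )
}

grid_row_params <- function(grid, i) {
  p <- as.list(grid[i, , drop = FALSE])
  p <- p[!vapply(p, function(v) is.na(v) || is.null(v), logical(1))]
  lapply(p, function(v) if (is.factor(v)) as.character(v) else v)
}

# Inner-CV G-Mean of one hyperparameter combination on (x, y) restricted to
# `idx`; confusion pooled over folds.
inner_gmean <- function(ev, idx, x, y, folds, seed) {
  cc <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- fit_evaluator(ev, x[tr, idx, drop = FALSE], y[tr], seed = seed)
    pred <- predict_evaluator(fit, x[!tr, idx, drop = FALSE])
    truth <- y[!tr]
    cc["tp"] <- cc["tp"] + sum(truth == 1 & pred == 1)
    cc["tn"] <- cc["tn"] + sum(truth == 0 & pred == 0)
    cc["fp"] <- cc["fp"] + sum(truth == 0 & pred == 1)
    cc["fn"] <- cc["fn"] + sum(truth == 1 & pred == 0)
  }
  g_mean(confusion_counts(cc["tp"], cc["tn"], cc["fp"], cc["fn"]))
}

#' Repeated double cross-validation of the selection variants
#'
#' For each external round the data are split (stratified) into disjoint
#' build and validation portions; the boosting ensemble runs on the build
#' portion only, every requested variant (including the voting baseline
#' `"T"`) extracts its subset from the shared graph, the classifier's
#' hyperparameters are tuned by stratified inner CV on the build portion
#' (model selection by G-Mean), and the final model — fit on the build
#' portion with the chosen hyperparameters and selected features — is
#' scored on the validation portion.
#'
#' @param data a `feature_matrix`.
#' @param variants variants to evaluate (subset of mT, MmT, mTC, MmTC, T).
#' @param protocol a [protocol_config()].
#' @param dataset_id identifier recorded in the result rows.
#' @param rounds,weighting,base_selector,base_params,j_weight,max_levels,sel_folds
#'   ensemble and J-optimization settings (see [gfs()]); `sel_folds` is the
#'   internal fold count of the kappa estimate inside J.
#' @param sel_ev evaluator used inside the selection search (a fast decision
#'   tree by default, independent of the externally tuned classifier).
#' @return a data.frame of run records (one row per variant x round) with
#'   the external metrics; the build/validation index sets of each round are
#'   attached as attribute `"splits"`.
#' @export
double_cv <- function(data, variants = c("mT", "MmT", "mTC", "MmTC", "T"),
                      protocol = protocol_config(), dataset_id = "DS",
                      rounds = 10L, weighting = "adaboost",
                      base_selector = "fast", base_params = list(),
                      j_weight = 0.5, max_levels = 20L, sel_folds = 5L,
                      sel_ev = evaluator("dt")) {
  stopifnot(inherits(data, "feature_matrix"),
            inherits(protocol, "protocol_config"))
  x <- data$x; y <- data$y
  if (length(unique(y)) < 2) stop("both classes must be present")
  grid <- protocol$hyper_grid
  records <- list()
  splits <- list()

  for (r in seq_len(protocol$external_rounds)) {
    round_seed <- protocol$seed + 1000L * r
    build <- stratified_split(y, protocol$split_fraction, round_seed)
    val <- setdiff(seq_len(nrow(x)), build)
    if (length(unique(y[build])) < 2 || length(unique(y[val])) < 2) {
      stop("stratification failure in round ", r)
    }
    splits[[r]] <- list(build = build, val = val)
    xb <- x[build, , drop = FALSE]; yb <- y[build]
    xv <- x[val, , drop = FALSE]; yv <- y[val]

    fit <- gfs(xb, yb, variants = variants, rounds = rounds,
               weighting = weighting, ev = sel_ev, j_weight = j_weight,
               max_levels = max_levels, inner_folds = sel_folds,
               base_selector = base_selector, base_params = base_params,
               seed = round_seed)

    folds <- stratified_folds(yb, protocol$inner_folds, round_seed)
    for (v in variants) {
      sel <- fit$results[[v]]$selected
      scores <- vapply(seq_len(nrow(grid)), function(i) {
        ev <- evaluator(protocol$classifier, grid_row_params(grid, i))
        inner_gmean(ev, sel, xb, yb, folds, round_seed)
      }, numeric(1))
      best <- which.max(scores)
      ev <- evaluator(protocol$classifier, grid_row_params(grid, best))
      model <- fit_evaluator(ev, xb[, sel, drop = FALSE], yb,
                             seed = round_seed)
      pred <- predict_evaluator(model, xv[, sel, drop = FALSE])
      rep0 <- metrics_report(yv, pred, sel, xv)
      records[[length(records) + 1]] <- cbind(
        data.frame(dataset = dataset_id, variant = v,
                   classifier = protocol$classifier, round = r,
                   params = paste(names(grid_row_params(grid, best)),
                                  unlist(grid_row_params(grid, best)),
                                  sep = "=", collapse = ";")),
        rep0
      )
    }
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  attr(out, "splits") <- splits
  out
}

#' Rank table of algorithms across datasets
#'
#' Cell values are the per-(dataset, algorithm) means of `metric` over
#' external rounds; within each dataset, rank 1 goes to the best algorithm
#' (largest value, or smallest when `minimize = TRUE`), ties receiving
#' average ranks.
#'
#' @param records a data.frame of run records from [double_cv()] (possibly
#'   concatenated over datasets), or a datasets x algorithms value matrix.
#' @param metric column to rank on (ignored for a matrix input).
#' @param minimize rank smaller values as better (for redundancy metrics).
#' @return an object of class `rank_table` with components `values`,
#'   `ranks` (both datasets x algorithms), `avg_ranks`, `algorithms`,
#'   `datasets`.
#' @export
build_rank_table <- function(records, metric = "g_mean", minimize = FALSE) {
  if (is.matrix(records)) {
    values <- records
    if (is.null(colnames(values))) {
      colnames(values) <- paste0("A", seq_len(ncol(values)))
    }
    if (is.null(rownames(values))) {
      rownames(values) <- paste0("D", seq_len(nrow(values)))
    }
  } else {
    if (!metric %in% names(records)) stop("unknown metric column: ", metric)
    agg <- stats::aggregate(records[[metric]],
                            by = list(dataset = records$dataset,
                                      variant = records$variant),
                            FUN = mean)
    values <- stats::xtabs(x ~ dataset + variant, data = agg)
    full <- stats::xtabs(~ dataset + variant, data = agg)
    if (any(full == 0)) stop("missing (dataset, variant) cell in the records")
    values <- matrix(values, nrow = nrow(values),
                     dimnames = dimnames(values))
  }
  ranks <- t(apply(values, 1, function(row) {
    v <- if (minimize) row else -row
    rank(v, ties.method = "average")
  }))
  dimnames(ranks) <- dimnames(values)
  structure(
    list(values = values, ranks = ranks,
         avg_ranks = colMeans(ranks),
         algorithms = colnames(values), datasets = rownames(values)),
    class = "rank_table"
  )
}

#' @export
print.rank_table <- function(x, ...) {
  cat(sprintf("Rank table: %d algorithms x %d datasets\n",
              length(x$algorithms), length(x$datasets)))
  print(round(x$avg_ranks, 3))
  invisible(x)
}
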