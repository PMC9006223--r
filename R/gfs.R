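# The user-facing fitting function: one call runs the boosting ensemble,
# accumulates the co-selection graph, and extracts the J-optimal subset for
# each requested combination variant (the four graph strategies plus the
# vote-threshold baseline T).

#' Graph-based ensemble feature selection
#'
#' Runs `rounds` boosting rounds of the base subset selector (FAST by
#' default), accumulating every round's selection — weighted by the round's
#' AdaBoost weight — in an undirected co-selection graph.  Final subsets are
#' then extracted from the single shared graph by each requested variant:
#' \describe{
#'   \item{mT}{threshold strategy, vertex threshold fixed at 0;}
#'   \item{MmT}{threshold strategy, both thresholds free;}
#'   \item{mTC}{chain strategy, vertex threshold fixed at 0;}
#'   \item{MmTC}{chain strategy, both thresholds free;}
#'   \item{T}{standard vote-threshold baseline on the vertex values.}
#' }
#' Each variant's threshold pair is chosen to maximize
#' `J = j_weight * kappa + (1 - j_weight) * r`, where kappa is Cohen's kappa
#' of the evaluator under stratified internal cross-validation restricted to
#' the candidate subset and `r = 1 - m/M` is the reduction.
#'
#' @param x numeric feature matrix (samples x features), nonnegative; or a
#'   `feature_matrix` from [read_matrix()] / [simulate_fragments()] (then
#'   `y` is taken from it).
#' @param y binary labels (0/1); ignored when `x` is a `feature_matrix`.
#' @param variants character vector of combination variants to extract.
#' @param rounds boosting rounds Tr.
#' @param weighting `"adaboost"` or `"uniform"` round weights.
#' @param ev evaluator spec (see [evaluator()]) used both for the round
#'   errors and inside J.
#' @param j_weight weight of kappa versus reduction in J.
#' @param max_levels cap on threshold-grid levels per axis.
#' @param inner_folds folds of the internal CV estimating kappa.
#' @param base_selector,base_params registered base selector and its
#'   parameters.
#' @param seed integer seed governing all randomness of the fit.
#' @return an object of class `gfs`: a list with the fitted `graph`,
#'   `votes`, per-round records `rounds`, a named list `results` of
#'   `selection_result`s, and the training data.
#' @examples
#' sim <- simulate_fragments(synth_spec(n_samples = 80, n_relevant = 2,
#'   copies_per_relevant = 1, n_irrelevant = 8, seed = 7))
#' fit <- gfs(sim$data, variants = c("mT", "T"), rounds = 3, seed = 7)
#' summary(fit)
#' coef(fit, variant = "mT")
#' @export
gfs <- function(x, y = NULL,
                variants = c("mT", "MmT", "mTC", "MmTC", "T"),
                rounds = 10L, weighting = "adaboost",
                ev = evaluator("dt"), j_weight = 0.5, max_levels = 20L,
                inner_folds = 5L, base_selector = "fast",
                base_params = list(), seed = 1L) {
  cl <- match.call()
  if (inherits(x, "feature_matrix")) {
    y <- x$y
    feature_names <- x$feature_names
    x <- x$x
  } else {
    x <- as.matrix(x)
    feature_names <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  }
  if (is.null(y)) stop("labels are required")
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  variants <- match.arg(variants, several.ok = TRUE)
  ev <- as_evaluator(ev)

  config <- ensemble_config(rounds = rounds, weighting = weighting,
                            base_selector = base_selector,
                            base_params = base_params, ev = ev, seed = seed)
  ens <- run_ensemble(x, y, config)

  results <- list()
  for (v in variants) {
    results[[v]] <- if (v == "T") {
      voting_baseline(ens$votes, x, y, ev, j_weight = j_weight,
                      max_levels = max_levels, inner_folds = inner_folds,
                      seed = seed)
    } else {
      optimize_selection(ens$graph, v, x, y, ev, j_weight = j_weight,
                         max_levels = max_levels, inner_folds = inner_folds,
                         seed = seed)
    }
  }

  structure(
    list(call = cl, graph = ens$graph, votes = ens$votes,
         rounds = ens$rounds, results = results,
         x = x, y = y, feature_names = feature_names,
         ev = ev, j_weight = j_weight, seed = seed),
    class = "gfs"
  )
}

#' @export
print.gfs <- function(x, ...) {
  cat("Graph-based ensemble feature selection\n")
  cat(sprintf("  %d samples, %d features, %d boosting rounds\n",
              nrow(x$x), ncol(x$x), length(x$rounds)))
  for (res in x$results) print(res)
  invisible(x)
}

#' @export
summary.gfs <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$results, function(r) {
    data.frame(variant = r$variant, m = length(r$selected),
               tau_v = r$tau_v, tau_e = r$tau_e,
               J = r$j_value, kappa = r$kappa, reduction = r$reduction)
  }))
  rownames(tab) <- NULL
  alphas <- vapply(object$rounds, `[[`, numeric(1), "alpha")
  errors <- vapply(object$rounds, `[[`, numeric(1), "error")
  out <- list(variants = tab,
              round_alphas = alphas, round_errors = errors,
              n = nrow(object$x), M = ncol(object$x))
  class(out) <- "summary.gfs"
  out
}

#' @export
print.summary.gfs <- function(x, ...) {
  cat(sprintf("Graph-based feature selection on %d samples x %d features\n",
              x$n, x$M))
  cat(sprintf("Boosting rounds: %d (mean error %.3f, mean alpha %.3f)\n\n",
              length(x$round_alphas), mean(x$round_errors),
              mean(x$round_alphas)))
  print(x$variants, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Selected features of a fitted variant
#'
#' @param object a fitted `gfs` object.
#' @param variant which variant's selection to return; `"best"` (default)
#'   picks the variant with the highest J.
#' @param ... unused.
#' @return named numeric vector: the vote (vertex) values of the selected
#'   features, named by feature, in index order.
#' @export
coef.gfs <- function(object, variant = "best", ...) {
  res <- pick_variant(object, variant)
  stats::setNames(object$votes[res$selected],
                  object$feature_names[res$selected])
}

pick_variant <- function(object, variant) {
  if (identical(variant, "best")) {
    js <- vapply(object$results, `[[`, numeric(1), "j_value")
    object$results[[which.max(js)]]
  } else {
    res <- object$results[[variant]]
    if (is.null(res)) stop("variant not fitted: ", variant)
    res
  }
}

#' Predict with a classifier refit on the selected features
#'
#' Refits the fit's evaluator on the full training data restricted to the
#' chosen variant's selected features, then predicts the new samples.
#'
#' @param object a fitted `gfs` object.
#' @param newdata matrix with the same feature columns as the training data.
#' @param variant variant whose selection to use (`"best"` by default).
#' @param ... unused.
#' @return integer vector of 0/1 predicted labels.
#' @export
predict.gfs <- function(object, newdata, variant = "best", ...) {
  res <- pick_variant(object, variant)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x)) stop("feature count mismatch")
  fit <- fit_evaluator(object$ev, object$x[, res$selected, drop = FALSE],
                       object$y, seed = object$seed)
  predict_evaluator(fit, newdata[, res$selected, drop = FALSE])
}

#' Plot a fitted selection
#'
#' Barplot of the vote (vertex) values with the chosen variant's selected
#' features highlighted and its vertex threshold drawn as a horizontal
#' line.
#'
#' @param x a fitted `gfs` object.
#' @param variant variant to highlight (`"best"` by default).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.gfs <- function(x, variant = "best", ...) {
  res <- pick_variant(x, variant)
  cols <- rep("grey70", length(x$votes))
  cols[res$selected] <- "firebrick"
  graphics::barplot(x$votes, col = cols, border = NA,
                    xlab = "feature", ylab = "weighted votes",
                    main = sprintf("%s selection (%d of %d features)",
                                   res$variant, length(res$selected),
                                   length(x$votes)), ...)
  if (res$tau_v > 0) graphics::abline(h = res$tau_v, lty = 2)
  invisible(x)
}
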