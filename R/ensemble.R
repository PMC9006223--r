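# Boosting ensemble driver.  Each round draws a weight-proportional
# bootstrap resample (the base selector takes no instance weights), runs the
# base selector on it, measures the weighted error of the evaluator trained
# on the selected features, derives the round weight alpha_t, updates the
# instance weights as in discrete AdaBoost, and records the selection into
# the co-selection graph and the companion vote vector with weight alpha_t.

#' Ensemble configuration
#'
#' @param rounds number of boosting rounds Tr (>= 1).
#' @param weighting `"adaboost"` (`alpha_t = log((1 - e_t) / e_t)`, clipped
#'   to `[0, alpha_max]`) or `"uniform"` (`alpha_t = 1`).
#' @param base_selector name of a registered base selector (default
#'   `"fast"`).
#' @param base_params named list of parameters handed to the base selector.
#' @param ev evaluator spec used to compute round errors.
#' @param alpha_max clip bound for adaboost round weights.
#' @param seed integer RNG seed.
#' @return an object of class `ensemble_config`.
#' @export
ensemble_config <- function(rounds = 10L, weighting = c("adaboost", "uniform"),
                            base_selector = "fast", base_params = list(),
                            ev = evaluator("dt"), alpha_max = 10,
                            seed = 1L) {
  weighting <- match.arg(weighting)
  rounds <- as.integer(rounds)
  if (is.na(rounds) || rounds < 1) stop("rounds must be >= 1")
  structure(
    list(rounds = rounds, weighting = weighting,
         base_selector = base_selector, base_params = base_params,
         ev = as_evaluator(ev), alpha_max = alpha_max,
         seed = as.integer(seed)),
    class = "ensemble_config"
  )
}

#' Run the feature-selection boosting ensemble
#'
#' @param x numeric feature matrix (samples x features).
#' @param y binary labels (0/1).
#' @param config an [ensemble_config()].
#' @return a list with components `graph` (the accumulated
#'   `selection_graph`), `votes` (the companion vote vector; always equal to
#'   the graph's vertex values), and `rounds` (a list of per-round records
#'   with `round`, `selected`, `alpha`, `error`).
#' @export
run_ensemble <- function(x, y, config = ensemble_config()) {
  stopifnot(inherits(config, "ensemble_config"))
  x <- as.matrix(x)
  n <- nrow(x); M <- ncol(x)
  if (length(y) != n) stop("label length mismatch")
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  selector <- get_base_selector(config$base_selector)

  graph <- selection_graph(M)
  rounds <- vector("list", config$rounds)
  w <- rep(1 / n, n)

  with_seed(config$seed, {
    for (t in seq_len(config$rounds)) {
      # weight-proportional bootstrap; redraw if a class goes missing
      idx <- NULL
      for (try in 1:10) {
        cand <- sample.int(n, n, replace = TRUE, prob = w)
        if (length(unique(y[cand])) == 2) { idx <- cand; break }
      }
      if (is.null(idx)) stop("degenerate single-class resample in round ", t)

      sel <- sort(selector(x[idx, , drop = FALSE], y[idx],
                           config$base_params, seed = config$seed + t))
      fit <- fit_evaluator(config$ev, x[idx, sel, drop = FALSE], y[idx],
                           seed = config$seed + t)
      pred <- predict_evaluator(fit, x[, sel, drop = FALSE])
      mis <- pred != y
      eps <- sum(w[mis])

      if (config$weighting == "uniform") {
        alpha <- 1
      } else if (eps <= 0) {
        alpha <- config$alpha_max
      } else if (eps >= 0.5) {
        alpha <- 0
      } else {
        alpha <- min(log((1 - eps) / eps), config$alpha_max)
      }

      graph <- record_selection(graph, sel, alpha)
      rounds[[t]] <- list(round = t, selected = sel, alpha = alpha, error = eps)

      if (eps <= 0 || eps >= 0.5) {
        w <- rep(1 / n, n)           # degenerate round: restart the weights
      } else {
        w[mis] <- w[mis] * exp(min(log((1 - eps) / eps), config$alpha_max))
        w <- w / sum(w)
      }
    }
  })
  list(graph = graph, votes = graph$v, rounds = rounds)
}
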