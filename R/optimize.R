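# Threshold-pair optimization: for each admissible (tau_v, tau_e) pair the
# graph yields a candidate subset; the subset is scored by
# J = w * kappa + (1 - w) * r, with kappa from stratified internal CV of the
# evaluator and r the reduction.  The pair maximizing J wins.

#' Selection result
#'
#' @param variant variant name (`"mT"`, `"MmT"`, `"mTC"`, `"MmTC"`, `"T"`).
#' @param tau_v,tau_e the winning threshold pair (vote threshold in `tau_v`
#'   for the voting baseline, `tau_e = 0` there).
#' @param selected sorted integer indices of the selected features.
#' @param j_value,kappa,reduction the criterion and its two components.
#' @return an object of class `selection_result`.
#' @export
selection_result <- function(variant, tau_v, tau_e, selected,
                             j_value, kappa, reduction) {
  structure(
    list(variant = variant, tau_v = tau_v, tau_e = tau_e,
         selected = sort(as.integer(selected)),
         j_value = j_value, kappa = kappa, reduction = reduction),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "%s selection: %d features (tau_v=%.4g, tau_e=%.4g)  J=%.4f  kappa=%.4f  r=%.4f\n",
    x$variant, length(x$selected), x$tau_v, x$tau_e,
    x$j_value, x$kappa, x$reduction))
  invisible(x)
}

# Score a list of candidate rows (tau_v, tau_e, selected-set) and return the
# winner under the tie rule: larger J, then larger r, then smaller tau_e,
# then smaller tau_v.  J is cached per distinct subset, so the result is
# identical to naive per-pair evaluation.
score_candidates <- function(cands, x, y, ev, folds, j_weight, seed) {
  M <- ncol(x)
  cache <- new.env(parent = emptyenv())
  n <- length(cands)
  J <- numeric(n); kap <- numeric(n); red <- numeric(n)
  tv <- numeric(n); te <- numeric(n)
  for (i in seq_len(n)) {
    sel <- cands[[i]]$selected
    key <- paste(sel, collapse = ",")
    if (!exists(key, envir = cache, inherits = FALSE)) {
      k <- cv_kappa(sel, x, y, ev, folds, seed = seed)
      r <- reduction(length(sel), M)
      assign(key, c(k = k, r = r), envir = cache)
    }
    kr <- get(key, envir = cache, inherits = FALSE)
    kap[i] <- kr["k"]; red[i] <- kr["r"]
    J[i] <- j_weight * kr["k"] + (1 - j_weight) * kr["r"]
    tv[i] <- cands[[i]]$tau_v; te[i] <- cands[[i]]$tau_e
  }
  best <- order(-J, -red, te, tv)[1]
  list(index = best, j = J[best], kappa = kap[best], r = red[best],
       tau_v = tv[best], tau_e = te[best], selected = cands[[best]]$selected)
}

#' Optimize the threshold pair of a graph-selection variant
#'
#' Enumerates the admissible threshold pairs of the variant (`tau_v` fixed
#' at 0 for `mT`/`mTC`), extracts the candidate subset for each via
#' [select_threshold()] (threshold strategies) or [select_chain()] (chain
#' strategies), scores each subset by `J = j_weight * kappa +
#' (1 - j_weight) * r` with kappa from stratified `inner_folds`-fold CV of
#' the evaluator on `x`/`y` (folds fixed by `seed` and shared across all
#' pairs), and returns the maximizer.  Ties go to the larger reduction, then
#' the smaller `tau_e`, then the smaller `tau_v`.
#'
#' @param graph a `selection_graph` accumulated over ensemble rounds.
#' @param variant `"mT"`, `"MmT"`, `"mTC"` or `"MmTC"`.
#' @param x training feature matrix (samples x features).
#' @param y binary labels (0/1).
#' @param ev evaluator spec (see [evaluator()]); default decision tree.
#' @param j_weight relative weight of kappa versus reduction in J (0.5).
#' @param max_levels threshold-grid cap per axis (see [grid_thresholds()]).
#' @param inner_folds folds of the internal CV used to estimate kappa.
#' @param seed RNG seed fixing the internal folds.
#' @param pairs optional data.frame (`tau_v`, `tau_e`) overriding the grid.
#' @return a `selection_result`.
#' @export
optimize_selection <- function(graph, variant = c("mT", "MmT", "mTC", "MmTC"),
                               x, y, ev = evaluator("dt"),
                               j_weight = 0.5, max_levels = 20L,
                               inner_folds = 5L, seed = 1L, pairs = NULL) {
  variant <- match.arg(variant)
  ev <- as_evaluator(ev)
  x <- as.matrix(x)
  if (ncol(x) != graph$M) stop("data and graph disagree on feature count")
  if (is.null(pairs)) pairs <- grid_thresholds(graph, max_levels)
  if (variant %in% c("mT", "mTC")) {
    pairs <- pairs[pairs$tau_v == 0, , drop = FALSE]
  }
  chain <- variant %in% c("mTC", "MmTC")
  cands <- list()
  for (r in seq_len(nrow(pairs))) {
    tv <- pairs$tau_v[r]; te <- pairs$tau_e[r]
    sel <- if (chain) {
      tryCatch(sort(select_chain(graph, tv, te)), error = function(e) integer(0))
    } else {
      select_threshold(graph, tv, te)
    }
    if (length(sel) > 0) {
      cands[[length(cands) + 1]] <- list(tau_v = tv, tau_e = te, selected = sel)
    }
  }
  if (length(cands) == 0) {
    stop("optimization failure: every threshold pair yields an empty selection")
  }
  folds <- stratified_folds(y, inner_folds, seed)
  best <- score_candidates(cands, x, y, ev, folds, j_weight, seed)
  selection_result(variant, best$tau_v, best$tau_e, best$selected,
                   best$j, best$kappa, best$r)
}

#' Standard vote-threshold baseline (T)
#'
#' The reference combiner: for each candidate vote threshold (0 plus the
#' distinct vote values, capped at `max_levels` equally spaced levels like
#' the graph grids) it forms the set of features with at least that many
#' (weighted) votes and scores it with the identical J procedure used by
#' [optimize_selection()] (same folds, same seed).  Equivalent to the
#' threshold strategy with `tau_e = 0`.
#'
#' @param votes numeric vote vector, one entry per feature.
#' @inheritParams optimize_selection
#' @return a `selection_result` with variant `"T"` (`tau_v` holding the
#'   winning vote threshold, `tau_e = 0`).
#' @export
voting_baseline <- function(votes, x, y, ev = evaluator("dt"),
                            j_weight = 0.5, max_levels = 20L,
                            inner_folds = 5L, seed = 1L) {
  if (length(votes) < 1) stop("empty vote vector")
  ev <- as_evaluator(ev)
  x <- as.matrix(x)
  if (ncol(x) != length(votes)) stop("data and votes disagree on feature count")
  thr <- sort(unique(c(0, votes)))
  if (length(thr) > max_levels) thr <- seq(0, max(votes), length.out = max_levels)
  cands <- list()
  for (t in thr) {
    sel <- which(votes >= t)
    if (length(sel) > 0) {
      cands[[length(cands) + 1]] <- list(tau_v = t, tau_e = 0, selected = sel)
    }
  }
  if (length(cands) == 0) stop("optimization failure: no nonempty vote set")
  folds <- stratified_folds(y, inner_folds, seed)
  best <- score_candidates(cands, x, y, ev, folds, j_weight, seed)
  selection_result("T", best$tau_v, best$tau_e, best$selected,
                   best$j, best$kappa, best$r)
}
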