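# The undirected co-selection graph: vertex values count (weighted)
# selections of each feature across ensemble rounds, edge values count joint
# selections of feature pairs.  Feature indices are 1-based throughout.

#' Create an empty co-selection graph
#'
#' @param M number of features (vertices), >= 1.
#' @return an object of class `selection_graph` with all vertex and edge
#'   values zero.  Internally the edge values are held in a dense symmetric
#'   M x M matrix with a zero diagonal; absent edges read as 0.
#' @export
selection_graph <- function(M) {
  M <- as.integer(M)
  if (is.na(M) || M < 1) stop("M must be a positive integer")
  structure(
    list(M = M, v = numeric(M), e = matrix(0, M, M)),
    class = "selection_graph"
  )
}

#' @export
print.selection_graph <- function(x, ...) {
  nz <- sum(x$e[upper.tri(x$e)] > 0)
  cat("Co-selection graph:", x$M, "features,",
      sum(x$v > 0), "with nonzero vertex value,",
      nz, "nonzero edges\n")
  invisible(x)
}

#' Record one round's selection into the graph
#'
#' Increases the vertex value of every selected feature and the edge value
#' of every unordered pair of selected features by `weight` (the boosting
#' round weight; 1 for unweighted voting).
#'
#' @param graph a `selection_graph`.
#' @param selected integer vector of selected feature indices (1-based).
#' @param weight nonnegative round weight.
#' @return the updated graph.
#' @export
record_selection <- function(graph, selected, weight = 1) {
  stopifnot(inherits(graph, "selection_graph"))
  selected <- unique(as.integer(selected))
  if (length(selected) < 1) stop("selection must contain at least one feature")
  if (any(selected < 1 | selected > graph$M)) stop("feature index out of range")
  if (!is.finite(weight) || weight < 0) stop("weight must be nonnegative")
  graph$v[selected] <- graph$v[selected] + weight
  if (length(selected) > 1) {
    graph$e[selected, selected] <- graph$e[selected, selected] + weight
    diag(graph$e)[selected] <- diag(graph$e)[selected] - weight
  }
  graph
}

#' Threshold-strategy feature selection (variants mT / MmT)
#'
#' Keeps features with vertex value at least `tau_v`, then sweeps every
#' unordered pair of survivors in ascending lexicographic order: if the
#' connecting edge value is below `tau_e`, the member with the smaller
#' vertex value is removed (the second member on ties).  A removed feature
#' takes part in no further pair checks.  With `tau_e = 0` no pair is ever
#' pruned, which reduces the strategy to a plain vote threshold.
#'
#' @param graph a `selection_graph`.
#' @param tau_v vertex threshold (>= 0).
#' @param tau_e edge threshold (>= 0).
#' @return sorted integer vector of surviving feature indices.
#' @export
select_threshold <- function(graph, tau_v, tau_e) {
  stopifnot(inherits(graph, "selection_graph"))
  if (!is.finite(tau_v) || !is.finite(tau_e) || tau_v < 0 || tau_e < 0) {
    stop("thresholds must be finite and nonnegative")
  }
  surv <- which(graph$v >= tau_v)
  k <- length(surv)
  if (k < 2) return(surv)
  alive <- rep(TRUE, k)
  for (a in seq_len(k - 1)) {
    if (!alive[a]) next
    for (b in seq((a + 1), k)) {
      if (!alive[a]) break
      if (!alive[b]) next
      i <- surv[a]; j <- surv[b]
      if (graph$e[i, j] < tau_e) {
        if (graph$v[i] < graph$v[j]) alive[a] <- FALSE else alive[b] <- FALSE
      }
    }
  }
  surv[alive]
}

#' Chain-strategy feature selection (variants mTC / MmTC)
#'
#' Candidate vertices are those with value at least `tau_v`.  The chain
#' starts at the candidate with the largest vertex value (smallest index on
#' ties); from the last selected vertex it repeatedly follows the strongest
#' edge of value at least `tau_e` leading to an unselected candidate
#' (smallest target index on ties), and stops when no such edge remains.
#'
#' @inheritParams select_threshold
#' @return integer vector of selected feature indices in chain order.
#' @export
select_chain <- function(graph, tau_v, tau_e) {
  stopifnot(inherits(graph, "selection_graph"))
  if (!is.finite(tau_v) || !is.finite(tau_e) || tau_v < 0 || tau_e < 0) {
    stop("thresholds must be finite and nonnegative")
  }
  cand <- which(graph$v >= tau_v)
  if (length(cand) == 0) stop("no feature passes the vertex threshold")
  start <- cand[which.max(graph$v[cand])]   # which.max takes the first max
  chain <- start
  in_chain <- logical(graph$M)
  in_chain[start] <- TRUE
  is_cand <- logical(graph$M)
  is_cand[cand] <- TRUE
  repeat {
    last <- chain[length(chain)]
    w <- graph$e[last, ]
    ok <- is_cand & !in_chain & w >= tau_e
    if (!any(ok)) break
    nxt <- which(ok)[which.max(w[ok])]
    chain <- c(chain, nxt)
    in_chain[nxt] <- TRUE
  }
  chain
}

#' Candidate threshold grid for a graph
#'
#' Vertex candidates are 0 plus the distinct vertex values; edge candidates
#' are 0 plus the distinct edge values.  A candidate list longer than
#' `max_levels` is replaced by `max_levels` equally spaced values spanning
#' `[0, max]`.  Returns the deduplicated cross product ordered by
#' (vertex, edge).
#'
#' @param graph a `selection_graph`.
#' @param max_levels maximum number of candidate levels per axis (>= 1).
#' @return a data.frame with columns `tau_v` and `tau_e`.
#' @export
grid_thresholds <- function(graph, max_levels = 20L) {
  stopifnot(inherits(graph, "selection_graph"))
  if (max_levels < 1) stop("max_levels must be >= 1")
  cap <- function(vals) {
    cands <- sort(unique(c(0, vals)))
    if (length(cands) > max_levels) {
      cands <- seq(0, max(vals), length.out = max_levels)
    }
    cands
  }
  vc <- cap(graph$v)
  ec <- cap(graph$e[upper.tri(graph$e)])
  out <- expand.grid(tau_e = ec, tau_v = vc,
                     KEEP.OUT.ATTRS = FALSE)[, c("tau_v", "tau_e")]
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Write a co-selection graph to JSON
#'
#' Nonzero vertex and edge values only; values are serialized as decimal
#' strings produced by full-precision `format` so that a reload is
#' bit-exact.
#'
#' @param graph a `selection_graph`.
#' @param path output file path (written atomically).
#' @return the path, invisibly.
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "selection_graph"))
  vi <- which(graph$v != 0)
  verts <- lapply(vi, function(i) {
    list(i, format(graph$v[i], digits = 17, scientific = FALSE))
  })
  ut <- which(upper.tri(graph$e) & graph$e != 0, arr.ind = TRUE)
  edges <- lapply(seq_len(nrow(ut)), function(r) {
    i <- ut[r, 1]; j <- ut[r, 2]
    list(i, j, format(graph$e[i, j], digits = 17, scientific = FALSE))
  })
  obj <- list(M = graph$M, vertices = verts, edges = edges)
  atomic_write(function(tmp) {
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA)
  }, path)
}

#' Read a co-selection graph from JSON
#'
#' @param path a file written by [write_graph()].
#' @return a `selection_graph`.
#' @export
read_graph <- function(path) {
  obj <- jsonlite::read_json(path)
  g <- selection_graph(obj$M)
  for (vv in obj$vertices) {
    g$v[vv[[1]]] <- as.numeric(vv[[2]])
  }
  for (ee in obj$edges) {
    i <- ee[[1]]; j <- ee[[2]]
    g$e[i, j] <- g$e[j, i] <- as.numeric(ee[[3]])
  }
  g
}
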