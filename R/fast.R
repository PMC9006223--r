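# FAST: fast clustering-based feature subset selection.  Features are first
# screened by symmetric uncertainty (SU) with the class; the survivors'
# complete SU-weighted graph is reduced to a maximum spanning tree; tree
# edges weaker than both endpoints' class relevance are cut; one
# representative (the most class-relevant feature) is kept per resulting
# cluster.

# Kruskal maximum spanning forest with a deterministic tie rule: edges are
# processed in order of decreasing weight, equal-weight edges in ascending
# (i, j).  Written here (rather than via a graph library) because the tie
# order is part of the algorithm's determinism contract.
max_spanning_tree <- function(n, edges) {
  if (n <= 1 || nrow(edges) == 0) {
    return(edges[0, , drop = FALSE])
  }
  ord <- order(-edges$w, edges$i, edges$j)
  edges <- edges[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  keep <- logical(nrow(edges))
  taken <- 0L
  for (r in seq_len(nrow(edges))) {
    ra <- find(edges$i[r]); rb <- find(edges$j[r])
    if (ra != rb) {
      parent[ra] <- rb
      keep[r] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  edges[keep, , drop = FALSE]
}

# Connected components of an undirected graph given as an edge list.
components_from_edges <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (r in seq_len(nrow(edges))) {
    ra <- find(edges$i[r]); rb <- find(edges$j[r])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1))
}

#' FAST feature subset selection
#'
#' Selects a nonredundant subset of features for a binary classification
#' problem: (1) features with class relevance `SU(f, y)` not exceeding
#' `relevance_threshold` are discarded; (2) the survivors' pairwise-SU
#' complete graph is reduced to a maximum spanning tree; (3) tree edges
#' whose SU is smaller than both endpoints' class relevance are removed;
#' (4) from each remaining connected component, the feature with maximal
#' class relevance is kept (smallest index on ties).
#'
#' @param x numeric matrix (samples x features), >= 2 features.
#' @param y binary labels (0/1).
#' @param relevance_threshold numeric SU cutoff, or `"auto"` for the rank
#'   heuristic: the SU of the `ceiling(sqrt(M) * log2(M))`-th ranked feature
#'   (clamped to the last rank).
#' @param bins equal-frequency bins used to discretize non-integer columns.
#' @return sorted integer vector of selected feature indices.
#' @export
fast_select <- function(x, y, relevance_threshold = "auto", bins = 5L) {
  x <- as.matrix(x)
  M <- ncol(x)
  if (M < 2) stop("need at least 2 features")
  disc <- lapply(seq_len(M), function(j) discretize(x[, j], bins))
  yd <- discretize(y, bins)
  su_class <- vapply(disc, function(d) su_discrete(d, yd), numeric(1))

  if (identical(relevance_threshold, "auto")) {
    k <- ceiling(sqrt(M) * log2(max(M, 2)))
    k <- min(max(1L, as.integer(k)), M)
    thr <- sort(su_class, decreasing = TRUE)[k]
    surv <- which(su_class >= thr & su_class > 0)
    if (length(surv) == 0) surv <- which(su_class > 0)
  } else {
    surv <- which(su_class > relevance_threshold)
  }
  if (length(surv) == 0) stop("no feature passes the relevance threshold")
  if (length(surv) == 1) return(surv)

  ns <- length(surv)
  pr <- utils::combn(ns, 2)
  w <- vapply(seq_len(ncol(pr)), function(c0) {
    su_discrete(disc[[surv[pr[1, c0]]]], disc[[surv[pr[2, c0]]]])
  }, numeric(1))
  edges <- data.frame(i = pr[1, ], j = pr[2, ], w = w)

  tree <- max_spanning_tree(ns, edges)
  rel <- su_class[surv]
  strong <- tree[!(tree$w < rel[tree$i] & tree$w < rel[tree$j]), , drop = FALSE]
  comp <- components_from_edges(ns, strong)
  kept <- vapply(unique(comp), function(cc) {
    members <- which(comp == cc)
    members[which.max(rel[members])]
  }, integer(1))
  sort(surv[kept])
}

# SU on already-discretized integer codes (no re-binning).
su_discrete <- function(xi, yi) {
  j <- joint_counts(xi, yi)
  p <- j / sum(j)
  hx <- entropy_bits(rowSums(p))
  hy <- entropy_bits(colSums(p))
  if (hx + hy == 0) return(0)
  mi <- max(hx + hy - entropy_bits(as.vector(p)), 0)
  min(2 * mi / (hx + hy), 1)
}

# --- base-selector plug-in registry ----------------------------------------

base_selector_registry <- new.env(parent = emptyenv())

#' Register a base feature selector
#'
#' A base selector is a function `(x, y, params, seed) -> integer indices`
#' applied once per ensemble round.  The `"fast"` selector ships
#' preregistered; others (ReliefF, information gain, ...) can be plugged in
#' by name.
#'
#' @param name selector name.
#' @param fn the selector function.
#' @export
register_base_selector <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = base_selector_registry)
  invisible(name)
}

#' Look up a registered base selector
#'
#' @param name selector name.
#' @return the selector function.
#' @export
get_base_selector <- function(name) {
  if (!exists(name, envir = base_selector_registry, inherits = FALSE)) {
    stop("unknown base selector: ", name)
  }
  get(name, envir = base_selector_registry, inherits = FALSE)
}

.onLoad <- function(libname, pkgname) {
  register_base_selector("fast", function(x, y, params, seed) {
    fast_select(x, y,
                relevance_threshold = params$relevance_threshold %||% "auto",
                bins = params$bins %||% 5L)
  })
}
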