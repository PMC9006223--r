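# Independent straight-line oracles used by the unit and acceptance tests.
# These re-simulate the stated selection rules directly and are kept free of
# the package's optimized/cached code paths.

# Random co-selection graph with small integer values (symmetric edge
# matrix, zero diagonal).
random_graph <- function(M, maxval = 5L) {
  g <- selection_graph(M)
  g$v <- as.numeric(sample(0:maxval, M, replace = TRUE))
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      g$e[i, j] <- g$e[j, i] <- sample(0:maxval, 1)
    }
  }
  g
}

# Literal transcription of the threshold strategy: vertex cut, then a single
# left-to-right sweep over pairs of the post-cut set in ascending (i, j),
# weak-edge pairs dropping the smaller-vertex member (the second on ties),
# removed features skipped thereafter.
oracle_select_threshold <- function(v, e, tau_v, tau_e) {
  surv <- which(v >= tau_v)
  removed <- c()
  for (i in surv) {
    for (j in surv[surv > i]) {
      if (i %in% removed || j %in% removed) next
      if (e[i, j] < tau_e) {
        if (v[i] < v[j]) removed <- c(removed, i) else removed <- c(removed, j)
      }
    }
  }
  setdiff(surv, removed)
}

# Literal transcription of the chain strategy.
oracle_select_chain <- function(v, e, tau_v, tau_e) {
  cand <- which(v >= tau_v)
  if (length(cand) == 0) return(NULL)
  best <- cand[order(-v[cand], cand)][1]
  chain <- best
  repeat {
    last <- chain[length(chain)]
    nxts <- setdiff(cand, chain)
    nxts <- nxts[e[last, nxts] >= tau_e]
    if (length(nxts) == 0) break
    nxt <- nxts[order(-e[last, nxts], nxts)][1]
    chain <- c(chain, nxt)
  }
  chain
}

# All admissible threshold pairs of a small graph, uncapped.
oracle_pairs <- function(g) {
  expand.grid(tau_v = sort(unique(c(0, g$v))),
              tau_e = sort(unique(c(0, g$e[upper.tri(g$e)]))))
}

# Exhaustive maximum-spanning-tree FAST reference for <= 7 features.
# Assumes all pairwise SU values are distinct so the tree is unique.
oracle_fast <- function(x, y, relevance_threshold) {
  M <- ncol(x)
  su_c <- vapply(seq_len(M), function(j) symmetric_uncertainty(x[, j], y),
                 numeric(1))
  surv <- which(su_c > relevance_threshold)
  if (length(surv) <= 1) return(surv)
  ns <- length(surv)
  prs <- utils::combn(ns, 2)
  w <- vapply(seq_len(ncol(prs)), function(c0) {
    symmetric_uncertainty(x[, surv[prs[1, c0]]], x[, surv[prs[2, c0]]])
  }, numeric(1))
  ne <- ncol(prs)
  best_w <- -Inf; best_tree <- NULL
  for (set in utils::combn(ne, ns - 1, simplify = FALSE)) {
    # is this edge subset a spanning tree? (connected on ns vertices)
    parent <- seq_len(ns)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    ok <- TRUE
    for (ei in set) {
      ra <- find(prs[1, ei]); rb <- find(prs[2, ei])
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (!ok) next
    tw <- sum(w[set])
    if (tw > best_w) { best_w <- tw; best_tree <- set }
  }
  rel <- su_c[surv]
  keep_edges <- best_tree[!(w[best_tree] < rel[prs[1, best_tree]] &
                              w[best_tree] < rel[prs[2, best_tree]])]
  parent <- seq_len(ns)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (ei in keep_edges) {
    ra <- find(prs[1, ei]); rb <- find(prs[2, ei])
    if (ra != rb) parent[ra] <- rb
  }
  comp <- vapply(seq_len(ns), find, integer(1))
  kept <- vapply(unique(comp), function(cc) {
    members <- which(comp == cc)
    members[which.max(rel[members])]
  }, integer(1))
  sort(surv[kept])
}

# Small balanced dataset with one perfectly predictive feature (column 1)
# and noise features; used across ensemble/selection tests.
toy_data <- function(n = 60, M = 6, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rbinom(n * M, 1, 0.4), n, M)
  x[, 1] <- y
  list(x = x, y = y)
}
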