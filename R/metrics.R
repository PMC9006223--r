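# Evaluation metrics: G-Mean, Cohen's kappa, reduction, mutual information,
# symmetric uncertainty, redundancy (MI- and correlation-based), and the
# coefficient of variation.  All information quantities are in bits (log2).

#' Confusion counts
#'
#' Lightweight container for a 2x2 confusion table of a binary classifier,
#' with the positive class taken as class 1.
#'
#' @param tp,tn,fp,fn nonnegative integer counts of true positives, true
#'   negatives, false positives and false negatives.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be nonnegative integers")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' Confusion counts from label vectors
#'
#' @param truth,pred binary vectors (0/1) of true and predicted labels.
#' @return a `confusion_counts` object.
#' @export
confusion_from_labels <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("length mismatch")
  confusion_counts(
    tp = sum(truth == 1 & pred == 1),
    tn = sum(truth == 0 & pred == 0),
    fp = sum(truth == 0 & pred == 1),
    fn = sum(truth == 1 & pred == 0)
  )
}

#' Geometric mean of sensitivity and specificity
#'
#' `sqrt(sensitivity * specificity)`, the usual headline metric for
#' imbalanced binary problems: a classifier that ignores the minority class
#' scores 0 regardless of raw accuracy.  A ratio with a zero denominator
#' (one class absent) is treated as 0.
#'
#' @param c a `confusion_counts` object.
#' @return G-Mean in \[0, 1\].
#' @export
g_mean <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  pos <- c$tp + c$fn
  neg <- c$tn + c$fp
  sens <- if (pos > 0) c$tp / pos else 0
  spec <- if (neg > 0) c$tn / neg else 0
  sqrt(sens * spec)
}

#' Cohen's kappa for a binary confusion table
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with `p_e` the
#' marginal-product chance agreement.  Returns 0 when `p_e == 1`
#' (degenerate one-cell table).
#'
#' @param c a `confusion_counts` object.
#' @return kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  n <- c$tp + c$tn + c$fp + c$fn
  if (n < 1) stop("empty confusion table")
  po <- (c$tp + c$tn) / n
  pe <- ((c$tp + c$fn) / n) * ((c$tp + c$fp) / n) +
    ((c$tn + c$fp) / n) * ((c$tn + c$fn) / n)
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(0)
  (po - pe) / (1 - pe)
}

#' Feature reduction
#'
#' Fraction of features eliminated by a selection: `1 - m / M`.
#'
#' @param m number of selected features.
#' @param M total number of features.
#' @return reduction in \[0, 1\].
#' @export
reduction <- function(m, M) {
  if (M < 1) stop("M must be >= 1")
  if (m < 0 || m > M) stop("m must satisfy 0 <= m <= M")
  1 - m / M
}

# Discretize a numeric vector for plug-in entropy estimation.  Integer-valued
# vectors (fragment counts) are used as-is; anything else is equal-frequency
# binned.  `bins` bounds the number of levels only in the continuous case.
discretize <- function(x, bins = 5L) {
  if (all(x == round(x))) return(as.integer(x))
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 1))
  if (length(qs) < 2) return(rep.int(0L, length(x)))
  as.integer(cut(x, breaks = qs, include.lowest = TRUE))
}

# Joint counts of two integer-coded vectors via a single tabulate pass.
joint_counts <- function(xi, yi) {
  ux <- sort(unique(xi)); uy <- sort(unique(yi))
  cx <- match(xi, ux); cy <- match(yi, uy)
  tab <- tabulate((cy - 1L) * length(ux) + cx, nbins = length(ux) * length(uy))
  matrix(tab, nrow = length(ux), ncol = length(uy))
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information (bits)
#'
#' Plug-in estimate `sum p(x,y) log2(p(x,y) / (p(x) p(y)))` over the observed
#' joint distribution of two discrete vectors; zero-probability cells
#' contribute 0.  Continuous inputs are equal-frequency binned first (see
#' `bins`).
#'
#' @param x,y vectors of equal length.
#' @param bins number of equal-frequency bins for non-integer inputs.
#' @return mutual information in bits, >= 0.
#' @export
mutual_information <- function(x, y, bins = 5L) {
  if (length(x) != length(y)) stop("length mismatch")
  j <- joint_counts(discretize(x, bins), discretize(y, bins))
  p <- j / sum(j)
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in seq_along(px)) {
    for (k in seq_along(py)) {
      if (p[i, k] > 0) mi <- mi + p[i, k] * log2(p[i, k] / (px[i] * py[k]))
    }
  }
  max(mi, 0)
}

#' Symmetric uncertainty
#'
#' Normalized mutual information `2 I(X;Y) / (H(X) + H(Y))` in \[0, 1\],
#' the edge and relevance weight used by the FAST feature-clustering
#' selector.  Defined as 0 when both entropies vanish (two constant
#' vectors).
#'
#' @inheritParams mutual_information
#' @return symmetric uncertainty in \[0, 1\].
#' @export
symmetric_uncertainty <- function(x, y, bins = 5L) {
  if (length(x) != length(y)) stop("length mismatch")
  j <- joint_counts(discretize(x, bins), discretize(y, bins))
  p <- j / sum(j)
  hx <- entropy_bits(rowSums(p))
  hy <- entropy_bits(colSums(p))
  if (hx + hy == 0) return(0)
  hxy <- entropy_bits(as.vector(p))
  mi <- max(hx + hy - hxy, 0)
  min(2 * mi / (hx + hy), 1)
}

#' Mutual-information redundancy of a feature set
#'
#' Mean pairwise mutual information (bits) over all unordered pairs of the
#' selected feature columns; 0 for a single feature.  Lower is less
#' redundant.
#'
#' @param m numeric matrix whose columns are the selected features.
#' @param bins number of equal-frequency bins for non-integer columns.
#' @return mean pairwise MI, >= 0.
#' @export
mi_redundancy <- function(m, bins = 5L) {
  m <- as.matrix(m)
  if (ncol(m) < 1) stop("empty feature set")
  if (ncol(m) == 1) return(0)
  disc <- lapply(seq_len(ncol(m)), function(j) discretize(m[, j], bins))
  pairs <- utils::combn(ncol(m), 2)
  vals <- apply(pairs, 2, function(pr) {
    jm <- joint_counts(disc[[pr[1]]], disc[[pr[2]]])
    p <- jm / sum(jm)
    px <- rowSums(p); py <- colSums(p)
    max(entropy_bits(px) + entropy_bits(py) - entropy_bits(as.vector(p)), 0)
  })
  mean(vals)
}

#' Correlation redundancy (AcRed)
#'
#' Mean absolute pairwise correlation over all unordered pairs of the
#' selected feature columns; 0 for a single feature.  A zero-variance column
#' contributes correlation 0 to each of its pairs.
#'
#' @param m numeric matrix whose columns are the selected features.
#' @param method correlation coefficient, `"pearson"` (default) or
#'   `"spearman"`.
#' @return mean absolute pairwise correlation in \[0, 1\].
#' @export
ac_red <- function(m, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- as.matrix(m)
  if (ncol(m) < 1) stop("empty feature set")
  if (ncol(m) == 1) return(0)
  sds <- apply(m, 2, stats::sd)
  pairs <- utils::combn(ncol(m), 2)
  vals <- apply(pairs, 2, function(pr) {
    if (sds[pr[1]] == 0 || sds[pr[2]] == 0) return(0)
    abs(stats::cor(m[, pr[1]], m[, pr[2]], method = method))
  })
  mean(vals)
}

#' Coefficient of variation
#'
#' `sigma / mu` with the population (divisor n) standard deviation.
#'
#' @param values numeric vector with nonzero mean.
#' @return the coefficient of variation.
#' @export
coefficient_of_variation <- function(values) {
  mu <- mean(values)
  if (mu == 0) stop("coefficient of variation undefined for zero mean")
  n <- length(values)
  sigma <- sqrt(sum((values - mu)^2) / n)
  sigma / mu
}

#' Full metrics report for one evaluated selection
#'
#' Bundles the external-validation metrics for one selected subset: G-Mean
#' and kappa of the classifier, reduction, and the two redundancy measures
#' computed on the selected columns of the evaluation data.
#'
#' @param truth,pred binary label vectors on the evaluation set.
#' @param selected integer indices of the selected features.
#' @param x the full feature matrix of the evaluation set (n x M).
#' @return a one-row data.frame with columns `g_mean`, `kappa`, `reduction`,
#'   `mi_red`, `ac_red`, `m`, `M`.
#' @export
metrics_report <- function(truth, pred, selected, x) {
  cc <- confusion_from_labels(truth, pred)
  sel <- x[, selected, drop = FALSE]
  data.frame(
    g_mean = g_mean(cc),
    kappa = cohen_kappa(cc),
    reduction = reduction(length(selected), ncol(x)),
    mi_red = mi_redundancy(sel),
    ac_red = ac_red(sel),
    m = length(selected),
    M = ncol(x)
  )
}
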