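# Synthetic fragment-occurrence data with planted structure: a handful of
# class-informative features, noisy duplicate copies of each (redundancy),
# and class-independent background features, under a configurable class
# imbalance.  Mimics sparse small-integer molecular fragment-count
# descriptors closely enough to exercise relevance, redundancy and
# imbalance handling; it has no real fragment co-occurrence chemistry.

#' Specification of a synthetic fragment-count dataset
#'
#' @param n_samples number of samples.
#' @param n_relevant number of planted class-informative features.
#' @param copies_per_relevant noisy duplicate copies planted per relevant
#'   feature (the redundancy structure).
#' @param n_irrelevant number of class-independent background features.
#' @param flip_noise per-entry corruption rate of each duplicate copy
#'   (in \[0, 0.5\]).
#' @param label_noise label flip rate applied after feature generation
#'   (in \[0, 0.5\]).
#' @param minority_fraction fraction of samples in the positive (minority)
#'   class, in (0, 0.5\].
#' @param count_mode `"binary"` presence/absence, or `"poisson-counts"`
#'   where each presence carries a small positive integer count.
#' @param p1,p0 presence probability of a relevant feature in the positive /
#'   negative class.
#' @param p_bg presence probability of an irrelevant feature (both classes).
#' @param seed integer RNG seed.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_samples = 300L, n_relevant = 6L,
                       copies_per_relevant = 1L, n_irrelevant = 48L,
                       flip_noise = 0.1, label_noise = 0.05,
                       minority_fraction = 0.5,
                       count_mode = c("binary", "poisson-counts"),
                       p1 = 0.8, p0 = 0.2, p_bg = 0.3, seed = 1L) {
  count_mode <- match.arg(count_mode)
  if (flip_noise < 0 || flip_noise > 0.5) stop("flip_noise must be in [0, 0.5]")
  if (label_noise < 0 || label_noise > 0.5) stop("label_noise must be in [0, 0.5]")
  if (minority_fraction <= 0 || minority_fraction > 0.5) {
    stop("minority_fraction must be in (0, 0.5]")
  }
  if (round(n_samples * minority_fraction) < 1) {
    stop("infeasible class counts: no positive sample")
  }
  structure(
    list(n_samples = as.integer(n_samples),
         n_relevant = as.integer(n_relevant),
         copies_per_relevant = as.integer(copies_per_relevant),
         n_irrelevant = as.integer(n_irrelevant),
         flip_noise = flip_noise, label_noise = label_noise,
         minority_fraction = minority_fraction,
         count_mode = count_mode, p1 = p1, p0 = p0, p_bg = p_bg,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

#' Generate a synthetic fragment-count dataset
#'
#' Column layout: the `n_relevant` parent features first, then the duplicate
#' copies (grouped by parent), then the irrelevant features.  Labels honor
#' `minority_fraction` exactly up to rounding; each relevant feature is
#' present with probability `p1` in the positive class and `p0` in the
#' negative; each duplicate equals its parent with independent per-entry
#' flips at rate `flip_noise`; `label_noise` then flips labels.  In
#' `"poisson-counts"` mode every presence carries a count `1 + Poisson(1)`.
#'
#' @param spec a [synth_spec()].
#' @return a list with `data` (a `feature_matrix`) and `truth` (a list with
#'   `relevant`, `redundant_groups`, `irrelevant` index sets partitioning
#'   the columns).
#' @export
simulate_fragments <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_samples
  M <- spec$n_relevant * (1L + spec$copies_per_relevant) + spec$n_irrelevant
  n_pos <- round(n * spec$minority_fraction)

  with_seed(spec$seed, {
    y <- integer(n)
    y[sample.int(n, n_pos)] <- 1L

    counts_mode <- spec$count_mode == "poisson-counts"
    draw_counts <- function(k) {
      if (counts_mode) 1L + stats::rpois(k, 1) else rep.int(1L, k)
    }
    xm <- matrix(0L, n, M)
    parents <- seq_len(spec$n_relevant)
    for (j in parents) {
      pr <- ifelse(y == 1L, spec$p1, spec$p0)
      pres <- stats::runif(n) < pr
      xm[pres, j] <- draw_counts(sum(pres))
    }
    col <- spec$n_relevant
    groups <- lapply(parents, function(j) j)
    for (j in parents) {
      for (c0 in seq_len(spec$copies_per_relevant)) {
        col <- col + 1L
        # a duplicate equals its parent except for per-entry presence flips
        v <- xm[, j]
        flip <- stats::runif(n) < spec$flip_noise
        newly_present <- flip & v == 0L
        v[flip] <- 0L
        v[newly_present] <- draw_counts(sum(newly_present))
        xm[, col] <- v
        groups[[j]] <- c(groups[[j]], col)
      }
    }
    irrel <- if (spec$n_irrelevant > 0) (col + 1L):M else integer(0)
    for (j in irrel) {
      pres <- stats::runif(n) < spec$p_bg
      xm[pres, j] <- draw_counts(sum(pres))
    }

    if (spec$label_noise > 0) {
      flip <- stats::runif(n) < spec$label_noise
      y[flip] <- 1L - y[flip]
    }

    data <- feature_matrix(
      xm, y,
      feature_names = sprintf("F%03d", seq_len(M)),
      sample_ids = sprintf("S%04d", seq_len(n))
    )
    list(
      data = data,
      truth = list(
        relevant = parents,
        redundant_groups = groups,
        irrelevant = irrel
      )
    )
  })
}
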