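# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals do not perturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Stratified fold assignment
#'
#' @param y binary labels (0/1).
#' @param k number of folds.
#' @param seed RNG seed for the shuffle.
#' @return integer vector of fold ids in 1..k, one per sample, with both
#'   classes spread as evenly as possible across folds.
#' @noRd
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified train/validation split
#' @noRd
stratified_split <- function(y, fraction, seed) {
  build <- integer(0)
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      n_build <- max(1L, round(fraction * length(idx)))
      n_build <- min(n_build, length(idx) - 1L)
      build <- c(build, sample(idx, n_build))
    }
  })
  sort(build)
}

# Atomic write: write to a sibling temp file, then rename over the target.
atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
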