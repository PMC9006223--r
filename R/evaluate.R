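# Classifier evaluator wrappers.  The package never re-implements
# classifiers: decision trees come from rpart, random forests from
# randomForest, support vector machines from e1071.  An evaluator spec is a
# small list naming the family and its hyperparameters; fitting and
# prediction go through one dispatcher so the selection code is
# classifier-agnostic.

#' Classifier evaluator specification
#'
#' @param family `"dt"` (decision tree / bagged trees), `"rf"` (random
#'   forest) or `"svm"` (support vector machine).
#' @param params named list of family hyperparameters:
#'   \describe{
#'     \item{dt}{`prune` (logical, cost-complexity pruning on/off) and
#'       `trials` (1 = single tree, >1 = bagged committee of that size).}
#'     \item{rf}{`ntree` (default 100); trees are fully grown
#'       (`nodesize = 1`) on bootstrap samples with the Gini criterion.}
#'     \item{svm}{`kernel` (`"linear"` or `"radial"`), `cost`, `gamma`.}
#'   }
#' @return an object of class `gfsel_evaluator`.
#' @export
evaluator <- function(family = c("dt", "rf", "svm"), params = list()) {
  family <- match.arg(family)
  structure(list(family = family, params = params), class = "gfsel_evaluator")
}

as_evaluator <- function(x) {
  if (inherits(x, "gfsel_evaluator")) return(x)
  if (is.character(x) && length(x) == 1) return(evaluator(x))
  stop("not an evaluator spec")
}

# x: numeric matrix; y: 0/1 vector.  Returns an opaque fitted model.
fit_evaluator <- function(ev, x, y, seed = 1L) {
  x <- as.matrix(x)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  df <- as.data.frame(x)
  df$.y <- factor(y, levels = c(0, 1))
  p <- ev$params
  fit1 <- switch(ev$family,
    dt = function(d) {
      cp <- if (isTRUE(p$prune %||% TRUE)) 0.01 else 0
      rpart::rpart(.y ~ ., data = d, method = "class",
                   control = rpart::rpart.control(cp = cp, xval = 0))
    },
    rf = function(d) {
      randomForest::randomForest(.y ~ ., data = d,
                                 ntree = p$ntree %||% 100L, nodesize = 1)
    },
    svm = function(d) {
      e1071::svm(.y ~ ., data = d,
                 kernel = p$kernel %||% "linear",
                 cost = p$cost %||% 1,
                 gamma = p$gamma %||% (1 / ncol(x)),
                 scale = FALSE)
    }
  )
  trials <- if (ev$family == "dt") p$trials %||% 1L else 1L
  models <- with_seed(seed, {
    if (trials > 1) {
      lapply(seq_len(trials), function(t) {
        idx <- sample.int(nrow(df), nrow(df), replace = TRUE)
        fit1(df[idx, , drop = FALSE])
      })
    } else {
      list(fit1(df))
    }
  })
  structure(list(models = models, family = ev$family,
                 features = colnames(x)),
            class = "gfsel_fitted")
}

# Returns integer 0/1 predictions; committees vote by majority (ties -> 1).
predict_evaluator <- function(fit, x) {
  x <- as.matrix(x)
  colnames(x) <- fit$features
  df <- as.data.frame(x)
  preds <- vapply(fit$models, function(m) {
    cls <- switch(fit$family,
      dt = as.character(predict(m, df, type = "class")),
      rf = as.character(predict(m, df)),
      svm = as.character(predict(m, df))
    )
    as.integer(cls)
  }, integer(nrow(df)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(df))
  as.integer(rowMeans(preds) >= 0.5)
}

# Kappa of an evaluator restricted to feature subset `idx`, by stratified
# k-fold CV with precomputed fold ids; confusion counts are pooled over
# folds before computing kappa so the estimate is deterministic and shared
# across every candidate subset.
cv_kappa <- function(idx, x, y, ev, folds, seed = 1L) {
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
  cohen_kappa(confusion_counts(cc["tp"], cc["tn"], cc["fp"], cc["fn"]))
}
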