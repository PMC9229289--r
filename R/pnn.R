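#' Fit a probabilistic neural network
#'
#' A PNN is a lazy Parzen-window classifier: the pattern layer stores every
#' training vector verbatim, the summation layer averages the Gaussian
#' kernel responses within each class and the output layer reports the
#' arguments of the maximal class score. Its single hyperparameter is the
#' smoothing factor `delta` (the kernel width).
#'
#' The kernel is implemented as printed in the source model,
#' `phi = exp(-||x - x_ij||^2 / delta^2) / (sqrt(2*pi) * delta^d)`, i.e.
#' with a `delta^2` exponent denominator and a `sqrt(2*pi)` normalisation.
#' Set `standard_gaussian = TRUE` for the textbook multivariate form with
#' `2 * delta^2` and `(2*pi)^(d/2)`; the choice never changes the predicted
#' label, only reported score magnitudes.
#'
#' @param features Data frame with numeric feature columns and a label
#'   column, or a numeric matrix (then supply `labels`).
#' @param delta Smoothing factor (> 0).
#' @param labels Label vector when `features` is a matrix.
#' @param label_col Name of the label column (default `"label"`).
#' @param standard_gaussian Use the textbook Gaussian form (see Details).
#' @return Object of class `pnn`: list with `x` (exemplar matrix), `y`
#'   (factor of exemplar classes), `classes` (ordered labels),
#'   `class_counts`, `d`, `delta`, `standard_gaussian`.
#' @export
pnn_fit <- function(features, delta = 1, labels = NULL, label_col = "label",
                    standard_gaussian = FALSE) {
  if (is.data.frame(features)) {
    if (!label_col %in% names(features)) {
      stop("feature data frame must contain a '", label_col, "' column")
    }
    labels <- features[[label_col]]
    drop <- c(label_col, intersect("cycle", names(features)))
    x <- as.matrix(features[, setdiff(names(features), drop), drop = FALSE])
  } else {
    x <- as.matrix(features)
    if (is.null(labels)) stop("labels must be supplied with a feature matrix")
  }
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    stop("delta must be a single positive number")
  }
  if (length(labels) != nrow(x)) stop("labels and feature rows differ in length")
  if (!is.numeric(x)) stop("feature columns must be numeric")
  if (any(!is.finite(x))) stop("features contain missing or non-finite values")
  classes <- sort(unique(labels))
  y <- factor(labels, levels = classes)
  counts <- table(y)
  if (any(counts == 0)) stop("every class needs at least one exemplar")
  structure(list(
    x = x, y = y, classes = classes,
    class_counts = as.integer(counts),
    d = ncol(x), delta = delta,
    standard_gaussian = isTRUE(standard_gaussian)
  ), class = "pnn")
}

#' @export
print.pnn <- function(x, ...) {
  cat(sprintf("<pnn> %d exemplars, %d classes, d = %d, delta = %g\n",
              nrow(x$x), length(x$classes), x$d, x$delta))
  invisible(x)
}

.pnn_denom <- function(model) {
  if (model$standard_gaussian) 2 * model$delta^2 else model$delta^2
}

# Squared Euclidean distances between rows of a (m x d) and b (n x d).
.sq_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  pmax(d2, 0)
}

#' Per-class PNN scores for one input vector
#'
#' Evaluates the summation-layer outputs `g_i`, the within-class means of
#' the pattern-layer kernels. With `normalized = TRUE` the class-independent
#' kernel normalisation constant is included, as it must be when scores are
#' reported; classification may drop it without changing the argmax.
#'
#' @param model A fitted [pnn_fit()] model.
#' @param x Numeric vector of length `model$d`.
#' @param normalized Include the kernel normalisation constant.
#' @return Named numeric vector of class scores in `model$classes` order.
#' @export
pnn_class_scores <- function(model, x, normalized = TRUE) {
  stopifnot(inherits(model, "pnn"))
  if (model$delta <= 0) stop("delta must be positive")
  x <- as.numeric(x)
  if (length(x) != model$d) {
    stop("input has ", length(x), " attributes but the model expects ", model$d)
  }
  d2 <- colSums((t(model$x) - x)^2)
  kern <- exp(-d2 / .pnn_denom(model))
  g <- as.numeric(tapply(kern, model$y, mean))
  if (normalized) {
    const <- if (model$standard_gaussian) {
      (2 * pi)^(model$d / 2) * model$delta^model$d
    } else {
      sqrt(2 * pi) * model$delta^model$d
    }
    g <- g / const
  }
  names(g) <- as.character(model$classes)
  g
}

#' Classify feature vectors with a PNN
#'
#' Predicts the class with the maximal summation-layer score for each row.
#' The computation is done in the log domain with a max shift so that very
#' small smoothing factors remain numerically stable (in the `delta -> 0`
#' limit the PNN reduces to the 1-nearest-neighbour rule). Exact ties are
#' broken in favour of the earliest class in `model$classes`.
#'
#' @param model A fitted [pnn_fit()] model.
#' @param newdata Numeric matrix or data frame of feature rows (a single
#'   vector is treated as one row). A label column, if present, is ignored.
#' @return Vector of predicted labels (same type as the training labels).
#' @export
pnn_classify <- function(model, newdata) {
  stopifnot(inherits(model, "pnn"))
  if (is.data.frame(newdata)) {
    keep <- setdiff(names(newdata), c("label", "cycle"))
    newdata <- as.matrix(newdata[, keep, drop = FALSE])
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != model$d) {
    stop("input has ", ncol(newdata), " attributes but the model expects ",
         model$d)
  }
  e <- -.sq_dist(newdata, model$x) / .pnn_denom(model)
  shift <- apply(e, 1L, max)
  kern <- exp(e - shift)
  indicator <- vapply(levels(model$y), function(l) as.numeric(model$y == l),
                      numeric(length(model$y)))
  counts <- matrix(model$class_counts, nrow(kern), length(model$classes),
                   byrow = TRUE)
  g <- (kern %*% indicator) / counts
  model$classes[max.col(g, ties.method = "first")]
}

#' Evaluate a PNN on a labelled test set
#'
#' Two error metrics are available: `"misclassification"` is the fraction of
#' wrong predictions; `"eq4_mse"` is the mean squared difference between
#' integer-coded true and predicted labels, the form used when subject
#' identities are numbered from 0. The squared-label metric penalises label
#' distance, which is meaningless for nominal identities, so the
#' misclassification rate is the default throughout the package.
#'
#' @param model A fitted [pnn_fit()] model.
#' @param test Data frame with feature columns and a `label` column.
#' @param metric `"misclassification"` or `"eq4_mse"`.
#' @return List with `predictions`, `truth`, `n`, `metric`, `error`.
#' @export
pnn_evaluate <- function(model, test,
                         metric = c("misclassification", "eq4_mse")) {
  metric <- match.arg(metric)
  if (!nrow(test)) stop("test set is empty")
  truth <- test$label
  if (is.null(truth)) stop("test set must contain a 'label' column")
  pred <- pnn_classify(model, test)
  err <- if (metric == "misclassification") {
    mean(as.character(pred) != as.character(truth))
  } else {
    yt <- suppressWarnings(as.numeric(as.character(truth)))
    yp <- suppressWarnings(as.numeric(as.character(pred)))
    if (any(is.na(yt)) || any(is.na(yp))) {
      stop("eq4_mse requires integer-codable labels")
    }
    mean((yt - yp)^2)
  }
  list(predictions = pred, truth = truth, n = length(truth),
       metric = metric, error = err)
}

#' Tune the PNN smoothing factor with the whale optimization algorithm
#'
#' Runs a one-dimensional WOA search over `delta` within `bounds`,
#' minimising the chosen validation error of a PNN fitted on `train` and
#' scored on `val`. The returned model is refitted with the best smoothing
#' factor found.
#'
#' @param train,val Disjoint labelled feature data frames.
#' @param woa_cfg A [woa_config()]; its `bounds` must be a single
#'   `(low, high)` interval for `delta`. Defaults to `[0.01, 10]`, pop 10,
#'   100 iterations.
#' @param fitness Validation metric, see [pnn_evaluate()].
#' @param standard_gaussian Passed to [pnn_fit()].
#' @return List with `delta`, `history` (best fitness per iteration,
#'   non-increasing), `fitness` (final best), `model`.
#' @export
tune_smoothing_factor <- function(train, val,
                                  woa_cfg = woa_config(bounds = c(0.01, 10)),
                                  fitness = c("misclassification", "eq4_mse"),
                                  standard_gaussian = FALSE) {
  fitness <- match.arg(fitness)
  fn <- function(pos) {
    model <- pnn_fit(train, delta = pos[1L],
                     standard_gaussian = standard_gaussian)
    pnn_evaluate(model, val, metric = fitness)$error
  }
  res <- woa_optimize(fn, woa_cfg)
  best_delta <- res$position[1L]
  list(delta = best_delta, history = res$history, fitness = res$fitness,
       model = pnn_fit(train, delta = best_delta,
                       standard_gaussian = standard_gaussian))
}
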