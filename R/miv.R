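#' Mean-impact-value configuration
#'
#' @param alpha Perturbation fraction applied multiplicatively to one
#'   feature at a time (`0 < alpha < 1`); 0.10 is the customary setting.
#' @param threshold Selection cutoff on `abs(MIV)`.
#' @return Object of class `miv_config`.
#' @export
miv_config <- function(alpha = 0.10, threshold = 0.10) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1")
  }
  if (!is.numeric(threshold) || threshold < 0) stop("threshold must be >= 0")
  structure(list(alpha = alpha, threshold = threshold), class = "miv_config")
}

#' Perturb one feature of a matrix
#'
#' Scales column `i` by `(1 + alpha)` or `(1 - alpha)`; every other entry is
#' returned bit-identical.
#'
#' @param x Numeric matrix or data frame of feature columns.
#' @param i Column index (1-based).
#' @param alpha Perturbation fraction.
#' @param sign `"plus"` or `"minus"`.
#' @return Perturbed copy of `x`.
#' @export
perturb_feature <- function(x, i, alpha, sign = c("plus", "minus")) {
  sign <- match.arg(sign)
  p <- if (is.data.frame(x)) ncol(x) else ncol(as.matrix(x))
  if (i < 1L || i > p) stop("feature index out of range: ", i)
  factor <- if (sign == "plus") 1 + alpha else 1 - alpha
  x[, i] <- x[, i] * factor
  x
}

#' Mean impact value of every feature
#'
#' For each feature `i` the predictor is evaluated on two copies of the data
#' with that feature scaled by `(1 + alpha)` and `(1 - alpha)`; the impact
#' vector is the elementwise difference of the two outputs and the MIV is
#' its mean over observations. The sign indicates the direction of the
#' association; the absolute value ranks relative importance.
#'
#' @param predict_fn Function mapping a feature matrix to one numeric output
#'   per row (for a PNN classifier: the numeric predicted label, see
#'   [pnn_predictor()]).
#' @param x Numeric matrix or data frame of features (observations in rows).
#' @param cfg A [miv_config()].
#' @return Object of class `miv_report`: list with `miv` (named, signed),
#'   `ranking` (feature names by decreasing `abs(miv)`), `selected` (logical
#'   mask, `abs(miv) > threshold`), `p`, `m`, `alpha`, `threshold`.
#' @export
compute_miv <- function(predict_fn, x, cfg = miv_config()) {
  stopifnot(inherits(cfg, "miv_config"))
  xm <- if (is.data.frame(x)) x[, setdiff(names(x), c("label", "cycle")),
                                drop = FALSE] else x
  p <- ncol(xm)
  m <- nrow(xm)
  nms <- colnames(xm)
  if (is.null(nms)) nms <- paste0("x", seq_len(p))
  miv <- numeric(p)
  for (i in seq_len(p)) {
    y1 <- predict_fn(perturb_feature(xm, i, cfg$alpha, "plus"))
    y2 <- predict_fn(perturb_feature(xm, i, cfg$alpha, "minus"))
    if (length(y1) != m || length(y2) != m) {
      stop("predict_fn must return one output per observation")
    }
    if (any(!is.finite(y1)) || any(!is.finite(y2))) {
      stop("non-finite predictor output while perturbing feature '",
           nms[i], "'")
    }
    miv[i] <- mean(y1 - y2)
  }
  names(miv) <- nms
  ord <- order(abs(miv), decreasing = TRUE)
  structure(list(
    miv = miv,
    ranking = nms[ord],
    selected = stats::setNames(abs(miv) > cfg$threshold, nms),
    p = p, m = m, alpha = cfg$alpha, threshold = cfg$threshold
  ), class = "miv_report")
}

#' @export
print.miv_report <- function(x, ...) {
  cat(sprintf("<miv_report> %d features, %d observations, alpha = %g\n",
              x$p, x$m, x$alpha))
  cat(sprintf("selected (|MIV| > %g): %d\n", x$threshold, sum(x$selected)))
  invisible(x)
}

#' Select features by absolute mean impact value
#'
#' @param report A [compute_miv()] report, or a named numeric vector of MIV
#'   values.
#' @param threshold Cutoff on `abs(MIV)`; defaults to the report's.
#' @return Character vector of retained feature names, most influential
#'   first.
#' @export
select_features <- function(report, threshold = NULL) {
  if (inherits(report, "miv_report")) {
    miv <- report$miv
    if (is.null(threshold)) threshold <- report$threshold
  } else {
    miv <- report
    if (is.null(threshold)) threshold <- 0.10
    if (is.null(names(miv))) names(miv) <- paste0("x", seq_along(miv))
  }
  ord <- order(abs(miv), decreasing = TRUE)
  ranked <- miv[ord]
  names(ranked)[abs(ranked) > threshold]
}

#' Numeric predictor view of a PNN classifier
#'
#' Wraps a fitted PNN so it returns one number per row (the predicted label
#' coerced to numeric), the scalar output form the impact-value screening
#' requires when subject identities are numbered from 0. With
#' `output = "score"` the winning class's summation-layer score is returned
#' instead.
#'
#' @param model A fitted [pnn_fit()] model.
#' @param output `"label"` (default) or `"score"`.
#' @return Function mapping a feature matrix to a numeric vector.
#' @export
pnn_predictor <- function(model, output = c("label", "score")) {
  output <- match.arg(output)
  if (output == "label") {
    function(x) as.numeric(as.character(pnn_classify(model, x)))
  } else {
    function(x) {
      x <- as.matrix(x)
      vapply(seq_len(nrow(x)), function(k) {
        max(pnn_class_scores(model, x[k, ]))
      }, numeric(1))
    }
  }
}
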