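#' Single-lead ECG signal container
#'
#' Bundles a uniformly sampled voltage series with its sampling rate. All
#' detectors and the feature extractor operate on this container; sample
#' indices are 1-based inside R and converted to 0-based only at the JSON
#' export boundary.
#'
#' @param samples Numeric vector of voltage samples (mV or arbitrary units).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param record_id Optional text label for the recording.
#' @return An object of class `ecg_signal` with fields `samples`, `fs`,
#'   `record_id`.
#' @examples
#' sig <- ecg_signal(sin(seq(0, 10, by = 0.01)), fs = 100)
#' sig$fs
#' @export
ecg_signal <- function(samples, fs, record_id = "") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number")
  }
  if (length(samples) < 2L) {
    stop("an ECG signal must contain at least 2 samples")
  }
  if (any(!is.finite(samples))) {
    stop("ECG samples must all be finite")
  }
  structure(list(samples = samples, fs = fs, record_id = as.character(record_id)),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %s: %d samples @ %g Hz (%.2f s)\n",
              if (nzchar(x$record_id)) x$record_id else "(unnamed)",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Wavelet filter banks for ECG delineation
#'
#' Returns the low-pass/high-pass pair of a named undecimated filter bank.
#' The default `"quadratic_spline"` bank is the derivative-of-smoothing pair
#' classically used for QRS delineation: low-pass `(1, 3, 3, 1)/8` and
#' high-pass `(2, -2)`. Detail coefficients then approximate the smoothed
#' derivative of the signal, so sharp waves appear as opposite-sign
#' modulus-maxima pairs with a zero-crossing at the wave peak.
#'
#' @param name Filter bank name.
#' @return List with components `h` (low-pass), `g` (high-pass), `name`.
#' @export
spline_wavelet_filters <- function(name = "quadratic_spline") {
  banks <- list(
    quadratic_spline = list(h = c(1, 3, 3, 1) / 8, g = c(2, -2))
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(banks)) {
    stop("unknown wavelet filter bank: ", paste(name, collapse = ", "))
  }
  c(banks[[name]], list(name = name))
}

# Insert (step - 1) zeros between filter taps (a-trous dilation).
atrous_upsample <- function(f, step) {
  if (step == 1L) return(f)
  out <- numeric((length(f) - 1L) * step + 1L)
  out[1L + (seq_along(f) - 1L) * step] <- f
  out
}

# Causal convolution y[n] = sum_k f[k+1] x[n-k] with symmetric (mirror)
# extension of x at both ends; output has the same length as x.
conv_mirror <- function(x, f) {
  n <- length(x)
  pad <- length(f)
  if (pad >= n) stop("signal too short for filter of length ", pad)
  xp <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  full <- stats::convolve(xp, rev(f), type = "open")
  full[pad + seq_len(n)]
}

# Detail coefficients S1..SJ of the undecimated (a-trous) transform.
atrous_decompose <- function(x, num_scales, bank) {
  approx <- x
  scales <- vector("list", num_scales)
  for (j in seq_len(num_scales)) {
    step <- 2L^(j - 1L)
    scales[[j]] <- conv_mirror(approx, atrous_upsample(bank$g, step))
    if (j < num_scales) approx <- conv_mirror(approx, atrous_upsample(bank$h, step))
  }
  names(scales) <- paste0("S", seq_len(num_scales))
  scales
}

.delay_cache <- new.env(parent = emptyenv())

#' Group delay of a wavelet scale
#'
#' The causal filter cascade shifts features towards larger sample indices;
#' a feature located at index `i` on scale `j` corresponds to time-domain
#' sample `i - scale_delay(j)`. The delay is the centroid of the absolute
#' cascade impulse response, rounded half-up to an integer, and grows with
#' the scale because the a-trous dilation lengthens the filters.
#'
#' @param scale_index Scale number (>= 1).
#' @param filter_name Filter bank name, see [spline_wavelet_filters()].
#' @return Integer delay in samples.
#' @export
scale_delay <- function(scale_index, filter_name = "quadratic_spline") {
  if (!is.numeric(scale_index) || length(scale_index) != 1L || scale_index < 1) {
    stop("scale_index must be a single integer >= 1")
  }
  scale_index <- as.integer(scale_index)
  key <- paste0(filter_name, "#", scale_index)
  cached <- .delay_cache[[key]]
  if (!is.null(cached)) return(cached)
  bank <- spline_wavelet_filters(filter_name)
  n <- 1024L
  k <- 512L
  x <- numeric(n)
  x[k] <- 1
  w <- atrous_decompose(x, scale_index, bank)[[scale_index]]
  a <- abs(w)
  centroid <- sum(seq_len(n) * a) / sum(a)
  d <- as.integer(floor(centroid - k + 0.5))
  .delay_cache[[key]] <- d
  d
}

#' Undecimated dyadic wavelet transform
#'
#' Computes detail coefficients at scales 1..`num_scales` of the a-trous
#' (stationary) wavelet transform with the named spline filter bank. Every
#' scale has the same length as the input; the transform is linear and
#' shift-equivariant away from the mirrored boundaries. Scale `j` is obtained
#' by convolving the input with the dilated high-pass after `j - 1` dilated
#' low-pass smoothing stages.
#'
#' @param signal An [ecg_signal()] or a plain numeric vector.
#' @param num_scales Number of detail scales (default 4).
#' @param filter_name Filter bank name.
#' @return Object of class `ecg_swt`: list with `scales` (named list
#'   `S1`..`SJ`), `delays` (per-scale group delay, samples), `filter_name`,
#'   `n` (input length).
#' @examples
#' sig <- ecg_signal(sin(2 * pi * 5 * seq(0, 2, by = 1 / 360)), fs = 360)
#' w <- dyadic_swt(sig)
#' lengths(w$scales)
#' @export
dyadic_swt <- function(signal, num_scales = 4L, filter_name = "quadratic_spline") {
  x <- if (inherits(signal, "ecg_signal")) signal$samples else as.numeric(signal)
  if (!is.numeric(num_scales) || length(num_scales) != 1L || num_scales < 1) {
    stop("num_scales must be a single integer >= 1")
  }
  num_scales <- as.integer(num_scales)
  if (any(!is.finite(x))) stop("signal contains non-finite samples")
  bank <- spline_wavelet_filters(filter_name)
  min_len <- 2L^num_scales * max(length(bank$h), length(bank$g))
  if (length(x) <= min_len) {
    stop("signal too short for a ", num_scales, "-scale transform: need more than ",
         min_len, " samples, got ", length(x))
  }
  scales <- atrous_decompose(x, num_scales, bank)
  structure(list(
    scales = scales,
    delays = vapply(seq_len(num_scales), scale_delay, integer(1),
                    filter_name = filter_name),
    filter_name = filter_name,
    n = length(x)
  ), class = "ecg_swt")
}

#' @export
print.ecg_swt <- function(x, ...) {
  cat(sprintf("<ecg_swt> %d scales of %d samples (%s), delays: %s\n",
              length(x$scales), x$n, x$filter_name,
              paste(x$delays, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.ecg_swt <- function(x, ...) {
  out <- data.frame(sample_index = seq_len(x$n) - 1L)
  for (nm in names(x$scales)) out[[nm]] <- x$scales[[nm]]
  out
}
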