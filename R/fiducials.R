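#' Detection configuration
#'
#' Tunable parameters of the fiducial detectors. Window lengths are stored in
#' samples and default to fractions of the sampling rate chosen from standard
#' ECG physiology: the P search window spans 0.20 s before the Q wave, the T
#' search window 0.30 s after the S wave, and windows are translated in 0.02 s
#' steps when no sub-threshold wave is found.
#'
#' @param fs Sampling rate in Hz (used only to derive the sample defaults).
#' @param w_p P search window length in samples.
#' @param w_t T search window length in samples.
#' @param step_a Window translation per attempt, in samples.
#' @param r_threshold_frac Fraction of `max(abs(S4))` gating R candidates.
#' @param refractory_s Minimum R-R interval in seconds; closer candidate
#'   pairs are merged keeping the larger modulus product.
#' @param pt_threshold_frac Fraction of the in-window `max(abs(S4))` that the
#'   scale-4 minimum must fall below for a P/T peak to be accepted.
#' @param max_translations Cap on the number of window translations.
#' @param polarity +1 for upright R/P/T waves, -1 for inverted leads.
#' @param qs_refine If `TRUE` (default) the Q/S position from the scale-1
#'   extremum walk is snapped to the raw-signal trough between the walk
#'   result and the R peak; `FALSE` returns the walk result itself.
#' @param qs_floor_frac Relative magnitude floor (fraction of global
#'   `max(abs(S1))`) below which scale-1 extrema are ignored as ripple.
#' @return Object of class `detection_config`.
#' @export
detection_config <- function(fs,
                             w_p = max(8L, round(0.20 * fs)),
                             w_t = max(8L, round(0.30 * fs)),
                             step_a = max(1L, round(0.02 * fs)),
                             r_threshold_frac = 0.3,
                             refractory_s = 0.2,
                             pt_threshold_frac = 0.25,
                             max_translations = 50L,
                             polarity = 1,
                             qs_refine = TRUE,
                             qs_floor_frac = 0.02) {
  if (missing(fs) || !is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (w_p <= 0 || w_t <= 0 || step_a <= 0) stop("window lengths must be positive")
  for (frac in c(r_threshold_frac, pt_threshold_frac)) {
    if (!is.numeric(frac) || frac <= 0 || frac > 1) {
      stop("threshold fractions must lie in (0, 1]")
    }
  }
  if (refractory_s <= 0) stop("refractory_s must be positive")
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1")
  structure(list(
    fs = fs,
    w_p = as.integer(w_p), w_t = as.integer(w_t), step_a = as.integer(step_a),
    r_threshold_frac = r_threshold_frac, refractory_s = refractory_s,
    pt_threshold_frac = pt_threshold_frac,
    max_translations = as.integer(max_translations),
    polarity = polarity, qs_refine = isTRUE(qs_refine),
    qs_floor_frac = qs_floor_frac
  ), class = "detection_config")
}

# Indices of strict local extrema (sign change of the first difference).
local_extrema <- function(v) {
  if (length(v) < 3L) return(integer(0))
  d <- diff(v)
  which(d[-length(d)] * d[-1L] < 0) + 1L
}

#' Detect R peaks on wavelet scale 4
#'
#' Opposite-sign modulus-maxima pairs on S4 whose magnitudes exceed a
#' fraction of the global scale-4 maximum mark QRS complexes; the
#' zero-crossing between a pair is corrected for the scale-4 group delay and
#' the R peak is taken as the absolute-amplitude maximum of the raw signal
#' within 100 ms of the corrected position. Candidates closer than the
#' refractory period are merged, keeping the pair with the larger modulus
#' product.
#'
#' @param decomp An [dyadic_swt()] decomposition aligned to `signal`.
#' @param signal The [ecg_signal()] the decomposition was computed from.
#' @param cfg A [detection_config()].
#' @return Increasing integer vector of R peak sample indices (possibly
#'   empty).
#' @export
detect_r_peaks <- function(decomp, signal, cfg = detection_config(signal$fs)) {
  stopifnot(inherits(decomp, "ecg_swt"), inherits(signal, "ecg_signal"))
  x <- signal$samples
  if (decomp$n != length(x)) stop("decomposition is not aligned to the signal")
  s4 <- decomp$scales[["S4"]]
  d4 <- decomp$delays[4L]
  fs <- signal$fs
  peak_max <- max(abs(s4))
  if (peak_max == 0) return(integer(0))
  thr <- cfg$r_threshold_frac * peak_max
  ext <- local_extrema(s4)
  ext <- ext[abs(s4[ext]) > thr]
  if (length(ext) < 2L) return(integer(0))

  max_span <- round(0.15 * fs)
  half_win <- round(0.10 * fs)
  n <- length(x)
  cand_r <- integer(0)
  cand_w <- numeric(0)
  i <- 1L
  while (i < length(ext)) {
    e1 <- ext[i]
    e2 <- ext[i + 1L]
    if (sign(s4[e1]) != sign(s4[e2]) && (e2 - e1) <= max_span) {
      seg <- s4[e1:e2]
      zc_rel <- which(seg[-length(seg)] * seg[-1L] <= 0)[1L]
      zc <- e1 + zc_rel - 1L
      pos <- zc - d4
      lo <- max(1L, pos - half_win)
      hi <- min(n, pos + half_win)
      cand_r <- c(cand_r, lo - 1L + which.max(abs(x[lo:hi])))
      cand_w <- c(cand_w, abs(s4[e1] * s4[e2]))
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  if (!length(cand_r)) return(integer(0))

  o <- order(cand_r)
  cand_r <- cand_r[o]
  cand_w <- cand_w[o]
  refractory <- round(cfg$refractory_s * fs)
  keep_r <- cand_r[1L]
  keep_w <- cand_w[1L]
  for (k in seq_along(cand_r)[-1L]) {
    last <- length(keep_r)
    if (cand_r[k] - keep_r[last] < refractory) {
      if (cand_w[k] > keep_w[last]) {
        keep_r[last] <- cand_r[k]
        keep_w[last] <- cand_w[k]
      }
    } else {
      keep_r <- c(keep_r, cand_r[k])
      keep_w <- c(keep_w, cand_w[k])
    }
  }
  unique(keep_r)
}

#' Mean R-R period
#'
#' Arithmetic mean of successive R peak differences, in samples. This is the
#' average cycle length that bounds the Q/S extremum walk and the P/T window
#' translations.
#'
#' @param r_peaks Increasing vector of R peak indices (length >= 2).
#' @return Mean R-R interval in samples.
#' @export
mean_rr <- function(r_peaks) {
  if (length(r_peaks) < 2L) {
    stop("at least two R peaks are required to estimate the mean R-R period")
  }
  mean(diff(as.numeric(r_peaks)))
}

# Walk away from `start` along |s1| and return the index of the third strict
# local extremum whose magnitude clears `floor_val`, or NA.
qs_extrema_walk <- function(s1, start, direction, bound, floor_val) {
  n <- length(s1)
  idx <- if (direction < 0) {
    seq(start, max(1L, start - bound))
  } else {
    seq(start, min(n, start + bound))
  }
  if (length(idx) < 3L) return(NA_integer_)
  v <- abs(s1[idx])
  ext <- local_extrema(v)
  ext <- ext[v[ext] > floor_val]
  if (length(ext) < 3L) return(NA_integer_)
  idx[ext[3L]]
}

#' Detect Q and S waves on wavelet scale 1
#'
#' For each R peak the detector walks outward on scale 1, collecting strict
#' local extrema of `abs(S1)`; the third extremum (delay-corrected) marks the
#' Q region on the left and the S region on the right, bounded by half the
#' mean R-R period. With `cfg$qs_refine` (the default) the mark is snapped to
#' the raw-signal trough between the mark and R, which lands on the Q/S
#' nadir; cycles with fewer than three extrema within the bound have that
#' wave reported as `NA`.
#'
#' @inheritParams detect_r_peaks
#' @param r_peaks R peak indices from [detect_r_peaks()].
#' @param tr Mean R-R period in samples, from [mean_rr()].
#' @return List with integer vectors `q` and `s` aligned to `r_peaks`
#'   (`NA` where undetected).
#' @export
detect_qs <- function(decomp, signal, r_peaks, tr,
                      cfg = detection_config(signal$fs)) {
  stopifnot(inherits(decomp, "ecg_swt"))
  if (!length(r_peaks)) stop("r_peaks must be non-empty")
  s1 <- decomp$scales[["S1"]]
  d1 <- decomp$delays[1L]
  x <- signal$samples
  fs <- signal$fs
  n <- length(s1)
  bound <- max(3L, round(0.5 * tr))
  floor_val <- cfg$qs_floor_frac * max(abs(s1))
  snap <- round(0.10 * fs)

  # Trough of the signed signal nearest to R within [lo, hi]; the ECG rises
  # monotonically from the Q/S nadir to the R peak, so the nearest local
  # minimum is the nadir itself. Falls back to the window minimum.
  nearest_trough <- function(lo, hi, from_right) {
    v <- cfg$polarity * x[lo:hi]
    minima <- local_extrema(v)
    minima <- minima[v[minima] < v[pmax(minima - 1L, 1L)]]
    if (length(minima)) {
      lo - 1L + if (from_right) max(minima) else min(minima)
    } else {
      lo - 1L + which.min(v)
    }
  }

  q <- s <- rep(NA_integer_, length(r_peaks))
  for (k in seq_along(r_peaks)) {
    r <- r_peaks[k]
    e3l <- qs_extrema_walk(s1, min(n, r + d1 - 1L), -1L, bound, floor_val)
    if (!is.na(e3l)) {
      pos <- e3l - d1
      if (cfg$qs_refine) {
        lo <- max(1L, r - snap)
        hi <- r - 1L
        if (lo <= hi) q[k] <- nearest_trough(lo, hi, from_right = TRUE)
      } else if (pos >= 1L) {
        q[k] <- pos
      }
    }
    e3r <- qs_extrema_walk(s1, min(n, r + d1 + 1L), 1L, bound, floor_val)
    if (!is.na(e3r)) {
      pos <- e3r - d1
      if (cfg$qs_refine) {
        lo <- r + 1L
        hi <- min(n, r + snap)
        if (lo <= hi) s[k] <- nearest_trough(lo, hi, from_right = FALSE)
      } else if (pos <= n) {
        s[k] <- pos
      }
    }
  }
  list(q = q, s = s)
}

# One windowed-transform search for a P (side = -1, anchored at Q) or
# T (side = +1, anchored at S) wave. Returns c(onset, peak, offset) or NAs.
pt_window_search <- function(x, fs, anchor, side, win_len, tr, cfg,
                             filter_name) {
  n <- length(x)
  limit <- if (side < 0) tr / 2 else 2 * tr / 3
  d4 <- scale_delay(4L, filter_name)
  bank <- spline_wavelet_filters(filter_name)
  min_len <- 2L^4L * max(length(bank$h), length(bank$g)) + 2L
  refine <- round(0.06 * fs)
  miss <- c(NA_integer_, NA_integer_, NA_integer_)

  for (ntr in 0:cfg$max_translations) {
    shift <- ntr * cfg$step_a
    if (win_len + shift > limit) break
    if (side < 0) {
      hi <- anchor - shift
      lo <- hi - win_len
    } else {
      lo <- anchor + shift
      hi <- lo + win_len
    }
    lo <- max(1L, lo)
    hi <- min(n, hi)
    if (hi - lo + 1L < min_len) {
      if (side < 0) lo <- max(1L, hi - min_len + 1L) else hi <- min(n, lo + min_len - 1L)
    }
    if (hi - lo + 1L < min_len) break

    w <- dyadic_swt(x[lo:hi], num_scales = 4L, filter_name = filter_name)
    s4 <- cfg$polarity * w$scales[["S4"]]
    len <- length(s4)
    # guard band on the anchor side: keeps the QRS recovery slope and the
    # mirror-boundary kink at the anchored edge out of both the threshold
    # and the search
    interior <- if (side < 0) seq_len(len - d4) else seq(2L * d4 + 1L, len)
    if (length(interior) < 3L) next
    mx <- max(abs(s4[interior]))
    if (mx == 0) next
    imin <- interior[which.min(s4[interior])]
    if (s4[imin] >= -cfg$pt_threshold_frac * mx) next
    before <- interior[interior < imin]
    if (!length(before)) next
    jon <- before[which.max(s4[before])]
    if (s4[jon] <= 0) next

    # the zero-crossing between the rising-slope maximum and the
    # falling-slope minimum marks the wave peak (delay-corrected)
    seg <- s4[jon:imin]
    zc_rel <- which(seg[-length(seg)] > 0 & seg[-1L] <= 0)[1L]
    if (is.na(zc_rel)) next
    peak0 <- lo - 1L + jon + zc_rel - 1L - d4
    rlo <- max(lo, peak0 - refine)
    rhi <- min(hi, peak0 + refine)
    if (rlo > rhi) next
    peak <- rlo - 1L + which.max(cfg$polarity * x[rlo:rhi])

    onset <- lo - 1L + jon - d4
    if (onset < 1L || onset >= peak) next
    offset <- peak + (peak - onset)
    if (offset > n) next
    return(c(onset, peak, offset))
  }
  miss
}

#' Detect P and T waves with locally windowed wavelet transforms
#'
#' A fresh four-scale wavelet transform is computed inside a window placed
#' before each Q wave (length `w_p`) and after each S wave (length `w_t`), so
#' the transform never sees the dominant R peak. A wave peak is accepted when
#' the scale-4 minimum inside the window falls below `-pt_threshold_frac *
#' max(abs(S4))`; the delay-corrected minimum is then refined to the
#' raw-signal extremum within 60 ms. The onset is the preceding scale-4
#' maximum and the offset mirrors the onset about the peak. Windows that fail
#' are translated outward by `step_a` until the P window would pass half the
#' mean R-R period (or the T window two thirds of it), after which the wave
#' is reported missing.
#'
#' @inheritParams detect_qs
#' @param q,s Per-cycle Q and S indices from [detect_qs()] (`NA` skips the
#'   cycle's wave).
#' @param filter_name Filter bank used for the local transforms.
#' @return Data frame with one row per cycle and integer columns `p_on`,
#'   `p_peak`, `p_off`, `t_on`, `t_peak`, `t_off` (`NA` where missing).
#' @export
detect_pt <- function(signal, q, s, tr, cfg = detection_config(signal$fs),
                      filter_name = "quadratic_spline") {
  stopifnot(inherits(signal, "ecg_signal"), length(q) == length(s))
  x <- signal$samples
  fs <- signal$fs
  n_cyc <- length(q)
  out <- data.frame(
    p_on = rep(NA_integer_, n_cyc), p_peak = NA_integer_, p_off = NA_integer_,
    t_on = NA_integer_, t_peak = NA_integer_, t_off = NA_integer_
  )
  for (k in seq_len(n_cyc)) {
    if (!is.na(q[k])) {
      out[k, c("p_on", "p_peak", "p_off")] <-
        pt_window_search(x, fs, q[k], -1L, cfg$w_p, tr, cfg, filter_name)
    }
    if (!is.na(s[k])) {
      out[k, c("t_on", "t_peak", "t_off")] <-
        pt_window_search(x, fs, s[k], 1L, cfg$w_t, tr, cfg, filter_name)
    }
  }
  out
}

# Ordering check p_on <= p_peak <= p_off < q < r < s < t_on <= t_peak <= t_off
# evaluated over the fiducials that are present.
fiducial_order_ok <- function(v) {
  strict <- c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  pres <- which(!is.na(v))
  if (length(pres) < 2L) return(TRUE)
  for (k in seq_len(length(pres) - 1L)) {
    i <- pres[k]
    j <- pres[k + 1L]
    links <- strict[i:(j - 1L)]
    if (any(links)) {
      if (v[j] <= v[i]) return(FALSE)
    } else if (v[j] < v[i]) {
      return(FALSE)
    }
  }
  TRUE
}

#' Assemble per-cycle fiducials and enforce ordering
#'
#' Combines the per-cycle detector outputs into a single table and drops
#' cycles whose present fiducials violate the physiological ordering
#' `p_on <= p_peak <= p_off < q < r < s < t_on <= t_peak <= t_off`. Dropping
#' rather than imputing keeps downstream features honest; the number of
#' excluded cycles is recorded in the `"excluded"` attribute.
#'
#' @param r R peak indices (one per cycle).
#' @param q,s Aligned Q and S indices (`NA` allowed).
#' @param pt Data frame from [detect_pt()] aligned to `r`.
#' @param tr Mean R-R period in samples.
#' @return Object of class `fiducial_set`: a data frame with columns
#'   `cycle`, `p_on`, `p_peak`, `p_off`, `q`, `r`, `s`, `t_on`, `t_peak`,
#'   `t_off`; attributes `mean_rr`, `r_all` (every detected R, for R-R
#'   intervals) and `excluded`.
#' @export
assemble_fiducials <- function(r, q, s, pt, tr) {
  n_cyc <- length(r)
  stopifnot(length(q) == n_cyc, length(s) == n_cyc, nrow(pt) == n_cyc)
  if (n_cyc > 1L && any(diff(r) <= 0)) stop("R peaks must be strictly increasing")
  fid <- data.frame(
    cycle = seq_len(n_cyc),
    p_on = as.integer(pt$p_on), p_peak = as.integer(pt$p_peak),
    p_off = as.integer(pt$p_off),
    q = as.integer(q), r = as.integer(r), s = as.integer(s),
    t_on = as.integer(pt$t_on), t_peak = as.integer(pt$t_peak),
    t_off = as.integer(pt$t_off)
  )
  ok <- vapply(seq_len(n_cyc), function(k) {
    fiducial_order_ok(as.numeric(fid[k, c("p_on", "p_peak", "p_off", "q", "r",
                                          "s", "t_on", "t_peak", "t_off")]))
  }, logical(1))
  excluded <- sum(!ok)
  if (excluded > 0) {
    message(excluded, " cycle(s) excluded for fiducial ordering violations")
  }
  out <- fid[ok, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, mean_rr = tr, r_all = as.integer(r), excluded = excluded,
            class = c("fiducial_set", "data.frame"))
}

#' Full fiducial delineation of one recording
#'
#' Convenience wrapper chaining the global wavelet transform, R peak
#' detection, mean R-R estimation, Q/S detection and the locally windowed
#' P/T search, and assembling the result.
#'
#' @inheritParams detect_r_peaks
#' @param filter_name Filter bank name.
#' @return A `fiducial_set` (see [assemble_fiducials()]); zero rows when
#'   fewer than two R peaks are found.
#' @export
detect_fiducials <- function(signal, cfg = detection_config(signal$fs),
                             filter_name = "quadratic_spline") {
  decomp <- dyadic_swt(signal, num_scales = 4L, filter_name = filter_name)
  r <- detect_r_peaks(decomp, signal, cfg)
  if (length(r) < 2L) {
    empty <- data.frame(cycle = integer(0), p_on = integer(0),
                        p_peak = integer(0), p_off = integer(0),
                        q = integer(0), r = integer(0), s = integer(0),
                        t_on = integer(0), t_peak = integer(0),
                        t_off = integer(0))
    return(structure(empty, mean_rr = NA_real_, r_all = r, excluded = 0L,
                     class = c("fiducial_set", "data.frame")))
  }
  tr <- mean_rr(r)
  qs <- detect_qs(decomp, signal, r, tr, cfg)
  pt <- detect_pt(signal, qs$q, qs$s, tr, cfg, filter_name)
  assemble_fiducials(r, qs$q, qs$s, pt, tr)
}
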