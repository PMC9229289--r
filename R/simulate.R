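# Run expr with a local RNG state seeded by `seed` (NULL = use current).
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Physiological parameter ranges of the synthetic subject generator
#'
#' One constants table from which every subject template is drawn, so tests
#' can audit that generated parameters stay in range. Each wave is a
#' Gaussian bump described by amplitude (mV), width (the Gaussian sigma, s)
#' and center offset from the R peak (s); heart rate is in bpm and
#' `rr_jitter` is the fractional cycle-to-cycle variation of the R-R
#' interval.
#'
#' @return Named list of `(low, high)` ranges.
#' @export
subject_template_ranges <- function() {
  list(
    p = list(amp = c(0.10, 0.25), width = c(0.030, 0.045),
             center = c(-0.24, -0.18)),
    q = list(amp = c(-0.25, -0.08), width = c(0.010, 0.016),
             center = c(-0.075, -0.055)),
    r = list(amp = c(0.90, 1.40), width = c(0.010, 0.018),
             center = c(0, 0)),
    s = list(amp = c(-0.30, -0.10), width = c(0.010, 0.016),
             center = c(0.055, 0.075)),
    t = list(amp = c(0.15, 0.40), width = c(0.055, 0.080),
             center = c(0.22, 0.28)),
    heart_rate = c(55, 85),
    rr_jitter = c(0.000, 0.020)
  )
}

#' Draw a synthetic subject template
#'
#' Per-subject P-QRS-T morphology: each wave's amplitude, width and center
#' offset is drawn uniformly from [subject_template_ranges()], giving stable
#' within-subject morphology and between-subject variation. The same seed
#' always yields the same template.
#'
#' @param seed RNG seed for the draw.
#' @param subject_id Label stored in the template.
#' @return Object of class `subject_template`.
#' @export
generate_subject <- function(seed = NULL, subject_id = "s0") {
  rng <- subject_template_ranges()
  with_local_seed(seed, {
    draw <- function(r) stats::runif(1, r[1], r[2])
    waves <- lapply(rng[c("p", "q", "r", "s", "t")], function(w) {
      list(amp = draw(w$amp), width = draw(w$width), center = draw(w$center))
    })
    structure(list(
      waves = waves,
      heart_rate = draw(rng$heart_rate),
      rr_jitter = draw(rng$rr_jitter),
      subject_id = subject_id
    ), class = "subject_template")
  })
}

#' Simulation options
#'
#' @param fs Sampling rate in Hz.
#' @param n_cycles Number of heartbeats to render.
#' @param noise_snr_db Additive white Gaussian noise level as signal-to-noise
#'   ratio in dB, or `NULL` for a noise-free recording.
#' @param wander_amp Baseline wander amplitude (mV, 0 disables).
#' @param wander_freq Baseline wander frequency (Hz).
#' @param seed RNG seed for jitter, noise and wander phase.
#' @return Object of class `sim_options`.
#' @export
sim_options <- function(fs = 360, n_cycles = 10L, noise_snr_db = NULL,
                        wander_amp = 0, wander_freq = 0.33, seed = NULL) {
  if (fs <= 0) stop("fs must be positive")
  if (n_cycles < 0) stop("n_cycles must be >= 0")
  structure(list(fs = fs, n_cycles = as.integer(n_cycles),
                 noise_snr_db = noise_snr_db, wander_amp = wander_amp,
                 wander_freq = wander_freq, seed = seed),
            class = "sim_options")
}

#' Render a synthetic ECG recording with exact ground truth
#'
#' Each cycle is the sum of five Gaussian bumps placed at the template's
#' offsets from the cycle's R time. Ground-truth peak indices are the
#' extrema of the rendered noise-free signal near each bump center; P and T
#' onsets/offsets are placed at center plus/minus twice the bump width.
#' Noise and baseline wander are added only after the truth is recorded, so
#' they can never alter it.
#'
#' @param template A [generate_subject()] template.
#' @param opt A [sim_options()].
#' @return List with `signal` (an [ecg_signal()]), `truth` (data frame with
#'   the same columns as a fiducial set), and `clean` (the noise-free
#'   samples).
#' @export
render_ecg <- function(template, opt = sim_options()) {
  stopifnot(inherits(template, "subject_template"))
  fs <- opt$fs
  if (opt$n_cycles == 0L) {
    return(list(signal = NULL,
                truth = data.frame(cycle = integer(0), p_on = integer(0),
                                   p_peak = integer(0), p_off = integer(0),
                                   q = integer(0), r = integer(0),
                                   s = integer(0), t_on = integer(0),
                                   t_peak = integer(0), t_off = integer(0)),
                clean = numeric(0)))
  }
  with_local_seed(opt$seed, {
    cycle_s <- 60 / template$heart_rate
    jit <- template$rr_jitter
    rr <- cycle_s * (1 + stats::runif(max(0L, opt$n_cycles - 1L), -jit, jit))
    lead_in <- 0.6 * cycle_s
    r_times <- lead_in + c(0, cumsum(rr))
    total <- r_times[length(r_times)] + 0.7 * cycle_s
    n <- ceiling(total * fs)
    tgrid <- (seq_len(n) - 1) / fs

    clean <- numeric(n)
    for (rt in r_times) {
      for (w in template$waves) {
        clean <- clean + w$amp * exp(-(tgrid - (rt + w$center))^2 /
                                       (2 * w$width^2))
      }
    }

    peak_at <- function(rt, w) {
      c0 <- rt + w$center
      idx <- which(tgrid >= c0 - 2 * w$width & tgrid <= c0 + 2 * w$width)
      idx[which.max(sign(w$amp) * clean[idx])]
    }
    truth <- do.call(rbind, lapply(seq_along(r_times), function(k) {
      rt <- r_times[k]
      wv <- template$waves
      data.frame(
        cycle = k,
        p_on = round((rt + wv$p$center - 2 * wv$p$width) * fs) + 1L,
        p_peak = peak_at(rt, wv$p),
        p_off = round((rt + wv$p$center + 2 * wv$p$width) * fs) + 1L,
        q = peak_at(rt, wv$q),
        r = peak_at(rt, wv$r),
        s = peak_at(rt, wv$s),
        t_on = round((rt + wv$t$center - 2 * wv$t$width) * fs) + 1L,
        t_peak = peak_at(rt, wv$t),
        t_off = round((rt + wv$t$center + 2 * wv$t$width) * fs) + 1L
      )
    }))

    x <- clean
    if (!is.null(opt$noise_snr_db)) {
      noise_sd <- sqrt(mean(clean^2) / 10^(opt$noise_snr_db / 10))
      x <- x + stats::rnorm(n, sd = noise_sd)
    }
    if (opt$wander_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      x <- x + opt$wander_amp * sin(2 * pi * opt$wander_freq * tgrid + phase)
    }
    list(signal = ecg_signal(x, fs, template$subject_id), truth = truth,
         clean = clean)
  })
}

#' Simulate a labelled multi-subject cohort
#'
#' Deterministically derives one template seed and one rendering seed per
#' subject from the master seed, renders `cycles_per_subject` cycles for
#' each and labels subjects `0 .. n_subjects - 1`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param cycles_per_subject Heartbeats per subject recording.
#' @param opt A [sim_options()]; its `seed` is the cohort master seed.
#' @return Object of class `ecg_cohort`: list of recordings, each
#'   `list(signal, truth, template, label)`.
#' @export
make_cohort <- function(n_subjects, cycles_per_subject = 10L,
                        opt = sim_options(seed = 1L)) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  seeds <- with_local_seed(opt$seed,
                           matrix(sample.int(.Machine$integer.max - 1L,
                                             2L * n_subjects),
                                  ncol = 2L))
  recordings <- lapply(seq_len(n_subjects), function(i) {
    label <- i - 1L
    template <- generate_subject(seeds[i, 1L],
                                 subject_id = sprintf("sub%03d", label))
    ropt <- opt
    ropt$n_cycles <- as.integer(cycles_per_subject)
    ropt$seed <- seeds[i, 2L]
    rec <- render_ecg(template, ropt)
    list(signal = rec$signal, truth = rec$truth, template = template,
         label = label)
  })
  structure(recordings, class = "ecg_cohort")
}

#' @export
print.ecg_cohort <- function(x, ...) {
  cat(sprintf("<ecg_cohort> %d subjects, %d cycles each\n", length(x),
              if (length(x)) nrow(x[[1]]$truth) else 0L))
  invisible(x)
}
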