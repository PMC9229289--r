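# Independent oracles and shared fixtures for the test suite.

# Compose the effective filter of detail scale j by direct polynomial
# convolution of the dilated stages (independent of the package's
# stage-by-stage implementation).
cascade_filter <- function(j, bank = spline_wavelet_filters()) {
  up <- function(f, step) {
    if (step == 1) return(f)
    out <- numeric((length(f) - 1) * step + 1)
    out[1 + (seq_along(f) - 1) * step] <- f
    out
  }
  conv <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1)
    for (i in seq_along(a)) {
      out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
    }
    out
  }
  f <- up(bank$g, 2^(j - 1))
  for (stage in rev(seq_len(j - 1))) f <- conv(up(bank$h, 2^(stage - 1)), f)
  f
}

# Direct causal convolution oracle: y[n] = sum_k f[k] x[n - k + 1], zero
# beyond the left boundary (valid away from boundaries only).
direct_conv <- function(x, f) {
  n <- length(x)
  y <- numeric(n)
  for (k in seq_along(f)) {
    idx <- seq_len(n - k + 1)
    y[idx + k - 1] <- y[idx + k - 1] + f[k] * x[idx]
  }
  y
}

# Brute-force 1-nearest-neighbour oracle.
nn_oracle <- function(train_x, train_y, test_x) {
  apply(test_x, 1, function(p) {
    d2 <- rowSums((train_x - matrix(p, nrow(train_x), ncol(train_x),
                                    byrow = TRUE))^2)
    train_y[which.min(d2)]
  })
}

# Hand-built subject template with fixed parameters (bypasses the RNG).
fixed_template <- function(heart_rate = 60, rr_jitter = 0,
                           subject_id = "fix") {
  structure(list(
    waves = list(
      p = list(amp = 0.18, width = 0.038, center = -0.20),
      q = list(amp = -0.12, width = 0.013, center = -0.065),
      r = list(amp = 1.20, width = 0.014, center = 0),
      s = list(amp = -0.20, width = 0.013, center = 0.065),
      t = list(amp = 0.30, width = 0.065, center = 0.25)
    ),
    heart_rate = heart_rate, rr_jitter = rr_jitter,
    subject_id = subject_id
  ), class = "subject_template")
}

# A 20-subject noise-free cohort with fiducials, shared across test files.
.fixture_env <- new.env()
shared_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cohort <- make_cohort(20, 10, sim_options(fs = 360, n_cycles = 10,
                                              seed = 1))
    .fixture_env$cohort <- lapply(cohort, function(rec) {
      rec$fiducials <- suppressMessages(detect_fiducials(rec$signal))
      rec
    })
  }
  .fixture_env$cohort
}
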