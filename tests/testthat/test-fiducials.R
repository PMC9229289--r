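test_that("mean R-R period is the mean of successive differences", {
  expect_equal(mean_rr(c(0, 100, 200)), 100)
  expect_equal(mean_rr(c(0, 100, 220)), 110)
  expect_error(mean_rr(c(500)), "two R peaks")
  expect_error(mean_rr(integer(0)), "two R peaks")
})

test_that("a flat signal yields no R peaks", {
  sig <- ecg_signal(numeric(3600), fs = 360)
  w <- dyadic_swt(sig)
  expect_identical(detect_r_peaks(w, sig), integer(0))
})

test_that("a single Gaussian bump is located at its argmax", {
  fs <- 360
  t <- (0:3599) / fs
  x <- 1.2 * exp(-(t - 1000 / fs)^2 / (2 * 0.015^2))
  sig <- ecg_signal(x, fs)
  r <- detect_r_peaks(dyadic_swt(sig), sig,
                      detection_config(fs))
  expect_length(r, 1L)
  expect_lte(abs(r - 1001L), 1L)  # 1-based index of sample at t = 1000/fs
})

test_that("simulator R peaks are recovered exactly per cycle", {
  rec <- render_ecg(fixed_template(), sim_options(fs = 360, n_cycles = 10))
  sig <- rec$signal
  r <- detect_r_peaks(dyadic_swt(sig), sig, detection_config(sig$fs))
  expect_length(r, 10L)
  expect_true(all(abs(r - rec$truth$r) <= 3))
  expect_equal(mean_rr(r), 360, tolerance = 2 / 360)
})

test_that("Q/S walk returns the third scale-1 extremum", {
  n <- 200L
  s1 <- numeric(n)
  r <- 100L
  s1[r - 4L] <- 1
  s1[r - 9L] <- -0.8
  s1[r - 15L] <- 0.6
  s1[r + 5L] <- -1
  s1[r + 11L] <- 0.7
  s1[r + 18L] <- -0.5
  decomp <- structure(list(
    scales = list(S1 = s1, S2 = numeric(n), S3 = numeric(n), S4 = numeric(n)),
    delays = c(0L, 0L, 0L, 0L), filter_name = "quadratic_spline", n = n
  ), class = "ecg_swt")
  sig <- ecg_signal(numeric(n), fs = 360)
  cfg <- detection_config(360, qs_refine = FALSE)
  qs <- detect_qs(decomp, sig, r_peaks = r, tr = 150, cfg = cfg)
  expect_identical(qs$q, r - 15L)
  expect_identical(qs$s, r + 18L)
})

test_that("Q and S are missing when scale 1 has too few extrema", {
  fs <- 360
  t <- (0:3599) / fs
  x <- 1.2 * exp(-(t - 5)^2 / (2 * 0.015^2))  # lone R-like bump
  sig <- ecg_signal(x, fs)
  decomp <- dyadic_swt(sig)
  qs <- detect_qs(decomp, sig, r_peaks = which.max(x), tr = 360,
                  cfg = detection_config(fs))
  expect_true(is.na(qs$q))
  expect_true(is.na(qs$s))
})

test_that("simulator Q/S/P/T land within tolerance of ground truth", {
  rec <- render_ecg(fixed_template(), sim_options(fs = 360, n_cycles = 10))
  fid <- suppressMessages(detect_fiducials(rec$signal))
  expect_equal(nrow(fid), 10L)
  tru <- rec$truth[fid$cycle, ]
  expect_true(all(abs(fid$q - tru$q) <= 5))
  expect_true(all(abs(fid$s - tru$s) <= 5))
  expect_true(all(abs(fid$p_peak - tru$p_peak) <= 5))
  expect_true(all(abs(fid$t_peak - tru$t_peak) <= 5))
})

test_that("flat inter-beat segments leave P and T missing without error", {
  fs <- 360
  sig <- ecg_signal(numeric(3600), fs)
  pt <- detect_pt(sig, q = c(800L, 1800L), s = c(830L, 1830L), tr = 1000,
                  cfg = detection_config(fs))
  expect_equal(nrow(pt), 2L)
  expect_true(all(is.na(unlist(pt))))
})

test_that("T offset mirrors the onset about the peak by construction", {
  rec <- render_ecg(fixed_template(), sim_options(fs = 360, n_cycles = 8))
  fid <- suppressMessages(detect_fiducials(rec$signal))
  det <- fid[!is.na(fid$t_peak), ]
  expect_gt(nrow(det), 0L)
  expect_identical(det$t_off - det$t_peak, det$t_peak - det$t_on)
  detp <- fid[!is.na(fid$p_peak), ]
  expect_identical(detp$p_off - detp$p_peak, detp$p_peak - detp$p_on)
})

test_that("cycles violating fiducial ordering are excluded, others kept", {
  pt <- data.frame(p_on = NA_integer_, p_peak = NA_integer_,
                   p_off = NA_integer_, t_on = NA_integer_,
                   t_peak = NA_integer_, t_off = NA_integer_)[c(1, 1), ]
  good <- suppressMessages(
    assemble_fiducials(r = c(100L, 400L), q = c(80L, 380L),
                       s = c(120L, 420L), pt = pt, tr = 300)
  )
  expect_equal(nrow(good), 2L)
  expect_identical(attr(good, "excluded"), 0L)

  bad <- suppressMessages(
    assemble_fiducials(r = c(100L, 400L), q = c(80L, 380L),
                       s = c(120L, 395L), pt = pt, tr = 300)
  )
  expect_equal(nrow(bad), 1L)
  expect_identical(attr(bad, "excluded"), 1L)
  expect_equal(bad$r, 100L)
})

test_that("shifting the signal shifts every emitted fiducial equally", {
  rec <- render_ecg(fixed_template(), sim_options(fs = 360, n_cycles = 6))
  x <- rec$signal$samples
  shift <- 100L
  sig1 <- ecg_signal(x, 360)
  sig2 <- ecg_signal(c(numeric(shift), x), 360)
  f1 <- suppressMessages(detect_fiducials(sig1))
  f2 <- suppressMessages(detect_fiducials(sig2))
  expect_equal(nrow(f1), nrow(f2))
  for (col in c("p_on", "p_peak", "p_off", "q", "r", "s", "t_on", "t_peak",
                "t_off")) {
    expect_identical(f2[[col]], f1[[col]] + shift)
  }
})
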