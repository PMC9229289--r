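make_cycle <- function(r = 1000L) {
  list(p_on = r - 120L, p_peak = r - 95L, p_off = r - 70L, q = r - 20L,
       r = r, s = r + 22L, t_on = r + 80L, t_peak = r + 120L,
       t_off = r + 160L)
}

test_that("distances are index differences over the sampling rate", {
  sig <- ecg_signal(sin(seq_len(2000) / 25), fs = 500)
  fv <- extract_features(make_cycle(), next_r = 1400L, sig)
  expect_length(fv, 22L)
  expect_named(fv, ecg_feature_names())
  expect_equal(unname(fv["d_R_Q"]), 20 / 500)   # 20 samples at 500 Hz
  expect_equal(unname(fv["d_R_R"]), 400 / 500)
  expect_equal(unname(fv["d_Pbeg_Pend"]), 50 / 500)
  expect_equal(unname(fv["a_R_Q"]), sig$samples[1000] - sig$samples[980])
  expect_true(all(is.finite(fv)))
})

test_that("identical fiducial offsets give identical vectors", {
  sig <- ecg_signal(rep(sin(seq_len(400) / 20), 5), fs = 400)
  f1 <- extract_features(make_cycle(500L), next_r = 900L, sig)
  f2 <- extract_features(make_cycle(900L), next_r = 1300L, sig)
  expect_equal(unname(f1), unname(f2))
})

test_that("missing fiducials reject the cycle with a reason", {
  sig <- ecg_signal(stats::rnorm(2000), fs = 500)
  cyc <- make_cycle()
  cyc$t_peak <- NA_integer_
  expect_error(extract_features(cyc, 1400L, sig), "t_peak")
})

test_that("amplitude scaling affects only the 6 amplitude features", {
  set.seed(3)
  x <- stats::rnorm(2000)
  s1 <- ecg_signal(x, 500)
  s2 <- ecg_signal(3 * x, 500)
  f1 <- extract_features(make_cycle(), 1400L, s1)
  f2 <- extract_features(make_cycle(), 1400L, s2)
  dist_names <- grep("^d_", ecg_feature_names(), value = TRUE)
  amp_names <- grep("^a_", ecg_feature_names(), value = TRUE)
  expect_equal(f1[dist_names], f2[dist_names])
  expect_equal(3 * f1[amp_names], f2[amp_names])
})

test_that("time-shifting a recording leaves all features unchanged", {
  rec <- render_ecg(fixed_template(), sim_options(fs = 360, n_cycles = 6))
  x <- rec$signal$samples
  shift <- 72L
  f1 <- suppressMessages(detect_fiducials(ecg_signal(x, 360)))
  f2 <- suppressMessages(detect_fiducials(ecg_signal(c(numeric(shift), x), 360)))
  d1 <- build_dataset(list(list(signal = ecg_signal(x, 360), fiducials = f1,
                                label = 0L)), 6L)
  d2 <- build_dataset(list(list(signal = ecg_signal(c(numeric(shift), x), 360),
                                fiducials = f2, label = 0L)), 6L)
  expect_equal(d1[ecg_feature_names()], d2[ecg_feature_names()])
})

test_that("build_dataset keeps the first complete cycles per subject", {
  cohort <- shared_cohort()[1:3]
  recs <- lapply(cohort, function(rec) {
    list(signal = rec$signal, fiducials = rec$fiducials, label = rec$label)
  })
  ds <- build_dataset(recs, cycles_per_subject = 10L)
  expect_equal(nrow(ds), 30L)
  expect_equal(as.vector(table(ds$label)), rep(10L, 3L))
  expect_named(ds, c(ecg_feature_names(), "label", "cycle"))
})

test_that("a shortfall of complete cycles warns and keeps what exists", {
  rec <- render_ecg(fixed_template(), sim_options(fs = 360, n_cycles = 3))
  fid <- suppressMessages(detect_fiducials(rec$signal))
  expect_warning(
    ds <- build_dataset(list(list(signal = rec$signal, fiducials = fid,
                                  label = "a")), cycles_per_subject = 10L),
    "complete cycle"
  )
  expect_lte(nrow(ds), 3L)
  expect_gt(nrow(ds), 0L)
})

test_that("an empty recording list gives an empty matrix", {
  ds <- build_dataset(list(), cycles_per_subject = 10L)
  expect_equal(nrow(ds), 0L)
  expect_true(all(ecg_feature_names() %in% names(ds)))
})

test_that("grouped votes follow the majority with ties to first seen", {
  votes <- group_cycles(c("A", "A", "B"), c("x", "x", "x"), k = 3L)
  expect_equal(votes$vote, "A")
  tie <- group_cycles(c("B", "A", "B", "A"), rep("x", 4), k = 4L)
  expect_equal(tie$vote, "B")
})

test_that("k = 1 grouping is identical to single-cycle classification", {
  preds <- c("A", "B", "A", "C", "C", "C")
  subj <- c("s1", "s1", "s1", "s2", "s2", "s2")
  votes <- group_cycles(preds, subj, k = 1L)
  expect_equal(votes$vote, preds)
  expect_equal(votes$subject, subj)
})

test_that("group votes match an exhaustive enumeration oracle", {
  set.seed(9)
  subj <- rep(paste0("s", 1:5), each = 9)
  preds <- ifelse(stats::runif(45) < 0.7, subj,
                  sample(paste0("s", 1:5), 45, replace = TRUE))
  votes <- group_cycles(preds, subj, k = 3L)
  oracle <- unlist(lapply(paste0("s", 1:5), function(sb) {
    p <- preds[subj == sb]
    vapply(1:3, function(g) {
      grp <- p[((g - 1) * 3 + 1):(g * 3)]
      counts <- vapply(unique(grp), function(u) sum(grp == u), integer(1))
      unique(grp)[which.max(counts)]
    }, character(1))
  }))
  expect_equal(votes$vote, oracle)
  expect_error(group_cycles(preds, subj, k = 10L), "fewer than k")
})
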