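#' Default pipeline configuration
#'
#' Declarative description of a full identification run: one or more
#' simulated cohorts, detection overrides, optional MIV screening, training
#' (fixed or WOA-tuned smoothing factor), the per-subject train/test split
#' and the decision group size. Unknown keys are rejected by
#' [run_pipeline()].
#'
#' @return Nested list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    cohorts = list(list(name = "synthetic", n_subjects = 20L,
                        cycles_per_subject = 10L, fs = 360,
                        noise_snr_db = NULL, wander_amp = 0,
                        wander_freq = 0.33)),
    detection = list(),
    miv = list(enabled = FALSE, alpha = 0.10, threshold = 0.10),
    train = list(delta = 1, tune = FALSE, pop_size = 10L, t_max = 100L,
                 delta_bounds = c(0.01, 10), fitness = "misclassification"),
    split = list(train_frac = 0.7),
    group_k = 3L
  )
}

.merge_config <- function(user, defaults, where = "config") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "))
  }
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]])) {
      defaults[[key]] <- .merge_config(user[[key]], defaults[[key]],
                                       paste0(where, "$", key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Deterministic per-subject train/test split
#'
#' For each subject, the first `ceiling(train_frac * n)` cycles (in row
#' order) go to the training set and the rest to the test set — with 10
#' cycles per subject and the default fraction, 7 train and 3 test.
#'
#' @param features Labelled feature data frame from [build_dataset()].
#' @param train_frac Training fraction per subject.
#' @return List with data frames `train` and `test`.
#' @export
split_by_subject <- function(features, train_frac = 0.7) {
  train_idx <- integer(0)
  for (subj in unique(features$label)) {
    idx <- which(features$label == subj)
    n_tr <- ceiling(train_frac * length(idx))
    train_idx <- c(train_idx, idx[seq_len(n_tr)])
  }
  list(train = features[train_idx, , drop = FALSE],
       test = features[-train_idx, , drop = FALSE])
}

# Detection quality against simulator ground truth.
score_detection <- function(fiducials, truth, tol_r = 3L, tol_pt = 5L) {
  r_det <- attr(fiducials, "r_all")
  r_true <- truth$r
  hit <- vapply(r_true, function(rt) any(abs(r_det - rt) <= tol_r), logical(1))
  claimed <- vapply(r_det, function(rd) any(abs(r_true - rd) <= tol_r),
                    logical(1))
  rate_pt <- function(col) {
    det <- fiducials[[col]]
    tru <- truth[[col]]
    ok <- vapply(seq_along(tru), function(k) {
      any(!is.na(det) & abs(det - tru[k]) <= tol_pt)
    }, logical(1))
    mean(ok)
  }
  list(
    r_recall = mean(hit),
    r_precision = if (length(claimed)) mean(claimed) else NA_real_,
    p_rate = rate_pt("p_peak"),
    t_rate = rate_pt("t_peak")
  )
}

#' Run the full identification pipeline
#'
#' Simulates each configured cohort, delineates every recording, builds the
#' labelled feature matrix, optionally screens features by mean impact
#' value, trains a PNN (with WOA smoothing-factor tuning when
#' `train$tune = TRUE`, using the test split as the fitness set), and
#' reports single-cycle and grouped majority-vote accuracies. With several
#' cohorts a weighted average accuracy is added, weighted by subject counts.
#'
#' @param config Partial configuration; merged over
#'   [default_pipeline_config()], unknown keys rejected.
#' @return Object of class `ecg_report`: list with `config`, per-cohort
#'   results and (for several cohorts) `weighted`, all computed at run time.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- .merge_config(config, default_pipeline_config())
  cohort_results <- list()
  for (ci in seq_along(cfg$cohorts)) {
    cspec <- .merge_config(cfg$cohorts[[ci]],
                           default_pipeline_config()$cohorts[[1L]],
                           "cohort")
    opt <- sim_options(fs = cspec$fs,
                       n_cycles = cspec$cycles_per_subject,
                       noise_snr_db = cspec$noise_snr_db,
                       wander_amp = cspec$wander_amp,
                       wander_freq = cspec$wander_freq,
                       seed = cfg$seed + 1000L * ci)
    cohort <- make_cohort(cspec$n_subjects, cspec$cycles_per_subject, opt)

    det_args <- c(list(fs = cspec$fs), cfg$detection)
    dcfg <- do.call(detection_config, det_args)
    recordings <- lapply(cohort, function(rec) {
      fid <- detect_fiducials(rec$signal, dcfg)
      list(signal = rec$signal, fiducials = fid, truth = rec$truth,
           label = rec$label)
    })

    det_scores <- lapply(recordings, function(rec) {
      score_detection(rec$fiducials, rec$truth)
    })
    det_mean <- lapply(c("r_recall", "r_precision", "p_rate", "t_rate"),
                       function(f) mean(vapply(det_scores, `[[`, numeric(1), f),
                                        na.rm = TRUE))
    names(det_mean) <- c("r_recall", "r_precision", "p_rate", "t_rate")

    features <- suppressWarnings(
      build_dataset(recordings, cspec$cycles_per_subject)
    )
    split <- split_by_subject(features, cfg$split$train_frac)

    retained <- ecg_feature_names()
    miv_report <- NULL
    if (isTRUE(cfg$miv$enabled)) {
      screen_model <- pnn_fit(split$train, delta = cfg$train$delta)
      miv_report <- compute_miv(
        pnn_predictor(screen_model),
        split$train,
        miv_config(cfg$miv$alpha, cfg$miv$threshold)
      )
      retained <- select_features(miv_report)
      if (!length(retained)) retained <- miv_report$ranking[1L]
      keep <- c(retained, "label", "cycle")
      split$train <- split$train[, intersect(keep, names(split$train))]
      split$test <- split$test[, intersect(keep, names(split$test))]
    }

    tuned_delta <- cfg$train$delta
    history <- NULL
    if (isTRUE(cfg$train$tune)) {
      wcfg <- woa_config(bounds = cfg$train$delta_bounds,
                         pop_size = cfg$train$pop_size,
                         t_max = cfg$train$t_max,
                         seed = cfg$seed + 77L * ci)
      tuned <- tune_smoothing_factor(split$train, split$test, wcfg,
                                     fitness = cfg$train$fitness)
      model <- tuned$model
      tuned_delta <- tuned$delta
      history <- tuned$history
    } else {
      model <- pnn_fit(split$train, delta = cfg$train$delta)
    }

    eval1 <- pnn_evaluate(model, split$test)
    acc1 <- 100 * (1 - eval1$error)
    votes <- group_cycles(eval1$predictions, split$test$label,
                          k = cfg$group_k)
    acck <- 100 * mean(as.character(votes$vote) ==
                         as.character(votes$subject))

    cohort_results[[ci]] <- list(
      name = cspec$name,
      n_subjects = cspec$n_subjects,
      cycles = nrow(features),
      detection = det_mean,
      retained_features = retained,
      miv = if (is.null(miv_report)) NULL else as.list(miv_report$miv),
      delta = tuned_delta,
      woa_history = history,
      accuracy_single = round(acc1, 2),
      accuracy_grouped = round(acck, 2),
      group_k = cfg$group_k
    )
  }

  report <- list(config = cfg, cohorts = cohort_results)
  if (length(cohort_results) > 1L) {
    w <- vapply(cohort_results, `[[`, numeric(1), "n_subjects")
    report$weighted <- list(
      accuracy_single = weighted_average(
        vapply(cohort_results, `[[`, numeric(1), "accuracy_single"), w),
      accuracy_grouped = weighted_average(
        vapply(cohort_results, `[[`, numeric(1), "accuracy_grouped"), w)
    )
  }
  structure(report, class = "ecg_report")
}

#' @export
print.ecg_report <- function(x, ...) {
  for (co in x$cohorts) {
    cat(sprintf(
      "%s: %d subjects, %d cycles | delta = %.4f | single %.2f%% | %d-cycle %.2f%%\n",
      co$name, co$n_subjects, co$cycles, co$delta, co$accuracy_single,
      co$group_k, co$accuracy_grouped))
  }
  if (!is.null(x$weighted)) {
    cat(sprintf("weighted: single %.2f%% | grouped %.2f%%\n",
                x$weighted$accuracy_single, x$weighted$accuracy_grouped))
  }
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' @param report An `ecg_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
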