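#' The 22 per-cycle characteristic values
#'
#' Fixed, ordered names of the feature vector: 16 interval features in
#' seconds (`d_*`, absolute fiducial index differences divided by the
#' sampling rate; `d_R_R` uses the next cycle's R peak) followed by 6 signed
#' amplitude features in signal units (`a_*`, sample value at the first
#' point minus sample value at the second). `Pbeg`/`Pend` denote P onset and
#' offset, `Tbeg`/`Tend` T onset and offset.
#'
#' @return Character vector of length 22.
#' @export
ecg_feature_names <- function() {
  c("d_R_R", "d_R_Q", "d_R_S", "d_R_P", "d_R_T",
    "d_R_Pbeg", "d_R_Pend", "d_R_Tbeg", "d_R_Tend",
    "d_Q_P", "d_Q_Pbeg", "d_S_T", "d_S_Tend", "d_P_T",
    "d_Pbeg_Pend", "d_Tbeg_Tend",
    "a_R_Q", "a_R_S", "a_Q_P", "a_S_T", "a_Pbeg_P", "a_Tbeg_T")
}

#' Extract the 22 characteristic values of one cycle
#'
#' @param cycle One row of a [fiducial_set][assemble_fiducials()] (data frame
#'   or list with fields `p_on`, `p_peak`, `p_off`, `q`, `r`, `s`, `t_on`,
#'   `t_peak`, `t_off`), all present.
#' @param next_r R peak index of the following cycle (for the R-R interval).
#' @param signal The [ecg_signal()] the fiducials refer to.
#' @return Named numeric vector of length 22 in [ecg_feature_names()] order.
#' @examples
#' sig <- ecg_signal(sin(seq_len(2000) / 40), fs = 500)
#' cyc <- list(p_on = 880, p_peak = 905, p_off = 930, q = 980, r = 1000,
#'             s = 1020, t_on = 1080, t_peak = 1120, t_off = 1160)
#' extract_features(cyc, next_r = 1400, sig)
#' @export
extract_features <- function(cycle, next_r, signal) {
  stopifnot(inherits(signal, "ecg_signal"))
  fields <- c("p_on", "p_peak", "p_off", "q", "r", "s", "t_on", "t_peak",
              "t_off")
  v <- vapply(fields, function(f) as.numeric(cycle[[f]]), numeric(1))
  if (any(is.na(v)) || is.na(next_r)) {
    stop("incomplete cycle: missing fiducial(s) ",
         paste(fields[is.na(v)], collapse = ", "))
  }
  fs <- signal$fs
  x <- signal$samples
  dsec <- function(a, b) abs(a - b) / fs
  amp <- function(a, b) x[a] - x[b]
  p_on <- v[["p_on"]]; p_peak <- v[["p_peak"]]; p_off <- v[["p_off"]]
  q <- v[["q"]]; r <- v[["r"]]; s <- v[["s"]]
  t_on <- v[["t_on"]]; t_peak <- v[["t_peak"]]; t_off <- v[["t_off"]]
  out <- c(
    dsec(next_r, r), dsec(r, q), dsec(r, s), dsec(r, p_peak), dsec(r, t_peak),
    dsec(r, p_on), dsec(r, p_off), dsec(r, t_on), dsec(r, t_off),
    dsec(q, p_peak), dsec(q, p_on), dsec(s, t_peak), dsec(s, t_off),
    dsec(p_peak, t_peak), dsec(p_on, p_off), dsec(t_on, t_off),
    amp(r, q), amp(r, s), amp(q, p_peak), amp(s, t_peak),
    amp(p_on, p_peak), amp(t_on, t_peak)
  )
  names(out) <- ecg_feature_names()
  out
}

#' Build a labelled feature matrix from delineated recordings
#'
#' Retains, per recording, the first `cycles_per_subject` cycles whose
#' fiducials are all present, extracts the 22 characteristic values of each
#' and stacks them with the subject label. The R-R interval of a cycle uses
#' the next detected R peak; the last cycle reuses the previous interval.
#' Row order is deterministic: recordings in input order, cycles in time
#' order.
#'
#' @param recordings List of `list(signal = <ecg_signal>, fiducials =
#'   <fiducial_set>, label = <subject id>)`.
#' @param cycles_per_subject Number of cycles to retain per subject.
#' @return Data frame with the 22 feature columns, plus `label` and `cycle`.
#' @export
build_dataset <- function(recordings, cycles_per_subject = 10L) {
  rows <- list()
  for (rec in recordings) {
    fid <- rec$fiducials
    sig <- rec$signal
    r_all <- attr(fid, "r_all")
    complete <- stats::complete.cases(
      fid[, c("p_on", "p_peak", "p_off", "q", "r", "s", "t_on", "t_peak",
              "t_off")]
    )
    keep <- which(complete)
    if (length(keep) < cycles_per_subject) {
      warning(sprintf("subject %s: only %d complete cycle(s) of %d requested",
                      rec$label, length(keep), cycles_per_subject))
    }
    keep <- keep[seq_len(min(length(keep), cycles_per_subject))]
    prev_rr <- NA_real_
    for (k in keep) {
      r_here <- fid$r[k]
      nxt <- r_all[r_all > r_here]
      next_r <- if (length(nxt)) nxt[1L] else r_here + prev_rr
      if (is.na(next_r)) next
      feats <- extract_features(fid[k, ], next_r, sig)
      prev_rr <- next_r - r_here
      rows[[length(rows) + 1L]] <- c(as.list(feats),
                                     list(label = rec$label,
                                          cycle = fid$cycle[k]))
    }
  }
  if (!length(rows)) {
    out <- as.data.frame(matrix(numeric(0), ncol = 22,
                                dimnames = list(NULL, ecg_feature_names())))
    out$label <- character(0)
    out$cycle <- integer(0)
    return(out)
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Majority-vote decisions over groups of consecutive cycles
#'
#' Splits the per-cycle predictions of each subject into consecutive,
#' non-overlapping groups of `k` cycles and returns one majority-vote label
#' per group (ties go to the label seen first within the group). With
#' `k = 1` this reduces to single-cycle classification.
#'
#' @param predictions Vector of predicted labels, ordered by subject then
#'   cycle.
#' @param subjects True subject label of each prediction (defines grouping).
#' @param k Cycles per decision group.
#' @return Data frame with columns `subject` (truth) and `vote` (decision),
#'   one row per complete group.
#' @export
group_cycles <- function(predictions, subjects, k = 3L) {
  stopifnot(length(predictions) == length(subjects))
  if (k < 1L) stop("k must be >= 1")
  out_subject <- c()
  out_vote <- c()
  for (subj in unique(subjects)) {
    idx <- which(subjects == subj)
    if (length(idx) < k) {
      stop("subject ", subj, " has fewer than k = ", k, " cycles")
    }
    n_groups <- length(idx) %/% k
    for (g in seq_len(n_groups)) {
      members <- predictions[idx[((g - 1L) * k + 1L):(g * k)]]
      tab <- table(factor(members, levels = unique(members)))
      out_subject <- c(out_subject, subj)
      out_vote <- c(out_vote, names(tab)[which.max(tab)])
    }
  }
  data.frame(subject = out_subject, vote = out_vote,
             stringsAsFactors = FALSE)
}
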