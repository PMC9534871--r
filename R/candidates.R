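#' Detector configuration
#'
#' Collects the tunable durations of the two-stage detector. All durations are
#' in milliseconds and converted to samples through the recording's sampling
#' rate; `t_s` (the autotriggering gap threshold) is in seconds.
#'
#' @param omega_lm_ms length of the centered local-maximum window used for
#'   candidate over-detection (default 270 ms).
#' @param omega_re_ms length of the centered window-minimum rule used to locate
#'   inspiration onset / expiration end (default 150 ms).
#' @param delta_ms matching tolerance: a detected peak within `delta_ms` of a
#'   ground-truth peak counts as that peak (default 140 ms, 10 ms under the
#'   minimum inter-peak distance seen in neonatal ground truth).
#' @param sigma amplitude scalar: onset/offset must fall below `sigma` times
#'   the smaller of the two flanking peak amplitudes (default 0.5).
#' @param t_s minimum silent-gap duration, in seconds, for an autotriggering
#'   episode (default 5).
#' @param window_len classifier input length in samples (default 256, i.e.
#'   2.56 s at 100 Hz, wide enough to hold one neonatal breath and its
#'   immediate context).
#' @return a list of class `detector_config`.
#' @export
detector_config <- function(omega_lm_ms = 270, omega_re_ms = 150,
                            delta_ms = 140, sigma = 0.5, t_s = 5,
                            window_len = 256) {
  stopifnot(omega_lm_ms > 0, omega_re_ms > 0, delta_ms > 0,
            sigma > 0, sigma <= 1, t_s > 0, window_len >= 2)
  structure(list(omega_lm_ms = omega_lm_ms, omega_re_ms = omega_re_ms,
                 delta_ms = delta_ms, sigma = sigma, t_s = t_s,
                 window_len = as.integer(window_len)),
            class = "detector_config")
}

#' Over-detect candidate peaks by the centered local-maximum rule
#'
#' A sample x is a candidate peak when its Edi value attains the maximum of
#' the centered window of length omega around x (half-width
#' `w = round(omega/2 / dt)` samples, so the window is `[x - w, x + w]`).
#' Samples closer than `w` to either end of the recording produce no
#' candidates (the rule requires x to sit in the middle of a full window). On
#' plateaus (runs of consecutive equal values that all attain the window
#' maximum) only the leftmost sample of each run is emitted, otherwise a flat
#' stretch would flood the candidate set.
#'
#' A smaller omega admits more candidates; the default 270 ms was tuned so
#' that every true neonatal inspiratory peak survives while the number of
#' artifact maxima stays manageable for the second-stage classifier.
#'
#' @param recording an [recording()] object.
#' @param omega_lm_ms window length in milliseconds (default 270).
#' @return an [peak_set()] with `source = "lm"`.
#' @export
detect_local_maxima <- function(recording, omega_lm_ms = 270) {
  stopifnot(inherits(recording, "edi_recording"), omega_lm_ms > 0)
  x <- recording$edi
  n <- length(x)
  w <- ms_to_samples(omega_lm_ms / 2, recording$sampling_rate)
  if (2L * w + 1L > n) stop("local-maximum window larger than the recording")
  if (w == 0L) {
    # degenerate window: every sample is its own maximum; plateau rule applies
    keep <- c(TRUE, diff(x) != 0)
    return(peak_set(which(keep), source = "lm",
                    patient_id = recording$patient_id))
  }
  winmax <- zoo::rollmax(x, k = 2L * w + 1L, align = "center")
  centers <- (w + 1L):(n - w)               # indices with a full window
  is_max <- x[centers] == winmax
  cand <- centers[is_max]
  if (length(cand) > 1L) {
    # leftmost-of-plateau: drop x if x-1 is also a candidate with equal value
    prev_in <- c(FALSE, diff(cand) == 1L)
    drop <- prev_in & c(FALSE, x[cand[-1L]] == x[cand[-length(cand)]])
    cand <- cand[!drop]
  }
  peak_set(cand, source = "lm", patient_id = recording$patient_id)
}

#' Candidate windows for the classifier
#'
#' Extracts, for each peak position, the centered excerpt of `window_len`
#' samples from the Edi channel, zero-padding where the window overruns the
#' recording, and z-normalizes each window independently (mean 0, sd 1; an
#' all-constant window becomes all zeros). These fixed-length excerpts are the
#' classifier input: one candidate breath plus its immediate context.
#'
#' @param recording an [recording()] object.
#' @param peaks an [peak_set()] of candidate centers.
#' @param window_len window length in samples (default 256).
#' @return a list of `candidate_window` objects, each with fields `center`,
#'   `values` (length `window_len`), `label`
#'   (`"true_peak"`/`"false_peak"`/`"unlabeled"`), and `patient_id`.
#' @export
extract_windows <- function(recording, peaks, window_len = 256) {
  stopifnot(inherits(recording, "edi_recording"),
            inherits(peaks, "edi_peakset"))
  window_len <- as.integer(window_len)
  x <- recording$edi
  n <- length(x)
  if (length(peaks$positions) &&
      (min(peaks$positions) < 1L || max(peaks$positions) > n)) {
    stop("peak position outside the recording")
  }
  half_l <- (window_len - 1L) %/% 2L        # samples left of the center
  lapply(peaks$positions, function(p) {
    idx <- (p - half_l):(p - half_l + window_len - 1L)
    v <- numeric(window_len)
    ok <- idx >= 1L & idx <= n
    v[ok] <- x[idx[ok]]
    s <- stats::sd(v)
    v <- if (is.na(s) || s == 0) numeric(window_len) else (v - mean(v)) / s
    structure(list(center = p, values = v, label = "unlabeled",
                   patient_id = recording$patient_id),
              class = "candidate_window")
  })
}

#' Label candidate windows against ground truth
#'
#' A candidate is a `true_peak` when a ground-truth peak lies within the
#' tolerance delta of its center; each ground-truth peak may validate at most
#' one candidate (one-to-one, nearest pair first, leftmost on distance ties),
#' so two candidates sitting on the same breath cannot both count as true.
#' All remaining candidates are `false_peak`.
#'
#' @param candidates list of windows from [extract_windows()].
#' @param ground_truth an [peak_set()] with the annotated peaks.
#' @param delta_ms tolerance in milliseconds (default 140).
#' @param sampling_rate Hz used to convert `delta_ms` to samples.
#' @return the same list with `label` filled in.
#' @export
label_candidates <- function(candidates, ground_truth, delta_ms = 140,
                             sampling_rate = 100) {
  centers <- vapply(candidates, `[[`, 0L, "center")
  m <- match_positions(centers, ground_truth$positions,
                       delta = ms_to_samples(delta_ms, sampling_rate))
  matched <- rep(FALSE, length(centers))
  if (nrow(m$pairs)) matched[m$pairs[, 1L]] <- TRUE
  for (i in seq_along(candidates)) {
    candidates[[i]]$label <- if (matched[i]) "true_peak" else "false_peak"
  }
  candidates
}
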