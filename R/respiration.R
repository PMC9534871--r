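#' Asynchrony event
#'
#' One double-triggering or autotriggering episode. Double triggering: two or
#' more positive-pressure inflations delivered within one neural breath
#' (episode = the breath's onset-to-offset interval). Autotriggering: an
#' inflation delivered inside a neural silence, i.e. a gap from one breath's
#' expiration end to the next breath's inspiration onset longer than the
#' threshold `t`; each such inflation is one event and the episode is the gap.
#'
#' @param kind `"double_triggering"` or `"autotriggering"`.
#' @param start,end sample indices of the episode interval.
#' @param n_inflations number of inflations involved.
#' @return a list of class `asynchrony_event`.
#' @export
asynchrony_event <- function(kind = c("double_triggering", "autotriggering"),
                             start, end, n_inflations = 1L) {
  kind <- match.arg(kind)
  stopifnot(start < end,
            !(kind == "double_triggering") || n_inflations >= 2L,
            n_inflations >= 1L)
  structure(list(kind = kind, start = as.integer(start), end = as.integer(end),
                 n_inflations = as.integer(n_inflations)),
            class = "asynchrony_event")
}

#' Segment neural breaths between detected peaks
#'
#' For each pair of adjacent peaks the rule scans the gap for the first sample
#' that (a) attains the minimum of its centered window of length
#' `omega_re_ms` and (b) lies below `sigma` times the smaller of the two
#' flanking peak amplitudes. Scanning from the later peak backwards, the first
#' qualifying sample is the inspiration onset of the breath peaking at that
#' later peak; scanning forwards from the earlier peak, the first qualifying
#' sample is the expiration end of the breath peaking at the earlier peak.
#' The window must lie entirely inside the gap. If no sample in a gap
#' qualifies (e.g. the valley never drops below the sigma threshold), the
#' global minimum of the gap is used for both boundaries and the affected
#' breaths are flagged, so breath counts remain usable for respiratory rate.
#'
#' Breaths are assembled as (onset, peak, offset) for every peak that has both
#' a preceding and a following gap; the first and last peak of a recording
#' therefore do not yield a complete breath.
#'
#' @param recording an [recording()] object.
#' @param peaks an [peak_set()] with at least 2 peaks.
#' @param omega_re_ms window-minimum length in milliseconds (default 150).
#' @param sigma amplitude scalar in (0, 1] (default 0.5).
#' @return list of `breath` objects: `onset`, `peak`, `offset` sample indices
#'   and a logical `flagged` marking fallback boundaries.
#' @export
detect_respiratory_events <- function(recording, peaks, omega_re_ms = 150,
                                      sigma = 0.5) {
  stopifnot(inherits(recording, "edi_recording"),
            inherits(peaks, "edi_peakset"), sigma > 0, sigma <= 1)
  p <- peaks$positions
  if (length(p) < 2L) stop("need at least 2 peaks to segment breaths")
  x <- recording$edi
  v <- ms_to_samples(omega_re_ms / 2, recording$sampling_rate)
  n <- length(x)
  # centered window minimum for every sample with a full window
  winmin <- rep(NA_real_, n)
  if (2L * v + 1L <= n) {
    winmin[(v + 1L):(n - v)] <- -zoo::rollmax(-x, k = 2L * v + 1L,
                                              align = "center")
  }
  m <- length(p)
  onset_of <- rep(NA_integer_, m)   # onset of breath peaking at p[k]
  offset_of <- rep(NA_integer_, m)  # offset of breath peaking at p[k]
  fb_onset <- rep(FALSE, m); fb_offset <- rep(FALSE, m)
  for (k in seq_len(m - 1L)) {
    a <- p[k]; b <- p[k + 1L]
    th <- sigma * min(x[a], x[b])
    lo <- a + 1L + v; hi <- b - 1L - v    # window fully inside the open gap
    qual <- integer(0)
    if (lo <= hi) {
      idx <- lo:hi
      qual <- idx[!is.na(winmin[idx]) & x[idx] == winmin[idx] & x[idx] < th]
    }
    if (length(qual)) {
      offset_of[k] <- qual[1L]            # first found scanning a -> b
      onset_of[k + 1L] <- qual[length(qual)]  # first found scanning b -> a
    } else {
      gap <- (a + 1L):(b - 1L)
      gmin <- gap[which.min(x[gap])]      # leftmost on ties
      offset_of[k] <- gmin; onset_of[k + 1L] <- gmin
      fb_offset[k] <- TRUE; fb_onset[k + 1L] <- TRUE
    }
  }
  out <- list()
  for (k in seq_len(m)) {
    if (!is.na(onset_of[k]) && !is.na(offset_of[k])) {
      out[[length(out) + 1L]] <- structure(
        list(onset = onset_of[k], peak = p[k], offset = offset_of[k],
             flagged = fb_onset[k] || fb_offset[k]),
        class = "breath")
    }
  }
  out
}

#' Respiratory rate per epoch from peak counts
#'
#' Counts peaks in consecutive non-overlapping epochs and scales to
#' breaths/min; a trailing partial epoch is dropped.
#'
#' @param peaks an [peak_set()].
#' @param n_total recording length in samples.
#' @param epoch_s epoch length in seconds (default 60).
#' @param sampling_rate Hz.
#' @return data.frame with columns `epoch` (1-based index) and `rate`
#'   (breaths/min).
#' @export
respiratory_rate <- function(peaks, n_total, epoch_s = 60,
                             sampling_rate = 100) {
  stopifnot(epoch_s > 0)
  e_len <- epoch_s * sampling_rate
  n_epochs <- floor(n_total / e_len)
  if (n_epochs < 1) stop("recording shorter than one epoch")
  counts <- vapply(seq_len(n_epochs), function(e) {
    sum(peaks$positions > (e - 1) * e_len & peaks$positions <= e * e_len)
  }, 0)
  data.frame(epoch = seq_len(n_epochs), rate = counts * 60 / epoch_s)
}

#' Detect positive-pressure inflations in the airway pressure channel
#'
#' An inflation is a maximal run of samples where pressure exceeds
#' `baseline + rise_frac * (peak - baseline)`, with baseline taken as the
#' `baseline_q` quantile of the channel (the PEEP plateau) and peak as the
#' `peak_q` quantile (near PIP). Runs separated by less than `merge_gap_ms`
#' are merged, then runs shorter than `min_dur_ms` are discarded as chatter.
#'
#' @param recording an [recording()] with a pressure channel.
#' @param rise_frac fraction of the baseline-to-peak rise used as threshold
#'   (default 0.5).
#' @param baseline_q,peak_q quantile levels for baseline and peak pressure
#'   (defaults 0.10 and 0.95).
#' @param min_dur_ms minimum inflation duration in ms (default 100).
#' @param merge_gap_ms gaps shorter than this are bridged (default 100).
#' @return list of `mechanical_inflation` objects: `start`, `end`,
#'   `peak_pressure`.
#' @export
detect_inflations <- function(recording, rise_frac = 0.5, baseline_q = 0.10,
                              peak_q = 0.95, min_dur_ms = 100,
                              merge_gap_ms = 100) {
  stopifnot(inherits(recording, "edi_recording"))
  pr <- recording$pressure
  if (is.null(pr)) stop("recording has no pressure channel")
  base <- stats::quantile(pr, baseline_q, names = FALSE)
  pk <- stats::quantile(pr, peak_q, names = FALSE)
  thr <- base + rise_frac * (pk - base)
  above <- pr > thr
  if (!any(above)) return(list())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(start = starts[r$values], end = ends[r$values])
  fs <- recording$sampling_rate
  merge_gap <- ms_to_samples(merge_gap_ms, fs)
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2L:nrow(runs)) {
      if (runs[i, "start"] - merged[nrow(merged), "end"] < merge_gap) {
        merged[nrow(merged), "end"] <- runs[i, "end"]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  min_dur <- ms_to_samples(min_dur_ms, fs)
  keep <- (merged[, "end"] - merged[, "start"] + 1L) >= min_dur
  merged <- merged[keep, , drop = FALSE]
  lapply(seq_len(nrow(merged)), function(i) {
    s <- merged[i, "start"]; e <- merged[i, "end"]
    structure(list(start = s, end = e, peak_pressure = max(pr[s:e])),
              class = "mechanical_inflation")
  })
}

#' Detect double-triggering episodes
#'
#' For each neural breath, inflations whose start lies within the breath's
#' onset-to-offset interval are counted; two or more constitute one
#' double-triggering event whose episode is the breath interval.
#'
#' @param breaths list of breaths from [detect_respiratory_events()], sorted.
#' @param inflations list from [detect_inflations()], sorted.
#' @return list of [asynchrony_event()] objects of kind `double_triggering`.
#' @export
detect_double_triggering <- function(breaths, inflations) {
  starts <- vapply(inflations, `[[`, 0L, "start")
  out <- list()
  for (b in breaths) {
    k <- sum(starts >= b$onset & starts <= b$offset)
    if (k >= 2L) {
      out[[length(out) + 1L]] <- asynchrony_event(
        "double_triggering", b$onset, b$offset, n_inflations = k)
    }
  }
  out
}

#' Detect autotriggering events
#'
#' For each gap between consecutive breaths (expiration end to the next
#' inspiration onset) lasting longer than `t_s` seconds, every inflation
#' starting inside the gap is one autotriggering event: a ventilator inflation
#' with no neural respiration behind it. The episode is the gap interval.
#'
#' @param breaths list of breaths, sorted.
#' @param inflations list of inflations, sorted.
#' @param t_s silent-gap threshold in seconds (default 5).
#' @param sampling_rate Hz.
#' @return list of [asynchrony_event()] objects of kind `autotriggering`.
#' @export
detect_autotriggering <- function(breaths, inflations, t_s = 5,
                                  sampling_rate = 100) {
  starts <- vapply(inflations, `[[`, 0L, "start")
  out <- list()
  if (length(breaths) < 2L) return(out)
  for (i in seq_len(length(breaths) - 1L)) {
    g0 <- breaths[[i]]$offset; g1 <- breaths[[i + 1L]]$onset
    if ((g1 - g0) / sampling_rate > t_s) {
      inside <- sum(starts > g0 & starts < g1)
      if (inside > 0L) {
        for (j in seq_len(inside)) {
          out[[length(out) + 1L]] <- asynchrony_event(
            "autotriggering", g0, g1, n_inflations = 1L)
        }
      }
    }
  }
  out
}
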