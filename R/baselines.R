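#' First-derivative peak detector with adaptive threshold (FDA)
#'
#' Splits the signal into consecutive blocks of `block_s` seconds, extracts
#' candidate peaks where the first difference changes sign from positive to
#' negative (on flat tops, the leftmost sample of the plateau), and keeps
#' candidates whose amplitude exceeds the block's adaptive threshold: the mean
#' Edi amplitude over the first `thresh_s` seconds of the block (or the whole
#' block when it is shorter). The final partial block is processed the same
#' way with its own threshold.
#'
#' @param recording an [recording()] at least `block_s` seconds long.
#' @param block_s block length in seconds (default 5).
#' @param thresh_s leading stretch of each block averaged for the threshold
#'   (default 2).
#' @return an [peak_set()] with `source = "fda"`.
#' @export
fda_detect <- function(recording, block_s = 5, thresh_s = 2) {
  stopifnot(inherits(recording, "edi_recording"))
  x <- recording$edi
  fs <- recording$sampling_rate
  n <- length(x)
  if (n < block_s * fs) stop("recording shorter than one FDA block")
  block_len <- as.integer(round(block_s * fs))
  thr_len <- as.integer(round(thresh_s * fs))
  starts <- seq(1L, n, by = block_len)
  out <- integer(0)
  for (s in starts) {
    e <- min(s + block_len - 1L, n)
    b <- x[s:e]
    cand <- sign_change_maxima(b)
    if (length(cand)) {
      thr <- mean(b[seq_len(min(thr_len, length(b)))])
      cand <- cand[b[cand] > thr]
      out <- c(out, cand + s - 1L)
    }
  }
  peak_set(out, source = "fda", patient_id = recording$patient_id)
}

#' @keywords internal
#' Indices where the first difference crosses from + to - (leftmost sample of
#' a flat top). A zero-run between a rise and a fall counts as part of the top.
sign_change_maxima <- function(b) {
  if (length(b) < 3L) return(integer(0))
  d <- diff(b)
  s <- sign(d)
  # backward-fill zeros with the next nonzero sign so a plateau inherits the
  # direction of the movement that ends it
  nz <- s != 0
  filled <- s
  if (any(nz)) {
    idx <- rev(seq_along(s))
    nxt <- 0
    for (i in idx) {
      if (s[i] != 0) nxt <- s[i] else filled[i] <- nxt
    }
  }
  which(s[-length(s)] > 0 & filled[-1L] < 0) + 1L
}

#' Moving-average peak detector with dynamic threshold (MAD)
#'
#' Mean-centers the signal, clips negative values to zero, squares, then
#' computes two centered moving averages: a short one at the event scale and a
#' long one at the breath scale. Maximal runs where the short average exceeds
#' the long one form blocks; each block contributes exactly one peak, the
#' sample with the largest (squared) amplitude inside it (leftmost on ties).
#' Blocks shorter than half the short window are discarded as noise chatter.
#'
#' @param recording an [recording()] object.
#' @param short_ms short (event-scale) moving-average window in ms
#'   (default 150).
#' @param long_ms long (breath-scale) moving-average window in ms
#'   (default 1000).
#' @return an [peak_set()] with `source = "mad"`.
#' @export
mad_detect <- function(recording, short_ms = 150, long_ms = 1000) {
  stopifnot(inherits(recording, "edi_recording"))
  x <- recording$edi
  fs <- recording$sampling_rate
  sq <- pmax(x - mean(x), 0)^2
  ls <- max(ms_to_samples(short_ms, fs), 1L)
  ll <- max(ms_to_samples(long_ms, fs), 1L)
  ma_s <- centered_ma(sq, ls)
  ma_l <- centered_ma(sq, ll)
  above <- ma_s > ma_l
  if (!any(above)) {
    return(peak_set(integer(0), source = "mad",
                    patient_id = recording$patient_id))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blocks <- cbind(start = starts[r$values], end = ends[r$values])
  keep <- (blocks[, "end"] - blocks[, "start"] + 1L) >= ls / 2
  blocks <- blocks[keep, , drop = FALSE]
  pk <- vapply(seq_len(nrow(blocks)), function(i) {
    idx <- blocks[i, "start"]:blocks[i, "end"]
    idx[which.max(sq[idx])]
  }, 0L)
  peak_set(sort(pk), source = "mad", patient_id = recording$patient_id)
}

#' @keywords internal
#' Centered moving average of window length `len`, truncated at the edges
#' (each output is the mean of the available samples in
#' [i - floor((len-1)/2), i + ceiling((len-1)/2)]). O(n) via cumulative sums.
centered_ma <- function(x, len) {
  n <- length(x)
  hl <- (len - 1L) %/% 2L
  hr <- len - 1L - hl
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - hl, 1L)
  hi <- pmin(seq_len(n) + hr, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
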