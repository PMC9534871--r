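#' Specification for a synthetic neonatal Edi recording
#'
#' Defines the conditions a generated recording emulates: a neonatal breath
#' train (high respiratory rate, short breaths) riding on a tonic baseline,
#' contaminated by white measurement noise, periodic cardiac artifact spikes,
#' slow baseline wander, and occasional esophageal-peristalsis bursts (smooth
#' bumps wider and slower than breaths that deliberately create false local
#' maxima for the classifier's negative class). A ventilator pressure channel
#' carries one triggered inflation per breath; double-triggered inflations and
#' inflations inside injected apneas can be added at specified rates.
#'
#' Default amplitudes are in microvolts on the scale of neonatal Edi
#' envelopes (breath peaks around 12 uV over a 1 uV tonic floor); the default
#' noise levels constitute the package's "moderate noise" condition; set all
#' noise amplitudes to zero for the clean limit.
#'
#' @param duration_s recording length in seconds.
#' @param rr_mean mean respiratory rate (breaths/min); neonates on assisted
#'   ventilation typically 40-60.
#' @param rr_cv coefficient of variation of the breath-to-breath interval.
#' @param peak_amp_mean mean inspiratory peak amplitude (uV).
#' @param peak_amp_cv coefficient of variation of peak amplitudes.
#' @param tonic_baseline tonic diaphragm activity floor (uV).
#' @param min_peak_spacing_ms minimum allowed inter-peak spacing (default 150).
#' @param noise_sd white noise standard deviation (uV).
#' @param cardiac_amp,cardiac_rate cardiac artifact spike amplitude (uV) and
#'   rate (beats/min).
#' @param wander_amp,wander_period_s baseline wander amplitude (uV) and period.
#' @param peristalsis_rate,peristalsis_amp,peristalsis_width_s burst rate
#'   (bursts/min), amplitude (uV) and width (s).
#' @param motion_rate,motion_amp,motion_width_s electrode motion artifacts:
#'   brief sharp transients (rate/min, amplitude in uV, width in s), the main
#'   source of false candidate peaks.
#' @param apnea_count number of injected apneic gaps.
#' @param apnea_duration_s duration of each apnea (must exceed the
#'   autotriggering threshold `t` for autotrigger injection to be meaningful).
#' @param double_trigger_rate expected double-triggering injections per minute.
#' @param autotrigger_count inflations injected into each apnea (integer;
#'   0 for none).
#' @param seed integer seed; the same spec and seed give bit-identical output.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(duration_s = 180, rr_mean = 50, rr_cv = 0.08,
                           peak_amp_mean = 12, peak_amp_cv = 0.2,
                           tonic_baseline = 1, min_peak_spacing_ms = 150,
                           noise_sd = 0.3, cardiac_amp = 0.8,
                           cardiac_rate = 150, wander_amp = 0.5,
                           wander_period_s = 20, peristalsis_rate = 2,
                           peristalsis_amp = 4, peristalsis_width_s = 2,
                           motion_rate = 10, motion_amp = 3,
                           motion_width_s = 0.25,
                           apnea_count = 0, apnea_duration_s = 7,
                           double_trigger_rate = 0, autotrigger_count = 0,
                           seed = 1) {
  spec <- list(duration_s = duration_s, rr_mean = rr_mean, rr_cv = rr_cv,
               peak_amp_mean = peak_amp_mean, peak_amp_cv = peak_amp_cv,
               tonic_baseline = tonic_baseline,
               min_peak_spacing_ms = min_peak_spacing_ms,
               noise_sd = noise_sd, cardiac_amp = cardiac_amp,
               cardiac_rate = cardiac_rate, wander_amp = wander_amp,
               wander_period_s = wander_period_s,
               peristalsis_rate = peristalsis_rate,
               peristalsis_amp = peristalsis_amp,
               peristalsis_width_s = peristalsis_width_s,
               motion_rate = motion_rate, motion_amp = motion_amp,
               motion_width_s = motion_width_s,
               apnea_count = apnea_count,
               apnea_duration_s = apnea_duration_s,
               double_trigger_rate = double_trigger_rate,
               autotrigger_count = autotrigger_count, seed = seed)
  stopifnot(duration_s > 0, rr_mean > 0, rr_cv >= 0, peak_amp_mean > 0,
            peak_amp_cv >= 0, tonic_baseline >= 0, noise_sd >= 0,
            cardiac_amp >= 0, wander_amp >= 0, peristalsis_rate >= 0,
            peristalsis_amp >= 0, motion_rate >= 0, motion_amp >= 0,
            apnea_count >= 0, apnea_duration_s > 0,
            double_trigger_rate >= 0, autotrigger_count >= 0,
            60000 / rr_mean > min_peak_spacing_ms)
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic Edi/pressure recording with ground truth
#'
#' Builds the Edi channel as tonic baseline + per-breath pulses + noise
#' components, clipped at zero. Each breath pulse is an asymmetric
#' raised-cosine: ~35% of the breath envelope rising to the peak (neural
#' inspiration) and ~65% decaying back (expiration); amplitudes and intervals
#' are jittered per breath. The pressure channel holds one square-ish
#' inflation per breath (ramped rise to PIP, delayed ~60 ms after the neural
#' onset) plus any injected double-trigger and autotrigger inflations. The
#' truth records every peak, breath, inflation and injected asynchrony event.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `recording` (an [recording()]) and `truth` (class
#'   `synthetic_truth`): `peaks` ([peak_set()] with source `ground_truth`),
#'   `breaths`, `inflations`, `events`.
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_recording_impl(spec))
}

#' @keywords internal
generate_recording_impl <- function(spec) {
  fs <- 100
  n <- as.integer(round(spec$duration_s * fs))
  t_mean <- 60 / spec$rr_mean                  # mean breath interval (s)
  min_gap <- spec$min_peak_spacing_ms / 1000

  # --- breath train: jittered intervals, truncated at the minimum spacing
  n_draw <- ceiling(spec$duration_s / t_mean * 1.6) + 8
  ints <- stats::rnorm(n_draw, t_mean, spec$rr_cv * t_mean)
  ints <- pmax(ints, max(min_gap * 1.05, 0.5 * t_mean))
  # apnea injection: widen randomly chosen interior intervals
  apnea_at <- integer(0)
  if (spec$apnea_count > 0) {
    # only intervals that will still fall inside the recording after all
    # apnea widenings are eligible, so every requested apnea materializes
    lo <- 4L
    hi <- min(n_draw - 4L,
              floor((spec$duration_s -
                       spec$apnea_count * spec$apnea_duration_s) / t_mean) - 3L)
    stopifnot(hi - lo + 1L >= spec$apnea_count)
    apnea_at <- sort(sample(lo:hi, spec$apnea_count))
    ints[apnea_at] <- ints[apnea_at] + spec$apnea_duration_s
  }
  pt <- cumsum(c(t_mean, ints))                # peak times (s)
  keep <- pt < spec$duration_s - 0.6 * t_mean
  pt <- pt[keep]
  m <- length(pt)
  apnea_gaps <- apnea_at[apnea_at < m]         # gap k is between peaks k, k+1
  pk <- as.integer(round(pt * fs)) + 1L        # 1-based sample indices

  amp <- spec$peak_amp_mean *
    pmax(1 + spec$peak_amp_cv * stats::rnorm(m), 0.5)

  # breath shape: the inspiratory rise occupies 35% x 95% of the breath's own
  # preceding inter-peak gap and the expiratory decay 65% x 95% of its
  # following gap, so every valley is a short neural silence (5% of its gap)
  # regardless of interval jitter; gaps are capped near the mean interval so
  # apnea-adjacent breaths stay normal-sized
  gap_prev <- c(t_mean, diff(pt))
  gap_next <- c(diff(pt), t_mean)
  rise <- pmax(as.integer(round(0.35 * 0.95 * pmin(gap_prev, 1.5 * t_mean) * fs)), 3L)
  decay <- pmax(as.integer(round(0.65 * 0.95 * pmin(gap_next, 1.5 * t_mean) * fs)), 3L)

  # pulse: raised-cosine inspiratory rise to a sharp apex, then a truncated
  # exponential expiratory decay (time constant a quarter of the decay span),
  # reaching the baseline exactly at the breath offset. The brisk initial
  # fall keeps the apex position well defined against noise.
  clean <- rep(spec$tonic_baseline, n)
  for (k in seq_len(m)) {
    r <- rise[k]; d <- decay[k]; p <- pk[k]
    iu <- (p - r):(p - 1L)
    id <- (p + 1L):(p + d)
    ok_u <- iu >= 1L & iu <= n
    ok_d <- id >= 1L & id <= n
    clean[iu[ok_u]] <- clean[iu[ok_u]] +
      amp[k] * 0.5 * (1 - cos(pi * (iu[ok_u] - (p - r)) / r))
    if (p >= 1L && p <= n) clean[p] <- clean[p] + amp[k]
    tau <- d / 4
    u <- id[ok_d] - p
    clean[id[ok_d]] <- clean[id[ok_d]] +
      amp[k] * (exp(-u / tau) - exp(-4)) / (1 - exp(-4))
  }

  # --- noise components
  tt <- (seq_len(n) - 1L) / fs
  noise <- numeric(n)
  if (spec$noise_sd > 0) noise <- noise + stats::rnorm(n, 0, spec$noise_sd)
  if (spec$cardiac_amp > 0 && spec$cardiac_rate > 0) {
    beat <- 60 / spec$cardiac_rate
    phase <- stats::runif(1, 0, beat)
    centers <- seq(phase, spec$duration_s, by = beat)
    w <- 0.06                                  # spike half-width (s)
    for (cc in centers) {
      idx <- which(abs(tt - cc) < w)
      noise[idx] <- noise[idx] +
        spec$cardiac_amp * 0.5 * (1 + cos(pi * (tt[idx] - cc) / w))
    }
  }
  if (spec$wander_amp > 0) {
    noise <- noise + spec$wander_amp *
      sin(2 * pi * tt / spec$wander_period_s + stats::runif(1, 0, 2 * pi))
  }
  if (spec$peristalsis_rate > 0 && spec$peristalsis_amp > 0) {
    n_burst <- stats::rpois(1, spec$peristalsis_rate * spec$duration_s / 60)
    if (n_burst > 0) {
      centers <- stats::runif(n_burst, 0, spec$duration_s)
      widths <- spec$peristalsis_width_s * stats::runif(n_burst, 0.7, 1.3)
      amps <- spec$peristalsis_amp * stats::runif(n_burst, 0.5, 1.2)
      for (j in seq_len(n_burst)) {
        sdw <- widths[j] / 4
        idx <- which(abs(tt - centers[j]) < 2.5 * sdw)
        noise[idx] <- noise[idx] +
          amps[j] * exp(-(tt[idx] - centers[j])^2 / (2 * sdw^2))
      }
    }
  }
  if (spec$motion_rate > 0 && spec$motion_amp > 0) {
    n_art <- stats::rpois(1, spec$motion_rate * spec$duration_s / 60)
    if (n_art > 0) {
      centers <- stats::runif(n_art, 0, spec$duration_s)
      amps <- spec$motion_amp * stats::runif(n_art, 0.6, 1.4)
      w <- spec$motion_width_s / 2
      for (j in seq_len(n_art)) {
        idx <- which(abs(tt - centers[j]) < w)
        noise[idx] <- noise[idx] +
          amps[j] * 0.5 * (1 + cos(pi * (tt[idx] - centers[j]) / w))
      }
    }
  }
  edi <- pmax(clean + noise, 0)

  # --- truth breaths (from pulse geometry)
  breaths <- lapply(seq_len(m), function(k) {
    structure(list(onset = pk[k] - rise[k], peak = pk[k],
                   offset = pk[k] + decay[k], flagged = FALSE),
              class = "breath")
  })

  # --- pressure channel: one inflation per breath, triggered shortly after
  # the neural onset and cycled off just past the Edi peak (as the assist
  # tracks the falling Edi)
  peep <- 5; pip <- 15
  delay <- as.integer(round(0.12 * fs))   # neural-to-pneumatic trigger lag
  inflations <- list()
  for (k in seq_len(m)) {
    s <- pk[k] - rise[k] + delay
    e <- pk[k] + as.integer(round(0.05 * decay[k]))
    if (s >= 1L && e <= n && e > s) {
      inflations[[length(inflations) + 1L]] <- list(start = s, end = e,
                                                    breath = k)
    }
  }

  events <- list()
  # double-trigger injection: a second inflation late in the breath
  if (spec$double_trigger_rate > 0) {
    n_dt <- stats::rpois(1, spec$double_trigger_rate * spec$duration_s / 60)
    eligible <- setdiff(2:(m - 1L),
                        c(apnea_gaps, apnea_gaps + 1L))  # keep apneas silent
    eligible <- eligible[decay[eligible] >= as.integer(round(0.7 * fs))]
    n_dt <- min(n_dt, length(eligible))
    if (n_dt > 0) {
      chosen <- sort(sample(eligible, n_dt))
      # a double trigger is an immediate re-trigger: the second inflation
      # follows the first while neural expiration is still under way
      for (k in chosen) {
        s <- pk[k] + as.integer(round(0.2 * decay[k]))
        e <- s + as.integer(round(0.25 * fs))
        inflations[[length(inflations) + 1L]] <- list(start = s, end = e,
                                                      breath = k)
        events[[length(events) + 1L]] <- asynchrony_event(
          "double_triggering", breaths[[k]]$onset, breaths[[k]]$offset,
          n_inflations = 2L)
      }
    }
  }
  # autotrigger injection: inflations inside each apneic gap
  if (spec$autotrigger_count > 0 && length(apnea_gaps)) {
    for (g in apnea_gaps) {
      g0 <- breaths[[g]]$offset; g1 <- breaths[[g + 1L]]$onset
      room <- (g1 - g0) / fs - 2      # keep 1 s clearance on both sides
      n_at <- min(spec$autotrigger_count, max(floor(room / 0.8), 0))
      if (n_at < 1) next
      pos <- as.integer(g0 + fs + round(
        seq(0, room * fs - 0.3 * fs, length.out = n_at)))
      for (s in pos) {
        e <- s + as.integer(round(0.25 * fs))
        inflations[[length(inflations) + 1L]] <- list(start = s, end = e,
                                                      breath = NA_integer_)
        events[[length(events) + 1L]] <- asynchrony_event(
          "autotriggering", g0, g1, n_inflations = 1L)
      }
    }
  }

  inflations <- inflations[order(vapply(inflations, `[[`, 0L, "start"))]
  pressure <- rep(peep, n)
  ramp <- as.integer(round(0.05 * fs))
  for (fl in inflations) {
    idx <- fl$start:fl$end
    prof <- rep(pip, length(idx))
    k <- seq_len(min(ramp, length(idx)))
    prof[k] <- peep + (pip - peep) * k / length(k)
    prof[length(prof) + 1L - rev(k)] <- peep + (pip - peep) * rev(k) / length(k)
    pressure[idx] <- pmax(pressure[idx], prof)
  }

  truth <- structure(
    list(peaks = peak_set(pk, source = "ground_truth",
                          patient_id = "synthetic", n = n),
         breaths = breaths,
         inflations = lapply(inflations, function(fl) {
           structure(list(start = fl$start, end = fl$end,
                          peak_pressure = pip),
                     class = "mechanical_inflation")
         }),
         events = events,
         apnea_gaps = apnea_gaps,
         spec = spec),
    class = "synthetic_truth")
  list(recording = recording(edi = edi, sampling_rate = fs,
                             pressure = pressure, patient_id = "synthetic"),
       truth = truth)
}

#' @keywords internal
#' Deterministic 31-bit hash of a string, folded with a numeric seed; gives
#' each synthetic patient an independent reproducible random stream.
stable_hash <- function(id, seed) {
  h <- as.numeric(seed) %% 2147483647
  for (c in utf8ToInt(id)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Generate a multi-patient synthetic benchmark
#'
#' Produces `n_patients` recordings from per-patient jittered copies of a
#' template spec (distinct respiratory rate, peak amplitude and noise level
#' per patient), with unique patient ids and per-patient random streams
#' derived by stable hashing of the patient id, so the benchmark is
#' deterministic in `seed` and insensitive to generation order.
#'
#' @param n_patients number of patients (>= 2).
#' @param template a [synthetic_spec()] used as the center of the jitter.
#' @param seed integer master seed.
#' @return list of `n_patients` elements, each `list(recording=, truth=)`.
#' @export
make_benchmark <- function(n_patients, template = synthetic_spec(), seed = 1) {
  stopifnot(n_patients >= 2, inherits(template, "synthetic_spec"))
  lapply(seq_len(n_patients), function(i) {
    id <- sprintf("P%02d", i)
    h <- stable_hash(id, seed)
    jit <- withr::with_seed(h, stats::runif(3, -1, 1))
    sp <- template
    sp$rr_mean <- template$rr_mean * (1 + 0.10 * jit[1])
    sp$peak_amp_mean <- template$peak_amp_mean * (1 + 0.15 * jit[2])
    sp$noise_sd <- template$noise_sd * (1 + 0.20 * jit[3])
    sp$seed <- (h + 1L) %% 2147483647
    out <- generate_recording(sp)
    out$recording$patient_id <- id
    out$truth$peaks$patient_id <- id
    out
  })
}
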