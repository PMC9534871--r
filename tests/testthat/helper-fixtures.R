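# Shared fixtures and slow-computation caches for the test suite.

# A clean periodic recording: 60 breaths/min, no noise, fixed amplitudes.
clean_spec <- function(duration_s = 60, seed = 1, ...) {
  args <- utils::modifyList(
    list(duration_s = duration_s, rr_mean = 60, rr_cv = 0, noise_sd = 0,
         cardiac_amp = 0, wander_amp = 0, peristalsis_rate = 0,
         motion_rate = 0, peak_amp_cv = 0, seed = seed),
    list(...))
  do.call(synthetic_spec, args)
}

# Brute-force local-maximum scan: tests every index against its full window,
# then keeps the leftmost sample of each equal-valued plateau run.
lm_brute <- function(x, w) {
  n <- length(x)
  hits <- integer(0)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    if (x[i] == max(x[(i - w):(i + w)])) hits <- c(hits, i)
  }
  if (length(hits) > 1L) {
    drop <- c(FALSE, diff(hits) == 1L & x[hits[-1L]] == x[hits[-length(hits)]])
    hits <- hits[!drop]
  }
  hits
}

# Brute-force breath-boundary scan for one gap (a, b): tests every index in
# scan order against the centered window-minimum and sigma conditions.
re_brute_gap <- function(x, a, b, v, sigma) {
  th <- sigma * min(x[a], x[b])
  lo <- a + 1L + v; hi <- b - 1L - v
  qual <- integer(0)
  if (lo <= hi) {
    for (i in lo:hi) {
      if (x[i] == min(x[(i - v):(i + v)]) && x[i] < th) qual <- c(qual, i)
    }
  }
  if (length(qual)) {
    list(offset = qual[1L], onset = qual[length(qual)], fallback = FALSE)
  } else {
    gap <- (a + 1L):(b - 1L)
    g <- gap[which.min(x[gap])]
    list(offset = g, onset = g, fallback = TRUE)
  }
}

# Exhaustive maximum one-to-one matching within delta (for <= 8 peaks):
# enumerates all assignments of detected peaks to truth peaks.
match_exhaustive_size <- function(detected, truth, delta) {
  nd <- length(detected); nt <- length(truth)
  if (!nd || !nt) return(0L)
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (nd - i + 1L) <= best) return()
    if (i > nd) { best <<- max(best, count); return() }
    recurse(i + 1L, used, count)                  # leave detected i unmatched
    for (j in seq_len(nt)) {
      if (!used[j] && abs(detected[i] - truth[j]) <= delta) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nt), 0L)
  best
}

# Random peak fixtures with realistic spacing (truth spacing >= 15 samples,
# as the minimum inter-peak distance guarantees): detected = jittered subset
# of the truth plus a few spurious detections.
random_peak_fixture <- function(n_truth, delta = 14L) {
  truth <- cumsum(sample(15:40, n_truth, replace = TRUE)) + 50L
  kept <- truth[stats::runif(n_truth) < 0.8]
  jit <- kept + sample((-delta):delta, length(kept), replace = TRUE)
  spur <- sample(max(truth) + (60:200), max(1L, n_truth %/% 2L))
  detected <- sort(unique(c(jit[jit > 0], spur)))
  list(truth = truth, detected = detected)
}

# Cache for the expensive end-to-end benchmark runs shared across acceptance
# blocks: built once per test session.
.accept_cache <- new.env(parent = emptyenv())

acceptance_benchmark <- function() {
  if (is.null(.accept_cache$bench)) {
    .accept_cache$bench <- make_benchmark(
      10, synthetic_spec(duration_s = 180), seed = 1)
  }
  .accept_cache$bench
}

acceptance_dnn_run <- function() {
  if (is.null(.accept_cache$dnn)) {
    bench <- acceptance_benchmark()
    ids <- vapply(bench, function(b) b$recording$patient_id, "")
    fold <- list(list(train = ids[1:7], test = ids[8:10]))
    cfg <- detector_config()
    lm_all <- evaluate_detector(bench, "lm", cfg, epoch_s = 30)
    lm_held <- evaluate_detector(bench[8:10], "lm", cfg, epoch_s = 30)
    dnn_held <- evaluate_detector(
      bench, "dnn", cfg,
      model_config = model_config_tiny(),
      train_config = train_config(max_epochs = 30, seed = 1),
      folds = fold, epoch_s = 30, seed = 1)
    .accept_cache$dnn <- list(lm_all = lm_all, lm_held = lm_held,
                              dnn_held = dnn_held)
  }
  .accept_cache$dnn
}
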