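#' @keywords internal
#' Size of the maximum one-to-one matching within delta, by dynamic
#' programming over the sorted positions (for points on a line a maximum
#' matching can always be chosen order-preserving, so an LCS-style recursion
#' is exact).
max_matching_size <- function(detected, truth, delta) {
  nd <- length(detected); nt <- length(truth)
  if (!nd || !nt) return(0L)
  prev <- integer(nt + 1L)
  for (i in seq_len(nd)) {
    cur <- integer(nt + 1L)
    ok <- abs(detected[i] - truth) <= delta
    for (j in seq_len(nt)) {
      cur[j + 1L] <- max(prev[j + 1L], cur[j],
                         prev[j] + (ok[j]))
    }
    prev <- cur
  }
  prev[nt + 1L]
}

#' @keywords internal
#' Order-preserving maximum matching with pairs recovered by backtracking;
#' among maximal choices it pairs the earliest compatible positions first.
max_matching_pairs <- function(detected, truth, delta) {
  nd <- length(detected); nt <- length(truth)
  M <- matrix(0L, nd + 1L, nt + 1L)
  for (i in nd:1L) {
    for (j in nt:1L) {
      best <- max(M[i + 1L, j], M[i, j + 1L])
      if (abs(detected[i] - truth[j]) <= delta) {
        best <- max(best, M[i + 1L, j + 1L] + 1L)
      }
      M[i, j] <- best
    }
  }
  pairs <- matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("detected", "truth")))
  i <- 1L; j <- 1L
  while (i <= nd && j <= nt) {
    if (abs(detected[i] - truth[j]) <= delta &&
        M[i, j] == M[i + 1L, j + 1L] + 1L) {
      pairs <- rbind(pairs, c(i, j)); i <- i + 1L; j <- j + 1L
    } else if (M[i + 1L, j] >= M[i, j + 1L]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  pairs
}

#' @keywords internal
#' One-to-one assignment of detected positions to truth positions. Pairs are
#' taken greedily in order of increasing absolute distance (ties broken by
#' the smaller detected index, then the smaller truth index); a pair is
#' accepted when both members are still unassigned and their distance is
#' within delta. With realistically spaced peaks the greedy assignment is
#' maximal; when dense overlapping detections make it sub-maximal, the exact
#' order-preserving maximum matching replaces it. Returns indices into the
#' input vectors.
match_positions <- function(detected, truth, delta) {
  nd <- length(detected); nt <- length(truth)
  empty <- matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("detected", "truth")))
  if (!nd || !nt) return(list(pairs = empty))
  # candidate pairs within delta; peaks are sparse so enumerate per detection
  di <- integer(0); ti <- integer(0); dist <- numeric(0)
  for (i in seq_len(nd)) {
    ok <- which(abs(truth - detected[i]) <= delta)
    if (length(ok)) {
      di <- c(di, rep(i, length(ok)))
      ti <- c(ti, ok)
      dist <- c(dist, abs(truth[ok] - detected[i]))
    }
  }
  if (!length(di)) return(list(pairs = empty))
  ord <- order(dist, di, ti)
  used_d <- rep(FALSE, nd); used_t <- rep(FALSE, nt)
  keep_d <- integer(0); keep_t <- integer(0)
  for (j in ord) {
    if (!used_d[di[j]] && !used_t[ti[j]]) {
      used_d[di[j]] <- TRUE; used_t[ti[j]] <- TRUE
      keep_d <- c(keep_d, di[j]); keep_t <- c(keep_t, ti[j])
    }
  }
  pairs <- cbind(detected = keep_d, truth = keep_t)
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  if (nrow(pairs) < max_matching_size(detected, truth, delta)) {
    pairs <- max_matching_pairs(detected, truth, delta)
    colnames(pairs) <- c("detected", "truth")
  }
  list(pairs = pairs)
}

#' Match detected peaks to ground truth within a tolerance window
#'
#' One-to-one matching: a detected peak within `delta_ms` of an unmatched
#' ground-truth peak is a true positive; leftover detections are false
#' positives; leftover truth peaks are false negatives. Assignment is greedy
#' by increasing distance with a leftmost tie-break; should dense overlapping
#' detections ever make the greedy assignment sub-maximal, the exact
#' order-preserving maximum matching is used instead, so the true-positive
#' count is always maximal.
#'
#' @param detected,truth [peak_set()] objects (sorted by construction).
#' @param delta_ms tolerance in milliseconds (default 140).
#' @param sampling_rate Hz used to convert the tolerance to samples.
#' @return a list of class `match_result`: counts `tp`, `fp`, `fn` and the
#'   matrix `pairs` of matched (detected index, truth index) positions.
#' @export
match_peaks <- function(detected, truth, delta_ms = 140, sampling_rate = 100) {
  stopifnot(inherits(detected, "edi_peakset"), inherits(truth, "edi_peakset"))
  delta <- ms_to_samples(delta_ms, sampling_rate)
  m <- match_positions(detected$positions, truth$positions, delta)
  tp <- nrow(m$pairs)
  structure(list(tp = tp,
                 fp = length(detected$positions) - tp,
                 fn = length(truth$positions) - tp,
                 pairs = cbind(
                   detected = detected$positions[m$pairs[, 1L]],
                   truth = truth$positions[m$pairs[, 2L]])),
            class = "match_result")
}

#' Precision, recall and F1 from a match result
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; an empty denominator
#' yields 0 by convention.
#'
#' @param match a `match_result` from [match_peaks()] or [match_events()], or
#'   any list with `tp`, `fp`, `fn` counts.
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
prf <- function(match) {
  tp <- match$tp; fp <- match$fp; fn <- match$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SSE/SST` with `SSE = mean((y - y_hat)^2)` and
#' `SST = mean((y - mean(y))^2)`. Unbounded below; 1 for a perfect prediction;
#' 0 for predicting the mean.
#'
#' @param y observed values (must not be constant).
#' @param y_hat predicted values, same length.
#' @return a single number in (-Inf, 1].
#' @export
r_squared <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2)
  mu <- mean(y)
  sst <- mean((y - mu)^2)
  if (sst == 0) stop("R^2 undefined: y is constant")
  1 - mean((y - y_hat)^2) / sst
}

#' Epoch-wise respiratory-rate agreement
#'
#' Computes the respiratory rate (breaths/min) per non-overlapping epoch from
#' the truth peaks (observed) and the detected peaks (predicted) and returns
#' their coefficient of determination. Sensitive to spurious detections: extra
#' peaks inflate the detected rate.
#'
#' @param detected,truth [peak_set()] objects.
#' @param n_total recording length in samples (trailing partial epoch dropped).
#' @param epoch_s epoch length in seconds (default 60).
#' @param sampling_rate Hz.
#' @return a single number, `R^2` of detected versus truth rates.
#' @export
rr_r_squared <- function(detected, truth, n_total, epoch_s = 60,
                         sampling_rate = 100) {
  y <- respiratory_rate(truth, n_total, epoch_s, sampling_rate)
  y_hat <- respiratory_rate(detected, n_total, epoch_s, sampling_rate)
  r_squared(y$rate, y_hat$rate)
}

#' Match asynchrony events by interval overlap
#'
#' One-to-one greedy matching by decreasing interval overlap (in samples);
#' events with zero overlap remain unmatched. Detected and truth lists must
#' hold events of one kind.
#'
#' @param detected,truth lists of [asynchrony_event()] objects, sorted by
#'   start.
#' @return a `match_result` (as for [match_peaks()], with `pairs` holding list
#'   indices).
#' @export
match_events <- function(detected, truth) {
  nd <- length(detected); nt <- length(truth)
  ov <- function(a, b) {
    max(0, min(a$end, b$end) - max(a$start, b$start))
  }
  di <- integer(0); ti <- integer(0); lap <- numeric(0)
  for (i in seq_len(nd)) for (j in seq_len(nt)) {
    o <- ov(detected[[i]], truth[[j]])
    if (o > 0) { di <- c(di, i); ti <- c(ti, j); lap <- c(lap, o) }
  }
  used_d <- rep(FALSE, nd); used_t <- rep(FALSE, nt)
  pairs <- matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("detected", "truth")))
  if (length(di)) {
    for (j in order(-lap, di, ti)) {
      if (!used_d[di[j]] && !used_t[ti[j]]) {
        used_d[di[j]] <- TRUE; used_t[ti[j]] <- TRUE
        pairs <- rbind(pairs, c(di[j], ti[j]))
      }
    }
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  }
  structure(list(tp = nrow(pairs), fp = nd - nrow(pairs),
                 fn = nt - nrow(pairs), pairs = pairs),
            class = "match_result")
}

#' Interpatient cross-validation folds
#'
#' Partitions patients into `k` test folds of near-equal size (sizes differ by
#' at most one), deterministically for a given seed. `k = length(patient_ids)`
#' yields leave-one-out cross-validation at the patient level.
#'
#' @param patient_ids character vector of distinct patient identifiers.
#' @param k number of folds, `2 <= k <= length(patient_ids)` (k = n for LOOCV).
#' @param seed integer seed for the shuffle.
#' @return list of `k` lists, each with `train` and `test` id vectors.
#' @export
interpatient_folds <- function(patient_ids, k, seed = 1) {
  patient_ids <- as.character(patient_ids)
  n <- length(patient_ids)
  stopifnot(!anyDuplicated(patient_ids), k >= 1, k <= n)
  shuffled <- withr::with_seed(seed, sample(patient_ids))
  assign_fold <- rep_len(seq_len(k), n)    # round-robin over the shuffle
  lapply(seq_len(k), function(f) {
    test <- shuffled[assign_fold == f]
    list(train = setdiff(patient_ids, test), test = test)
  })
}

#' Evaluate a peak detector over a synthetic benchmark
#'
#' Runs a detector on every patient of a benchmark (a list of
#' `(recording, truth)` pairs from [make_benchmark()]), matches its peaks to
#' the ground truth within `delta_ms`, and reports per-patient precision,
#' recall, F1 and the epoch-wise respiratory-rate R-squared, plus their
#' across-patient mean and population standard deviation.
#'
#' For `method = "dnn"` the classifier is trained on the training patients of
#' each fold only (interpatient splitting), then applied to that fold's test
#' patients; other methods need no training and are evaluated on all patients.
#'
#' @param benchmark list of `list(recording=, truth=)` pairs.
#' @param method `"lm"`, `"fda"`, `"mad"`, or `"dnn"`.
#' @param config a [detector_config()].
#' @param model_config,train_config for `method = "dnn"`: a [model_config()]
#'   and [train_config()].
#' @param folds for `"dnn"`: list of `list(train=, test=)` patient-id splits
#'   (default: [interpatient_folds()] with `k` folds).
#' @param k number of folds when `folds` is not given (default 5).
#' @param epoch_s respiratory-rate epoch length in seconds (default 60).
#' @param seed seed controlling fold assignment and training.
#' @return a list of class `metrics_report`: `per_patient` (data.frame with
#'   one row per evaluated patient) and `aggregate` (mean and sd rows).
#' @export
evaluate_detector <- function(benchmark, method = c("lm", "fda", "mad", "dnn"),
                              config = detector_config(),
                              model_config = NULL, train_config = NULL,
                              folds = NULL, k = 5, epoch_s = 60, seed = 1) {
  method <- match.arg(method)
  stopifnot(length(benchmark) >= 2)
  ids <- vapply(benchmark, function(b) b$recording$patient_id, "")
  names(benchmark) <- ids
  run_simple <- function(rec) {
    switch(method,
           lm = detect_local_maxima(rec, config$omega_lm_ms),
           fda = fda_detect(rec),
           mad = mad_detect(rec))
  }
  rows <- list()
  eval_patient <- function(b, det) {
    m <- match_peaks(det, b$truth$peaks, config$delta_ms,
                     b$recording$sampling_rate)
    s <- prf(m)
    r2 <- rr_r_squared(det, b$truth$peaks, n_samples(b$recording),
                       epoch_s, b$recording$sampling_rate)
    data.frame(patient_id = b$recording$patient_id,
               precision = s[["precision"]], recall = s[["recall"]],
               f1 = s[["f1"]], r2 = r2)
  }
  if (method != "dnn") {
    rows <- lapply(benchmark, function(b) eval_patient(b, run_simple(b$recording)))
  } else {
    stopifnot(!is.null(model_config), !is.null(train_config))
    if (is.null(folds)) folds <- interpatient_folds(ids, k, seed)
    for (fold in folds) {
      wins <- list()
      for (id in fold$train) {
        b <- benchmark[[id]]
        cand <- detect_local_maxima(b$recording, config$omega_lm_ms)
        w <- extract_windows(b$recording, cand, config$window_len)
        wins <- c(wins, label_candidates(w, b$truth$peaks, config$delta_ms,
                                         b$recording$sampling_rate))
      }
      model <- build_model(model_config, seed = seed)
      fit <- train_classifier(model, wins, train_config)
      for (id in fold$test) {
        b <- benchmark[[id]]
        cand <- detect_local_maxima(b$recording, config$omega_lm_ms)
        det <- classify_peaks(fit$model, b$recording, cand, config)
        rows[[id]] <- eval_patient(b, det)
      }
    }
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  agg <- data.frame(stat = c("mean", "sd"),
                    precision = c(mean(per$precision), pop_sd(per$precision)),
                    recall = c(mean(per$recall), pop_sd(per$recall)),
                    f1 = c(mean(per$f1), pop_sd(per$f1)),
                    r2 = c(mean(per$r2), pop_sd(per$r2)))
  structure(list(method = method, per_patient = per, aggregate = agg),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> method %s over %d patients\n", x$method,
              nrow(x$per_patient)))
  agg <- x$aggregate
  cat(sprintf("  precision %.3f (%.3f)  recall %.3f (%.3f)  f1 %.3f (%.3f)  r2 %.3f (%.3f)\n",
              agg$precision[1], agg$precision[2], agg$recall[1], agg$recall[2],
              agg$f1[1], agg$f1[2], agg$r2[1], agg$r2[2]))
  invisible(x)
}
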