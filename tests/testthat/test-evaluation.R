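test_that("peak matching handles identity, emptiness and the tie fixture", {
  t5 <- peak_set(c(100L, 200L, 300L, 400L, 500L), source = "ground_truth")
  m <- match_peaks(t5, t5)
  expect_equal(c(m$tp, m$fp, m$fn), c(5L, 0L, 0L))
  m0 <- match_peaks(peak_set(integer(0), source = "lm"), t5)
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(0L, 0L, 5L))
  # two detections straddling one truth peak at equal distance: the leftmost
  # detection wins the pair, the other is a false positive
  m1 <- match_peaks(peak_set(c(100L, 110L), source = "lm"),
                    peak_set(105L, source = "ground_truth"), delta_ms = 140)
  expect_equal(c(m1$tp, m1$fp, m1$fn), c(1L, 1L, 0L))
  expect_equal(unname(m1$pairs[, "detected"]), 100L)
})

test_that("matching counts are symmetric under swapping detected and truth", {
  set.seed(12)
  for (i in 1:10) {
    fx <- random_peak_fixture(8)
    a <- match_peaks(peak_set(fx$detected, source = "lm"),
                     peak_set(fx$truth, source = "ground_truth"))
    b <- match_peaks(peak_set(fx$truth, source = "ground_truth"),
                     peak_set(fx$detected, source = "lm"))
    expect_equal(a$tp, b$tp)
    expect_equal(a$fp, b$fn)
    expect_equal(a$fn, b$fp)
  }
})

test_that("greedy matching attains the exhaustive maximum on small fixtures", {
  set.seed(23)
  for (i in 1:30) {
    fx <- random_peak_fixture(sample(2:8, 1))
    m <- match_peaks(peak_set(fx$detected, source = "lm"),
                     peak_set(fx$truth, source = "ground_truth"))
    expect_equal(m$tp, match_exhaustive_size(fx$detected, fx$truth, 14L))
    # one-to-one: no index reused
    expect_equal(anyDuplicated(m$pairs[, "detected"]), 0L)
    expect_equal(anyDuplicated(m$pairs[, "truth"]), 0L)
  }
})

test_that("precision, recall and F1 follow the count formulas", {
  expect_equal(unname(prf(list(tp = 1, fp = 0, fn = 0))), c(1, 1, 1))
  expect_equal(unname(prf(list(tp = 0, fp = 3, fn = 2))), c(0, 0, 0))
  v <- prf(list(tp = 3, fp = 1, fn = 2))
  expect_equal(unname(v), c(0.75, 0.6, 2 * 0.75 * 0.6 / 1.35),
               tolerance = 1e-12)
  expect_equal(round(v[["f1"]], 4), 0.6667)
  # F1 is the harmonic mean: between min and max of P and R when both > 0
  set.seed(3)
  for (i in 1:20) {
    tp <- sample(1:50, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    s <- prf(list(tp = tp, fp = fp, fn = fn))
    expect_gte(s[["f1"]], min(s[["precision"]], s[["recall"]]) - 1e-12)
    expect_lte(s[["f1"]], max(s[["precision"]], s[["recall"]]) + 1e-12)
  }
})

test_that("coefficient of determination follows the mean-square form", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(1, 2, 4)), 0.5)
  expect_lt(r_squared(y, c(10, 10, 10)), 0)   # unbounded below
  expect_error(r_squared(c(2, 2, 2), y), "constant")
  expect_error(r_squared(1, 1), "length")
})

test_that("respiratory-rate agreement uses epoch-wise rates", {
  truth <- peak_set(seq(50L, 17900L, by = 100L), source = "ground_truth")
  expect_equal(rr_r_squared(truth, truth, 18000, epoch_s = 60), 1)
  # drop every 2nd peak: detected rate is half the truth everywhere; with a
  # non-constant truth rate the value matches the hand formula
  truth2 <- peak_set(c(seq(50L, 5900L, by = 100L),
                       seq(6050L, 11900L, by = 150L),
                       seq(12050L, 17900L, by = 100L)),
                     source = "ground_truth")
  det2 <- peak_set(truth2$positions[c(TRUE, FALSE)], source = "dnn")
  y <- respiratory_rate(truth2, 18000, 60, 100)$rate
  y_hat <- respiratory_rate(det2, 18000, 60, 100)$rate
  expect_equal(rr_r_squared(det2, truth2, 18000, epoch_s = 60),
               1 - mean((y - y_hat)^2) / mean((y - mean(y))^2))
})

test_that("event matching is one-to-one by interval overlap", {
  ev <- function(s, e) asynchrony_event("autotriggering", s, e, 1L)
  truth <- list(ev(100, 300), ev(500, 700), ev(900, 1100))
  m <- match_events(truth, truth)
  expect_equal(c(m$tp, m$fp, m$fn), c(3L, 0L, 0L))
  disj <- list(ev(2000, 2100), ev(2200, 2300), ev(2400, 2500))
  m2 <- match_events(disj, truth)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0L, 3L, 3L))
  # partial overlaps: detected 1 overlaps truth 1 and 2; the larger overlap
  # wins, leaving truth 1 for detected 0's zero-overlap... (none) -> fn
  det <- list(ev(250, 550), ev(660, 720))
  m3 <- match_events(det, truth)
  expect_equal(m3$tp, 2L)
  expect_equal(m3$pairs[, "truth"], c(1L, 2L))
  # overlap-maximal: detected (250,550) overlaps truth1 by 50, truth2 by 50;
  # detected (660,720) overlaps truth2 by 40 only; exhaustive maximum is 2
})

test_that("interpatient folds partition patients with balanced sizes", {
  ids <- sprintf("P%02d", 1:17)
  f5 <- interpatient_folds(ids, k = 5, seed = 2)
  sizes <- sort(vapply(f5, function(f) length(f$test), 0L))
  expect_equal(sizes, c(3L, 3L, 3L, 4L, 4L))
  all_test <- unlist(lapply(f5, `[[`, "test"))
  expect_setequal(all_test, ids)
  expect_equal(anyDuplicated(all_test), 0L)
  for (f in f5) {
    expect_setequal(c(f$train, f$test), ids)
    expect_length(intersect(f$train, f$test), 0L)
  }
  # k = n is leave-one-out
  floo <- interpatient_folds(ids, k = 17, seed = 2)
  expect_true(all(vapply(floo, function(f) length(f$test), 0L) == 1L))
  expect_setequal(unlist(lapply(floo, `[[`, "test")), ids)
  # deterministic in the seed
  expect_identical(interpatient_folds(ids, 5, seed = 4),
                   interpatient_folds(ids, 5, seed = 4))
  expect_error(interpatient_folds(ids, 18), "k <= n")
})

test_that("a perfect detector scores 1.0 across the board", {
  bench <- make_benchmark(3, clean_spec(duration_s = 150, rr_cv = 0.12,
                                        peak_amp_cv = 0.15), seed = 6)
  rep <- evaluate_detector(bench, "mad", epoch_s = 15)
  expect_equal(nrow(rep$per_patient), 3L)
  expect_equal(rep$aggregate$precision, c(1, 0))
  expect_equal(rep$aggregate$recall, c(1, 0))
  expect_equal(rep$aggregate$f1, c(1, 0))
  expect_equal(rep$aggregate$r2, c(1, 0))
})

test_that("LM over-detection shows near-perfect recall, imperfect precision", {
  bench <- make_benchmark(2, synthetic_spec(duration_s = 120), seed = 5)
  rep <- evaluate_detector(bench, "lm", epoch_s = 30)
  expect_gte(rep$aggregate$recall[1], 0.98)
  expect_lt(rep$aggregate$precision[1], 1)
})
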