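# independent per-layer parameter-count oracle, computed from the block plan
expected_param_count <- function(cfg) {
  plan <- edipeaks:::block_plan(cfg)
  k <- cfg$kernel_size; g <- cfg$cardinality
  conv <- function(c_in, c_out, groups) k * (c_in %/% groups) * c_out + c_out
  bn <- function(c) 2 * c
  total <- conv(cfg$in_channels, cfg$base_filters, 1) + bn(cfg$base_filters)
  for (i in seq_len(cfg$n_block)) {
    if (i > 1) total <- total + bn(plan$in_ch[i])
    total <- total + conv(plan$in_ch[i], plan$out_ch[i], g) +
      bn(plan$out_ch[i]) + conv(plan$out_ch[i], plan$out_ch[i], g)
  }
  c_last <- plan$out_ch[cfg$n_block]
  total + bn(c_last) + c_last * cfg$n_classes + cfg$n_classes
}

test_that("model configuration invariants are enforced", {
  expect_error(model_config(base_filters = 20, cardinality = 16))
  expect_error(model_config(n_block = 0))
  expect_error(model_config(n_classes = 1))
  cfg <- model_config()
  expect_equal(cfg$kernel_size, 16L)
  expect_equal(cfg$n_block, 48L)
  expect_equal(cfg$base_filters, 352L)
})

test_that("forward pass yields class logits for any input length", {
  model <- build_model(model_config_tiny(), seed = 1)
  for (L in c(100L, 256L)) {
    X <- array(rnorm(L * 2), c(1L, L, 2L))
    fw <- edipeaks:::model_forward(model, X)
    expect_equal(dim(fw$logits), c(2L, 2L))
    expect_true(all(is.finite(fw$logits)))
  }
  # parameter count does not depend on the input length
  expect_equal(count_parameters(model), count_parameters(model))
})

test_that("parameter count matches the layer-by-layer oracle", {
  for (cfg in list(model_config_tiny(),
                   model_config_tiny(base_filters = 32, cardinality = 8),
                   model_config_tiny(n_block = 9, increasefilter_gap = 3))) {
    model <- build_model(cfg, seed = 1, init = "zero")
    expect_equal(count_parameters(model), expected_param_count(cfg))
  }
})

test_that("doubling the base width scales parameters 2x to 4x", {
  a <- count_parameters(build_model(model_config_tiny(), init = "zero"))
  b <- count_parameters(build_model(model_config_tiny(base_filters = 32),
                                    init = "zero"))
  expect_gt(b / a, 2)
  expect_lt(b / a, 4)
})

test_that("compiled convolution agrees with the reference implementation", {
  set.seed(14)
  for (i in 1:6) {
    g <- sample(c(1, 2, 4), 1)
    C_in <- g * sample(1:3, 1)
    C_out <- g * sample(1:3, 1)
    k <- sample(c(3, 16), 1)
    s <- sample(1:2, 1)
    L <- sample(c(19, 64), 1)
    X <- array(rnorm(C_in * L * 2), c(C_in, L, 2))
    W <- array(rnorm(C_out * (C_in / g) * k), c(C_out, C_in / g, k))
    b <- rnorm(C_out)
    f <- edipeaks:::conv1d_forward(X, W, b, s, g)
    fr <- edipeaks:::conv1d_forward_ref(X, W, b, s, g)
    expect_equal(f$Y, fr$Y, tolerance = 1e-12)
    dY <- array(rnorm(length(f$Y)), dim(f$Y))
    bw <- edipeaks:::conv1d_backward(dY, f$cache)
    bwr <- edipeaks:::conv1d_backward_ref(dY, fr$cache)
    expect_equal(bw$dX, bwr$dX, tolerance = 1e-12)
    expect_equal(array(bw$dW, dim(bwr$dW)), bwr$dW, tolerance = 1e-12)
    expect_equal(as.numeric(bw$db), as.numeric(bwr$db), tolerance = 1e-12)
  }
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(9)
  cfg <- model_config_tiny(n_block = 4, base_filters = 8, cardinality = 2,
                           kernel_size = 5)
  model <- build_model(cfg, seed = 2)
  X <- array(rnorm(1 * 40 * 3), c(1, 40, 3))
  y <- c(1L, 2L, 1L)
  fw <- edipeaks:::model_forward(model, X, training = TRUE)
  ce <- edipeaks:::softmax_xent(fw$logits, y)
  gr <- edipeaks:::model_backward(model, fw$caches, ce$dlogits)
  loss_at <- function(m) {
    f <- edipeaks:::model_forward(m, X, training = TRUE)
    edipeaks:::softmax_xent(f$logits, y)$loss
  }
  eps <- 1e-5
  for (nm in sample(names(model$par), 8)) {
    i <- sample(length(model$par[[nm]]), 1)
    mp <- model; mp$par[[nm]][i] <- mp$par[[nm]][i] + eps
    mm <- model; mm$par[[nm]][i] <- mm$par[[nm]][i] - eps
    num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
    expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})

test_that("the plateau schedule reduces the rate and stops on stagnation", {
  st <- edipeaks:::plateau_init(0.001, factor = 0.1, lr_patience = 5,
                                stop_patience = 7)
  st <- edipeaks:::plateau_step(st, 1.0)   # first value improves on Inf
  expect_equal(st$lr, 0.001)
  for (i in 1:5) st <- edipeaks:::plateau_step(st, 1.0)  # no improvement
  expect_equal(st$lr, 0.001 * 0.1)         # reduced after 5 stale epochs
  st <- edipeaks:::plateau_step(st, 1.0)   # 6th stale epoch
  expect_equal(st$lr, 1e-4)                # patience counter was reset
  expect_false(st$stop)
  st <- edipeaks:::plateau_step(st, 1.0)   # 7th stale epoch
  expect_true(st$stop)
  # an improvement resets both counters
  st2 <- edipeaks:::plateau_init(0.001, 0.1, 5, 7)
  st2 <- edipeaks:::plateau_step(st2, 1.0)
  for (i in 1:4) st2 <- edipeaks:::plateau_step(st2, 1.0)
  st2 <- edipeaks:::plateau_step(st2, 0.5)
  expect_equal(st2$lr, 0.001)
  expect_equal(st2$bad_stop, 0L)
})

# linearly separable toy windows: positives carry a tall centered bump
toy_windows <- function(n_pos, n_neg, len = 64L, seed = 1) {
  withr::with_seed(seed, {
    mk <- function(amp, label) lapply(seq_len(if (label == "true_peak") n_pos
                                              else n_neg), function(i) {
      v <- amp * exp(-((seq_len(len)) - len / 2)^2 / 30) + rnorm(len, 0, 0.1)
      v <- (v - mean(v)) / sd(v)
      structure(list(center = len %/% 2L, values = v, label = label,
                     patient_id = "toy"), class = "candidate_window")
    })
    c(mk(10, "true_peak"), mk(0.1, "false_peak"))
  })
}

test_that("training separates a linearly separable toy problem", {
  wins <- toy_windows(40, 40)
  model <- build_model(model_config_tiny(), seed = 1)
  fit <- train_classifier(model, wins,
                          train_config(max_epochs = 20, seed = 1))
  # history contract
  expect_lte(nrow(fit$history), 20L)
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
  # the learning-rate column must follow the plateau rule recomputed from
  # the recorded validation losses
  st <- edipeaks:::plateau_init(0.001, 0.1, 5, 7)
  for (e in seq_len(nrow(fit$history))) {
    expect_equal(fit$history$lr[e], st$lr)
    st <- edipeaks:::plateau_step(st, fit$history$val_loss[e])
  }
  # perfect separation within the epoch budget
  pred <- predict_windows(fit$model, wins)
  expect_equal(pred, vapply(wins, `[[`, "", "label"))
})

test_that("training rejects unlabeled or single-class inputs", {
  wins <- toy_windows(10, 10)
  only_pos <- Filter(function(w) w$label == "true_peak", wins)
  model <- build_model(model_config_tiny(), seed = 1)
  expect_error(train_classifier(model, only_pos, train_config()),
               "single class")
  unl <- wins
  unl[[1]]$label <- "unlabeled"
  expect_error(train_classifier(model, unl, train_config()), "labeled")
})

test_that("classification only removes candidates, never adds", {
  out <- generate_recording(synthetic_spec(duration_s = 20, seed = 19))
  cand <- detect_local_maxima(out$recording, 270)
  model <- build_model(model_config_tiny(), seed = 3)   # untrained
  kept <- classify_peaks(model, out$recording, cand, detector_config())
  expect_true(all(kept$positions %in% cand$positions))
  expect_equal(kept$source, "dnn")
  empty <- classify_peaks(model, out$recording,
                          peak_set(integer(0), source = "lm"),
                          detector_config())
  expect_length(empty$positions, 0L)
})
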