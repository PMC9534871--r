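# Numerical primitives for the 1D residual network. Tensors are 3D arrays
# with dim (channels, length, batch); column-major order makes the channel
# dimension fastest, so im2col reduces to a reshape and grouped convolution
# to one GEMM per group.

#' @keywords internal
#' "same"-padding geometry for stride s: output length ceil(L/s), total pad
#' max((L_out-1)*s + k - L, 0), split left-biased-down (floor on the left).
conv_same_geom <- function(L, k, s) {
  L_out <- ceiling(L / s)
  pad <- max((L_out - 1L) * s + k - L, 0L)
  list(L_out = as.integer(L_out), pl = as.integer(pad %/% 2L),
       pad = as.integer(pad))
}

#' @keywords internal
#' Grouped 1D convolution, compiled path. The cache keeps the input and
#' weights; the im2col matrix is rebuilt in the backward kernel.
conv1d_forward <- function(X, W, b, stride = 1L, groups = 1L) {
  g <- conv_same_geom(dim(X)[2L], dim(W)[3L], stride)
  Y <- conv1d_fw_cpp(X, W, as.numeric(b), stride, groups, g$pl, g$L_out)
  list(Y = Y, cache = list(X = X, W = W, stride = stride, groups = groups,
                           pl = g$pl))
}

#' @keywords internal
conv1d_backward <- function(dY, cache) {
  conv1d_bw_cpp(dY, cache$X, cache$W, cache$stride, cache$groups, cache$pl)
}

#' @keywords internal
#' Reference (pure R) grouped convolution via explicit im2col; kept as the
#' independent oracle the compiled path is tested against.
conv1d_forward_ref <- function(X, W, b, stride = 1L, groups = 1L) {
  d <- dim(X); C_in <- d[1L]; L <- d[2L]; N <- d[3L]
  dw <- dim(W); C_out <- dw[1L]; k <- dw[3L]
  g <- conv_same_geom(L, k, stride)
  Xp <- array(0, c(C_in, L + g$pad, N))
  Xp[, g$pl + seq_len(L), ] <- X
  idx <- outer(seq_len(k), (seq_len(g$L_out) - 1L) * stride, `+`)  # k x L_out
  patches <- Xp[, as.vector(idx), , drop = FALSE]
  dim(patches) <- c(C_in * k, g$L_out * N)
  Y <- matrix(0, C_out, g$L_out * N)
  cpg_in <- C_in %/% groups; cpg_out <- C_out %/% groups
  row_idx <- vector("list", groups)
  for (gi in seq_len(groups)) {
    ch <- (gi - 1L) * cpg_in + seq_len(cpg_in)
    rows <- as.vector(outer(ch, (seq_len(k) - 1L) * C_in, `+`))
    row_idx[[gi]] <- rows
    oc <- (gi - 1L) * cpg_out + seq_len(cpg_out)
    Wg <- W[oc, , , drop = FALSE]
    dim(Wg) <- c(cpg_out, cpg_in * k)
    Y[oc, ] <- Wg %*% patches[rows, , drop = FALSE]
  }
  Y <- Y + b                       # recycles down the C_out dimension
  dim(Y) <- c(C_out, g$L_out, N)
  list(Y = Y,
       cache = list(patches = patches, idx = idx, geom = g, dimX = d,
                    W = W, stride = stride, groups = groups,
                    row_idx = row_idx))
}

#' @keywords internal
conv1d_backward_ref <- function(dY, cache) {
  d <- cache$dimX; C_in <- d[1L]; L <- d[2L]; N <- d[3L]
  W <- cache$W; dw <- dim(W); C_out <- dw[1L]; k <- dw[3L]
  g <- cache$geom
  groups <- cache$groups
  cpg_in <- C_in %/% groups; cpg_out <- C_out %/% groups
  dYm <- dY; dim(dYm) <- c(C_out, g$L_out * N)
  db <- rowSums(dYm)
  dW <- array(0, dw)
  dM <- matrix(0, C_in * k, g$L_out * N)
  for (gi in seq_len(groups)) {
    oc <- (gi - 1L) * cpg_out + seq_len(cpg_out)
    rows <- cache$row_idx[[gi]]
    Wg <- W[oc, , , drop = FALSE]
    dim(Wg) <- c(cpg_out, cpg_in * k)
    dYg <- dYm[oc, , drop = FALSE]
    dWg <- dYg %*% t(cache$patches[rows, , drop = FALSE])
    dim(dWg) <- c(cpg_out, cpg_in, k)
    dW[oc, , ] <- dWg
    dM[rows, ] <- crossprod(Wg, dYg)
  }
  dim(dM) <- c(C_in, k, g$L_out, N)
  dXp <- array(0, c(C_in, L + g$pad, N))
  for (j in seq_len(k)) {
    pj <- cache$idx[j, ]
    dXp[, pj, ] <- dXp[, pj, ] + dM[, j, , ]
  }
  dX <- dXp[, g$pl + seq_len(L), , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

#' @keywords internal
bn_forward <- function(X, gamma, beta, run_mean, run_var, training,
                       momentum = 0.1, eps = 1e-5) {
  d <- dim(X); C <- d[1L]
  Xm <- X; dim(Xm) <- c(C, prod(d[-1L]))
  if (training) {
    mu <- rowMeans(Xm)
    va <- rowMeans(Xm^2) - mu^2
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * va
  } else {
    mu <- run_mean; va <- run_var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- (Xm - mu) * invstd          # per-channel vectors recycle along dim 1
  Y <- gamma * xhat + beta
  dim(Y) <- d
  list(Y = Y, run_mean = run_mean, run_var = run_var,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, dimX = d))
}

#' @keywords internal
bn_backward <- function(dY, cache) {
  d <- cache$dimX; C <- d[1L]; m <- prod(d[-1L])
  dYm <- dY; dim(dYm) <- c(C, m)
  xhat <- cache$xhat
  dgamma <- rowSums(dYm * xhat)
  dbeta <- rowSums(dYm)
  dxhat <- dYm * cache$gamma
  dX <- (cache$invstd / m) *
    (m * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

#' @keywords internal
relu_forward <- function(X) list(Y = pmax(X, 0), cache = X > 0)

#' @keywords internal
relu_backward <- function(dY, cache) dY * cache

#' @keywords internal
#' Max-pool with kernel = stride and "same" padding (pads with -Inf), so the
#' output length matches the strided convolution path of the same block.
maxpool_forward <- function(X, stride) {
  d <- dim(X); C <- d[1L]; L <- d[2L]; N <- d[3L]
  g <- conv_same_geom(L, stride, stride)
  Xp <- array(-Inf, c(C, L + g$pad, N))
  Xp[, g$pl + seq_len(L), ] <- X
  best <- Xp[, (seq_len(g$L_out) - 1L) * stride + 1L, , drop = FALSE]
  arg <- array(1L, dim(best))
  if (stride > 1L) {
    for (j in 2L:stride) {
      cand <- Xp[, (seq_len(g$L_out) - 1L) * stride + j, , drop = FALSE]
      better <- cand > best
      best[better] <- cand[better]
      arg[better] <- j
    }
  }
  list(Y = best, cache = list(arg = arg, geom = g, stride = stride, dimX = d))
}

#' @keywords internal
maxpool_backward <- function(dY, cache) {
  d <- cache$dimX
  g <- cache$geom; s <- cache$stride
  dXp <- array(0, c(d[1L], d[2L] + g$pad, d[3L]))
  for (j in seq_len(s)) {
    pj <- (seq_len(g$L_out) - 1L) * s + j
    mask <- cache$arg == j
    contrib <- dY * mask
    dXp[, pj, ] <- dXp[, pj, ] + contrib
  }
  dXp[, g$pl + seq_len(d[2L]), , drop = FALSE]
}

#' @keywords internal
#' Global average pooling over the temporal dimension: (C, L, N) -> (C, N).
gap_forward <- function(X) {
  d <- dim(X)
  Xm <- aperm(X, c(2L, 1L, 3L))
  dim(Xm) <- c(d[2L], d[1L] * d[3L])
  list(Y = matrix(colSums(Xm) / d[2L], d[1L], d[3L]), cache = d)
}

#' @keywords internal
gap_backward <- function(dY, cache) {
  d <- cache
  dX <- array(apply(dY, 2L, function(col) rep(col, d[2L])), d) / d[2L]
  dX
}

#' @keywords internal
#' Mean cross-entropy of logits (n_classes, N) against 1-based class labels;
#' returns the loss and the gradient w.r.t. the logits.
softmax_xent <- function(logits, y, class_weights = NULL) {
  N <- ncol(logits)
  zmax <- apply(logits, 2L, max)
  z <- sweep(logits, 2L, zmax)
  lse <- log(colSums(exp(z)))
  logp <- sweep(z, 2L, lse)
  w <- if (is.null(class_weights)) rep(1, N) else class_weights[y]
  picked <- logp[cbind(y, seq_len(N))]
  loss <- -sum(w * picked) / sum(w)
  p <- exp(logp)
  onehot <- matrix(0, nrow(logits), N)
  onehot[cbind(y, seq_len(N))] <- 1
  dlogits <- sweep(p - onehot, 2L, w, `*`) / sum(w)
  list(loss = loss, dlogits = dlogits)
}

#' @keywords internal
#' Plateau learning-rate schedule with early stopping: multiply the rate by
#' `factor` after `lr_patience` epochs without validation-loss improvement,
#' stop after `stop_patience` such epochs.
plateau_init <- function(lr, factor = 0.1, lr_patience = 5L,
                         stop_patience = 7L) {
  list(lr = lr, factor = factor, lr_patience = lr_patience,
       stop_patience = stop_patience, best = Inf, bad_lr = 0L,
       bad_stop = 0L, stop = FALSE, improved = FALSE)
}

#' @keywords internal
plateau_step <- function(state, val_loss) {
  if (val_loss < state$best) {
    state$best <- val_loss
    state$bad_lr <- 0L
    state$bad_stop <- 0L
    state$improved <- TRUE
  } else {
    state$bad_lr <- state$bad_lr + 1L
    state$bad_stop <- state$bad_stop + 1L
    state$improved <- FALSE
    if (state$bad_lr >= state$lr_patience) {
      state$lr <- state$lr * state$factor
      state$bad_lr <- 0L
    }
    if (state$bad_stop >= state$stop_patience) state$stop <- TRUE
  }
  state
}
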