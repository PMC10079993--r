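# Forward/backward engine for the compact CNN. All tensors are plain R
# arrays; convolutions along the width axis are expressed as multiplications
# by (sparse-patterned) Toeplitz matrices built from the kernels, which keeps
# every layer a handful of BLAS calls.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Batch normalization on a K x M matrix (K elements per map, M maps).
bn_forward_mat <- function(X, gamma, beta, state, training) {
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu)
    v <- colMeans(xc^2)
    istd <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(xc, 2, istd, `*`)
    state$mean <- (1 - BN_MOMENTUM) * state$mean + BN_MOMENTUM * mu
    state$var <- (1 - BN_MOMENTUM) * state$var + BN_MOMENTUM * v
    Y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
    list(Y = Y, cache = list(xhat = xhat, istd = istd), state = state)
  } else {
    xhat <- sweep(sweep(X, 2, state$mean), 2, 1 / sqrt(state$var + BN_EPS), `*`)
    Y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
    list(Y = Y, cache = NULL, state = state)
  }
}

bn_backward_mat <- function(dY, cache, gamma) {
  K <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, `*`)
  dX <- sweep(dxhat - matrix(colMeans(dxhat), K, ncol(dY), byrow = TRUE) -
                sweep(xhat, 2, colMeans(dxhat * xhat), `*`),
              2, cache$istd, `*`)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

elu_fwd <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_bwd <- function(dy, y) dy * ifelse(y > 0, 1, y + 1)

# Non-overlapping average pooling along the last axis of [B, M, W].
pool_fwd <- function(x, p) {
  d <- dim(x)
  wout <- d[3] %/% p
  out <- array(0, c(d[1], d[2], wout))
  for (w in seq_len(wout))
    out[, , w] <- apply(x[, , (w - 1) * p + seq_len(p), drop = FALSE], c(1, 2), mean)
  out
}

pool_bwd <- function(dy, p, w_in) {
  d <- dim(dy)
  dx <- array(0, c(d[1], d[2], w_in))
  for (w in seq_len(d[3]))
    for (k in seq_len(p)) dx[, , (w - 1) * p + k] <- dy[, , w] / p
  dx
}

#' Forward pass of the compact CNN
#'
#' @param model A `cnn_model` from [build_model()].
#' @param x Input array `[batch, channels, width]` (for the pli variant, the
#'   22 x 22 connectivity matrix of each sample).
#' @param training Training mode: batch statistics for normalization and
#'   active dropout. In evaluation mode running statistics are used and
#'   dropout is the identity.
#' @return List with `logp` (batch x classes log-probabilities), `cache` (for
#'   backprop) and the updated `model` (running batch-norm statistics).
#' @export
forward_cnn <- function(model, x, training = FALSE) {
  s <- model$spec; p <- model$params
  d <- dim(x)
  abort_if(length(d) != 3 || d[2] != s$n_channels || d[3] != s$input_width,
           sprintf("input must be [batch, %d, %d]", s$n_channels, s$input_width))
  B <- d[1]; H <- d[2]; W0 <- d[3]
  cache <- list()

  # temporal convolution (bias-free), per filter
  Xm <- x; dim(Xm) <- c(B * H, W0)
  T1 <- lapply(seq_len(s$F1), function(f) conv_index_matrix(p$conv1_K[, f], model$ci1))
  y1 <- array(0, c(B, H, W0, s$F1))
  for (f in seq_len(s$F1)) y1[, , , f] <- Xm %*% T1[[f]]
  cache$Xm <- Xm

  # batch norm 1 (map = last axis)
  y1m <- y1; dim(y1m) <- c(B * H * W0, s$F1)
  bn1 <- bn_forward_mat(y1m, p$bn1_gamma, p$bn1_beta, model$bn$bn1, training)
  model$bn$bn1 <- bn1$state
  y2 <- bn1$Y; dim(y2) <- c(B, H, W0, s$F1)
  cache$bn1 <- bn1$cache

  # depthwise spatial convolution: collapses the channel axis
  z3 <- array(0, c(B, s$M2, W0))
  Ym_list <- vector("list", s$F1)
  for (f in seq_len(s$F1)) {
    Yf <- y2[, , , f]
    Ym_list[[f]] <- matrix(aperm(Yf, c(2, 1, 3)), H)   # H x (B*W0)
  }
  for (j in seq_len(s$M2)) {
    f <- (j - 1) %/% s$D + 1L
    z3[, j, ] <- matrix(p$dw_W[, j] %*% Ym_list[[f]], B, W0)
  }
  cache$Ym_list <- Ym_list

  # batch norm 2 + ELU + pool1 + dropout
  z3m <- aperm(z3, c(1, 3, 2)); dim(z3m) <- c(B * W0, s$M2)
  bn2 <- bn_forward_mat(z3m, p$bn2_gamma, p$bn2_beta, model$bn$bn2, training)
  model$bn$bn2 <- bn2$state
  cache$bn2 <- bn2$cache
  a2 <- elu_fwd(bn2$Y)
  cache$a2 <- a2
  z4 <- aperm(array(a2, c(B, W0, s$M2)), c(1, 3, 2))   # [B, M2, W0]
  z4p <- pool_fwd(z4, s$pool1_width)                   # [B, M2, W1]
  if (training) {
    keep <- 1 - s$dropout_rate
    mask1 <- array(stats::runif(length(z4p)) < keep, dim(z4p)) / keep
    z4p <- z4p * mask1
    cache$mask1 <- mask1
  }
  cache$z4p <- z4p

  # separable convolution: depthwise temporal then pointwise
  W1 <- s$w_after_pool1; W2 <- s$w_after_sep
  Tsep <- lapply(seq_len(s$M2), function(m) conv_index_matrix(p$sep_K[, m], model$ci_sep))
  z5 <- array(0, c(B, s$M2, W2))
  for (m in seq_len(s$M2)) z5[, m, ] <- z4p[, m, , drop = TRUE] %*% Tsep[[m]]
  Xp <- aperm(z5, c(1, 3, 2)); dim(Xp) <- c(B * W2, s$M2)
  z6 <- Xp %*% p$pw_W                                  # (B*W2) x F2
  cache$Xp <- Xp; cache$Tsep <- Tsep

  # batch norm 3 + ELU + pool2 (+ trailing global mean) + dropout
  bn3 <- bn_forward_mat(z6, p$bn3_gamma, p$bn3_beta, model$bn$bn3, training)
  model$bn$bn3 <- bn3$state
  cache$bn3 <- bn3$cache
  a3 <- elu_fwd(bn3$Y)
  cache$a3 <- a3
  z7 <- aperm(array(a3, c(B, W2, s$F2)), c(1, 3, 2))   # [B, F2, W2]
  z7p <- pool_fwd(z7, s$pool2_width)                   # [B, F2, W3]
  W3 <- dim(z7p)[3]
  feat <- if (W3 > 1) apply(z7p, c(1, 2), mean) else z7p[, , 1, drop = TRUE]
  if (is.null(dim(feat))) feat <- matrix(feat, B, s$F2)
  if (training) {
    keep <- 1 - s$dropout_rate
    mask2 <- matrix(stats::runif(length(feat)) < keep, B, s$F2) / keep
    feat <- feat * mask2
    cache$mask2 <- mask2
  }
  cache$feat <- feat; cache$W3 <- W3

  # classification convolution (1x1, with bias) + log-softmax
  logits <- sweep(feat %*% p$cls_W, 2, p$cls_b, `+`)
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  logp <- logits - lse
  cache$prob <- exp(logp)
  list(logp = logp, cache = cache, model = model)
}

#' Backward pass: gradients of the loss w.r.t. every trainable parameter
#'
#' @param model A `cnn_model`.
#' @param cache Cache from a training-mode [forward_cnn()] call.
#' @param dlogp Gradient of the loss w.r.t. the log-probabilities.
#' @return Named list of gradients, parallel to `model$params`.
#' @export
backward_cnn <- function(model, cache, dlogp) {
  s <- model$spec; p <- model$params
  B <- nrow(dlogp)
  grads <- list()

  # log-softmax + classifier
  dlogits <- dlogp - cache$prob * rowSums(dlogp)
  grads$cls_W <- t(cache$feat) %*% dlogits
  grads$cls_b <- colSums(dlogits)
  dfeat <- dlogits %*% t(p$cls_W)

  if (!is.null(cache$mask2)) dfeat <- dfeat * cache$mask2
  # undo global mean + pool2
  W2 <- s$w_after_sep; W3 <- cache$W3
  dz7p <- array(0, c(B, s$F2, W3))
  for (w in seq_len(W3)) dz7p[, , w] <- dfeat / W3
  dz7 <- pool_bwd(dz7p, s$pool2_width, W2)             # [B, F2, W2]
  da3 <- aperm(dz7, c(1, 3, 2)); dim(da3) <- c(B * W2, s$F2)

  dz6 <- elu_bwd(da3, cache$a3)
  bn3 <- bn_backward_mat(dz6, cache$bn3, p$bn3_gamma)
  grads$bn3_gamma <- bn3$dgamma; grads$bn3_beta <- bn3$dbeta

  grads$pw_W <- t(cache$Xp) %*% bn3$dX
  dXp <- bn3$dX %*% t(p$pw_W)                          # (B*W2) x M2
  dz5 <- aperm(array(dXp, c(B, W2, s$M2)), c(1, 3, 2)) # [B, M2, W2]

  W1 <- s$w_after_pool1
  grads$sep_K <- matrix(0, s$sep_kernel, s$M2)
  dz4p <- array(0, c(B, s$M2, W1))
  for (m in seq_len(s$M2)) {
    xm <- cache$z4p[, m, , drop = TRUE]
    dm <- dz5[, m, , drop = TRUE]
    if (is.null(dim(xm))) { xm <- matrix(xm, B, W1); dm <- matrix(dm, B, W2) }
    grads$sep_K[, m] <- conv_index_grad(t(xm) %*% dm, model$ci_sep)
    dz4p[, m, ] <- dm %*% t(cache$Tsep[[m]])
  }

  if (!is.null(cache$mask1)) dz4p <- dz4p * cache$mask1
  W0 <- s$input_width; H <- s$n_channels
  dz4 <- pool_bwd(dz4p, s$pool1_width, W0)             # [B, M2, W0]
  da2 <- aperm(dz4, c(1, 3, 2)); dim(da2) <- c(B * W0, s$M2)
  dz3m <- elu_bwd(da2, cache$a2)
  bn2 <- bn_backward_mat(dz3m, cache$bn2, p$bn2_gamma)
  grads$bn2_gamma <- bn2$dgamma; grads$bn2_beta <- bn2$dbeta
  dz3 <- aperm(array(bn2$dX, c(B, W0, s$M2)), c(1, 3, 2))  # [B, M2, W0]

  # depthwise spatial convolution
  grads$dw_W <- matrix(0, H, s$M2)
  dy2 <- array(0, c(B, H, W0, s$F1))
  for (j in seq_len(s$M2)) {
    f <- (j - 1) %/% s$D + 1L
    dvec <- as.vector(dz3[, j, ])                      # length B*W0
    grads$dw_W[, j] <- cache$Ym_list[[f]] %*% dvec
    dYf <- p$dw_W[, j] %o% dvec                        # H x (B*W0)
    dy2[, , , f] <- dy2[, , , f] + aperm(array(dYf, c(H, B, W0)), c(2, 1, 3))
  }

  dy2m <- dy2; dim(dy2m) <- c(B * H * W0, s$F1)
  bn1 <- bn_backward_mat(dy2m, cache$bn1, p$bn1_gamma)
  grads$bn1_gamma <- bn1$dgamma; grads$bn1_beta <- bn1$dbeta
  dy1 <- bn1$dX; dim(dy1) <- c(B, H, W0, s$F1)

  grads$conv1_K <- matrix(0, s$temporal_kernel, s$F1)
  for (f in seq_len(s$F1)) {
    dYfm <- dy1[, , , f]; dim(dYfm) <- c(B * H, W0)
    grads$conv1_K[, f] <- conv_index_grad(t(cache$Xm) %*% dYfm, model$ci1)
  }
  grads[names(model$params)]
}

#' Weighted negative log-likelihood loss for log-probability inputs
#'
#' `l_n = -w_{y_n} x_{n, y_n}` averaged with weight normalization
#' `sum(l_n) / sum(w_{y_n})`; with uniform weights this is the mean negative
#' log-probability of the true classes.
#'
#' @param logp Batch x classes matrix of log-probabilities.
#' @param labels Integer class labels in `1..C`.
#' @param weights Optional per-class weights (length C, default uniform).
#' @return List with scalar `loss` and `dlogp` gradient matrix.
#' @export
nll_loss <- function(logp, labels, weights = NULL) {
  C <- ncol(logp); n <- nrow(logp)
  abort_if(any(labels < 1 | labels > C),
           sprintf("labels must lie in 1..%d", C))
  if (is.null(weights)) weights <- rep(1, C)
  w <- weights[labels]
  idx <- cbind(seq_len(n), labels)
  loss <- sum(-w * logp[idx]) / sum(w)
  dlogp <- matrix(0, n, C)
  dlogp[idx] <- -w / sum(w)
  list(loss = loss, dlogp = dlogp)
}
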