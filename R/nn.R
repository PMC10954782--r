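# Internal layer machinery of the 3D CNN. Activations are arrays
# (D, H, W, C, B); convolution, batch normalization and max-pooling run in
# compiled code, the dense head in base R over BLAS.

# ---- weighted softmax cross-entropy ----
# logits: (B, K); y: integer class in 1..K; w: per-class weights

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

ce_loss <- function(logits, y, class_w) {
  p <- softmax_rows(logits)
  wy <- class_w[y]
  sw <- sum(wy)
  ll <- -log(pmax(p[cbind(seq_along(y), y)], 1e-12))
  loss <- sum(wy * ll) / sw
  dlogits <- p
  dlogits[cbind(seq_along(y), y)] <- dlogits[cbind(seq_along(y), y)] - 1
  dlogits <- dlogits * (wy / sw)
  list(loss = loss, dlogits = dlogits)
}

# ---- full network forward/backward ----
# params: canonical named list (see build_cnn); x: (D,H,W,1,B)

cnn_forward <- function(params, x, training, drop_p, update_bn = training) {
  spec <- attr(params, "spec")
  a <- x
  caches <- vector("list", 4)
  for (b in 1:4) {
    w <- params[[paste0("conv", b, "_w")]]
    z <- .conv3d_forward(a, w, params[[paste0("conv", b, "_b")]], spec$pad)
    gamma <- params[[paste0("bn", b, "_gamma")]]
    bn <- .bn_relu_forward(z, gamma, params[[paste0("bn", b, "_beta")]],
                           params[[paste0("bn", b, "_mean")]],
                           params[[paste0("bn", b, "_var")]], training, 0.1, 1e-5)
    if (update_bn) {
      params[[paste0("bn", b, "_mean")]] <- bn$rmean
      params[[paste0("bn", b, "_var")]] <- bn$rvar
    }
    pl <- .maxpool3d_forward(bn$out, spec$pool_windows[b])
    caches[[b]] <- list(a_in = a, xhat = bn$xhat, istd = bn$istd,
                        gamma = gamma, relu = bn$mask,
                        idx = pl$idx, rdim = dim(bn$out))
    a <- pl$out
  }
  B <- dim(a)[5]
  feat <- t(matrix(a, ncol = B))
  if (training && drop_p > 0) {
    m1 <- matrix(runif(length(feat)) >= drop_p, nrow(feat)) / (1 - drop_p)
    featd <- feat * m1
  } else { m1 <- NULL; featd <- feat }
  h <- sweep(featd %*% params$fc1_w, 2, params$fc1_b, `+`)
  hmask <- h > 0
  hr <- h * hmask
  if (training && drop_p > 0) {
    m2 <- matrix(runif(length(hr)) >= drop_p, nrow(hr)) / (1 - drop_p)
    hd <- hr * m2
  } else { m2 <- NULL; hd <- hr }
  logits <- sweep(hd %*% params$fc2_w, 2, params$fc2_b, `+`)
  list(logits = logits, params = params,
       cache = list(conv = caches, feat = featd, pooled_dim = dim(a),
                    m1 = m1, hmask = hmask, hd = hd, m2 = m2))
}

cnn_backward <- function(params, fwd, dlogits) {
  spec <- attr(params, "spec")
  ca <- fwd$cache
  g <- list()
  g$fc2_w <- t(ca$hd) %*% dlogits
  g$fc2_b <- colSums(dlogits)
  dh <- dlogits %*% t(params$fc2_w)
  if (!is.null(ca$m2)) dh <- dh * ca$m2
  dh <- dh * ca$hmask
  g$fc1_w <- t(ca$feat) %*% dh
  g$fc1_b <- colSums(dh)
  dfeat <- dh %*% t(params$fc1_w)
  if (!is.null(ca$m1)) dfeat <- dfeat * ca$m1
  da <- array(t(dfeat), ca$pooled_dim)
  for (b in 4:1) {
    cb <- ca$conv[[b]]
    dr <- .maxpool3d_backward(da, cb$idx, as.integer(cb$rdim))
    bnb <- .bn_relu_backward(dr, cb$relu, cb$xhat, cb$istd, cb$gamma)
    g[[paste0("bn", b, "_gamma")]] <- bnb$dgamma
    g[[paste0("bn", b, "_beta")]] <- bnb$dbeta
    cv <- .conv3d_backward(cb$a_in, params[[paste0("conv", b, "_w")]],
                           bnb$dx, spec$pad)
    g[[paste0("conv", b, "_w")]] <- cv$dw
    g[[paste0("conv", b, "_b")]] <- cv$db
    da <- cv$dx
  }
  g
}

# Adam with the classic coupled L2 penalty added to the gradient
adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0)

adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}
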