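# MLP classification head over flattened class capsules:
# C*n -> 128 -> 256 -> C with BatchNorm (momentum 0.05), LeakyReLU (slope
# 0.2) and dropout 0.5 after each hidden layer. Hand-authored forward and
# backward passes; BatchNorm uses batch statistics in train mode and
# exponentially updated running statistics in eval mode.

mlp_init <- function(d_in, h1 = 128L, h2 = 256L, n_out = 3L) {
  glorot <- function(fi, fo) matrix(rnorm(fi * fo, 0, sqrt(2 / (fi + fo))), fi, fo)
  list(W1 = glorot(d_in, h1), b1 = numeric(h1),
       g1 = rep(1, h1), be1 = numeric(h1),
       W2 = glorot(h1, h2), b2 = numeric(h2),
       g2 = rep(1, h2), be2 = numeric(h2),
       W3 = glorot(h2, n_out), b3 = numeric(n_out))
}

mlp_state_init <- function(h1 = 128L, h2 = 256L) {
  list(mu1 = numeric(h1), var1 = rep(1, h1),
       mu2 = numeric(h2), var2 = rep(1, h2))
}

BN_EPS <- 1e-5

bn_forward <- function(z, gamma, beta, run_mu, run_var, mode, momentum) {
  B <- nrow(z)
  if (mode == "train") {
    if (B < 2L)
      stopf("degenerate batch: BatchNorm in train mode needs batch size >= 2")
    mu <- colMeans(z)
    va <- colMeans(z^2) - mu^2            # biased batch variance
    va[va < 0] <- 0
    run_mu <- (1 - momentum) * run_mu + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * va * B / (B - 1)
  } else {
    mu <- run_mu
    va <- run_var
  }
  inv <- 1 / sqrt(va + BN_EPS)
  xhat <- sweep(sweep(z, 2L, mu), 2L, inv, `*`)
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(y = y, xhat = xhat, inv = inv, run_mu = run_mu, run_var = run_var)
}

bn_backward <- function(gy, xhat, inv, gamma) {
  B <- nrow(gy)
  dgamma <- colSums(gy * xhat)
  dbeta <- colSums(gy)
  dxhat <- sweep(gy, 2L, gamma, `*`)
  t1 <- sweep(dxhat, 2L, colMeans(dxhat))
  t2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), `*`)
  dz <- sweep(t1 - t2, 2L, inv, `*`)
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

leaky <- function(z, slope) ifelse(z > 0, z, slope * z)
leaky_vjp <- function(z, g, slope) g * ifelse(z > 0, 1, slope)

#' MLP head forward pass
#'
#' Flattens the `(batch, n, C)` class-capsule array into `C * n` columns and
#' applies linear -> BatchNorm -> LeakyReLU -> dropout twice (to 128 then
#' 256 units) followed by a linear map to `C` logits. Dropout is active only
#' in train mode; eval mode normalizes with running statistics and is fully
#' deterministic.
#'
#' @param v class-capsule array `(batch, n, C)` (or an already flattened
#'   matrix).
#' @param params,state parameter and running-statistic lists from the fitted
#'   model (`model$params$mlp`, `model$bn_state`).
#' @param mode `"train"` or `"eval"`.
#' @param dropout,slope,momentum head hyperparameters.
#' @return list with `logits`, updated `state`, and a `cache` for backprop.
#' @export
mlp_forward <- function(v, params, state, mode = c("eval", "train"),
                        dropout = 0.5, slope = 0.2, momentum = 0.05) {
  mode <- match.arg(mode)
  h <- if (is.matrix(v)) v else flatten_caps(v)
  B <- nrow(h)
  z1 <- h %*% params$W1 + rep(params$b1, each = B)
  bn1 <- bn_forward(z1, params$g1, params$be1, state$mu1, state$var1, mode, momentum)
  a1 <- leaky(bn1$y, slope)
  if (mode == "train" && dropout > 0) {
    m1 <- matrix(runif(length(a1)) >= dropout, nrow(a1), ncol(a1)) / (1 - dropout)
    d1 <- a1 * m1
  } else { m1 <- NULL; d1 <- a1 }
  z2 <- d1 %*% params$W2 + rep(params$b2, each = B)
  bn2 <- bn_forward(z2, params$g2, params$be2, state$mu2, state$var2, mode, momentum)
  a2 <- leaky(bn2$y, slope)
  if (mode == "train" && dropout > 0) {
    m2 <- matrix(runif(length(a2)) >= dropout, nrow(a2), ncol(a2)) / (1 - dropout)
    d2 <- a2 * m2
  } else { m2 <- NULL; d2 <- a2 }
  logits <- d2 %*% params$W3 + rep(params$b3, each = B)
  state$mu1 <- bn1$run_mu; state$var1 <- bn1$run_var
  state$mu2 <- bn2$run_mu; state$var2 <- bn2$run_var
  list(logits = logits, state = state,
       cache = list(h = h, bn1 = bn1, bn2 = bn2, m1 = m1, m2 = m2,
                    d1 = d1, d2 = d2, slope = slope))
}

mlp_backward <- function(glogits, cache, params) {
  gW3 <- t(cache$d2) %*% glogits
  gb3 <- colSums(glogits)
  gd2 <- glogits %*% t(params$W3)
  ga2 <- if (is.null(cache$m2)) gd2 else gd2 * cache$m2
  gy2 <- leaky_vjp(cache$bn2$y, ga2, cache$slope)
  bb2 <- bn_backward(gy2, cache$bn2$xhat, cache$bn2$inv, params$g2)
  gW2 <- t(cache$d1) %*% bb2$dz
  gb2 <- colSums(bb2$dz)
  gd1 <- bb2$dz %*% t(params$W2)
  ga1 <- if (is.null(cache$m1)) gd1 else gd1 * cache$m1
  gy1 <- leaky_vjp(cache$bn1$y, ga1, cache$slope)
  bb1 <- bn_backward(gy1, cache$bn1$xhat, cache$bn1$inv, params$g1)
  gW1 <- t(cache$h) %*% bb1$dz
  gb1 <- colSums(bb1$dz)
  gh <- bb1$dz %*% t(params$W1)
  list(grads = list(W1 = gW1, b1 = gb1, g1 = bb1$dgamma, be1 = bb1$dbeta,
                    W2 = gW2, b2 = gb2, g2 = bb2$dgamma, be2 = bb2$dbeta,
                    W3 = gW3, b3 = gb3),
       gh = gh)
}

# (B, n, C) -> (B, C*n); column (j-1)*n + d holds dimension d of class j
flatten_caps <- function(v) {
  d <- dim(v)
  do.call(cbind, lapply(seq_len(d[3]), function(j) matrix(v[, , j], d[1], d[2])))
}

unflatten_caps <- function(h, n, C) {
  B <- nrow(h)
  v <- array(0, c(B, n, C))
  for (j in seq_len(C)) v[, , j] <- h[, ((j - 1L) * n + 1L):(j * n), drop = FALSE]
  v
}
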