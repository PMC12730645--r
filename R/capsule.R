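#' Squash nonlinearity
#'
#' Maps a vector to the same direction with norm compressed into `[0, 1)`:
#' `v = (||s||^2 / (1 + ||s||^2)) * s / ||s||`; the zero vector maps to
#' zero. For a matrix, rows are squashed independently.
#'
#' @param s numeric vector, or matrix whose rows are vectors.
#' @return object of the same shape.
#' @export
squash <- function(s) {
  if (is.matrix(s)) return(squash_rows(s))
  as.vector(squash_rows(matrix(s, nrow = 1L)))
}

squash_rows <- function(m) {
  n2 <- rowSums(m * m)
  m * (sqrt(n2) / (1 + n2))
}

# vector-Jacobian product of squash_rows: rows of g are upstream gradients
# at rows of s; grad = f(r) g + f'(r)/r (s.g) s with f(r) = r/(1+r^2)
squash_rows_vjp <- function(s, g) {
  n2 <- rowSums(s * s)
  r <- sqrt(n2)
  f <- r / (1 + n2)
  fp <- (1 - n2) / (1 + n2)^2
  dot <- rowSums(s * g)
  coef <- ifelse(r > 1e-12, fp * dot / r, 0)
  g * f + s * coef
}

#' Euclidean lengths of class capsules
#'
#' @param v class-capsule array `(batch, dim, class)`, a `(dim, class)`
#'   matrix for one sample, or a single vector.
#' @return matrix `(batch, class)` of lengths (vector input: a scalar).
#' @export
capsule_lengths <- function(v) {
  if (is.null(dim(v))) return(sqrt(sum(v * v)))
  if (length(dim(v)) == 2L) v <- array(v, c(1L, dim(v)))
  caps_lengths(v)
}

caps_lengths <- function(v) {
  # v: (B, n, C) -> (B, C)
  d <- dim(v)
  out <- matrix(0, d[1], d[3])
  for (j in seq_len(d[3]))
    out[, j] <- sqrt(rowSums(matrix(v[, , j], d[1], d[2])^2))
  out
}

#' Primary capsule layer
#'
#' Affine map of the input features to `m * n` values, reshaped to `m`
#' capsules of dimension `n` and squashed per capsule (the fully connected
#' replacement for convolutional primary capsules).
#'
#' @param x numeric matrix `(batch, n_features)` (a vector is treated as one
#'   sample).
#' @param w_prim weight matrix `(n_features, m * n)`.
#' @param b_prim bias vector of length `m * n`.
#' @param m,n number of primary capsules and capsule dimension.
#' @return array `(batch, n, m)` of squashed primary capsules.
#' @export
primary_caps <- function(x, w_prim, b_prim, m = 16L, n = 8L) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != nrow(w_prim))
    stopf("x has %d features but w_prim expects %d", ncol(x), nrow(w_prim))
  if (ncol(w_prim) != m * n || length(b_prim) != m * n)
    stopf("w_prim/b_prim are not sized for %d capsules of dim %d", m, n)
  s <- x %*% w_prim + rep(b_prim, each = nrow(x))
  v <- array(0, c(nrow(x), n, m))
  for (k in seq_len(m)) {
    cols <- ((k - 1L) * n + 1L):(k * n)
    v[, , k] <- squash_rows(s[, cols, drop = FALSE])
  }
  v
}

#' Prediction vectors from primary capsules
#'
#' `u_hat[k -> j] = W_kj %*% v_k` for every primary capsule `k` and class
#' `j`, each pair having its exclusive `n x n` matrix.
#'
#' @param v_prim array `(batch, n, m)` from [primary_caps()].
#' @param w_caps array `(n, n, m, C)` of per-pair weight matrices.
#' @return array `(batch, n, m, C)` of prediction vectors.
#' @export
prediction_vectors <- function(v_prim, w_caps) {
  d <- dim(v_prim)
  dw <- dim(w_caps)
  if (length(dw) != 4L || dw[1] != d[2] || dw[2] != d[2] || dw[3] != d[3])
    stopf("w_caps shape is inconsistent with v_prim")
  B <- d[1]; n <- d[2]; m <- d[3]; C <- dw[4]
  u <- array(0, c(B, n, m, C))
  for (k in seq_len(m)) {
    vk <- matrix(v_prim[, , k], B, n)
    for (j in seq_len(C))
      u[, , k, j] <- vk %*% t(w_caps[, , k, j])
  }
  u
}

# softmax over the class axis of a (B, m, C) array
routing_softmax <- function(b_log) {
  d <- dim(b_log)
  mx <- b_log[, , 1]
  for (j in seq_len(d[3])[-1]) mx <- pmax(mx, b_log[, , j])
  e <- array(0, d)
  for (j in seq_len(d[3])) e[, , j] <- exp(b_log[, , j] - mx)
  s <- e[, , 1]
  for (j in seq_len(d[3])[-1]) s <- s + e[, , j]
  for (j in seq_len(d[3])) e[, , j] <- e[, , j] / s
  e
}

#' Dynamic routing with adaptive per-class iteration counts
#'
#' Classic agreement routing: logits start at zero; each iteration the
#' couplings are the class-axis softmax of the logits, class capsules
#' aggregate coupling-weighted prediction vectors through [squash()], and
#' logits grow by the agreement `u_hat . v`. After `r_base` iterations the
#' variance of each class capsule's length over the batch sets an extra
#' per-class iteration budget `extra_j = round(alpha * Var_j)` (or
#' `ceiling`); routing continues with class `j`'s logit column and capsule
#' frozen once its extra iterations are exhausted.
#'
#' @param u prediction-vector array `(batch, n, m, C)`.
#' @param r_base base iteration count (default 3).
#' @param alpha adaptive adjustment coefficient (default 1; 0 reproduces
#'   fixed `r_base`-iteration routing exactly).
#' @param rounding `"nearest"` or `"ceil"` for the extra-iteration count.
#' @param keep_cache keep per-iteration internals (needed for full
#'   backpropagation through the routing loop).
#' @return list with `v` `(batch, n, C)` class capsules, `coupling`
#'   `(batch, m, C)`, `iterations` (per-class totals), and optionally
#'   `cache`.
#' @export
dynamic_routing <- function(u, r_base = 3L, alpha = 1, rounding = c("nearest", "ceil"),
                            keep_cache = FALSE) {
  rounding <- match.arg(rounding)
  if (!is_count(r_base)) stopf("r_base must be a positive integer")
  if (any(!is.finite(u))) stopf("u must be finite")
  d <- dim(u)
  B <- d[1]; n <- d[2]; m <- d[3]; C <- d[4]
  uk <- vector("list", m)                 # u[[k]][[j]]: (B, n) matrices
  for (k in seq_len(m))
    uk[[k]] <- lapply(seq_len(C), function(j) matrix(u[, , k, j], B, n))

  b_log <- array(0, c(B, m, C))
  v <- array(0, c(B, n, C))
  cache <- if (keep_cache) list() else NULL

  route_iter <- function(b_log, v, active, record) {
    cc <- routing_softmax(b_log)
    s <- array(0, c(B, n, C))
    for (j in active) {
      sj <- matrix(0, B, n)
      for (k in seq_len(m)) sj <- sj + uk[[k]][[j]] * cc[, k, j]
      s[, , j] <- sj
      v[, , j] <- squash_rows(sj)
    }
    agree <- array(0, c(B, m, C))
    for (j in active) {
      vj <- matrix(v[, , j], B, n)
      for (k in seq_len(m)) agree[, k, j] <- rowSums(uk[[k]][[j]] * vj)
    }
    if (record && keep_cache)
      cache[[length(cache) + 1L]] <<- list(cc = cc, s = s, v = v, active = active)
    list(b_log = b_log + agree, v = v, cc = cc)
  }

  all_j <- seq_len(C)
  for (it in seq_len(r_base)) {
    st <- route_iter(b_log, v, all_j, record = TRUE)
    b_log <- st$b_log; v <- st$v; cc <- st$cc
  }

  lens <- caps_lengths(v)
  var_j <- if (B > 1) apply(lens, 2L, var) else rep(0, C)
  extra <- if (alpha == 0) rep(0L, C) else {
    e <- alpha * var_j
    as.integer(if (rounding == "ceil") ceiling(e) else round(e))
  }
  extra[extra < 0L] <- 0L
  if (any(extra > 0L)) {
    for (t in seq_len(max(extra))) {
      active <- which(extra >= t)
      st <- route_iter(b_log, v, active, record = FALSE)
      # frozen classes keep their logit columns and capsules
      for (j in active) {
        b_log[, , j] <- st$b_log[, , j]
        v[, , j] <- st$v[, , j]
      }
      cc <- st$cc
    }
  }
  out <- list(v = v, coupling = cc, iterations = r_base + extra,
              length_variance = var_j)
  if (keep_cache) out$cache <- cache
  out
}

# backward through routing, detached couplings: gradients flow only through
# the final aggregation v_j = squash(sum_k cc_kj u_kj) with cc constant
routing_vjp_detached <- function(u, cache, grad_v) {
  d <- dim(u)
  B <- d[1]; n <- d[2]; m <- d[3]; C <- d[4]
  last <- cache[[length(cache)]]
  gu <- array(0, d)
  for (j in seq_len(C)) {
    gs <- squash_rows_vjp(matrix(last$s[, , j], B, n),
                          matrix(grad_v[, , j], B, n))
    for (k in seq_len(m)) gu[, , k, j] <- gs * last$cc[, k, j]
  }
  gu
}

# full backward through the unrolled routing iterations (fixed iteration
# count, i.e. alpha = 0); differentiates couplings, agreements and logits
routing_vjp_full <- function(u, cache, grad_v) {
  d <- dim(u)
  B <- d[1]; n <- d[2]; m <- d[3]; C <- d[4]
  R <- length(cache)
  gu <- array(0, d)
  gB <- array(0, c(B, m, C))          # grad wrt logits entering iteration t
  gV <- grad_v
  for (t in rev(seq_len(R))) {
    st <- cache[[t]]
    # logits update B_{t+1} = B_t + agree(u, v_t) was consumed downstream
    if (t < R) {
      for (j in seq_len(C)) {
        gvj <- matrix(0, B, n)
        for (k in seq_len(m)) {
          gu[, , k, j] <- gu[, , k, j] + st$v[, , j] * gB[, k, j]
          gvj <- gvj + u[, , k, j] * gB[, k, j]
        }
        gV[, , j] <- gV[, , j] + gvj
      }
    }
    gcc <- array(0, c(B, m, C))
    for (j in seq_len(C)) {
      gs <- squash_rows_vjp(matrix(st$s[, , j], B, n),
                            matrix(gV[, , j], B, n))
      for (k in seq_len(m)) {
        gu[, , k, j] <- gu[, , k, j] + gs * st$cc[, k, j]
        gcc[, k, j] <- rowSums(u[, , k, j] * gs)
      }
    }
    # softmax (over j) backward into the logits of iteration t
    dot <- matrix(0, B, m)
    for (j in seq_len(C)) dot <- dot + st$cc[, , j] * gcc[, , j]
    gBt <- array(0, c(B, m, C))
    for (j in seq_len(C)) gBt[, , j] <- st$cc[, , j] * (gcc[, , j] - dot)
    gB <- gBt + gB                     # B_t feeds both softmax_t and B_{t+1}
    gV <- array(0, c(B, n, C))
  }
  # B_1 = 0 is a constant; its gradient is dropped
  gu
}
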