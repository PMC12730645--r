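# Independent reference implementations used as oracles. These are written
# as plain, loop-based direct evaluations of the defining formulas and stay
# independent of the package's vectorized code paths.

ref_squash <- function(s) {
  r2 <- sum(s^2)
  if (r2 == 0) return(s * 0)
  (r2 / (1 + r2)) * s / sqrt(r2)
}

# fixed-iteration dynamic routing, one sample at a time, straight from the
# update equations: softmax couplings over classes, weighted aggregation,
# squash, agreement-based logit update
ref_routing_fixed <- function(u, iters = 3L) {
  d <- dim(u)                       # (B, n, m, C)
  B <- d[1]; n <- d[2]; m <- d[3]; C <- d[4]
  v_out <- array(0, c(B, n, C))
  cc_out <- array(0, c(B, m, C))
  for (b in seq_len(B)) {
    blog <- matrix(0, m, C)
    v <- matrix(0, n, C)
    for (it in seq_len(iters)) {
      cc <- t(apply(blog, 1L, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
      if (m == 1L) cc <- matrix(cc, 1L, C)
      for (j in seq_len(C)) {
        s <- numeric(n)
        for (k in seq_len(m)) s <- s + cc[k, j] * u[b, , k, j]
        v[, j] <- ref_squash(s)
      }
      for (k in seq_len(m)) for (j in seq_len(C))
        blog[k, j] <- blog[k, j] + sum(u[b, , k, j] * v[, j])
    }
    v_out[b, , ] <- v
    cc_out[b, , ] <- cc
  }
  list(v = v_out, coupling = cc_out)
}

# direct-formula moment statistics of one value set (population variance,
# excess kurtosis, adjusted skewness, CV), mirroring the documented
# conventions but computed with explicit loops
ref_family_stats <- function(v) {
  n <- length(v)
  if (n == 0) return(c(0, 0, 0, 0, 0))
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  m3 <- sum((v - m)^3) / n
  m4 <- sum((v - m)^4) / n
  kurt <- if (n >= 2 && m2 > 1e-24) m4 / m2^2 - 3 else 0
  skew <- if (n >= 3 && m2 > 1e-24) sqrt(n * (n - 1)) / (n - 2) * m3 / m2^1.5 else 0
  cv <- if (abs(m) > 1e-12) sqrt(m2) / abs(m) else 0
  c(m, kurt, skew, m2, cv)
}

ref_margin_loss <- function(lengths, y, m_plus = 0.9, m_minus = 0.1, beta = 0.5) {
  B <- nrow(lengths)
  total <- 0
  for (i in seq_len(B)) for (j in seq_len(ncol(lengths))) {
    l <- lengths[i, j]
    total <- total + y[i, j] * max(0, m_plus - l)^2 +
      beta * (1 - y[i, j]) * max(0, l - m_minus)^2
  }
  total / B
}

ref_weighted_ce <- function(logits, y, w = NULL) {
  if (is.null(w)) w <- rep(1, ncol(logits))
  total <- 0
  for (i in seq_len(nrow(logits))) {
    p <- exp(logits[i, ]) / sum(exp(logits[i, ]))
    for (j in seq_len(ncol(logits)))
      total <- total + w[j] * y[i, j] * log(p[j])
  }
  -total / nrow(logits)
}

# paint per-velocity-sample labels from an event table (half-open ranges)
event_sample_labels <- function(events, n_velocities) {
  out <- character(n_velocities)
  for (i in seq_len(nrow(events)))
    out[events$start_idx[i]:(events$end_idx[i] - 1L)] <- events$kind[i]
  out
}

# small deterministic recording with a known fixation-saccade-fixation plan
toy_recording <- function(rate_hz = 240, fix1 = 48L, sacc = 6L, fix2 = 48L,
                          speed = 300) {
  n_steps <- fix1 + sacc + fix2
  x <- numeric(n_steps + 1L)
  for (i in seq_len(n_steps))
    x[i + 1L] <- x[i] + if (i > fix1 && i <= fix1 + sacc) speed / rate_hz else 0
  new_toy <- list(time = (0:n_steps) / rate_hz, x = x, y = numeric(n_steps + 1L),
                  pupil = rep(3.5, n_steps + 1L),
                  confidence = rep(1, n_steps + 1L), rate_hz = rate_hz,
                  subject_id = "T", trial_id = "T1", label = 0L,
                  events = data.frame(
                    kind = c("fixation", "saccade", "fixation"),
                    start_idx = c(1L, fix1 + 1L, fix1 + sacc + 1L),
                    end_idx = c(fix1 + 1L, fix1 + sacc + 1L, n_steps + 1L)))
  structure(new_toy, class = "gaze_recording")
}

# classic fixed-iteration routing with no adaptive machinery at all,
# written directly from the published update rule in the same batched
# accumulation order as the package (so bit-identity is meaningful);
# independent correctness is covered by ref_routing_fixed above
fixed_routing_batched <- function(u, iters = 3L) {
  d <- dim(u)
  B <- d[1]; n <- d[2]; m <- d[3]; C <- d[4]
  b_log <- array(0, c(B, m, C))
  v <- array(0, c(B, n, C))
  cc <- NULL
  for (it in seq_len(iters)) {
    mx <- b_log[, , 1]
    for (j in seq_len(C)[-1]) mx <- pmax(mx, b_log[, , j])
    e <- array(0, c(B, m, C))
    for (j in seq_len(C)) e[, , j] <- exp(b_log[, , j] - mx)
    s <- e[, , 1]
    for (j in seq_len(C)[-1]) s <- s + e[, , j]
    for (j in seq_len(C)) e[, , j] <- e[, , j] / s
    cc <- e
    for (j in seq_len(C)) {
      sj <- matrix(0, B, n)
      for (k in seq_len(m)) sj <- sj + matrix(u[, , k, j], B, n) * cc[, k, j]
      v[, , j] <- gazecaps::squash(sj)
    }
    for (j in seq_len(C)) {
      vj <- matrix(v[, , j], B, n)
      for (k in seq_len(m))
        b_log[, k, j] <- b_log[, k, j] + rowSums(matrix(u[, , k, j], B, n) * vj)
    }
  }
  list(v = v, coupling = cc)
}

# three widely separated Gaussian classes; easy supervised check
sep_features <- function(n_per_class = 60, d = 6, gap = 8, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(0:2, function(cl)
    matrix(rnorm(n_per_class * d, mean = cl * gap), n_per_class, d)))
  list(x = x, y = rep(0:2, each = n_per_class))
}

toy_caps_config <- function(F, m = 4L, n = 3L, C = 3L, alpha = 0,
                            routing_grad = "full", dropout = 0,
                            hidden = c(7L, 9L)) {
  list(n_features = F, n_primary = m, capsule_dim = n, n_classes = C,
       r_base = 3L, alpha = alpha, rounding = "nearest",
       routing_grad = routing_grad, hidden = as.integer(hidden),
       leaky_slope = 0.2, dropout = dropout, bn_momentum = 0.05,
       loss = loss_config())
}
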