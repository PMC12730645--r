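test_that("squash matches its closed form and handles extremes", {
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  s <- c(0.6, 0.8)                       # unit norm: squashed norm 1/2
  expect_equal(sqrt(sum(squash(s)^2)), 0.5, tolerance = 1e-12)
  big <- c(1000, 0, 0)
  vb <- squash(big)
  expect_equal(sqrt(sum(vb^2)), 1e6 / (1 + 1e6), tolerance = 1e-12)
  expect_equal(vb / sqrt(sum(vb^2)), big / 1000, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:20) {
    s <- rnorm(sample(2:10, 1)) * 10^runif(1, -3, 3)
    v <- squash(s)
    expect_equal(v, ref_squash(s), tolerance = 1e-12)
    n2 <- sum(s^2)
    expect_equal(sqrt(sum(v^2)), n2 / (1 + n2), tolerance = 1e-9)
    expect_lt(sqrt(sum(v^2)), 1)
  }
})

test_that("primary capsules have the configured shape and norms below one", {
  set.seed(2)
  F <- 26L; m <- 16L; n <- 8L
  w <- matrix(rnorm(F * m * n), F, m * n)
  b <- rnorm(m * n)
  x <- matrix(rnorm(5 * F), 5, F)
  v <- primary_caps(x, w, b, m, n)
  expect_equal(dim(v), c(5L, n, m))
  lens <- apply(v, c(1, 3), function(z) sqrt(sum(z^2)))
  expect_true(all(lens < 1))
  # zero weights and bias: all capsules zero
  v0 <- primary_caps(x, w * 0, b * 0, m, n)
  expect_equal(max(abs(v0)), 0)
  expect_error(primary_caps(x[, 1:10], w, b, m, n), "features")
})

test_that("prediction vectors apply per-pair matrices", {
  set.seed(3)
  B <- 4L; n <- 8L; m <- 16L; C <- 3L
  vp <- array(rnorm(B * n * m), c(B, n, m))
  wid <- array(0, c(n, n, m, C))
  for (k in seq_len(m)) for (j in seq_len(C)) wid[, , k, j] <- diag(n)
  u <- prediction_vectors(vp, wid)
  expect_equal(dim(u), c(B, n, m, C))      # 48 vectors of dim 8 per sample
  for (j in seq_len(C)) expect_equal(u[, , , j], vp)
  expect_equal(max(abs(prediction_vectors(vp * 0, wid))), 0)

  w <- array(rnorm(n * n * m * C, 0, 0.3), c(n, n, m, C))
  u2 <- prediction_vectors(vp, w)
  expect_equal(as.vector(u2[2, , 5, 3]),
               as.vector(w[, , 5, 3] %*% vp[2, , 5]), tolerance = 1e-12)
})

test_that("routing couplings start uniform and always sum to one", {
  set.seed(4)
  B <- 6L; n <- 4L; m <- 5L; C <- 3L
  u <- array(rnorm(B * n * m * C), c(B, n, m, C))
  rt <- dynamic_routing(u, r_base = 1L, alpha = 0)
  expect_equal(as.vector(rt$coupling), rep(1 / C, B * m * C), tolerance = 1e-12)
  rt3 <- dynamic_routing(u, r_base = 3L, alpha = 1, keep_cache = TRUE)
  for (st in rt3$cache) {
    sums <- st$cc[, , 1]
    for (j in 2:C) sums <- sums + st$cc[, , j]
    expect_equal(as.vector(sums), rep(1, B * m), tolerance = 1e-6)
  }
  lens <- capsule_lengths(rt3$v)
  expect_true(all(lens < 1))
})

test_that("adaptive routing with alpha = 0 equals fixed 3-iteration routing", {
  set.seed(5)
  u <- array(rnorm(8 * 6 * 10 * 3), c(8, 6, 10, 3))
  adaptive_off <- dynamic_routing(u, r_base = 3L, alpha = 0)
  # bit-identity against classic routing with no adaptive machinery
  fixed <- fixed_routing_batched(u, iters = 3L)
  expect_identical(adaptive_off$v, fixed$v)
  expect_identical(adaptive_off$coupling, fixed$coupling)
  expect_equal(adaptive_off$iterations, rep(3L, 3))
  # numerical agreement with the independent per-sample oracle
  oracle <- ref_routing_fixed(u, iters = 3L)
  expect_equal(adaptive_off$v, oracle$v, tolerance = 1e-12)
  expect_equal(adaptive_off$coupling, oracle$coupling, tolerance = 1e-12)
})

test_that("identical samples give zero length variance and base iterations", {
  set.seed(6)
  one <- array(rnorm(1 * 4 * 5 * 3), c(1, 4, 5, 3))
  u <- array(0, c(8, 4, 5, 3))
  for (b in 1:8) u[b, , , ] <- one[1, , , ]
  rt <- dynamic_routing(u, r_base = 3L, alpha = 1)
  expect_equal(rt$length_variance, rep(0, 3), tolerance = 1e-20)
  expect_equal(rt$iterations, rep(3L, 3))
})

test_that("single-primary-capsule routing matches brute-force recursion", {
  set.seed(7)
  u <- array(rnorm(2 * 5 * 1 * 3), c(2, 5, 1, 3))
  # the brute-force oracle shows the couplings are NOT constant across
  # classes once logits update, but every class capsule stays collinear
  # with its prediction vector (S_j is always a positive multiple of u_1j)
  for (iters in c(1L, 3L, 5L)) {
    rt <- dynamic_routing(u, r_base = iters, alpha = 0)
    oracle <- ref_routing_fixed(u, iters = iters)
    expect_equal(rt$v, oracle$v, tolerance = 1e-12)
    for (b in 1:2) for (j in 1:3) {
      vj <- rt$v[b, , j]
      uj <- u[b, , 1, j]
      cosang <- sum(vj * uj) / sqrt(sum(vj^2) * sum(uj^2))
      expect_equal(cosang, 1, tolerance = 1e-9)
    }
  }
  # at the first iteration the coupling is uniform, so V_j = squash(u_1j / C)
  r1 <- dynamic_routing(u, r_base = 1L, alpha = 0)
  for (j in 1:3)
    expect_equal(r1$v[, , j], t(apply(u[, , 1, j] / 3, 1, ref_squash)),
                 tolerance = 1e-12)
})

test_that("capsule lengths follow the Euclidean norm", {
  expect_equal(capsule_lengths(c(0, 0, 0, 0)), 0)
  expect_equal(capsule_lengths(c(0.6, 0.8, 0, 0)), 1)
  v <- array(rnorm(24), c(2, 4, 3))
  lens <- capsule_lengths(v)
  expect_equal(lens[2, 3], sqrt(sum(v[2, , 3]^2)), tolerance = 1e-12)
})

test_that("the MLP head flattens 3x8 capsules into 24 inputs and is
           deterministic in eval mode", {
  set.seed(8)
  C <- 3L; n <- 8L
  params <- gazecaps:::mlp_init(C * n, 128L, 256L, C)
  state <- gazecaps:::mlp_state_init(128L, 256L)
  expect_equal(nrow(params$W1), 24L)
  v <- array(rnorm(4 * n * C, 0, 0.3), c(4, n, C))
  h <- gazecaps:::flatten_caps(v)
  expect_equal(dim(h), c(4L, 24L))
  expect_equal(h[2, (2 - 1) * n + 3], v[2, 3, 2])
  out1 <- mlp_forward(v, params, state, mode = "eval")
  out2 <- mlp_forward(v, params, state, mode = "eval")
  expect_identical(out1$logits, out2$logits)
  expect_equal(dim(out1$logits), c(4L, C))
  # train mode refuses a single-sample batch (degenerate batch statistics)
  expect_error(mlp_forward(v[1, , , drop = FALSE], params, state,
                           mode = "train"), "degenerate")
})

test_that("margin loss and weighted CE match direct-formula oracles", {
  cfg <- loss_config()
  # worked case: true length 0.95, others 0.05: both hinges inactive
  expect_equal(margin_loss(matrix(c(0.95, 0.05, 0.05), 1),
                           matrix(c(1, 0, 0), 1), cfg), 0)
  # all lengths 0.5: (0.9-0.5)^2 + 0.5 * 2 * (0.5-0.1)^2 = 0.32
  expect_equal(margin_loss(matrix(0.5, 1, 3), matrix(c(0, 1, 0), 1), cfg),
               0.32, tolerance = 1e-12)
  # uniform logits, unit weights: ln C
  expect_equal(weighted_ce(matrix(0, 3, 3), diag(3)), log(3), tolerance = 1e-12)
  set.seed(9)
  for (i in 1:10) {
    B <- sample(2:6, 1); C <- sample(2:4, 1)
    lens <- matrix(runif(B * C), B, C)
    y <- diag(C)[sample(C, B, replace = TRUE), , drop = FALSE]
    expect_equal(margin_loss(lens, y, cfg), ref_margin_loss(lens, y),
                 tolerance = 1e-7)
    logits <- matrix(rnorm(B * C, 0, 2), B, C)
    w <- runif(C, 0.5, 2)
    expect_equal(weighted_ce(logits, y, w), ref_weighted_ce(logits, y, w),
                 tolerance = 1e-7)
    # doubling all weights doubles the loss
    expect_equal(weighted_ce(logits, y, 2 * w),
                 2 * weighted_ce(logits, y, w), tolerance = 1e-9)
  }
})

test_that("class-weight refresh follows the misclassification-rate rule", {
  conf <- rbind(c(9, 1, 0), c(1, 8, 1), c(2, 1, 7))  # errors 0.1, 0.2, 0.3
  w <- update_class_weights(conf, eps = 1e-9)
  expect_equal(w, c(0.5, 1.0, 1.5), tolerance = 1e-6)
  # equal errors: unit weights
  eq <- rbind(c(8, 1, 1), c(1, 8, 1), c(1, 1, 8))
  expect_equal(update_class_weights(eq), rep(1, 3), tolerance = 1e-12)
  # zero errors: eps smoothing keeps weights at one
  expect_equal(update_class_weights(diag(c(5, 5, 5))), rep(1, 3))
  # absent class keeps its previous weight
  ab <- rbind(c(4, 1, 0), c(0, 0, 0), c(1, 0, 4))
  w2 <- update_class_weights(ab, prev = c(1, 1.7, 1))
  expect_equal(w2[2], 1.7)
})

test_that("total loss mixes margin and CE with weight lambda", {
  expect_equal(total_loss(0.32, log(3), lambda = 0.1), 0.32 + 0.1 * log(3))
  expect_equal(total_loss(0.5, 2, lambda = 0), 0.5)
})

test_that("backpropagated gradients match finite differences", {
  set.seed(10)
  F <- 6L
  cfg <- toy_caps_config(F)
  params <- gazecaps:::caps_params_init(F, cfg$n_primary, cfg$capsule_dim,
                                        cfg$n_classes, cfg$hidden[1],
                                        cfg$hidden[2])
  x <- matrix(rnorm(2 * F), 2, F)
  y <- c(0L, 1L)
  w <- c(1.2, 0.8, 1.0)
  g <- capsnet_loss_gradients(x, y, params, cfg, class_weights = w)
  fd <- function(pname, idx, h = 1e-5) {
    pp <- params; pp[[pname]][idx] <- pp[[pname]][idx] + h
    pm <- params; pm[[pname]][idx] <- pm[[pname]][idx] - h
    (capsnet_loss_gradients(x, y, pp, cfg, class_weights = w)$loss -
       capsnet_loss_gradients(x, y, pm, cfg, class_weights = w)$loss) / (2 * h)
  }
  for (pname in c("W_prim", "b_prim", "w_caps", "W1", "g1", "W3", "b3")) {
    idxs <- sample(length(params[[pname]]), min(6, length(params[[pname]])))
    for (idx in idxs) {
      num <- fd(pname, idx)
      ana <- g$grads[[pname]][idx]
      expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-6), 1e-4)
    }
  }
  # full-mode gradients require a fixed iteration count
  cfg_bad <- toy_caps_config(F, alpha = 1, routing_grad = "full")
  expect_error(capsnet_loss_gradients(x, y, params, cfg_bad), "alpha = 0")
})

test_that("detached-coupling gradients are exact when couplings are
           input-independent", {
  set.seed(12)
  F <- 5L
  cfg <- toy_caps_config(F, routing_grad = "detached")
  cfg$r_base <- 1L                    # couplings are softmax(0): constant
  params <- gazecaps:::caps_params_init(F, cfg$n_primary, cfg$capsule_dim,
                                        cfg$n_classes, cfg$hidden[1],
                                        cfg$hidden[2])
  x <- matrix(rnorm(2 * F), 2, F)
  y <- c(2L, 0L)
  g <- capsnet_loss_gradients(x, y, params, cfg)
  for (idx in sample(length(params$W_prim), 5)) {
    h <- 1e-5
    pp <- params; pp[[1]][idx] <- pp[[1]][idx] + h
    pm <- params; pm[[1]][idx] <- pm[[1]][idx] - h
    num <- (capsnet_loss_gradients(x, y, pp, cfg)$loss -
              capsnet_loss_gradients(x, y, pm, cfg)$loss) / (2 * h)
    expect_lt(abs(num - g$grads$W_prim[idx]) /
                max(abs(num) + abs(g$grads$W_prim[idx]), 1e-6), 1e-4)
  }
})
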