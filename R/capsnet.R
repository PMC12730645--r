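# ---- network forward / backward ------------------------------------------

caps_params_init <- function(F, m, n, C, h1, h2) {
  glorot <- function(fi, fo) matrix(rnorm(fi * fo, 0, sqrt(2 / (fi + fo))), fi, fo)
  p <- list(
    W_prim = glorot(F, m * n),
    b_prim = numeric(m * n),
    w_caps = array(rnorm(n * n * m * C, 0, sqrt(1 / n)), c(n, n, m, C))
  )
  c(p, mlp_init(C * n, h1, h2, C))
}

stack_caps_weights <- function(w_caps) {
  d <- dim(w_caps)                       # (n, n, m, C)
  lapply(seq_len(d[3]), function(k)
    do.call(cbind, lapply(seq_len(d[4]), function(j) t(w_caps[, , k, j]))))
}

caps_forward <- function(x, params, bn_state, cfg, mode = "eval",
                         class_weights = NULL, y_onehot = NULL,
                         keep_cache = FALSE) {
  B <- nrow(x)
  m <- cfg$n_primary; n <- cfg$capsule_dim; C <- cfg$n_classes
  sp <- x %*% params$W_prim + rep(params$b_prim, each = B)
  vp <- array(0, c(B, n, m))
  for (k in seq_len(m))
    vp[, , k] <- squash_rows(sp[, ((k - 1L) * n + 1L):(k * n), drop = FALSE])
  wstack <- stack_caps_weights(params$w_caps)
  u <- array(0, c(B, n, m, C))
  for (k in seq_len(m)) {
    blk <- matrix(vp[, , k], B, n) %*% wstack[[k]]
    for (j in seq_len(C)) u[, , k, j] <- blk[, ((j - 1L) * n + 1L):(j * n)]
  }
  rt <- dynamic_routing(u, r_base = cfg$r_base, alpha = cfg$alpha,
                        rounding = cfg$rounding, keep_cache = TRUE)
  lens <- caps_lengths(rt$v)
  mf <- mlp_forward(rt$v, params, bn_state, mode = mode,
                    dropout = cfg$dropout, slope = cfg$leaky_slope,
                    momentum = cfg$bn_momentum)
  out <- list(v = rt$v, coupling = rt$coupling, iterations = rt$iterations,
              lengths = lens, logits = mf$logits, bn_state = mf$state)
  if (!is.null(y_onehot)) {
    out$margin <- margin_loss(lens, y_onehot, cfg$loss)
    out$ce <- weighted_ce(mf$logits, y_onehot, class_weights)
    out$loss <- total_loss(out$margin, out$ce, cfg$loss$lambda)
  }
  if (keep_cache)
    out$cache <- list(sp = sp, vp = vp, u = u, routing = rt$cache,
                      wstack = wstack, mlp = mf$cache)
  out
}

caps_backward <- function(x, y_onehot, fwd, params, cfg, class_weights = NULL) {
  B <- nrow(x)
  m <- cfg$n_primary; n <- cfg$capsule_dim; C <- cfg$n_classes
  ca <- fwd$cache
  # cross-entropy branch through the MLP
  glogits <- cfg$loss$lambda * weighted_ce_vjp(fwd$logits, y_onehot, class_weights)
  mb <- mlp_backward(glogits, ca$mlp, params)
  gV <- unflatten_caps(mb$gh, n, C)
  # margin branch straight from the capsule lengths
  gl <- margin_loss_vjp(fwd$lengths, y_onehot, cfg$loss)
  for (j in seq_len(C)) {
    lj <- fwd$lengths[, j]
    sc <- ifelse(lj > 1e-12, gl[, j] / lj, 0)
    gV[, , j] <- gV[, , j] + matrix(fwd$v[, , j], B, n) * sc
  }
  gu <- if (identical(cfg$routing_grad, "full"))
    routing_vjp_full(ca$u, ca$routing, gV)
  else
    routing_vjp_detached(ca$u, ca$routing, gV)
  gw_caps <- array(0, dim(params$w_caps))
  gsp <- matrix(0, B, m * n)
  for (k in seq_len(m)) {
    gk <- do.call(cbind, lapply(seq_len(C), function(j) matrix(gu[, , k, j], B, n)))
    vk <- matrix(ca$vp[, , k], B, n)
    gws <- crossprod(vk, gk)                    # n x (n*C)
    for (j in seq_len(C))
      gw_caps[, , k, j] <- t(gws[, ((j - 1L) * n + 1L):(j * n), drop = FALSE])
    gvk <- gk %*% t(ca$wstack[[k]])
    cols <- ((k - 1L) * n + 1L):(k * n)
    gsp[, cols] <- squash_rows_vjp(ca$sp[, cols, drop = FALSE], gvk)
  }
  grads <- mb$grads
  grads$W_prim <- crossprod(x, gsp)
  grads$b_prim <- colSums(gsp)
  grads$w_caps <- gw_caps
  grads
}

#' Total loss and parameter gradients at a given parameter point
#'
#' Runs one forward/backward pass of the full network (primary capsules,
#' routing, margin loss, MLP head, weighted cross-entropy) and returns the
#' loss components together with the gradient of the total loss with
#' respect to every parameter. Intended for verification (e.g.
#' finite-difference gradient checks) and for extending the optimizer.
#'
#' With `routing_grad = "full"` the gradient is backpropagated through the
#' unrolled routing iterations (requires `alpha = 0`, i.e. a fixed
#' iteration count); `"detached"` treats the couplings as
#' non-differentiated control flow, matching common capsule
#' implementations.
#'
#' @param x standardized feature matrix `(batch, F)`.
#' @param y integer class labels `0 .. C-1`.
#' @param params parameter list as produced by an existing fit
#'   (`model$params`) or internally initialized.
#' @param config model configuration list (`model$config`).
#' @param class_weights optional positive per-class weights for the
#'   cross-entropy term.
#' @param mode `"train"` (batch statistics; dropout as configured) or
#'   `"eval"`.
#' @return list with `loss`, `margin`, `ce` and `grads`.
#' @export
capsnet_loss_gradients <- function(x, y, params, config, class_weights = NULL,
                                   mode = "train") {
  if (identical(config$routing_grad, "full") && config$alpha != 0)
    stopf("routing_grad = \"full\" requires alpha = 0 (fixed iteration count)")
  yo <- onehot(as.integer(y), config$n_classes)
  st <- mlp_state_init(config$hidden[1], config$hidden[2])
  fwd <- caps_forward(x, params, st, config, mode = mode,
                      class_weights = class_weights, y_onehot = yo,
                      keep_cache = TRUE)
  grads <- caps_backward(x, yo, fwd, params, config, class_weights)
  list(loss = fwd$loss, margin = fwd$margin, ce = fwd$ce, grads = grads)
}

# ---- AdamW with cosine-annealed learning rate ----------------------------

adamw_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adamw_step <- function(params, grads, opt, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + weight_decay * params[[nm]])
  }
  list(params = params, opt = opt)
}

cosine_lr <- function(lr, epoch, epochs)
  lr * 0.5 * (1 + cos(pi * (epoch - 1) / max(1, epochs)))

# ---- the fitting function ------------------------------------------------

#' Fit a capsule-network emotion classifier
#'
#' Trains the full network -- fully connected primary capsules, dynamic
#' routing with adaptive per-class iteration counts, class-capsule margin
#' loss, MLP head with class-weighted cross-entropy -- with AdamW and a
#' cosine-annealed learning rate. Features are standardized by
#' training-set statistics; optionally the training portion is
#' SMOTE-balanced, and a small stratified validation split drives the
#' per-epoch class-weight refresh.
#'
#' @param x numeric feature matrix (rows = samples, e.g. windows).
#' @param y class labels (factor or coercible to one).
#' @param n_primary,capsule_dim number and dimension of primary capsules
#'   (defaults 16 and 8).
#' @param r_base,alpha,rounding routing iteration base count (3), adaptive
#'   coefficient (1) and extra-iteration rounding mode.
#' @param routing_grad `"detached"` (couplings as non-differentiated control
#'   flow; default) or `"full"` (backprop through the unrolled loop;
#'   requires `alpha = 0`).
#' @param hidden MLP hidden layer sizes (default `c(128, 256)`).
#' @param leaky_slope,dropout,bn_momentum MLP head hyperparameters
#'   (defaults 0.2, 0.5, 0.05).
#' @param loss a [loss_config()].
#' @param lr,weight_decay,batch_size,epochs AdamW learning rate (1e-3),
#'   decoupled weight decay (1e-4), batch size (32) and epoch count
#'   (default 100).
#' @param val_fraction stratified fraction of the training data held out
#'   for the class-weight refresh (default 0.1; 0 disables the refresh).
#' @param smote balance classes in the training portion with
#'   [smote_oversample()] (default TRUE).
#' @param smote_k SMOTE neighbour count (default 5).
#' @param standardize center/scale features by training statistics
#'   (default TRUE).
#' @param seed optional integer seed making the fit fully reproducible.
#' @param verbose print per-epoch progress.
#' @return an object of class `capsnet` with elements `params`, `bn_state`,
#'   `config`, `classes`, `center`, `scale`, `class_weights`, `history`.
#' @seealso [predict.capsnet()], [capsnet_cv()], [evaluate()]
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(200, 0), 50), matrix(rnorm(200, 3), 50))
#' y <- rep(c("calm", "excited"), each = 50)
#' fit <- capsnet(x, y, epochs = 3, seed = 1, smote = FALSE)
#' table(predict(fit, x), y)
#' @export
capsnet <- function(x, y, n_primary = 16L, capsule_dim = 8L,
                    r_base = 3L, alpha = 1, rounding = "nearest",
                    routing_grad = c("detached", "full"),
                    hidden = c(128L, 256L), leaky_slope = 0.2, dropout = 0.5,
                    bn_momentum = 0.05, loss = loss_config(),
                    lr = 1e-3, weight_decay = 1e-4, batch_size = 32L,
                    epochs = 100L, val_fraction = 0.1,
                    smote = TRUE, smote_k = 5L, standardize = TRUE,
                    seed = NULL, verbose = FALSE) {
  routing_grad <- match.arg(routing_grad)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  yf <- factor(y)
  if (nlevels(yf) < 2L) stopf("need at least 2 classes")
  if (!is_count(batch_size, 2L)) stopf("batch_size must be >= 2")
  if (!is_count(epochs, 0L)) stopf("epochs must be a non-negative integer")
  if (nrow(x) != length(yf)) stopf("x and y sizes disagree")
  if (!is.null(seed)) set.seed(seed)
  C <- nlevels(yf)
  yi <- as.integer(yf) - 1L

  cfg <- list(n_features = ncol(x), n_primary = as.integer(n_primary),
              capsule_dim = as.integer(capsule_dim), n_classes = C,
              r_base = as.integer(r_base), alpha = alpha, rounding = rounding,
              routing_grad = routing_grad, hidden = as.integer(hidden),
              leaky_slope = leaky_slope, dropout = dropout,
              bn_momentum = bn_momentum, loss = loss,
              lr = lr, weight_decay = weight_decay,
              batch_size = as.integer(batch_size), epochs = as.integer(epochs),
              val_fraction = val_fraction)

  # stratified validation split for the class-weight refresh
  n <- nrow(x)
  val_idx <- integer(0)
  if (val_fraction > 0) {
    for (cl in seq_len(C) - 1L) {
      ic <- which(yi == cl)
      nv <- floor(val_fraction * length(ic))
      if (nv >= 1L && length(ic) - nv >= 2L)
        val_idx <- c(val_idx, sample(ic, nv))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)

  center <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  if (standardize) {
    center <- colMeans(x[tr_idx, , drop = FALSE])
    scl <- apply(x[tr_idx, , drop = FALSE], 2L, sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
  }
  xs <- sweep(sweep(x, 2L, center), 2L, scl, `/`)
  xtr <- xs[tr_idx, , drop = FALSE]; ytr <- yi[tr_idx]
  xval <- xs[val_idx, , drop = FALSE]; yval <- yi[val_idx]
  if (smote) {
    bal <- smote_oversample(xtr, ytr, k_neighbors = smote_k)
    xtr <- bal$x; ytr <- bal$y
  }

  params <- caps_params_init(ncol(x), cfg$n_primary, cfg$capsule_dim, C,
                             cfg$hidden[1], cfg$hidden[2])
  bn_state <- mlp_state_init(cfg$hidden[1], cfg$hidden[2])
  opt <- adamw_init(params)
  w <- rep(1, C)
  hist <- vector("list", epochs)

  for (ep in seq_len(epochs)) {
    lr_t <- cosine_lr(lr, ep, epochs)
    perm <- sample.int(nrow(xtr))
    nb <- max(1L, nrow(xtr) %/% batch_size)
    split_id <- rep(seq_len(nb), length.out = nrow(xtr))  # keeps batches >= 2
    batches <- split(perm, split_id)
    ep_loss <- 0; ep_hit <- 0
    for (b in batches) {
      xb <- xtr[b, , drop = FALSE]
      yo <- onehot(ytr[b], C)
      fwd <- caps_forward(xb, params, bn_state, cfg, mode = "train",
                          class_weights = w, y_onehot = yo, keep_cache = TRUE)
      if (!is.finite(fwd$loss))
        stopf("non-finite loss at epoch %d (lr %.3g); aborting", ep, lr_t)
      bn_state <- fwd$bn_state
      grads <- caps_backward(xb, yo, fwd, params, cfg, class_weights = w)
      st <- adamw_step(params, grads, opt, lr_t, weight_decay)
      params <- st$params; opt <- st$opt
      ep_loss <- ep_loss + fwd$loss * length(b)
      ep_hit <- ep_hit + sum(max.col(fwd$logits) - 1L == ytr[b])
    }
    row <- data.frame(epoch = ep, lr = lr_t,
                      train_loss = ep_loss / nrow(xtr),
                      train_acc = ep_hit / nrow(xtr),
                      val_loss = NA_real_, val_acc = NA_real_)
    if (length(val_idx)) {
      ev <- caps_forward(xval, params, bn_state, cfg, mode = "eval",
                         class_weights = w, y_onehot = onehot(yval, C))
      pred <- max.col(ev$logits) - 1L
      conf <- confusion_counts(yval, pred, C)
      w <- update_class_weights(conf, eps = loss$weight_eps, prev = w)
      row$val_loss <- ev$loss
      row$val_acc <- mean(pred == yval)
    }
    hist[[ep]] <- row
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  acc %.3f  val %.3f",
                      ep, lr_t, row$train_loss, row$train_acc, row$val_acc))
  }

  structure(list(params = params, bn_state = bn_state, config = cfg,
                 classes = levels(yf), center = center, scale = scl,
                 class_weights = w,
                 history = if (epochs) do.call(rbind, hist) else
                   data.frame(epoch = integer(0)),
                 call = match.call()),
            class = "capsnet")
}

# ---- prediction and methods ----------------------------------------------

#' Predict from a fitted capsule network
#'
#' @param object a fitted [capsnet()] model.
#' @param newdata feature matrix with the columns the model was trained on.
#' @param type `"class"` (factor of predicted labels), `"prob"` (softmax
#'   probabilities of the MLP head), `"logits"`, `"lengths"` (class-capsule
#'   lengths), `"capsules"` (the `(batch, dim, class)` capsule array) or
#'   `"coupling"` (routing coupling coefficients `(batch, m, C)`).
#' @param batch_size forward-pass chunk size.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.capsnet <- function(object, newdata,
                            type = c("class", "prob", "logits", "lengths",
                                     "capsules", "coupling"),
                            batch_size = 512L, ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (ncol(x) != object$config$n_features)
    stopf("newdata has %d features; the model expects %d",
          ncol(x), object$config$n_features)
  xs <- sweep(sweep(x, 2L, object$center), 2L, object$scale, `/`)
  chunks <- split(seq_len(nrow(xs)),
                  ceiling(seq_len(nrow(xs)) / batch_size))
  pieces <- lapply(chunks, function(idx) {
    fwd <- caps_forward(xs[idx, , drop = FALSE], object$params,
                        object$bn_state, object$config, mode = "eval")
    switch(type,
           class = ,
           prob = ,
           logits = fwd$logits,
           lengths = fwd$lengths,
           capsules = fwd$v,
           coupling = fwd$coupling)
  })
  if (type %in% c("capsules", "coupling")) {
    out <- array(0, c(nrow(xs), dim(pieces[[1]])[2], dim(pieces[[1]])[3]))
    at <- 0L
    for (p in pieces) {
      out[at + seq_len(dim(p)[1]), , ] <- p
      at <- at + dim(p)[1]
    }
    return(out)
  }
  res <- do.call(rbind, pieces)
  switch(type,
         logits = ,
         lengths = res,
         prob = exp(log_softmax(res)),
         class = factor(object$classes[max.col(res)],
                        levels = object$classes))
}

#' @export
print.capsnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<capsnet> %d features -> %d primary capsules (dim %d) -> %d classes\n",
              cfg$n_features, cfg$n_primary, cfg$capsule_dim, cfg$n_classes))
  cat(sprintf("  routing: %d base iterations, alpha = %g (%s gradients)\n",
              cfg$r_base, cfg$alpha, cfg$routing_grad))
  cat(sprintf("  MLP head %d-%d, dropout %.2f; loss: margin + %g * weighted CE\n",
              cfg$hidden[1], cfg$hidden[2], cfg$dropout, cfg$loss$lambda))
  if (nrow(x$history))
    cat(sprintf("  trained %d epochs; final train acc %.3f, val acc %s\n",
                nrow(x$history), tail(x$history$train_acc, 1),
                format(tail(x$history$val_acc, 1), digits = 3)))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.capsnet <- function(object, ...) {
  print(object)
  cat("\nClass weights (last refresh):\n")
  print(setNames(round(object$class_weights, 4), object$classes))
  if (nrow(object$history)) {
    cat("\nTraining history (last 5 epochs):\n")
    print(tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.capsnet <- function(object, ...) object$params

#' Plot training curves of a fitted capsule network
#'
#' @param x a fitted [capsnet()] model.
#' @param which `"loss"` or `"accuracy"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.capsnet <- function(x, which = c("loss", "accuracy"), ...) {
  which <- match.arg(which)
  h <- x$history
  if (!nrow(h)) stopf("model has no training history")
  cols <- if (which == "loss") c("train_loss", "val_loss") else
    c("train_acc", "val_acc")
  matplot(h$epoch, as.matrix(h[, cols]), type = "l", lty = 1,
          col = c("black", "firebrick"), xlab = "epoch", ylab = which, ...)
  legend("topright", legend = c("train", "validation"), lty = 1,
         col = c("black", "firebrick"), bty = "n")
  invisible(x)
}
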