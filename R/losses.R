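#' Loss configuration for the dual-loss objective
#'
#' @param m_plus true-class capsule-length threshold (default 0.9).
#' @param m_minus non-true-class threshold (default 0.1).
#' @param beta down-weight of the negative-class margin term (default 0.5).
#' @param lambda cross-entropy mixing weight in the total loss (default 0.1).
#' @param weight_eps smoothing constant of the class-weight update
#'   (default 1e-3).
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(m_plus = 0.9, m_minus = 0.1, beta = 0.5,
                        lambda = 0.1, weight_eps = 1e-3) {
  if (!(m_minus >= 0 && m_minus < m_plus && m_plus <= 1))
    stopf("need 0 <= m_minus < m_plus <= 1")
  if (beta < 0 || lambda < 0 || weight_eps <= 0)
    stopf("beta, lambda must be >= 0 and weight_eps > 0")
  structure(list(m_plus = m_plus, m_minus = m_minus, beta = beta,
                 lambda = lambda, weight_eps = weight_eps),
            class = "loss_config")
}

onehot <- function(y, C) {
  out <- matrix(0, length(y), C)
  out[cbind(seq_along(y), y + 1L)] <- 1
  out
}

#' Margin loss on class-capsule lengths
#'
#' Mean over the batch of
#' `sum_j [ y_j max(0, m_plus - l_j)^2 + beta (1 - y_j) max(0, l_j - m_minus)^2 ]`.
#'
#' @param lengths matrix `(batch, C)` of capsule lengths in `[0, 1]`.
#' @param y_onehot matrix `(batch, C)` one-hot labels.
#' @param cfg a [loss_config()].
#' @return scalar loss.
#' @export
margin_loss <- function(lengths, y_onehot, cfg = loss_config()) {
  if (is.null(dim(lengths))) lengths <- matrix(lengths, nrow = 1L)
  if (is.null(dim(y_onehot))) y_onehot <- matrix(y_onehot, nrow = 1L)
  pos <- pmax(0, cfg$m_plus - lengths)
  neg <- pmax(0, lengths - cfg$m_minus)
  mean(rowSums(y_onehot * pos^2 + cfg$beta * (1 - y_onehot) * neg^2))
}

margin_loss_vjp <- function(lengths, y_onehot, cfg) {
  B <- nrow(lengths)
  pos <- pmax(0, cfg$m_plus - lengths)
  neg <- pmax(0, lengths - cfg$m_minus)
  (-2 * y_onehot * pos + 2 * cfg$beta * (1 - y_onehot) * neg) / B
}

log_softmax <- function(z) {
  mx <- apply(z, 1L, max)
  zs <- z - mx
  zs - log(rowSums(exp(zs)))
}

#' Class-weighted cross-entropy over MLP logits
#'
#' `-(1/B) sum_i sum_j w_j y_ij log softmax(z_i)_j`; with uniform unit
#' weights this is the ordinary cross-entropy.
#'
#' @param logits matrix `(batch, C)`.
#' @param y_onehot matrix `(batch, C)` one-hot labels.
#' @param weights positive per-class weight vector (default all 1).
#' @return scalar loss.
#' @export
weighted_ce <- function(logits, y_onehot, weights = NULL) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  if (is.null(dim(y_onehot))) y_onehot <- matrix(y_onehot, nrow = 1L)
  C <- ncol(logits)
  if (is.null(weights)) weights <- rep(1, C)
  if (any(weights <= 0)) stopf("class weights must be positive")
  ls <- log_softmax(logits)
  -mean(rowSums(sweep(y_onehot * ls, 2L, weights, `*`)))
}

weighted_ce_vjp <- function(logits, y_onehot, weights = NULL) {
  B <- nrow(logits)
  C <- ncol(logits)
  if (is.null(weights)) weights <- rep(1, C)
  p <- exp(log_softmax(logits))
  wy <- as.vector(y_onehot %*% weights)       # weight of each row's true class
  (p - y_onehot) * wy / B
}

#' Validation-driven class-weight refresh
#'
#' `error_j = 1 - recall_j` on the validation confusion matrix;
#' `w_j = (error_j + eps) / (mean_k error_k + eps)`. A class absent from the
#' validation set keeps its previous weight.
#'
#' @param confusion `C x C` count matrix, rows = truth, columns = prediction.
#' @param eps smoothing constant (keeps weights defined and positive when
#'   all errors vanish).
#' @param prev previous weight vector (used for absent classes; default all
#'   1).
#' @return numeric weight vector of length `C`.
#' @export
update_class_weights <- function(confusion, eps = 1e-3, prev = NULL) {
  confusion <- as.matrix(confusion)
  C <- nrow(confusion)
  if (is.null(prev)) prev <- rep(1, C)
  support <- rowSums(confusion)
  present <- support > 0
  err <- rep(NA_real_, C)
  err[present] <- 1 - diag(confusion)[present] / support[present]
  mean_err <- mean(err[present])
  w <- prev
  w[present] <- (err[present] + eps) / (mean_err + eps)
  w
}

#' Total dual loss
#'
#' @param margin margin-loss value.
#' @param ce weighted cross-entropy value.
#' @param lambda mixing weight (default 0.1).
#' @return `margin + lambda * ce`.
#' @export
total_loss <- function(margin, ce, lambda = 0.1) margin + lambda * ce
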