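#' SMOTE oversampling to the majority-class count
#'
#' For each minority class, synthetic samples are convex combinations
#' `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)` and `x_nn` one of the `k`
#' nearest same-class neighbours (Euclidean distance), until every class
#' reaches the majority count. Intended for use inside training folds only.
#'
#' @param x numeric feature matrix.
#' @param y class labels (any type; returned unchanged in type).
#' @param k_neighbors neighbour count (default 5; capped at class size - 1).
#' @param seed optional integer seed.
#' @return list with the augmented `x`, `y` and a logical `synthetic`
#'   marker.
#' @export
smote_oversample <- function(x, y, k_neighbors = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(x)
  if (!is_count(k_neighbors)) stopf("k_neighbors must be a positive integer")
  counts <- table(y)
  target <- max(counts)
  new_x <- list(); new_y <- list()
  for (cl in names(counts)) {
    need <- target - counts[[cl]]
    if (need == 0) next
    idx <- which(y == cl)
    xc <- x[idx, , drop = FALSE]
    if (length(idx) == 1L) {
      warning(sprintf("class %s has a single sample; duplicating it", cl))
      syn <- xc[rep(1L, need), , drop = FALSE]
    } else {
      k <- min(k_neighbors, length(idx) - 1L)
      d <- as.matrix(dist(xc))
      diag(d) <- Inf
      nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
      base <- sample.int(length(idx), need, replace = TRUE)
      pick <- nn[cbind(base, sample.int(k, need, replace = TRUE))]
      u <- runif(need)
      syn <- xc[base, , drop = FALSE] +
        u * (xc[pick, , drop = FALSE] - xc[base, , drop = FALSE])
    }
    new_x[[cl]] <- syn
    new_y[[cl]] <- rep(y[idx[1L]], need)
  }
  if (!length(new_x))
    return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x))))
  xa <- rbind(x, do.call(rbind, new_x))
  ya <- c(y, unlist(new_y, use.names = FALSE))
  list(x = xa, y = ya,
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, nrow(xa) - nrow(x))))
}
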