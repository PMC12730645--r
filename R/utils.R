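`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# trailing rolling mean with expanding prefix: element i averages
# x[max(1, i - w + 1) .. i]; causal, no future leakage
rolling_mean_trailing <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n <= 1L) return(x)
  cs <- cumsum(x)
  i <- seq_len(n)
  lo <- pmax(i - w, 0L)
  width <- i - lo
  (cs - c(0, cs)[lo + 1L]) / width
}
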