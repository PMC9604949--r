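#' @keywords internal
"_PACKAGE"

## Internal argument checks ---------------------------------------------------

stop_if <- function(cond, ..., call. = FALSE) {
  if (isTRUE(cond)) stop(..., call. = call.)
}

assert_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) &&
    (if (positive) x > 0 else x >= 0)
  stop_if(!ok, sprintf("`%s` must be a %s integer", name,
                       if (positive) "positive" else "non-negative"))
  as.integer(x)
}

assert_prob <- function(x, name) {
  ok <- is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  stop_if(!ok, sprintf("`%s` must lie in [0, 1]", name))
  as.numeric(x)
}

## Sample (n-1) standard deviation per row of a matrix, without apply().
row_sds <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  sqrt(pmax(rowSums((m - mu)^2), 0) / (n - 1))
}

## seed helper: derive a per-task 32-bit seed from a base seed
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483587L
}
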