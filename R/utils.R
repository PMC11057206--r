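#' Haldane map function
#'
#' Convert a genetic distance in Morgans to a recombination fraction under
#' the Haldane (no-interference, Poisson crossover) model, and back.
#'
#' @param d genetic distance in Morgans (non-negative).
#' @return `haldane()` returns recombination fractions in \[0, 0.5);
#'   `haldane_inverse()` returns distances in Morgans.
#' @examples
#' haldane(0.5)            # ~0.316
#' haldane_inverse(0.001)  # ~0.001 for small r
#' @export
haldane <- function(d) {
  stopifnot(all(d >= 0))
  (1 - exp(-2 * d)) / 2
}

#' @param r recombination fraction in \[0, 0.5).
#' @rdname haldane
#' @export
haldane_inverse <- function(r) {
  stopifnot(all(r >= 0), all(r < 0.5))
  -log(1 - 2 * r) / 2
}

# Set the RNG seed only when one is supplied; NULL leaves the current
# RNG state untouched so callers can manage streams themselves.
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# Draw independent sub-seeds (for per-trait simulations) from the current
# RNG stream; kept below .Machine$integer.max.
draw_seeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

# Unbiased sample variance of the columns of a matrix.
col_vars <- function(x) {
  n <- nrow(x)
  stopifnot(n >= 2)
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

row_vars <- function(x) {
  n <- ncol(x)
  stopifnot(n >= 2)
  mu <- rowMeans(x)
  (rowSums(x^2) - n * mu^2) / (n - 1)
}
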