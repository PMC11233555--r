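#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a session seed
#'
#' All randomness in a simulated session flows from a single integer seed;
#' independent components (behavior, kernels, spikes, shuffles, ...) draw from
#' sub-seeds derived deterministically from it, so that changing one component
#' does not perturb the random stream of another.
#'
#' @param seed integer master seed.
#' @param component character tag naming the consumer.
#' @return An integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(component))
  h <- 0
  for (ch in utf8ToInt(component)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 2654435 + h) %% 2147483647)
}

# wrap angles into [-pi, pi)
wrap_angle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

# truncated, unit-sum Gaussian kernel with sd sigma_bins (in bins)
gaussian_kernel <- function(sigma_bins, half_width = 4) {
  stopifnot(sigma_bins > 0)
  r <- max(1L, ceiling(half_width * sigma_bins))
  k <- exp(-0.5 * ((-r:r) / sigma_bins)^2)
  k / sum(k)
}

# centered moving-window convolution of a vector with a unit-sum kernel,
# renormalizing at the edges so mass is preserved
conv_same <- function(x, kernel) {
  n <- length(x)
  r <- (length(kernel) - 1L) / 2L
  xp <- c(rep(0, r), x, rep(0, r))
  out <- stats::filter(xp, kernel, method = "convolution", sides = 2)
  out <- as.numeric(out[(r + 1L):(r + n)])
  out
}

# Poisson log-likelihood of counts y under per-bin means mu
poisson_loglik <- function(y, mu) {
  mu <- pmax(mu, 1e-300)
  sum(y * log(mu) - mu - lgamma(y + 1))
}

# fold assignment for k-fold CV over units of `ids` (e.g. trial labels),
# deterministic given the ids
fold_ids <- function(ids, k) {
  u <- unique(ids)
  f <- rep_len(seq_len(k), length(u))
  f[match(ids, u)]
}

# cross-validated R^2 against the test-set mean (can be negative)
cv_r2 <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop("zero-variance response in R^2 computation")
  1 - sum((y - yhat)^2) / sst
}
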