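# Population decoding: unit matching, lasso cross-validation, the
# noise-correlation shuffle, and the nonlinear network decoder.

# apply the tuning-preserving shuffle separately within each context
shuffle_by_context <- function(counts, y, context, seed = 2) {
  out <- unclass(counts)
  for (ctx in unique(context)) {
    b <- context == ctx
    out[, b] <- shuffle_noise_correlations(
      unclass(counts)[, b, drop = FALSE], y[b], n_shuffles = 1,
      seed = seed + match(ctx, unique(context)))[[1]]
  }
  structure(out, bin_width = attr(counts, "bin_width") %||% 0.006,
            class = "spike_counts")
}

test_that("population matching is exact, deterministic, and rate-targeted", {
  set.seed(30)
  rates <- matrix(rexp(40 * 100, 1 / 6), 40, 100)
  expect_equal(match_population(rates[1:10, ]), 1:10)
  expect_error(match_population(rates[1:5, ]), "fewer than")
  sel <- match_population(rates, n = 10, reference = rep(6, 10))
  expect_identical(sel, match_population(rates, n = 10, reference = rep(6, 10)))
  # closer to the 6 Hz reference than random draws are on average
  d_sel <- abs(mean(rowMeans(rates)[sel]) - 6)
  d_rand <- mean(replicate(1000, abs(mean(rowMeans(rates)[sample(40, 10)]) - 6)))
  expect_lt(d_sel, d_rand)
})

test_that("lasso decoding is near-perfect on a realizable target and at chance on noise", {
  set.seed(31)
  n <- 4000
  rates <- matrix(rnorm(10 * n, 10, 2), 10, n)
  trial <- rep(1:40, each = 100)
  w <- rnorm(10)
  y <- drop(crossprod(rates, w))
  res <- lasso_cv_decode(rates, y, trial, "within")
  expect_gte(res$mean_r2, 0.99)
  expect_equal(res$folds, 5L)
  nulls <- vapply(1:4, function(s) {
    y0 <- rnorm(n)
    lasso_cv_decode(rates, y0, trial, "within", seed = s)$mean_r2
  }, numeric(1))
  expect_lte(mean(nulls), 0)
  expect_error(lasso_cv_decode(rates, y, rep(1:5, each = 800), "within"),
               ">= 10 trials")
  expect_error(lasso_cv_decode(rates, y, trial, "cross"), "context")
})

test_that("the shuffle preserves per-neuron per-bin histograms exactly and kills cross-neuron correlation", {
  set.seed(32)
  n <- 10000
  y <- runif(n, 0, 100)
  shared <- rnorm(n)
  counts <- rbind(rpois(n, exp(0.5 + shared)), rpois(n, exp(0.5 + shared)))
  r0 <- cor(counts[1, ], counts[2, ])
  expect_gt(r0, 0.3)
  sh <- shuffle_noise_correlations(counts, y, n_bins = 15, n_shuffles = 3,
                                   seed = 7)
  expect_length(sh, 3)
  g <- cut(y, quantile(y, seq(0, 1, length.out = 16)), include.lowest = TRUE)
  for (u in 1:2) for (lev in levels(g)) {
    expect_identical(sort(sh[[1]][u, g == lev]), sort(counts[u, g == lev]))
  }
  # within-bin cross-neuron correlation collapses
  r_within <- mean(vapply(levels(g), function(lev)
    cor(sh[[1]][1, g == lev], sh[[1]][2, g == lev]), numeric(1)))
  expect_lt(abs(r_within), 0.05)
  # distinct sub-seeds give distinct shuffles
  expect_false(identical(sh[[1]], sh[[2]]))
})

test_that("single-point bins pass through the shuffle as the identity", {
  counts <- rbind(1:6, 6:1)
  y <- 1:6   # six bins, one point each with n_bins >= 6
  sh <- shuffle_noise_correlations(counts, y, n_bins = 6, n_shuffles = 1)
  expect_identical(sh[[1]], counts)
})

test_that("conditioning on a second variable preserves its within-bin structure", {
  set.seed(33)
  n <- 6000
  y <- runif(n); v <- runif(n)
  counts <- rbind(rpois(n, 1 + y), rpois(n, 1 + v))
  sh <- shuffle_noise_correlations(counts, y, n_bins = 5, n_shuffles = 1,
                                   second_variable = v, seed = 3)[[1]]
  gy <- cut(y, quantile(y, seq(0, 1, length.out = 6)), include.lowest = TRUE)
  gv <- cut(v, quantile(v, seq(0, 1, length.out = 6)), include.lowest = TRUE)
  joint <- interaction(gy, gv)
  for (lev in sample(levels(joint), 5)) {
    idx <- joint == lev
    if (sum(idx) < 2) next
    expect_identical(sort(sh[2, idx]), sort(counts[2, idx]))
  }
})

test_that("read-out regimes dissociate: stable transfers, translated does not", {
  rp <- simulate_readout_population("stable", seed = 8)
  rates <- estimate_rates(rp$counts)
  hi <- rp$context == "high"
  wi <- lasso_cv_decode(rates[, hi], rp$y[hi], rp$trial[hi], "within")
  cr <- lasso_cv_decode(rates, rp$y, rp$trial, "cross", context = rp$context)
  expect_gt(cr$mean_r2, 0)
  expect_lt(abs(cr$mean_r2 - wi$mean_r2), 0.15)
  rp2 <- simulate_readout_population("translated", seed = 8)
  rates2 <- estimate_rates(rp2$counts)
  cr2 <- lasso_cv_decode(rates2, rp2$y, rp2$trial, "cross",
                         context = rp2$context)
  expect_lt(cr2$mean_r2, cr$mean_r2 - 0.3)
})

test_that("destroying co-fluctuations abolishes coupling-dependent cross-context decoding", {
  rp <- simulate_readout_population("coupled", seed = 8)
  hi <- rp$context == "high"
  rates <- estimate_rates(rp$counts)
  cr <- lasso_cv_decode(rates, rp$y, rp$trial, "cross", context = rp$context)
  expect_gt(cr$mean_r2, 0)
  sh <- shuffle_by_context(rp$counts, rp$y, rp$context)
  rs <- estimate_rates(sh)
  wi_sh <- lasso_cv_decode(rs[, hi], rp$y[hi], rp$trial[hi], "within")
  cr_sh <- lasso_cv_decode(rs, rp$y, rp$trial, "cross", context = rp$context)
  expect_gt(wi_sh$mean_r2, 0)
  expect_lte(cr_sh$mean_r2, 0)
})

test_that("the network decoder is reproducible and tracks the lasso on linear ground truth", {
  set.seed(34)
  n <- 3000
  rates <- matrix(rexp(10 * n, 1 / 5), 10, n)
  trial <- rep(1:30, each = 100)
  y <- drop(crossprod(rates, rnorm(10, 0, 0.5)))
  a1 <- ann_decode(rates, y, trial, "within", epochs = 150, seed = 3)
  a2 <- ann_decode(rates, y, trial, "within", epochs = 150, seed = 3)
  expect_identical(a1$r2, a2$r2)
  l1 <- lasso_cv_decode(rates, y, trial, "within")
  expect_lt(abs(a1$mean_r2 - l1$mean_r2), 0.05)
  expect_error(ann_decode(rates, rep(1, n), trial), "zero-variance")
})

test_that("the network decoder beats the lasso on a quadratic read-out", {
  set.seed(35)
  n <- 4000
  rates <- matrix(rexp(10 * n, 1 / 5), 10, n)
  trial <- rep(1:40, each = 100)
  w <- rnorm(10, 0, 0.3)
  lin <- drop(crossprod(rates, w))
  y <- (lin - mean(lin))^2 / sd(lin)
  a <- ann_decode(rates, y, trial, "within", epochs = 200, seed = 4)
  l <- lasso_cv_decode(rates, y, trial, "within")
  expect_gt(a$mean_r2, l$mean_r2)
})
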