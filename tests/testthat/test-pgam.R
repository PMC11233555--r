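# Core fitter: objective arithmetic, closed forms, optimizer contract,
# smoothness selection, fit scores, inclusion test, tuning curves.

simple_design <- function(n = 3) {
  # intercept-only design with a dummy penalized block of zeros is awkward;
  # use a tiny covariate block instead when a penalty is needed
  build_design(data.frame(x = seq(0, 1, length.out = n)),
               trial = rep(1L, n))
}

test_that("penalized log-likelihood matches hand-computed Poisson arithmetic", {
  n <- 3
  y <- c(0, 1, 2)
  d <- list(X = matrix(1, n, 1), blocks = list(), S = list(), trial = NULL,
            n = n)
  class(d) <- "pgam_design"
  # intercept 0 -> rate 1 per bin: sum(-1 + y*0 - log(y!))
  expect_equal(penalized_loglik(0, numeric(0), d, y),
               sum(-1 + y * 0 - lgamma(y + 1)))
  expect_error(penalized_loglik(0, numeric(0), d, c(-1, 0, 1)), "nonnegative")
})

test_that("penalty term is linear in lambda with slope -0.5 t(b) S b", {
  set.seed(3)
  d <- simple_design(50)
  beta <- rnorm(ncol(d$X))
  y <- rpois(50, 1)
  l0 <- penalized_loglik(beta, c(x = 1), d, y)
  l1 <- penalized_loglik(beta, c(x = 2), d, y)
  bS <- beta[d$blocks$x$cols]
  expect_equal(l1 - l0, -0.5 * 1 * drop(crossprod(bS, d$S$x %*% bS)),
               tolerance = 1e-10)
  expect_equal(penalized_loglik(beta, c(x = 0), d, y),
               sum(dpois(y, exp(drop(d$X %*% beta)), log = TRUE)))
})

test_that("intercept-only fit equals the closed-form Poisson MLE", {
  set.seed(4)
  y <- rpois(500, 3.7)
  d <- list(X = matrix(1, 500, 1, dimnames = list(NULL, "(Intercept)")),
            blocks = list(), S = list(), trial = NULL, n = 500)
  class(d) <- "pgam_design"
  f <- fit_beta(d, y, numeric(0))
  expect_equal(unname(f$beta), log(mean(y)), tolerance = 1e-8)
  expect_true(f$converged)
})

test_that("optimizer meets its gradient contract and recovers a known tuning curve", {
  set.seed(5)
  n <- 20000
  x <- runif(n, 0, 10)
  truth <- function(v) 0.8 * sin(v) - 0.3 * v / 10
  y <- rpois(n, exp(0.5 + truth(x)))
  d <- build_design(data.frame(x = x), trial = rep(1:40, each = 500))
  f <- fit_beta(d, y, 1)
  expect_lt(f$grad_norm, 1e-6 * (1 + max(abs(f$beta))))
  expect_true(isSymmetric(f$vcov, tol = 1e-8))
  expect_gte(min(eigen(f$vcov, symmetric = TRUE, only.values = TRUE)$values), 0)
  grid <- seq(0.2, 9.8, length.out = 100)
  sp <- d$blocks$x$spec
  B <- build_basis(sp, grid) %*% d$blocks$x$transform
  est <- drop(B %*% f$beta[d$blocks$x$cols])
  tr <- truth(grid)
  expect_gt(cor(est, tr - mean(tr)), 0.95)
})

test_that("an all-zero count series with penalty yields a finite fit and near-zero rate", {
  d <- simple_design(200)
  f <- suppressWarnings(fit_beta(d, rep(0L, 200), 1, max_iter = 30L))
  expect_true(all(is.finite(f$beta)))
  expect_lt(max(exp(drop(d$X %*% f$beta))), 1e-3)
})

test_that("extreme smoothing drives the fitted curve to its linear null space", {
  set.seed(6)
  n <- 20000
  x <- runif(n, 0, 10)
  y <- rpois(n, exp(0.3 + 0.6 * sin(x)))
  d <- build_design(data.frame(x = x), trial = rep(1:40, each = 500))
  f <- fit_beta(d, y, 1e8)
  grid <- seq(1, 9, length.out = 50)
  B <- build_basis(d$blocks$x$spec, grid) %*% d$blocks$x$transform
  est <- drop(B %*% f$beta[d$blocks$x$cols])
  curvature <- diff(diff(est))
  expect_lt(max(abs(curvature)), 1e-4)
})

test_that("cross-validated smoothness selection prefers smoother fits for flat truth", {
  set.seed(7)
  n <- 12000
  x <- runif(n, 0, 10)
  trial <- rep(1:40, each = 300)
  grid <- 10^seq(-2, 4, length.out = 8)
  d <- build_design(data.frame(x = x), trial = trial)
  y_flat <- rpois(n, exp(0.5))
  lam_flat <- select_lambda(d, y_flat, grid = grid)
  expect_equal(unname(attr(lam_flat, "multiplier")["signal"]), max(grid))
  y_curved <- rpois(n, exp(0.5 + 1.5 * sin(1.5 * x)))
  lam_curv <- select_lambda(d, y_curved, grid = grid)
  expect_lt(unname(attr(lam_curv, "multiplier")["signal"]), unname(attr(lam_flat, "multiplier")["signal"]))
  # degenerate cases
  expect_equal(unname(attr(select_lambda(d, y_flat, grid = 3.14, folds = 2),
                           "multiplier")["signal"]), 3.14)
  expect_error(select_lambda(d, y_flat, grid = grid, folds = 1), "folds")
  expect_error(select_lambda(d, y_flat, grid = numeric(0)), "empty")
})

test_that("pseudo-R2 reproduces its defining cases and a hand-computed value", {
  expect_equal(pseudo_r2(-10, -25, -25), 0)   # model = null
  expect_equal(pseudo_r2(-10, -10, -25), 1)   # model = saturated
  y <- c(0, 1, 2); mu_hat <- c(0.5, 1.0, 1.5); mu_bar <- rep(1, 3)
  ll <- function(m) sum(dpois(y, m, log = TRUE))
  ll_y <- sum(dpois(y, pmax(y, 1e-12), log = TRUE))
  expect_equal(pseudo_r2(ll_y, ll(mu_hat), ll(mu_bar)),
               1 - (ll_y - ll(mu_hat)) / (ll_y - ll(mu_bar)))
  expect_error(pseudo_r2(-10, -12, -10), "null")
})

test_that("smoothed R2 is 1 for a perfect prediction and 0 for a constant one", {
  set.seed(8)
  y <- rpois(3000, exp(0.4 + sin(seq_len(3000) / 80)))
  k <- spikecoupling:::gaussian_kernel(0.020 / 0.006)
  ys <- spikecoupling:::conv_same(y, k)
  expect_equal(smoothed_r2(y, ys), 1, tolerance = 1e-10)
  expect_error(smoothed_r2(rep(0, 100), rep(1, 100)), "variance")
  # independently coded correlation on a known modulated series
  mu <- exp(0.4 + sin(seq_len(3000) / 80))
  expect_equal(smoothed_r2(y, mu), cor(ys, mu)^2, tolerance = 1e-12)
})

test_that("inclusion test returns 1 for a zero block and is powered for real structure", {
  s <- small_session()
  cov <- s$beh$covariates
  fit <- pgam(s$counts[1, ], covariates = cov$channels[, "lin_vel", drop = FALSE],
              history = TRUE, trial = cov$trial, lambda = 10, seed = 1)
  expect_lt(fit$p_values[["lin_vel"]], 1e-4)
  fit0 <- fit
  fit0$coefficients[fit0$blocks$lin_vel$cols] <- 0
  expect_equal(inclusion_test(fit0, "lin_vel"), 1)
  expect_error(inclusion_test(fit, "nope"), "no such predictor")
})

test_that("tuning curves carry valid confidence bands and respect their domain", {
  s <- small_session()
  cov <- s$beh$covariates
  fit <- pgam(s$counts[1, ], covariates = cov$channels[, "lin_vel", drop = FALSE],
              history = TRUE, trial = cov$trial, lambda = 10, seed = 1)
  tc <- tuning_curve(fit, "lin_vel")
  expect_true(all(tc$lower <= tc$estimate & tc$estimate <= tc$upper))
  expect_error(tuning_curve(fit, "lin_vel", grid = c(-5, 10)), "domain")
  # a zeroed block gives a flat curve at 0 with a symmetric band
  fit0 <- fit
  fit0$coefficients[fit0$blocks$lin_vel$cols] <- 0
  tc0 <- tuning_curve(fit0, "lin_vel")
  expect_equal(tc0$estimate, rep(0, nrow(tc0)))
  expect_equal(tc0$upper, -tc0$lower, tolerance = 1e-10)
})

test_that("pgam object methods are coherent (print, coef, predict, residuals, simulate)", {
  s <- small_session()
  cov <- s$beh$covariates
  fit <- pgam(s$counts[1, ], covariates = cov$channels[, "lin_vel", drop = FALSE],
              history = TRUE, trial = cov$trial, lambda = 10, seed = 1)
  expect_output(print(fit), "pseudo-R2")
  expect_equal(length(coef(fit, "lin_vel")), length(fit$blocks$lin_vel$cols))
  mu <- predict(fit)
  expect_equal(predict(fit, type = "link"), log(mu))
  # predicting on the training inputs reproduces the fitted values
  mu2 <- predict(fit, newdata = list(
    covariates = cov$channels[, "lin_vel", drop = FALSE],
    history = s$counts[1, ], trial = cov$trial))
  expect_equal(unname(mu2), unname(mu), tolerance = 1e-10)
  r <- residuals(fit, "pearson")
  expect_equal(unname(r), unname((fit$y - mu) / sqrt(mu)), tolerance = 1e-10)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(length(mu), 2))
  expect_true(all(sim >= 0))
})

test_that("refitting data simulated from the fitted class gives positive held-out pseudo-R2", {
  s <- small_session()
  cov <- s$beh$covariates
  fit <- pgam(s$counts[1, ], covariates = cov$channels[, "lin_vel", drop = FALSE],
              history = FALSE, trial = cov$trial, lambda = 10, seed = 1)
  set.seed(99)
  y_sim <- rpois(length(fit$fitted), fit$fitted)
  refit <- pgam(y_sim, covariates = cov$channels[, "lin_vel", drop = FALSE],
                history = FALSE, trial = cov$trial, lambda = 10, seed = 2)
  expect_gt(unname(refit$pseudo_r2["test"]), 0)
  expect_false(refit$excluded)
})
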