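# Rate estimation, time-warping, condition-averaged PCA, and the d-prime
# permutation test, each checked against direct numerical oracles.

test_that("Gaussian rate estimation preserves spike mass and handles constants", {
  dt <- 0.006
  z <- matrix(0, 1, 2000)
  expect_equal(estimate_rates(z, bin_width = dt), z)
  ones <- matrix(1, 1, 2000)
  r <- estimate_rates(ones, bin_width = dt)
  mid <- 500:1500
  expect_equal(unname(r[1, mid]), rep(1 / dt, length(mid)), tolerance = 1e-9)
  # a single spike spreads into a bump of unit integral
  one <- matrix(0, 1, 2001); one[1, 1000] <- 1
  rb <- estimate_rates(one, bin_width = dt)
  expect_equal(sum(rb) * dt, 1, tolerance = 1e-6)
  expect_error(estimate_rates(ones, sigma = 0), "positive")
})

test_that("time-warping preserves endpoints, constants, and identity length", {
  x <- matrix(seq(2, 8, length.out = 50), 1)  # linear ramp
  w <- timewarp(x, 50)
  expect_equal(w, x, tolerance = 1e-12)
  w2 <- timewarp(x, 101)
  expect_equal(w2[1, 1], 2); expect_equal(w2[1, 101], 8)
  expect_equal(max(abs(diff(diff(w2[1, ])))), 0, tolerance = 1e-10)
  const <- matrix(3, 2, 17)
  expect_true(all(timewarp(const, 40) == 3))
  expect_error(timewarp(matrix(1, 1, 1), 10), "2 bins")
})

test_that("condition-averaged PCA matches an SVD oracle and its own contracts", {
  set.seed(20)
  N <- 6; T_ <- 30
  warped <- lapply(1:12, function(i) matrix(rnorm(N * T_), N, T_) + i / 6)
  cat_lab <- rep(c("a", "b", "c", "d"), each = 3)
  lt <- condition_average_pca(warped, cat_lab)
  # orthonormal axes
  expect_equal(unname(crossprod(lt$rotation)), diag(ncol(lt$rotation)),
               tolerance = 1e-10)
  expect_true(all(diff(lt$explained) <= 1e-12))
  expect_lte(sum(lt$explained), 1 + 1e-12)
  # SVD oracle on the stacked centered matrix
  stacked <- do.call(rbind, lapply(lt$category_means, t))
  Xc <- scale(stacked, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  expect_equal(lt$explained, sv$d^2 / sum(sv$d^2), tolerance = 1e-8)
  recon <- sv$u %*% diag(sv$d) %*% t(sv$v)
  expect_equal(recon, Xc, tolerance = 1e-8, ignore_attr = TRUE)
  # projections reproduce Xc %*% rotation blockwise
  proj_all <- do.call(rbind, lt$projections)
  expect_equal(unname(proj_all), unname(Xc %*% lt$rotation), tolerance = 1e-8)
})

test_that("a rank-one population loads entirely on the first component", {
  base <- sin(seq(0, 3, length.out = 40))
  warped <- lapply(1:6, function(i) outer(c(1, 2, 3), base) * (1 + i / 10))
  lt <- condition_average_pca(warped, rep(c("a", "b"), each = 3))
  expect_equal(lt$explained[1], 1, tolerance = 1e-10)
  expect_error(condition_average_pca(list(matrix(1, 1, 5)), "a"), "2 units")
})

test_that("d-prime is near zero for a shared generator and grows with a translation", {
  set.seed(21)
  N <- 8; T_ <- 25; n_tr <- 120
  sites <- matrix(runif(18, -100, 100), 9, 2)
  site <- sample(1:9, n_tr, replace = TRUE)
  density <- rep(c("high", "low"), length.out = n_tr)
  base <- matrix(rnorm(N * T_), N, T_)
  mk_trial <- function(i, offset = 0) {
    site_eff <- outer(rnorm(N, sd = 0.2) + sites[site[i], 1] / 100, rep(1, T_))
    base + site_eff + matrix(rnorm(N * T_, sd = 0.5), N, T_) + offset
  }
  warped0 <- lapply(1:n_tr, function(i) mk_trial(i))
  dp0 <- trajectory_dprime(warped0, sites[site, ], density, n_perm = 400,
                           match_radius = 10, max_dims = 6, seed = 3)
  expect_true(all(abs(dp0$dprime) < 0.25))
  expect_false(dp0$low_confidence)
  # determinism
  dp0b <- trajectory_dprime(warped0, sites[site, ], density, n_perm = 400,
                            match_radius = 10, max_dims = 6, seed = 3)
  expect_identical(dp0$dprime, dp0b$dprime)
  # translated low-density dynamics separate, more so for larger offsets
  mk_set <- function(delta) lapply(1:n_tr, function(i)
    mk_trial(i, offset = if (density[i] == "low") delta else 0))
  dp1 <- trajectory_dprime(mk_set(1), sites[site, ], density, n_perm = 400,
                           match_radius = 10, max_dims = 6, seed = 3)
  dp2 <- trajectory_dprime(mk_set(2), sites[site, ], density, n_perm = 400,
                           match_radius = 10, max_dims = 6, seed = 3)
  expect_gt(dp1$dprime[3], 1)
  expect_gt(dp2$dprime[3], dp1$dprime[3])
})

test_that("warp_session segments rewarded trials and matches trial counts", {
  s <- small_session()
  ws <- warp_session(s$counts, s$beh$covariates, s$beh$trials, T_out = 20)
  expect_equal(length(ws$warped), sum(s$beh$trials$rewarded))
  expect_true(all(vapply(ws$warped, ncol, integer(1)) == 20))
  expect_true(all(vapply(ws$warped, nrow, integer(1)) == nrow(s$counts)))
  expect_equal(nrow(ws$target), length(ws$warped))
})
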