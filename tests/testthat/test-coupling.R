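test_that("coupling strength is the L2 norm and homogeneous of degree one", {
  expect_equal(coupling_strength(c(0, 0, 0)), 0)
  expect_equal(coupling_strength(c(3, 4)), 5)
  b <- c(0.2, -0.5, 0.1)
  expect_equal(coupling_strength(2 * b), 2 * coupling_strength(b))
  expect_error(coupling_strength(numeric(0)), "empty")
  expect_equal(coupling_kernel_integral(c(1, -1), bin_width = 0.006), 0.012)
})

test_that("kernel stability is the Pearson correlation with its edge cases", {
  k <- c(0.5, 0.3, 0.1, -0.1, 0, 0)
  expect_equal(coupling_stability(k, k), 1)
  expect_equal(coupling_stability(k, -k), -1)
  expect_warning(r <- coupling_stability(rep(1, 6), k), "zero-variance")
  expect_true(is.na(r))
  expect_error(coupling_stability(k, k[1:3]), "lag grids")
  # independent smooth kernels are uncorrelated on average
  set.seed(10)
  rs <- replicate(1000, {
    a <- spikecoupling:::smooth_coefs(6, 1)
    b <- spikecoupling:::smooth_coefs(6, 1)
    cor(a, b)
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("stability references order correctly on partially remapped couplings", {
  ck <- simulate_coupling_estimates(n_sessions = 4, n_pairs = 40,
                                    remap_frac = 0.5, est_noise_sd = 0.35,
                                    seed = 3)
  cc <- chance_ceiling(ck, n_chance = 800, seed = 4)
  expect_gt(median(cc$ceiling), median(cc$cross))
  expect_gt(median(cc$cross), median(cc$chance))
  expect_lt(wilcox.test(cc$ceiling, cc$cross)$p.value, 0.01)
  expect_lt(wilcox.test(cc$cross, cc$chance)$p.value, 0.01)
})

test_that("stable couplings look like ceiling; fully remapped ones look like chance", {
  stable <- simulate_coupling_estimates(n_sessions = 3, n_pairs = 40,
                                        remap_frac = 0, est_noise_sd = 0.35,
                                        seed = 5)
  cc <- chance_ceiling(stable, n_chance = 500, seed = 6)
  expect_gt(wilcox.test(cc$cross, cc$ceiling)$p.value, 0.05)
  remap <- simulate_coupling_estimates(n_sessions = 3, n_pairs = 40,
                                       remap_frac = 1, est_noise_sd = 0.35,
                                       seed = 7)
  cc2 <- chance_ceiling(remap, n_chance = 500, seed = 8)
  expect_gt(wilcox.test(cc2$cross, cc2$chance)$p.value, 0.05)
  one <- simulate_coupling_estimates(n_sessions = 1, n_pairs = 10, seed = 9)
  expect_error(chance_ceiling(one), "2 sessions")
})

test_that("coupling probability vs distance recovers flat, degenerate, and monotone shapes", {
  set.seed(11)
  n <- 4000
  d <- runif(n, 100, 2000)
  # distance-independent significance at rate 0.2
  rec <- data.frame(distance = d, significant = runif(n) < 0.2)
  fit <- coupling_probability_vs_distance(rec)
  grid <- seq(150, 1900, length.out = 30)
  p <- fit$predict(grid)
  se <- sqrt(0.2 * 0.8 / n) * 4
  expect_true(all(abs(p - 0.2) < 0.2 * 0.5))
  expect_lt(abs(fit$p_at - 0.2), 0.05)
  # all significant: degenerate prediction of 1 everywhere
  rec1 <- data.frame(distance = d[1:50], significant = TRUE)
  expect_warning(f1 <- coupling_probability_vs_distance(rec1), "degenerate")
  expect_equal(f1$predict(c(100, 500, 1500)), c(1, 1, 1))
  # monotone-decreasing truth recovered as a decreasing curve
  p_true <- plogis(2 - d / 400)
  rec2 <- data.frame(distance = d, significant = runif(n) < p_true)
  f2 <- coupling_probability_vs_distance(rec2)
  pg <- f2$predict(grid)
  expect_true(all(diff(pg) < 0.02))
  expect_gt(cor(pg, plogis(2 - grid / 400)), 0.98)
})

test_that("evoked STA is null for independent units and recovers an injected 1 Hz effect", {
  set.seed(12)
  n <- 200000
  dt <- 0.006
  snd <- rpois(n, 5 * dt)
  rcv <- rpois(n, 10 * dt)
  ev <- evoked_sta(snd, rcv, window = 1:6, bin_width = dt)
  # each lag's STA has Monte-Carlo sd ~ sqrt(rate/ (n_spk dt)); peak of 6 lags
  n_spk <- sum(snd)
  se <- sqrt(10 / (n_spk * dt))
  expect_lt(abs(as.numeric(ev)), 4 * se)
  # inject +1 Hz for lags 1..2 (12 ms) after each sender spike
  rate <- rep(10, n)
  idx <- which(snd > 0)
  for (l in 1:2) rate[pmin(idx + l, n)] <- rate[pmin(idx + l, n)] + 1
  rcv2 <- rpois(n, rate * dt)
  ev2 <- evoked_sta(snd, rcv2, window = 1:2, bin_width = dt)
  expect_lt(abs(as.numeric(ev2) - 1), 4 * se)
  expect_error(evoked_sta(snd, snd), "self-pairs")
  expect_error(evoked_sta(rep(0, 100), rpois(100, 1)), "no spikes")
})

test_that("tuning gain and stability apply the stability threshold", {
  x <- sin(seq(0, 2 * pi, length.out = 50))
  r <- tuning_gain_and_stability(x, x)
  expect_equal(r$stability, 1)
  expect_equal(r$gain, 1, tolerance = 1e-10)
  r2 <- tuning_gain_and_stability(x, 0.8 * x)
  expect_equal(r2$gain, 0.8, tolerance = 1e-10)
  expect_false(r2$excluded)
  set.seed(13)
  noisy <- 0.2 * x + rnorm(50)
  while (cor(x, noisy) > 0.4) noisy <- 0.2 * x + rnorm(50)
  r3 <- tuning_gain_and_stability(x, noisy)
  expect_true(r3$excluded)
  expect_true(is.na(r3$gain))
  expect_warning(tuning_gain_and_stability(rep(1, 50), x), "zero-variance")
})

test_that("session filter enforces both retention criteria", {
  s <- data.frame(session = 1:4, n_coupled = c(4, 10, 10, 6),
                  pseudo_r2 = c(0.05, 0.005, 0.05, 0.02))
  kept <- session_filter(s)
  expect_equal(kept$session, c(3L, 4L))
})

test_that("coupling records expose strength, significance and kernels from fits", {
  s <- coupled_session()
  cov <- s$beh$covariates
  counts <- unclass(s$counts)
  fits <- list()
  for (u in 1:2) {
    fits[[paste0("unit", u)]] <- pgam(
      counts[u, ], covariates = cov$channels[, "lin_vel", drop = FALSE],
      coupling = t(counts[setdiff(1:2, u), , drop = FALSE]),
      history = TRUE, trial = cov$trial, lambda = 10, seed = u)
  }
  rec <- coupling_records(fits, units = attr(s$counts, "units"))
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$strength >= 0))
  k <- attr(rec, "kernels")
  expect_equal(ncol(k), 6L)
  # the injected 1 -> 2 kernel is detected as significant
  inj <- rec[rec$sender == "unit1" & rec$receiver == "unit2", ]
  expect_true(inj$significant)
})
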