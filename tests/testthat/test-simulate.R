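# Generator contracts: determinism, stated task ranges, endpoint-gain
# construction, kinematic consistency, manipulation algebra, and the Poisson
# spiking engine checked against histogram and spike-triggered-average
# oracles.

test_that("identical config and seed reproduce the session bitwise", {
  cfg <- session_config(n_trials = 15L, seed = 42L)
  a <- simulate_behavior(cfg)
  b <- simulate_behavior(cfg)
  expect_identical(a$trials, b$trials)
  expect_identical(a$covariates$channels, b$covariates$channels)
  pc <- population_config(n_units = 3L, coupling_density = 0.3)
  expect_identical(sample_ground_truth(pc, seed = 5),
                   sample_ground_truth(pc, seed = 5))
  s1 <- simulate_spikes(sample_ground_truth(pc, seed = 5), a$covariates, seed = 9)
  s2 <- simulate_spikes(sample_ground_truth(pc, seed = 5), b$covariates, seed = 9)
  expect_identical(unclass(s1), unclass(s2))
})

test_that("targets respect the configured radial and angular ranges", {
  cfg <- session_config(n_trials = 400L, seed = 1L)
  tr <- simulate_behavior(cfg, trajectories = FALSE)$trials
  expect_true(all(tr$target_r >= 1 & tr$target_r <= 4))
  expect_true(all(tr$target_theta >= -45 & tr$target_theta <= 45))
  # both contexts appear at roughly the configured mix
  expect_gt(mean(tr$density == "high"), 0.35)
  expect_lt(mean(tr$density == "high"), 0.65)
})

test_that("a noiseless unit-gain agent stops exactly on target", {
  cfg <- session_config(n_trials = 40L,
                        behavior_gain = c(radial = 1, angular = 1),
                        endpoint_noise_sd = c(high = 0, low = 0),
                        abort_prob = 0, no_stop_prob = 0, seed = 2L)
  tr <- simulate_behavior(cfg)$trials
  expect_equal(tr$endpoint_r, tr$target_r, tolerance = 1e-8)
  expect_equal(tr$endpoint_theta, tr$target_theta, tolerance = 1e-6)
  g <- suppressWarnings(behavioral_gain(filter_trials(tr), "radial"))
  expect_equal(g$gain, 1, tolerance = 1e-8)
  expect_equal(g$intercept, 0, tolerance = 1e-8)
})

test_that("endpoint regression recovers a configured gain within its CI", {
  cfg <- session_config(n_trials = 2000L,
                        behavior_gain = c(radial = 0.85, angular = 0.85),
                        endpoint_noise_sd = c(high = 10, low = 10),
                        abort_prob = 0, no_stop_prob = 0, seed = 3L)
  tr <- simulate_behavior(cfg, trajectories = FALSE)$trials
  # independent OLS oracle on the generated endpoints
  ols <- lm(endpoint_r ~ target_r, data = tr)
  ci <- confint(ols)["target_r", ]
  expect_gt(0.85, ci[1]); expect_lt(0.85, ci[2])
  g <- behavioral_gain(filter_trials(tr), "radial")
  expect_equal(g$gain, unname(coef(ols)["target_r"]), tolerance = 1e-10)
})

test_that("integrated linear velocity equals the recorded displacement", {
  s <- small_session()
  cov <- s$beh$covariates
  dt <- cov$bin_width
  for (id in s$beh$trials$trial_id[1:10]) {
    path <- sum(cov$channels$lin_vel[cov$trial == id] / 100) * dt
    expect_equal(path, s$beh$trials$displacement[s$beh$trials$trial_id == id],
                 tolerance = 2 * dt * 2)  # one bin at max speed
  }
  expect_true(all(abs(cov$channels$lin_vel) <= s$cfg$max_linear_speed + 1e-9))
  expect_true(all(cov$channels$lfp_theta >= -pi & cov$channels$lfp_theta < pi))
  expect_true(all(unlist(cov$events) %in% 0:1))
})

test_that("invalid session configurations are rejected", {
  expect_error(simulate_behavior(session_config(n_trials = 0L)), "empty")
  expect_error(session_config(behavior_gain = c(radial = -1, angular = 1)),
               "invalid config")
  expect_error(session_config(density_mix = 1.5), "density_mix")
  expect_error(session_config(target_radial_range = c(4, 1)), "ordered")
})

test_that("coupling-graph density draws the expected number of directed kernels", {
  pc0 <- population_config(n_units = 6L, coupling_density = 0)
  expect_length(sample_ground_truth(pc0, seed = 1)$coupling, 0)
  pc <- population_config(n_units = 20L, coupling_density = 0.2)
  counts <- vapply(1:15, function(s)
    length(sample_ground_truth(pc, seed = s)$coupling), numeric(1))
  n_pairs <- 20 * 19
  ci <- qbinom(c(0.025, 0.975), n_pairs * 15, 0.2)
  expect_gte(sum(counts), ci[1])
  expect_lte(sum(counts), ci[2])
  expect_error(population_config(n_units = 0L), "empty")
})

test_that("context manipulations obey their algebraic contracts", {
  pc <- population_config(n_units = 5L, coupling_density = 0.4)
  pop <- sample_ground_truth(pc, seed = 3)
  expect_identical(apply_context_manipulation(pop, context_manipulation("none")),
                   pop)
  # coupling gain: every kernel norm exactly doubled, tuning untouched
  m2 <- apply_context_manipulation(pop, context_manipulation("coupling_gain",
                                                             magnitude = 2))
  for (i in seq_along(pop$coupling))
    expect_equal(coupling_strength(m2$coupling[[i]]$beta),
                 2 * coupling_strength(pop$coupling[[i]]$beta))
  expect_identical(m2$tuning, pop$tuning)
  # tuning gain: coupling kernels bitwise unchanged
  mt <- apply_context_manipulation(pop, context_manipulation("tuning_gain",
                                                             magnitude = 0.7))
  expect_identical(mt$coupling, pop$coupling)
  expect_equal(mt$tuning[[1]][[1]]$beta, 0.7 * pop$tuning[[1]][[1]]$beta)
  # strength-preserving remap: norms within 1e-10 relative, shapes decorrelate
  mr <- apply_context_manipulation(pop, context_manipulation(
    "coupling_remap", preserve_strength = TRUE, seed = 8))
  ratios <- vapply(seq_along(pop$coupling), function(i)
    coupling_strength(mr$coupling[[i]]$beta) /
      coupling_strength(pop$coupling[[i]]$beta), numeric(1))
  expect_true(all(abs(ratios - 1) < 1e-10))
  cors <- vapply(seq_along(pop$coupling), function(i) {
    ka <- drop(build_basis(pop$coupling[[i]]$spec) %*% pop$coupling[[i]]$beta)
    kb <- drop(build_basis(mr$coupling[[i]]$spec) %*% mr$coupling[[i]]$beta)
    cor(ka, kb)
  }, numeric(1))
  expect_lt(mean(abs(cors)), 0.8)
  expect_error(apply_context_manipulation(pop, context_manipulation(
    "tuning_gain", magnitude = 1, target_units = 99L)), "unknown target")
  expect_error(context_manipulation("coupling_gain", magnitude = 0),
               "magnitude")
})

test_that("with all kernels silenced the spiking engine is homogeneous Poisson at the baseline rate", {
  cfg <- session_config(n_trials = 60L, seed = 4L)
  cov <- simulate_behavior(cfg)$covariates
  pc <- population_config(n_units = 1L, covariates = list(),
                          baseline_range = c(5, 5))
  pop <- sample_ground_truth(pc, seed = 1)
  pop$history[[1]] <- NULL
  counts <- simulate_spikes(pop, cov, seed = 6)
  n <- ncol(counts)
  rate_hat <- sum(counts) / (n * cfg$bin_width)
  se <- sqrt(5 / (n * cfg$bin_width))
  expect_lt(abs(rate_hat - 5), 3 * se)
  # generative consistency: mean of exp(model log-rate) matches the mean count
  expect_lt(abs(mean(counts) - 5 * cfg$bin_width), 3 * se * cfg$bin_width)
})

test_that("empirical tuning of simulated spikes matches exp(baseline + kernel)", {
  cfg <- session_config(n_trials = 150L, seed = 5L)
  cov <- simulate_behavior(cfg)$covariates
  pc <- population_config(n_units = 1L, covariates = list(lin_vel = c(0, 200)),
                          baseline_range = c(10, 10), tuning_sd = 0.5)
  pop <- sample_ground_truth(pc, seed = 2)
  pop$history[[1]] <- NULL
  counts <- simulate_spikes(pop, cov, seed = 3)
  v <- cov$channels$lin_vel
  br <- seq(0, 200, by = 25)
  bin <- cut(v, br, include.lowest = TRUE)
  emp <- tapply(counts[1, ], bin, mean) / cfg$bin_width
  mid <- (br[-1] + br[-length(br)]) / 2
  tk <- pop$tuning[[1]]$lin_vel
  th <- exp(pop$baseline[1] + drop(build_basis(tk$spec, mid) %*% tk$beta))
  n_per <- tapply(counts[1, ], bin, length)
  se <- sqrt(th / (n_per * cfg$bin_width))
  ok <- n_per > 200
  expect_true(all(abs(emp[ok] - th[ok]) < 4 * se[ok]))
})

test_that("an injected excitatory kernel leaves a causal footprint in the receiver STA", {
  s <- coupled_session()
  snd <- s$counts[1, ]; rcv <- s$counts[2, ]
  sta_post <- evoked_sta(snd, rcv, window = 1:6, bin_width = 0.006)
  expect_gt(as.numeric(sta_post), 1)   # strong excitatory kernel
  # acausal side is flat: peak in a pre-spike window is comparatively tiny
  sta_pre <- attr(evoked_sta(snd, rcv, window = -12:-7,
                             baseline_window = -24:-19), "sta")
  base <- attr(evoked_sta(snd, rcv, window = 1:6), "baseline")
  expect_lt(max(abs(sta_pre - base)), as.numeric(sta_post) / 2)
})

test_that("spiking engine validates its inputs", {
  cfg <- session_config(n_trials = 5L, seed = 6L)
  cov <- simulate_behavior(cfg)$covariates
  pc <- population_config(n_units = 1L,
                          covariates = list(not_a_channel = c(0, 1)))
  pop <- sample_ground_truth(pc, seed = 1)
  expect_error(simulate_spikes(pop, cov, seed = 1), "missing")
})
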