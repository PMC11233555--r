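# Reproduction studies: self-contained simulate-and-recover experiments, one
# per headline property of the analysis pipeline. Each takes a seed, runs the
# full path (generator -> fit -> analysis) at a desk-scale problem size, and
# returns the measured quantities. The vignette documents the study designs
# and the problem sizes.

#' Tuning-function recovery study
#'
#' Simulates a population of units with strong smooth tuning to three
#' continuous covariates (several-fold rate modulation, as in cortical
#' recordings), fits the encoding model per unit with cross-validated
#' smoothness, and correlates each fitted tuning curve with its ground truth
#' over the central 90 percent of the covariate's sampled range.
#'
#' @param seed integer seed.
#' @param n_units number of units (default 15).
#' @param n_trials session length (default 140 trials, about 8e4 6-ms bins).
#' @return A list with `r` (per unit x covariate correlations), `frac_above`
#'   (fraction with r > 0.9), `n_bins`.
#' @export
study_tuning_recovery <- function(seed = 1L, n_units = 15L, n_trials = 140L) {
  cfg <- session_config(n_trials = n_trials,
                        seed = derive_seed(seed, "tune_session"))
  beh <- simulate_behavior(cfg)
  covs <- list(lin_vel = c(0, 200), ang_vel = c(-90, 90),
               dist_target = c(0, 500))
  pc <- population_config(n_units = n_units, coupling_density = 0,
                          tuning_sd = 0.5, baseline_range = c(5, 20),
                          covariates = covs)
  pop <- sample_ground_truth(pc, seed = derive_seed(seed, "tune_pop"))
  counts <- simulate_spikes(pop, beh$covariates,
                            seed = derive_seed(seed, "tune_spikes"))
  cov <- beh$covariates
  ch <- cov$channels[, names(covs)]
  rs <- c()
  for (u in seq_len(n_units)) {
    fit <- pgam(counts[u, ], covariates = ch, history = TRUE,
                trial = cov$trial, seed = u)
    for (nm in names(covs)) {
      tk <- pop$tuning[[u]][[nm]]
      qs <- stats::quantile(ch[[nm]], c(0.05, 0.95))
      grid <- seq(qs[1], qs[2], length.out = 80)
      rs <- c(rs, stats::cor(tuning_curve(fit, nm, grid)$estimate,
                             drop(build_basis(tk$spec, grid) %*% tk$beta)))
    }
  }
  list(r = rs, frac_above = mean(rs > 0.9), n_bins = length(cov$time))
}

#' Coupling-filter recovery and false-positive study
#'
#' For several independent populations of 10 units, injects 20 directed
#' coupling kernels (two per receiver, balanced excitation/inhibition),
#' simulates spiking, fits the fully coupled encoding model per unit, and
#' measures: the correlation between fitted and true kernels over the lag
#' window; the detection rate of true kernels and the rejection rate of the
#' 70 null pairs per population at the p < 0.001 inclusion threshold; and the
#' fraction of units whose held-out pseudo-R-squared improves when coupling
#' filters are included (coupled vs uncoupled refit).
#'
#' @param seed integer seed.
#' @param n_pops number of independent populations (3 gives 210 null pairs).
#' @param n_trials session length per population.
#' @return A list with `kernel_r`, `mean_kernel_r`, `null_p`, `n_null`,
#'   `null_rejections`, `true_detected`, `n_true`, `coupled_better_frac`,
#'   and per-unit pseudo-R-squared vectors.
#' @export
study_coupling_recovery <- function(seed = 1L, n_pops = 3L, n_trials = 90L) {
  kernel_r <- c(); null_p <- c(); true_p <- c()
  pr_coupled <- c(); pr_uncoupled <- c()
  for (p in seq_len(n_pops)) {
    sseed <- derive_seed(seed, paste0("couple_pop_", p))
    cfg <- session_config(n_trials = n_trials, seed = sseed)
    beh <- simulate_behavior(cfg)
    cov <- beh$covariates
    pc <- population_config(n_units = 10L, coupling_density = 0,
                            tuning_sd = 0.4, baseline_range = c(5, 15),
                            covariates = list(lin_vel = c(0, 200)))
    pop <- inject_coupling(sample_ground_truth(pc, seed = sseed + 1L),
                           n_per_receiver = 2L, strength = c(0.5, 0.9),
                           seed = sseed + 2L)
    counts <- simulate_spikes(pop, cov, seed = sseed + 3L)
    lsc <- NULL
    fits <- list()
    for (u in 1:10) {
      fit <- pgam(counts[u, ], covariates = cov$channels[, "lin_vel",
                                                         drop = FALSE],
                  coupling = t(counts[-u, , drop = FALSE]), history = TRUE,
                  trial = cov$trial, lambda_scale = lsc, seed = u)
      if (is.null(lsc)) lsc <- fit$lambda_scale
      fits[[paste0("unit", u)]] <- fit
      pr_coupled <- c(pr_coupled, fit$pseudo_r2["test"])
      fit0 <- pgam(counts[u, ], covariates = cov$channels[, "lin_vel",
                                                          drop = FALSE],
                   history = TRUE, trial = cov$trial, lambda_scale = lsc,
                   seed = u)
      pr_uncoupled <- c(pr_uncoupled, fit0$pseudo_r2["test"])
    }
    rec <- coupling_records(fits, units = attr(counts, "units"))
    true_keys <- vapply(pop$coupling, function(cp)
      paste0("unit", cp$sender, " unit", cp$receiver), character(1))
    is_true <- paste(rec$sender, rec$receiver) %in% true_keys
    null_p <- c(null_p, rec$p_value[!is_true])
    true_p <- c(true_p, rec$p_value[is_true])
    k <- attr(rec, "kernels")
    for (i in which(is_true)) {
      cp <- pop$coupling[[match(paste(rec$sender[i], rec$receiver[i]),
                                true_keys)]]
      kernel_r <- c(kernel_r,
                    stats::cor(k[i, ], drop(build_basis(cp$spec) %*% cp$beta)))
    }
  }
  list(kernel_r = kernel_r, mean_kernel_r = mean(kernel_r),
       null_p = null_p, n_null = length(null_p),
       null_rejections = sum(null_p < 0.001),
       true_detected = sum(true_p < 0.001), n_true = length(true_p),
       coupled_better_frac = mean(pr_coupled > pr_uncoupled),
       pseudo_r2_coupled = unname(pr_coupled),
       pseudo_r2_uncoupled = unname(pr_uncoupled))
}

#' Inclusion-test calibration study
#'
#' Fits the encoding model to constant-rate Poisson counts with one smooth
#' covariate that is independent of the spiking, many times, and reports the
#' empirical false-inclusion rate at a nominal level.
#'
#' @param seed integer seed.
#' @param n_fits number of null fits (default 200).
#' @param n_bins bins per fit.
#' @param alpha nominal level (default 0.05).
#' @return A list with `p_values`, `fpr`, `ci` (exact binomial 95 percent
#'   interval around `alpha` for `n_fits`).
#' @export
study_inclusion_calibration <- function(seed = 1L, n_fits = 200L,
                                        n_bins = 4000L, alpha = 0.05) {
  trial <- rep(seq_len(10L), each = n_bins / 10L)
  lsc <- NULL
  pvals <- numeric(n_fits)
  for (i in seq_len(n_fits)) {
    set.seed(derive_seed(seed, paste0("calib_", i)))
    y <- stats::rpois(n_bins, 0.06)
    x <- as.numeric(stats::filter(stats::rnorm(n_bins), 0.95,
                                  method = "recursive"))
    fit <- pgam(y, covariates = data.frame(x = x), history = FALSE,
                trial = trial, lambda_scale = lsc, seed = i)
    if (is.null(lsc)) lsc <- fit$lambda_scale
    pvals[i] <- fit$p_values[["x"]]
  }
  list(p_values = pvals, fpr = mean(pvals < alpha),
       ci = stats::qbinom(c(0.025, 0.975), n_fits, alpha) / n_fits)
}

#' Noise-correlation shuffle contract study
#'
#' Two strongly co-fluctuating Poisson units conditioned on a continuous
#' variable: verifies the per-neuron per-bin count multisets are preserved
#' exactly and measures the mean within-bin cross-neuron correlation before
#' and after shuffling.
#'
#' @param seed integer seed.
#' @param n_bins number of time samples (default 1e4).
#' @return A list with `histograms_identical`, `r_before`, `r_after`.
#' @export
study_shuffle_contract <- function(seed = 1L, n_bins = 10000L) {
  set.seed(derive_seed(seed, "shuffle_contract"))
  y <- stats::runif(n_bins, 0, 100)
  shared <- stats::rnorm(n_bins)
  counts <- rbind(stats::rpois(n_bins, exp(0.3 + 0.8 * shared)),
                  stats::rpois(n_bins, exp(0.3 + 0.8 * shared)))
  sh <- shuffle_noise_correlations(counts, y, n_bins = 15, n_shuffles = 1,
                                   seed = derive_seed(seed, "shuffle"))[[1]]
  br <- unique(stats::quantile(y, seq(0, 1, length.out = 16)))
  g <- cut(y, br, include.lowest = TRUE)
  hist_ok <- all(vapply(levels(g), function(lev) {
    idx <- g == lev
    identical(sort(sh[1, idx]), sort(counts[1, idx])) &&
      identical(sort(sh[2, idx]), sort(counts[2, idx]))
  }, logical(1)))
  within_r <- function(m) mean(vapply(levels(g), function(lev)
    stats::cor(m[1, g == lev], m[2, g == lev]), numeric(1)), na.rm = TRUE)
  list(histograms_identical = hist_ok, r_before = within_r(counts),
       r_after = within_r(sh))
}

#' Cross-context decoding dissociation study
#'
#' Runs the three read-out regimes of [simulate_readout_population()] through
#' the full decoding path (rate estimation, within- and cross-context lasso,
#' tuning-preserving shuffle applied within context) and returns the
#' cross-validated R-squared of each condition.
#'
#' @param seed integer seed.
#' @return A list with per-regime `within`, `cross`, and for the coupled
#'   regime `within_shuffled`, `cross_shuffled`.
#' @export
study_decoding_dissociation <- function(seed = 1L) {
  out <- list()
  for (kind in c("stable", "translated", "coupled")) {
    rp <- simulate_readout_population(kind, seed = derive_seed(seed, kind))
    rates <- estimate_rates(rp$counts)
    hi <- rp$context == "high"
    wi <- lasso_cv_decode(rates[, hi, drop = FALSE], rp$y[hi], rp$trial[hi],
                          "within", seed = seed)
    cr <- lasso_cv_decode(rates, rp$y, rp$trial, "cross",
                          context = rp$context, seed = seed)
    res <- list(within = wi$mean_r2, cross = cr$mean_r2)
    if (kind == "coupled") {
      sh <- shuffle_within_context(rp$counts, rp$y, rp$context,
                                   n_shuffles = 1,
                                   seed = derive_seed(seed, "dissoc_shuffle"))[[1]]
      rs <- estimate_rates(structure(sh, bin_width = 0.006,
                                     class = "spike_counts"))
      res$within_shuffled <- lasso_cv_decode(rs[, hi, drop = FALSE],
                                             rp$y[hi], rp$trial[hi],
                                             "within", seed = seed)$mean_r2
      res$cross_shuffled <- lasso_cv_decode(rs, rp$y, rp$trial, "cross",
                                            context = rp$context,
                                            seed = seed)$mean_r2
    }
    out[[kind]] <- res
  }
  out
}

#' Latent-trajectory d-prime study
#'
#' Simulates sessions whose two density contexts share one generative model
#' (and identical behavioral statistics, so contexts are exchangeable), runs
#' the d-prime permutation test per session, and averages d-prime per
#' retained-dimension count across sessions; then repeats with the
#' low-density population activity translated by a fixed rate offset.
#'
#' @param seed integer seed.
#' @param n_sessions sessions to average over (default 4).
#' @param n_trials trials per session (default 600, matching the scale of a
#'   recording session).
#' @param offset translation in spikes/s for the alternative condition.
#' @return A list with `dprime_null`, `dprime_translated` (mean per
#'   dimension count 1..10), and the per-session matrices.
#' @export
study_dprime <- function(seed = 1L, n_sessions = 4L, n_trials = 600L,
                         offset = 5) {
  null_m <- NULL; tran_m <- NULL
  for (s in seq_len(n_sessions)) {
    sseed <- derive_seed(seed, paste0("dprime_", s))
    cfg <- session_config(n_trials = n_trials, n_target_sites = 9L,
                          endpoint_noise_sd = c(high = 20, low = 20),
                          seed = sseed)
    pc <- population_config(n_units = 10L, coupling_density = 0,
                            baseline_range = c(5, 20), tuning_sd = 0.5,
                            covariates = list(lin_vel = c(0, 200),
                                              dist_target = c(0, 500)))
    pop <- sample_ground_truth(pc, seed = sseed + 1L)
    sim <- simulate_session(cfg, pop)
    ws <- warp_session(sim$counts, sim$covariates, sim$trials, T_out = 50L)
    dp0 <- trajectory_dprime(ws$warped, ws$target, ws$density,
                             n_perm = 1000L, match_radius = 10,
                             max_dims = 10L, seed = sseed + 2L)
    warped_t <- ws$warped
    for (i in which(ws$density == "low"))
      warped_t[[i]] <- warped_t[[i]] + offset
    dp1 <- trajectory_dprime(warped_t, ws$target, ws$density,
                             n_perm = 1000L, match_radius = 10,
                             max_dims = 10L, seed = sseed + 2L)
    null_m <- rbind(null_m, dp0$dprime)
    tran_m <- rbind(tran_m, dp1$dprime)
  }
  list(dprime_null = colMeans(null_m), dprime_translated = colMeans(tran_m),
       per_session_null = null_m, per_session_translated = tran_m)
}

#' Coupling-stability reference-ordering study
#'
#' Partially remapped synthetic coupling estimates across sessions: the
#' cross-context stability distribution should sit between the odd/even-trial
#' ceiling and the cross-session chance distribution, with both gaps
#' significant by rank-sum test.
#'
#' @param seed integer seed.
#' @param remap_frac fraction of remapped pairs (default 0.5).
#' @return A list with the three median correlations and the two rank-sum
#'   p-values, plus the `stability_summary`.
#' @export
study_stability_references <- function(seed = 1L, remap_frac = 0.5) {
  ck <- simulate_coupling_estimates(n_sessions = 4L, n_pairs = 40L,
                                    remap_frac = remap_frac,
                                    est_noise_sd = 0.35,
                                    seed = derive_seed(seed, "stabref"))
  cc <- chance_ceiling(ck, n_chance = 800L,
                       seed = derive_seed(seed, "stabref_chance"))
  list(median_ceiling = stats::median(cc$ceiling),
       median_cross = stats::median(cc$cross),
       median_chance = stats::median(cc$chance),
       p_ceiling_vs_cross = stats::wilcox.test(cc$ceiling, cc$cross)$p.value,
       p_cross_vs_chance = stats::wilcox.test(cc$cross, cc$chance)$p.value,
       summary = cc)
}

#' Coupling strength/stability dissociation study
#'
#' Per session: a 6-unit population with a balanced injected coupling graph;
#' the low-density context either doubles every coupling kernel
#' (gain modulation) or redraws kernel shapes at preserved strength (remap).
#' Encoding models are refit separately per context and the session-mean
#' fitted strength ratio (low/high) and mean kernel-space stability r over
#' the injected pairs are averaged across sessions.
#'
#' @param seed integer seed.
#' @param n_sessions sessions per manipulation (default 3).
#' @param n_trials trials per session (default 250).
#' @return A list with `gain = c(ratio, stability)` and
#'   `remap = c(ratio, stability)` (cross-session means) plus per-session
#'   values.
#' @export
study_strength_stability <- function(seed = 1L, n_sessions = 3L,
                                     n_trials = 250L) {
  run_one <- function(manip, sseed) {
    cfg <- session_config(n_trials = n_trials, seed = sseed)
    beh <- simulate_behavior(cfg)
    cov <- beh$covariates
    pc <- population_config(n_units = 6L, coupling_density = 0,
                            tuning_sd = 0.4, baseline_range = c(8, 18),
                            covariates = list(lin_vel = c(0, 200)))
    pop_hi <- inject_coupling(sample_ground_truth(pc, seed = sseed + 1L),
                              n_per_receiver = 2L, strength = c(0.3, 0.5),
                              excitatory_frac = 0.5, seed = sseed + 2L)
    pop_lo <- apply_context_manipulation(pop_hi, manip)
    hi_ids <- beh$trials$trial_id[beh$trials$density == "high"]
    hi <- cov$trial %in% hi_ids
    counts <- matrix(0L, 6L, length(cov$time))
    counts[, hi] <- unclass(simulate_spikes(
      pop_hi, subset_covariates(cov, hi), seed = sseed + 3L))
    counts[, !hi] <- unclass(simulate_spikes(
      pop_lo, subset_covariates(cov, !hi), seed = sseed + 4L))
    rownames(counts) <- paste0("unit", 1:6)
    lsc <- NULL
    fits <- list(high = list(), low = list())
    for (ctx in c("high", "low")) {
      b <- if (ctx == "high") hi else !hi
      for (u in 1:6) {
        f <- pgam(counts[u, b],
                  covariates = cov$channels[b, "lin_vel", drop = FALSE],
                  coupling = t(counts[-u, b, drop = FALSE]), history = TRUE,
                  trial = cov$trial[b], lambda_scale = lsc, seed = u)
        if (is.null(lsc)) lsc <- f$lambda_scale
        fits[[ctx]][[paste0("unit", u)]] <- f
      }
    }
    rec_hi <- coupling_records(fits$high, condition = "high")
    rec_lo <- coupling_records(fits$low, condition = "low")
    m <- match(paste(rec_hi$sender, rec_hi$receiver),
               paste(rec_lo$sender, rec_lo$receiver))
    true_keys <- vapply(pop_hi$coupling, function(cp)
      paste0("unit", cp$sender, " unit", cp$receiver), character(1))
    it <- paste(rec_hi$sender, rec_hi$receiver) %in% true_keys
    k_hi <- attr(rec_hi, "kernels"); k_lo <- attr(rec_lo, "kernels")
    stab <- vapply(which(it), function(i)
      stats::cor(k_hi[i, ], k_lo[m[i], ]), numeric(1))
    c(ratio = mean(rec_lo$strength[m][it]) / mean(rec_hi$strength[it]),
      stability = mean(stab))
  }
  res <- list()
  for (kind in c("gain", "remap")) {
    manip <- if (kind == "gain")
      context_manipulation("coupling_gain", magnitude = 2)
    else context_manipulation("coupling_remap", preserve_strength = TRUE,
                              seed = derive_seed(seed, "ss_remap"))
    per <- t(vapply(seq_len(n_sessions), function(s)
      run_one(manip, derive_seed(seed, paste0("ss_", kind, "_", s))),
      numeric(2)))
    res[[kind]] <- colMeans(per)
    res[[paste0(kind, "_sessions")]] <- per
  }
  res
}

#' Behavioral-pipeline study
#'
#' Many simulated sessions with radial gain 0.85 and context-asymmetric
#' endpoint noise (high-density 20 cm, low-density 30 cm): per session and
#' context, trials are filtered, the endpoint gain is estimated by
#' regression, and the endpoint SEM is computed; gains should be unbiased on
#' average and the endpoint SEM larger in the noisier (low-density) context
#' in nearly every session.
#'
#' @param seed integer seed.
#' @param n_sessions number of sessions (default 100).
#' @param n_trials trials per session (default 1000, matching the scale of a
#'   recording session).
#' @return A list with per-session gain and SEM vectors and their summaries.
#' @export
study_behavior_pipeline <- function(seed = 1L, n_sessions = 100L,
                                    n_trials = 1000L) {
  gain_h <- gain_l <- sem_h <- sem_l <- numeric(n_sessions)
  for (s in seq_len(n_sessions)) {
    cfg <- session_config(n_trials = n_trials,
                          behavior_gain = c(radial = 0.85, angular = 0.80),
                          endpoint_noise_sd = c(high = 20, low = 30),
                          seed = derive_seed(seed, paste0("beh_", s)))
    tr <- filter_trials(simulate_behavior(cfg, trajectories = FALSE)$trials)
    hi <- tr[tr$density == "high", ]; lo <- tr[tr$density == "low", ]
    gain_h[s] <- behavioral_gain(hi, "radial")$gain
    gain_l[s] <- behavioral_gain(lo, "radial")$gain
    sem_h[s] <- endpoint_variability(hi)
    sem_l[s] <- endpoint_variability(lo)
  }
  list(gain_high = gain_h, gain_low = gain_l,
       mean_gain_high = mean(gain_h), mean_gain_low = mean(gain_l),
       sem_high = sem_h, sem_low = sem_l,
       frac_sem_ordered = mean(sem_l > sem_h))
}
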