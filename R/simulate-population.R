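# Ground-truth populations and Poisson spike generation. Units carry a
# baseline log-rate, B-spline tuning kernels over task covariates, optional
# event-response kernels, a strictly causal spike-history kernel, and directed
# strictly causal coupling kernels; spiking is sampled bin-sequentially so
# coupling and history terms only ever see already-sampled past counts.

#' Configuration of a ground-truth population
#'
#' @param n_units number of units.
#' @param area area label attached to every unit.
#' @param covariates named list of covariate value ranges the units are tuned
#'   to, e.g. `list(lin_vel = c(0, 200))`.
#' @param tuning_sd sd of the (smooth random) tuning coefficients, in log-rate
#'   units.
#' @param baseline_range baseline firing-rate range in Hz.
#' @param coupling_density probability that each ordered unit pair carries a
#'   coupling kernel.
#' @param coupling_strength range of coupling-kernel coefficient norms.
#' @param coupling_window,history_window causal lag windows in bins.
#' @param history_peak magnitude of the (suppressive) spike-history kernel at
#'   lag 1, in log-rate units.
#' @param event_names event trains the units respond to (default none).
#' @param event_sd sd of event-kernel coefficients.
#' @param electrode_pitch electrode grid pitch in micrometers.
#' @param clip log-rate clipping bound (natural log) preventing runaway
#'   excitatory loops.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_units = 10L, area = "A",
                              covariates = list(lin_vel = c(0, 200),
                                                dist_target = c(0, 450)),
                              tuning_sd = 0.35, baseline_range = c(3, 12),
                              coupling_density = 0,
                              coupling_strength = c(0.4, 0.8),
                              coupling_window = 6L, history_window = 6L,
                              history_peak = 1.0, event_names = character(0),
                              event_sd = 0.2, electrode_pitch = 400,
                              clip = 7) {
  if (n_units < 1L) stop("empty population")
  if (coupling_density < 0 || coupling_density > 1)
    stop("coupling_density must be in [0,1]")
  structure(as.list(environment()), class = "population_config")
}

# smooth random coefficient vector: white noise passed through a short
# moving average, centered, scaled to a target sd
smooth_coefs <- function(d, sd_target) {
  raw <- stats::rnorm(d + 2L)
  sm <- (raw[1:d] + raw[2:(d + 1L)] + raw[3:(d + 2L)]) / 3
  sm <- sm - mean(sm)
  s <- stats::sd(sm)
  if (s == 0) sm else sm * sd_target / s
}

# coefficients representing a target kernel shape on a lag basis
kernel_coefs <- function(spec, values) {
  B <- build_basis(spec, seq(spec$domain[1], spec$domain[2]))
  qr.solve(B, values)
}

#' Sample a ground-truth population
#'
#' Draws per-unit baselines, smooth random tuning kernels, a suppressive
#' spike-history kernel, optional event kernels, and directed coupling kernels
#' on random ordered pairs. Reproducible given the seed.
#'
#' @param config a [population_config()].
#' @param seed integer seed.
#' @return An object of class `ground_truth_population` with elements `units`
#'   (metadata incl. electrode coordinates), `baseline` (log Hz), `tuning`,
#'   `events`, `history`, `coupling` (list of sender/receiver kernel records),
#'   and `clip`.
#' @export
sample_ground_truth <- function(config, seed = 1L) {
  stopifnot(inherits(config, "population_config"))
  set.seed(derive_seed(seed, "ground_truth"))
  U <- config$n_units
  units <- data.frame(
    unit = seq_len(U), area = config$area,
    elec_x = config$electrode_pitch * sample.int(10L, U, replace = TRUE),
    elec_y = config$electrode_pitch * sample.int(10L, U, replace = TRUE))
  baseline <- log(stats::runif(U, config$baseline_range[1],
                               config$baseline_range[2]))
  tuning <- lapply(seq_len(U), function(u) {
    lapply(config$covariates, function(rng) {
      sp <- basis_spec("tuning", "continuous", domain = rng, n_interior = 4L)
      list(spec = sp, beta = smooth_coefs(sp$dim, config$tuning_sd))
    })
  })
  events <- lapply(seq_len(U), function(u) {
    out <- lapply(config$event_names, function(nm) {
      sp <- basis_spec(nm, "event")
      list(spec = sp, beta = smooth_coefs(sp$dim, config$event_sd))
    })
    stats::setNames(out, config$event_names)
  })
  hist_spec <- basis_spec("spike_history", "history",
                          domain = c(1, config$history_window))
  history <- lapply(seq_len(U), function(u) {
    lags <- seq_len(config$history_window)
    vals <- -config$history_peak * exp(-(lags - 1) / 1.5)
    list(spec = hist_spec, beta = kernel_coefs(hist_spec, vals))
  })
  coupling <- list()
  if (config$coupling_density > 0 && U > 1L) {
    cp_spec <- basis_spec("coupling", "coupling",
                          domain = c(1, config$coupling_window))
    for (s in seq_len(U)) for (r in seq_len(U)) {
      if (s == r) next
      if (stats::runif(1) < config$coupling_density) {
        beta <- smooth_coefs(cp_spec$dim, 1)
        # orient the kernel so most couplings are net-excitatory
        kern <- drop(build_basis(cp_spec) %*% beta)
        if ((sum(kern) < 0) != (stats::runif(1) < 0.3)) beta <- -beta
        nrm <- stats::runif(1, config$coupling_strength[1],
                            config$coupling_strength[2])
        beta <- beta / sqrt(sum(beta^2)) * nrm
        coupling[[length(coupling) + 1L]] <-
          list(sender = s, receiver = r, spec = cp_spec, beta = beta)
      }
    }
  }
  structure(list(units = units, baseline = baseline, tuning = tuning,
                 events = events, history = history, coupling = coupling,
                 config = config, clip = config$clip),
            class = "ground_truth_population")
}

#' @export
print.ground_truth_population <- function(x, ...) {
  cat(sprintf("ground_truth_population: %d units (area %s), %d coupling kernels\n",
              nrow(x$units), x$units$area[1], length(x$coupling)))
  invisible(x)
}

#' Describe a context manipulation
#'
#' @param kind `"none"`, `"tuning_gain"` (multiply tuning kernels),
#'   `"coupling_gain"` (multiply coupling kernels), or `"coupling_remap"`
#'   (redraw coupling-kernel shapes).
#' @param magnitude positive gain for the gain kinds.
#' @param target_units unit indices the manipulation applies to (default all).
#' @param preserve_strength for `coupling_remap`: rescale each redrawn kernel
#'   to its original coefficient norm.
#' @param seed seed for the remap redraw.
#' @return An object of class `context_manipulation`.
#' @export
context_manipulation <- function(kind = c("none", "tuning_gain",
                                          "coupling_gain", "coupling_remap"),
                                 magnitude = 1, target_units = NULL,
                                 preserve_strength = FALSE, seed = 1L) {
  kind <- match.arg(kind)
  if (kind %in% c("tuning_gain", "coupling_gain") && magnitude <= 0)
    stop("magnitude must be > 0 for gain manipulations")
  structure(list(kind = kind, magnitude = magnitude,
                 target_units = target_units,
                 preserve_strength = preserve_strength, seed = seed),
            class = "context_manipulation")
}

#' Apply a context manipulation to a population
#'
#' Returns a modified copy; the input population is unchanged. `tuning_gain`
#' multiplies tuning kernels of the target units by the magnitude;
#' `coupling_gain` multiplies coupling kernels whose receiver is a target
#' unit; `coupling_remap` redraws coupling-kernel shapes (optionally rescaled
#' to the original norm, so strength is preserved while shape is not).
#'
#' @param pop a [sample_ground_truth()] population.
#' @param m a [context_manipulation()].
#' @return A new `ground_truth_population`.
#' @export
apply_context_manipulation <- function(pop, m) {
  stopifnot(inherits(pop, "ground_truth_population"),
            inherits(m, "context_manipulation"))
  targets <- m$target_units %||% pop$units$unit
  if (!all(targets %in% pop$units$unit)) stop("unknown target units")
  out <- pop
  if (m$kind == "none") return(out)
  if (m$kind == "tuning_gain") {
    for (u in targets) out$tuning[[u]] <- lapply(pop$tuning[[u]], function(tk) {
      tk$beta <- tk$beta * m$magnitude
      tk
    })
  } else if (m$kind == "coupling_gain") {
    out$coupling <- lapply(pop$coupling, function(cp) {
      if (cp$receiver %in% targets) cp$beta <- cp$beta * m$magnitude
      cp
    })
  } else if (m$kind == "coupling_remap") {
    set.seed(derive_seed(m$seed, "coupling_remap"))
    out$coupling <- lapply(pop$coupling, function(cp) {
      if (!(cp$receiver %in% targets)) return(cp)
      new_beta <- smooth_coefs(length(cp$beta), 1)
      if (m$preserve_strength) {
        cp$beta <- new_beta / sqrt(sum(new_beta^2)) * sqrt(sum(cp$beta^2))
      } else {
        cp$beta <- new_beta * stats::sd(cp$beta)
      }
      cp
    })
  } else stop("unknown manipulation kind")
  out
}

# lag-indexed coupling matrices K[[l]][receiver, sender]; history on diagonal
.coupling_matrices <- function(pop) {
  U <- nrow(pop$units)
  L <- 0L
  for (cp in pop$coupling) L <- max(L, cp$spec$domain[2])
  for (h in pop$history) if (!is.null(h)) L <- max(L, h$spec$domain[2])
  if (L == 0L) return(NULL)
  K <- lapply(seq_len(L), function(l) matrix(0, U, U))
  for (u in seq_len(U)) {
    h <- pop$history[[u]]
    if (!is.null(h)) {
      vals <- drop(build_basis(h$spec, seq(h$spec$domain[1], h$spec$domain[2])) %*% h$beta)
      for (i in seq_along(vals)) {
        l <- h$spec$domain[1] + i - 1L
        K[[l]][u, u] <- K[[l]][u, u] + vals[i]
      }
    }
  }
  for (cp in pop$coupling) {
    vals <- drop(build_basis(cp$spec, seq(cp$spec$domain[1], cp$spec$domain[2])) %*% cp$beta)
    for (i in seq_along(vals)) {
      l <- cp$spec$domain[1] + i - 1L
      K[[l]][cp$receiver, cp$sender] <- K[[l]][cp$receiver, cp$sender] + vals[i]
    }
  }
  K
}

# static (covariate- and event-driven) log-rate in Hz, bins x units
.static_lograte <- function(pop, cov) {
  n <- length(cov$time)
  U <- nrow(pop$units)
  eta <- matrix(rep(pop$baseline, each = n), n, U)
  for (u in seq_len(U)) {
    for (nm in names(pop$tuning[[u]])) {
      x <- cov$channels[[nm]]
      if (is.null(x)) stop("covariate channel missing for tuning kernel: ", nm)
      tk <- pop$tuning[[u]][[nm]]
      eta[, u] <- eta[, u] + drop(build_basis(tk$spec, x) %*% tk$beta)
    }
    for (nm in names(pop$events[[u]])) {
      z <- cov$events[[nm]]
      if (is.null(z)) stop("event train missing for event kernel: ", nm)
      ek <- pop$events[[u]][[nm]]
      eta[, u] <- eta[, u] +
        drop(temporal_block(z, ek$spec, cov$trial) %*% ek$beta)
    }
  }
  eta
}

#' Simulate Poisson spike counts from a ground-truth population
#'
#' Bin-sequential sampling: the log rate at bin t is the static covariate- and
#' event-driven part plus coupling and history contributions from
#' already-sampled past counts only (strictly causal), clipped at the
#' population's clip bound, then counts are drawn as
#' Poisson(exp(log-rate in Hz) * bin width). Dynamic terms never cross trial
#' boundaries.
#'
#' @param pop a [sample_ground_truth()] population.
#' @param cov a `covariate_frame` from [simulate_behavior()].
#' @param seed integer seed.
#' @return A units x bins integer matrix of class `spike_counts` with the unit
#'   metadata in `attr(, "units")` and the bin width in `attr(, "bin_width")`.
#' @export
simulate_spikes <- function(pop, cov, seed = 1L) {
  stopifnot(inherits(pop, "ground_truth_population"),
            inherits(cov, "covariate_frame"))
  set.seed(derive_seed(seed, "spikes"))
  dt <- cov$bin_width
  eta_static <- .static_lograte(pop, cov)
  if (any(!is.finite(eta_static))) stop("non-finite log-rate")
  n <- nrow(eta_static); U <- ncol(eta_static)
  K <- .coupling_matrices(pop)
  L <- length(K)
  clip <- pop$clip
  y <- matrix(0L, n, U)
  if (L == 0L) {
    lam <- exp(pmin(pmax(eta_static, -clip), clip)) * dt
    y[] <- stats::rpois(n * U, lam)
  } else {
    eta_dyn <- matrix(0, n, U)
    trial <- cov$trial
    for (t in seq_len(n)) {
      eta <- pmin(pmax(eta_static[t, ] + eta_dyn[t, ], -clip), clip)
      yt <- stats::rpois(U, exp(eta) * dt)
      y[t, ] <- yt
      if (any(yt > 0)) {
        lmax <- min(L, n - t)
        for (l in seq_len(lmax)) {
          if (trial[t + l] != trial[t]) break
          eta_dyn[t + l, ] <- eta_dyn[t + l, ] + drop(K[[l]] %*% yt)
        }
      }
    }
  }
  counts <- t(y)
  rownames(counts) <- paste0("unit", seq_len(U))
  structure(counts, units = pop$units, bin_width = dt, class = "spike_counts")
}

#' @export
print.spike_counts <- function(x, ...) {
  cat(sprintf("spike_counts: %d units x %d bins, mean rate %.2f Hz\n",
              nrow(x), ncol(x), mean(x) / attr(x, "bin_width")))
  invisible(x)
}

# subset a covariate frame to a set of bins (keeping trial structure)
subset_covariates <- function(cov, bins) {
  structure(list(time = cov$time[bins],
                 channels = cov$channels[bins, , drop = FALSE],
                 events = cov$events[bins, , drop = FALSE],
                 trial = cov$trial[bins], bin_width = cov$bin_width,
                 position = cov$position[bins, , drop = FALSE]),
            class = "covariate_frame")
}

#' Simulate a full two-context session
#'
#' Generates behavior and covariates from `config`, then spikes: high-density
#' trials from `pop`, low-density trials from the population obtained by
#' applying `manipulation` to `pop` (or from `pop_low` if given directly).
#'
#' @param config a [session_config()].
#' @param pop the high-density-context ground-truth population.
#' @param manipulation a [context_manipulation()] defining the low-density
#'   context (default none).
#' @param pop_low optional explicit low-density population.
#' @return A list with `trials`, `covariates`, `counts`, `pop_high`,
#'   `pop_low`.
#' @export
simulate_session <- function(config, pop,
                             manipulation = context_manipulation("none"),
                             pop_low = NULL) {
  beh <- simulate_behavior(config)
  pop_low <- pop_low %||% apply_context_manipulation(pop, manipulation)
  cov <- beh$covariates
  hi_trials <- beh$trials$trial_id[beh$trials$density == "high"]
  hi_bins <- cov$trial %in% hi_trials
  counts <- matrix(0L, nrow(pop$units), length(cov$time))
  if (any(hi_bins))
    counts[, hi_bins] <- unclass(simulate_spikes(
      pop, subset_covariates(cov, hi_bins),
      seed = derive_seed(config$seed, "spikes_high")))
  if (any(!hi_bins))
    counts[, !hi_bins] <- unclass(simulate_spikes(
      pop_low, subset_covariates(cov, !hi_bins),
      seed = derive_seed(config$seed, "spikes_low")))
  rownames(counts) <- paste0("unit", seq_len(nrow(pop$units)))
  counts <- structure(counts, units = pop$units, bin_width = cov$bin_width,
                      class = "spike_counts")
  list(trials = beh$trials, covariates = cov, counts = counts,
       pop_high = pop, pop_low = pop_low)
}

#' Inject a fixed directed coupling graph into a population
#'
#' Replaces the population's coupling kernels with a controlled set: each
#' receiver gets `n_per_receiver` incoming kernels from distinct random
#' senders, with net-excitatory smooth shapes and coefficient norms drawn
#' from `strength`. Used by recovery studies where every unit must carry a
#' known amount of incoming coupling.
#'
#' @param pop a [sample_ground_truth()] population.
#' @param n_per_receiver incoming kernels per unit.
#' @param strength range of coefficient norms.
#' @param window coupling window in bins.
#' @param excitatory_frac fraction of kernels oriented net-excitatory; 0.5
#'   gives a balanced network whose rates stay stable under strong coupling.
#' @param seed integer seed.
#' @return The modified population (input unchanged).
#' @export
inject_coupling <- function(pop, n_per_receiver = 2L, strength = c(0.5, 0.9),
                            window = 6L, excitatory_frac = 0.8, seed = 1L) {
  stopifnot(inherits(pop, "ground_truth_population"))
  set.seed(derive_seed(seed, "inject_coupling"))
  U <- nrow(pop$units)
  if (n_per_receiver > U - 1L) stop("too many kernels per receiver")
  cp_spec <- basis_spec("coupling", "coupling", domain = c(1, window))
  pop$coupling <- list()
  for (r in seq_len(U)) {
    for (s in sample(setdiff(seq_len(U), r), n_per_receiver)) {
      beta <- smooth_coefs(cp_spec$dim, 1)
      want_exc <- stats::runif(1) < excitatory_frac
      if ((sum(build_basis(cp_spec) %*% beta) < 0) == want_exc) beta <- -beta
      beta <- beta / sqrt(sum(beta^2)) *
        stats::runif(1, strength[1], strength[2])
      pop$coupling[[length(pop$coupling) + 1L]] <-
        list(sender = s, receiver = r, spec = cp_spec, beta = beta)
    }
  }
  pop
}

#' Simulate a population with a configurable cross-context read-out
#'
#' Constructs Poisson count matrices over two density contexts for the
#' decoding analyses, with a per-bin latent task variable (distance to
#' target, declining over each trial) and one of three read-out regimes:
#'
#' * `"stable"`: every unit keeps the same tuning to the variable in both
#'   contexts, with independent per-unit noise — a context-invariant
#'   read-out, so a decoder trained in one context transfers to the other.
#' * `"translated"`: as stable, but in the low-density context each unit's
#'   rate is offset proportionally to its tuning weight — the population
#'   activity is translated along the read-out direction, so a decoder
#'   trained on high density mispredicts low density.
#' * `"coupled"`: units come in pairs riding on a shared slow co-fluctuation
#'   (the coupling-induced noise). The pair-difference tuning to the variable
#'   is identical in both contexts, while the pair common-mode tuning flips
#'   sign across contexts. A decoder trained on intact data converges on the
#'   difference read-out — it cancels the strong shared noise — and therefore
#'   transfers across contexts. Shuffling whitens the shared noise, so a
#'   decoder trained on shuffled data leans on the (larger) common-mode
#'   tuning of single units, which reverses in the other context: the
#'   cross-context transfer collapses while within-context decoding is
#'   unaffected.
#'
#' Rates are counts per bin: baseline 0.6 (1.0 for the coupled regime);
#' stable/translated tuning amplitude 0.15; coupled difference amplitude
#' 0.15 and common-mode amplitude 0.2; shared-noise sd 0.8 with a 100 ms
#' correlation time; independent-noise sd 0.05-0.1. These put the
#' pair-difference signal-to-noise far above the common-mode one on intact
#' data and reverse that ordering after shuffling.
#'
#' @param kind read-out regime, see above.
#' @param n_units number of units (even; default 10, the matched population
#'   size of the decoding analyses).
#' @param n_trials trials per context.
#' @param trial_bins bins per trial.
#' @param bin_width bin width in seconds.
#' @param seed integer seed.
#' @return A list with `counts` (units x bins, `spike_counts`), `y` (the
#'   latent variable per bin, cm), `trial`, `context` (per bin), `kind`.
#' @export
simulate_readout_population <- function(kind = c("stable", "translated",
                                                 "coupled"),
                                        n_units = 10L, n_trials = 60L,
                                        trial_bins = 150L, bin_width = 0.006,
                                        seed = 1L) {
  kind <- match.arg(kind)
  set.seed(derive_seed(seed, paste0("readout_", kind)))
  n_tr_total <- 2L * n_trials
  context <- rep(rep(c("high", "low"), each = 1L), length.out = n_tr_total)
  y0 <- stats::runif(n_tr_total, 250, 400)
  y <- unlist(lapply(seq_len(n_tr_total), function(i)
    y0[i] * seq(1, 0, length.out = trial_bins)))
  trial <- rep(seq_len(n_tr_total), each = trial_bins)
  ctx_bin <- context[trial]
  n <- length(y)
  g <- (y - 325) / 150                      # standardized latent signal
  base <- 0.6; A <- 0.15
  ar_smooth <- function(n, tau_bins, sd) {
    rho <- exp(-1 / tau_bins)
    e <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
    as.numeric(stats::filter(e, rho, method = "recursive"))
  }
  lam <- matrix(0, n_units, n)
  if (kind == "coupled") {
    A_d <- 0.18; A_c <- 0.22; base_c <- 1.0
    s_ctx <- ifelse(ctx_bin == "high", 1, -1)   # common mode flips in low
    for (k in seq_len(n_units %/% 2L)) {
      shared <- ar_smooth(n, tau_bins = 17, sd = 0.8)
      eps1 <- ar_smooth(n, 17, 0.05); eps2 <- ar_smooth(n, 17, 0.05)
      lam[2L * k - 1L, ] <- base_c + (A_d + s_ctx * A_c) * g + shared + eps1
      lam[2L * k, ] <- base_c + (-A_d + s_ctx * A_c) * g + shared + eps2
    }
  } else {
    a <- A * rep_len(c(1, -1), n_units) * stats::runif(n_units, 0.7, 1.3)
    for (u in seq_len(n_units)) {
      lam[u, ] <- base + a[u] * g + ar_smooth(n, 17, 0.1)
      if (kind == "translated")
        lam[u, ctx_bin == "low"] <- lam[u, ctx_bin == "low"] + 1.5 * a[u]
    }
  }
  counts <- matrix(stats::rpois(n_units * n, pmax(lam, 0.01)), n_units, n)
  rownames(counts) <- paste0("unit", seq_len(n_units))
  counts <- structure(counts, bin_width = bin_width, class = "spike_counts")
  list(counts = counts, y = y, trial = trial, context = ctx_bin, kind = kind)
}

#' Simulate estimated coupling kernels across sessions and contexts
#'
#' Generates the kernel-level data structure consumed by [chance_ceiling()]
#' without refitting encoding models: per session and pair, a smooth true
#' kernel; the low-density kernel equals the high-density one for stable pairs
#' and is redrawn for a `remap_frac` fraction; "estimates" add independent
#' Gaussian noise emulating refit noise. All estimate types carry the same
#' noise magnitude: the chance/ceiling references are meant to isolate kernel
#' identity, and equal estimator variance makes the odd/even ceiling an exact
#' upper bound for the cross-context correlation.
#'
#' @param n_sessions,n_pairs sessions and directed pairs per session.
#' @param n_lags kernel length in lag bins.
#' @param remap_frac fraction of pairs whose low-density kernel is redrawn.
#' @param est_noise_sd estimation noise sd relative to kernel sd.
#' @param seed integer seed.
#' @return A `coupling_kernels` object: `info` data frame (session, sender,
#'   receiver, condition, split, remapped) plus the aligned `kernels` matrix.
#' @export
simulate_coupling_estimates <- function(n_sessions = 4L, n_pairs = 30L,
                                        n_lags = 6L, remap_frac = 0.5,
                                        est_noise_sd = 0.3, seed = 1L) {
  if (n_sessions < 1L || n_pairs < 1L) stop("need at least one session and pair")
  set.seed(derive_seed(seed, "coupling_estimates"))
  smooth_kernel <- function() {
    k <- smooth_coefs(n_lags, 1)
    k / sqrt(sum(k^2))
  }
  info <- list(); kern <- list()
  add <- function(ses, pair, cond, split, remapped, k) {
    info[[length(info) + 1L]] <<- data.frame(
      session = ses, sender = 2L * pair - 1L, receiver = 2L * pair,
      condition = cond, split = split, remapped = remapped)
    kern[[length(kern) + 1L]] <<- k
  }
  for (ses in seq_len(n_sessions)) for (p in seq_len(n_pairs)) {
    k_hi <- smooth_kernel()
    remapped <- stats::runif(1) < remap_frac
    k_lo <- if (remapped) smooth_kernel() else k_hi
    noise <- function(s) stats::rnorm(n_lags, 0, s)
    add(ses, p, "high", "all", remapped, k_hi + noise(est_noise_sd))
    add(ses, p, "low", "all", remapped, k_lo + noise(est_noise_sd))
    add(ses, p, "high", "odd", remapped, k_hi + noise(est_noise_sd))
    add(ses, p, "high", "even", remapped, k_hi + noise(est_noise_sd))
  }
  structure(list(info = do.call(rbind, info), kernels = do.call(rbind, kern)),
            class = "coupling_kernels")
}
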