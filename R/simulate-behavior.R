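# Closed-loop navigation-to-target session generator. A steering agent drives
# to a briefly cued target on a ground plane using joystick-like linear and
# angular velocity control. The agent is a noisy proportional controller with
# an explicit per-dimension endpoint gain: its aim point is
# gain * target (in polar coordinates) plus per-trial Gaussian endpoint noise
# whose sd depends on the optic-flow density context, so the behavioral
# regression downstream recovers the configured gain by construction.

#' Configuration of a simulated navigation session
#'
#' Defaults are the task conditions of the navigation-to-target paradigm:
#' targets uniform over 1-4 m radial and -45..45 degree angular range, 6 ms
#' bins, joystick limits 200 cm/s linear and 90 deg/s angular, two interleaved
#' optic-flow density contexts, reward within 60 cm of the target center, and
#' a 7 s trial cap. A fraction of trials is aborted early (< 0.5 m travelled)
#' and a fraction never stops, matching the trial-exclusion rules exercised
#' downstream.
#'
#' @param n_trials number of trials.
#' @param bin_width bin width in seconds.
#' @param target_radial_range radial target range in meters.
#' @param target_angular_range angular target range in degrees.
#' @param max_linear_speed,max_angular_speed joystick limits (cm/s, deg/s).
#' @param reward_radius reward boundary in cm (60 by default; 65 appears as an
#'   alternative in the source literature and is accepted here as config).
#' @param density_mix probability that a trial is high-density.
#' @param behavior_gain named numeric, endpoint gain per dimension
#'   (`radial`, `angular`).
#' @param endpoint_noise_sd named numeric, per-context endpoint noise sd in cm
#'   (`high`, `low`).
#' @param max_trial_duration trial cap in seconds.
#' @param abort_prob,no_stop_prob fractions of aborted / never-stopping trials.
#' @param n_target_sites NULL for continuous-uniform targets, or an integer to
#'   draw targets from that many fixed locations (used when analyses need
#'   repeated target positions).
#' @param seed master session seed; all components draw sub-seeds from it.
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_trials = 200L, bin_width = 0.006,
                           target_radial_range = c(1, 4),
                           target_angular_range = c(-45, 45),
                           max_linear_speed = 200, max_angular_speed = 90,
                           reward_radius = 60, density_mix = 0.5,
                           behavior_gain = c(radial = 0.85, angular = 0.80),
                           endpoint_noise_sd = c(high = 20, low = 30),
                           max_trial_duration = 7,
                           abort_prob = 0.13, no_stop_prob = 0.05,
                           n_target_sites = NULL, seed = 1L) {
  if (n_trials < 0) stop("n_trials must be nonnegative")
  if (bin_width <= 0) stop("bin_width must be positive")
  if (diff(target_radial_range) <= 0 || diff(target_angular_range) <= 0)
    stop("target ranges must be nonempty and ordered")
  if (density_mix < 0 || density_mix > 1) stop("density_mix must be in [0,1]")
  if (any(behavior_gain < 0)) stop("invalid config: behavior_gain must be >= 0")
  if (any(endpoint_noise_sd < 0)) stop("endpoint noise sd must be >= 0")
  if (is.null(names(behavior_gain))) names(behavior_gain) <- c("radial", "angular")
  if (is.null(names(endpoint_noise_sd))) names(endpoint_noise_sd) <- c("high", "low")
  structure(as.list(environment()), class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf(paste0("session_config: %d trials, %.0f ms bins, targets r in ",
                     "[%g,%g] m / theta in [%g,%g] deg\n  gains (r, theta) = ",
                     "(%.2f, %.2f), endpoint noise (high, low) = (%g, %g) cm, ",
                     "seed %d\n"),
              x$n_trials, 1000 * x$bin_width, x$target_radial_range[1],
              x$target_radial_range[2], x$target_angular_range[1],
              x$target_angular_range[2], x$behavior_gain["radial"],
              x$behavior_gain["angular"], x$endpoint_noise_sd["high"],
              x$endpoint_noise_sd["low"], as.integer(x$seed)))
  invisible(x)
}

polar2cart <- function(r, theta_deg) {
  th <- theta_deg * pi / 180
  cbind(x = r * sin(th), y = r * cos(th))
}

cart2polar <- function(x, y) {
  list(r = sqrt(x^2 + y^2), theta = atan2(x, y) * 180 / pi)
}

#' Simulate closed-loop navigation behavior
#'
#' Generates one trajectory per trial from the noisy proportional-control
#' steering agent, plus the full per-bin covariate frame: linear/angular
#' velocity and acceleration, distances travelled, distance to target, a
#' smooth gaze proxy, wrapped LFP band phases (band-limited phase oscillators),
#' binary event trains, and the per-bin trial index.
#'
#' @param config a [session_config()].
#' @param trajectories if FALSE, only the trial table is generated (fast path
#'   for behavior-only studies); the covariate frame is NULL.
#' @return A list with `trials` (trial table) and `covariates` (a
#'   `covariate_frame`: `time`, `channels`, `events`, `trial`, `bin_width`).
#' @export
simulate_behavior <- function(config, trajectories = TRUE) {
  stopifnot(inherits(config, "session_config"))
  if (config$n_trials == 0L) stop("empty session: n_trials is 0")
  set.seed(derive_seed(config$seed, "behavior"))
  n <- config$n_trials
  dt <- config$bin_width

  if (!is.null(config$n_target_sites)) {
    site_r <- stats::runif(config$n_target_sites, config$target_radial_range[1],
                           config$target_radial_range[2])
    site_th <- stats::runif(config$n_target_sites, config$target_angular_range[1],
                            config$target_angular_range[2])
    site <- sample.int(config$n_target_sites, n, replace = TRUE)
    target_r <- site_r[site]; target_th <- site_th[site]
  } else {
    target_r <- stats::runif(n, config$target_radial_range[1],
                             config$target_radial_range[2])
    target_th <- stats::runif(n, config$target_angular_range[1],
                              config$target_angular_range[2])
  }
  density <- ifelse(stats::runif(n) < config$density_mix, "high", "low")
  kind <- sample(c("normal", "abort", "no_stop"), n, replace = TRUE,
                 prob = c(1 - config$abort_prob - config$no_stop_prob,
                          config$abort_prob, config$no_stop_prob))

  # aim point: gain-scaled target plus per-trial endpoint noise, applied in
  # polar coordinates (radially in cm; angularly as the same arc length at
  # the aim radius), so endpoint_r = gain * target_r + noise exactly and the
  # per-dimension endpoint regression is unbiased by construction
  g <- config$behavior_gain
  noise_sd_m <- config$endpoint_noise_sd[density] / 100
  aim_r <- pmax(g["radial"] * target_r + stats::rnorm(n, 0, noise_sd_m), 0.01)
  aim_th <- g["angular"] * target_th +
    stats::rnorm(n, 0, noise_sd_m / pmax(aim_r, 0.5) * 180 / pi)
  aim <- polar2cart(aim_r, aim_th)
  target_xy <- polar2cart(target_r, target_th)

  vmax <- config$max_linear_speed / 100          # m/s
  wmax <- config$max_angular_speed * pi / 180    # rad/s
  rt_bins <- pmax(1L, round((0.20 + stats::runif(n, 0, 0.10)) / dt))
  post_bins <- round(0.5 / dt)
  abort_len <- stats::runif(n, 0.10, 0.45)       # path length at abort (m)

  if (!trajectories) {
    # endpoints are analytic by construction: the controller converges on the
    # aim point (normal trials), stops early along the path (aborts), or
    # wanders past it (no-stop); path length is approximated by the straight
    # aim distance, adequate for trial filtering
    aim_dist <- sqrt(rowSums(aim^2))
    endpoint <- aim
    ab <- kind == "abort"
    endpoint[ab, ] <- aim[ab, , drop = FALSE] *
      (abort_len[ab] / pmax(aim_dist[ab], 1e-9))
    displacement <- ifelse(ab, pmin(abort_len, aim_dist), aim_dist)
    stopped <- kind != "no_stop"
    ep <- cart2polar(endpoint[, 1], endpoint[, 2])
    d_end <- sqrt(rowSums((endpoint - target_xy)^2))
    rewarded <- stopped & d_end <= config$reward_radius / 100
    dur <- rt_bins * dt + displacement / (vmax * 0.7) + 0.5
    t_on <- cumsum(c(0, dur[-n] + post_bins * dt))
    trials <- data.frame(
      trial_id = seq_len(n), target_r = target_r, target_theta = target_th,
      endpoint_r = ep$r, endpoint_theta = ep$theta,
      target_x = target_xy[, 1], target_y = target_xy[, 2],
      endpoint_x = endpoint[, 1], endpoint_y = endpoint[, 2],
      density = density, stopped = stopped,
      t_target_on = t_on, t_move_on = t_on + rt_bins * dt,
      t_move_off = t_on + dur,
      t_reward = ifelse(rewarded, t_on + dur + 0.25, NA_real_),
      rewarded = rewarded, displacement = displacement, endpoint_dist = d_end)
    return(list(trials = trials, covariates = NULL))
  }

  trials <- vector("list", n)
  cov_list <- vector("list", n)
  t0 <- 0
  for (i in seq_len(n)) {
    res <- .simulate_trial(aim[i, ], target_xy[i, ], kind[i], rt_bins[i],
                           post_bins, abort_len[i], vmax, wmax, dt,
                           config$max_trial_duration, trajectories)
    ep <- cart2polar(res$endpoint[1], res$endpoint[2])
    d_end <- sqrt(sum((res$endpoint - target_xy[i, ])^2))
    rewarded <- res$stopped && d_end <= config$reward_radius / 100
    trials[[i]] <- data.frame(
      trial_id = i, target_r = target_r[i], target_theta = target_th[i],
      endpoint_r = ep$r, endpoint_theta = ep$theta,
      target_x = target_xy[i, 1], target_y = target_xy[i, 2],
      endpoint_x = res$endpoint[1], endpoint_y = res$endpoint[2],
      density = density[i], stopped = res$stopped,
      t_target_on = t0, t_move_on = t0 + rt_bins[i] * dt,
      t_move_off = t0 + res$stop_bin * dt,
      t_reward = if (rewarded) t0 + res$reward_bin * dt else NA_real_,
      rewarded = rewarded, displacement = res$displacement,
      endpoint_dist = d_end)
    if (trajectories) {
      cv <- res$cov
      cv$trial <- i
      cv$time <- t0 + dt * (seq_len(nrow(cv)) - 1L)
      if (rewarded) cv$reward[res$reward_bin] <- 1
      cov_list[[i]] <- cv
    }
    t0 <- t0 + res$n_bins * dt
  }
  trials <- do.call(rbind, trials)

  covariates <- NULL
  if (trajectories) {
    cv <- do.call(rbind, cov_list)
    covariates <- .finish_covariates(cv, config)
  }
  list(trials = trials, covariates = covariates)
}

# one trial of the proportional-control agent; internal units: meters, radians
.simulate_trial <- function(aim, target, kind, rt_bins, post_bins, abort_len,
                            vmax, wmax, dt, max_dur, trajectories) {
  max_bins <- round(max_dur / dt)
  pos <- c(0, 0); head_ang <- 0
  v <- numeric(max_bins + post_bins); w <- numeric(max_bins + post_bins)
  px <- numeric(max_bins + post_bins); py <- numeric(max_bins + post_bins)
  path <- 0
  goal <- aim
  stopped <- FALSE; stop_bin <- max_bins
  v_noise <- 0; w_noise <- 0
  b <- rt_bins
  while (b < max_bins) {
    b <- b + 1L
    dvec <- goal - pos
    dist <- sqrt(sum(dvec^2))
    if (kind != "no_stop" && dist < 0.02) { stopped <- TRUE; stop_bin <- b - 1L; b <- b - 1L; break }
    if (kind == "no_stop" && dist < 0.05) {
      # wander: pick a new nearby goal and keep moving until the time cap
      goal <- goal + stats::rnorm(2, 0, 0.4)
    }
    bearing <- atan2(dvec[1], dvec[2])
    # continuous joystick jitter on both axes (the controller re-corrects)
    w_noise <- 0.97 * w_noise + stats::rnorm(1, 0, 0.055)
    w_t <- max(-wmax, min(wmax, 4 * wrap_angle(bearing - head_ang) + w_noise))
    v_noise <- 0.9 * v_noise + stats::rnorm(1, 0, 0.05)
    v_t <- min(vmax, max(0, min(vmax, 1.8 * dist)) * exp(v_noise))
    head_ang <- head_ang + w_t * dt
    step <- v_t * dt
    pos <- pos + step * c(sin(head_ang), cos(head_ang))
    path <- path + step
    v[b] <- v_t; w[b] <- w_t; px[b] <- pos[1]; py[b] <- pos[2]
    if (kind == "abort" && path >= abort_len) { stopped <- TRUE; stop_bin <- b; break }
  }
  if (stopped && kind == "normal") pos <- aim   # controller converges on goal
  n_bins <- (if (stopped) stop_bin else max_bins) + post_bins
  px[(stop_bin + 1L):n_bins] <- pos[1]; py[(stop_bin + 1L):n_bins] <- pos[2]
  if (rt_bins > 0) { px[seq_len(rt_bins)] <- 0; py[seq_len(rt_bins)] <- 0 }
  reward_bin <- min(n_bins, stop_bin + round(0.25 / dt))
  cov <- NULL
  if (trajectories) {
    idx <- seq_len(n_bins)
    cov <- data.frame(
      lin_vel = v[idx] * 100, ang_vel = w[idx] * 180 / pi,
      pos_x = px[idx], pos_y = py[idx],
      dist_target = sqrt((px[idx] - target[1])^2 + (py[idx] - target[2])^2) * 100,
      target_on = 0, move_on = 0, move_off = 0, reward = 0)
    cov$target_on[1] <- 1
    cov$move_on[min(rt_bins + 1L, n_bins)] <- 1
    if (stopped) cov$move_off[stop_bin] <- 1
  }
  list(endpoint = pos, stopped = stopped, stop_bin = stop_bin,
       displacement = path, n_bins = n_bins, reward_bin = reward_bin,
       cov = cov)
}

# derived channels that need the concatenated session: accelerations,
# cumulative distances, gaze proxy, LFP band phases
.finish_covariates <- function(cv, config) {
  dt <- config$bin_width
  n <- nrow(cv)
  new_trial <- c(TRUE, cv$trial[-1] != cv$trial[-n])
  d_lin <- c(0, diff(cv$lin_vel)) / dt
  d_ang <- c(0, diff(cv$ang_vel)) / dt
  d_lin[new_trial] <- 0; d_ang[new_trial] <- 0
  lin_step <- cv$lin_vel * dt          # cm per bin
  ang_step <- abs(cv$ang_vel) * dt
  lin_dist <- stats::ave(lin_step, cv$trial, FUN = cumsum)
  ang_dist <- stats::ave(ang_step, cv$trial, FUN = cumsum)

  set.seed(derive_seed(config$seed, "gaze_and_lfp"))
  # smooth gaze proxy: slow noisy pursuit signal riding on the turning rate
  ar1 <- function(n, rho, sd) {
    e <- stats::rnorm(n, 0, sd)
    as.numeric(stats::filter(e, rho, method = "recursive"))
  }
  eye_h <- 0.9 * (cv$ang_vel * 0.05) + ar1(n, 0.98, 0.15)
  eye_v <- -atan2(10, pmax(cv$dist_target, 10)) * 180 / pi + ar1(n, 0.98, 0.1)
  lfp_phase <- function(freq) {
    dphi <- 2 * pi * freq * dt + stats::rnorm(n, 0, 0.25)
    wrap_angle(cumsum(dphi))
  }
  channels <- data.frame(
    lin_vel = cv$lin_vel, ang_vel = cv$ang_vel,
    lin_acc = d_lin, ang_acc = d_ang,
    lin_dist = lin_dist, ang_dist = ang_dist,
    dist_target = cv$dist_target,
    eye_hori = eye_h, eye_vert = eye_v,
    lfp_theta = lfp_phase(8), lfp_alpha = lfp_phase(11),
    lfp_beta = lfp_phase(20))
  events <- data.frame(target_on = cv$target_on, move_on = cv$move_on,
                       move_off = cv$move_off, reward = cv$reward)
  structure(list(time = cv$time, channels = channels, events = events,
                 trial = cv$trial, bin_width = dt,
                 position = cbind(x = cv$pos_x, y = cv$pos_y)),
            class = "covariate_frame")
}

#' @export
print.covariate_frame <- function(x, ...) {
  cat(sprintf("covariate_frame: %d bins (%.0f ms), %d channels, %d event trains, %d trials\n",
              length(x$time), 1000 * x$bin_width, ncol(x$channels),
              ncol(x$events), length(unique(x$trial))))
  invisible(x)
}
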