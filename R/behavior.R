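# Behavioral analyses: trial filtering, endpoint-gain regression, endpoint
# variability, and reward fraction. Targets and endpoints are expressed in
# polar coordinates (radial distance r in meters, eccentricity theta in
# degrees); the angular dimension is treated linearly since targets span only
# +/-45 degrees.

#' Filter trials for behavioral analysis
#'
#' Removes aborted trials (displacement < 0.5 m, the animal gave up early) and
#' trials with no stop within the maximum trial duration.
#'
#' @param trials a trial table with `displacement` and `stopped` columns.
#' @param min_displacement abort threshold in meters.
#' @return The retained rows, with attribute `n_excluded`.
#' @export
filter_trials <- function(trials, min_displacement = 0.5) {
  if (!all(c("displacement", "stopped") %in% names(trials)))
    stop("trial table needs displacement and stopped columns")
  keep <- trials$displacement >= min_displacement & trials$stopped
  out <- trials[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("no trials retained after filtering")
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Behavioral gain regression
#'
#' Ordinary least squares of the endpoint on the target location in one
#' dimension: `response = gain * target + intercept`. Gain 1 means no over- or
#' under-shooting; gains below 1 indicate undershooting.
#'
#' @param trials a (filtered) trial table.
#' @param dimension `"radial"` (meters) or `"angular"` (degrees).
#' @return A list with `gain`, `intercept`, `r_squared`, `gain_ci` (95
#'   percent), `n`.
#' @export
behavioral_gain <- function(trials, dimension = c("radial", "angular")) {
  dimension <- match.arg(dimension)
  if (nrow(trials) < 3L) stop("need at least 3 trials")
  x <- if (dimension == "radial") trials$target_r else trials$target_theta
  y <- if (dimension == "radial") trials$endpoint_r else trials$endpoint_theta
  if (stats::sd(x) == 0) stop("constant targets: regression is singular")
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit)["x", ]
  list(gain = unname(stats::coef(fit)["x"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = summary(fit)$r.squared,
       gain_ci = unname(ci), n = nrow(trials))
}

#' Euclidean distance to target
#'
#' Distance between the current position and the target center, combining the
#' azimuth and depth offsets: `sqrt(dx^2 + dy^2)`.
#'
#' @param position n x 2 matrix (or length-2 vector) of positions.
#' @param target length-2 target position in the same planar frame and units.
#' @return Nonnegative distances.
#' @export
distance_to_target <- function(position, target) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 2)
  if (ncol(position) != 2L || length(target) != 2L)
    stop("position and target must be planar (x, y)")
  sqrt((position[, 1] - target[1])^2 + (position[, 2] - target[2])^2)
}

#' Endpoint variability
#'
#' Standard error of the mean of the per-trial endpoint distances to target,
#' rendering the two-dimensional endpoint scatter into a single dimension.
#'
#' @param trials a (filtered) trial table with an `endpoint_dist` column (or
#'   target/endpoint coordinates from which it is computed).
#' @return The SEM (same units as the distances).
#' @export
endpoint_variability <- function(trials) {
  if (nrow(trials) < 2L) stop("need at least 2 trials")
  d <- trials$endpoint_dist
  if (is.null(d))
    d <- sqrt((trials$endpoint_x - trials$target_x)^2 +
                (trials$endpoint_y - trials$target_y)^2)
  stats::sd(d) / sqrt(length(d))
}

#' Fraction of rewarded trials
#'
#' @param trials a (filtered) trial table with endpoint distances to target.
#' @param radius reward radius, same units as `endpoint_dist`.
#' @return Fraction in `[0, 1]`.
#' @export
reward_fraction <- function(trials, radius) {
  if (radius < 0) stop("radius must be nonnegative")
  if (nrow(trials) == 0L) return(NA_real_)
  mean(trials$endpoint_dist <= radius)
}

#' Per-session behavioral summary
#'
#' Applies [filter_trials()], then computes gain, intercept, R-squared,
#' endpoint SEM, and reward fraction per dimension and density context.
#'
#' @param trials a raw trial table from [simulate_behavior()].
#' @param reward_radius reward radius in meters.
#' @param session session label carried into the output.
#' @return A data frame, one row per dimension x density.
#' @export
behavior_summary <- function(trials, reward_radius = 0.6, session = 1L) {
  ft <- filter_trials(trials)
  out <- list()
  for (dens in unique(ft$density)) {
    sub <- ft[ft$density == dens, , drop = FALSE]
    for (dim in c("radial", "angular")) {
      g <- behavioral_gain(sub, dim)
      out[[length(out) + 1L]] <- data.frame(
        session = session, dimension = dim, density = dens,
        gain = g$gain, intercept = g$intercept, r_squared = g$r_squared,
        endpoint_sem = endpoint_variability(sub),
        reward_fraction = reward_fraction(sub, reward_radius),
        n_retained = nrow(sub),
        n_excluded = attr(ft, "n_excluded"))
    }
  }
  do.call(rbind, out)
}
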