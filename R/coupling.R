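# Coupling-filter analyses: strength, cross-context stability, permutation
# chance/ceiling references, distance-resolved coupling probability, evoked
# spike-triggered averages, tuning gain/stability, and session-level filters.

#' Coupling strength
#'
#' L2 norm of the coefficient block defining a coupling filter (homogeneous of
#' degree one: doubling the coefficients doubles the strength). The integral
#' of the absolute kernel over the lag window is available as a secondary
#' metric via [coupling_kernel_integral()].
#'
#' @param beta the coupling coefficient block.
#' @return A nonnegative scalar.
#' @export
coupling_strength <- function(beta) {
  if (length(beta) == 0L) stop("empty coefficient block")
  sqrt(sum(beta^2))
}

#' Integrated absolute coupling kernel (secondary strength metric)
#'
#' @param kernel the coupling filter evaluated per lag bin.
#' @param bin_width bin width in seconds.
#' @return Area under |kernel| over the lag window.
#' @export
coupling_kernel_integral <- function(kernel, bin_width = 0.006) {
  if (length(kernel) == 0L) stop("empty kernel")
  sum(abs(kernel)) * bin_width
}

#' Coupling-filter stability
#'
#' Pearson correlation between a pair's coupling kernels estimated in two
#' contexts, computed on the kernels evaluated at every lag bin.
#'
#' @param kernel_a,kernel_b kernels on the same lag grid.
#' @return Correlation in `[-1, 1]`; `NA` (with a warning) for a
#'   zero-variance kernel.
#' @export
coupling_stability <- function(kernel_a, kernel_b) {
  if (length(kernel_a) != length(kernel_b)) stop("kernels on different lag grids")
  if (stats::sd(kernel_a) == 0 || stats::sd(kernel_b) == 0) {
    warning("zero-variance kernel: stability undefined")
    return(NA_real_)
  }
  stats::cor(kernel_a, kernel_b)
}

#' Chance and ceiling references for coupling stability
#'
#' Cross-context stability (high vs low density, same pair) is compared
#' against a chance distribution — correlations between kernels of pairs
#' drawn from different sessions — and a ceiling distribution — correlations
#' of the same pair's kernels refit on odd vs even trials within one
#' condition.
#'
#' @param ck a `coupling_kernels` object (see
#'   [simulate_coupling_estimates()] for the structure: `info` data frame with
#'   session/sender/receiver/condition/split and aligned `kernels` matrix).
#' @param n_chance number of cross-session pairings to draw.
#' @param seed seed for the chance draw.
#' @return A `stability_summary`: vectors `cross`, `chance`, `ceiling`, and
#'   per-session mean cross-context stability.
#' @export
chance_ceiling <- function(ck, n_chance = 1000L, seed = 1L) {
  info <- ck$info; kern <- ck$kernels
  if (length(unique(info$session)) < 2L)
    stop("chance level needs at least 2 sessions")
  key <- function(cond, split) info$condition == cond & info$split == split
  hi <- which(key("high", "all")); lo <- which(key("low", "all"))
  pair_id <- paste(info$session, info$sender, info$receiver)
  m <- match(pair_id[hi], pair_id[lo])
  cross <- vapply(seq_along(hi), function(i) {
    if (is.na(m[i])) return(NA_real_)
    suppressWarnings(coupling_stability(kern[hi[i], ], kern[lo[m[i]], ]))
  }, numeric(1))
  odd <- which(key("high", "odd")); even <- which(key("high", "even"))
  me <- match(pair_id[odd], pair_id[even])
  ceiling_r <- vapply(seq_along(odd), function(i) {
    if (is.na(me[i])) return(NA_real_)
    suppressWarnings(coupling_stability(kern[odd[i], ], kern[even[me[i]], ]))
  }, numeric(1))
  if (length(ceiling_r) == 0L) stop("no odd/even refits available for ceiling")
  set.seed(derive_seed(seed, "chance_pairings"))
  ses_hi <- info$session[hi]
  chance <- numeric(n_chance)
  for (i in seq_len(n_chance)) {
    a <- sample(seq_along(hi), 1L)
    b <- sample(which(ses_hi != ses_hi[a]), 1L)
    chance[i] <- suppressWarnings(
      coupling_stability(kern[hi[a], ], kern[hi[b], ]))
  }
  per_session <- tapply(cross, info$session[hi], mean, na.rm = TRUE)
  structure(list(cross = cross[!is.na(cross)],
                 chance = chance[!is.na(chance)],
                 ceiling = ceiling_r[!is.na(ceiling_r)],
                 session_means = per_session,
                 n = c(cross = sum(!is.na(cross)), chance = length(chance),
                       ceiling = sum(!is.na(ceiling_r)))),
            class = "stability_summary")
}

#' @export
print.stability_summary <- function(x, ...) {
  cat(sprintf(paste0("coupling stability: median cross-context r = %.3f ",
                     "(chance %.3f, ceiling %.3f)\n"),
              stats::median(x$cross), stats::median(x$chance),
              stats::median(x$ceiling)))
  invisible(x)
}

#' Coupling probability as a function of electrode distance
#'
#' Logistic model `p(coupled) = inverse-logit(f(distance))` with f a B-spline,
#' fit to the binary significance of each pair; reports the fitted curve and
#' its prediction at a reference distance (500 micrometers by default).
#'
#' @param records data frame with `distance` (micrometers) and `significant`
#'   (logical or 0/1) per directed pair.
#' @param at reference distance for the headline prediction.
#' @param df spline degrees of freedom.
#' @return A list with `predict` (vectorized probability function), `at`,
#'   `p_at`, and the fitted `glm`.
#' @export
coupling_probability_vs_distance <- function(records, at = 500, df = 4L) {
  c01 <- as.numeric(records$significant)
  d <- records$distance
  if (all(c01 == c01[1])) {
    warning("all pairs share one significance outcome: degenerate fit")
    p <- c01[1]
    return(list(predict = function(x) rep(p, length(x)), at = at, p_at = p,
                fit = NULL))
  }
  fit <- stats::glm(c01 ~ splines::bs(d, df = df), family = stats::binomial())
  pred <- function(x) {
    as.numeric(stats::predict(fit, newdata = data.frame(d = x),
                              type = "response"))
  }
  list(predict = pred, at = at, p_at = pred(at), fit = fit)
}

#' Evoked spike-triggered average
#'
#' Average receiver firing rate around sender spikes, minus the baseline rate
#' in a pre-spike window; returns the peak signed deviation in Hz. Self-pairs
#' are rejected (the autocorrelation is not an interaction).
#'
#' @param sender,receiver spike-count vectors on the same time grid.
#' @param window post-spike lag window in bins (default 1..6, i.e. 36 ms).
#' @param baseline_window pre-spike window in bins used as baseline (default
#'   -6..-1).
#' @param bin_width bin width in seconds.
#' @return The peak deviation from baseline in Hz, with the full STA (Hz per
#'   lag) in `attr(, "sta")` and the baseline in `attr(, "baseline")`.
#' @export
evoked_sta <- function(sender, receiver, window = 1:6,
                       baseline_window = -6:-1, bin_width = 0.006) {
  if (identical(sender, receiver))
    stop("self-pairs are rejected: evoked STA needs distinct units")
  if (length(sender) != length(receiver)) stop("length mismatch")
  spk <- which(sender > 0)
  if (length(spk) == 0L) stop("sender has no spikes: STA undefined")
  n <- length(receiver)
  avg_at <- function(lags) {
    vapply(lags, function(l) {
      idx <- spk + l
      ok <- idx >= 1L & idx <= n
      w <- sender[spk[ok]]
      sum(w * receiver[idx[ok]]) / sum(w) / bin_width
    }, numeric(1))
  }
  sta <- avg_at(window)
  baseline <- mean(avg_at(baseline_window))
  dev <- sta - baseline
  peak <- dev[which.max(abs(dev))]
  structure(peak, sta = sta, baseline = baseline, lags = window)
}

#' Tuning gain and stability across contexts
#'
#' Stability is the Pearson correlation between a unit's tuning curves in the
#' two contexts (on a common grid); the gain is the slope of the
#' through-the-data linear regression of the low-density curve on the
#' high-density curve, computed only for stably tuned units (r > 0.5), which
#' is the stability criterion applied before any gain analysis.
#'
#' @param curve_high,curve_low tuning-curve values on a common grid.
#' @param r_threshold stability threshold below which the unit is excluded
#'   from the gain analysis.
#' @return A list with `stability`, `gain` (NA when excluded), `excluded`.
#' @export
tuning_gain_and_stability <- function(curve_high, curve_low,
                                      r_threshold = 0.5) {
  if (length(curve_high) != length(curve_low)) stop("curves on different grids")
  if (stats::sd(curve_high) == 0 || stats::sd(curve_low) == 0) {
    warning("zero-variance tuning curve")
    return(list(stability = NA_real_, gain = NA_real_, excluded = TRUE))
  }
  r <- stats::cor(curve_high, curve_low)
  if (r > r_threshold) {
    fit <- stats::lm(curve_low ~ curve_high)
    list(stability = r, gain = unname(stats::coef(fit)["curve_high"]),
         excluded = FALSE)
  } else {
    list(stability = r, gain = NA_real_, excluded = TRUE)
  }
}

#' Session retention filter
#'
#' Retains sessions with at least `min_coupled` coupled units and a mean
#' encoding-model pseudo-R-squared above `min_pseudo_r2`, the inclusion
#' criteria applied before any cross-session statistic.
#'
#' @param summaries data frame with `n_coupled` and `pseudo_r2` per session.
#' @param min_coupled minimum coupled-unit count (default 5).
#' @param min_pseudo_r2 minimum mean pseudo-R-squared (default 0.01).
#' @return The retained rows.
#' @export
session_filter <- function(summaries, min_coupled = 5L, min_pseudo_r2 = 0.01) {
  keep <- summaries$n_coupled >= min_coupled &
    summaries$pseudo_r2 > min_pseudo_r2
  summaries[keep, , drop = FALSE]
}

#' Extract directed coupling records from fitted encoding models
#'
#' One row per (receiver fit, sender) coupling block: strength (L2 norm of
#' the coefficient block), inclusion p-value, significance at p < 0.001,
#' electrode distance, and the kernel evaluated at every lag bin.
#'
#' @param fits named list of [pgam()] fits, one per receiver unit; names are
#'   unit labels matching the sender columns used at fit time.
#' @param units optional unit metadata (`unit`, `elec_x`, `elec_y`) for
#'   electrode distances.
#' @param condition,session labels carried into the output.
#' @param alpha significance threshold on the inclusion test.
#' @return A data frame with the kernel matrix in `attr(, "kernels")`.
#' @export
coupling_records <- function(fits, units = NULL, condition = "high",
                             session = 1L, alpha = 0.001) {
  rows <- list(); kerns <- list()
  for (rec in names(fits)) {
    fit <- fits[[rec]]
    cps <- grep("^coupling_", names(fit$blocks), value = TRUE)
    for (nm in cps) {
      snd <- sub("^coupling_", "", nm)
      beta <- fit$coefficients[fit$blocks[[nm]]$cols]
      kern <- drop(build_basis(fit$blocks[[nm]]$spec) %*% beta)
      dist <- NA_real_
      if (!is.null(units)) {
        i <- match(rec, paste0("unit", units$unit))
        j <- match(snd, paste0("unit", units$unit))
        if (!is.na(i) && !is.na(j))
          dist <- sqrt((units$elec_x[i] - units$elec_x[j])^2 +
                         (units$elec_y[i] - units$elec_y[j])^2)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        session = session, condition = condition, sender = snd,
        receiver = rec, distance = dist,
        strength = coupling_strength(beta),
        p_value = fit$p_values[[nm]],
        significant = fit$p_values[[nm]] < alpha)
      kerns[[length(kerns) + 1L]] <- kern
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "kernels") <- do.call(rbind, kerns)
  out
}
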