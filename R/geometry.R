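# Latent population dynamics: rate estimation by Gaussian smoothing, linear
# time-warping of trials to a common length, condition-averaged PCA of the
# stacked category-mean trajectories, and a permutation d-prime test comparing
# trajectory distances within and between density contexts.

#' Estimate instantaneous firing rates by Gaussian smoothing
#'
#' Convolves each unit's spike counts with a Gaussian kernel (sd 100 ms by
#' default) normalized to unit mass, so the total spike count is preserved,
#' and converts to spikes/s.
#'
#' @param counts units x bins matrix (a `spike_counts` or plain matrix).
#' @param sigma kernel sd in seconds.
#' @param bin_width bin width in seconds (taken from the object if present).
#' @return A units x bins matrix of rates in spikes/s.
#' @export
estimate_rates <- function(counts, sigma = 0.1, bin_width = NULL) {
  if (sigma <= 0) stop("sigma must be positive")
  bin_width <- bin_width %||% attr(counts, "bin_width") %||% 0.006
  k <- gaussian_kernel(sigma / bin_width)
  m <- unclass(counts)
  out <- t(apply(m, 1, conv_same, kernel = k)) / bin_width
  dimnames(out) <- dimnames(m)
  out
}

#' Linearly time-warp a trial to a fixed number of points
#'
#' Linear interpolation of each unit's rate series onto `T_out` equally
#' spaced points spanning the trial; the first and last samples are preserved
#' exactly.
#'
#' @param rates units x bins rate matrix for one trial (a vector is treated
#'   as one unit).
#' @param T_out number of output time points.
#' @return A units x `T_out` matrix.
#' @export
timewarp <- function(rates, T_out = 100L) {
  if (is.null(dim(rates))) rates <- matrix(rates, nrow = 1)
  n <- ncol(rates)
  if (n < 2L) stop("trial shorter than 2 bins cannot be warped")
  xo <- seq(1, n, length.out = T_out)
  t(apply(rates, 1, function(r) stats::approx(seq_len(n), r, xout = xo)$y))
}

#' Condition-averaged PCA of warped population trajectories
#'
#' Groups trials into categories (target-location bin x density), averages the
#' warped rates within each category, stacks the category means into a
#' `(T * C * D) x N` matrix, and computes its PCA (column-centered). Each
#' category's mean trajectory is returned projected on the axes.
#'
#' @param warped list of trials, each a units x T warped rate matrix.
#' @param category factor/vector of category labels, one per trial; empty
#'   categories are dropped with a warning.
#' @param n_components number of axes to keep (default all).
#' @return A `latent_trajectories` object: `rotation` (axes, orthonormal
#'   columns), `explained` (variance ratios, nonincreasing), `projections`
#'   (list per category of T x k matrices), `center`, `category_means`.
#' @export
condition_average_pca <- function(warped, category, n_components = NULL) {
  stopifnot(length(warped) == length(category))
  N <- nrow(warped[[1]])
  if (N < 2L) stop("population PCA needs at least 2 units")
  cats <- unique(as.character(category))
  means <- list()
  for (cc in cats) {
    idx <- which(as.character(category) == cc)
    if (length(idx) == 0L) next
    means[[cc]] <- Reduce(`+`, warped[idx]) / length(idx)
  }
  if (length(means) < length(cats))
    warning("dropped empty categories")
  stacked <- do.call(rbind, lapply(means, t))   # (T*C*D) x N
  pc <- stats::prcomp(stacked, center = TRUE, scale. = FALSE)
  k <- n_components %||% ncol(pc$rotation)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  proj <- lapply(means, function(m)
    scale(t(m), center = pc$center, scale = FALSE) %*%
      pc$rotation[, seq_len(k), drop = FALSE])
  structure(list(rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 explained = expl[seq_len(k)], center = pc$center,
                 projections = proj, category_means = means,
                 n_units = N),
            class = "latent_trajectories")
}

#' @export
print.latent_trajectories <- function(x, ...) {
  cat(sprintf("latent_trajectories: %d units, %d categories, PC1 %.1f%% var\n",
              x$n_units, length(x$projections), 100 * x$explained[1]))
  invisible(x)
}

#' Permutation d-prime test of cross-context trajectory stability
#'
#' PCA axes are fit on all (rewarded) trials of the session. Then, per
#' resample: draw a reference high-density trial; draw one high- and one
#' low-density comparison trial whose target lies within the match radius of
#' the reference trial's target; project all three on the first `d` axes; and
#' record the Frobenius distances reference-to-same-density and
#' reference-to-other-density. After all resamples,
#' `d' = (mu_between - mu_within) / sqrt((var_between + var_within) / 2)`,
#' repeated for 1..`max_dims` retained components. A d-prime near zero means
#' the latent dynamics are interchangeable across contexts.
#'
#' @param warped list of warped rate matrices (units x T), one per trial.
#' @param target n x 2 matrix of target positions (cm) per trial.
#' @param density per-trial context labels (`"high"`/`"low"`).
#' @param n_perm number of resamples.
#' @param match_radius target-matching radius in the units of `target`
#'   (default 10 cm).
#' @param max_dims compute d-prime for 1..max_dims retained components.
#' @param seed integer seed.
#' @return A `dprime_result`: `dprime` (per dimension count), `within` and
#'   `between` distance matrices (resamples x dims), `n_success`,
#'   `low_confidence` flag (fewer than 100 successful resamples).
#' @export
trajectory_dprime <- function(warped, target, density, n_perm = 1000L,
                              match_radius = 10, max_dims = 10L, seed = 1L) {
  stopifnot(length(warped) == length(density), nrow(target) == length(warped))
  N <- nrow(warped[[1]])
  max_dims <- min(max_dims, N)
  stacked <- do.call(rbind, lapply(warped, t))
  pc <- stats::prcomp(stacked, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(max_dims), drop = FALSE]
  proj <- lapply(warped, function(m)
    scale(t(m), center = pc$center, scale = FALSE) %*% rot)
  hi <- which(density == "high"); lo <- which(density == "low")
  if (length(hi) < 2L || length(lo) < 1L)
    stop("need at least two high-density and one low-density trial")
  set.seed(derive_seed(seed, "dprime_resampling"))
  within <- matrix(NA_real_, n_perm, max_dims)
  between <- matrix(NA_real_, n_perm, max_dims)
  n_success <- 0L
  for (i in seq_len(n_perm)) {
    ref <- sample(hi, 1L)
    d2 <- sqrt((target[, 1] - target[ref, 1])^2 +
                 (target[, 2] - target[ref, 2])^2)
    cand_hi <- setdiff(hi[d2[hi] <= match_radius], ref)
    cand_lo <- lo[d2[lo] <= match_radius]
    if (length(cand_hi) == 0L || length(cand_lo) == 0L) next
    a <- proj[[ref]]
    b <- proj[[if (length(cand_hi) == 1L) cand_hi else sample(cand_hi, 1L)]]
    c_ <- proj[[if (length(cand_lo) == 1L) cand_lo else sample(cand_lo, 1L)]]
    n_success <- n_success + 1L
    for (d in seq_len(max_dims)) {
      within[i, d] <- sqrt(sum((a[, 1:d, drop = FALSE] - b[, 1:d, drop = FALSE])^2))
      between[i, d] <- sqrt(sum((a[, 1:d, drop = FALSE] - c_[, 1:d, drop = FALSE])^2))
    }
  }
  ok <- stats::complete.cases(within[, 1], between[, 1])
  dprime <- vapply(seq_len(max_dims), function(d) {
    w <- within[ok, d]; b <- between[ok, d]
    (mean(b) - mean(w)) / sqrt((stats::var(b) + stats::var(w)) / 2)
  }, numeric(1))
  structure(list(dprime = dprime, within = within[ok, , drop = FALSE],
                 between = between[ok, , drop = FALSE],
                 n_success = n_success, n_perm = n_perm,
                 match_radius = match_radius,
                 low_confidence = n_success < 100L),
            class = "dprime_result")
}

#' @export
print.dprime_result <- function(x, ...) {
  cat(sprintf("trajectory d-prime: %s (dims 1..%d), %d/%d resamples%s\n",
              paste(sprintf("%.2f", x$dprime), collapse = " "),
              length(x$dprime), x$n_success, x$n_perm,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Segment, smooth, and warp a session into per-trial trajectories
#'
#' Convenience wrapper: estimates rates, segments each trial from target
#' onset to movement offset, and time-warps to a common length. Trials
#' shorter than two bins are dropped.
#'
#' @param counts units x bins `spike_counts`.
#' @param cov the session `covariate_frame`.
#' @param trials the trial table.
#' @param T_out warped length.
#' @param sigma smoothing sd in seconds.
#' @param rewarded_only restrict to rewarded trials (the default, matching
#'   the latent-dynamics analyses).
#' @return A list with `warped` (list of units x T matrices), `trials` (the
#'   rows used), `target` (n x 2 cm), `density`.
#' @export
warp_session <- function(counts, cov, trials, T_out = 100L, sigma = 0.1,
                         rewarded_only = TRUE) {
  rates <- estimate_rates(counts, sigma = sigma, bin_width = cov$bin_width)
  use <- if (rewarded_only) trials[trials$rewarded, , drop = FALSE] else trials
  warped <- list(); keep <- logical(nrow(use))
  for (i in seq_len(nrow(use))) {
    tr <- use$trial_id[i]
    bins <- which(cov$trial == tr & cov$time >= use$t_target_on[i] &
                    cov$time <= use$t_move_off[i])
    if (length(bins) < 2L) next
    keep[i] <- TRUE
    warped[[length(warped) + 1L]] <- timewarp(rates[, bins, drop = FALSE], T_out)
  }
  use <- use[keep, , drop = FALSE]
  list(warped = warped,
       trials = use,
       target = cbind(use$target_x, use$target_y) * 100,
       density = use$density)
}
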