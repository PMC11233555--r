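# Penalized Poisson GAM core: log mu_t = sum_j f_j(x_jt) + sum_k (f_k * z_k)_t,
# each f on a B-spline basis with an integrated-squared-curvature penalty
# -0.5 * lambda_f * t(beta_f) S_f beta_f. Fitting is penalized Newton (IRLS)
# with step halving; the posterior covariance is the inverse penalized
# negative Hessian at the optimum.

#' Penalized Poisson log-likelihood
#'
#' The Poisson log-likelihood of the counts under rate `exp(X beta)` plus the
#' curvature penalties `-0.5 * lambda_f * t(beta_f) S_f beta_f`.
#'
#' @param beta coefficient vector (length `ncol(design$X)`).
#' @param lambda scalar or named per-block penalty scales.
#' @param design a [build_design()] object.
#' @param y nonnegative integer counts, one per design row.
#' @return The penalized log-likelihood (a scalar).
#' @export
penalized_loglik <- function(beta, lambda, design, y) {
  if (any(y < 0) || any(y != floor(y))) stop("counts must be nonnegative integers")
  if (length(y) != nrow(design$X)) stop("length(y) must match design rows")
  eta <- drop(design$X %*% beta)
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  P <- full_penalty(design, lambda)
  poisson_loglik(y, exp(eta)) - 0.5 * drop(crossprod(beta, P %*% beta))
}

#' Maximize the penalized likelihood at fixed smoothness
#'
#' Penalized iteratively reweighted least squares (Newton with step halving).
#' Returns the maximizer, its posterior covariance (inverse penalized negative
#' Hessian), and convergence diagnostics. Non-convergence within the iteration
#' cap is flagged, not silent.
#'
#' @param design a [build_design()] object.
#' @param y counts.
#' @param lambda scalar or named per-block penalty scales.
#' @param beta_init optional warm start.
#' @param tol relative objective-change tolerance.
#' @param max_iter iteration cap.
#' @param hessian if FALSE, skip the covariance computation (used inside CV).
#' @return A list with `beta`, `vcov` (posterior), `fisher` (unpenalized
#'   information at the optimum), `loglik`, `converged`, `grad_norm`, `iter`.
#' @export
fit_beta <- function(design, y, lambda, beta_init = NULL, tol = 1e-8,
                     max_iter = 100L, hessian = TRUE) {
  X <- design$X
  if (any(y < 0)) stop("counts must be nonnegative")
  P <- full_penalty(design, lambda)
  p <- ncol(X)
  beta <- beta_init %||% c(log(max(mean(y), 1e-8)), rep(0, p - 1L))
  eta <- pmin(drop(X %*% beta), 30)
  mu <- exp(eta)
  obj <- poisson_loglik(y, mu) - 0.5 * drop(crossprod(beta, P %*% beta))
  converged <- FALSE
  iter <- 0L
  grad <- rep(NA_real_, p)
  for (iter in seq_len(max_iter)) {
    grad <- drop(crossprod(X, y - mu)) - drop(P %*% beta)
    H <- crossprod(X * sqrt(mu)) + P
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) {
      bad <- names(which(sapply(design$blocks, function(b)
        any(diag(H)[b$cols] < 1e-10))))
      stop("singular penalized Hessian",
           if (length(bad)) paste0(" in block(s): ", paste(bad, collapse = ", ")))
    }
    delta <- backsolve(ch, forwardsolve(t(ch), grad))
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      eta_new <- pmin(drop(X %*% beta_new), 30)
      mu_new <- exp(eta_new)
      obj_new <- poisson_loglik(y, mu_new) -
        0.5 * drop(crossprod(beta_new, P %*% beta_new))
      if (is.finite(obj_new) && obj_new >= obj - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { obj_new <- obj; beta_new <- beta; mu_new <- mu; break }
    }
    done <- abs(obj_new - obj) < tol * (abs(obj) + 1)
    beta <- beta_new; mu <- mu_new; obj <- obj_new
    if (done) { converged <- TRUE; break }
  }
  grad <- drop(crossprod(X, y - mu)) - drop(P %*% beta)
  out <- list(beta = stats::setNames(drop(beta), colnames(X)), loglik = obj,
              converged = converged, iter = iter,
              grad_norm = max(abs(grad)))
  if (hessian) {
    H <- crossprod(X * sqrt(mu)) + P
    Vb <- chol2inv(chol(H))
    dimnames(Vb) <- list(colnames(X), colnames(X))
    out$vcov <- Vb
    out$fisher <- H - P
  }
  out$fitted <- mu
  out
}

#' Select the smoothness scale by cross-validation
#'
#' Chooses the penalty scale minimizing the mean held-out unpenalized Poisson
#' deviance across folds, on a log-spaced grid. One shared scale is applied to
#' every penalized block. Folds are formed by trial when a trial index is in
#' the design, else by contiguous chunks. Fits are warm-started along the grid.
#'
#' @param design a [build_design()] object.
#' @param y counts.
#' @param grid candidate multipliers (default 8 log-spaced points,
#'   1e-2..1e4), applied on the normalized penalty scale: the per-block
#'   penalty is `lambda_f = multiplier / mean(diag(S_f))`, so a multiplier is
#'   comparable across blocks whose domains (and hence curvature scales)
#'   differ by orders of magnitude. One multiplier is selected per block
#'   class ("signal": continuous and event tuning; "temporal": spike-history
#'   and coupling filters) by coordinate descent over the grid, alternating
#'   between the classes until the choice stabilizes (at most `max_passes`
#'   passes).
#' @param folds number of CV folds (>= 2).
#' @param max_passes coordinate-descent passes over the block classes.
#' @return Named numeric vector: the selected scale per penalized block, with
#'   attributes `multiplier` (per class), `cv_deviance` (per grid point,
#'   last pass) and `grid`.
#' @export
select_lambda <- function(design, y, grid = 10^seq(-2, 4, length.out = 8),
                          folds = 5L, max_passes = 2L) {
  if (length(grid) == 0L) stop("empty lambda grid")
  if (folds < 2L) stop("cross-validation needs at least 2 folds")
  grid <- sort(grid, decreasing = TRUE)  # warm-start from smoothest
  ids <- design$trial %||% ceiling(seq_along(y) / (length(y) / folds))
  fold <- fold_ids(ids, folds)
  group_of <- vapply(design$blocks, function(b)
    if (b$class %in% c("history", "coupling")) "temporal" else "signal",
    character(1))
  groups <- intersect(c("signal", "temporal"), unique(group_of))
  mult <- stats::setNames(rep(stats::median(grid), length(groups)), groups)
  if (length(groups) == 1L) max_passes <- 1L
  score <- NULL
  for (pass in seq_len(max_passes)) {
    mult_old <- mult
    for (gr in groups) {
      score <- rep(0, length(grid))
      n_ok <- rep(0L, length(grid))
      for (k in seq_len(folds)) {
        tr <- fold != k
        d_tr <- design
        d_tr$X <- design$X[tr, , drop = FALSE]
        d_tr$trial <- design$trial[tr]
        beta <- NULL
        for (g in seq_along(grid)) {
          m_try <- mult
          m_try[gr] <- grid[g]
          fit <- tryCatch(
            fit_beta(d_tr, y[tr], lambda_from_scale(design, m_try),
                     beta_init = beta, tol = 1e-6, max_iter = 50L,
                     hessian = FALSE),
            error = function(e) NULL)
          if (is.null(fit)) next
          beta <- fit$beta
          mu_te <- exp(pmin(drop(design$X[!tr, , drop = FALSE] %*% fit$beta), 30))
          y_te <- y[!tr]
          dev <- 2 * (ifelse(y_te > 0, y_te * log(y_te / mu_te), 0) -
                        (y_te - mu_te))
          score[g] <- score[g] + mean(dev)
          n_ok[g] <- n_ok[g] + 1L
        }
      }
      if (all(n_ok == 0L)) stop("all cross-validation fits failed")
      score[n_ok < max(n_ok)] <- Inf
      score <- score / pmax(n_ok, 1L)
      mult[gr] <- grid[which.min(score)]
    }
    if (identical(mult, mult_old)) break
  }
  lam <- lambda_from_scale(design, mult)
  attr(lam, "multiplier") <- mult
  attr(lam, "cv_deviance") <- stats::setNames(score, signif(grid, 3))
  attr(lam, "grid") <- grid
  lam
}

# per-block penalty scales from normalized multipliers (scalar, or named per
# block class: "signal" for continuous/event, "temporal" for history/coupling)
lambda_from_scale <- function(design, multiplier) {
  vapply(names(design$S), function(nm) {
    b <- design$blocks[[nm]]
    m <- if (length(multiplier) == 1L && is.null(names(multiplier)))
      as.numeric(multiplier)
    else {
      gr <- if (b$class %in% c("history", "coupling")) "temporal" else "signal"
      as.numeric(multiplier[gr])
    }
    m / b$pen_scale
  }, numeric(1))
}

#' Fit a penalized Poisson GAM encoding model to one unit
#'
#' The model: the unit's log firing rate is a sum of B-spline tuning functions
#' of continuous task covariates plus causal temporal filters convolved with
#' event trains, the unit's own spike history, and other units' spike trains
#' (coupling filters). Each smooth carries an integrated-squared-curvature
#' penalty whose scale is selected by cross-validated held-out deviance. Trials
#' are split 80/20 into train and held-out test sets; fit quality is scored by
#' the likelihood-ratio pseudo-R-squared on both, and by the squared
#' correlation between Gaussian-smoothed counts and the predicted rate.
#'
#' @param y the unit's spike counts per time bin.
#' @param covariates data frame of per-bin continuous covariates (or NULL).
#' @param events data frame of binary event trains (or NULL).
#' @param coupling matrix of other units' counts (bins x sender units, named
#'   columns), or NULL for an uncoupled model.
#' @param history include a spike-history filter (default TRUE).
#' @param trial per-bin trial index; required for the trial-wise train/test
#'   split (when NULL, contiguous pseudo-trials of 500 bins are used).
#' @param specs optional named list of [basis_spec()] overrides.
#' @param lambda penalty scale(s), raw per-block values (scalar recycled);
#'   NULL selects by [select_lambda()] on the training set.
#' @param lambda_scale alternatively, a normalized smoothness multiplier (as
#'   returned in `attr(select_lambda(...), "multiplier")` or stored in a
#'   previous fit's `$lambda_scale`), converted to per-block scales for this
#'   design; convenient for sharing one selected smoothness across units.
#' @param train_frac fraction of trials used for fitting (default 0.8).
#' @param bin_width bin width in seconds (default 0.006).
#' @param cv_folds,lambda_grid passed to [select_lambda()].
#' @param seed seed for the train/test trial split.
#' @return An object of class `pgam`; see [summary.pgam()], [tuning_curve()],
#'   [inclusion_test()], [coupling_records()].
#' @export
pgam <- function(y, covariates = NULL, events = NULL, coupling = NULL,
                 history = TRUE, trial = NULL, specs = NULL, lambda = NULL,
                 lambda_scale = NULL, train_frac = 0.8, bin_width = 0.006,
                 cv_folds = 5L, lambda_grid = 10^seq(-2, 4, length.out = 8),
                 seed = 1L) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(trial)) trial <- ceiling(seq_len(n) / 500)
  design <- build_design(covariates, events,
                         history = if (isTRUE(history)) y else NULL,
                         coupling = coupling, trial = trial, specs = specs)
  if (design$n != n) stop("design rows do not match length(y)")
  tr_ids <- unique(trial)
  set.seed(derive_seed(seed, "train_test_split"))
  n_test <- max(1L, round(length(tr_ids) * (1 - train_frac)))
  test_ids <- sample(tr_ids, n_test)
  is_train <- !(trial %in% test_ids)
  if (sum(y[is_train]) == 0)
    stop("unit has zero spikes in the training trials; flagged unfit")

  d_tr <- design
  d_tr$X <- design$X[is_train, , drop = FALSE]
  d_tr$trial <- trial[is_train]
  if (is.null(lambda)) {
    lambda <- if (!is.null(lambda_scale))
      lambda_from_scale(design, lambda_scale)
    else select_lambda(d_tr, y[is_train], grid = lambda_grid,
                       folds = cv_folds)
  }
  fit <- fit_beta(d_tr, y[is_train], lambda)
  if (!fit$converged)
    warning("penalized IRLS did not converge within the iteration cap")

  # sandwich covariance: asymptotic covariance of the penalized estimator
  Vb <- fit$vcov
  Vf <- Vb %*% fit$fisher %*% Vb

  mu_all <- exp(pmin(drop(design$X %*% fit$beta), 30))
  obj <- structure(list(
    coefficients = fit$beta, blocks = design$blocks, specs = specs,
    lambda = lambda,
    lambda_scale = attr(lambda, "multiplier") %||% lambda_scale,
    vcov = Vb, vcov_freq = Vf,
    converged = fit$converged, grad_norm = fit$grad_norm, iter = fit$iter,
    fitted = mu_all, y = y, trial = trial, is_train = is_train,
    bin_width = bin_width, S = design$S), class = "pgam")

  obj$p_values <- vapply(setdiff(names(design$blocks), character(0)),
                         function(nm) inclusion_test(obj, nm), numeric(1))
  obj$pseudo_r2 <- c(
    train = .pseudo_r2_data(y[is_train], mu_all[is_train], mean(y[is_train])),
    test = .pseudo_r2_data(y[!is_train], mu_all[!is_train], mean(y[is_train])))
  obj$excluded <- is.finite(obj$pseudo_r2["test"]) && obj$pseudo_r2["test"] < 0
  obj$smoothed_r2 <- tryCatch(
    smoothed_r2(y[!is_train], mu_all[!is_train], bin_width = bin_width),
    error = function(e) NA_real_)
  obj
}

.pseudo_r2_data <- function(y, mu, ybar) {
  ll_y <- poisson_loglik(y, pmax(y, 1e-12))
  ll_hat <- poisson_loglik(y, mu)
  ll_bar <- poisson_loglik(y, rep(max(ybar, 1e-12), length(y)))
  if (ll_y == ll_bar) return(NA_real_)
  pseudo_r2(ll_y, ll_hat, ll_bar)
}

#' Likelihood-ratio pseudo-R-squared
#'
#' `1 - (L(y) - L(yhat)) / (L(y) - L(ybar))`: the fraction of the gap between
#' the constant-rate null likelihood and the saturated likelihood that the
#' model closes. Zero when the model is no better than the null, one when it
#' matches the data exactly; negative values (overfitting on held-out data)
#' are allowed and are the exclusion signal used downstream.
#'
#' @param loglik_y saturated log-likelihood of the counts.
#' @param loglik_yhat model log-likelihood.
#' @param loglik_ybar constant-rate null log-likelihood.
#' @return A scalar (at most 1).
#' @export
pseudo_r2 <- function(loglik_y, loglik_yhat, loglik_ybar) {
  if (loglik_y <= loglik_ybar) stop("saturated likelihood must exceed the null")
  1 - (loglik_y - loglik_yhat) / (loglik_y - loglik_ybar)
}

#' Smoothed R-squared of a rate prediction
#'
#' Squared Pearson correlation between the spike counts convolved with a
#' Gaussian kernel (sd 20 ms by default) and the predicted per-bin rate.
#'
#' @param y spike counts.
#' @param mu predicted per-bin mean (same length).
#' @param sigma smoothing sd in seconds.
#' @param bin_width bin width in seconds.
#' @return Squared correlation in `[0, 1]`.
#' @export
smoothed_r2 <- function(y, mu, sigma = 0.020, bin_width = 0.006) {
  if (length(y) != length(mu)) stop("length mismatch")
  ys <- conv_same(y, gaussian_kernel(sigma / bin_width))
  if (stats::sd(ys) == 0) stop("zero-variance smoothed counts")
  stats::cor(ys, mu)^2
}

#' Covariate inclusion test
#'
#' Block Wald chi-square test that a predictor's whole coefficient block is
#' zero, using the asymptotic (sandwich) covariance of the penalized estimator
#' derived from the posterior covariance; degrees of freedom equal the block
#' size. Downstream coupling analyses call a filter significant at p < 0.001.
#'
#' @param fit a [pgam()] fit.
#' @param predictor block name (e.g. `"lin_vel"`, `"coupling_unit3"`).
#' @return The p-value.
#' @export
inclusion_test <- function(fit, predictor) {
  b <- fit$blocks[[predictor]]
  if (is.null(b)) stop("no such predictor block: ", predictor)
  ix <- b$cols
  beta <- fit$coefficients[ix]
  if (all(beta == 0)) return(1)
  V <- fit$vcov_freq[ix, ix, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e)
    solve(V + diag(1e-10 * max(diag(V)), nrow(V))))
  stat <- drop(crossprod(beta, Vi %*% beta))
  stats::pchisq(stat, df = length(ix), lower.tail = FALSE)
}

#' Evaluate a fitted tuning function with confidence band
#'
#' Evaluates `basis %*% beta_f` for one predictor on a grid (continuous terms:
#' covariate values; temporal terms: lag bins), with a pointwise 95 percent
#' interval from the block posterior covariance (delta method; on the log-rate
#' scale).
#'
#' @param fit a [pgam()] fit.
#' @param predictor block name.
#' @param grid evaluation points (default: 100 points over the domain, or
#'   every lag bin for temporal terms).
#' @return A data frame with columns `x`, `estimate`, `lower`, `upper` and
#'   attribute `scale = "log-rate"`.
#' @export
tuning_curve <- function(fit, predictor, grid = NULL) {
  b <- fit$blocks[[predictor]]
  if (is.null(b)) stop("no such predictor block: ", predictor)
  sp <- b$spec
  if (is.null(grid)) {
    grid <- if (sp$class == "continuous")
      seq(sp$domain[1], sp$domain[2], length.out = 100L)
    else seq(sp$domain[1], sp$domain[2])
  }
  if (any(grid < sp$domain[1] | grid > sp$domain[2]))
    stop("grid outside the predictor domain")
  B <- build_basis(sp, grid)
  if (!is.null(b$transform)) B <- B %*% b$transform
  beta <- fit$coefficients[b$cols]
  V <- fit$vcov[b$cols, b$cols, drop = FALSE]
  est <- drop(B %*% beta)
  se <- sqrt(pmax(rowSums((B %*% V) * B), 0))
  out <- data.frame(x = grid, estimate = est,
                    lower = est - 1.96 * se, upper = est + 1.96 * se)
  attr(out, "scale") <- "log-rate"
  attr(out, "predictor") <- predictor
  class(out) <- c("tuning_curve", "data.frame")
  out
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.pgam <- function(x, ...) {
  cat("Penalized Poisson GAM encoding model\n")
  cat(sprintf("  %d time bins (%d train / %d test), %d predictors, %d coefficients\n",
              length(x$y), sum(x$is_train), sum(!x$is_train),
              length(x$blocks), length(x$coefficients)))
  cat(sprintf("  pseudo-R2: train %.4f, held-out %.4f%s\n",
              x$pseudo_r2["train"], x$pseudo_r2["test"],
              if (isTRUE(x$excluded)) "  [flagged: excluded (overfit)]" else ""))
  invisible(x)
}

#' @export
summary.pgam <- function(object, ...) {
  tab <- data.frame(
    predictor = names(object$blocks),
    class = vapply(object$blocks, function(b) b$class, character(1)),
    df = vapply(object$blocks, function(b) length(b$cols), integer(1)),
    strength = vapply(object$blocks, function(b)
      sqrt(sum(object$coefficients[b$cols]^2)), numeric(1)),
    p_value = object$p_values[names(object$blocks)],
    row.names = NULL)
  structure(list(table = tab, pseudo_r2 = object$pseudo_r2,
                 smoothed_r2 = object$smoothed_r2, lambda = object$lambda,
                 converged = object$converged, excluded = object$excluded),
            class = "summary.pgam")
}

#' @export
print.summary.pgam <- function(x, ...) {
  cat("Penalized Poisson GAM fit\n")
  cat(sprintf("  lambda = %.3g, converged = %s\n",
              unname(x$lambda[1]), x$converged))
  cat(sprintf("  pseudo-R2 train %.4f / held-out %.4f, smoothed R2 %.4f\n\n",
              x$pseudo_r2["train"], x$pseudo_r2["test"], x$smoothed_r2))
  print(transform(x$table, p_value = format.pval(p_value, digits = 3)),
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.pgam <- function(object, predictor = NULL, ...) {
  if (is.null(predictor)) return(object$coefficients)
  b <- object$blocks[[predictor]]
  if (is.null(b)) stop("no such predictor block: ", predictor)
  object$coefficients[b$cols]
}

#' Predict from a fitted encoding model
#'
#' @param object a [pgam()] fit.
#' @param newdata optional list with elements `covariates`, `events`,
#'   `coupling`, `history`, `trial` matching the structure the model was fit
#'   with; when NULL the fitted values are returned.
#' @param type `"response"` (per-bin Poisson mean) or `"link"` (log mean).
#' @param ... unused.
#' @export
predict.pgam <- function(object, newdata = NULL, type = c("response", "link"),
                         ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    mu <- object$fitted
    return(if (type == "response") mu else log(mu))
  }
  specs <- lapply(object$blocks, function(b) b$spec)
  transforms <- lapply(object$blocks, function(b) b$transform)
  d <- build_design(newdata$covariates, newdata$events,
                    history = newdata$history,
                    coupling = newdata$coupling,
                    trial = newdata$trial, specs = specs,
                    transforms = transforms)
  if (!identical(names(d$blocks), names(object$blocks)))
    stop("newdata predictors do not match the fitted model")
  eta <- pmin(drop(d$X %*% object$coefficients), 30)
  if (type == "response") exp(eta) else eta
}

#' @export
residuals.pgam <- function(object, type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  y <- object$y; mu <- object$fitted
  if (type == "pearson") return((y - mu) / sqrt(pmax(mu, 1e-12)))
  d <- 2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  sign(y - mu) * sqrt(pmax(d, 0))
}

#' Simulate spike counts from a fitted model
#'
#' Draws Poisson counts conditional on the fitted per-bin rate (i.e. on the
#' realized covariate, event, history and coupling inputs of the recording).
#'
#' @param object a [pgam()] fit.
#' @param nsim number of simulated count vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @export
simulate.pgam <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted
  out <- replicate(nsim, stats::rpois(length(mu), mu))
  as.data.frame(out)
}

#' @export
logLik.pgam <- function(object, ...) {
  tr <- object$is_train
  structure(poisson_loglik(object$y[tr], object$fitted[tr]),
            df = sum(vapply(object$blocks, function(b) length(b$cols),
                            integer(1))) + 1,
            class = "logLik")
}

#' Plot fitted tuning functions and temporal filters
#'
#' One panel per predictor block: the posterior-mean curve on the log-rate
#' scale with its 95 percent band.
#'
#' @param x a [pgam()] fit.
#' @param predictors which blocks to draw (default all).
#' @param ... passed to [graphics::plot()].
#' @export
plot.pgam <- function(x, predictors = names(x$blocks), ...) {
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(predictors)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (nm in predictors) {
    tc <- tuning_curve(x, nm)
    graphics::plot(tc$x, tc$estimate, type = "l",
                   ylim = range(tc$lower, tc$upper),
                   xlab = if (x$blocks[[nm]]$class == "continuous") nm
                          else paste(nm, "(lag, bins)"),
                   ylab = "log-rate", main = nm, ...)
    graphics::lines(tc$x, tc$lower, lty = 2)
    graphics::lines(tc$x, tc$upper, lty = 2)
    graphics::abline(h = 0, col = "grey60")
  }
  invisible(x)
}
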