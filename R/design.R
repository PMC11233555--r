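# Design-matrix construction: one disjoint column block per predictor, plus an
# intercept in column 1. Continuous blocks are the basis evaluated at the
# covariate values, column-centered so each smooth is orthogonal to the
# intercept (the subtracted constants leave the curvature penalty unchanged).
# Temporal blocks (event / history / coupling) are causal convolutions of the
# driving train with the lag basis; lags never cross trial boundaries.

# shift x back by `lag` bins without crossing trial boundaries
lag_within_trials <- function(x, lag, trial) {
  n <- length(x)
  if (lag == 0L) return(x)
  out <- c(rep(0, lag), x[seq_len(n - lag)])
  if (!is.null(trial)) {
    tr_lag <- c(rep(NA, lag), trial[seq_len(n - lag)])
    out[is.na(tr_lag) | tr_lag != trial] <- 0
  }
  out
}

# convolve a driving train with the lag basis of a temporal spec
temporal_block <- function(z, spec, trial) {
  lags <- seq(spec$domain[1], spec$domain[2])
  B <- build_basis(spec, lags)
  X <- matrix(0, length(z), spec$dim)
  nz <- which(z != 0)
  if (length(nz)) {
    for (i in seq_along(lags)) {
      zl <- lag_within_trials(z, as.integer(lags[i]), trial)
      X <- X + tcrossprod(zl, B[i, ])
    }
  }
  X
}

#' Build the model design matrix
#'
#' Assembles the full design from continuous covariates, event trains, and
#' (optionally) other units' spike counts, as one disjoint column block per
#' predictor plus an intercept. Also returns the curvature penalty of each
#' block and the block index map used by the fitter and by all downstream
#' per-predictor statistics.
#'
#' @param covariates data frame (or NULL) of per-bin continuous covariates.
#' @param events data frame (or NULL) of binary per-bin event trains.
#' @param history numeric vector (or NULL) of the unit's own spike counts, for
#'   the spike-history filter.
#' @param coupling matrix (or NULL) of other units' counts, time bins in rows,
#'   one named column per sender unit.
#' @param trial per-bin trial index (or NULL); temporal filters never reach
#'   across trial boundaries.
#' @param specs optional named list of [basis_spec()]s overriding the defaults
#'   (continuous: 10 interior knots at empirical quantiles; events: 300 ms
#'   causal window; history/coupling: 36 ms strictly causal window).
#' @param transforms optional named list of constraint reparameterizations to
#'   reuse (e.g. from a fitted model) instead of deriving them from the data.
#' @return A list with elements `X` (design matrix, intercept first), `blocks`
#'   (per-predictor column spans, specs, and centering constants), and `S`
#'   (per-block penalty matrices).
#' @export
build_design <- function(covariates = NULL, events = NULL, history = NULL,
                         coupling = NULL, trial = NULL, specs = NULL,
                         transforms = NULL) {
  n <- max(nrow(covariates) %||% 0L, nrow(events) %||% 0L,
           length(history), nrow(coupling) %||% 0L)
  if (n == 0L) stop("no predictors supplied")
  cols <- list(`(Intercept)` = matrix(1, n, 1))
  blocks <- list()
  S <- list()
  add_block <- function(name, X, spec, transform = NULL, Smat = NULL) {
    cols[[name]] <<- X
    blocks[[name]] <<- list(spec = spec, class = spec$class,
                            transform = transform)
    S[[name]] <<- Smat %||% penalty_matrix(spec)
  }
  get_spec <- function(name, default) specs[[name]] %||% default

  for (nm in names(covariates) %||% character(0)) {
    x <- covariates[[nm]]
    if (length(x) != n) stop("covariate length mismatch: ", nm)
    if (stats::sd(x, na.rm = TRUE) == 0) {
      warning("dropping constant covariate column: ", nm)
      next
    }
    sp <- get_spec(nm, basis_spec(nm, "continuous", x = x))
    X <- build_basis(sp, x)
    # sum-to-zero constraint: the basis is a partition of unity, so the raw
    # block is confounded with the intercept (and the constant lies in the
    # curvature-penalty null space); reparameterize onto the orthogonal
    # complement of the constraint vector colSums(X)
    Z <- transforms[[nm]] %||%
      qr.Q(qr(matrix(colSums(X), ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
    Sz <- crossprod(Z, penalty_matrix(sp) %*% Z)
    add_block(nm, X %*% Z, sp, transform = Z, Smat = (Sz + t(Sz)) / 2)
  }
  for (nm in names(events) %||% character(0)) {
    z <- events[[nm]]
    if (length(z) != n) stop("event train length mismatch: ", nm)
    if (!all(z %in% c(0, 1))) stop("event train must be binary: ", nm)
    if (sum(z) == 0) {
      warning("dropping empty event train: ", nm)
      next
    }
    sp <- get_spec(nm, basis_spec(nm, "event"))
    add_block(nm, temporal_block(z, sp, trial), sp)
  }
  if (!is.null(history)) {
    if (length(history) != n) stop("history counts length mismatch")
    sp <- get_spec("spike_history", basis_spec("spike_history", "history"))
    add_block("spike_history", temporal_block(history, sp, trial), sp)
  }
  if (!is.null(coupling)) {
    if (is.null(colnames(coupling)))
      colnames(coupling) <- paste0("unit", seq_len(ncol(coupling)))
    for (j in seq_len(ncol(coupling))) {
      nm <- paste0("coupling_", colnames(coupling)[j])
      sp <- get_spec(nm, basis_spec(nm, "coupling"))
      add_block(nm, temporal_block(coupling[, j], sp, trial), sp)
    }
  }
  if (length(cols) < 2L) stop("no usable predictors after filtering")
  for (nm in names(cols))
    colnames(cols[[nm]]) <- if (ncol(cols[[nm]]) == 1L && nm == "(Intercept)")
      nm else paste0(nm, seq_len(ncol(cols[[nm]])))
  X <- do.call(cbind, cols)
  # record column spans
  at <- 1L
  idx <- list()
  for (nm in names(cols)) {
    w <- ncol(cols[[nm]])
    idx[[nm]] <- seq.int(at, at + w - 1L)
    at <- at + w
  }
  for (nm in names(blocks)) {
    blocks[[nm]]$cols <- idx[[nm]]
    # natural scale of the block's penalty; smoothness multipliers are
    # searched on the normalized scale so one multiplier is comparable
    # across blocks with very different domains (cf. mgcv's rescaling)
    blocks[[nm]]$pen_scale <- mean(diag(S[[nm]]))
  }
  structure(list(X = X, blocks = blocks, S = S, trial = trial, n = n),
            class = "pgam_design")
}

# full penalty matrix Sum_f lambda_f S_f embedded in coefficient space
full_penalty <- function(design, lambda) {
  p <- ncol(design$X)
  P <- matrix(0, p, p)
  for (nm in names(design$S)) {
    lam <- if (length(lambda) == 1L) as.numeric(lambda)
           else if (nm %in% names(lambda)) as.numeric(lambda[nm]) else 0
    if (lam != 0) {
      ix <- design$blocks[[nm]]$cols
      P[ix, ix] <- P[ix, ix] + lam * design$S[[nm]]
    }
  }
  P
}
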