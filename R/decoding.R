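# Population decoding of continuous task variables from instantaneous firing
# rates: lasso regression with trial-wise cross-validation, a small
# feed-forward network as a nonlinear reference decoder, unit matching across
# populations, and the tuning-preserving shuffle that destroys noise
# correlations while leaving per-unit signal content intact.

#' Match a population to a reference firing-rate distribution
#'
#' Greedy nearest-rate matching: selects `n` units whose mean firing rates
#' best match a reference rate sample (for area comparisons on an equal
#' footing). Deterministic given the inputs.
#'
#' @param rates units x bins rate matrix.
#' @param n number of units to select (default 10).
#' @param reference numeric vector of reference mean rates; when NULL, the
#'   `n` units closest to the population median rate are taken.
#' @return Integer indices of the selected units.
#' @export
match_population <- function(rates, n = 10L, reference = NULL) {
  m <- rowMeans(rates)
  if (length(m) < n) stop("fewer than n units available")
  if (length(m) == n) return(seq_along(m))
  avail <- seq_along(m)
  ref <- reference %||% rep(stats::median(m), n)
  ref <- rep_len(ref, n)
  picked <- integer(0)
  for (r in sort(ref)) {
    j <- avail[which.min(abs(m[avail] - r))]
    picked <- c(picked, j)
    avail <- setdiff(avail, j)
  }
  sort(picked)
}

# lasso penalty grid: log-spaced multiples of the null-score scale
.lasso_grid <- function(X, y, n = 20L) {
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  lmax <- max(abs(crossprod(Xc, yc))) / length(y)
  lmax * 10^seq(2, -4, length.out = n)
}

#' Lasso decoding of a task variable from population rates
#'
#' Within-context mode: five repetitions, each holding out a distinct 10
#' percent of trials, with the penalty chosen by 5-fold trial-wise
#' cross-validated grid search on the remaining 90 percent; reports the
#' held-out R-squared per repetition. Cross-context mode: train on all
#' high-density bins (penalty by the same CV), evaluate R-squared on all
#' low-density bins.
#'
#' @param rates units x bins rate matrix (from [estimate_rates()]).
#' @param y the per-bin variable to decode.
#' @param trial per-bin trial index (folds are formed by trial).
#' @param mode `"within"` or `"cross"`.
#' @param context per-bin context labels, required for `"cross"` (train on
#'   `"high"`, test on `"low"`).
#' @param seed seed for the repetition split.
#' @return A `decoding_result`: `r2` (per fold), `mean_r2`, `mode`,
#'   `decoder = "lasso"`, `n_units`.
#' @export
lasso_cv_decode <- function(rates, y, trial, mode = c("within", "cross"),
                            context = NULL, seed = 1L) {
  mode <- match.arg(mode)
  X <- t(unclass(rates))
  stopifnot(nrow(X) == length(y), length(trial) == length(y))
  fit_eval <- function(tr_idx, te_idx) {
    grid <- .lasso_grid(X[tr_idx, , drop = FALSE], y[tr_idx])
    cv <- glmnet::cv.glmnet(X[tr_idx, , drop = FALSE], y[tr_idx],
                            alpha = 1, lambda = grid, nfolds = 5,
                            foldid = fold_ids(trial[tr_idx], 5L))
    pred <- as.numeric(stats::predict(cv, X[te_idx, , drop = FALSE],
                                      s = "lambda.min"))
    cv_r2(y[te_idx], pred)
  }
  if (mode == "within") {
    ids <- unique(trial)
    if (length(ids) < 10L) stop("within-context decoding needs >= 10 trials")
    set.seed(derive_seed(seed, "decode_split"))
    ids <- sample(ids)
    tenth <- split(ids, rep_len(seq_len(10L), length(ids)))
    r2 <- vapply(seq_len(5L), function(k) {
      te <- trial %in% tenth[[k]]
      fit_eval(which(!te), which(te))
    }, numeric(1))
  } else {
    if (is.null(context)) stop("cross-context decoding needs context labels")
    tr <- which(context == "high"); te <- which(context == "low")
    if (!length(tr) || !length(te)) stop("both contexts must be present")
    r2 <- fit_eval(tr, te)
  }
  structure(list(r2 = r2, mean_r2 = mean(r2), mode = mode, decoder = "lasso",
                 n_units = ncol(X), folds = length(r2)),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("%s decoding (%s): mean CV R2 = %.3f over %d fold(s)\n",
              x$decoder, x$mode, x$mean_r2, x$folds))
  invisible(x)
}

#' Shuffle counts within bins of a conditioning variable
#'
#' Destroys neuron-to-neuron noise correlations while keeping signal content:
#' the conditioning variable is discretized into `n_bins` quantile bins, and
#' for each neuron independently the counts at time points falling in the
#' same bin (and the same bin of an optional second variable) are permuted.
#' Per-neuron per-bin count multisets are preserved exactly; bins with a
#' single time point are left as the identity.
#'
#' @param counts units x bins count (or rate) matrix.
#' @param y the conditioning variable per bin (e.g. distance to target).
#' @param n_bins number of discretization bins (default 15).
#' @param n_shuffles number of independent shuffles to return (default 10).
#' @param second_variable optional second conditioning variable (e.g. linear
#'   velocity), discretized the same way; permutation is then within joint
#'   bins.
#' @param seed integer seed; each shuffle uses a distinct sub-seed.
#' @return A list of `n_shuffles` shuffled matrices.
#' @export
shuffle_noise_correlations <- function(counts, y, n_bins = 15L,
                                       n_shuffles = 10L,
                                       second_variable = NULL, seed = 1L) {
  m <- unclass(counts)
  stopifnot(ncol(m) == length(y))
  cut_q <- function(v) {
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 2L) return(rep(1L, length(v)))
    as.integer(cut(v, br, include.lowest = TRUE))
  }
  g <- cut_q(y)
  if (!is.null(second_variable)) {
    stopifnot(length(second_variable) == length(y))
    g <- paste(g, cut_q(second_variable))
  }
  groups <- split(seq_along(y), g)
  lapply(seq_len(n_shuffles), function(s) {
    set.seed(derive_seed(seed, paste0("noise_shuffle_", s)))
    out <- m
    for (idx in groups) {
      if (length(idx) < 2L) next
      for (u in seq_len(nrow(m))) out[u, idx] <- m[u, sample(idx)]
    }
    attributes(out) <- attributes(m)
    out
  })
}

#' Shuffle noise correlations separately within each context
#'
#' Applies [shuffle_noise_correlations()] independently to the bins of each
#' context (the shuffle must never move counts between density conditions,
#' which would launder context-specific tuning across contexts).
#'
#' @param counts units x bins matrix.
#' @param y conditioning variable per bin.
#' @param context per-bin context labels.
#' @param ... passed to [shuffle_noise_correlations()] (`n_bins`,
#'   `second_variable` is subset per context automatically when given).
#' @param n_shuffles,seed as in [shuffle_noise_correlations()].
#' @param second_variable optional second conditioning variable per bin.
#' @return A list of `n_shuffles` shuffled matrices.
#' @export
shuffle_within_context <- function(counts, y, context, n_bins = 15L,
                                   n_shuffles = 10L, second_variable = NULL,
                                   seed = 1L) {
  m <- unclass(counts)
  out <- lapply(seq_len(n_shuffles), function(s) m)
  for (ctx in unique(context)) {
    b <- context == ctx
    sh <- shuffle_noise_correlations(
      m[, b, drop = FALSE], y[b], n_bins = n_bins, n_shuffles = n_shuffles,
      second_variable = second_variable[b],
      seed = derive_seed(seed, paste0("ctx_", ctx)))
    for (s in seq_len(n_shuffles)) out[[s]][, b] <- sh[[s]]
  }
  lapply(out, function(x) {
    attributes(x) <- attributes(m)
    x
  })
}

relu <- function(x) pmax(x, 0)

#' Nonlinear decoding with a small feed-forward network
#'
#' A 10-20-1 fully connected network: rectified-linear activations on the
#' input and hidden layers, a linear output, no biases, mean-squared-error
#' loss with an L2 weight penalty, trained with the Adam optimizer (adaptive
#' learning rate via the usual moment estimates), early-stopped on a held-out
#' validation split. Weights are initialized from a normal distribution
#' (sd 0.1). Inputs are scaled by their training sd and the target is
#' centered (added back at prediction), so the bias-free architecture is well
#' posed. The cross-validation protocol matches [lasso_cv_decode()].
#'
#' @param rates units x bins rate matrix (10 units after matching).
#' @param y the per-bin variable to decode.
#' @param trial per-bin trial index.
#' @param mode `"within"` or `"cross"`.
#' @param context per-bin context labels for `"cross"`.
#' @param hidden hidden-layer width (default 20).
#' @param epochs training-epoch cap (default 500).
#' @param l2 L2 penalty on the weights.
#' @param lr Adam step size.
#' @param seed integer seed (initialization and splits).
#' @return A `decoding_result` with `decoder = "ann"`.
#' @export
ann_decode <- function(rates, y, trial, mode = c("within", "cross"),
                       context = NULL, hidden = 20L, epochs = 500L,
                       l2 = 1e-4, lr = 0.01, seed = 1L) {
  mode <- match.arg(mode)
  X <- t(unclass(rates))
  stopifnot(nrow(X) == length(y))
  if (stats::sd(y) == 0) stop("zero-variance target")
  fit_eval <- function(tr_idx, te_idx, tag) {
    xs <- apply(X[tr_idx, , drop = FALSE], 2, stats::sd)
    xs[xs == 0] <- 1
    Xtr <- sweep(X[tr_idx, , drop = FALSE], 2, xs, "/")
    Xte <- sweep(X[te_idx, , drop = FALSE], 2, xs, "/")
    ym <- mean(y[tr_idx])
    net <- .ann_train(Xtr, y[tr_idx] - ym, hidden, epochs, l2, lr,
                      seed = derive_seed(seed, paste0("ann_", tag)))
    pred <- .ann_forward(net, Xte)$yhat + ym
    cv_r2(y[te_idx], pred)
  }
  if (mode == "within") {
    ids <- unique(trial)
    if (length(ids) < 10L) stop("within-context decoding needs >= 10 trials")
    set.seed(derive_seed(seed, "decode_split"))
    ids <- sample(ids)
    tenth <- split(ids, rep_len(seq_len(10L), length(ids)))
    r2 <- vapply(seq_len(5L), function(k) {
      te <- trial %in% tenth[[k]]
      fit_eval(which(!te), which(te), k)
    }, numeric(1))
  } else {
    if (is.null(context)) stop("cross-context decoding needs context labels")
    r2 <- fit_eval(which(context == "high"), which(context == "low"), "cross")
  }
  structure(list(r2 = r2, mean_r2 = mean(r2), mode = mode, decoder = "ann",
                 n_units = ncol(X), folds = length(r2)),
            class = "decoding_result")
}

.ann_forward <- function(net, X) {
  h0 <- relu(X)
  h1 <- relu(h0 %*% t(net$W1))
  list(h0 = h0, h1 = h1, yhat = drop(h1 %*% t(net$W2)))
}

.ann_train <- function(X, y, hidden, epochs, l2, lr, seed,
                       val_frac = 0.1, patience = 20L, batch = 256L) {
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  W1 <- matrix(stats::rnorm(hidden * p, 0, 0.1), hidden, p)
  W2 <- matrix(stats::rnorm(hidden, 0, 0.1), 1, hidden)
  val <- sample.int(n, max(1L, round(val_frac * n)))
  trn <- setdiff(seq_len(n), val)
  mW1 <- vW1 <- W1 * 0; mW2 <- vW2 <- W2 * 0
  b1 <- b2 <- 0.9; b2m <- 0.999; epsa <- 1e-8
  best <- list(W1 = W1, W2 = W2, loss = Inf, since = 0L)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(trn)
    for (start in seq(1L, length(ord), by = batch)) {
      idx <- ord[start:min(start + batch - 1L, length(ord))]
      fw <- .ann_forward(list(W1 = W1, W2 = W2), X[idx, , drop = FALSE])
      err <- fw$yhat - y[idx]
      nb <- length(idx)
      gW2 <- (t(err) %*% fw$h1) * (2 / nb) + 2 * l2 * W2
      dh1 <- (err %*% W2) * (fw$h1 > 0)
      gW1 <- (t(dh1) %*% fw$h0) * (2 / nb) + 2 * l2 * W1
      step <- step + 1L
      upd <- function(W, g, m, v) {
        m <- b1 * m + (1 - b1) * g
        v <- b2m * v + (1 - b2m) * g^2
        mh <- m / (1 - b1^step); vh <- v / (1 - b2m^step)
        list(W = W - lr * mh / (sqrt(vh) + epsa), m = m, v = v)
      }
      u1 <- upd(W1, gW1, mW1, vW1); W1 <- u1$W; mW1 <- u1$m; vW1 <- u1$v
      u2 <- upd(W2, gW2, mW2, vW2); W2 <- u2$W; mW2 <- u2$m; vW2 <- u2$v
    }
    fv <- .ann_forward(list(W1 = W1, W2 = W2), X[val, , drop = FALSE])
    vloss <- mean((fv$yhat - y[val])^2)
    if (vloss < best$loss - 1e-8) {
      best <- list(W1 = W1, W2 = W2, loss = vloss, since = 0L)
    } else {
      best$since <- best$since + 1L
      if (best$since >= patience) break
    }
  }
  list(W1 = best$W1, W2 = best$W2, val_loss = best$loss, epochs = ep)
}
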