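# End-to-end orchestration: simulate -> encode -> coupling -> geometry ->
# decode -> summarize, with the session-retention filters applied before any
# cross-session statistic, plus plain-text session IO.

# short stable hash of a configuration (provenance stamp on outputs)
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Configure a synthetic multi-area experiment
#'
#' Each "area" is a ground-truth population plus the context manipulation
#' distinguishing its low-density regime: an MSTd-like area gain-modulates
#' (tuning and coupling gain), while 7a-like and dlPFC-like areas remap the
#' shape of their coupling kernels (strength-preserving by default).
#'
#' @param areas named list; each element a list with fields `population`
#'   (a [population_config()]) and `manipulation`
#'   (a [context_manipulation()]).
#' @param session a [session_config()] shared across areas.
#' @param n_sessions number of sessions per area.
#' @param stages which analysis stages to run.
#' @param seed master seed.
#' @param output_dir optional directory for CSV outputs (created if missing).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(
    areas = list(
      MSTd = list(population = population_config(n_units = 6L, area = "MSTd",
                                                 coupling_density = 0.3),
                  manipulation = context_manipulation("coupling_gain",
                                                      magnitude = 1.5)),
      dlPFC = list(population = population_config(n_units = 6L, area = "dlPFC",
                                                  coupling_density = 0.3),
                   manipulation = context_manipulation("coupling_remap",
                                                       preserve_strength = TRUE))),
    session = session_config(n_trials = 60L),
    n_sessions = 1L,
    stages = c("behavior", "encoding", "coupling", "decoding"),
    seed = 1L, output_dir = NULL) {
  for (a in areas) {
    if (!inherits(a$population, "population_config") ||
        !inherits(a$manipulation, "context_manipulation"))
      stop("each area needs a population_config and a context_manipulation")
  }
  structure(list(areas = areas, session = session, n_sessions = n_sessions,
                 stages = stages, seed = seed, output_dir = output_dir),
            class = "experiment_config")
}

#' Run a synthetic multi-area experiment end to end
#'
#' For every area and session: simulate the two-context session, summarize
#' behavior, fit per-unit coupled encoding models separately per context,
#' extract coupling records and their cross-context stability, and decode
#' distance to target within and across contexts. Produces a session-level
#' summary table with full provenance (session id, seed, config hash) and,
#' when `output_dir` is set, CSV files per stage.
#'
#' @param config an [experiment_config()].
#' @param encoding_covariates continuous channels entering the encoding
#'   models.
#' @return A list with `summary` (session-level data frame), `details`
#'   (per-area/session objects), and `hash`.
#' @export
run_experiment <- function(config,
                           encoding_covariates = c("lin_vel", "dist_target")) {
  stopifnot(inherits(config, "experiment_config"))
  hash <- config_hash(config)
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("created output directory: ", out_dir)
  }
  summary_rows <- list(); details <- list()
  for (area in names(config$areas)) {
    a <- config$areas[[area]]
    for (ses in seq_len(config$n_sessions)) {
      seed <- derive_seed(config$seed, paste0(area, "_session_", ses))
      scfg <- config$session
      scfg$seed <- seed
      stage <- "simulate"
      res <- tryCatch({
        pop <- sample_ground_truth(a$population, seed = seed)
        sim <- simulate_session(scfg, pop, a$manipulation)
        row <- data.frame(area = area, session = ses, seed = seed,
                          config_hash = hash)
        det <- list(sim = sim)
        if ("behavior" %in% config$stages) {
          stage <- "behavior"
          bs <- behavior_summary(sim$trials, session = ses)
          det$behavior <- bs
          rad <- bs[bs$dimension == "radial", ]
          row$gain_high <- rad$gain[rad$density == "high"][1]
          row$gain_low <- rad$gain[rad$density == "low"][1]
        }
        if (any(c("encoding", "coupling") %in% config$stages)) {
          stage <- "encoding"
          enc <- .fit_session_encoders(sim, encoding_covariates)
          det$fits <- enc
          row$mean_pseudo_r2 <- mean(enc$pseudo_r2, na.rm = TRUE)
          if ("coupling" %in% config$stages) {
            stage <- "coupling"
            cpl <- .session_coupling(enc, sim)
            det$coupling <- cpl
            row$n_coupled <- cpl$n_coupled
            row$mean_stability <- cpl$mean_stability
            row$strength_ratio <- cpl$strength_ratio
          }
        }
        if ("decoding" %in% config$stages) {
          stage <- "decoding"
          dec <- .session_decoding(sim)
          det$decoding <- dec
          row$within_r2 <- dec$within$mean_r2
          row$cross_r2 <- dec$cross$mean_r2
        }
        if ("geometry" %in% config$stages) {
          stage <- "geometry"
          ws <- warp_session(sim$counts, sim$covariates, sim$trials,
                             T_out = 50L)
          dp <- trajectory_dprime(ws$warped, ws$target, ws$density,
                                  n_perm = 200L, seed = seed)
          det$dprime <- dp
          row$dprime_2d <- dp$dprime[min(2L, length(dp$dprime))]
        }
        list(row = row, det = det)
      }, error = function(e) {
        stop(sprintf("stage '%s' failed for area %s session %d: %s",
                     stage, area, ses, conditionMessage(e)))
      })
      summary_rows[[paste(area, ses)]] <- res$row
      details[[paste(area, ses)]] <- res$det
    }
  }
  nms <- unique(unlist(lapply(summary_rows, names)))
  summary_rows <- lapply(summary_rows, function(r) {
    r[setdiff(nms, names(r))] <- NA
    r[nms]
  })
  summ <- do.call(rbind, summary_rows)
  if (!is.null(out_dir))
    utils::write.csv(summ, file.path(out_dir, "session_summary.csv"),
                     row.names = FALSE)
  list(summary = summ, details = details, hash = hash)
}

# fit coupled encoding models per unit, separately per context
.fit_session_encoders <- function(sim, covariate_names) {
  counts <- unclass(sim$counts)
  cov <- sim$covariates
  U <- nrow(counts)
  fits <- list(high = list(), low = list())
  lscale <- NULL
  pr2 <- c()
  for (ctx in c("high", "low")) {
    ids <- sim$trials$trial_id[sim$trials$density == ctx]
    bins <- cov$trial %in% ids
    for (u in seq_len(U)) {
      fit <- pgam(counts[u, bins],
                  covariates = cov$channels[bins, covariate_names,
                                            drop = FALSE],
                  coupling = t(counts[-u, bins, drop = FALSE]),
                  trial = cov$trial[bins], lambda_scale = lscale,
                  bin_width = cov$bin_width, seed = u)
      if (is.null(lscale)) lscale <- fit$lambda_scale
      fits[[ctx]][[paste0("unit", u)]] <- fit
      pr2 <- c(pr2, fit$pseudo_r2["test"])
    }
  }
  list(fits = fits, pseudo_r2 = pr2, lambda_scale = lscale)
}

# cross-context coupling summary for one session
.session_coupling <- function(enc, sim) {
  units <- attr(sim$counts, "units")
  rec_hi <- coupling_records(enc$fits$high, units, condition = "high")
  rec_lo <- coupling_records(enc$fits$low, units, condition = "low")
  k_hi <- attr(rec_hi, "kernels"); k_lo <- attr(rec_lo, "kernels")
  key <- function(r) paste(r$sender, r$receiver)
  m <- match(key(rec_hi), key(rec_lo))
  stab <- vapply(seq_len(nrow(rec_hi)), function(i)
    suppressWarnings(coupling_stability(k_hi[i, ], k_lo[m[i], ])), numeric(1))
  sig_both <- rec_hi$significant & rec_lo$significant[m]
  list(records = rbind(rec_hi, rec_lo),
       stability = stab, sig_both = sig_both,
       n_coupled = sum(rec_hi$significant),
       mean_stability = mean(stab[sig_both], na.rm = TRUE),
       strength_ratio = mean(rec_lo$strength[m][sig_both]) /
         mean(rec_hi$strength[sig_both]))
}

# within- and cross-context lasso decoding of distance to target
.session_decoding <- function(sim) {
  cov <- sim$covariates
  rates <- estimate_rates(sim$counts, bin_width = cov$bin_width)
  keep <- match_population(rates, n = min(10L, nrow(rates)))
  ctx <- ifelse(cov$trial %in%
                  sim$trials$trial_id[sim$trials$density == "high"],
                "high", "low")
  y <- cov$channels$dist_target
  hi <- ctx == "high"
  list(within = lasso_cv_decode(rates[keep, hi, drop = FALSE], y[hi],
                                cov$trial[hi], mode = "within"),
       cross = lasso_cv_decode(rates[keep, , drop = FALSE], y, cov$trial,
                               mode = "cross", context = ctx))
}

#' Correlate two session-level metrics
#'
#' Pearson correlation across sessions (two-sided, uncorrected), e.g. mean
#' coupling stability against cross-context decoding accuracy.
#'
#' @param summary session-level data frame (after [session_filter()]).
#' @param x,y column names.
#' @param min_sessions minimum sessions required.
#' @return A list with `r`, `p`, `n`.
#' @export
session_correlations <- function(summary, x, y, min_sessions = 5L) {
  xs <- summary[[x]]; ys <- summary[[y]]
  ok <- stats::complete.cases(xs, ys)
  if (sum(ok) < min_sessions)
    stop("need at least ", min_sessions, " sessions after filtering")
  if (stats::sd(xs[ok]) == 0 || stats::sd(ys[ok]) == 0)
    stop("constant metric: correlation undefined")
  ct <- stats::cor.test(xs[ok], ys[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Write a simulated session as a plain-text bundle
#'
#' One directory per session: `trials.csv`, `channels.csv`, `events.csv`,
#' `counts.csv` (units x bins), and `config.yaml`.
#'
#' @param sim a [simulate_session()] result (or a `simulate_behavior()`
#'   result without counts).
#' @param dir target directory (created if needed).
#' @param config the [session_config()] used (written as YAML).
#' @return `dir`, invisibly.
#' @export
write_session <- function(sim, dir, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(sim$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  cov <- sim$covariates
  if (!is.null(cov)) {
    ch <- cbind(time = cov$time, trial = cov$trial, cov$channels)
    utils::write.csv(ch, file.path(dir, "channels.csv"), row.names = FALSE)
    utils::write.csv(cov$events, file.path(dir, "events.csv"),
                     row.names = FALSE)
  }
  if (!is.null(sim$counts))
    utils::write.csv(as.data.frame(unclass(sim$counts)),
                     file.path(dir, "counts.csv"), row.names = TRUE)
  if (!is.null(config))
    yaml::write_yaml(lapply(unclass(config), function(x)
      if (is.numeric(x)) as.numeric(x) else x),
      file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a session bundle written by [write_session()]
#'
#' @param dir the session directory.
#' @return A list with `trials`, `covariates`, `counts` (NULL when absent),
#'   `config`.
#' @export
read_session <- function(dir) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  covariates <- NULL
  if (file.exists(file.path(dir, "channels.csv"))) {
    ch <- utils::read.csv(file.path(dir, "channels.csv"))
    ev <- utils::read.csv(file.path(dir, "events.csv"))
    cfg_bw <- 0.006
    if (file.exists(file.path(dir, "config.yaml")))
      cfg_bw <- yaml::read_yaml(file.path(dir, "config.yaml"))$bin_width
    covariates <- structure(list(
      time = ch$time, trial = ch$trial,
      channels = ch[, setdiff(names(ch), c("time", "trial")), drop = FALSE],
      events = ev, bin_width = cfg_bw, position = NULL),
      class = "covariate_frame")
  }
  counts <- NULL
  if (file.exists(file.path(dir, "counts.csv"))) {
    cdf <- utils::read.csv(file.path(dir, "counts.csv"), row.names = 1)
    counts <- structure(as.matrix(cdf), bin_width = covariates$bin_width %||% 0.006,
                        class = "spike_counts")
  }
  config <- if (file.exists(file.path(dir, "config.yaml")))
    yaml::read_yaml(file.path(dir, "config.yaml")) else NULL
  list(trials = trials, covariates = covariates, counts = counts,
       config = config)
}

#' Expected layout of a deposited recording session (loader stub)
#'
#' The analyses in this package run on simulated sessions; users with access
#' to a deposited dataset can adapt their files to the same bundle layout and
#' use [read_session()]: `trials.csv` with the trial table columns documented
#' there, `channels.csv` / `events.csv` on a uniform 6 ms grid, and
#' `counts.csv` with one row per unit. This function only documents that
#' contract.
#'
#' @param dir a directory in the expected layout.
#' @return See [read_session()].
#' @export
read_recorded_session <- function(dir) {
  read_session(dir)
}
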