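#' Specify a B-spline basis for one model term
#'
#' Every model term — a continuous tuning function, an event response filter, a
#' spike-history filter, or a unit-to-unit coupling filter — is represented on a
#' B-spline basis. Continuous terms live on the value range of the covariate;
#' temporal terms live on a window of time lags measured in bins, with coupling
#' and history filters strictly causal (lags start at 1 bin) and event filters
#' starting at lag 0.
#'
#' Knot placement follows common practice for spike-train encoding models:
#' continuous covariates get interior knots at empirical quantiles (or equally
#' spaced when no data are supplied); temporal filters get raised-cosine-spaced
#' knots, denser at short lags where filter structure concentrates. Boundary
#' knots are replicated to full multiplicity so the basis spans `order` columns
#' plus one per interior knot and forms a partition of unity on the domain.
#'
#' @param name character, the predictor name.
#' @param class one of `"continuous"`, `"event"`, `"history"`, `"coupling"`.
#' @param domain numeric length-2 range. For continuous terms the covariate
#'   value range; for temporal terms the lag window in bins (defaults: coupling
#'   and history `c(1, 6)` i.e. 36 ms at 6 ms bins; event `c(0, 49)`).
#' @param n_interior number of interior knots (default 10 for continuous, 0 for
#'   coupling/history, 4 for event filters).
#' @param order spline order (4 = cubic).
#' @param knots optional full knot vector (overrides placement); must be
#'   nondecreasing with boundary multiplicity `order`.
#' @param x optional data vector; continuous interior knots are placed at its
#'   quantiles.
#' @return An object of class `basis_spec`.
#' @export
basis_spec <- function(name,
                       class = c("continuous", "event", "history", "coupling"),
                       domain = NULL, n_interior = NULL, order = 4L,
                       knots = NULL, x = NULL) {
  class <- match.arg(class)
  order <- as.integer(order)
  if (order < 1L) stop("spline order must be >= 1")
  if (is.null(domain)) {
    domain <- switch(class,
      continuous = if (!is.null(x)) range(x, finite = TRUE) else
        stop("continuous basis needs a domain or data"),
      event = c(0, 49),
      history = c(1, 6),
      coupling = c(1, 6))
  }
  if (length(domain) != 2L || !all(is.finite(domain)) || diff(domain) <= 0)
    stop("domain must be a nonempty ordered range")
  if (class != "continuous" && domain[1] < (if (class == "event") 0 else 1))
    stop("temporal windows must be causal (coupling/history lags start at 1)")
  if (is.null(n_interior)) {
    n_interior <- switch(class, continuous = 10L, event = 4L, 0L)
  }
  if (is.null(knots)) {
    interior <- if (n_interior > 0L) {
      if (class == "continuous" && !is.null(x)) {
        # unique, strictly interior quantiles: point masses in the data must
        # not produce coincident (or boundary-colliding) knots
        q <- unique(stats::quantile(x, probs = seq_len(n_interior) / (n_interior + 1),
                                    names = FALSE, na.rm = TRUE))
        q <- q[q > domain[1] & q < domain[2]]
        eps <- 1e-6 * diff(domain)
        q <- q[c(TRUE, diff(q) > eps)]
        q
      } else if (class == "continuous") {
        seq(domain[1], domain[2], length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
      } else {
        # raised-cosine spacing: dense at short lags
        u <- seq_len(n_interior) / (n_interior + 1)
        domain[1] + diff(domain) * (1 - cos(u * pi / 2))
      }
    } else numeric(0)
    knots <- sort(c(rep(domain[1], order), interior, rep(domain[2], order)))
  } else {
    if (is.unsorted(knots)) stop("knots must be nondecreasing")
    if (length(knots) < 2L * order) stop("too few knots for the given order")
    domain <- range(knots)
  }
  dim <- length(knots) - order
  if (dim < 1L) stop("too few knots for the given order")
  structure(list(name = name, class = class, domain = domain,
                 knots = as.numeric(knots), order = order, dim = dim),
            class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("B-spline basis '%s' (%s): order %d, dim %d, domain [%g, %g]\n",
              x$name, x$class, x$order, x$dim, x$domain[1], x$domain[2]))
  invisible(x)
}

#' Evaluate a B-spline basis
#'
#' Returns the basis evaluation matrix at the supplied points (columns are the
#' basis functions). Points outside the domain give all-zero rows. Inside the
#' domain the columns sum to one (partition of unity).
#'
#' @param spec a [basis_spec()].
#' @param x evaluation points (values for continuous terms, integer lags for
#'   temporal terms). Defaults to a 200-point grid (continuous) or every lag
#'   bin in the window (temporal).
#' @param derivs derivative order to evaluate (0 = the basis itself).
#' @return A `length(x)` by `spec$dim` matrix.
#' @export
build_basis <- function(spec, x = NULL, derivs = 0L) {
  stopifnot(inherits(spec, "basis_spec"))
  if (is.null(x)) {
    x <- if (spec$class == "continuous")
      seq(spec$domain[1], spec$domain[2], length.out = 200L)
    else seq(spec$domain[1], spec$domain[2])
  }
  B <- matrix(0, length(x), spec$dim)
  inside <- is.finite(x) & x >= spec$domain[1] & x <= spec$domain[2]
  if (any(inside)) {
    xi <- x[inside]
    # splineDesign is left-continuous at the right boundary only with a nudge
    xi[xi == spec$domain[2]] <- spec$domain[2] - 1e-9 * max(1, abs(spec$domain[2]))
    B[inside, ] <- splines::splineDesign(spec$knots, xi, ord = spec$order,
                                         derivs = rep(derivs, length(xi)),
                                         outer.ok = TRUE)
  }
  colnames(B) <- paste0(spec$name, seq_len(spec$dim))
  B
}

#' Curvature penalty matrix of a B-spline basis
#'
#' Computes `S = integral of b''(x) b''(x)^T dx` over the basis domain, so that
#' the quadratic form `t(beta) S beta` equals the integrated squared second
#' derivative of the spline with coefficients `beta`. Uses per-interval
#' Gauss-Legendre quadrature, exact for the piecewise-polynomial integrand of
#' any order up to 6.
#'
#' @param spec a [basis_spec()]; requires `order >= 3` so the second derivative
#'   exists.
#' @return A symmetric positive semidefinite `dim x dim` matrix.
#' @export
penalty_matrix <- function(spec) {
  stopifnot(inherits(spec, "basis_spec"))
  if (spec$order < 3L) stop("curvature penalty needs spline order >= 3")
  kn <- unique(spec$knots)
  S <- matrix(0, spec$dim, spec$dim)
  # 3-point Gauss-Legendre nodes/weights on [-1, 1]
  gx <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gw <- c(5, 8, 5) / 9
  for (i in seq_len(length(kn) - 1L)) {
    a <- kn[i]; b <- kn[i + 1L]
    h <- (b - a) / 2
    pts <- a + h * (gx + 1)
    B2 <- splines::splineDesign(spec$knots, pts, ord = spec$order,
                                derivs = rep(2L, length(pts)), outer.ok = TRUE)
    S <- S + h * crossprod(B2 * sqrt(gw), B2 * sqrt(gw))
  }
  dimnames(S) <- list(paste0(spec$name, seq_len(spec$dim)),
                      paste0(spec$name, seq_len(spec$dim)))
  (S + t(S)) / 2
}
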