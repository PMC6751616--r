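#' Finite beta-mixture margin distributions
#'
#' The non-inferiority margin for each safety event is modelled as a
#' distribution on (0, 1) rather than a fixed number: a mixture of at most
#' three beta densities, `sum_k w_k Beta(a_k, b_k)`, fitted from expert
#' elicitation. `beta_mixture()` builds and validates such an object.
#'
#' @param shape1 numeric vector of first beta shape parameters `a_k`
#'   (1 to 3 components), all strictly positive.
#' @param shape2 numeric vector of second shape parameters `b_k`, same
#'   length as `shape1`.
#' @param weights mixture weights `w_k`, non-negative, summing to 1. May be
#'   omitted for a single component. Components with zero weight are
#'   dropped.
#' @param check_density if `TRUE` (default) verify by quadrature that the
#'   density integrates to 1 within 1e-6.
#' @return an object of class `beta_mixture` with elements `shape1`,
#'   `shape2`, `weights` and `k` (number of components).
#' @examples
#' m <- beta_mixture(c(1, 10), c(200, 30), c(0.6, 0.4))
#' mixture_cdf(m, 0.1)
#' @export
beta_mixture <- function(shape1, shape2, weights = NULL, check_density = TRUE) {
  if (length(shape1) != length(shape2))
    stopf("shape1 and shape2 must have the same length")
  if (is.null(weights)) {
    if (length(shape1) != 1L)
      stopf("weights must be supplied for a multi-component mixture")
    weights <- 1
  }
  if (length(weights) != length(shape1))
    stopf("weights must match the number of components")
  if (!is.numeric(shape1) || !is.numeric(shape2) ||
      any(!is.finite(shape1)) || any(!is.finite(shape2)) ||
      any(shape1 <= 0) || any(shape2 <= 0))
    stopf("all shape parameters must be finite and strictly positive")
  if (any(weights < 0)) stopf("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9)
    stopf("weights must sum to 1 (got %.12f)", sum(weights))
  keep <- weights > 0
  shape1 <- shape1[keep]; shape2 <- shape2[keep]; weights <- weights[keep]
  if (length(shape1) < 1L || length(shape1) > 3L)
    stopf("a beta mixture must have 1 to 3 components with positive weight")
  obj <- structure(
    list(shape1 = as.numeric(shape1), shape2 = as.numeric(shape2),
         weights = as.numeric(weights), k = length(shape1)),
    class = "beta_mixture")
  if (check_density) {
    # analytic mass is 1 by construction; the quadrature guards against
    # pathological shapes that break downstream numerics. Piecewise over
    # knots at the component means so that very sharp components are not
    # missed by the adaptive rule.
    knots <- sort(unique(c(0, shape1 / (shape1 + shape2), 1)))
    mass <- sum(vapply(seq_len(length(knots) - 1), function(i)
      stats::integrate(function(x) mixture_density(obj, x),
                       knots[i], knots[i + 1], rel.tol = 1e-9,
                       stop.on.error = FALSE)$value, numeric(1)))
    if (abs(mass - 1) > 1e-6)
      stopf("mixture density integrates to %.8f, not 1", mass)
  }
  obj
}

#' @export
print.beta_mixture <- function(x, ...) {
  cat(sprintf("Beta mixture with %d component(s):\n", x$k))
  for (k in seq_len(x$k))
    cat(sprintf("  w = %.4f  Beta(%.4g, %.4g)  mean = %.4f\n",
                x$weights[k], x$shape1[k], x$shape2[k],
                x$shape1[k] / (x$shape1[k] + x$shape2[k])))
  invisible(x)
}

#' Density, distribution function, sampling and mean of a beta mixture
#'
#' @param mixture a [beta_mixture()].
#' @param x,q evaluation points in \[0, 1\].
#' @param n number of draws.
#' @param seed optional integer seed; draws are reproducible given the seed
#'   and do not disturb the caller's RNG state.
#' @return `mixture_density` and `mixture_cdf` return numeric vectors;
#'   `mixture_sample` a numeric vector of `n` draws; `mixture_mean` a
#'   scalar.
#' @export
mixture_density <- function(mixture, x) {
  stopifnot(inherits(mixture, "beta_mixture"))
  out <- numeric(length(x))
  for (k in seq_len(mixture$k))
    out <- out + mixture$weights[k] *
      stats::dbeta(x, mixture$shape1[k], mixture$shape2[k])
  out
}

#' @rdname mixture_density
#' @export
mixture_cdf <- function(mixture, q) {
  stopifnot(inherits(mixture, "beta_mixture"))
  if (any(q < 0 | q > 1)) stopf("q must lie in [0, 1]")
  out <- numeric(length(q))
  for (k in seq_len(mixture$k))
    out <- out + mixture$weights[k] *
      stats::pbeta(q, mixture$shape1[k], mixture$shape2[k])
  out
}

#' @rdname mixture_density
#' @export
mixture_sample <- function(mixture, n, seed = NULL) {
  stopifnot(inherits(mixture, "beta_mixture"))
  if (n < 1) stopf("n must be >= 1")
  with_seed(seed, {
    comp <- sample.int(mixture$k, n, replace = TRUE, prob = mixture$weights)
    stats::rbeta(n, mixture$shape1[comp], mixture$shape2[comp])
  })
}

#' @rdname mixture_density
#' @export
mixture_mean <- function(mixture) {
  stopifnot(inherits(mixture, "beta_mixture"))
  sum(mixture$weights * mixture$shape1 / (mixture$shape1 + mixture$shape2))
}

#' Point-mass (degenerate) margin
#'
#' A fixed-number non-inferiority margin, used to compare the
#' distribution-margin approach with the classical fixed-margin one and as
#' a building block in tests.
#'
#' @param value margin location in \[0, 1\].
#' @return an object of class `point_margin`.
#' @export
point_margin <- function(value) {
  assert_scalar_prob(value, "value")
  structure(list(value = value), class = "point_margin")
}

#' @export
print.point_margin <- function(x, ...) {
  cat(sprintf("Point-mass margin at %.4f\n", x$value))
  invisible(x)
}

# Draw n margin values from a beta_mixture, point_margin or bare scalar.
sample_margin <- function(margin, n) {
  if (inherits(margin, "beta_mixture")) {
    comp <- sample.int(margin$k, n, replace = TRUE, prob = margin$weights)
    stats::rbeta(n, margin$shape1[comp], margin$shape2[comp])
  } else if (inherits(margin, "point_margin")) {
    rep(margin$value, n)
  } else if (is.numeric(margin) && length(margin) == 1L && is.finite(margin)) {
    rep(margin, n)
  } else stopf("invalid margin: must be a beta_mixture, point_margin or scalar")
}
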