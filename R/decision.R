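#' Beta priors for the two arms
#'
#' A `prior_pair` holds the beta prior parameters of the event rate in the
#' control arm (`i = 0`) and the experimental arm (`i = 1`).
#'
#' @param alpha0,beta0 control-arm prior shape parameters, > 0.
#' @param alpha1,beta1 experimental-arm prior shape parameters, > 0.
#' @param label optional identifier (1 to 13 for the sensitivity grid of
#'   [build_prior_grid()]).
#' @return an object of class `prior_pair`.
#' @export
prior_pair <- function(alpha0, beta0, alpha1, beta1, label = NULL) {
  vals <- c(alpha0, beta0, alpha1, beta1)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("all prior parameters must be finite and > 0")
  structure(list(control = c(shape1 = alpha0, shape2 = beta0),
                 experimental = c(shape1 = alpha1, shape2 = beta1),
                 label = label),
            class = "prior_pair")
}

#' @export
print.prior_pair <- function(x, ...) {
  cat(sprintf("Prior pair%s: control Beta(%.4g, %.4g), experimental Beta(%.4g, %.4g)\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$control[1], x$control[2],
              x$experimental[1], x$experimental[2]))
  invisible(x)
}

#' Cumulative trial counts per interim analysis
#'
#' Validated container for the sequential count data of one event:
#' cumulative subjects and events per arm at each interim analysis.
#'
#' @param analysis integer analysis indices `l = 1, ..., L` (ascending).
#' @param n0,y0 cumulative subjects and events in the control arm.
#' @param n1,y1 cumulative subjects and events in the experimental arm.
#' @return a data frame of class `trial_counts`.
#' @export
trial_counts <- function(analysis, n0, y0, n1, y1) {
  df <- data.frame(analysis = as.integer(analysis), n0 = n0, y0 = y0,
                   n1 = n1, y1 = y1)
  if (is.unsorted(df$analysis, strictly = TRUE))
    stopf("analysis indices must be strictly increasing")
  for (arm in list(c("y0", "n0"), c("y1", "n1"))) {
    y <- df[[arm[1]]]; n <- df[[arm[2]]]
    if (any(y < 0) || any(y > n))
      stopf("events must satisfy 0 <= Y <= n (%s)", arm[1])
    if (is.unsorted(n) || is.unsorted(y))
      stopf("cumulative counts must be non-decreasing (%s)", arm[1])
  }
  class(df) <- c("trial_counts", "data.frame")
  df
}

#' Conjugate posterior update
#'
#' The binomial likelihood with a beta prior gives a beta posterior in
#' closed form: `Beta(alpha + Y, beta + n - Y)` per arm. No sampler is
#' needed for the posterior itself.
#'
#' @param prior a [prior_pair()].
#' @param counts one analysis row: a list or one-row data frame with
#'   `n0`, `y0`, `n1`, `y1`.
#' @return an object of class `posterior_pair` with beta parameters per
#'   arm.
#' @examples
#' posterior_update(prior_pair(1, 1, 1, 1), list(n0 = 10, y0 = 3, n1 = 10, y1 = 3))
#' @export
posterior_update <- function(prior, counts) {
  stopifnot(inherits(prior, "prior_pair"))
  for (f in c("n0", "y0", "n1", "y1"))
    if (is.null(counts[[f]])) stopf("counts is missing '%s'", f)
  if (counts$y0 > counts$n0 || counts$y1 > counts$n1 ||
      counts$y0 < 0 || counts$y1 < 0)
    stopf("events must satisfy 0 <= Y <= n")
  structure(list(
    control = c(shape1 = unname(prior$control[1] + counts$y0),
                shape2 = unname(prior$control[2] + counts$n0 - counts$y0)),
    experimental = c(shape1 = unname(prior$experimental[1] + counts$y1),
                     shape2 = unname(prior$experimental[2] + counts$n1 - counts$y1))),
    class = "posterior_pair")
}

#' Posterior probability that the excess exceeds the margin distribution
#'
#' Monte-Carlo evaluation of
#' `P(theta1 - theta0 > D | data)`, where `theta_i` are drawn from their
#' conjugate beta posteriors and `D` from the margin distribution (a beta
#' mixture, or a point mass for the classical fixed-margin rule). The
#' integral over the margin is handled by sampling `D` jointly with the
#' posteriors.
#'
#' @param posterior a `posterior_pair` from [posterior_update()].
#' @param margin a [beta_mixture()], [point_margin()] or bare scalar.
#' @param n_samples Monte-Carlo sample size (>= 1000; default 1e5).
#' @param seed integer seed; mandatory for reproducibility.
#' @return a list with `probability`, `mc_se` (binomial standard error of
#'   the Monte-Carlo mean) and `n_samples`.
#' @export
prob_exceeds_margin <- function(posterior, margin, n_samples = 1e5,
                                seed = NULL) {
  stopifnot(inherits(posterior, "posterior_pair"))
  if (n_samples < 1000) stopf("n_samples must be >= 1000")
  with_seed(seed, {
    t1 <- stats::rbeta(n_samples, posterior$experimental[1],
                       posterior$experimental[2])
    t0 <- stats::rbeta(n_samples, posterior$control[1],
                       posterior$control[2])
    x <- sample_margin(margin, n_samples)
    p <- mean(t1 - t0 > x)
    list(probability = p,
         mc_se = sqrt(p * (1 - p) / n_samples),
         n_samples = as.integer(n_samples))
  })
}

#' Threshold decision
#'
#' Concludes an unacceptable excess when the posterior probability reaches
#' the prespecified threshold; the comparison is closed (`>=`).
#'
#' @param probability posterior probability in \[0, 1\].
#' @param threshold decision threshold in \[0, 1\].
#' @return logical flag.
#' @export
decide <- function(probability, threshold) {
  assert_scalar_prob(probability, "probability")
  assert_scalar_prob(threshold, "threshold")
  probability >= threshold
}

#' Apply the sequential decision rule over the interim analyses
#'
#' Evaluates the decision rule at each interim analysis in order and
#' reports the first analysis at which the rule fires (the stopping
#' analysis); later analyses are still evaluated for reporting. Raw
#' (unrounded) thresholds are used for every comparison.
#'
#' @param x either a numeric vector of posterior probabilities (one per
#'   analysis), or a [trial_counts()] data frame, in which case `prior`
#'   and `margin` must be supplied and probabilities are computed by
#'   [prob_exceeds_margin()].
#' @param schedule a [solve_schedule()] object, or a numeric vector of
#'   raw thresholds of matching length.
#' @param prior,margin required in counts mode.
#' @param n_samples,seed Monte-Carlo settings for counts mode.
#' @return a data frame of class `monitoring_result` with one row per
#'   analysis (`analysis`, `probability`, `mc_se`, `threshold`, `flag`)
#'   and attribute `stopping_analysis` (`NA` if the rule never fires).
#' @export
monitor_sequential <- function(x, schedule, prior = NULL, margin = NULL,
                               n_samples = 1e5, seed = NULL) {
  thr <- if (inherits(schedule, "threshold_schedule")) schedule$values
         else as.numeric(schedule)
  if (inherits(x, "trial_counts") ||
      (is.data.frame(x) && all(c("n0", "y0", "n1", "y1") %in% names(x)))) {
    if (is.null(prior) || is.null(margin))
      stopf("counts mode requires 'prior' and 'margin'")
    L <- nrow(x)
    if (length(thr) != L)
      stopf("schedule length %d does not match %d analyses", length(thr), L)
    probs <- se <- numeric(L)
    for (l in seq_len(L)) {
      post <- posterior_update(prior, x[l, ])
      r <- prob_exceeds_margin(post, margin, n_samples,
                               seed = if (is.null(seed)) NULL
                                      else derive_seed(seed, l))
      probs[l] <- r$probability; se[l] <- r$mc_se
    }
    analysis <- x$analysis
  } else {
    probs <- as.numeric(x)
    if (length(thr) != length(probs))
      stopf("schedule length %d does not match %d analyses",
            length(thr), length(probs))
    se <- rep(NA_real_, length(probs))
    analysis <- seq_along(probs)
  }
  flag <- probs >= thr
  out <- data.frame(analysis = analysis, probability = probs, mc_se = se,
                    threshold = thr, flag = flag)
  attr(out, "stopping_analysis") <-
    if (any(flag)) analysis[which(flag)[1]] else NA_integer_
  class(out) <- c("monitoring_result", "data.frame")
  out
}

#' @export
print.monitoring_result <- function(x, ...) {
  print.data.frame(data.frame(analysis = x$analysis,
                              probability = round(x$probability, 4),
                              threshold = round(x$threshold, 4),
                              flag = x$flag), row.names = FALSE)
  s <- attr(x, "stopping_analysis")
  cat(if (is.na(s)) "Rule never fired.\n"
      else sprintf("First flagged at analysis %d.\n", s))
  invisible(x)
}

#' The 13-prior sensitivity grid
#'
#' Builds the array of prior pairs compared in the sensitivity analysis:
#' prior 1 is the non-informative `Beta(1,1)` in both arms; priors 2-13
#' cross three prior locations for the arm difference
#' `E(pi1 - pi0)` in `{0, median_difference, control_rate}` with four
#' precision levels `{1, 1/3, 1/10, 1/20}`. Precision `p` scales a base
#' effective sample size `S0`, so each arm's prior satisfies
#' `alpha + beta = p * S0`; the control prior mean is the reference
#' prevalence and the experimental prior mean is shifted by the location.
#'
#' @param control_rate reference prevalence of the event, in (0, 1).
#' @param median_difference median elicited acceptable difference, in
#'   (0, 1).
#' @param base_ess base effective sample size `S0` (default 10).
#' @param eps clamp for the experimental prior mean (default 1e-3).
#' @return a list of 13 [prior_pair()] objects labelled 1 to 13.
#' @export
build_prior_grid <- function(control_rate, median_difference,
                             base_ess = 10, eps = 1e-3) {
  if (!(control_rate > 0 && control_rate < 1))
    stopf("control_rate must lie in (0, 1)")
  if (!(median_difference > 0 && median_difference < 1))
    stopf("median_difference must lie in (0, 1)")
  grid <- vector("list", 13L)
  grid[[1]] <- prior_pair(1, 1, 1, 1, label = 1L)
  locations <- c(0, median_difference, control_rate)
  precisions <- c(1, 1 / 3, 1 / 10, 1 / 20)
  label <- 2L
  for (loc in locations) {
    for (prec in precisions) {
      ess <- prec * base_ess
      m0 <- control_rate
      m1 <- clamp(control_rate + loc, eps, 1 - eps)
      grid[[label]] <- prior_pair(m0 * ess, (1 - m0) * ess,
                                  m1 * ess, (1 - m1) * ess, label = label)
      label <- label + 1L
    }
  }
  grid
}
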