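#' Configuration for margin fitting from elicitation data
#'
#' Collects the numerical knobs of the elicitation module in one validated
#' object, with defaults chosen for routine use.
#'
#' @param criterion goodness-of-fit criterion used to compare fits; one of
#'   `"bic"` (default; penalises extra components), `"aic"`,
#'   `"neg_loglik"` or `"ks"` (Kolmogorov-Smirnov distance). For every
#'   criterion, lower is better.
#' @param eps boundary clamp for elicited differences: values are forced
#'   into `[eps, 1 - eps]` because zero is not an admissible
#'   non-inferiority margin. Default 1e-3.
#' @param n_restarts seeded EM restarts per component count (default 10).
#' @param max_iter maximum EM iterations (default 500).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param shape_bounds bounds for beta shape parameters during
#'   optimisation (default `c(1e-3, 1e4)`).
#' @param weight_grid weight grid for the manual two-component method:
#'   21 values 0, 0.05, ..., 1.
#' @param seed integer seed controlling EM restarts.
#' @return a list of class `elicit_config`.
#' @export
elicit_config <- function(criterion = "bic", eps = 1e-3, n_restarts = 10,
                          max_iter = 500, tol = 1e-6,
                          shape_bounds = c(1e-3, 1e4),
                          weight_grid = seq(0, 1, by = 0.05), seed = 1L) {
  criterion <- match.arg(criterion, criterion_names)
  if (eps <= 0 || eps >= 0.5) stopf("eps must lie in (0, 0.5)")
  if (shape_bounds[1] <= 0 || shape_bounds[2] <= shape_bounds[1])
    stopf("invalid shape_bounds")
  structure(list(criterion = criterion, eps = eps,
                 n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 shape_bounds = shape_bounds, weight_grid = weight_grid,
                 seed = as.integer(seed)),
            class = "elicit_config")
}

make_diagnostics <- function(method_id, mixture, values, chosen_cut = NULL,
                             chosen_weight = NULL, extra = list()) {
  d <- list(method_id = method_id,
            log_likelihood = -unname(fit_criteria(mixture, values)["neg_loglik"]),
            criterion_values = as.list(fit_criteria(mixture, values)),
            chosen_cut = chosen_cut, chosen_weight = chosen_weight)
  c(d, extra)
}

#' Acceptable differences between arms from expert answers
#'
#' Each expert states the maximum event rate `h` they would tolerate in the
#' experimental arm given the reference prevalence; the acceptable
#' difference is `d = h - control_rate`, clamped into `[eps, 1 - eps]`
#' since zero (or a negative value) is not an admissible non-inferiority
#' margin.
#'
#' @param answers data frame of expert answers for a single event, with at
#'   least columns `expert_id`, `event_id` and `acceptable_rate`
#'   (see [read_expert_answers()]).
#' @param control_rate reference prevalence of the event in the control
#'   arm, strictly inside (0, 1).
#' @param config an [elicit_config()] supplying `eps`.
#' @return a list of class `elicited_differences` with `event_id`,
#'   `control_rate`, `differences` (expert order preserved) and
#'   `n_experts`.
#' @export
compute_differences <- function(answers, control_rate,
                                config = elicit_config()) {
  if (is.null(answers) || nrow(answers) == 0L) stopf("no elicitation data")
  need <- c("expert_id", "event_id", "acceptable_rate")
  if (!all(need %in% names(answers)))
    stopf("answers must have columns %s", paste(need, collapse = ", "))
  ev <- unique(answers$event_id)
  if (length(ev) != 1L) stopf("answers mix multiple events: %s",
                              paste(ev, collapse = ", "))
  h <- answers$acceptable_rate
  if (!is_prob(h)) stopf("acceptable_rate values must lie in [0, 1]")
  if (!(control_rate > 0 && control_rate < 1))
    stopf("control_rate must lie strictly inside (0, 1)")
  d <- clamp(h - control_rate, config$eps, 1 - config$eps)
  structure(list(event_id = ev, control_rate = control_rate,
                 differences = as.numeric(d), n_experts = length(d)),
            class = "elicited_differences")
}

#' Fit a beta mixture by EM with component-count selection
#'
#' Fits finite beta mixtures with `K = 1, ..., max_components` components
#' by expectation-maximisation with seeded restarts, then selects K by the
#' configured criterion. This is the first of the three fitting methods
#' compared by [select_margin_fit()].
#'
#' @param values elicited differences strictly inside (0, 1).
#' @param max_components maximal number of components, 1 to 3.
#' @param config an [elicit_config()].
#' @return a list `list(mixture, diagnostics)`; `diagnostics` carries the
#'   log-likelihood trace of the winning EM run (non-decreasing by
#'   construction) and the criterion value of each candidate K.
#' @export
fit_mixture_em <- function(values, max_components = 3,
                           config = elicit_config()) {
  if (max_components < 1 || max_components > 3)
    stopf("max_components must be 1, 2 or 3")
  if (length(unique(values)) < 2L * max_components)
    stopf("need at least %d distinct values", 2L * max_components)
  if (any(values <= 0 | values >= 1))
    stopf("values must lie strictly inside (0, 1)")
  candidates <- list()
  for (K in seq_len(max_components)) {
    if (K == 1L) {
      f <- fit_beta_ml(values, config)
      run <- list(weights = 1, shape1 = f$shape1, shape2 = f$shape2,
                  loglik = f$loglik, loglik_trace = f$loglik, iterations = 1L)
    } else {
      run <- em_fixed_k(values, K, config)
      if (is.null(run)) { warnf("EM failed for K = %d; skipped", K); next }
    }
    mix <- beta_mixture(run$shape1, run$shape2, run$weights)
    candidates[[as.character(K)]] <-
      list(K = K, run = run, mixture = mix,
           criteria = fit_criteria(mix, values))
  }
  if (length(candidates) == 0L) stopf("EM failed for every component count")
  crit <- vapply(candidates, function(c) c$criteria[[config$criterion]],
                 numeric(1))
  best <- candidates[[which.min(crit)]]
  diag <- make_diagnostics(
    "em_mixture", best$mixture, values,
    extra = list(k_selected = best$K,
                 loglik_trace = best$run$loglik_trace,
                 per_k_criterion = crit))
  list(mixture = best$mixture, diagnostics = diag)
}

# Fit both sides of a dichotomisation cut; the left side holds the `cut`
# smallest values. Degenerate sides fall back to a sharp spike.
fit_cut_sides <- function(xs, cut, bounds) {
  fit_side <- function(v) {
    if (length(unique(v)) < 2L) {
      ab <- beta_mom(v[1], 0, bounds)
      list(shape1 = ab[1], shape2 = ab[2], degenerate = TRUE)
    } else {
      f <- beta_ml_suff(beta_suffstats(v), bounds)
      f$degenerate <- FALSE
      f
    }
  }
  list(left = fit_side(xs[seq_len(cut)]),
       right = fit_side(xs[(cut + 1):length(xs)]))
}

#' Fit a two-component mixture by dichotomisation search
#'
#' The second fitting method: the sorted differences are split at every
#' admissible cut (from the split isolating the two smallest values to the
#' split isolating the two largest), a beta density is fitted on each side,
#' and mixtures over the weight grid 0, 0.05, ..., 1 are scored with the
#' configured criterion. The best (cut, weight) pair wins, with
#' `w2 = 1 - w1`.
#'
#' @inheritParams fit_mixture_em
#' @return `list(mixture, diagnostics)`; `diagnostics$chosen_cut` is the
#'   number of values on the left of the retained split and
#'   `diagnostics$chosen_weight` the retained `w1`.
#' @export
fit_manual_two_component <- function(values, config = elicit_config()) {
  n <- length(values)
  if (n < 4L) stopf("need at least 4 values for the dichotomisation search")
  if (any(values <= 0 | values >= 1))
    stopf("values must lie strictly inside (0, 1)")
  xs <- sort(values)
  cuts <- 2:(n - 2)
  grid <- config$weight_grid
  best <- NULL
  for (cut in cuts) {
    sides <- fit_cut_sides(xs, cut, config$shape_bounds)
    any_degen <- sides$left$degenerate || sides$right$degenerate
    if (any_degen)
      warnf("cut %d: a side had < 2 distinct values; spike fallback used", cut)
    # only the configured criterion is evaluated inside the search; the
    # full criterion set is recomputed for the retained fit
    d1 <- stats::dbeta(xs, sides$left$shape1, sides$left$shape2)
    d2 <- stats::dbeta(xs, sides$right$shape1, sides$right$shape2)
    use_ks <- config$criterion == "ks"
    if (use_ks) {
      FL <- stats::pbeta(xs, sides$left$shape1, sides$left$shape2)
      FR <- stats::pbeta(xs, sides$right$shape1, sides$right$shape2)
      iup <- seq_len(n) / n; ilo <- (seq_len(n) - 1) / n
    }
    for (w in grid) {
      dens <- w * d1 + (1 - w) * d2
      if (any(dens <= 0)) next
      k_active <- if (w %in% c(0, 1)) 1L else 2L
      np <- 2 * k_active + (k_active - 1L)
      val <- if (use_ks) {
        Fm <- w * FL + (1 - w) * FR
        max(pmax(abs(iup - Fm), abs(ilo - Fm)))
      } else {
        ll <- sum(log(dens))
        switch(config$criterion, neg_loglik = -ll,
               aic = -2 * ll + 2 * np, bic = -2 * ll + np * log(n))
      }
      if (is.null(best) || val < best$value)
        best <- list(value = val, cut = cut, w = w, sides = sides)
    }
  }
  if (is.null(best)) stopf("dichotomisation search failed")
  s <- best$sides
  mix <- if (best$w == 1) beta_mixture(s$left$shape1, s$left$shape2)
         else if (best$w == 0) beta_mixture(s$right$shape1, s$right$shape2)
         else beta_mixture(c(s$left$shape1, s$right$shape1),
                           c(s$left$shape2, s$right$shape2),
                           c(best$w, 1 - best$w))
  diag <- make_diagnostics("manual_two_component", mix, values,
                           chosen_cut = best$cut, chosen_weight = best$w)
  list(mixture = mix, diagnostics = diag)
}

#' Fit a three-component mixture by the hybrid method
#'
#' The third fitting method combines the previous two: the left component
#' and its weight `w1` come from the retained dichotomisation of
#' [fit_manual_two_component()]; the right side is refitted as a
#' two-component EM mixture whose weights are rescaled by `1 - w1`, giving
#' final weights `(w1, (1 - w1) v1, (1 - w1) v2)`.
#'
#' @inheritParams fit_mixture_em
#' @return `list(mixture, diagnostics)`. When the right side is too small
#'   (or degenerate) for a two-component EM, the two-component result is
#'   returned with a warning.
#' @export
fit_hybrid <- function(values, config = elicit_config()) {
  if (length(values) < 6L) stopf("need at least 6 values for the hybrid fit")
  manual <- fit_manual_two_component(values, config)
  cut <- manual$diagnostics$chosen_cut
  w1 <- manual$diagnostics$chosen_weight
  xs <- sort(values)
  right <- xs[(cut + 1):length(xs)]
  if (length(unique(right)) < 4L || w1 >= 1) {
    warnf("right side unsuitable for 2-component EM; falling back to the two-component fit")
    manual$diagnostics$method_id <- "hybrid"
    return(manual)
  }
  em_right <- tryCatch(em_fixed_k(right, 2L, config), error = function(e) NULL)
  if (is.null(em_right)) {
    warnf("2-component EM failed on the right side; falling back to the two-component fit")
    manual$diagnostics$method_id <- "hybrid"
    return(manual)
  }
  left <- fit_cut_sides(xs, cut, config$shape_bounds)$left
  shapes1 <- c(left$shape1, em_right$shape1)
  shapes2 <- c(left$shape2, em_right$shape2)
  weights <- c(w1, (1 - w1) * em_right$weights)
  mix <- beta_mixture(shapes1, shapes2, weights)
  diag <- make_diagnostics("hybrid", mix, values,
                           chosen_cut = cut, chosen_weight = w1)
  list(mixture = mix, diagnostics = diag)
}

#' Fit the margin distribution by all three methods and keep the best
#'
#' Runs the EM mixture fit, the manual dichotomisation fit and the hybrid
#' fit, compares them on the configured criterion and returns the winner.
#' Ties are broken by fewer components, then by method order
#' (EM, manual, hybrid). Methods whose preconditions fail simply do not
#' compete.
#'
#' @inheritParams fit_mixture_em
#' @return `list(mixture, diagnostics)`; `diagnostics$comparison` is a data
#'   frame with one row per competing method (criterion value and component
#'   count).
#' @export
select_margin_fit <- function(values, config = elicit_config()) {
  methods <- list(
    em_mixture = function() fit_mixture_em(values, 3L, config),
    manual_two_component = function() fit_manual_two_component(values, config),
    hybrid = function() fit_hybrid(values, config))
  fits <- list()
  for (m in names(methods)) {
    f <- tryCatch(suppressWarnings(methods[[m]]()), error = function(e) NULL)
    if (!is.null(f)) fits[[m]] <- f
  }
  if (length(fits) == 0L) stopf("no fitting method succeeded")
  cmp <- data.frame(
    method = names(fits),
    criterion = vapply(fits, function(f)
      f$diagnostics$criterion_values[[config$criterion]], numeric(1)),
    k = vapply(fits, function(f) f$mixture$k, integer(1)),
    row.names = NULL)
  ord <- order(cmp$criterion, cmp$k, match(cmp$method, names(methods)))
  winner <- fits[[cmp$method[ord[1]]]]
  winner$diagnostics$comparison <- cmp
  winner$diagnostics$criterion_used <- config$criterion
  winner
}

#' Median severity weight of an event
#'
#' Experts score the relative severity of each event on \[0, 100\], with
#' death fixed at 100 by convention; the event weight `W` is the median
#' score across experts and drives the class-b misclassification
#' constraint (see [max_class_b()]).
#'
#' @param weights numeric vector of severity scores in \[0, 100\] (one per
#'   expert), or a data frame with a `severity_weight` column.
#' @return the median weight, a scalar.
#' @export
median_weight <- function(weights) {
  if (is.data.frame(weights)) weights <- weights$severity_weight
  if (length(weights) < 1L) stopf("no severity weights")
  if (any(weights < 0 | weights > 100))
    stopf("severity weights must lie in [0, 100]")
  stats::median(weights)
}
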