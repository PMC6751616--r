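#' Simulation settings for operating-characteristics calibration
#'
#' @param n_per_arm planned subjects per arm at the final analysis
#'   (default 162, the expected < 28-week subgroup size).
#' @param L number of interim analyses (default 11).
#' @param accrual cumulative per-arm sample sizes at each analysis; default
#'   equal increments `ceiling(n_per_arm * l / L)`. Must be strictly
#'   increasing with final entry `n_per_arm`.
#' @param n_trials simulated trials per scenario (default 1000).
#' @param mc_samples Monte-Carlo draws per posterior evaluation
#'   (default 1e5; reduce for exploratory runs).
#' @param seed master seed; every random stream is derived from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_per_arm = 162, L = 11, accrual = NULL,
                       n_trials = 1000, mc_samples = 1e5, seed = 1L) {
  if (is.null(accrual)) accrual <- ceiling(n_per_arm * seq_len(L) / L)
  if (length(accrual) != L) stopf("accrual must have length L = %d", L)
  if (is.unsorted(accrual, strictly = TRUE))
    stopf("accrual must be strictly increasing")
  if (accrual[L] != n_per_arm)
    stopf("final accrual entry (%d) must equal n_per_arm (%d)",
          accrual[L], n_per_arm)
  structure(list(n_per_arm = as.integer(n_per_arm), L = as.integer(L),
                 accrual = as.integer(accrual),
                 n_trials = as.integer(n_trials),
                 mc_samples = as.integer(mc_samples),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Build the five calibration scenarios
#'
#' The experimental-arm prevalence is the control prevalence times a
#' scenario multiplier (1, 2/3, 1.5, 2, 3 for scenarios A-E), rounded to
#' two decimals and capped at 1. Truth labels say which decision counts as
#' correct: scenarios become truly "Unacceptable" for an event from a
#' per-event scenario index onwards (default: from scenario C for the two
#' most frequent events, from scenario D for the others, matching the
#' worked four-event configuration).
#'
#' @param theta0 named vector of control-arm prevalences per event, in
#'   (0, 1).
#' @param unacceptable_from integer vector (per event): index of the first
#'   scenario (1 = A, ..., 5 = E) whose difference is truly Unacceptable.
#'   Defaults to `c(3, 3, 4, 4)` for four events; required otherwise.
#' @return a list of 5 scenario objects (`scenario_id`, `index`,
#'   `multiplier`, `theta0`, `theta1`, `truth`).
#' @export
build_scenarios <- function(theta0, unacceptable_from = NULL) {
  if (!is_prob(theta0) || any(theta0 <= 0) || any(theta0 >= 1))
    stopf("control prevalences must lie in (0, 1)")
  J <- length(theta0)
  if (is.null(names(theta0))) names(theta0) <- paste0("event", seq_len(J))
  if (is.null(unacceptable_from)) {
    if (J == 4L) unacceptable_from <- c(3L, 3L, 4L, 4L)
    else stopf("unacceptable_from must be given for %d events", J)
  }
  if (length(unacceptable_from) != J)
    stopf("unacceptable_from must have one entry per event")
  multipliers <- c(1, 2 / 3, 1.5, 2, 3)
  ids <- LETTERS[1:5]
  lapply(1:5, function(s) {
    theta1 <- pmin(1, round(multipliers[s] * theta0, 2))
    names(theta1) <- names(theta0)
    truth <- ifelse(s >= unacceptable_from, "Unacceptable", "Acceptable")
    names(truth) <- names(theta0)
    list(scenario_id = ids[s], index = s, multiplier = multipliers[s],
         theta0 = theta0, theta1 = theta1, truth = truth)
  })
}

#' Severity-weighted class-b misclassification cap
#'
#' The tolerated rate of class-b misclassifications (concluding
#' "Acceptable" when the excess is truly unacceptable) is relaxed for less
#' severe events: `0.1 + 0.5 * (100 - W) / 100` for median severity weight
#' `W`.
#'
#' @param W severity weight(s) in \[0, 100\] (death = 100).
#' @return maximal class-b misclassification rate(s).
#' @examples
#' max_class_b(c(100, 88, 70, 60))  # 0.10 0.16 0.25 0.30
#' @export
max_class_b <- function(W) {
  if (any(W < 0 | W > 100)) stopf("W must lie in [0, 100]")
  0.1 + 0.5 * (100 - W) / 100
}

#' Misclassification constraints for rule selection
#'
#' @param max_class_a maximal class-a rate (falsely concluding an
#'   unacceptable excess), default 0.10.
#' @param max_class_b_per_event named vector of per-event class-b caps,
#'   typically [max_class_b()] of the median severity weights.
#' @return a list of class `constraint_spec`.
#' @export
constraint_spec <- function(max_class_a = 0.10, max_class_b_per_event) {
  if (!is_prob(max_class_a) || !is_prob(max_class_b_per_event))
    stopf("constraint rates must lie in [0, 1]")
  structure(list(max_class_a = max_class_a,
                 max_class_b_per_event = max_class_b_per_event),
            class = "constraint_spec")
}

# Draw cumulative per-arm event counts for n_trials trials of one event:
# increments are Binomial(delta n_l, theta). Returns an L x n_trials matrix.
draw_cumulative_counts <- function(accrual, theta, n_trials) {
  dn <- diff(c(0L, accrual))
  inc <- matrix(stats::rbinom(length(dn) * n_trials, size = dn, prob = theta),
                nrow = length(dn))
  apply(inc, 2, cumsum)
}

# Vectorised posterior probabilities for one event at one analysis across
# trials, chunked to bound memory.
posterior_probs_vec <- function(a1, b1, a0, b0, margin, m) {
  n_trials <- length(a1)
  p <- numeric(n_trials)
  block <- max(1L, floor(2e7 / m))
  for (start in seq(1L, n_trials, by = block)) {
    idx <- start:min(start + block - 1L, n_trials)
    nb <- length(idx)
    t1 <- stats::rbeta(m * nb, rep(a1[idx], each = m), rep(b1[idx], each = m))
    t0 <- stats::rbeta(m * nb, rep(a0[idx], each = m), rep(b0[idx], each = m))
    x <- sample_margin(margin, m * nb)
    p[idx] <- colMeans(matrix(t1 - t0 > x, nrow = m))
  }
  p
}

#' Simulate sequential trials under one scenario
#'
#' Generates `n_trials` trials: cumulative binomial event counts per arm on
#' the accrual grid, conjugate posterior updates at each evaluated
#' analysis, and Monte-Carlo posterior probabilities against each event's
#' margin. With a threshold schedule the sequential rule is applied and a
#' trial concludes "Unacceptable" for an event as soon as it is flagged at
#' any analysis.
#'
#' All streams derive from `config$seed`, the scenario and the event, so
#' the simulated count data are identical across priors and schedules,
#' exactly as in a sensitivity analysis over a fixed set of simulated
#' trials.
#'
#' @param scenario one element of [build_scenarios()].
#' @param config a [sim_config()].
#' @param prior a [prior_pair()] applied to every event, or a named list
#'   of prior pairs, one per event (the sensitivity grid is built per
#'   event from its own control rate, sharing labels across events).
#' @param margins named list of margin objects per event (a single margin
#'   is recycled).
#' @param schedule optional: a [schedule_table()] matrix, a named list of
#'   [solve_schedule()] objects, or `NULL` for probabilities only.
#' @param analyses `"all"` (default) or `"final"` (final-analysis
#'   probabilities only, much faster; no sequential conclusions).
#' @return a list of class `trial_simulation`: `probabilities` (array
#'   trials x analyses x events), `conclusions` (trials x events logical,
#'   `TRUE` = Unacceptable concluded; `NULL` without a schedule),
#'   `scenario_id`, `truth`, `analyses`.
#' @export
simulate_trials <- function(scenario, config, prior, margins,
                            schedule = NULL, analyses = c("all", "final")) {
  analyses <- match.arg(analyses)
  events <- names(scenario$theta0)
  J <- length(events)
  if (inherits(margins, c("beta_mixture", "point_margin")) ||
      (is.numeric(margins) && length(margins) == 1L))
    margins <- stats::setNames(rep(list(margins), J), events)
  if (!all(events %in% names(margins)))
    stopf("margins must be named for every event")
  sched_list <- NULL
  if (!is.null(schedule)) {
    sched_list <- if (is.matrix(schedule)) attr(schedule, "schedules")
                  else schedule
    if (!all(events %in% names(sched_list)))
      stopf("schedule must cover every event")
    if (any(vapply(sched_list[events], function(s) s$L, integer(1)) !=
            config$L))
      stopf("schedule length mismatch: expected L = %d", config$L)
  }
  priors <- if (inherits(prior, "prior_pair"))
    stats::setNames(rep(list(prior), J), events)
  else {
    if (!all(events %in% names(prior)))
      stopf("per-event priors must be named for every event")
    prior
  }
  eval_idx <- if (analyses == "final") config$L else seq_len(config$L)
  Tn <- config$n_trials
  probs <- array(NA_real_, dim = c(Tn, length(eval_idx), J),
                 dimnames = list(NULL, eval_idx, events))
  conclusions <- if (!is.null(sched_list) && analyses == "all")
    matrix(FALSE, Tn, J, dimnames = list(NULL, events)) else NULL
  for (j in seq_len(J)) {
    ev <- events[j]
    with_seed(derive_seed(config$seed, scenario$index, j), {
      y0 <- draw_cumulative_counts(config$accrual, scenario$theta0[j], Tn)
      y1 <- draw_cumulative_counts(config$accrual, scenario$theta1[j], Tn)
      for (ii in seq_along(eval_idx)) {
        l <- eval_idx[ii]
        n_l <- config$accrual[l]
        pr <- priors[[ev]]
        probs[, ii, j] <- posterior_probs_vec(
          a1 = pr$experimental[1] + y1[l, ],
          b1 = pr$experimental[2] + n_l - y1[l, ],
          a0 = pr$control[1] + y0[l, ],
          b0 = pr$control[2] + n_l - y0[l, ],
          margin = margins[[ev]], m = config$mc_samples)
      }
    })
    if (!is.null(conclusions)) {
      thr <- sched_list[[ev]]$values
      conclusions[, j] <-
        rowSums(sweep(probs[, , j, drop = FALSE][, , 1], 2, thr, `>=`)) > 0
    }
  }
  structure(list(probabilities = probs, conclusions = conclusions,
                 scenario_id = scenario$scenario_id, truth = scenario$truth,
                 analyses = analyses),
            class = "trial_simulation")
}

#' Class-a / class-b misclassification accounting
#'
#' Cross-tabulates per-trial conclusions against truth labels. `A` counts
#' trials concluding "Unacceptable" among truly Acceptable trials (class
#' a), `B` trials concluding "Acceptable" among truly Unacceptable trials
#' (class b); `rate_a = A / (A + C)` and `rate_b = B / (B + D)`, `NA` when
#' a denominator is zero.
#'
#' @param conclusions logical (`TRUE` = Unacceptable concluded) or
#'   character (`"Unacceptable"` / `"Acceptable"`) vector.
#' @param truth character or logical vector of truth labels, aligned.
#' @return a list of class `misclassification_table` with `A`, `B`, `C`,
#'   `D`, `rate_a`, `rate_b`.
#' @export
misclassification_rates <- function(conclusions, truth) {
  if (length(conclusions) != length(truth))
    stopf("conclusions and truth labels are not aligned")
  as_u <- function(x) {
    if (is.logical(x)) return(x)
    if (!all(x %in% c("Acceptable", "Unacceptable")))
      stopf("labels must be 'Acceptable' or 'Unacceptable'")
    x == "Unacceptable"
  }
  cu <- as_u(conclusions); tu <- as_u(truth)
  A <- sum(cu & !tu); C <- sum(!cu & !tu)
  B <- sum(!cu & tu); D <- sum(cu & tu)
  structure(list(A = A, B = B, C = C, D = D,
                 rate_a = if (A + C > 0) A / (A + C) else NA_real_,
                 rate_b = if (B + D > 0) B / (B + D) else NA_real_),
            class = "misclassification_table")
}

#' @export
print.misclassification_table <- function(x, ...) {
  cat(sprintf("A=%d B=%d C=%d D=%d  rate_a=%s rate_b=%s\n", x$A, x$B, x$C,
              x$D, format(x$rate_a, digits = 3),
              format(x$rate_b, digits = 3)))
  invisible(x)
}

#' Calibrate final-analysis thresholds over the prior grid
#'
#' For each candidate prior, simulates all scenarios (final analysis
#' only), pools the trials per event with their scenario truth labels, and
#' computes class-a / class-b rates for each candidate final threshold
#' `tau_L` on a grid inside (0.5, 1). By construction `rate_a` is
#' non-increasing and `rate_b` non-decreasing in `tau_L`.
#'
#' @param scenarios list from [build_scenarios()].
#' @param config a [sim_config()].
#' @param prior_grid list of [prior_pair()] objects (e.g.
#'   [build_prior_grid()]), or a list whose elements are themselves named
#'   per-event lists of prior pairs sharing one label.
#' @param margins named list of margins per event.
#' @param threshold_grid candidate final thresholds, strictly inside
#'   (0.5, 1); default `seq(0.51, 0.99, by = 0.01)`.
#' @return a data frame (`prior_label`, `event_id`, `tau_final`, `rate_a`,
#'   `rate_b`) of class `calibration_result`.
#' @export
calibrate_final_thresholds <- function(scenarios, config, prior_grid,
                                       margins,
                                       threshold_grid = seq(0.51, 0.99,
                                                            by = 0.01)) {
  if (any(threshold_grid <= 0.5 | threshold_grid >= 1))
    stopf("threshold grid must lie strictly inside (0.5, 1)")
  if (inherits(prior_grid, "prior_pair")) prior_grid <- list(prior_grid)
  events <- names(scenarios[[1]]$theta0)
  rows <- list()
  for (prior in prior_grid) {
    finals <- lapply(scenarios, function(sc)
      simulate_trials(sc, config, prior, margins, analyses = "final"))
    label <- if (inherits(prior, "prior_pair")) prior$label
             else prior[[1]]$label
    for (ev in events) {
      p <- unlist(lapply(finals, function(f) f$probabilities[, 1, ev]))
      tu <- unlist(lapply(scenarios, function(sc)
        rep(sc$truth[ev] == "Unacceptable", config$n_trials)))
      for (tau in threshold_grid) {
        mt <- misclassification_rates(p >= tau, tu)
        rows[[length(rows) + 1L]] <- data.frame(
          prior_label = if (is.null(label)) NA_integer_ else label,
          event_id = ev, tau_final = tau,
          rate_a = mt$rate_a, rate_b = mt$rate_b)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_result", "data.frame")
  out
}

#' Sequential operating characteristics of the four schedule families
#'
#' Runs the full sequential rule (all interim analyses) for each threshold
#' family, pooling trials over scenarios, and reports per-event class-a /
#' class-b rates. Used to pick the family that keeps overall rates within
#' the constraints.
#'
#' @param scenarios,config,prior,margins as in [simulate_trials()].
#' @param tau_finals named vector of selected final thresholds per event.
#' @param families character vector of families to evaluate.
#' @param tau_first first-analysis anchor (default 0.95).
#' @return data frame (`family`, `event_id`, `rate_a`, `rate_b`).
#' @export
evaluate_families <- function(scenarios, config, prior, margins, tau_finals,
                              families = c("uniform", "linear",
                                           "exponential", "logarithmic"),
                              tau_first = 0.95) {
  events <- names(scenarios[[1]]$theta0)
  rows <- list()
  for (fam in families) {
    sched <- lapply(tau_finals[events], function(tf)
      solve_schedule(fam, config$L, tau_first, tf))
    names(sched) <- events
    sims <- lapply(scenarios, function(sc)
      simulate_trials(sc, config, prior, margins, schedule = sched))
    for (ev in events) {
      cu <- unlist(lapply(sims, function(s) s$conclusions[, ev]))
      tu <- unlist(lapply(scenarios, function(sc)
        rep(sc$truth[ev] == "Unacceptable", config$n_trials)))
      mt <- misclassification_rates(cu, tu)
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, event_id = ev, rate_a = mt$rate_a, rate_b = mt$rate_b)
    }
  }
  do.call(rbind, rows)
}

#' Select the decision rule from calibration results
#'
#' Applies the misclassification constraints to the final-threshold
#' calibration: a (prior, event, `tau_L`) combination is admissible when
#' `rate_a <= max_class_a` and `rate_b <=` the event's class-b cap. One
#' prior common to all events is retained (among priors admissible for
#' every event, the one minimising the summed class-b rates at the chosen
#' thresholds, then the lowest label); per event the smallest admissible
#' `tau_L` is kept, which minimises the class-b rate subject to the
#' class-a cap. If sequential family rates are supplied, the family
#' keeping all rates within the constraints (smallest total
#' misclassification among those) is retained.
#'
#' @param calibration a [calibrate_final_thresholds()] result.
#' @param constraints a [constraint_spec()].
#' @param family_rates optional [evaluate_families()] result.
#' @return a list of class `safety_rule`: `admissible`, `prior_label`,
#'   `tau_final` (named per event), `family`, `rates` (per-event rates at
#'   the retained thresholds), and a `nearest_miss` report when no rule is
#'   admissible.
#' @export
select_rule <- function(calibration, constraints, family_rates = NULL) {
  if (nrow(calibration) == 0L) stopf("empty calibration results")
  stopifnot(inherits(constraints, "constraint_spec"))
  events <- unique(calibration$event_id)
  caps <- constraints$max_class_b_per_event
  if (!all(events %in% names(caps)))
    stopf("class-b caps missing for some events")
  per_prior <- split(calibration, calibration$prior_label)
  candidates <- list()
  misses <- list()
  for (pl in names(per_prior)) {
    pc <- per_prior[[pl]]
    taus <- rates <- stats::setNames(rep(NA_real_, length(events)), events)
    rb <- ra <- taus
    excess <- 0
    ok <- TRUE
    for (ev in events) {
      pe <- pc[pc$event_id == ev, ]
      adm <- !is.na(pe$rate_a) & !is.na(pe$rate_b) &
        pe$rate_a <= constraints$max_class_a & pe$rate_b <= caps[[ev]]
      if (any(adm)) {
        i <- which(adm)[which.min(pe$tau_final[adm])]
        taus[ev] <- pe$tau_final[i]; ra[ev] <- pe$rate_a[i]
        rb[ev] <- pe$rate_b[i]
      } else {
        ok <- FALSE
        excess <- excess + min(pmax(0, pe$rate_a - constraints$max_class_a) +
                               pmax(0, pe$rate_b - caps[[ev]]), na.rm = TRUE)
      }
    }
    if (ok) candidates[[pl]] <- list(prior_label = as.integer(pl),
                                     tau_final = taus, rate_a = ra,
                                     rate_b = rb, total_b = sum(rb))
    else misses[[pl]] <- excess
  }
  if (length(candidates) == 0L) {
    nm <- unlist(misses)
    return(structure(list(
      admissible = FALSE, prior_label = NA_integer_, tau_final = NULL,
      family = NA_character_,
      nearest_miss = data.frame(prior_label = as.integer(names(nm)),
                                constraint_excess = unname(nm))),
      class = "safety_rule"))
  }
  ord <- order(vapply(candidates, `[[`, numeric(1), "total_b"),
               as.integer(names(candidates)))
  best <- candidates[[ord[1]]]
  family <- NA_character_
  fam_detail <- NULL
  if (!is.null(family_rates)) {
    fams <- unique(family_rates$family)
    tot <- adm <- stats::setNames(numeric(length(fams)), fams)
    for (f in fams) {
      fr <- family_rates[family_rates$family == f, ]
      adm[f] <- all(fr$rate_a <= constraints$max_class_a, na.rm = TRUE) &&
        all(fr$rate_b <= caps[fr$event_id], na.rm = TRUE)
      tot[f] <- sum(fr$rate_a, fr$rate_b, na.rm = TRUE)
    }
    pool <- if (any(adm == 1)) fams[adm == 1] else fams
    family <- pool[which.min(tot[pool])]
    fam_detail <- data.frame(family = fams, admissible = as.logical(adm),
                             total_misclassification = unname(tot))
  }
  structure(list(admissible = TRUE, prior_label = best$prior_label,
                 tau_final = best$tau_final,
                 rates = data.frame(event_id = events,
                                    rate_a = unname(best$rate_a[events]),
                                    rate_b = unname(best$rate_b[events])),
                 family = family, family_detail = fam_detail,
                 constraints = constraints),
            class = "safety_rule")
}

#' @export
print.safety_rule <- function(x, ...) {
  if (!x$admissible) {
    cat("No admissible rule under the constraints; nearest misses:\n")
    print(x$nearest_miss, row.names = FALSE)
    return(invisible(x))
  }
  cat(sprintf("Selected prior: %d; family: %s\n", x$prior_label,
              if (is.na(x$family)) "(not evaluated)" else x$family))
  cat("Final thresholds and pooled rates:\n")
  print(cbind(x$rates, tau_final = unname(x$tau_final[x$rates$event_id])),
        row.names = FALSE)
  invisible(x)
}
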