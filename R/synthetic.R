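# Seeded generators for elicitation answers and sequential trial data, so
# the whole pipeline is testable without any external dataset.

#' Specification of the synthetic expert-answer generator
#'
#' The generator emulates the salient feature of real margin elicitations
#' for severe events: a majority of experts tolerate (almost) no excess,
#' producing a spike of differences near zero, while a minority accept a
#' diffuse, clearly positive difference. Differences are drawn from the
#' two-cluster mixture `spike_probability * Beta(spike_shape) +
#' (1 - spike_probability) * Beta(diffuse_shape)` and added to the
#' control rate.
#'
#' @param n_experts number of answering experts (default 43).
#' @param spike_probability weight of the near-zero cluster (default 0.6:
#'   a majority of experts concede essentially no excess).
#' @param spike_shape beta parameters of the near-zero cluster (default
#'   `c(1, 200)`, mean 0.005).
#' @param diffuse_shape beta parameters of the diffuse cluster (default
#'   `c(4, 36)`, mean 0.1).
#' @param weight_sd standard deviation of severity scores around each
#'   event's central weight (default 10; scores are rounded and truncated
#'   to \[0, 100\]).
#' @return a list of class `expert_spec`.
#' @export
expert_spec <- function(n_experts = 43, spike_probability = 0.6,
                        spike_shape = c(1, 200), diffuse_shape = c(4, 36),
                        weight_sd = 10) {
  if (!is_prob(spike_probability)) stopf("spike_probability must be in [0, 1]")
  if (any(c(spike_shape, diffuse_shape) <= 0))
    stopf("cluster shapes must be positive")
  structure(list(n_experts = as.integer(n_experts),
                 spike_probability = spike_probability,
                 spike_shape = spike_shape, diffuse_shape = diffuse_shape,
                 weight_sd = weight_sd),
            class = "expert_spec")
}

#' Generate synthetic expert-elicitation answers
#'
#' @param spec an [expert_spec()].
#' @param events data frame with columns `event_id`, `control_rate` and
#'   `weight_center` (central severity score per event; use 100 for
#'   death).
#' @param seed integer seed.
#' @return a data frame with columns `expert_id`, `event_id`,
#'   `acceptable_rate`, `severity_weight` — the dialect consumed by
#'   [compute_differences()] and [read_expert_answers()].
#' @export
generate_expert_answers <- function(spec, events, seed = 1L) {
  stopifnot(inherits(spec, "expert_spec"))
  need <- c("event_id", "control_rate", "weight_center")
  if (!all(need %in% names(events)))
    stopf("events must have columns %s", paste(need, collapse = ", "))
  E <- spec$n_experts
  with_seed(seed, {
    out <- lapply(seq_len(nrow(events)), function(i) {
      spike <- stats::runif(E) < spec$spike_probability
      d <- ifelse(spike,
                  stats::rbeta(E, spec$spike_shape[1], spec$spike_shape[2]),
                  stats::rbeta(E, spec$diffuse_shape[1], spec$diffuse_shape[2]))
      h <- clamp(events$control_rate[i] + d, 0, 1)
      w <- clamp(round(stats::rnorm(E, events$weight_center[i],
                                    spec$weight_sd)), 0, 100)
      if (events$weight_center[i] >= 100) w <- rep(100, E)  # death convention
      data.frame(expert_id = paste0("E", seq_len(E)),
                 event_id = events$event_id[i],
                 acceptable_rate = h, severity_weight = w)
    })
    do.call(rbind, out)
  })
}

#' Specification of the synthetic sequential trial generator
#'
#' @param theta0,theta1 named per-event prevalences in \[0, 1\] for the
#'   control and experimental arms.
#' @param accrual cumulative per-arm sample sizes at each analysis,
#'   strictly increasing.
#' @return a list of class `trial_spec`.
#' @export
trial_spec <- function(theta0, theta1, accrual) {
  if (!is_prob(theta0) || !is_prob(theta1))
    stopf("prevalences must lie in [0, 1]")
  if (length(theta0) != length(theta1))
    stopf("theta0 and theta1 must have the same length")
  if (is.unsorted(accrual, strictly = TRUE))
    stopf("accrual must be strictly increasing")
  if (is.null(names(theta0)))
    names(theta0) <- names(theta1) <- paste0("event", seq_along(theta0))
  structure(list(theta0 = theta0, theta1 = theta1,
                 accrual = as.integer(accrual)),
            class = "trial_spec")
}

#' Generate one synthetic sequential trial dataset
#'
#' Event counts accrue as independent binomial increments
#' `Binomial(delta n_l, theta)` on the accrual grid and are reported
#' cumulatively, so the count at the final analysis is distributed as a
#' single `Binomial(n_L, theta)` draw.
#'
#' @param spec a [trial_spec()].
#' @param seed integer seed.
#' @return a named list of [trial_counts()] data frames, one per event.
#' @export
generate_trial_dataset <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "trial_spec"))
  with_seed(seed, {
    L <- length(spec$accrual)
    out <- lapply(seq_along(spec$theta0), function(j) {
      y0 <- drop(draw_cumulative_counts(spec$accrual, spec$theta0[j], 1L))
      y1 <- drop(draw_cumulative_counts(spec$accrual, spec$theta1[j], 1L))
      trial_counts(seq_len(L), n0 = spec$accrual, y0 = y0,
                   n1 = spec$accrual, y1 = y1)
    })
    stats::setNames(out, names(spec$theta0))
  })
}
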