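#' Solve a per-analysis decision-threshold schedule
#'
#' Four function families define how the decision threshold decreases over
#' the interim analyses `l = 1, ..., L`:
#' \describe{
#'   \item{uniform}{`tau_l = tau_final` for every analysis (the first-
#'     analysis anchor is deliberately ignored).}
#'   \item{linear}{`tau_l = a * l + b`.}
#'   \item{exponential}{`tau_l = a * exp(l) + b` (a linear function of
#'     `exp(l)`).}
#'   \item{logarithmic}{`tau_l = a * log(l) + b`.}
#' }
#' Non-uniform families are anchored through the two fixed points
#' `(1, tau_first)` and `(L, tau_final)`, which determines `(a, b)`
#' uniquely. Raw values are kept for decision making; 3-decimal rounding
#' is presentation only.
#'
#' @param family one of `"uniform"`, `"linear"`, `"exponential"`,
#'   `"logarithmic"`.
#' @param L number of analyses, >= 2.
#' @param tau_first first-analysis anchor, conventionally 0.95.
#' @param tau_final final-analysis threshold `tau_L`.
#' @return an object of class `threshold_schedule` with `values` (raw),
#'   `rounded` (3 decimals), `coefficients` `(a, b)` for non-uniform
#'   families, and the inputs.
#' @examples
#' s <- solve_schedule("exponential", L = 11, tau_first = 0.95, tau_final = 0.63)
#' s$rounded[10]  # 0.832
#' @export
solve_schedule <- function(family = c("uniform", "linear", "exponential",
                                      "logarithmic"),
                           L, tau_first = 0.95, tau_final) {
  family <- match.arg(family)
  if (L < 2) stopf("L must be >= 2")
  assert_scalar_prob(tau_first, "tau_first")
  assert_scalar_prob(tau_final, "tau_final")
  if (tau_first <= 0 || tau_first >= 1 || tau_final <= 0 || tau_final >= 1)
    stopf("anchors must lie strictly inside (0, 1)")
  if (tau_final > tau_first)
    warnf("tau_final > tau_first: increasing threshold schedule")
  l <- seq_len(L)
  if (family == "uniform") {
    values <- rep(tau_final, L)
    coefficients <- NULL
  } else {
    g <- switch(family, linear = l, exponential = exp(l), logarithmic = log(l))
    a <- (tau_final - tau_first) / (g[L] - g[1])
    b <- tau_first - a * g[1]
    values <- a * g + b
    coefficients <- c(a = a, b = b)
  }
  structure(list(family = family, L = as.integer(L), tau_first = tau_first,
                 tau_final = tau_final, values = values,
                 rounded = round(values, 3), coefficients = coefficients),
            class = "threshold_schedule")
}

#' @export
print.threshold_schedule <- function(x, ...) {
  cat(sprintf("%s threshold schedule, L = %d, anchors (%.3f, %.3f)\n",
              x$family, x$L, x$tau_first, x$tau_final))
  print(stats::setNames(x$rounded, seq_len(x$L)))
  invisible(x)
}

#' Threshold table for several events
#'
#' Solves one schedule per event (each with its own final threshold) and
#' assembles the analysis-by-event matrix of rounded thresholds, the
#' layout used to prespecify the full decision rule.
#'
#' @param events data frame with columns `event_id` and `tau_final` (one
#'   row per event, ids unique).
#' @param family,L,tau_first passed to [solve_schedule()].
#' @return an `L x n_events` matrix of 3-decimal thresholds with attribute
#'   `schedules` (the list of full [solve_schedule()] objects, raw values
#'   included).
#' @export
schedule_table <- function(events, family = "exponential", L = 11,
                           tau_first = 0.95) {
  if (nrow(events) < 1L) stopf("need at least one event")
  if (anyDuplicated(events$event_id))
    stopf("duplicate event_id in schedule table")
  schedules <- lapply(seq_len(nrow(events)), function(i)
    solve_schedule(family, L, tau_first, events$tau_final[i]))
  names(schedules) <- events$event_id
  m <- vapply(schedules, function(s) s$rounded, numeric(L))
  rownames(m) <- seq_len(L)
  attr(m, "schedules") <- schedules
  m
}
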