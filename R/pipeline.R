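#' Fit margin distributions for every event in an answer table
#'
#' Convenience driver over the elicitation module: splits the answer table
#' by event, computes clamped acceptable differences against each event's
#' control rate, fits the margin by the three competing methods and keeps
#' the best, and records the median severity weight and median difference
#' (both needed downstream for constraints and priors).
#'
#' @param answers expert-answer data frame (see [read_expert_answers()]).
#' @param control_rates named vector of control-arm reference prevalences
#'   per event.
#' @param config an [elicit_config()].
#' @return a named list per event, each element holding `mixture`,
#'   `diagnostics`, `differences` (the [compute_differences()] object),
#'   `median_difference` and `median_weight`.
#' @export
fit_margins <- function(answers, control_rates, config = elicit_config()) {
  events <- unique(answers$event_id)
  miss <- setdiff(events, names(control_rates))
  if (length(miss) > 0)
    stopf("control rates missing for event(s): %s",
          paste(miss, collapse = ", "))
  out <- lapply(events, function(ev) {
    sub <- answers[answers$event_id == ev, ]
    d <- compute_differences(sub, control_rates[[ev]], config)
    fit <- select_margin_fit(d$differences, config)
    list(mixture = fit$mixture, diagnostics = fit$diagnostics,
         differences = d,
         median_difference = stats::median(d$differences),
         median_weight = median_weight(sub$severity_weight))
  })
  stats::setNames(out, events)
}
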