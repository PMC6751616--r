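# CSV / JSON / YAML interfaces. All artefacts are plain text.

#' Read and write expert-answer tables
#'
#' The expert-answer CSV dialect has a header row and columns
#' `expert_id,event_id,acceptable_rate,severity_weight`, plus optional
#' covariate columns.
#'
#' @param path file path.
#' @param answers data frame in the same dialect.
#' @return `read_expert_answers` returns a validated data frame.
#' @export
read_expert_answers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("expert_id", "event_id", "acceptable_rate", "severity_weight")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stopf("expert answers file is missing column(s): %s",
          paste(miss, collapse = ", "))
  if (!is_prob(df$acceptable_rate))
    stopf("acceptable_rate values must lie in [0, 1]")
  if (any(df$severity_weight < 0 | df$severity_weight > 100))
    stopf("severity_weight values must lie in [0, 100]")
  df
}

#' @rdname read_expert_answers
#' @export
write_expert_answers <- function(answers, path) {
  utils::write.csv(answers, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write sequential trial-count tables
#'
#' One CSV per event with header
#' `analysis_index,arm,n_cum,events_cum`; `arm` is 0 (control) or 1
#' (experimental) and counts are cumulative.
#'
#' @param path file path.
#' @param counts a [trial_counts()] data frame.
#' @return `read_trial_counts` returns a [trial_counts()] data frame.
#' @export
read_trial_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analysis_index", "arm", "n_cum", "events_cum")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stopf("trial counts file is missing column(s): %s",
          paste(miss, collapse = ", "))
  w <- function(arm) df[df$arm == arm, ][order(df$analysis_index[df$arm == arm]), ]
  a0 <- w(0); a1 <- w(1)
  if (nrow(a0) != nrow(a1) || !all(a0$analysis_index == a1$analysis_index))
    stopf("arms must report the same analyses")
  trial_counts(a0$analysis_index, n0 = a0$n_cum, y0 = a0$events_cum,
               n1 = a1$n_cum, y1 = a1$events_cum)
}

#' @rdname read_trial_counts
#' @export
write_trial_counts <- function(counts, path) {
  long <- rbind(
    data.frame(analysis_index = counts$analysis, arm = 0L,
               n_cum = counts$n0, events_cum = counts$y0),
    data.frame(analysis_index = counts$analysis, arm = 1L,
               n_cum = counts$n1, events_cum = counts$y1))
  long <- long[order(long$analysis_index, long$arm), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fitted margin to JSON
#'
#' @param mixture a [beta_mixture()].
#' @param path file path.
#' @param event_id,control_rate,n_experts provenance fields.
#' @param diagnostics optional fit diagnostics (method and criterion are
#'   stored).
#' @return `read_margin_json` returns a list with the provenance fields
#'   and `mixture`, a [beta_mixture()].
#' @export
write_margin_json <- function(mixture, path, event_id = NA,
                              control_rate = NA, n_experts = NA,
                              diagnostics = NULL) {
  stopifnot(inherits(mixture, "beta_mixture"))
  obj <- list(
    event_id = event_id, control_rate = control_rate,
    n_experts = n_experts,
    components = lapply(seq_len(mixture$k), function(k)
      list(a = mixture$shape1[k], b = mixture$shape2[k],
           w = mixture$weights[k])),
    method = if (is.null(diagnostics)) NA else diagnostics$method_id,
    criterion = if (is.null(diagnostics)) NULL else
      list(name = diagnostics$criterion_used %||% "bic",
           value = diagnostics$criterion_values[[
             diagnostics$criterion_used %||% "bic"]]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_margin_json
#' @export
read_margin_json <- function(path) {
  obj <- jsonlite::read_json(path)
  comp <- obj$components
  mix <- beta_mixture(vapply(comp, function(c) c$a, numeric(1)),
                      vapply(comp, function(c) c$b, numeric(1)),
                      vapply(comp, function(c) c$w, numeric(1)))
  list(event_id = obj$event_id,
       control_rate = obj$control_rate %||% NA,
       n_experts = obj$n_experts %||% NA,
       mixture = mix, method = obj$method %||% NA,
       criterion = obj$criterion)
}

#' Serialize and restore a complete decision rule
#'
#' A complete rule consists of the retained prior label, the per-event
#' final thresholds, the threshold family and the full analysis-by-event
#' threshold matrix. The matrix is regenerated on read and must match the
#' serialized one bit-for-bit at 3 decimals.
#'
#' @param rule a list of class `safety_rule` from [select_rule()], with a
#'   non-missing `family`.
#' @param path file path.
#' @param L,tau_first schedule parameters used to materialise the matrix.
#' @return `read_rule` returns the rule list with elements `prior_label`,
#'   `tau_final`, `family`, `L`, `tau_first` and `thresholds` (the
#'   [schedule_table()] matrix).
#' @export
write_rule <- function(rule, path, L = 11, tau_first = 0.95) {
  if (!isTRUE(rule$admissible) || is.null(rule$tau_final) ||
      is.na(rule$prior_label) || is.null(rule$family) || is.na(rule$family))
    stopf("rule is incomplete: need admissible rule with prior, thresholds and family")
  events <- names(rule$tau_final)
  tab <- schedule_table(data.frame(event_id = events,
                                   tau_final = unname(rule$tau_final)),
                        family = rule$family, L = L, tau_first = tau_first)
  obj <- list(prior_label = rule$prior_label, family = rule$family,
              L = L, tau_first = tau_first,
              tau_final_per_event = as.list(rule$tau_final),
              thresholds = unname(apply(tab, 1, as.list)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_rule
#' @export
read_rule <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stopf("malformed rule JSON: %s",
                                            conditionMessage(e)))
  taus <- unlist(obj$tau_final_per_event)
  tab <- schedule_table(data.frame(event_id = names(taus),
                                   tau_final = unname(taus)),
                        family = obj$family, L = obj$L,
                        tau_first = obj$tau_first)
  stored <- do.call(rbind, lapply(obj$thresholds, function(r)
    unlist(r)))
  if (!isTRUE(all.equal(matrix(stored, nrow(stored)),
                        matrix(tab, nrow(tab)), tolerance = 0)))
    stopf("stored threshold matrix does not match the regenerated schedule")
  list(prior_label = obj$prior_label, tau_final = taus,
       family = obj$family, L = obj$L, tau_first = obj$tau_first,
       thresholds = tab)
}

#' Serialize a threshold schedule table to JSON
#'
#' @param table a [schedule_table()] matrix.
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_schedule_json <- function(table, path) {
  schedules <- attr(table, "schedules")
  s1 <- schedules[[1]]
  obj <- list(family = s1$family, L = s1$L, tau_first = s1$tau_first,
              tau_final_per_event = lapply(schedules, `[[`, "tau_final"),
              values = unname(apply(table, 1, as.list)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# --- run configuration -------------------------------------------------------

config_defaults <- list(
  simulation = list(n_per_arm = 162L, L = 11L, n_trials = 1000L,
                    mc_samples = 100000L),
  constraints = list(max_class_a = 0.10),
  log_level = "info")

known_config_fields <- c("schema_version", "events", "simulation",
                         "constraints", "seed", "paths", "log_level")

#' Load and validate a run configuration
#'
#' Configurations are YAML (or JSON, by file extension) with a versioned
#' schema. Required: `events`, a list of records with `event_id`,
#' `control_rate` and optionally `weight` and `unacceptable_from`; and
#' `seed` for stochastic commands. Defaults are filled in explicitly:
#' `L = 11`, `n_trials = 1000`, `mc_samples = 100000`, `n_per_arm = 162`,
#' `max_class_a = 0.10`. Unknown top-level fields produce a warning,
#' missing required fields an error naming the field.
#'
#' @param path config file path.
#' @return a validated list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (is.null(cfg$events)) stopf("config is missing required field 'events'")
  unknown <- setdiff(names(cfg), known_config_fields)
  if (length(unknown) > 0)
    warnf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  for (ev in cfg$events) {
    if (is.null(ev$event_id) || is.null(ev$control_rate))
      stopf("each event needs 'event_id' and 'control_rate'")
    if (ev$control_rate <= 0 || ev$control_rate >= 1)
      stopf("control_rate for '%s' must lie in (0, 1)", ev$event_id)
  }
  sim <- utils::modifyList(config_defaults$simulation,
                           cfg$simulation %||% list())
  con <- utils::modifyList(config_defaults$constraints,
                           cfg$constraints %||% list())
  out <- list(schema_version = cfg$schema_version %||% 1L,
              events = cfg$events, simulation = sim, constraints = con,
              seed = cfg$seed %||% NULL, paths = cfg$paths %||% list(),
              log_level = cfg$log_level %||% config_defaults$log_level)
  class(out) <- "run_config"
  out
}

#' @rdname load_config
#' @param config a `run_config` object.
#' @export
save_config <- function(config, path) {
  obj <- unclass(config)
  obj$seed <- obj$seed %||% NULL
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(obj, path)
  invisible(path)
}
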