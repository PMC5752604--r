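#' Build a fully resolved scenario parameter set
#'
#' A scenario is the complete numeric parameterization of one run: the number
#' of pregnancies, the fraction delivering in each care setting, and — after
#' resolution against a model definition — a full table of per-setting
#' penetration/utilization for every intervention, per-intervention efficacy,
#' per-sub-condition incidence and case fatality rates, and transfer
#' probabilities. Overrides patch the model's defaults; anything not
#' overridden is taken from the model.
#'
#' @param model The `mnh_model` the scenario parameterizes.
#' @param scenario_id Identifier string.
#' @param births Number of pregnancies in the modelled time frame (>= 0).
#' @param setting_distribution Numeric named by `home`, `clinic`, `hospital`;
#'   must sum to 1 within `1e-9`.
#' @param coverage_overrides Optional data frame with columns `intervention`
#'   (uid `"id/kind"`, or bare id to hit every kind), `setting`, and any of
#'   `penetration`, `utilization`. `setting = "all"` patches all three.
#' @param efficacy_overrides Optional named numeric, names being intervention
#'   uids (or bare ids).
#' @param rate_overrides Optional data frame with column `subcondition` and
#'   any of `unprevented_incidence`, `untreated_cfr`, `treated_cfr`,
#'   `fetal_death_rate_untreated`, `fetal_death_rate_treated`.
#' @param transfer_overrides Optional data frame with columns `from`, `to`,
#'   `subcondition`, `probability` patching (or adding) transfer rules.
#' @param bounds Optional `list(low = ..., high = ...)`, each element a list
#'   with any of `coverage`, `efficacy`, `rates`, `transfers` in the formats
#'   above, defining the low/high sensitivity variants.
#' @return A validated object of class `mnh_scenario` carrying the resolved
#'   tables plus the hash of the model it was resolved against.
#' @seealso [load_scenario()], [write_scenario()], [preset_no_intervention()]
#' @export
scenario_parameters <- function(model, scenario_id, births,
                                setting_distribution,
                                coverage_overrides = NULL,
                                efficacy_overrides = NULL,
                                rate_overrides = NULL,
                                transfer_overrides = NULL,
                                bounds = NULL) {
  stopifnot(inherits(model, "mnh_model"))
  dist <- per_setting_distribution(setting_distribution)
  params <- structure(list(
    scenario_id = as.character(scenario_id),
    births = as.numeric(births),
    setting_distribution = dist,
    coverage = default_coverage_table(model),
    efficacy = default_efficacy_table(model),
    rates = default_rate_table(model),
    transfers = transfer_table(model$transfers),
    bounds = bounds,
    model_hash = content_hash(model)
  ), class = "mnh_scenario")
  params <- apply_scenario_overrides(params, list(
    coverage = coverage_overrides, efficacy = efficacy_overrides,
    rates = rate_overrides, transfers = transfer_overrides))
  validate_scenario(params, model)
  params
}

per_setting_distribution <- function(x) {
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x)) || !setequal(names(x), settings())) {
    abort_validation("must be named by the three settings home/clinic/hospital",
                     field = "setting_distribution")
  }
  x <- x[settings()]
  check_prob(x, "setting_distribution")
  if (abs(sum(x) - 1) > 1e-9) {
    abort_validation(sprintf("must sum to 1 within 1e-9 (got %.12g)", sum(x)),
                     field = "setting_distribution")
  }
  x
}

default_coverage_table <- function(model) {
  if (length(model$interventions) == 0) {
    return(data.frame(intervention = character(), id = character(),
                      kind = character(), setting = character(),
                      penetration = numeric(), utilization = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(model$interventions, function(iv) {
    data.frame(intervention = intervention_uid(iv), id = iv$id, kind = iv$kind,
               setting = settings(),
               penetration = unname(iv$penetration[settings()]),
               utilization = unname(iv$utilization[settings()]),
               stringsAsFactors = FALSE)
  }))
}

default_efficacy_table <- function(model) {
  data.frame(
    intervention = vapply(model$interventions, intervention_uid, ""),
    efficacy = vapply(model$interventions, `[[`, 0, "efficacy"),
    fetal_efficacy = vapply(model$interventions, `[[`, 0, "fetal_efficacy"),
    neonatal_efficacy = vapply(model$interventions, `[[`, 0, "neonatal_efficacy"),
    stringsAsFactors = FALSE
  )
}

default_rate_table <- function(model) {
  data.frame(
    subcondition = sub_ids(model),
    unprevented_incidence = vapply(model$sub_conditions, `[[`, 0, "unprevented_incidence"),
    untreated_cfr = vapply(model$sub_conditions, `[[`, 0, "untreated_cfr"),
    treated_cfr = vapply(model$sub_conditions, `[[`, 0, "treated_cfr"),
    fetal_death_rate_untreated = vapply(model$sub_conditions, `[[`, 0, "fetal_death_rate_untreated"),
    fetal_death_rate_treated = vapply(model$sub_conditions, `[[`, 0, "fetal_death_rate_treated"),
    stringsAsFactors = FALSE
  )
}

as_override_frame <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(x)
  # list of records (as read from JSON)
  do.call(rbind, lapply(x, function(rec) as.data.frame(rec, stringsAsFactors = FALSE)))
}

apply_scenario_overrides <- function(params, ov) {
  cov <- as_override_frame(ov$coverage)
  if (!is.null(cov) && nrow(cov) > 0) {
    for (i in seq_len(nrow(cov))) {
      hit <- params$coverage$intervention == cov$intervention[i] |
        params$coverage$id == cov$intervention[i]
      if (!any(hit)) {
        abort_validation(sprintf("unknown intervention '%s'", cov$intervention[i]),
                         field = "coverage_overrides")
      }
      st <- cov$setting[i] %||% "all"
      if (!identical(st, "all")) {
        check_setting(st, "coverage_overrides.setting")
        hit <- hit & params$coverage$setting == st
      }
      if (!is.null(cov$penetration) && !is.na(cov$penetration[i])) {
        params$coverage$penetration[hit] <- cov$penetration[i]
      }
      if (!is.null(cov$utilization) && !is.na(cov$utilization[i])) {
        params$coverage$utilization[hit] <- cov$utilization[i]
      }
    }
  }
  eff <- ov$efficacy
  if (!is.null(eff)) {
    if (is.list(eff)) eff <- unlist(eff)
    for (nm in names(eff)) {
      hit <- params$efficacy$intervention == nm |
        sub("/.*$", "", params$efficacy$intervention) == nm
      if (!any(hit)) abort_validation(sprintf("unknown intervention '%s'", nm),
                                      field = "efficacy_overrides")
      params$efficacy$efficacy[hit] <- unname(eff[nm])
    }
  }
  rates <- as_override_frame(ov$rates)
  if (!is.null(rates) && nrow(rates) > 0) {
    cols <- intersect(names(rates), setdiff(names(params$rates), "subcondition"))
    for (i in seq_len(nrow(rates))) {
      hit <- params$rates$subcondition == rates$subcondition[i]
      if (!any(hit)) abort_validation(sprintf("unknown sub-condition '%s'", rates$subcondition[i]),
                                      field = "rate_overrides")
      for (cl in cols) {
        if (!is.na(rates[[cl]][i])) params$rates[[cl]][hit] <- rates[[cl]][i]
      }
    }
  }
  trs <- as_override_frame(ov$transfers)
  if (!is.null(trs) && nrow(trs) > 0) {
    for (i in seq_len(nrow(trs))) {
      hit <- params$transfers$from == trs$from[i] &
        params$transfers$to == trs$to[i] &
        params$transfers$subcondition == trs$subcondition[i]
      if (any(hit)) {
        params$transfers$probability[hit] <- trs$probability[i]
      } else {
        params$transfers <- rbind(params$transfers,
          data.frame(from = trs$from[i], to = trs$to[i],
                     subcondition = trs$subcondition[i],
                     probability = trs$probability[i], stringsAsFactors = FALSE))
      }
    }
  }
  params
}

#' Validate a scenario parameter set
#'
#' @param params An `mnh_scenario`.
#' @param model Optional `mnh_model` to cross-check id resolution and the
#'   stored model hash against.
#' @return `params`, invisibly; throws `mnh_validation_error` otherwise.
#' @export
validate_scenario <- function(params, model = NULL) {
  if (params$births < 0 || !is.finite(params$births)) {
    abort_validation("births must be a non-negative finite number", "births")
  }
  per_setting_distribution(params$setting_distribution)
  check_prob(params$coverage$penetration, "coverage.penetration")
  check_prob(params$coverage$utilization, "coverage.utilization")
  check_prob(params$efficacy$efficacy, "efficacy")
  check_prob(params$efficacy$fetal_efficacy, "fetal_efficacy")
  check_prob(params$efficacy$neonatal_efficacy, "neonatal_efficacy")
  for (cl in setdiff(names(params$rates), "subcondition")) {
    check_prob(params$rates[[cl]], paste0("rates.", cl))
  }
  bad <- params$rates$treated_cfr > params$rates$untreated_cfr
  if (any(bad)) {
    abort_validation(sprintf("treated_cfr exceeds untreated_cfr for '%s'",
                             params$rates$subcondition[bad][1]), "rates")
  }
  bad <- params$rates$fetal_death_rate_treated > params$rates$fetal_death_rate_untreated
  if (any(bad)) {
    abort_validation(sprintf("fetal_death_rate_treated exceeds fetal_death_rate_untreated for '%s'",
                             params$rates$subcondition[bad][1]), "rates")
  }
  check_prob(params$transfers$probability, "transfers.probability")
  if (nrow(params$transfers) > 0) {
    rk_ok <- setting_rank(params$transfers$to) > setting_rank(params$transfers$from)
    if (!all(rk_ok)) {
      abort_validation("transfers must move strictly up the care ladder", "transfers")
    }
  }
  check_transfer_sums(params$transfers, "transfers")
  if (!is.null(model)) {
    if (!identical(params$model_hash, content_hash(model))) {
      abort_validation("scenario was resolved against a different model definition",
                       "model_hash")
    }
  }
  invisible(params)
}

# ---------------------------------------------------------------------------
# file IO

#' Read a scenario parameter file and resolve it against a model
#'
#' The file stores overrides (possibly full tables, as written by
#' [write_scenario()]); defaults come from `model`. The returned object is
#' fully resolved: every intervention/setting has a concrete penetration and
#' utilization, every sub-condition concrete rates.
#'
#' @param path Path to a scenario JSON file.
#' @param model The `mnh_model` to resolve against.
#' @return A validated `mnh_scenario`.
#' @export
load_scenario <- function(path, model) {
  if (!file.exists(path)) abort_parse(sprintf("scenario file '%s' does not exist", path))
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) abort_parse(sprintf("cannot parse '%s': %s", path, conditionMessage(e))))
  ver <- raw$schema_version %||% MODEL_SCHEMA_VERSION
  if (!identical(ver, MODEL_SCHEMA_VERSION)) {
    abort_validation(sprintf("unknown schema_version '%s'", ver), "schema_version")
  }
  bounds <- raw$bounds
  if (!is.null(bounds)) {
    bounds <- lapply(bounds, function(b) list(
      coverage = as_override_frame(b$coverage),
      efficacy = b$efficacy,
      rates = as_override_frame(b$rates),
      transfers = as_override_frame(b$transfers)))
  }
  scenario_parameters(
    model,
    scenario_id = raw$scenario_id %||% basename(path),
    births = raw$births,
    setting_distribution = raw$setting_distribution,
    coverage_overrides = as_override_frame(raw$coverage),
    efficacy_overrides = raw$efficacy,
    rate_overrides = as_override_frame(raw$rates),
    transfer_overrides = as_override_frame(raw$transfers),
    bounds = bounds
  )
}

frame_to_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Write a scenario parameter file
#'
#' Writes the *resolved* tables in full, so that loading the file back against
#' the same model reproduces the parameter set field-for-field.
#'
#' @param params An `mnh_scenario`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(params, path) {
  eff <- stats::setNames(as.list(params$efficacy$efficacy), params$efficacy$intervention)
  out <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    scenario_id = params$scenario_id,
    births = params$births,
    setting_distribution = as.list(params$setting_distribution),
    coverage = frame_to_records(params$coverage[, c("intervention", "setting",
                                                    "penetration", "utilization")]),
    efficacy = eff,
    rates = frame_to_records(params$rates),
    transfers = if (nrow(params$transfers) > 0) frame_to_records(params$transfers) else list(),
    bounds = serialize_bounds(params$bounds)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

serialize_bounds <- function(bounds) {
  if (is.null(bounds)) return(NULL)
  lapply(bounds, function(b) {
    out <- list()
    if (!is.null(b$coverage)) out$coverage <- frame_to_records(as_override_frame(b$coverage))
    if (!is.null(b$efficacy)) out$efficacy <- as.list(unlist(b$efficacy))
    if (!is.null(b$rates)) out$rates <- frame_to_records(as_override_frame(b$rates))
    if (!is.null(b$transfers)) out$transfers <- frame_to_records(as_override_frame(b$transfers))
    out
  })
}

#' Zero out every intervention's penetration and utilization
#'
#' Produces the no-intervention preset used for historical calibration: with
#' all coverage at zero, expected deaths collapse to the closed form
#' `births × incidence × untreated CFR` for every sub-condition. Idempotent.
#'
#' @param params An `mnh_scenario`.
#' @return A copy of `params` with all penetrations and utilizations set to 0.
#' @export
preset_no_intervention <- function(params) {
  stopifnot(inherits(params, "mnh_scenario"))
  params$coverage$penetration <- 0
  params$coverage$utilization <- 0
  params
}

#' @export
print.mnh_scenario <- function(x, ...) {
  cat(sprintf("<mnh_scenario> '%s': %s births; setting mix %s; %d coverage rows%s\n",
              x$scenario_id, format(x$births, big.mark = ","),
              paste(sprintf("%s %.0f%%", names(x$setting_distribution),
                            100 * x$setting_distribution), collapse = ", "),
              nrow(x$coverage),
              if (is.null(x$bounds)) "" else "; low/high bounds attached"))
  invisible(x)
}
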