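#' Run a full scenario
#'
#' Evaluates every maternal sub-condition through the decision tree, collects
#' the induced neonatal incidence, then evaluates every neonatal
#' sub-condition (the dependency is strictly one-way). Sub-conditions are
#' independent: no comorbidity interaction is modelled. Purely deterministic:
#' identical inputs give bit-identical outputs, and the result embeds content
#' hashes of both inputs.
#'
#' @param model An `mnh_model`.
#' @param params A resolved `mnh_scenario` (must have been resolved against
#'   `model`).
#' @param adjustment Optional scalar multiplier applied to the reported death
#'   *totals* only, to account for mortality causes outside the model's
#'   scope. Default 1 (no adjustment); per-sub-condition entries are never
#'   adjusted.
#' @return An object of class `mnh_result` with per-sub-condition `deaths`
#'   (data frame: `subcondition`, `condition`, `population`, `deaths`),
#'   expected `cases`, population `totals`, sub-results (including strata
#'   traces), and input hashes.
#' @export
run_scenario <- function(model, params, adjustment = 1) {
  stopifnot(inherits(model, "mnh_model"), inherits(params, "mnh_scenario"))
  if (!identical(params$model_hash, content_hash(model))) {
    abort_validation("scenario was resolved against a different model definition",
                     "model_hash")
  }
  pops <- vapply(model$sub_conditions, `[[`, "", "population")
  maternal <- model$sub_conditions[pops == "maternal"]
  neonatal <- model$sub_conditions[pops == "neonatal"]

  m_res <- lapply(maternal, run_subcondition, model = model, params = params)
  extra <- propagate_neonatal(m_res, model)
  n_res <- lapply(neonatal, function(sub) {
    run_subcondition(sub, model, params, extra_incidence = extra[[sub$id]])
  })
  sub_results <- c(m_res, n_res)
  names(sub_results) <- vapply(sub_results, `[[`, "", "subcondition_id")

  rows <- list()
  for (r in sub_results) {
    if (r$population == "maternal") {
      rows[[length(rows) + 1]] <- data.frame(
        subcondition = r$subcondition_id, condition = r$condition_id,
        population = c("maternal", "fetal"),
        deaths = c(r$maternal_deaths, r$fetal_deaths), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        subcondition = r$subcondition_id, condition = r$condition_id,
        population = "neonatal", deaths = r$neonatal_deaths,
        stringsAsFactors = FALSE)
    }
  }
  deaths <- do.call(rbind, rows)
  totals <- vapply(population_types(), function(p) {
    sum(deaths$deaths[deaths$population == p])
  }, 0) * adjustment

  structure(list(
    scenario_id = params$scenario_id,
    births = params$births,
    deaths = deaths,
    cases = stats::setNames(vapply(sub_results, `[[`, 0, "cases"),
                            names(sub_results)),
    totals = totals,
    adjustment = adjustment,
    sub_results = sub_results,
    bounds = NULL,
    model_hash = params$model_hash,
    params_hash = content_hash(params)
  ), class = "mnh_result")
}

#' @export
print.mnh_result <- function(x, ...) {
  cat(sprintf("<mnh_result> scenario '%s' (%s births)\n", x$scenario_id,
              format(x$births, big.mark = ",")))
  cat(sprintf("  expected deaths: maternal %.1f, fetal %.1f, neonatal %.1f\n",
              x$totals[["maternal"]], x$totals[["fetal"]], x$totals[["neonatal"]]))
  if (!is.null(x$bounds)) {
    cat(sprintf("  bounds (total deaths): low-variant %.1f, high-variant %.1f\n",
                sum(x$bounds$low$totals), sum(x$bounds$high$totals)))
  }
  invisible(x)
}

#' Lives saved between two scenarios
#'
#' Reference deaths minus comparison deaths, per population type and per
#' sub-condition. Both results must come from the same model definition
#' (checked by content hash) and the same cohort size.
#'
#' @param reference,comparison `mnh_result` objects (reference is typically
#'   the lower-coverage scenario).
#' @return An object of class `mnh_lives_saved`: `totals` (named numeric per
#'   population type) and `by_subcondition` (data frame with a `saved`
#'   column).
#' @export
lives_saved <- function(reference, comparison) {
  stopifnot(inherits(reference, "mnh_result"), inherits(comparison, "mnh_result"))
  if (!identical(reference$model_hash, comparison$model_hash)) {
    abort_validation("results come from different model definitions", "model_hash")
  }
  if (!identical(reference$births, comparison$births)) {
    abort_validation("results come from different cohort sizes", "births")
  }
  key <- function(d) paste(d$subcondition, d$population)
  stopifnot(identical(key(reference$deaths), key(comparison$deaths)))
  by_sub <- reference$deaths[, c("subcondition", "condition", "population")]
  by_sub$saved <- reference$deaths$deaths - comparison$deaths$deaths
  structure(list(
    reference_id = reference$scenario_id,
    comparison_id = comparison$scenario_id,
    totals = reference$totals - comparison$totals,
    by_subcondition = by_sub
  ), class = "mnh_lives_saved")
}

#' @export
print.mnh_lives_saved <- function(x, ...) {
  cat(sprintf("<mnh_lives_saved> '%s' vs '%s': maternal %.1f, fetal %.1f, neonatal %.1f\n",
              x$reference_id, x$comparison_id, x$totals[["maternal"]],
              x$totals[["fetal"]], x$totals[["neonatal"]]))
  invisible(x)
}

#' Calibrate an un-prevented incidence to a historical mortality target
#'
#' Under the no-intervention preset, expected deaths per pregnancy are
#' `incidence * untreated_cfr`, so the incidence reproducing a historical
#' no-intervention mortality rate is simply `target / untreated_cfr`. Targets
#' above the case fatality rate are infeasible.
#'
#' @param target_mortality_rate Historical deaths per pregnancy from the
#'   sub-condition, with no interventions available.
#' @param untreated_cfr Untreated case fatality rate, in `(0, 1]`.
#' @return The calibrated incidence probability.
#' @export
calibrate_incidence <- function(target_mortality_rate, untreated_cfr) {
  check_prob(target_mortality_rate, "target_mortality_rate")
  check_prob(untreated_cfr, "untreated_cfr")
  if (untreated_cfr <= 0) {
    abort_validation("untreated_cfr must be positive", "untreated_cfr")
  }
  if (target_mortality_rate > untreated_cfr) {
    stop(errorCondition(
      sprintf("infeasible calibration: target mortality %.4g exceeds untreated CFR %.4g",
              target_mortality_rate, untreated_cfr),
      class = c("mnh_infeasible_calibration", "mnh_validation_error", "error",
                "condition")))
  }
  target_mortality_rate / untreated_cfr
}

#' Run a scenario at its low and high parameter variants
#'
#' The central estimate is complemented by two full deterministic runs using
#' the scenario's `bounds$low` and `bounds$high` override sets (no interval
#' arithmetic). Under monotone parameter variants (e.g. high incidence and
#' CFR with low coverage) the two runs bracket the central death counts.
#'
#' @param model An `mnh_model`.
#' @param params An `mnh_scenario` with a non-`NULL` `bounds` field.
#' @param adjustment Passed to [run_scenario()].
#' @return The central `mnh_result` with `bounds = list(low =, high =)`
#'   attached (each a full `mnh_result`).
#' @export
sensitivity_bounds <- function(model, params, adjustment = 1) {
  if (is.null(params$bounds)) {
    abort_validation("scenario has no low/high bounds", "bounds")
  }
  if (!all(c("low", "high") %in% names(params$bounds))) {
    abort_validation("bounds must contain both 'low' and 'high' variants", "bounds")
  }
  central <- run_scenario(model, params, adjustment)
  variant <- function(ov) {
    p <- apply_scenario_overrides(params, list(
      coverage = ov$coverage, efficacy = ov$efficacy,
      rates = ov$rates, transfers = ov$transfers))
    p$bounds <- NULL
    validate_scenario(p)
    run_scenario(model, p, adjustment)
  }
  central$bounds <- list(low = variant(params$bounds$low),
                         high = variant(params$bounds$high))
  central
}

#' Tidy table of a scenario result
#'
#' One row per (sub-condition, population), with expected cases and — when
#' bounds were evaluated — the low/high-variant death counts.
#'
#' @param result An `mnh_result`.
#' @return A data frame with columns `scenario_id`, `subcondition`,
#'   `condition`, `population`, `deaths`, `cases`, `low`, `high`.
#' @export
results_table <- function(result) {
  stopifnot(inherits(result, "mnh_result"))
  df <- result$deaths
  df$scenario_id <- result$scenario_id
  df$cases <- unname(result$cases[df$subcondition])
  if (!is.null(result$bounds)) {
    df$low <- result$bounds$low$deaths$deaths
    df$high <- result$bounds$high$deaths$deaths
  } else {
    df$low <- NA_real_
    df$high <- NA_real_
  }
  df[, c("scenario_id", "subcondition", "condition", "population", "deaths",
         "cases", "low", "high")]
}
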