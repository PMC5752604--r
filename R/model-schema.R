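MODEL_SCHEMA_VERSION <- "1.0"

#' Define a cause-specific sub-condition
#'
#' A sub-condition is one specific etiology inside a mortality cause (for
#' example atonic uterus inside maternal hemorrhage). It carries the
#' "un-prevented" incidence (the fraction of pregnancies that would develop it
#' with no preventive intervention), the case fatality rates with and without
#' successful treatment, and — for maternal sub-conditions — the fetal death
#' rates and incremental neonatal-condition incidence it induces.
#'
#' @param id Unique sub-condition identifier.
#' @param condition_id Parent condition (e.g. `"maternal_hemorrhage"`).
#' @param population `"maternal"` or `"neonatal"`. Fetal outcomes arise only
#'   as consequences of maternal sub-conditions and are not free-standing.
#' @param unprevented_incidence Probability per pregnancy of developing the
#'   sub-condition when no preventive intervention exists.
#' @param untreated_cfr Probability of death given the sub-condition and no
#'   successful treatment.
#' @param treated_cfr Residual probability of death after successful
#'   treatment; must not exceed `untreated_cfr`. Default 0.
#' @param fetal_death_rate_untreated,fetal_death_rate_treated Probability of
#'   fetal death per maternal case, without / with successful maternal
#'   treatment (maternal sub-conditions only; must be 0 for neonatal ones).
#' @param neonatal_links Named numeric: incremental incidence of each linked
#'   neonatal sub-condition per untreated maternal case.
#' @param neonatal_links_treated Named numeric with the same names: the
#'   incidence contribution per successfully treated maternal case. Defaults
#'   to `neonatal_links` (treatment confers no neonatal benefit unless an
#'   intervention carries `neonatal_efficacy > 0`).
#' @return An object of class `mnh_subcondition`.
#' @export
sub_condition <- function(id, condition_id,
                          population = c("maternal", "neonatal"),
                          unprevented_incidence, untreated_cfr,
                          treated_cfr = 0,
                          fetal_death_rate_untreated = 0,
                          fetal_death_rate_treated = 0,
                          neonatal_links = NULL,
                          neonatal_links_treated = NULL) {
  population <- match.arg(population)
  links <- as_named_numeric(neonatal_links)
  links_t <- if (is.null(neonatal_links_treated)) links else as_named_numeric(neonatal_links_treated)
  structure(list(
    id = as.character(id),
    condition_id = as.character(condition_id),
    population = population,
    unprevented_incidence = as.numeric(unprevented_incidence),
    untreated_cfr = as.numeric(untreated_cfr),
    treated_cfr = as.numeric(treated_cfr),
    fetal_death_rate_untreated = as.numeric(fetal_death_rate_untreated),
    fetal_death_rate_treated = as.numeric(fetal_death_rate_treated),
    neonatal_links = links,
    neonatal_links_treated = links_t
  ), class = "mnh_subcondition")
}

as_named_numeric <- function(x) {
  if (is.null(x) || length(x) == 0) return(stats::setNames(numeric(0), character(0)))
  v <- unlist(x)
  storage.mode(v) <- "double"
  v
}

#' Define an intervention
#'
#' An intervention prevents, diagnoses, or treats one or more sub-conditions.
#' Receipt in each setting is governed by penetration (availability) and
#' utilization (appropriate use given availability); efficacy — the
#' probability of success under ideal conditions — is a single
#' setting-independent value.
#'
#' @param id Intervention identifier. The same id may appear twice with
#'   different `kind`/`timing_tags` (e.g. oxytocin as prophylaxis and again
#'   as treatment); the pair `(id, kind)` must be unique.
#' @param kind One of `"preventive"`, `"diagnostic"`, `"treatment"`.
#' @param targets Character vector of sub-condition ids this intervention
#'   applies to.
#' @param efficacy Probability of success under ideal conditions
#'   (setting-independent).
#' @param penetration,utilization Either a scalar (recycled over settings) or
#'   a numeric named by `home`, `clinic`, `hospital`.
#' @param fetal_efficacy Probability that a treatment which successfully
#'   treats the mother also removes the residual fetal death risk
#'   (treatments only; default 0).
#' @param neonatal_efficacy Probability that a successful maternal treatment
#'   also removes the residual neonatal-condition incidence contribution
#'   (treatments only; default 0).
#' @param composition Either `list(mode = "layer")` (order-independent,
#'   combined as independent events) or `list(mode = "line", order = k)`
#'   (given only after line `k - 1` was received and failed).
#' @param single_use Logical; `TRUE` for interventions that can be given at
#'   most once per pregnancy pathway (e.g. cesarean delivery).
#' @param timing_tags Character vector distinguishing re-uses of the same
#'   agent at different care stages.
#' @return An object of class `mnh_intervention`.
#' @export
intervention <- function(id, kind = c("preventive", "diagnostic", "treatment"),
                         targets, efficacy, penetration, utilization,
                         fetal_efficacy = 0, neonatal_efficacy = 0,
                         composition = list(mode = "layer"),
                         single_use = FALSE, timing_tags = character()) {
  kind <- match.arg(kind)
  structure(list(
    id = as.character(id),
    kind = kind,
    targets = as.character(targets),
    efficacy = as.numeric(efficacy),
    penetration = per_setting(penetration, paste0("intervention '", id, "' penetration")),
    utilization = per_setting(utilization, paste0("intervention '", id, "' utilization")),
    fetal_efficacy = as.numeric(fetal_efficacy),
    neonatal_efficacy = as.numeric(neonatal_efficacy),
    composition = composition,
    single_use = isTRUE(single_use),
    timing_tags = as.character(timing_tags)
  ), class = "mnh_intervention")
}

intervention_uid <- function(iv) paste(iv$id, iv$kind, sep = "/")

#' Define a transfer rule
#'
#' A transfer moves a *diagnosed* patient from one care setting to a strictly
#' higher one (home < clinic < hospital) with a given probability, where they
#' face the destination setting's treatment penetration and utilization.
#'
#' @param from,to Setting labels; `to` must rank above `from`.
#' @param probability Probability of transfer given a positive diagnosis at
#'   `from`.
#' @param subconditions Character vector of sub-condition ids the rule
#'   applies to.
#' @return An object of class `mnh_transfer`.
#' @export
transfer_rule <- function(from, to, probability, subconditions) {
  structure(list(
    from = as.character(from),
    to = as.character(to),
    probability = as.numeric(probability),
    subconditions = as.character(subconditions)
  ), class = "mnh_transfer")
}

#' Assemble and validate a model definition
#'
#' @param sub_conditions List of [sub_condition()] objects.
#' @param interventions List of [intervention()] objects.
#' @param transfers List of [transfer_rule()] objects.
#' @param schema_version Schema version string; only `"1.0"` is accepted.
#' @return A validated object of class `mnh_model`.
#' @seealso [load_model()], [write_model()]
#' @export
model_definition <- function(sub_conditions, interventions = list(),
                             transfers = list(),
                             schema_version = MODEL_SCHEMA_VERSION) {
  model <- structure(list(
    schema_version = as.character(schema_version),
    sub_conditions = sub_conditions,
    interventions = interventions,
    transfers = transfers
  ), class = "mnh_model")
  validate_model(model)
  model
}

sub_ids <- function(model) vapply(model$sub_conditions, `[[`, "", "id")

model_sub <- function(model, id) {
  i <- match(id, sub_ids(model))
  if (is.na(i)) return(NULL)
  model$sub_conditions[[i]]
}

#' Validate a model definition
#'
#' Checks every structural invariant: probability ranges, `treated_cfr <=
#' untreated_cfr` (and the fetal analogue), id resolution, unique and
#' contiguous line orders per (sub-condition, kind) group, upward-only
#' transfers with outgoing probabilities summing to at most 1, absence of
#' fetal/neonatal fields on neonatal sub-conditions, and single-use
#' constraints on each sub-condition pathway.
#'
#' @param model An `mnh_model`.
#' @return The model, invisibly. Throws a classed condition
#'   (`mnh_validation_error`) naming the offending field otherwise.
#' @export
validate_model <- function(model) {
  if (!identical(model$schema_version, MODEL_SCHEMA_VERSION)) {
    abort_validation(sprintf("unknown schema_version '%s' (this build reads %s)",
                             model$schema_version, MODEL_SCHEMA_VERSION),
                     field = "schema_version")
  }
  ids <- sub_ids(model)
  if (anyDuplicated(ids)) {
    abort_validation(sprintf("duplicate sub-condition id '%s'", ids[duplicated(ids)][1]),
                     field = "sub_conditions")
  }
  neonatal_ids <- ids[vapply(model$sub_conditions, `[[`, "", "population") == "neonatal"]

  for (sc in model$sub_conditions) {
    f <- function(x) sprintf("sub_conditions[%s].%s", sc$id, x)
    if (!sc$population %in% c("maternal", "neonatal")) {
      abort_validation("population must be maternal or neonatal", f("population"))
    }
    check_prob(sc$unprevented_incidence, f("unprevented_incidence"))
    check_prob(sc$untreated_cfr, f("untreated_cfr"))
    check_prob(sc$treated_cfr, f("treated_cfr"))
    check_prob(sc$fetal_death_rate_untreated, f("fetal_death_rate_untreated"))
    check_prob(sc$fetal_death_rate_treated, f("fetal_death_rate_treated"))
    check_prob(sc$neonatal_links, f("neonatal_links"))
    check_prob(sc$neonatal_links_treated, f("neonatal_links_treated"))
    if (sc$treated_cfr > sc$untreated_cfr) {
      abort_validation("treated_cfr exceeds untreated_cfr", f("treated_cfr"))
    }
    if (sc$fetal_death_rate_treated > sc$fetal_death_rate_untreated) {
      abort_validation("fetal_death_rate_treated exceeds fetal_death_rate_untreated",
                       f("fetal_death_rate_treated"))
    }
    if (sc$population == "neonatal") {
      if (sc$fetal_death_rate_untreated != 0 || sc$fetal_death_rate_treated != 0 ||
          length(sc$neonatal_links) > 0) {
        abort_validation("neonatal sub-conditions carry no fetal rates or neonatal links",
                         f("population"))
      }
    } else {
      bad <- setdiff(names(sc$neonatal_links), neonatal_ids)
      if (length(bad) > 0) {
        abort_validation(sprintf("neonatal link target '%s' is not a neonatal sub-condition", bad[1]),
                         f("neonatal_links"))
      }
      if (!setequal(names(sc$neonatal_links), names(sc$neonatal_links_treated))) {
        abort_validation("neonatal_links_treated must name the same sub-conditions as neonatal_links",
                         f("neonatal_links_treated"))
      }
      if (length(sc$neonatal_links) > 0) {
        lt <- sc$neonatal_links_treated[names(sc$neonatal_links)]
        if (any(lt > sc$neonatal_links)) {
          abort_validation("treated-stratum neonatal link rate exceeds untreated rate",
                           f("neonatal_links_treated"))
        }
      }
    }
  }

  uids <- vapply(model$interventions, intervention_uid, "")
  if (anyDuplicated(uids)) {
    abort_validation(sprintf("duplicate intervention (id, kind) pair '%s'",
                             uids[duplicated(uids)][1]), field = "interventions")
  }
  for (iv in model$interventions) {
    f <- function(x) sprintf("interventions[%s].%s", intervention_uid(iv), x)
    check_prob(iv$efficacy, f("efficacy"))
    check_prob(iv$fetal_efficacy, f("fetal_efficacy"))
    check_prob(iv$neonatal_efficacy, f("neonatal_efficacy"))
    bad <- setdiff(iv$targets, ids)
    if (length(bad) > 0) {
      abort_validation(sprintf("target sub-condition '%s' does not resolve", bad[1]),
                       f("targets"))
    }
    mode <- iv$composition$mode %||% "layer"
    if (!mode %in% c("layer", "line")) {
      abort_validation(sprintf("unknown composition mode '%s'", mode), f("composition.mode"))
    }
    if (mode == "line") {
      ord <- iv$composition$order
      if (is.null(ord) || !is.numeric(ord) || ord < 1 || ord != round(ord)) {
        abort_validation("line composition requires a positive integer order",
                         f("composition.order"))
      }
    }
  }

  # line orders unique and contiguous from 1 within each (sub-condition, kind)
  for (sid in ids) {
    for (kind in c("preventive", "diagnostic", "treatment")) {
      ords <- sort(vapply(
        Filter(function(iv) iv$kind == kind && sid %in% iv$targets &&
                 identical(iv$composition$mode %||% "layer", "line"),
               model$interventions),
        function(iv) as.numeric(iv$composition$order), 0))
      if (length(ords) > 0 && !identical(ords, as.numeric(seq_along(ords)))) {
        abort_validation(
          sprintf("line orders for (%s, %s) must be unique and contiguous from 1, got [%s]",
                  sid, kind, paste(ords, collapse = ", ")),
          field = "interventions")
      }
    }
    report <- check_usage_constraints(pathway_for(model, sid))
    if (any(report$violation)) {
      abort_validation(
        sprintf("single-use intervention '%s' appears more than once on the pathway of '%s'",
                report$intervention_id[report$violation][1], sid),
        field = "interventions")
    }
  }

  for (i in seq_along(model$transfers)) {
    tr <- model$transfers[[i]]
    f <- function(x) sprintf("transfers[%d].%s", i, x)
    check_setting(tr$from, f("from"))
    check_setting(tr$to, f("to"))
    check_prob(tr$probability, f("probability"))
    if (!tr$to %in% c("clinic", "hospital") ||
        setting_rank(tr$to) <= setting_rank(tr$from)) {
      abort_validation("transfers must move strictly up the ladder home < clinic < hospital",
                       f("to"))
    }
    bad <- setdiff(tr$subconditions, ids)
    if (length(bad) > 0) {
      abort_validation(sprintf("sub-condition '%s' does not resolve", bad[1]),
                       f("subconditions"))
    }
  }
  check_transfer_sums(transfer_table(model$transfers), "transfers")

  invisible(model)
}

transfer_table <- function(transfers) {
  if (length(transfers) == 0) {
    return(data.frame(from = character(), to = character(),
                      subcondition = character(), probability = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(transfers, function(tr) {
    data.frame(from = tr$from, to = tr$to, subcondition = tr$subconditions,
               probability = tr$probability, stringsAsFactors = FALSE)
  }))
}

check_transfer_sums <- function(tab, field) {
  if (nrow(tab) == 0) return(invisible(TRUE))
  key <- paste(tab$subcondition, tab$from)
  if (anyDuplicated(paste(key, tab$to))) {
    abort_validation("duplicate transfer rule for the same (sub-condition, from, to)", field)
  }
  sums <- tapply(tab$probability, key, sum)
  if (any(sums > 1 + 1e-12)) {
    abort_validation(
      sprintf("outgoing transfer probabilities for (%s) sum to %.4f > 1",
              names(sums)[which(sums > 1 + 1e-12)[1]], max(sums)), field)
  }
  invisible(TRUE)
}

# all (intervention, stage) slots touching one sub-condition, for usage checks
pathway_for <- function(model, sub_id) {
  ivs <- Filter(function(iv) sub_id %in% iv$targets, model$interventions)
  stage_of <- c(preventive = "prevention", diagnostic = "diagnosis",
                treatment = "treatment")
  data.frame(
    intervention_id = vapply(ivs, `[[`, "", "id"),
    stage = unname(stage_of[vapply(ivs, `[[`, "", "kind")]),
    single_use = vapply(ivs, `[[`, TRUE, "single_use"),
    timing = vapply(ivs, function(iv) paste(sort(iv$timing_tags), collapse = "+"), ""),
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# file IO (JSON dialect)

#' Read a model definition file
#'
#' The on-disk dialect is versioned JSON; [write_model()] is its inverse and
#' the pair round-trips field-for-field. See the packaged
#' `inst/extdata/model-schema.md` for the full schema.
#'
#' @param path Path to a model-definition JSON file.
#' @return A validated `mnh_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("model file '%s' does not exist", path))
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) abort_parse(sprintf("cannot parse '%s': %s", path, conditionMessage(e))))
  model_from_list(raw)
}

model_from_list <- function(raw) {
  subs <- lapply(raw$sub_conditions, function(s) {
    sub_condition(
      id = s$id, condition_id = s$condition_id, population = s$population,
      unprevented_incidence = s$unprevented_incidence,
      untreated_cfr = s$untreated_cfr,
      treated_cfr = s$treated_cfr %||% 0,
      fetal_death_rate_untreated = s$fetal_death_rate_untreated %||% 0,
      fetal_death_rate_treated = s$fetal_death_rate_treated %||% 0,
      neonatal_links = s$neonatal_links,
      neonatal_links_treated = s$neonatal_links_treated
    )
  })
  ivs <- lapply(raw$interventions, function(v) {
    intervention(
      id = v$id, kind = v$kind, targets = unlist(v$targets),
      efficacy = v$efficacy,
      penetration = unlist(v$penetration), utilization = unlist(v$utilization),
      fetal_efficacy = v$fetal_efficacy %||% 0,
      neonatal_efficacy = v$neonatal_efficacy %||% 0,
      composition = lapply(v$composition %||% list(mode = "layer"), identity),
      single_use = isTRUE(v$single_use),
      timing_tags = as.character(unlist(v$timing_tags))
    )
  })
  trs <- lapply(raw$transfers, function(t) {
    transfer_rule(from = t$from, to = t$to, probability = t$probability,
                  subconditions = unlist(t$subconditions))
  })
  model_definition(subs, ivs, trs,
                   schema_version = raw$schema_version %||% "(missing)")
}

model_to_list <- function(model) {
  list(
    schema_version = model$schema_version,
    sub_conditions = lapply(model$sub_conditions, function(s) {
      out <- list(id = s$id, condition_id = s$condition_id,
                  population = s$population,
                  unprevented_incidence = s$unprevented_incidence,
                  untreated_cfr = s$untreated_cfr, treated_cfr = s$treated_cfr,
                  fetal_death_rate_untreated = s$fetal_death_rate_untreated,
                  fetal_death_rate_treated = s$fetal_death_rate_treated)
      if (length(s$neonatal_links) > 0) {
        out$neonatal_links <- as.list(s$neonatal_links)
        out$neonatal_links_treated <- as.list(s$neonatal_links_treated)
      }
      out
    }),
    interventions = lapply(model$interventions, function(v) {
      list(id = v$id, kind = v$kind, targets = as.list(v$targets),
           efficacy = v$efficacy,
           penetration = as.list(v$penetration),
           utilization = as.list(v$utilization),
           fetal_efficacy = v$fetal_efficacy,
           neonatal_efficacy = v$neonatal_efficacy,
           composition = v$composition,
           single_use = v$single_use,
           timing_tags = as.list(v$timing_tags))
    }),
    transfers = lapply(model$transfers, function(t) {
      list(from = t$from, to = t$to, probability = t$probability,
           subconditions = as.list(t$subconditions))
    })
  )
}

#' Write a model definition file
#'
#' @param model An `mnh_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.mnh_model <- function(x, ...) {
  pops <- vapply(x$sub_conditions, `[[`, "", "population")
  cat(sprintf("<mnh_model> schema %s: %d sub-conditions (%d maternal, %d neonatal), %d interventions, %d transfer rules\n",
              x$schema_version, length(x$sub_conditions), sum(pops == "maternal"),
              sum(pops == "neonatal"), length(x$interventions), length(x$transfers)))
  invisible(x)
}
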