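#' Create a cohort stratum
#'
#' A stratum is an expected-count mass of pregnancies labelled by care
#' setting, condition status, diagnosis status, and treatment outcome. The
#' deterministic engine moves expected mass between strata; nothing is ever
#' rounded until report rendering.
#'
#' @param mass Expected number of pregnancies (non-negative).
#' @param setting One of [settings()].
#' @param condition_positive,diagnosed,treated Logical flags (`NA` where not
#'   yet determined / not applicable).
#' @return An object of class `mnh_stratum`.
#' @export
cohort_stratum <- function(mass, setting, condition_positive = NA,
                           diagnosed = NA, treated = NA) {
  if (!is.numeric(mass) || is.na(mass) || mass < 0) {
    abort_validation("mass must be non-negative", "stratum.mass")
  }
  check_setting(setting, "stratum.setting")
  if (isTRUE(diagnosed) && !isTRUE(condition_positive)) {
    abort_validation("a diagnosed stratum must be condition-positive", "stratum.diagnosed")
  }
  structure(list(mass = as.numeric(mass), setting = setting,
                 condition_positive = condition_positive,
                 diagnosed = diagnosed, treated = treated),
            class = "mnh_stratum")
}

#' Initial cohort strata for a scenario
#'
#' One stratum per care setting, with mass `births * setting fraction`.
#' Masses always sum to `births`.
#'
#' @param params An `mnh_scenario`.
#' @return List of three `mnh_stratum` objects (home, clinic, hospital).
#' @export
initial_strata <- function(params) {
  out <- lapply(settings(), function(s) {
    cohort_stratum(params$births * params$setting_distribution[[s]], s)
  })
  assert_conserved(params$births,
                   vapply(out, `[[`, 0, "mass"), "initial_strata")
  out
}

#' Split a stratum by prevention outcome
#'
#' Condition-positive mass is `mass * unprevented_incidence *
#' (1 - prevention_success)`; everyone else (never-would-have-developed plus
#' successfully prevented) is condition-negative and carries zero mortality
#' risk from this sub-condition.
#'
#' @param stratum An `mnh_stratum`.
#' @param sub An `mnh_subcondition` (its `unprevented_incidence` is used).
#' @param prevention_success Combined stage success probability of the
#'   preventive interventions at the stratum's setting.
#' @param extra_incidence Additional incident case mass entering this stratum
#'   (used for maternal-induced neonatal cases); subject to prevention.
#' @return `list(positive =, negative =)` of `mnh_stratum`.
#' @export
apply_prevention <- function(stratum, sub, prevention_success,
                             extra_incidence = 0) {
  check_prob(prevention_success, "prevention_success")
  at_risk <- stratum$mass * sub$unprevented_incidence + extra_incidence
  pos <- at_risk * (1 - prevention_success)
  neg <- stratum$mass + extra_incidence - pos
  out <- list(
    positive = cohort_stratum(pos, stratum$setting, condition_positive = TRUE),
    negative = cohort_stratum(neg, stratum$setting, condition_positive = FALSE)
  )
  assert_conserved(stratum$mass + extra_incidence, c(pos, neg), "apply_prevention")
  out
}

#' Split a condition-positive stratum by diagnosis
#'
#' Only diagnosed mass can go on to transfer or treatment; undiagnosed mass
#' faces the untreated case fatality rate. Condition-negative strata are never
#' granted treatment benefit (false positives receive none), so they simply
#' never enter this split.
#'
#' @param positive A condition-positive `mnh_stratum`.
#' @param diagnosis_success Combined stage success probability of the
#'   diagnostics at the stratum's setting.
#' @return `list(diagnosed =, undiagnosed =)`.
#' @export
apply_diagnosis <- function(positive, diagnosis_success) {
  check_prob(diagnosis_success, "diagnosis_success")
  if (!isTRUE(positive$condition_positive)) {
    abort_validation("diagnosis applies to condition-positive strata only",
                     "apply_diagnosis")
  }
  d <- positive$mass * diagnosis_success
  out <- list(
    diagnosed = cohort_stratum(d, positive$setting, TRUE, diagnosed = TRUE),
    undiagnosed = cohort_stratum(positive$mass - d, positive$setting, TRUE,
                                 diagnosed = FALSE)
  )
  assert_conserved(positive$mass, c(d, positive$mass - d), "apply_diagnosis")
  out
}

#' Split a diagnosed stratum across transfer destinations
#'
#' At most one transfer per pregnancy per sub-condition, taken immediately
#' after diagnosis and before treatment. Movers adopt the destination setting
#' (and hence its treatment penetration/utilization); the stay probability is
#' `1 - sum(transfer probabilities)`.
#'
#' @param diagnosed A diagnosed `mnh_stratum`.
#' @param rules Data frame of applicable rules (columns `to`, `probability`),
#'   already filtered to the stratum's setting and sub-condition.
#' @return List of diagnosed strata (stayers first, then one per destination);
#'   masses sum to the input mass.
#' @export
apply_transfer <- function(diagnosed, rules) {
  if (is.null(rules) || nrow(rules) == 0) {
    return(list(diagnosed))
  }
  check_prob(rules$probability, "transfer.probability")
  ptot <- sum(rules$probability)
  if (ptot > 1 + 1e-12) {
    abort_validation(sprintf("transfer probabilities out of '%s' sum to %.4f > 1",
                             diagnosed$setting, ptot), "transfers")
  }
  out <- c(
    list(cohort_stratum(diagnosed$mass * (1 - ptot), diagnosed$setting, TRUE,
                        diagnosed = TRUE)),
    lapply(seq_len(nrow(rules)), function(i) {
      cohort_stratum(diagnosed$mass * rules$probability[i], rules$to[i], TRUE,
                     diagnosed = TRUE)
    })
  )
  assert_conserved(diagnosed$mass, vapply(out, `[[`, 0, "mass"), "apply_transfer")
  out
}

#' Split a diagnosed stratum by treatment outcome
#'
#' @param diagnosed A diagnosed `mnh_stratum` (post-transfer).
#' @param treatment_success Combined treatment stage success at the stratum's
#'   (destination) setting.
#' @return `list(success =, failure =)`.
#' @export
apply_treatment <- function(diagnosed, treatment_success) {
  check_prob(treatment_success, "treatment_success")
  if (!isTRUE(diagnosed$diagnosed)) {
    abort_validation("treatment requires a diagnosed stratum", "apply_treatment")
  }
  s <- diagnosed$mass * treatment_success
  out <- list(
    success = cohort_stratum(s, diagnosed$setting, TRUE, TRUE, treated = TRUE),
    failure = cohort_stratum(diagnosed$mass - s, diagnosed$setting, TRUE, TRUE,
                             treated = FALSE)
  )
  assert_conserved(diagnosed$mass, c(s, diagnosed$mass - s), "apply_treatment")
  out
}

#' Expected deaths over a set of terminal strata
#'
#' Mass that was never diagnosed, never treated, or failed treatment dies at
#' the untreated case fatality rate; successfully treated mass at the (lower)
#' treated rate. Fetal deaths are computed analogously from the stratum-
#' specific fetal death rates; a `fetal_rate` column, when present, overrides
#' the default rate for a stratum (used for mass whose treatment also
#' delivered its distinct fetal benefit).
#'
#' @param strata Either a list of `mnh_stratum` objects or a data frame with
#'   columns `mass`, `treated` (logical; `NA` counts as untreated) and
#'   optionally `fetal_rate`.
#' @param sub An `mnh_subcondition` supplying the rates.
#' @return `list(maternal_deaths =, fetal_deaths =)` (fetal 0 for neonatal
#'   sub-conditions, where the "maternal" slot is the deaths of that
#'   population).
#' @export
compute_mortality <- function(strata, sub) {
  df <- strata_frame(strata)
  treated <- !is.na(df$treated) & df$treated
  cfr <- ifelse(treated, sub$treated_cfr, sub$untreated_cfr)
  deaths <- sum(df$mass * cfr)
  if (sub$population == "maternal") {
    frate <- ifelse(treated, sub$fetal_death_rate_treated,
                    sub$fetal_death_rate_untreated)
    if (!is.null(df$fetal_rate)) {
      frate <- ifelse(is.na(df$fetal_rate), frate, df$fetal_rate)
    }
    fetal <- sum(df$mass * frate)
  } else {
    fetal <- 0
  }
  list(maternal_deaths = deaths, fetal_deaths = fetal)
}

strata_frame <- function(strata) {
  if (is.data.frame(strata)) return(strata)
  data.frame(
    mass = vapply(strata, `[[`, 0, "mass"),
    setting = vapply(strata, `[[`, "", "setting"),
    treated = vapply(strata, function(s) as.logical(s$treated), NA),
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# stage composition against resolved scenario tables

# resolved items feeding one (sub-condition, kind, setting) stage
stage_items <- function(model, params, sub_id, kind, setting) {
  out <- list()
  for (iv in model$interventions) {
    if (iv$kind != kind || !sub_id %in% iv$targets) next
    uid <- intervention_uid(iv)
    cov <- params$coverage[params$coverage$intervention == uid &
                             params$coverage$setting == setting, ]
    eff <- params$efficacy[params$efficacy$intervention == uid, ]
    out[[uid]] <- list(
      uid = uid,
      receive = coverage(cov$penetration, cov$utilization),
      efficacy = eff$efficacy,
      fetal_efficacy = eff$fetal_efficacy,
      neonatal_efficacy = eff$neonatal_efficacy,
      mode = iv$composition$mode %||% "layer",
      order = iv$composition$order %||% NA_real_
    )
  }
  out
}

# collapse stage items into success / failure / no-benefit probabilities.
# "no benefit" terms: probability that NO administered-and-successful
# intervention also delivered its fetal (resp. neonatal) benefit; benefits are
# drawn independently with probability fetal_efficacy / neonatal_efficacy per
# succeeding intervention. Closed forms:
#   layers:      P(no benefit) = prod(1 - s_i * b_i)
#   line group:  P(no benefit) = 1 - sum(adm_k * e_k * b_k)
# and P(success & no benefit) = P(no benefit) - P(failure).
compose_stage <- function(items) {
  if (length(items) == 0) {
    return(list(success = 0, fail = 1, no_fetal = 1, no_neonatal = 1,
                administered = stats::setNames(numeric(0), character(0))))
  }
  layers <- Filter(function(x) x$mode == "layer", items)
  lines <- Filter(function(x) x$mode == "line", items)
  adm <- c()

  s_l <- vapply(layers, function(x) success(x$receive, x$efficacy), 0)
  fail <- if (length(s_l)) prod(1 - s_l) else 1
  no_f <- if (length(layers)) {
    prod(vapply(layers, function(x) 1 - success(x$receive, x$efficacy) * x$fetal_efficacy, 0))
  } else 1
  no_n <- if (length(layers)) {
    prod(vapply(layers, function(x) 1 - success(x$receive, x$efficacy) * x$neonatal_efficacy, 0))
  } else 1
  adm <- stats::setNames(vapply(layers, `[[`, 0, "receive"),
                         vapply(layers, `[[`, "", "uid"))

  if (length(lines) > 0) {
    ord <- order(vapply(lines, `[[`, 0, "order"))
    lines <- lines[ord]
    lt <- data.frame(receive = vapply(lines, `[[`, 0, "receive"),
                     efficacy = vapply(lines, `[[`, 0, "efficacy"))
    cl <- compose_lines(lt)
    fail <- fail * (1 - cl$overall)
    e <- lt$efficacy
    no_f <- no_f * (1 - sum(cl$administered * e *
                              vapply(lines, `[[`, 0, "fetal_efficacy")))
    no_n <- no_n * (1 - sum(cl$administered * e *
                              vapply(lines, `[[`, 0, "neonatal_efficacy")))
    adm <- c(adm, stats::setNames(cl$administered, vapply(lines, `[[`, "", "uid")))
  }
  list(success = 1 - fail, fail = fail, no_fetal = no_f, no_neonatal = no_n,
       administered = adm)
}

# ---------------------------------------------------------------------------
# full decision tree for one sub-condition

#' Run one sub-condition through the full decision tree
#'
#' Executes, per initial care setting: cohort initialisation, prevention,
#' diagnosis, transfer (once, after diagnosis, before treatment), treatment at
#' the final setting, and mortality accounting. Maternal sub-conditions also
#' accumulate fetal deaths and incremental neonatal-condition incidence
#' (attributed to each stratum's final setting).
#'
#' @param sub An `mnh_subcondition` (typically an element of
#'   `model$sub_conditions`).
#' @param model The `mnh_model`.
#' @param params A resolved `mnh_scenario`.
#' @param extra_incidence Optional data frame `(setting, mass)` of additional
#'   incident case mass (maternal-induced neonatal cases).
#' @return An object of class `mnh_subresult`: expected `cases`,
#'   `maternal_deaths`, `fetal_deaths`, `neonatal_deaths`,
#'   `neonatal_contributions` (data frame `neonatal_id`, `setting`, `mass`),
#'   `administered` (expected receipt counts per intervention uid), and a
#'   tidy `strata_trace` audit trail.
#' @export
run_subcondition <- function(sub, model, params, extra_incidence = NULL) {
  rates <- params$rates[params$rates$subcondition == sub$id, ]
  if (nrow(rates) != 1) {
    abort_validation(sprintf("no scenario rates for sub-condition '%s'", sub$id),
                     "rates")
  }
  # effective sub-condition: model structure + scenario rates
  eff_sub <- sub
  eff_sub$unprevented_incidence <- rates$unprevented_incidence
  eff_sub$untreated_cfr <- rates$untreated_cfr
  eff_sub$treated_cfr <- rates$treated_cfr
  eff_sub$fetal_death_rate_untreated <- rates$fetal_death_rate_untreated
  eff_sub$fetal_death_rate_treated <- rates$fetal_death_rate_treated

  trace <- list()
  push <- function(step, st, origin = NA_character_, fetal_benefit = NA) {
    trace[[length(trace) + 1]] <<- data.frame(
      step = step, setting = st$setting, origin = origin, mass = st$mass,
      condition_positive = st$condition_positive, diagnosed = st$diagnosed,
      treated = st$treated, fetal_benefit = fetal_benefit,
      stringsAsFactors = FALSE)
  }

  administered <- stats::setNames(numeric(0), character(0))
  tally <- function(adm, eligible_mass) {
    for (uid in names(adm)) {
      cur <- unname(administered[uid])
      if (is.na(cur)) cur <- 0
      administered[uid] <<- cur + adm[[uid]] * eligible_mass
    }
  }

  terminal <- list() # rows: mass, treated, fetal_rate, setting, neonatal kind
  contrib <- list()
  cases_total <- 0

  for (st0 in initial_strata(params)) {
    s <- st0$setting
    extra <- 0
    if (!is.null(extra_incidence)) {
      hit <- extra_incidence$setting == s
      if (any(hit)) extra <- sum(extra_incidence$mass[hit])
    }
    push("initial", st0)
    if (extra > 0) push("initial_extra", cohort_stratum(extra, s))

    prev <- compose_stage(stage_items(model, params, sub$id, "preventive", s))
    tally(prev$administered, st0$mass)
    split <- apply_prevention(st0, eff_sub, prev$success, extra_incidence = extra)
    push("prevention", split$positive)
    push("prevention", split$negative)
    cases_total <- cases_total + split$positive$mass

    diag <- compose_stage(stage_items(model, params, sub$id, "diagnostic", s))
    tally(diag$administered, split$positive$mass)
    dsplit <- apply_diagnosis(split$positive, diag$success)
    push("diagnosis", dsplit$diagnosed)
    push("diagnosis", dsplit$undiagnosed)

    terminal[[length(terminal) + 1]] <- data.frame(
      mass = dsplit$undiagnosed$mass, treated = FALSE, fetal_rate = NA_real_,
      setting = s, stringsAsFactors = FALSE)

    rules <- params$transfers[params$transfers$subcondition == sub$id &
                                params$transfers$from == s, , drop = FALSE]
    parcels <- apply_transfer(dsplit$diagnosed, rules)
    for (p in parcels) push("transfer", p, origin = s)

    for (p in parcels) {
      if (p$mass == 0 && length(model$interventions) == 0) next
      tr <- compose_stage(stage_items(model, params, sub$id, "treatment", p$setting))
      tally(tr$administered, p$mass)
      tsplit <- apply_treatment(p, tr$success)
      push("treatment", tsplit$success, origin = s)
      push("treatment", tsplit$failure, origin = s)

      succ_no_fb <- p$mass * (tr$no_fetal - tr$fail)
      succ_fb <- tsplit$success$mass - succ_no_fb
      succ_no_nb <- p$mass * (tr$no_neonatal - tr$fail)
      succ_nb <- tsplit$success$mass - succ_no_nb
      assert_conserved(tsplit$success$mass, c(succ_no_fb, succ_fb), "fetal benefit split")
      assert_conserved(tsplit$success$mass, c(succ_no_nb, succ_nb), "neonatal benefit split")

      terminal[[length(terminal) + 1]] <- data.frame(
        mass = c(tsplit$failure$mass, succ_no_fb, succ_fb),
        treated = c(FALSE, TRUE, TRUE),
        fetal_rate = c(NA_real_, NA_real_, 0),
        setting = p$setting, stringsAsFactors = FALSE)

      # link-induced neonatal cases keep the original delivery setting:
      # maternal referral changes maternal treatment access only, so the
      # diagnosis gate stays exactly equivalent to the treatment gate
      if (sub$population == "maternal" && length(sub$neonatal_links) > 0) {
        for (nid in names(sub$neonatal_links)) {
          contrib[[length(contrib) + 1]] <- data.frame(
            neonatal_id = nid, setting = s,
            mass = tsplit$failure$mass * sub$neonatal_links[[nid]] +
              succ_no_nb * sub$neonatal_links_treated[[nid]],
            stringsAsFactors = FALSE)
        }
      }
    }
    if (sub$population == "maternal" && length(sub$neonatal_links) > 0) {
      for (nid in names(sub$neonatal_links)) {
        contrib[[length(contrib) + 1]] <- data.frame(
          neonatal_id = nid, setting = s,
          mass = dsplit$undiagnosed$mass * sub$neonatal_links[[nid]],
          stringsAsFactors = FALSE)
      }
    }
  }

  term <- do.call(rbind, terminal)
  mort <- compute_mortality(term, eff_sub)
  contrib_df <- if (length(contrib) > 0) {
    agg <- do.call(rbind, contrib)
    stats::aggregate(mass ~ neonatal_id + setting, data = agg, FUN = sum)
  } else {
    data.frame(neonatal_id = character(), setting = character(),
               mass = numeric(), stringsAsFactors = FALSE)
  }

  structure(list(
    subcondition_id = sub$id,
    condition_id = sub$condition_id,
    population = sub$population,
    cases = cases_total,
    maternal_deaths = if (sub$population == "maternal") mort$maternal_deaths else 0,
    fetal_deaths = mort$fetal_deaths,
    neonatal_deaths = if (sub$population == "neonatal") mort$maternal_deaths else 0,
    neonatal_contributions = contrib_df,
    administered = administered,
    strata_trace = do.call(rbind, trace)
  ), class = "mnh_subresult")
}

#' Collect maternal-induced neonatal incidence
#'
#' Aggregates the per-setting neonatal-condition incidence contributions of
#' the evaluated maternal sub-conditions. Successfully treated maternal
#' strata contribute at the reduced, treated-link rate (zero for the mass
#' whose treatment also delivered its neonatal benefit); the flow is strictly
#' one-way — neonatal results never feed back into maternal or fetal deaths.
#'
#' @param maternal_results List of `mnh_subresult` for maternal
#'   sub-conditions.
#' @param model The `mnh_model` (used to verify the link targets).
#' @return Named list: neonatal sub-condition id -> data frame
#'   `(setting, mass)` of added incident case mass.
#' @export
propagate_neonatal <- function(maternal_results, model) {
  all_contrib <- do.call(rbind, c(
    list(data.frame(neonatal_id = character(), setting = character(),
                    mass = numeric(), stringsAsFactors = FALSE)),
    lapply(maternal_results, `[[`, "neonatal_contributions")))
  out <- list()
  for (nid in unique(all_contrib$neonatal_id)) {
    rows <- all_contrib[all_contrib$neonatal_id == nid, , drop = FALSE]
    out[[nid]] <- stats::aggregate(mass ~ setting, data = rows, FUN = sum)
  }
  out
}
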