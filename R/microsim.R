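#' Individual-level Monte Carlo oracle
#'
#' Re-implements the decision tree by explicit per-individual Bernoulli event
#' sequencing — setting assignment, condition onset, per-intervention receipt
#' and success (with line cascades walked event by event), diagnosis,
#' transfer, treatment, and death draws. It deliberately shares none of the
#' analytic engine's probability-composition code and exists purely to verify
#' it: as `n` grows, simulated death rates converge to the analytic expected
#' rates.
#'
#' The production model itself is deterministic; this stochastic module is a
#' verification harness, not a forecasting mode.
#'
#' @param model An `mnh_model`.
#' @param params A resolved `mnh_scenario` (its `births` is ignored; rates are
#'   per pregnancy).
#' @param n Number of simulated pregnancies.
#' @param seed Integer seed; the same seed and configuration give an
#'   identical event stream.
#' @return An object of class `mnh_microsim`: `deaths` (data frame
#'   `subcondition`, `population`, `deaths`, `rate`), `cases` (named counts),
#'   `n`, `seed`.
#' @export
microsim <- function(model, params, n = 1e5, seed = 1L) {
  stopifnot(inherits(model, "mnh_model"), inherits(params, "mnh_scenario"),
            n >= 1)
  set.seed(as.integer(seed))
  setting_draw <- sample(settings(), n, replace = TRUE,
                         prob = params$setting_distribution[settings()])

  pops <- vapply(model$sub_conditions, `[[`, "", "population")
  deaths_rows <- list()
  cases <- stats::setNames(numeric(0), character(0))
  extra_settings <- list() # neonatal id -> character vector of case settings

  for (sub in model$sub_conditions[pops == "maternal"]) {
    r <- sim_one_sub(model, params, sub, setting_draw)
    cases[sub$id] <- r$cases
    deaths_rows[[length(deaths_rows) + 1]] <- data.frame(
      subcondition = sub$id, population = c("maternal", "fetal"),
      deaths = c(r$deaths, r$fetal_deaths), stringsAsFactors = FALSE)
    for (nid in names(r$link_settings)) {
      extra_settings[[nid]] <- c(extra_settings[[nid]], r$link_settings[[nid]])
    }
  }
  for (sub in model$sub_conditions[pops == "neonatal"]) {
    r <- sim_one_sub(model, params, sub, setting_draw,
                     extra_case_settings = extra_settings[[sub$id]])
    cases[sub$id] <- r$cases
    deaths_rows[[length(deaths_rows) + 1]] <- data.frame(
      subcondition = sub$id, population = "neonatal", deaths = r$deaths,
      stringsAsFactors = FALSE)
  }
  deaths <- do.call(rbind, deaths_rows)
  deaths$rate <- deaths$deaths / n
  structure(list(deaths = deaths, cases = cases, n = n, seed = seed),
            class = "mnh_microsim")
}

# simulate one sub-condition for the whole cohort; vectorized over
# individuals, but every stochastic step is an explicit per-individual draw.
sim_one_sub <- function(model, params, sub, setting_draw,
                        extra_case_settings = NULL) {
  n <- length(setting_draw)
  rates <- params$rates[params$rates$subcondition == sub$id, ]

  # onset draws: base incidence over the cohort, plus maternal-induced cases
  would <- stats::runif(n) < rates$unprevented_incidence
  st <- c(setting_draw[would], extra_case_settings)
  k <- length(st)
  if (k == 0) {
    return(list(cases = 0, deaths = 0, fetal_deaths = 0,
                link_settings = list()))
  }

  prevented <- sim_stage(model, params, sub$id, "preventive", st)$success
  st <- st[!prevented]
  k <- length(st)
  cases <- k
  if (k == 0) {
    return(list(cases = 0, deaths = 0, fetal_deaths = 0, link_settings = list()))
  }

  diagnosed <- sim_stage(model, params, sub$id, "diagnostic", st)$success

  # transfer draw for diagnosed individuals only, one move at most
  final_st <- st
  for (s in settings()) {
    rules <- params$transfers[params$transfers$subcondition == sub$id &
                                params$transfers$from == s, , drop = FALSE]
    if (nrow(rules) == 0) next
    idx <- which(diagnosed & st == s)
    if (length(idx) == 0) next
    u <- stats::runif(length(idx))
    cum <- cumsum(rules$probability)
    dest <- rep(s, length(idx))
    for (j in rev(seq_len(nrow(rules)))) {
      dest[u < cum[j]] <- rules$to[j]
    }
    final_st[idx] <- dest
  }

  tr <- sim_stage(model, params, sub$id, "treatment", final_st,
                  active = diagnosed, want_benefit = TRUE)
  treated <- tr$success # implies diagnosed

  death_p <- ifelse(treated, rates$treated_cfr, rates$untreated_cfr)
  died <- stats::runif(k) < death_p

  fetal_deaths <- 0
  link_settings <- list()
  if (sub$population == "maternal") {
    fet_p <- ifelse(treated,
                    ifelse(tr$fetal_benefit, 0, rates$fetal_death_rate_treated),
                    rates$fetal_death_rate_untreated)
    fetal_deaths <- sum(stats::runif(k) < fet_p)
    for (nid in names(sub$neonatal_links)) {
      link_p <- ifelse(treated,
                       ifelse(tr$neonatal_benefit, 0,
                              sub$neonatal_links_treated[[nid]]),
                       sub$neonatal_links[[nid]])
      hit <- stats::runif(k) < link_p
      # induced neonatal cases keep the original delivery setting (maternal
      # referral changes maternal treatment access only)
      link_settings[[nid]] <- st[hit]
    }
  }
  list(cases = cases, deaths = sum(died), fetal_deaths = fetal_deaths,
       link_settings = link_settings)
}

# per-individual stage walk: each layer is an independent receive/success
# draw; the line cascade is walked in order, an individual reaching line k
# only after receiving and failing line k - 1. Benefits (fetal/neonatal) are
# drawn per succeeding intervention.
sim_stage <- function(model, params, sub_id, kind, st, active = NULL,
                      want_benefit = FALSE) {
  k <- length(st)
  if (is.null(active)) active <- rep(TRUE, k)
  succ <- rep(FALSE, k)
  fb <- rep(FALSE, k)
  nb <- rep(FALSE, k)

  ivs <- Filter(function(iv) iv$kind == kind && sub_id %in% iv$targets,
                model$interventions)
  if (length(ivs) == 0 || k == 0) {
    return(list(success = succ, fetal_benefit = fb, neonatal_benefit = nb))
  }

  recv_prob <- function(iv, st_vec) {
    uid <- intervention_uid(iv)
    cov <- params$coverage[params$coverage$intervention == uid, ]
    pen <- stats::setNames(cov$penetration, cov$setting)[st_vec]
    use <- stats::setNames(cov$utilization, cov$setting)[st_vec]
    unname(pen * use)
  }
  eff_of <- function(iv) {
    e <- params$efficacy[params$efficacy$intervention == intervention_uid(iv), ]
    e
  }

  is_line <- vapply(ivs, function(iv) identical(iv$composition$mode %||% "layer", "line"), TRUE)
  layers <- ivs[!is_line]
  lines <- ivs[is_line]
  if (length(lines) > 0) {
    lines <- lines[order(vapply(lines, function(iv) as.numeric(iv$composition$order), 0))]
  }

  for (iv in layers) {
    e <- eff_of(iv)
    got <- active & (stats::runif(k) < recv_prob(iv, st))
    ok <- got & (stats::runif(k) < e$efficacy)
    succ <- succ | ok
    if (want_benefit) {
      fb <- fb | (ok & (stats::runif(k) < e$fetal_efficacy))
      nb <- nb | (ok & (stats::runif(k) < e$neonatal_efficacy))
    }
  }

  eligible <- active # eligible for the next line: received previous and failed
  for (j in seq_along(lines)) {
    iv <- lines[[j]]
    e <- eff_of(iv)
    got <- eligible & (stats::runif(k) < recv_prob(iv, st))
    ok <- got & (stats::runif(k) < e$efficacy)
    succ <- succ | ok
    if (want_benefit) {
      fb <- fb | (ok & (stats::runif(k) < e$fetal_efficacy))
      nb <- nb | (ok & (stats::runif(k) < e$neonatal_efficacy))
    }
    eligible <- got & !ok
  }
  list(success = succ, fetal_benefit = fb, neonatal_benefit = nb)
}

#' Compare analytic and simulated death rates
#'
#' Computes, per (sub-condition, population), the z-score of the simulated
#' death rate against the analytic expected rate under the binomial standard
#' error `sqrt(p (1 - p) / n)`, and flags `|z| > threshold` (default 4).
#'
#' @param analytic An `mnh_result` from [run_scenario()].
#' @param simulated An `mnh_microsim` from [microsim()] on the same model and
#'   parameters.
#' @param threshold Flagging threshold in standard errors.
#' @return Data frame with columns `subcondition`, `population`,
#'   `analytic_rate`, `simulated_rate`, `z`, `flagged`.
#' @export
oracle_compare <- function(analytic, simulated, threshold = 4) {
  stopifnot(inherits(analytic, "mnh_result"), inherits(simulated, "mnh_microsim"))
  n <- simulated$n
  a <- analytic$deaths
  a$analytic_rate <- a$deaths / analytic$births
  key <- paste(a$subcondition, a$population)
  s <- simulated$deaths
  skey <- paste(s$subcondition, s$population)
  a$simulated_rate <- s$rate[match(key, skey)]
  p <- pmin(pmax(a$analytic_rate, 0), 1)
  se <- sqrt(p * (1 - p) / n)
  z <- ifelse(se == 0,
              ifelse(a$simulated_rate == a$analytic_rate, 0, Inf),
              (a$simulated_rate - a$analytic_rate) / se)
  a$z <- z
  a$flagged <- abs(z) > threshold
  a[, c("subcondition", "population", "analytic_rate", "simulated_rate", "z",
        "flagged")]
}
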