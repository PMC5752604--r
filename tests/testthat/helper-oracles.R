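# independent brute-force oracles for probability composition, plus shared
# tiny fixtures. These enumerate joint Bernoulli outcomes explicitly and are
# kept free of the package's composition formulas.

# P(at least one layer succeeds), by enumeration of all 2^n joint outcomes
enum_layers <- function(successes) {
  n <- length(successes)
  if (n == 0) return(0)
  total <- 0
  for (mask in seq_len(2^n) - 1) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    p <- prod(ifelse(bits == 1, successes, 1 - successes))
    if (any(bits == 1)) total <- total + p
  }
  total
}

# P(cascade success) for ordered lines, by explicit event-tree recursion:
# at line k the remaining mass either does not receive it (cascade ends),
# receives and succeeds, or receives, fails and proceeds to line k + 1
enum_lines <- function(receive, efficacy) {
  rec <- function(k, pmass) {
    if (k > length(receive)) return(0)
    pmass * receive[k] * efficacy[k] +
      rec(k + 1, pmass * receive[k] * (1 - efficacy[k]))
  }
  rec(1, 1)
}

# administered mass fraction per line, same event tree
enum_lines_administered <- function(receive, efficacy) {
  adm <- numeric(length(receive))
  pmass <- 1
  for (k in seq_along(receive)) {
    adm[k] <- pmass * receive[k]
    pmass <- adm[k] * (1 - efficacy[k])
  }
  adm
}

# minimal two-condition model: one maternal sub-condition feeding one
# neonatal sub-condition, with one intervention per stage
toy_model <- function(link = 0.3, link_treated = link) {
  model_definition(
    sub_conditions = list(
      sub_condition("eclampsia", "hypertension", "maternal",
                    unprevented_incidence = 0.1, untreated_cfr = 0.02,
                    treated_cfr = 0,
                    fetal_death_rate_untreated = 0.2,
                    fetal_death_rate_treated = 0.05,
                    neonatal_links = c(asphyxia = link),
                    neonatal_links_treated = c(asphyxia = link_treated)),
      sub_condition("asphyxia", "birth_asphyxia", "neonatal",
                    unprevented_incidence = 0.03, untreated_cfr = 0.3,
                    treated_cfr = 0.05)
    ),
    interventions = list(
      intervention("aspirin", "preventive", "eclampsia", efficacy = 0.3,
                   penetration = 0.5, utilization = 0.8),
      intervention("bp_screen", "diagnostic", "eclampsia", efficacy = 0.8,
                   penetration = c(home = 0.2, clinic = 0.6, hospital = 0.9),
                   utilization = 0.8),
      intervention("mgso4", "treatment", "eclampsia", efficacy = 0.6,
                   penetration = c(home = 0, clinic = 0.4, hospital = 0.8),
                   utilization = 0.8, fetal_efficacy = 0.5,
                   neonatal_efficacy = 0.4),
      intervention("resuscitation", "treatment", "asphyxia", efficacy = 0.5,
                   penetration = c(home = 0.1, clinic = 0.5, hospital = 0.8),
                   utilization = 0.7)
    ),
    transfers = list(
      transfer_rule("home", "hospital", 0.4, c("eclampsia", "asphyxia")),
      transfer_rule("clinic", "hospital", 0.3, c("eclampsia"))
    )
  )
}

toy_scenario <- function(model = toy_model(), births = 1000, ...) {
  scenario_parameters(model, "toy", births,
                      c(home = 0.5, clinic = 0.3, hospital = 0.2), ...)
}

# largest relative step-to-step mass-conservation gap recomputed from the
# audit trail (0 means every split conserved mass exactly)
trace_conservation_gap <- function(result) {
  gap <- 0
  rel <- function(a, b) abs(a - b) / max(1, abs(a))
  for (r in result$sub_results) {
    tr <- r$strata_trace
    entering <- sum(tr$mass[tr$step %in% c("initial", "initial_extra")])
    prevented <- sum(tr$mass[tr$step == "prevention"])
    positive <- sum(tr$mass[tr$step == "prevention" & tr$condition_positive])
    diagnosis <- sum(tr$mass[tr$step == "diagnosis"])
    diagnosed <- sum(tr$mass[tr$step == "diagnosis" & tr$diagnosed])
    transferred <- sum(tr$mass[tr$step == "transfer"])
    treated <- sum(tr$mass[tr$step == "treatment"])
    gap <- max(gap, rel(entering, prevented), rel(positive, diagnosis),
               rel(diagnosed, transferred), rel(transferred, treated))
  }
  gap
}

expect_trace_conserved <- function(result, tol = 1e-9) {
  expect_lt(trace_conservation_gap(result), tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
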