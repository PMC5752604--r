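#' Default model structure: major causes of maternal, fetal and neonatal death
#'
#' Encodes the standard condition / sub-condition inventory for maternal and
#' neonatal mortality modelling in low-resource settings: maternal obstructed
#' labor, infection (sepsis, syphilis, malaria), hemorrhage (placental
#' abruption, placenta previa, ruptured uterus, lacerations, atonic uterus,
#' retained placenta) and hypertensive disorders; fetal distress with an IUGR
#' leaf; and neonatal infection, birth asphyxia and preterm birth (with RDS,
#' IVH and NEC leaves). A representative set of preventive, diagnostic,
#' treatment and transfer interventions is attached, exercising layered
#' combination, line cascades, single-use constraints (cesarean) and
#' dual-timing re-use (oxytocin as prophylaxis and as treatment).
#'
#' **All numeric parameters are synthetic placeholders**, chosen to be
#' epidemiologically plausible in scale for a low-resource setting; they are
#' not estimates of any published data version and carry no evidential
#' weight. The structure is the fixture; the numbers are a demonstration.
#'
#' @return A validated `mnh_model`.
#' @export
default_model <- function() {
  subs <- list(
    # --- maternal ---------------------------------------------------------
    sub_condition("obstructed_labor", "obstructed_labor", "maternal",
                  unprevented_incidence = 0.05, untreated_cfr = 0.04,
                  treated_cfr = 0.002,
                  fetal_death_rate_untreated = 0.25, fetal_death_rate_treated = 0.03,
                  neonatal_links = c(birth_asphyxia = 0.30),
                  neonatal_links_treated = c(birth_asphyxia = 0.30)),
    sub_condition("sepsis", "maternal_infection", "maternal",
                  unprevented_incidence = 0.05, untreated_cfr = 0.15,
                  treated_cfr = 0.01,
                  fetal_death_rate_untreated = 0.10, fetal_death_rate_treated = 0.02,
                  neonatal_links = c(neonatal_sepsis = 0.20),
                  neonatal_links_treated = c(neonatal_sepsis = 0.20)),
    sub_condition("syphilis", "maternal_infection", "maternal",
                  unprevented_incidence = 0.03, untreated_cfr = 0.002,
                  fetal_death_rate_untreated = 0.20, fetal_death_rate_treated = 0.02),
    sub_condition("malaria", "maternal_infection", "maternal",
                  unprevented_incidence = 0.10, untreated_cfr = 0.01,
                  treated_cfr = 0.001,
                  fetal_death_rate_untreated = 0.08, fetal_death_rate_treated = 0.01,
                  neonatal_links = c(preterm_birth_complications = 0.10),
                  neonatal_links_treated = c(preterm_birth_complications = 0.10)),
    sub_condition("placental_abruption", "maternal_hemorrhage", "maternal",
                  unprevented_incidence = 0.01, untreated_cfr = 0.10,
                  treated_cfr = 0.01,
                  fetal_death_rate_untreated = 0.40, fetal_death_rate_treated = 0.10),
    sub_condition("placenta_previa", "maternal_hemorrhage", "maternal",
                  unprevented_incidence = 0.005, untreated_cfr = 0.10,
                  treated_cfr = 0.005,
                  fetal_death_rate_untreated = 0.30, fetal_death_rate_treated = 0.05),
    sub_condition("ruptured_uterus", "maternal_hemorrhage", "maternal",
                  unprevented_incidence = 0.005, untreated_cfr = 0.30,
                  treated_cfr = 0.02,
                  fetal_death_rate_untreated = 0.70, fetal_death_rate_treated = 0.20),
    sub_condition("lacerations", "maternal_hemorrhage", "maternal",
                  unprevented_incidence = 0.02, untreated_cfr = 0.02,
                  treated_cfr = 0.001),
    sub_condition("atonic_uterus", "maternal_hemorrhage", "maternal",
                  unprevented_incidence = 0.08, untreated_cfr = 0.05,
                  treated_cfr = 0.003),
    sub_condition("retained_placenta", "maternal_hemorrhage", "maternal",
                  unprevented_incidence = 0.02, untreated_cfr = 0.04,
                  treated_cfr = 0.002),
    sub_condition("preeclampsia_eclampsia", "hypertensive_disorders", "maternal",
                  unprevented_incidence = 0.04, untreated_cfr = 0.08,
                  treated_cfr = 0.005,
                  fetal_death_rate_untreated = 0.20, fetal_death_rate_treated = 0.04,
                  neonatal_links = c(birth_asphyxia = 0.15,
                                     preterm_birth_complications = 0.20),
                  neonatal_links_treated = c(birth_asphyxia = 0.15,
                                             preterm_birth_complications = 0.20)),
    sub_condition("fetal_distress", "fetal_distress", "maternal",
                  unprevented_incidence = 0.04, untreated_cfr = 0,
                  fetal_death_rate_untreated = 0.30, fetal_death_rate_treated = 0.05,
                  neonatal_links = c(birth_asphyxia = 0.25),
                  neonatal_links_treated = c(birth_asphyxia = 0.25)),
    # IUGR leaf kept as structure with zeroed defaults
    sub_condition("iugr", "fetal_distress", "maternal",
                  unprevented_incidence = 0, untreated_cfr = 0,
                  fetal_death_rate_untreated = 0, fetal_death_rate_treated = 0),
    # --- neonatal ---------------------------------------------------------
    sub_condition("neonatal_sepsis", "neonatal_infection", "neonatal",
                  unprevented_incidence = 0.05, untreated_cfr = 0.25,
                  treated_cfr = 0.02),
    sub_condition("birth_asphyxia", "birth_asphyxia", "neonatal",
                  unprevented_incidence = 0.03, untreated_cfr = 0.30,
                  treated_cfr = 0.05),
    sub_condition("preterm_birth_complications", "preterm_birth", "neonatal",
                  unprevented_incidence = 0.08, untreated_cfr = 0.12,
                  treated_cfr = 0.02),
    # preterm-birth leaves kept as structure with zeroed defaults
    sub_condition("rds", "preterm_birth", "neonatal",
                  unprevented_incidence = 0, untreated_cfr = 0),
    sub_condition("ivh", "preterm_birth", "neonatal",
                  unprevented_incidence = 0, untreated_cfr = 0),
    sub_condition("nec", "preterm_birth", "neonatal",
                  unprevented_incidence = 0, untreated_cfr = 0)
  )

  hosp_only <- c(home = 0, clinic = 0, hospital = 0.7)
  facility <- c(home = 0, clinic = 0.5, hospital = 0.8)
  broad <- c(home = 0.3, clinic = 0.6, hospital = 0.9)

  ivs <- list(
    # prevention
    intervention("oxytocin", "preventive", targets = c("atonic_uterus"),
                 efficacy = 0.5, penetration = facility, utilization = 0.8,
                 timing_tags = "third_stage_prophylaxis"),
    intervention("uterine_massage", "preventive", targets = c("atonic_uterus"),
                 efficacy = 0.2, penetration = broad, utilization = 0.7),
    intervention("clean_delivery_kit", "preventive", targets = c("sepsis", "neonatal_sepsis"),
                 efficacy = 0.3, penetration = broad, utilization = 0.8),
    intervention("itn_bednet", "preventive", targets = c("malaria"),
                 efficacy = 0.5, penetration = c(home = 0.4, clinic = 0.5, hospital = 0.5),
                 utilization = 0.7),
    intervention("chlorhexidine_cord_care", "preventive", targets = c("neonatal_sepsis"),
                 efficacy = 0.25, penetration = broad, utilization = 0.8),
    # diagnostics
    intervention("partograph", "diagnostic", targets = c("obstructed_labor"),
                 efficacy = 0.85, penetration = facility, utilization = 0.6),
    intervention("fever_screen", "diagnostic", targets = c("sepsis"),
                 efficacy = 0.7, penetration = broad, utilization = 0.8),
    intervention("syphilis_rdt", "diagnostic", targets = c("syphilis"),
                 efficacy = 0.85, penetration = facility, utilization = 0.7),
    intervention("malaria_rdt", "diagnostic", targets = c("malaria"),
                 efficacy = 0.9, penetration = facility, utilization = 0.8),
    intervention("blood_loss_assessment", "diagnostic",
                 targets = c("placental_abruption", "placenta_previa",
                             "ruptured_uterus", "lacerations", "atonic_uterus",
                             "retained_placenta"),
                 efficacy = 0.75, penetration = broad, utilization = 0.8),
    intervention("bp_proteinuria_screen", "diagnostic",
                 targets = c("preeclampsia_eclampsia"),
                 efficacy = 0.8, penetration = facility, utilization = 0.7),
    intervention("fetal_heart_monitoring", "diagnostic", targets = c("fetal_distress"),
                 efficacy = 0.7, penetration = facility, utilization = 0.6),
    intervention("newborn_danger_signs", "diagnostic",
                 targets = c("neonatal_sepsis", "birth_asphyxia",
                             "preterm_birth_complications"),
                 efficacy = 0.7, penetration = broad, utilization = 0.8),
    # treatments
    intervention("cesarean_delivery", "treatment",
                 targets = c("obstructed_labor", "fetal_distress"),
                 efficacy = 0.9, penetration = hosp_only, utilization = 0.8,
                 fetal_efficacy = 0.8, neonatal_efficacy = 0.7,
                 single_use = TRUE),
    intervention("antibiotics_oral", "treatment", targets = c("sepsis"),
                 efficacy = 0.6, penetration = broad, utilization = 0.8,
                 fetal_efficacy = 0.4, neonatal_efficacy = 0.4,
                 composition = list(mode = "line", order = 1)),
    intervention("antibiotics_iv", "treatment", targets = c("sepsis"),
                 efficacy = 0.85, penetration = facility, utilization = 0.8,
                 fetal_efficacy = 0.5, neonatal_efficacy = 0.5,
                 composition = list(mode = "line", order = 2)),
    intervention("penicillin", "treatment", targets = c("syphilis"),
                 efficacy = 0.95, penetration = facility, utilization = 0.8,
                 fetal_efficacy = 0.8),
    intervention("act_antimalarial", "treatment", targets = c("malaria"),
                 efficacy = 0.9, penetration = facility, utilization = 0.8,
                 fetal_efficacy = 0.5, neonatal_efficacy = 0.4),
    intervention("emergency_cesarean_hemorrhage", "treatment",
                 targets = c("placental_abruption", "placenta_previa",
                             "ruptured_uterus"),
                 efficacy = 0.85, penetration = hosp_only, utilization = 0.8,
                 fetal_efficacy = 0.6, single_use = TRUE),
    intervention("suturing", "treatment", targets = c("lacerations"),
                 efficacy = 0.9, penetration = facility, utilization = 0.8),
    intervention("oxytocin", "treatment", targets = c("atonic_uterus"),
                 efficacy = 0.7, penetration = facility, utilization = 0.8,
                 composition = list(mode = "line", order = 1),
                 timing_tags = "postpartum_treatment"),
    intervention("misoprostol", "treatment", targets = c("atonic_uterus"),
                 efficacy = 0.6, penetration = broad, utilization = 0.7,
                 composition = list(mode = "line", order = 2)),
    intervention("balloon_tamponade", "treatment", targets = c("atonic_uterus"),
                 efficacy = 0.75, penetration = hosp_only, utilization = 0.7,
                 composition = list(mode = "line", order = 3)),
    intervention("manual_removal_placenta", "treatment",
                 targets = c("retained_placenta"),
                 efficacy = 0.85, penetration = facility, utilization = 0.8),
    intervention("mgso4", "treatment", targets = c("preeclampsia_eclampsia"),
                 efficacy = 0.6, penetration = c(home = 0, clinic = 0.3, hospital = 0.6),
                 utilization = 0.7),
    intervention("cesarean_or_induction", "treatment",
                 targets = c("preeclampsia_eclampsia"),
                 efficacy = 0.85, penetration = hosp_only, utilization = 0.7,
                 fetal_efficacy = 0.6, neonatal_efficacy = 0.6,
                 single_use = TRUE),
    intervention("antibiotics_neonatal", "treatment", targets = c("neonatal_sepsis"),
                 efficacy = 0.8, penetration = facility, utilization = 0.8),
    intervention("bag_mask_resuscitation", "treatment", targets = c("birth_asphyxia"),
                 efficacy = 0.5, penetration = facility, utilization = 0.7,
                 composition = list(mode = "line", order = 1)),
    intervention("advanced_resuscitation", "treatment", targets = c("birth_asphyxia"),
                 efficacy = 0.7, penetration = hosp_only, utilization = 0.7,
                 composition = list(mode = "line", order = 2)),
    intervention("kangaroo_care", "treatment",
                 targets = c("preterm_birth_complications"),
                 efficacy = 0.4, penetration = broad, utilization = 0.7),
    intervention("antenatal_corticosteroids", "treatment",
                 targets = c("preterm_birth_complications"),
                 efficacy = 0.45, penetration = facility, utilization = 0.6)
  )

  major <- c("obstructed_labor", "sepsis", "placental_abruption",
             "placenta_previa", "ruptured_uterus", "atonic_uterus",
             "retained_placenta", "preeclampsia_eclampsia", "fetal_distress",
             "neonatal_sepsis", "birth_asphyxia", "preterm_birth_complications")
  trs <- list(
    transfer_rule("home", "clinic", 0.25, major),
    transfer_rule("home", "hospital", 0.15, major),
    transfer_rule("clinic", "hospital", 0.35, major)
  )
  model_definition(subs, ivs, trs)
}

#' Baseline current-care scenario for the default model
#'
#' Synthetic placeholder coverage reflecting the model defaults, with a
#' typical low-resource delivery-place mix (half of births at home).
#'
#' @param births Cohort size (default 100000 pregnancies).
#' @param model The model to resolve against (default [default_model()]).
#' @return An `mnh_scenario`.
#' @export
default_scenario <- function(births = 1e5, model = default_model()) {
  scenario_parameters(
    model, scenario_id = "current_care_synthetic", births = births,
    setting_distribution = c(home = 0.5, clinic = 0.3, hospital = 0.2))
}

#' Stepwise magnesium-sulfate demonstration scenarios
#'
#' A four-step coverage ladder for eclampsia care built on the default model,
#' demonstrating care-cascade bottleneck decomposition: (1) the drug alone at
#' full penetration/utilization in clinic and hospital; (2) plus universal
#' diagnosis; (3) plus universal access to cesarean delivery or induction;
#' (4) plus strengthened transfer to hospital. Each step is a full scenario;
#' comparing consecutive steps with [lives_saved()] shows which cascade stage
#' is binding. Parameters are synthetic placeholders.
#'
#' @param births Cohort size.
#' @param model The model to resolve against.
#' @return Named list of four `mnh_scenario` objects.
#' @export
mgso4_ladder <- function(births = 1e5, model = default_model()) {
  dist <- c(home = 0.5, clinic = 0.3, hospital = 0.2)
  mk <- function(id, coverage = NULL, transfers = NULL) {
    scenario_parameters(model, scenario_id = id, births = births,
                        setting_distribution = dist,
                        coverage_overrides = coverage,
                        transfer_overrides = transfers)
  }
  cov <- function(...) {
    recs <- list(...)
    do.call(rbind, lapply(recs, function(r) {
      data.frame(intervention = r[[1]], setting = r[[2]],
                 penetration = as.numeric(r[[3]]),
                 utilization = as.numeric(r[[4]]), stringsAsFactors = FALSE)
    }))
  }
  drug <- cov(list("mgso4/treatment", "clinic", 1, 1),
              list("mgso4/treatment", "hospital", 1, 1))
  diagnosis <- cov(list("bp_proteinuria_screen/diagnostic", "all", 1, 1))
  delivery <- cov(list("cesarean_or_induction/treatment", "clinic", 1, 1),
                  list("cesarean_or_induction/treatment", "hospital", 1, 1))
  transfer_up <- data.frame(
    from = c("home", "home", "clinic"), to = c("clinic", "hospital", "hospital"),
    subcondition = "preeclampsia_eclampsia", probability = c(0.1, 0.8, 0.8),
    stringsAsFactors = FALSE)
  list(
    step1_drug_only = mk("mgso4_step1_drug_only", drug),
    step2_plus_diagnosis = mk("mgso4_step2_plus_diagnosis",
                              rbind(drug, diagnosis)),
    step3_plus_delivery = mk("mgso4_step3_plus_delivery",
                             rbind(drug, diagnosis, delivery)),
    step4_plus_transfer = mk("mgso4_step4_plus_transfer",
                             rbind(drug, diagnosis, delivery),
                             transfers = transfer_up)
  )
}

#' Generate a random valid scenario parameter set
#'
#' Draws incidences, case fatality rates (treated <= untreated), fetal death
#' rates, per-setting coverage and transfer probabilities from fixed uniform
#' ranges, deterministically per seed. Penetration and utilization are drawn
#' jointly per intervention and sorted so that availability never decreases
#' up the care ladder (home <= clinic <= hospital), reflecting how facility
#' capability scales in practice. Every generated set passes full validation
#' by construction.
#'
#' @param seed Integer seed.
#' @param model The model to parameterize (default [default_model()]).
#' @param births Cohort size.
#' @return An `mnh_scenario`.
#' @export
generate_random_params <- function(seed, model = default_model(), births = 1e5) {
  set.seed(as.integer(seed))
  u <- stats::runif(3, 0.1, 1)
  dist <- u / sum(u)
  # exact unit sum within 1e-9 despite float division
  dist[3] <- 1 - dist[1] - dist[2]
  names(dist) <- settings()

  ids <- sub_ids(model)
  inc <- stats::runif(length(ids), 0.01, 0.15)
  ucfr <- stats::runif(length(ids), 0.02, 0.30)
  pops <- vapply(model$sub_conditions, `[[`, "", "population")
  fdr_u <- ifelse(pops == "maternal", stats::runif(length(ids), 0, 0.3), 0)
  rates <- data.frame(
    subcondition = ids,
    unprevented_incidence = inc,
    untreated_cfr = ucfr,
    treated_cfr = ucfr * stats::runif(length(ids), 0, 0.3),
    fetal_death_rate_untreated = fdr_u,
    fetal_death_rate_treated = fdr_u * stats::runif(length(ids), 0, 1),
    stringsAsFactors = FALSE)

  cov <- list()
  eff <- stats::setNames(numeric(0), character(0))
  for (iv in model$interventions) {
    uid <- intervention_uid(iv)
    pen <- sort(stats::runif(3, 0, 0.9))
    use <- sort(stats::runif(3, 0.2, 1))
    cov[[length(cov) + 1]] <- data.frame(
      intervention = uid, setting = settings(), penetration = pen,
      utilization = use, stringsAsFactors = FALSE)
    eff[uid] <- stats::runif(1, 0.3, 0.95)
  }
  coverage_overrides <- if (length(cov) > 0) do.call(rbind, cov) else NULL

  trs <- transfer_table(model$transfers)
  if (nrow(trs) > 0) {
    key <- paste(trs$subcondition, trs$from)
    for (k in unique(key)) {
      idx <- which(key == k)
      total <- stats::runif(1, 0, 0.8)
      w <- stats::runif(length(idx))
      trs$probability[idx] <- total * w / sum(w)
    }
  }

  scenario_parameters(
    model, scenario_id = sprintf("random_seed_%d", as.integer(seed)),
    births = births, setting_distribution = dist,
    coverage_overrides = coverage_overrides,
    efficacy_overrides = eff,
    rate_overrides = rates,
    transfer_overrides = if (nrow(trs) > 0) trs else NULL)
}
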