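test_that("initial strata split births by the setting mix and conserve mass", {
  model <- toy_model()
  p <- toy_scenario(model)
  st <- initial_strata(p)
  expect_equal(vapply(st, `[[`, 0, "mass"), c(500, 300, 200))
  expect_equal(vapply(st, `[[`, "", "setting"), settings())
  p0 <- toy_scenario(model, births = 0)
  expect_equal(sum(vapply(initial_strata(p0), `[[`, 0, "mass")), 0)
})

test_that("prevention, diagnosis and treatment splits follow the tree arithmetic", {
  sub <- toy_model()$sub_conditions[[1]]
  st <- cohort_stratum(1000, "home")
  sp <- apply_prevention(st, sub, 0.3)
  expect_equal(sp$positive$mass, 1000 * 0.1 * 0.7)
  expect_equal(sp$negative$mass, 1000 - 70)
  expect_equal(apply_prevention(st, sub, 1)$positive$mass, 0)
  expect_equal(apply_prevention(st, sub, 0)$positive$mass, 100)

  pos <- cohort_stratum(70, "home", condition_positive = TRUE)
  d <- apply_diagnosis(pos, 0.5)
  expect_equal(d$diagnosed$mass, 35)
  expect_equal(d$undiagnosed$mass, 35)
  expect_equal(apply_diagnosis(pos, 0)$diagnosed$mass, 0)
  # condition-negative strata never enter diagnosis/treatment
  expect_error(apply_diagnosis(cohort_stratum(10, "home", FALSE), 0.5),
               class = "mnh_validation_error")

  t <- apply_treatment(cohort_stratum(60, "home", TRUE, TRUE), 0.8)
  expect_equal(t$success$mass, 48)
  expect_equal(t$failure$mass, 12)
  expect_equal(apply_treatment(cohort_stratum(60, "home", TRUE, TRUE), 0)$success$mass, 0)
  expect_equal(apply_treatment(cohort_stratum(60, "home", TRUE, TRUE), 1)$failure$mass, 0)
  expect_error(apply_treatment(cohort_stratum(60, "home", TRUE, FALSE), 0.5),
               class = "mnh_validation_error")
})

test_that("transfers split diagnosed mass upward and conserve it", {
  d <- cohort_stratum(100, "home", TRUE, TRUE)
  rules <- data.frame(to = "hospital", probability = 0.6)
  out <- apply_transfer(d, rules)
  expect_equal(vapply(out, `[[`, 0, "mass"), c(40, 60))
  expect_equal(vapply(out, `[[`, "", "setting"), c("home", "hospital"))
  expect_equal(apply_transfer(d, NULL), list(d))
  rules2 <- data.frame(to = c("clinic", "hospital"), probability = c(0.7, 0.6))
  expect_error(apply_transfer(d, rules2), class = "mnh_validation_error")
  out2 <- apply_transfer(d, data.frame(to = c("clinic", "hospital"),
                                       probability = c(0.3, 0.4)))
  expect_equal(sum(vapply(out2, `[[`, 0, "mass")), 100)
})

test_that("mortality accounting matches the hand-worked example", {
  sub <- sub_condition("x", "c", "maternal", unprevented_incidence = 0.1,
                       untreated_cfr = 0.02, treated_cfr = 0)
  # 1000 untreated cases at CFR 0.02
  m <- compute_mortality(data.frame(mass = 1000, treated = FALSE), sub)
  expect_equal(m$maternal_deaths, 20)
  # all treated at treated_cfr 0
  expect_equal(compute_mortality(data.frame(mass = 1000, treated = TRUE),
                                 sub)$maternal_deaths, 0)
  # 48 treated (cfr 0), 12 failed + 35 undiagnosed at 0.02 -> 0.94
  m <- compute_mortality(data.frame(mass = c(48, 12, 35),
                                    treated = c(TRUE, FALSE, FALSE)), sub)
  expect_equal(m$maternal_deaths, 0.94)
})

test_that("zero coverage collapses to the closed form, per sub-condition", {
  model <- toy_model()
  p <- preset_no_intervention(toy_scenario(model))
  res <- run_scenario(model, p)
  ecl <- res$sub_results$eclampsia
  expect_equal(ecl$cases, 1000 * 0.1)
  expect_equal(ecl$maternal_deaths, 1000 * 0.1 * 0.02, tolerance = 1e-12)
  expect_equal(ecl$fetal_deaths, 1000 * 0.1 * 0.2, tolerance = 1e-12)
  # neonatal sub receives maternal-induced incidence on top of its own
  asph <- res$sub_results$asphyxia
  expected_cases <- 1000 * 0.03 + 1000 * 0.1 * 0.3
  expect_equal(asph$cases, expected_cases, tolerance = 1e-12)
  expect_equal(asph$neonatal_deaths, expected_cases * 0.3, tolerance = 1e-12)
  expect_trace_conserved(res)
})

test_that("undiagnosed mass is untreatable: diagnosis gates treatment", {
  model <- toy_model()
  p <- toy_scenario(model)
  zero_kind <- function(params, kind) {
    params$coverage$penetration[params$coverage$kind == kind] <- 0
    params$coverage$utilization[params$coverage$kind == kind] <- 0
    params
  }
  no_diag <- run_scenario(model, zero_kind(p, "diagnostic"))
  no_treat <- run_scenario(model, zero_kind(p, "treatment"))
  expect_equal(no_diag$deaths$deaths, no_treat$deaths$deaths)
  expect_equal(no_diag$totals, no_treat$totals)
})

test_that("neonatal benefit of maternal treatment scales link contributions", {
  # neonatal_efficacy 1 removes the treated stratum's contribution entirely
  model1 <- toy_model()
  model1$interventions[[3]]$neonatal_efficacy <- 1
  model1 <- validate_model(model1)
  p1 <- scenario_parameters(model1, "s", 1000,
                            c(home = 0, clinic = 0, hospital = 1))
  r1 <- run_subcondition(model1$sub_conditions[[1]], model1, p1)
  # treated mass contributes zero; untreated at the full link rate
  tr <- r1$strata_trace
  untreated <- sum(tr$mass[tr$step == "diagnosis" & !tr$diagnosed]) +
    sum(tr$mass[tr$step == "treatment" & !tr$treated])
  expect_equal(sum(r1$neonatal_contributions$mass), untreated * 0.3)

  # neonatal_efficacy 0 with equal link rates: treated and untreated
  # strata contribute at the same rate
  model0 <- toy_model()
  model0$interventions[[3]]$neonatal_efficacy <- 0
  model0 <- validate_model(model0)
  p0 <- scenario_parameters(model0, "s", 1000,
                            c(home = 0, clinic = 0, hospital = 1))
  r0 <- run_subcondition(model0$sub_conditions[[1]], model0, p0)
  expect_equal(sum(r0$neonatal_contributions$mass), r0$cases * 0.3)
  # contribution mass never exceeds maternal case mass (link rate <= 1)
  expect_lte(sum(r0$neonatal_contributions$mass), r0$cases)
})

test_that("administered tallies and traces are recorded", {
  model <- toy_model()
  p <- toy_scenario(model)
  r <- run_subcondition(model$sub_conditions[[1]], model, p)
  expect_true(all(c("aspirin/preventive", "bp_screen/diagnostic",
                    "mgso4/treatment") %in% names(r$administered)))
  expect_true(all(r$administered >= 0))
  # prevention offered to the whole cohort, diagnosis only to cases
  expect_lte(r$administered[["bp_screen/diagnostic"]], r$cases)
  expect_true(all(c("initial", "prevention", "diagnosis", "transfer",
                    "treatment") %in% r$strata_trace$step))
})
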