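test_that("model and scenario files round-trip field-for-field", {
  model <- toy_model()
  mpath <- withr::local_tempfile(fileext = ".json")
  write_model(model, mpath)
  expect_equal(load_model(mpath), model, tolerance = 0)

  params <- toy_scenario(model, bounds = list(
    low = list(rates = data.frame(subcondition = "eclampsia",
                                  unprevented_incidence = 0.08)),
    high = list(rates = data.frame(subcondition = "eclampsia",
                                   unprevented_incidence = 0.12))))
  spath <- withr::local_tempfile(fileext = ".json")
  write_scenario(params, spath)
  reloaded <- load_scenario(spath, model)
  # bounds normalise to override frames on both sides; compare resolved state
  expect_equal(reloaded[setdiff(names(reloaded), "bounds")],
               params[setdiff(names(params), "bounds")], tolerance = 0)
  expect_equal(sensitivity_bounds(model, reloaded)$bounds$low$totals,
               sensitivity_bounds(model, params)$bounds$low$totals)
})

test_that("schema gates reject malformed input", {
  model <- toy_model()
  expect_error(load_model(tempfile()), class = "mnh_parse_error")
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(load_model(bad), class = "mnh_parse_error")
  lst <- mnhimpact:::model_to_list(model)
  lst$schema_version <- "9.9"
  jsonlite::write_json(lst, bad, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(bad), class = "mnh_validation_error")
})

test_that("type invariants are enforced with a failing fixture each", {
  mk_sub <- function(...) {
    args <- utils::modifyList(
      list(id = "x", condition_id = "c", population = "maternal",
           unprevented_incidence = 0.1, untreated_cfr = 0.1), list(...))
    do.call(sub_condition, args)
  }
  base <- function(subs = list(mk_sub()), ivs = list(), trs = list()) {
    model_definition(subs, ivs, trs)
  }
  expect_s3_class(base(), "mnh_model")
  # treated_cfr > untreated_cfr
  expect_error(base(list(mk_sub(treated_cfr = 0.5))),
               class = "mnh_validation_error")
  # fetal rates out of order
  expect_error(base(list(mk_sub(fetal_death_rate_untreated = 0.1,
                                fetal_death_rate_treated = 0.2))),
               class = "mnh_validation_error")
  # probability out of range
  expect_error(base(list(mk_sub(unprevented_incidence = 1.2))),
               class = "mnh_validation_error")
  # neonatal sub-condition with fetal/link fields
  expect_error(base(list(mk_sub(population = "neonatal",
                                fetal_death_rate_untreated = 0.1))),
               class = "mnh_validation_error")
  # dangling link target
  expect_error(base(list(mk_sub(neonatal_links = c(nowhere = 0.1)))),
               class = "mnh_validation_error")
  # dangling intervention target
  expect_error(base(ivs = list(intervention("i", "treatment", "ghost",
                                            efficacy = 0.5, penetration = 0.5,
                                            utilization = 0.5))),
               class = "mnh_validation_error")
  # non-contiguous line orders
  lines <- function(o1, o2) list(
    intervention("a", "treatment", "x", efficacy = 0.5, penetration = 0.5,
                 utilization = 0.5, composition = list(mode = "line", order = o1)),
    intervention("b", "treatment", "x", efficacy = 0.5, penetration = 0.5,
                 utilization = 0.5, composition = list(mode = "line", order = o2)))
  expect_s3_class(base(ivs = lines(1, 2)), "mnh_model")
  expect_error(base(ivs = lines(1, 3)), class = "mnh_validation_error")
  expect_error(base(ivs = lines(2, 3)), class = "mnh_validation_error")
  # transfers must move up the ladder, and sums stay <= 1
  expect_error(base(trs = list(transfer_rule("clinic", "home", 0.5, "x"))),
               class = "mnh_validation_error")
  expect_error(base(trs = list(transfer_rule("home", "clinic", 0.6, "x"),
                               transfer_rule("home", "hospital", 0.6, "x"))),
               class = "mnh_validation_error")
  # settings other than the three labels never validate
  expect_error(base(trs = list(transfer_rule("home", "tertiary", 0.5, "x"))),
               class = "mnh_validation_error")
})

test_that("dual-timing id re-use validates; duplicate single-use does not", {
  subs <- list(sub_condition("hem", "hemorrhage", "maternal",
                             unprevented_incidence = 0.1, untreated_cfr = 0.05))
  oxy <- function(kind, tag) {
    intervention("oxytocin", kind, "hem", efficacy = 0.5, penetration = 0.5,
                 utilization = 0.5, timing_tags = tag)
  }
  expect_s3_class(model_definition(subs, list(oxy("preventive", "prophylaxis"),
                                              oxy("treatment", "treatment"))),
                  "mnh_model")
  ces <- function(kind) {
    intervention("cesarean", kind, "hem", efficacy = 0.8, penetration = 0.5,
                 utilization = 0.5, single_use = TRUE)
  }
  expect_error(model_definition(subs, list(ces("preventive"), ces("treatment"))),
               class = "mnh_validation_error")
})

test_that("scenario validation catches bad distributions, ids and ranges", {
  model <- toy_model()
  mk <- function(dist, ...) {
    scenario_parameters(model, "s", 1000, dist, ...)
  }
  good <- c(home = 0.5, clinic = 0.3, hospital = 0.2)
  expect_s3_class(mk(good), "mnh_scenario")
  expect_error(mk(c(home = 0.5, clinic = 0.3, hospital = 0.1)),
               class = "mnh_validation_error")
  expect_error(mk(good, coverage_overrides = data.frame(
    intervention = "ghost", setting = "all", penetration = 1, utilization = 1)),
    class = "mnh_validation_error")
  expect_error(mk(good, coverage_overrides = data.frame(
    intervention = "mgso4/treatment", setting = "all", penetration = 1.5,
    utilization = 1)), class = "mnh_validation_error")
  expect_error(mk(good, rate_overrides = data.frame(
    subcondition = "eclampsia", treated_cfr = 0.5)),
    class = "mnh_validation_error")
  # full-coverage clinic+hospital override (the classic scale-up shape)
  up <- mk(good, coverage_overrides = data.frame(
    intervention = c("mgso4/treatment", "mgso4/treatment"),
    setting = c("clinic", "hospital"), penetration = 1, utilization = 1))
  cov <- up$coverage[up$coverage$intervention == "mgso4/treatment", ]
  expect_equal(cov$penetration[cov$setting != "home"], c(1, 1))
  expect_equal(cov$penetration[cov$setting == "home"], 0)
})

test_that("run_scenario refuses a scenario resolved against another model", {
  m1 <- toy_model()
  m2 <- toy_model(link = 0.2)
  p1 <- toy_scenario(m1)
  expect_error(run_scenario(m2, p1), class = "mnh_validation_error")
})
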