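test_that("the default model encodes the expected condition inventory", {
  m <- default_model()
  conds <- unique(vapply(m$sub_conditions, `[[`, "", "condition_id"))
  expect_true(all(c("obstructed_labor", "maternal_infection",
                    "maternal_hemorrhage", "hypertensive_disorders") %in% conds))
  by_cond <- function(cid) {
    vapply(Filter(function(s) s$condition_id == cid, m$sub_conditions),
           `[[`, "", "id")
  }
  expect_setequal(by_cond("maternal_hemorrhage"),
                  c("placental_abruption", "placenta_previa", "ruptured_uterus",
                    "lacerations", "atonic_uterus", "retained_placenta"))
  expect_setequal(by_cond("maternal_infection"), c("sepsis", "syphilis", "malaria"))
  neo <- vapply(Filter(function(s) s$population == "neonatal", m$sub_conditions),
                `[[`, "", "condition_id")
  expect_true(all(c("neonatal_infection", "birth_asphyxia", "preterm_birth") %in% neo))
  # optional figure leaves ship with zeroed defaults
  for (leaf in c("rds", "ivh", "nec", "iugr")) {
    sc <- mnhimpact:::model_sub(m, leaf)
    expect_equal(sc$unprevented_incidence, 0)
  }
})

test_that("the shipped model file equals the in-code constructor", {
  path <- system.file("extdata", "default_model.json", package = "mnhimpact")
  expect_equal(load_model(path), default_model(), tolerance = 0)
})

test_that("shipped scenario files load and the coverage ladder is ordered", {
  m <- default_model()
  dir <- system.file("extdata", "scenarios", package = "mnhimpact")
  for (f in list.files(dir, full.names = TRUE)) {
    expect_s3_class(load_scenario(f, m), "mnh_scenario")
  }
  cur <- load_scenario(file.path(dir, "current_care.json"), m)
  hi <- load_scenario(file.path(dir, "high_income.json"), m)
  expect_true(all(hi$coverage$penetration >= cur$coverage$penetration))
  expect_true(all(hi$coverage$utilization >= cur$coverage$utilization))
})

test_that("the magnesium-sulfate ladder saves progressively more lives", {
  m <- default_model()
  steps <- mgso4_ladder(births = 1e5, model = m)
  base <- run_scenario(m, default_scenario(model = m))
  saved <- vapply(steps, function(p) {
    lives_saved(base, run_scenario(m, p))$totals[["maternal"]]
  }, 0)
  expect_true(all(diff(saved) > -1e-9)) # each added cascade step helps
  expect_gt(saved[[4]], saved[[1]])
})

test_that("random parameter generation is seed-stable and always valid", {
  m <- default_model()
  p1 <- generate_random_params(7, m)
  p2 <- generate_random_params(7, m)
  expect_identical(p1, p2)
  expect_false(identical(generate_random_params(8, m)$rates, p1$rates))
  for (seed in 1:25) {
    p <- generate_random_params(seed, m)
    expect_silent(validate_scenario(p, m))
    expect_true(all(p$rates$treated_cfr <= p$rates$untreated_cfr))
    # availability never decreases up the care ladder
    for (uid in unique(p$coverage$intervention)) {
      cv <- p$coverage[p$coverage$intervention == uid, ]
      cv <- cv[match(settings(), cv$setting), ]
      expect_true(all(diff(cv$penetration) >= 0))
      expect_true(all(diff(cv$utilization) >= 0))
    }
  }
})

test_that("the CLI validates, runs and compares scenario files", {
  dir <- withr::local_tempdir()
  mpath <- system.file("extdata", "default_model.json", package = "mnhimpact")
  s_cur <- system.file("extdata", "scenarios", "current_care.json",
                       package = "mnhimpact")
  s_hi <- system.file("extdata", "scenarios", "high_income.json",
                      package = "mnhimpact")
  expect_equal(suppressMessages(
    mnh_cli(c("validate", "--model", mpath, "--scenario", s_cur))), 0L)
  expect_equal(suppressMessages(mnh_cli(c("validate", "--model", mpath))), 1L)
  expect_equal(suppressMessages(mnh_cli("frobnicate")), 2L)

  out <- file.path(dir, "run.csv")
  expect_equal(suppressMessages(
    mnh_cli(c("run", "--model", mpath, "--scenario", s_cur, "--out", out,
              "--no-intervention"))), 0L)
  tab <- utils::read.csv(out)
  # no-intervention output equals the closed form (maternal rows)
  m <- default_model()
  for (sc in m$sub_conditions) {
    if (sc$population != "maternal") next
    got <- tab$deaths[tab$subcondition == sc$id & tab$population == "maternal"]
    expect_equal(got, 1e5 * sc$unprevented_incidence * sc$untreated_cfr,
                 tolerance = 1e-12)
  }

  cmp <- file.path(dir, "cmp.csv")
  expect_equal(suppressMessages(
    mnh_cli(c("compare", "--model", mpath, "--scenario", s_cur,
              "--scenario2", s_hi, "--out", cmp))), 0L)
  saved <- utils::read.csv(cmp)
  expect_true(all(saved$saved >= -1e-9))

  targets <- file.path(dir, "targets.json")
  jsonlite::write_json(list(list(subcondition = "sepsis",
                                 target_mortality_rate = 0.003)),
                       targets, auto_unbox = TRUE)
  cal <- file.path(dir, "cal.csv")
  expect_equal(suppressMessages(
    mnh_cli(c("calibrate", "--model", mpath, "--targets", targets,
              "--out", cal))), 0L)
  expect_equal(utils::read.csv(cal)$calibrated_incidence, 0.003 / 0.15)

  expect_equal(suppressMessages(
    mnh_cli(c("verify", "--seeds", "2", "--n", "20000", "--seed", "42"))), 0L)
})
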