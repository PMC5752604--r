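test_that("coverage and success are range-checked products", {
  expect_equal(coverage(0.8, 0.5), 0.4)
  expect_equal(coverage(1, 1), 1)
  expect_equal(coverage(0, 0.9), 0)
  expect_equal(success(0.4, 0.5), 0.2)
  expect_equal(success(1, 0.37), 0.37)
  expect_equal(success(0.9, 0), 0)
  expect_error(coverage(1.1, 0.5), class = "mnh_validation_error")
  expect_error(success(0.5, -0.1), class = "mnh_validation_error")
})

test_that("compose_layers matches brute-force enumeration", {
  expect_equal(compose_layers(c(0.5, 0.5)), 0.75)
  expect_equal(compose_layers(numeric(0)), 0)
  # frozen from enum_layers(c(0.2, 0.3, 0.5)): 8 joint Bernoulli outcomes
  expect_equal(enum_layers(c(0.2, 0.3, 0.5)), 0.72)
  expect_equal(compose_layers(c(0.2, 0.3, 0.5)), 0.72)
  set.seed(11)
  for (i in 1:20) {
    s <- runif(sample(1:5, 1))
    expect_equal(compose_layers(s), enum_layers(s))
  }
})

test_that("compose_lines matches the event-tree oracle", {
  r <- compose_lines(list(c(1, 0.6), c(1, 0.5)))
  expect_equal(r$overall, 0.8)
  expect_equal(r$administered, c(1, 0.4))
  r <- compose_lines(list(c(0.5, 0.6), c(1, 1)))
  expect_equal(r$overall, 0.5) # non-receivers of line 1 never reach line 2
  expect_equal(r$administered, c(0.5, 0.2))
  expect_equal(compose_lines(list()), list(overall = 0, administered = numeric(0)))
  # single line is equivalent to a single layer
  expect_equal(compose_lines(list(c(0.7, 0.4)))$overall,
               compose_layers(0.7 * 0.4))
  set.seed(12)
  for (i in 1:20) {
    k <- sample(1:4, 1)
    cr <- runif(k); ef <- runif(k)
    got <- compose_lines(data.frame(receive = cr, efficacy = ef))
    expect_equal(got$overall, enum_lines(cr, ef))
    expect_equal(got$administered, enum_lines_administered(cr, ef))
  }
})

test_that("layers are permutation-invariant; lines are not", {
  set.seed(13)
  for (i in 1:20) {
    s <- runif(sample(2:6, 1))
    expect_equal(compose_layers(s), compose_layers(sample(s)))
  }
  # concrete witness of order dependence: unequal (receive, efficacy) pairs
  a <- compose_lines(list(c(0.5, 0.9), c(1, 0.2)))$overall
  b <- compose_lines(list(c(1, 0.2), c(0.5, 0.9)))$overall
  expect_false(isTRUE(all.equal(a, b)))
  # while the same masses as layers are order-free
  expect_equal(compose_layers(c(0.45, 0.2)), compose_layers(c(0.2, 0.45)))
})

test_that("line cascades with certain receipt collapse to layers", {
  set.seed(14)
  for (i in 1:20) {
    e <- runif(sample(1:5, 1))
    lines <- lapply(e, function(x) c(1, x))
    expect_equal(compose_lines(lines)$overall, compose_layers(e))
  }
})

test_that("composition is monotone and stays in [0, 1]", {
  set.seed(15)
  for (i in 1:50) {
    s <- runif(sample(1:5, 1))
    v <- compose_layers(s)
    expect_gte(v, 0); expect_lte(v, 1)
    j <- sample(seq_along(s), 1)
    s2 <- s; s2[j] <- s2[j] + (1 - s2[j]) * runif(1)
    expect_gte(compose_layers(s2), v)

    k <- sample(1:4, 1)
    cr <- runif(k); ef <- runif(k)
    v <- compose_lines(data.frame(receive = cr, efficacy = ef))$overall
    expect_gte(v, 0); expect_lte(v, 1)
    j <- sample(k, 1)
    cr2 <- cr; cr2[j] <- cr2[j] + (1 - cr2[j]) * runif(1)
    ef2 <- ef; ef2[j] <- ef2[j] + (1 - ef2[j]) * runif(1)
    expect_gte(compose_lines(data.frame(receive = cr2, efficacy = ef))$overall, v)
    expect_gte(compose_lines(data.frame(receive = cr, efficacy = ef2))$overall, v)
  }
})

test_that("combine_stage composes layers and line groups independently", {
  expect_equal(combine_stage(layers = 0.2,
                             line_groups = list(list(c(1, 0.5)))), 0.6)
  expect_equal(combine_stage(), 0)
  set.seed(16)
  s <- runif(4)
  expect_equal(combine_stage(layers = s), compose_layers(s))
  # an intervention in two groups is a configuration error
  expect_error(combine_stage(layers = c(a = 0.2),
                             line_groups = list(c(a = 0.3))),
               class = "mnh_validation_error")
  # stage combination agrees with a direct Bernoulli simulation
  set.seed(17)
  n <- 2e4
  for (rep in 1:3) {
    lay <- runif(2)
    cr <- runif(2); ef <- runif(2)
    analytic <- combine_stage(layers = lay,
                              line_groups = list(data.frame(receive = cr,
                                                            efficacy = ef)))
    ok <- matrix(runif(n * 2) < rep(lay, each = n), n)
    hit <- ok[, 1] | ok[, 2]
    got1 <- runif(n) < cr[1]
    ok1 <- got1 & (runif(n) < ef[1])
    got2 <- got1 & !ok1 & (runif(n) < cr[2])
    ok2 <- got2 & (runif(n) < ef[2])
    hit <- hit | ok1 | ok2
    se <- sqrt(analytic * (1 - analytic) / n)
    expect_lt(abs(mean(hit) - analytic), 4 * se + 1e-12)
  }
})

test_that("usage constraints flag repeated single-use interventions only", {
  pathway <- data.frame(
    intervention_id = c("cesarean", "cesarean"),
    stage = c("treatment", "treatment"),
    single_use = TRUE, timing = "", stringsAsFactors = FALSE)
  rep1 <- check_usage_constraints(pathway)
  expect_true(rep1$violation)
  # same agent at different points of care is allowable
  oxy <- data.frame(
    intervention_id = "oxytocin", stage = c("prevention", "treatment"),
    single_use = FALSE, timing = c("prophylaxis", "treatment"),
    stringsAsFactors = FALSE)
  expect_false(any(check_usage_constraints(oxy)$violation))
  # even a single-use agent may recur when timings differ
  oxy$single_use <- TRUE
  expect_false(any(check_usage_constraints(oxy)$violation))
  expect_equal(nrow(check_usage_constraints(oxy[0, ])), 0)
})
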