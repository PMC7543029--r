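test_that("candidate upgrades enumerate the legal one-step moves", {
  spec <- eh_spec(3, effects = list(eh_effect("age"), eh_effect("dep", form = "categorical")))
  ups <- candidate_upgrades(spec, "age")
  labels <- vapply(ups, format, "")
  expect_length(ups, 2)  # linear -> spline, proportional -> time-dependent
  expect_true(any(grepl("age\\[spline3\\]", labels)))
  expect_true(any(grepl("age\\[linear\\]\\*log\\(t\\)", labels)))
  # categorical variables only gain time-dependency
  expect_length(candidate_upgrades(spec, "dep"), 1)
  # a maximal form has no further single-variable moves
  spec_max <- eh_spec(3, effects = list(eh_effect("age", form = "spline", tdep = TRUE)))
  expect_length(candidate_upgrades(spec_max, "age"), 0)
  # interactions: adding is legal with both mains present; a time-dependent
  # upgrade requires the interaction to exist first
  ia1 <- candidate_upgrades(spec, "age:dep")
  expect_length(ia1, 1)
  expect_false(ia1[[1]]$interactions[[1]]$tdep)
  with_ia <- ia1[[1]]
  ia2 <- candidate_upgrades(with_ia, "age:dep")
  expect_length(ia2, 1)
  expect_true(ia2[[1]]$interactions[[1]]$tdep)
  expect_error(candidate_upgrades(eh_spec(3, effects = list(eh_effect("age"))),
                                  "age:dep"),
               "both main effects")
})

test_that("interaction hierarchy is enforced at spec construction", {
  expect_error(eh_spec(3, effects = list(eh_effect("age")),
                       interactions = list(eh_interaction("age", "dep"))),
               "requires main effect")
})

test_that("the retention rule keeps models within the threshold and drops the rest", {
  f1 <- const_hazard_fit(0.2); f2 <- const_hazard_fit(0.3); f3 <- const_hazard_fit(0.4)
  # criterion gaps 0 / 1.9 / 2.1 relative to the best model
  ms <- model_set(list(f1, f2, f3), criterion = "AIC", xic = c(100, 101.9, 102.1))
  expect_equal(ms$delta, c(0, 1.9, 2.1))
  keep <- ms$delta <= 2
  expect_equal(unname(keep), c(TRUE, TRUE, FALSE))
})

test_that("stepwise selection returns the minimal model set deterministically", {
  sc <- scenario_preset("colon", n = 1200, years = c(2001, 2005),
                        censor_date = 2011, seed = 5)
  d <- simulate_cohort(sc)
  base <- eh_spec(3, effects = list(eh_effect("age"), eh_effect("year")))
  ms1 <- select_models(d, base, sc$life_table, criterion = "BIC")
  ms2 <- select_models(d, base, sc$life_table, criterion = "BIC")
  expect_identical(tidy(ms1), tidy(ms2))
  # the best model is first, its delta is 0, every retained delta <= threshold
  expect_equal(ms1$delta[1], 0)
  expect_true(all(ms1$delta <= ms1$threshold))
  expect_equal(ms1$xic, sort(ms1$xic))
  # specs are distinct after deduplication
  labels <- vapply(ms1$models, function(f) format(f$spec), "")
  expect_false(anyDuplicated(labels) > 0)
  # the search log records comparisons
  expect_gt(nrow(ms1$log), 0)
})

test_that("a strong time-dependent effect is found by the search", {
  lt <- make_synthetic_life_table(sexes = "male")
  sc <- registry_scenario(n = 3000, life_table = lt, years = c(2000, 2005),
                          baseline = list(shape = 1.1, rate = 0.3),
                          effects = list(
                            list(variable = "age", beta = 0.02, center = 70),
                            list(variable = "age", beta = 0.015, center = 70,
                                 tdep = TRUE)),
                          censor_date = 2012, seed = 9)
  d <- simulate_cohort(sc)
  base <- eh_spec(3, effects = list(eh_effect("age")))
  ms <- select_models(d, base, lt, criterion = "AIC")
  labels <- vapply(ms$models, function(f) format(f$spec), "")
  expect_true(any(grepl("age\\[linear\\]\\*log\\(t\\)|age\\[spline3\\]\\*log\\(t\\)",
                        labels)))
})
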