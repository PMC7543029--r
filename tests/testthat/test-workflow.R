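test_that("artificial censoring truncates follow-up at the cut-off date", {
  d <- tibble::tibble(year = c(2008.5, 2010.25, 2011.5),
                      time = c(5, 3, 2), status = c(1L, 1L, 1L))
  out <- artificially_censor(d, 2011)
  # the 2011.5 diagnosis is dropped entirely
  expect_equal(nrow(out), 2)
  expect_equal(out$time, c(2.5, 0.75))
  expect_equal(out$status, c(0L, 0L))
  # records already ending before the cut-off are untouched
  d2 <- tibble::tibble(year = 2008, time = 1.5, status = 1L)
  expect_equal(artificially_censor(d2, 2011), d2)
})

test_that("the leakage guard rejects follow-up beyond the censoring date", {
  ok <- tibble::tibble(year = 2009, time = 1.5, status = 1L)
  expect_silent(netmma:::assert_no_leakage(ok, 2011))
  bad <- tibble::tibble(year = 2009, time = 3.5, status = 1L)
  expect_error(netmma:::assert_no_leakage(bad, 2011), "leakage")
})

test_that("study designs enforce the window/prediction/projection geometry", {
  expect_error(study_design(windows = list(c(2005, 2009)), censor_date = 2011,
                            prediction_year = 2010, projection_year = 2011),
               "inside every window")
  expect_error(study_design(windows = list(c(2005, 2011)), censor_date = 2011,
                            prediction_year = 2011, projection_year = 2011),
               "outside every window")
  expect_error(study_design(windows = list(c(2005, 2010)), censor_date = 2009,
                            prediction_year = 2010, projection_year = 2011),
               "end the windows")
})

test_that("run_study produces per-window model sets, arms and evaluations", {
  sc <- scenario_preset("colon", n = 1500, years = c(2005, 2011),
                        censor_date = 2016, seed = 21)
  d <- simulate_cohort(sc)
  design <- study_design(windows = list(c(2005, 2010)), censor_date = 2011,
                         prediction_year = 2010, projection_year = 2011,
                         criterion = "BIC", horizons = c(1, 5))
  base <- eh_spec(3, effects = list(eh_effect("age"), eh_effect("year")))
  res <- run_study(d, sc$life_table, design, base, scenario = sc)
  w <- res$windows[["2005-2010"]]
  expect_s3_class(w$model_set, "model_set")
  expect_s3_class(w$evaluation_prediction$ma, "evaluation_report")
  expect_s3_class(w$evaluation_projection$ma, "evaluation_report")
  expect_s3_class(w$period_curve, "ns_curve")
  # RMISD summaries exist for both horizons and all arms
  for (arm in c("ma", "simple")) {
    summ <- attr(w$evaluation_prediction[[arm]], "rmisd")
    expect_equal(sort(summ$horizon), c(1, 5))
    expect_true(all(summ$rmisd >= 0))
  }
  # the manifest records cohort sizes and retained-model counts
  expect_equal(res$manifest$n_prediction,
               sum(floor(d$year) == 2010))
  expect_equal(res$manifest$n_projection,
               sum(floor(d$year) == 2011))
  expect_gte(res$manifest$models_retained[["2005-2010"]], 1)
  # reruns on identical inputs reproduce identical evaluations
  res2 <- run_study(d, sc$life_table, design, base, scenario = sc)
  expect_equal(attr(res2$windows[[1]]$evaluation_prediction$ma, "rmisd"),
               attr(w$evaluation_prediction$ma, "rmisd"))
})

test_that("patient files round-trip through delimited text with column maps", {
  d <- tibble::tibble(agex = c(60, 70), sexe = "m", quintile = c(1, 5),
                      yr = c(2005.5, 2006.5), fup = c(400, 800), dead = c(1, 0))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d, path, row.names = FALSE)
  pats <- read_patients(path, col_map = c(age = "agex", sex = "sexe",
                                          dep = "quintile", year = "yr",
                                          time = "fup", status = "dead"),
                        day_counts = TRUE)
  expect_equal(pats$time, c(400, 800) / 365.25)
  expect_named(pats, c("age", "sex", "dep", "year", "time", "status"))
})

test_that("net survival curves export as delimited text", {
  curve <- netmma:::new_ns_curve(c(1, 5), c(0.8, 0.5), c(1e-4, 2e-4),
                                 provenance = "pp-cohort")
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve(curve, path)
  back <- utils::read.csv(path)
  expect_equal(back$estimate, c(0.8, 0.5))
  expect_equal(back$provenance, rep("pp-cohort", 2))
})
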