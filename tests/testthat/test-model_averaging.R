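test_that("criterion weights normalise the model likelihoods exp(-delta/2)", {
  f <- const_hazard_fit(0.2)
  expect_equal(xic_weights(model_set(list(f), xic = 123.4)), 1)
  ms2 <- model_set(list(f, f), xic = c(100, 102))
  w <- xic_weights(ms2)
  expect_equal(w, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))), tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # k models with identical criteria share the weight equally
  ms4 <- model_set(list(f, f, f, f), xic = rep(50, 4))
  expect_equal(xic_weights(ms4), rep(0.25, 4))
  # weights are invariant to adding a constant to all criteria
  expect_equal(xic_weights(model_set(list(f, f), xic = c(1100, 1102))), w)
})

test_that("evidence ratios grow exponentially in the criterion gap", {
  f <- const_hazard_fit(0.2)
  for (delta in c(2, 4, 8)) {
    ms <- model_set(list(f, f), xic = c(0, delta))
    expect_equal(evidence_ratio(ms, 1, 2), exp(delta / 2), tolerance = 1e-12)
  }
  ms <- model_set(list(f, f, f), xic = c(0, 3, 7))
  expect_equal(evidence_ratio(ms, 1, 1), 1)
  # multiplicativity e(m,n) * e(n,k) = e(m,k)
  expect_equal(evidence_ratio(ms, 1, 2) * evidence_ratio(ms, 2, 3),
               evidence_ratio(ms, 1, 3), tolerance = 1e-12)
})

test_that("a single-model set reproduces that model's predictions exactly", {
  d <- sim_ph_linear(300, beta = 0.5, seed = 41)
  fit <- fit_excess_hazard(d, eh_spec(2, effects = list(eh_effect("x"))))
  ms <- model_set(list(fit))
  times <- c(0.5, 1, 3)
  ap <- average_predictions(ms, d[1:20, ], times)
  pq <- netmma:::eh_predict_quantities(fit, d[1:20, ], times)
  expect_equal(matrix(ap$individual$hazard, 20), pq$hazard)
  expect_equal(matrix(ap$individual$cum_hazard, 20), pq$cum_hazard)
  coh <- predict_net_survival(fit, d[1:20, ], times)
  expect_equal(ap$cohort$estimate, coh$estimate)
})

test_that("averaging acts on predicted hazards, then exponentiates the averaged
           cumulative hazard (not the other way around)", {
  # two constant-hazard models with Lambda(1) = 1 and 2, equal weights
  f1 <- const_hazard_fit(1); f2 <- const_hazard_fit(2)
  ms <- model_set(list(f1, f2), xic = c(0, 0))
  ap <- average_predictions(ms, tibble::tibble(x = 1), times = 1)
  expect_equal(ap$individual$hazard, 1.5)        # mean of 1 and 2
  expect_equal(ap$individual$cum_hazard, 1.5, tolerance = 1e-10)
  # exp(-mean(Lambda)) = 0.2231, not mean(exp(-Lambda)) = 0.2518
  expect_equal(ap$individual$survival, exp(-1.5), tolerance = 1e-10)
  expect_equal(round(ap$individual$survival, 4), 0.2231)
  expect_false(isTRUE(all.equal(ap$individual$survival,
                                mean(exp(-c(1, 2))), tolerance = 1e-3)))
})

test_that("the unconditional variance combines within- and between-model spread", {
  # all models identical with common variance v: result is v
  expect_equal(unconditional_variance(c(0.5, 0.3, 0.2), rep(1.7, 3), rep(0.04, 3)),
               0.04, tolerance = 1e-12)
  # zero within-variance, estimates theta +/- d, equal weights: result d^2
  d <- 0.3
  expect_equal(unconditional_variance(c(0.5, 0.5), c(1 + d, 1 - d), c(0, 0)),
               d^2, tolerance = 1e-12)
  # three-model case against a direct one-line evaluation of the formula
  w <- c(0.5, 0.3, 0.2); est <- c(1.0, 1.2, 0.8); v <- c(0.01, 0.02, 0.04)
  ma <- sum(w * est)
  oracle <- sum(w * sqrt(v + (est - ma)^2))^2
  expect_equal(unconditional_variance(w, est, v), oracle, tolerance = 1e-14)
  # never smaller than the squared weighted sum of within-model SDs
  expect_gte(unconditional_variance(w, est, v), sum(w * sqrt(v))^2)
  expect_error(unconditional_variance(w, est, c(-0.1, 0, 0)), "non-negative")
})

test_that("averaged predictions carry the unconditional variance elementwise", {
  d <- sim_ph_linear(400, beta = 0.5, seed = 43)
  f1 <- fit_excess_hazard(d, eh_spec(2, effects = list(eh_effect("x"))))
  f2 <- fit_excess_hazard(d, eh_spec(2))
  ms <- model_set(list(f1, f2))
  w <- xic_weights(ms)
  times <- c(1, 2)
  ap <- average_predictions(ms, d[1:5, ], times)
  p1 <- netmma:::eh_predict_quantities(ms$models[[1]], d[1:5, ], times)
  p2 <- netmma:::eh_predict_quantities(ms$models[[2]], d[1:5, ], times)
  for (i in 1:5) {
    for (j in seq_along(times)) {
      est <- c(p1$hazard[i, j], p2$hazard[i, j])
      v <- c(p1$var_hazard[i, j], p2$var_hazard[i, j])
      expected <- unconditional_variance(w, est, v)
      got <- ap$individual$var_hazard[ap$individual$.row == i &
                                        ap$individual$time == times[j]]
      expect_equal(got, expected, tolerance = 1e-10)
    }
  }
})
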