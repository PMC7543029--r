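test_that("log excess hazard composes baseline and effects as stated", {
  fit <- const_hazard_fit(0.2)
  p <- tibble::tibble(x = 2)
  for (tt in c(0.3, 1, 4)) {
    expect_equal(exp(log_excess_hazard(fit, p, tt)), 0.2)
  }
  expect_error(log_excess_hazard(fit, p, 0), "positive")

  # proportional linear effect beta = 0.5 at x = 2 (centered at 0)
  spec <- eh_spec(baseline_df = 0, effects = list(eh_effect("x")))
  frame <- list(spec = spec, baseline = NULL,
                terms = list(list(effect = spec$effects[[1]], center = 0, basis = NULL)))
  fit2 <- const_hazard_fit(0.2)
  fit2$spec <- spec; fit2$frame <- frame
  fit2$coef <- c(`(Intercept)` = log(0.2), x = 0.5)
  fit2$vcov <- diag(2)
  expect_equal(exp(log_excess_hazard(fit2, p, 1)), 0.2 * exp(1))

  # time-dependent effect pivots at t = 1 where log(t) = 0
  spec3 <- eh_spec(baseline_df = 0, effects = list(eh_effect("x", tdep = TRUE)))
  frame3 <- list(spec = spec3, baseline = NULL,
                 terms = list(list(effect = spec3$effects[[1]], center = 0, basis = NULL)))
  fit3 <- const_hazard_fit(0.2)
  fit3$spec <- spec3; fit3$frame <- frame3
  fit3$coef <- c(`(Intercept)` = log(0.2), x = 0.3, `x:log(t)` = 0.3)
  fit3$vcov <- diag(3)
  p1 <- tibble::tibble(x = 1)
  expect_equal(exp(log_excess_hazard(fit3, p1, 1)), 0.2 * exp(0.3))
})

test_that("cumulative excess hazard matches closed forms via quadrature", {
  fit <- const_hazard_fit(0.2)
  p <- tibble::tibble(x = 1)
  expect_equal(cumulative_excess_hazard(fit, p, 5), 1.0, tolerance = 1e-10)
  expect_equal(cumulative_excess_hazard(fit, p, 1e-12), 0, tolerance = 1e-10)
  # Weibull-type hazard 0.3 * 1.5 * t^0.5: log lam = log(0.45) + 0.5 log t
  spec <- eh_spec(baseline_df = 1)
  frame <- list(spec = spec,
                baseline = netmma:::new_spline_basis(numeric(0), c(0, 1), "log"),
                terms = list())
  fitw <- const_hazard_fit(1)
  fitw$spec <- spec; fitw$frame <- frame
  fitw$coef <- c(log(0.45), 0.5); fitw$vcov <- diag(2)
  expect_equal(cumulative_excess_hazard(fitw, p, 2), 0.3 * 2^1.5, tolerance = 1e-4)
  # 20-node and 60-node quadrature agree (sqrt hazard is not polynomial, so
  # agreement is to quadrature accuracy, not machine precision)
  expect_equal(cumulative_excess_hazard(fitw, p, 2, nodes = 60),
               cumulative_excess_hazard(fitw, p, 2, nodes = 20), tolerance = 1e-4)
})

test_that("the excess hazard log-likelihood matches hand-computed values", {
  lt <- flat_life_table(rate = 0.1)
  spec <- eh_spec(baseline_df = 0)
  one <- tibble::tibble(time = 1, status = 1, age = 70, year = 2010,
                        sex = "m", stratum = "all")
  expect_equal(eh_log_likelihood(one, spec, log(0.2), table = lt),
               log(0.3) - 0.2, tolerance = 1e-10)
  cens <- tibble::tibble(time = 2, status = 0, age = 70, year = 2010,
                         sex = "m", stratum = "all")
  expect_equal(eh_log_likelihood(cens, spec, log(0.2), table = lt),
               -0.4, tolerance = 1e-10)
})

test_that("with no background mortality the likelihood is the classical one", {
  d <- sim_exponential(80, rate = 0.4, seed = 5)
  # independent closed form: sum(delta) log(lam) - lam * sum(t)
  lam <- 0.31
  classical <- sum(d$status) * log(lam) - lam * sum(d$time)
  expect_equal(eh_log_likelihood(d, eh_spec(0), log(lam)), classical,
               tolerance = 1e-9)
})

test_that("intercept-only fit recovers the exponential MLE and its AIC", {
  d <- sim_exponential(300, rate = 0.3, seed = 7)
  fit <- fit_excess_hazard(d, eh_spec(0))
  dd <- sum(d$status); Tt <- sum(d$time)
  expect_equal(exp(fit$coef[[1]]), dd / Tt, tolerance = 1e-7)
  expect_equal(fit$AIC, -2 * (dd * log(dd / Tt) - dd) + 2, tolerance = 1e-7)
  expect_equal(fit$AIC, -2 * fit$loglik + 2 * fit$p)
  expect_equal(fit$BIC, -2 * fit$loglik + fit$p * log(fit$n_events))
  # covariance is symmetric positive definite
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("a proportional linear effect is recovered within 2 SE", {
  d <- sim_ph_linear(2000, beta = 0.5, seed = 13)
  fit <- fit_excess_hazard(d, eh_spec(3, effects = list(eh_effect("x"))))
  est <- tidy(fit)
  bx <- est[est$term == "x", ]
  expect_lt(abs(bx$estimate - 0.5), 2 * bx$std.error)
})

test_that("degenerate inputs fail loudly", {
  d <- sim_exponential(50, seed = 2)
  d$status <- 0L
  expect_error(fit_excess_hazard(d, eh_spec(0)), "zero events")
  d2 <- sim_ph_linear(100, seed = 3)
  d2$x2 <- 2 * d2$x  # exactly collinear
  spec <- eh_spec(3, effects = list(eh_effect("x"), eh_effect("x2")))
  expect_error(fit_excess_hazard(d2, spec), "rank deficient")
})

test_that("the fitted log-likelihood is invariant to affine covariate recoding", {
  d <- sim_ph_linear(500, beta = 0.4, seed = 21)
  f1 <- fit_excess_hazard(d, eh_spec(2, effects = list(eh_effect("x"))))
  d2 <- d; d2$x <- 2 * d$x + 5
  f2 <- fit_excess_hazard(d2, eh_spec(2, effects = list(eh_effect("x"))))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f2$coef[["x"]], f1$coef[["x"]] / 2, tolerance = 1e-4)
})

test_that("net survival predictions behave as convex cohort combinations", {
  d <- sim_ph_linear(400, beta = 0.6, seed = 8)
  fit <- fit_excess_hazard(d, eh_spec(2, effects = list(eh_effect("x"))))
  grid <- c(0.5, 1, 2, 4)
  ind <- predict_net_survival(fit, d[1:30, ], grid, type = "individual")
  coh <- predict_net_survival(fit, d[1:30, ], grid, type = "cohort")
  for (g in grid) {
    si <- ind$survival[ind$time == g]
    expect_gte(coh$estimate[coh$time == g], min(si))
    expect_lte(coh$estimate[coh$time == g], max(si))
  }
  # identical patients: cohort equals individual
  same <- d[rep(1, 10), ]
  coh2 <- predict_net_survival(fit, same, 2)
  ind2 <- predict_net_survival(fit, same[1, ], 2, type = "individual")
  expect_equal(coh2$estimate, ind2$survival)
  # constant hazard closed form
  cf <- const_hazard_fit(0.2)
  expect_equal(predict_net_survival(cf, tibble::tibble(x = 1), 5)$estimate,
               exp(-1), tolerance = 1e-10)
})

test_that("fits serialize to JSON and round-trip with identical predictions", {
  skip_if_not_installed("jsonlite")
  d <- sim_ph_linear(300, beta = 0.5, seed = 31)
  fit <- fit_excess_hazard(d, eh_spec(3, effects = list(eh_effect("x"))))
  path <- withr::local_tempfile(fileext = ".json")
  write_eh_fit(fit, path)
  fit2 <- read_eh_fit(path)
  expect_equal(fit2$coef, fit$coef)
  expect_equal(fit2$AIC, fit$AIC)
  nd <- d[1:5, ]
  expect_equal(log_excess_hazard(fit2, nd, 2), log_excess_hazard(fit, nd, 2))
  expect_equal(cumulative_excess_hazard(fit2, nd, 3),
               cumulative_excess_hazard(fit, nd, 3))
})
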