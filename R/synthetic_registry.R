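#' Synthetic cancer-registry cohorts with known true net survival
#'
#' Generates registry-like patient cohorts from a fully specified data
#' generating process: covariates (age at diagnosis, sex, deprivation
#' quintile, decimal diagnosis date), a true excess hazard with optionally
#' time-dependent covariate effects, other-cause death times drawn from a
#' population life table, and administrative censoring at a calendar cut-off.
#' Because the true excess hazard is known in closed form, every downstream
#' method (model fitting, selection, averaging, Pohar-Perme estimation,
#' RMISD) can be checked against exact truth.
#'
#' @name synthetic_registry
NULL

#' Define a synthetic registry scenario
#'
#' The true excess hazard is Weibull-like with log-time-linear covariate
#' interactions:
#' \deqn{\lambda_E(t, x) = \rho \kappa t^{\kappa - 1}
#'   \exp\{\eta(x) + \zeta(x) \log t\}}
#' where \eqn{\eta(x) = \sum \beta_k f_k(x)} collects proportional effects
#' and \eqn{\zeta(x) = \sum \beta_k f_k(x)} time-dependent ones. The
#' cumulative hazard is then available in closed form,
#' \eqn{\Lambda_E(t) = \rho\kappa e^{\eta} t^{\kappa+\zeta}/(\kappa+\zeta)},
#' so event times are drawn by exact inversion.
#'
#' @param n Cohort size.
#' @param life_table A [life_table()] covering all attained ages and years of
#'   the follow-up window.
#' @param years Diagnosis window `c(first, last)` in calendar years;
#'   diagnosis dates are uniform over `[first, last + 1)`.
#' @param age Age-at-diagnosis generator: list with `mean`, `sd`, `min`,
#'   `max` (truncated normal by rejection-free clamping).
#' @param dep_probs Probabilities of deprivation quintiles 1-5.
#' @param sex Single label (e.g. `"male"`) or named probability vector.
#' @param baseline List `shape` (\eqn{\kappa}) and `rate` (\eqn{\rho});
#'   \eqn{\Lambda_E(1) = \rho e^{\eta}} when \eqn{\zeta = 0}.
#' @param effects List of true effects: each a list with `variable`, `beta`,
#'   optional `fun` (transform of the covariate, default centred identity),
#'   optional `center` and `tdep` flag.
#' @param censor_date Administrative censoring date (decimal year) applied to
#'   the generated follow-up, e.g. `2011` for censoring on 31 December 2010.
#' @param seed Integer seed; fixed seed gives byte-identical cohorts.
#' @return An object of class `registry_scenario`.
#' @export
registry_scenario <- function(n, life_table, years = c(1990, 2010),
                              age = list(mean = 70, sd = 11, min = 15, max = 99),
                              dep_probs = rep(0.2, 5),
                              sex = "male",
                              baseline = list(shape = 1.2, rate = 0.25),
                              effects = list(),
                              censor_date = max(years) + 1,
                              seed = 1L) {
  stopifnot(n >= 1, length(years) == 2, years[2] >= years[1])
  if (abs(sum(dep_probs) - 1) > 1e-8) {
    stop("dep_probs must sum to 1", call. = FALSE)
  }
  if (is.numeric(sex) && abs(sum(sex) - 1) > 1e-8) {
    stop("sex probabilities must sum to 1", call. = FALSE)
  }
  if (censor_date <= years[1]) {
    stop("censoring date must lie after the earliest diagnosis date (no follow-up otherwise)",
         call. = FALSE)
  }
  stopifnot(baseline$shape > 0, baseline$rate > 0)
  structure(list(n = as.integer(n), life_table = life_table, years = years,
                 age = age, dep_probs = dep_probs, sex = sex,
                 baseline = baseline, effects = effects,
                 censor_date = censor_date, seed = as.integer(seed)),
            class = "registry_scenario")
}

# independent named RNG streams derived from the scenario seed, so adding a
# draw to one stream does not shift the others
stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L)
  (as.integer(seed) * 1009L + h) %% 2147483587L
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, name))
  force(expr)
}

# proportional (eta) and time-dependent (zeta) true linear predictors
scenario_predictors <- function(scenario, data) {
  eta <- rep(0, nrow(data)); zeta <- rep(0, nrow(data))
  for (e in scenario$effects) {
    x <- data[[e$variable]]
    if (is.null(x)) stop("scenario effect variable missing: ", e$variable, call. = FALSE)
    v <- if (!is.null(e$fun)) e$fun(x) else as.numeric(x) - (e$center %||% 0)
    if (isTRUE(e$tdep)) zeta <- zeta + e$beta * v else eta <- eta + e$beta * v
  }
  list(eta = eta, zeta = zeta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# closed-form true cumulative excess hazard
scenario_cum_hazard <- function(scenario, eta, zeta, t) {
  kap <- scenario$baseline$shape; rho <- scenario$baseline$rate
  n <- max(length(eta), length(zeta), length(t))
  eta <- rep_len(eta, n); zeta <- rep_len(zeta, n); t <- rep_len(t, n)
  pw <- kap + zeta
  if (any(pw <= 0)) {
    stop("time-dependent effects make shape + zeta <= 0 for some subjects; ",
         "the true cumulative hazard would not diverge", call. = FALSE)
  }
  out <- rho * kap * exp(eta) * t^pw / pw
  out[t <= 0] <- 0
  out
}

#' True net survival under a scenario
#'
#' \eqn{\exp\{-\Lambda_{E,true}(t)\}} from the scenario's closed-form true
#' hazard, per row of `newdata`.
#'
#' @param scenario A [registry_scenario()].
#' @param newdata Data frame with the scenario's effect variables.
#' @param t Time(s) since diagnosis, `>= 0` (length 1 or `nrow(newdata)`).
#' @return Numeric vector of survival probabilities.
#' @export
true_net_survival <- function(scenario, newdata, t) {
  stopifnot(inherits(scenario, "registry_scenario"))
  newdata <- tibble::as_tibble(newdata)
  pr <- scenario_predictors(scenario, newdata)
  t <- rep_len(t, nrow(newdata))
  exp(-scenario_cum_hazard(scenario, pr$eta, pr$zeta, t))
}

#' Simulate a registry cohort
#'
#' Covariates are drawn from the scenario generators; a cancer death time is
#' drawn by exact inversion of the true cumulative excess hazard; an
#' other-cause death time by inversion of the patient's piecewise-constant
#' expected cumulative hazard from the life table; the observed time is the
#' minimum of both death times and administrative censoring, with
#' `status = 1` if either death precedes censoring (observed, all-cause
#' mortality).
#'
#' @param scenario A [registry_scenario()].
#' @return A tibble of patient records: `id`, `age`, `sex`, `dep` (quintile),
#'   `stratum`, `year` (decimal diagnosis date), `time`, `status`, plus the
#'   truth columns `true_ns1` and `true_ns5` (per-patient true 1- and 5-year
#'   net survival) as a `truth` attribute together with the scenario.
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "registry_scenario"))
  n <- scenario$n
  tab <- scenario$life_table
  seed <- scenario$seed

  age <- with_stream(seed, "age", {
    a <- stats::rnorm(n, scenario$age$mean, scenario$age$sd)
    pmin(pmax(a, scenario$age$min), scenario$age$max)
  })
  dep <- with_stream(seed, "dep",
                     sample.int(5, n, replace = TRUE, prob = scenario$dep_probs))
  sex <- if (is.character(scenario$sex)) {
    rep(scenario$sex, n)
  } else {
    with_stream(seed, "sex",
                sample(names(scenario$sex), n, replace = TRUE, prob = scenario$sex))
  }
  year <- with_stream(seed, "year",
                      stats::runif(n, scenario$years[1], scenario$years[2] + 1))
  cens <- scenario$censor_date - year
  if (all(cens <= 0)) {
    stop("administrative censoring precedes every diagnosis: no follow-up",
         call. = FALSE)
  }

  data <- tibble::tibble(id = seq_len(n), age = age, sex = sex,
                         dep = dep, stratum = as.character(dep), year = year)

  # cancer death by inversion of the closed-form true cumulative hazard
  pr <- scenario_predictors(scenario, data)
  u_e <- with_stream(seed, "excess", stats::runif(n))
  kap <- scenario$baseline$shape; rho <- scenario$baseline$rate
  pw <- kap + pr$zeta
  if (any(pw <= 0)) stop("shape + zeta must stay positive", call. = FALSE)
  t_cancer <- ((-log(u_e)) * pw / (rho * kap * exp(pr$eta)))^(1 / pw)

  # other-cause death from the patient's life-table path
  u_p <- with_stream(seed, "popmort", stats::runif(n))
  horizon <- pmax(cens, 0) + 1
  t_other <- vapply(seq_len(n), function(i) {
    path <- lp_path(tab, age[i], year[i], sex[i], as.character(dep[i]), horizon[i])
    lp_path_invert(path, -log(u_p[i]))
  }, 0)

  death <- pmin(t_cancer, t_other)
  status <- as.integer(death < cens)
  time <- pmax(pmin(death, cens), EH_MIN_TIME)

  data$time <- time
  data$status <- status
  truth <- tibble::tibble(
    id = data$id,
    eta = pr$eta, zeta = pr$zeta,
    true_ns1 = exp(-scenario_cum_hazard(scenario, pr$eta, pr$zeta, 1)),
    true_ns5 = exp(-scenario_cum_hazard(scenario, pr$eta, pr$zeta, 5)))
  attr(data, "truth") <- truth
  attr(data, "scenario") <- scenario
  data
}

#' Build a synthetic population life table
#'
#' Gompertz-type rates \eqn{rate(a) = a_0 e^{b\,a}} per stratum with a mild
#' log-linear calendar trend:
#' `rate = a0 * exp(b * age) * stratum_mult * exp(year_trend * (year - min(year)))`.
#'
#' @param age_range,year_range Integer ranges `c(min, max)`.
#' @param sexes Character vector of sex labels.
#' @param strata Character vector of stratum labels.
#' @param a0,b Gompertz intercept and slope.
#' @param stratum_mult Named (or positional) multipliers per stratum.
#' @param sex_mult Multipliers per sex.
#' @param year_trend Log-linear calendar trend per year (0 = none).
#' @param warn_rate,max_rate Warning / hard-cap thresholds on the annual rate.
#' @return A [life_table()].
#' @export
make_synthetic_life_table <- function(age_range = c(15, 99),
                                      year_range = c(1985, 2020),
                                      sexes = "male",
                                      strata = as.character(1:5),
                                      a0 = 2e-5, b = 0.095,
                                      stratum_mult = seq(0.85, 1.35,
                                                         length.out = length(strata)),
                                      sex_mult = rep(1, length(sexes)),
                                      year_trend = -0.005,
                                      warn_rate = 1, max_rate = 10) {
  grid <- expand.grid(age = seq(age_range[1], age_range[2]),
                      year = seq(year_range[1], year_range[2]),
                      sex = sexes, stratum = strata,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sm <- stratum_mult[match(grid$stratum, strata)]
  xm <- sex_mult[match(grid$sex, sexes)]
  grid$rate <- a0 * exp(b * grid$age) * sm * xm *
    exp(year_trend * (grid$year - year_range[1]))
  if (any(grid$rate > max_rate)) {
    stop(sprintf("synthetic life-table rates exceed the hard cap of %.3g per year",
                 max_rate), call. = FALSE)
  }
  if (any(grid$rate > warn_rate)) {
    warning(sprintf("%d synthetic life-table cell(s) exceed %.3g per year",
                    sum(grid$rate > warn_rate), warn_rate), call. = FALSE)
  }
  life_table(grid)
}

#' Scenario presets for three qualitative cancer regimes
#'
#' Ready-made data generating processes mirroring three qualitative regimes:
#' `"lung"` (high lethality, irregular calendar trend with a slope break),
#' `"colon"` (moderate lethality, steady moderate trend) and `"breast"` (low
#' lethality, steady slow trend, female). All effect sizes are this package's
#' own choices for realistic registry-like behaviour; they are not estimates
#' from any registry.
#'
#' @param name `"lung"`, `"colon"` or `"breast"`.
#' @param n Cohort size.
#' @param life_table Optional [life_table()]; by default a synthetic
#'   Gompertz table covering 1985-2020 is built.
#' @param years Diagnosis window.
#' @param censor_date Administrative censoring date (decimal year).
#' @param seed Integer seed.
#' @return A [registry_scenario()].
#' @export
scenario_preset <- function(name = c("colon", "lung", "breast"), n = 2000,
                            life_table = NULL, years = c(2000, 2010),
                            censor_date = max(years) + 1, seed = 1L) {
  name <- match.arg(name)
  sex <- if (name == "breast") "female" else "male"
  if (is.null(life_table)) {
    life_table <- make_synthetic_life_table(sexes = sex)
  }
  year0 <- mean(years)
  base <- switch(name,
    lung = list(shape = 0.85, rate = 1.1),
    colon = list(shape = 1.1, rate = 0.28),
    breast = list(shape = 1.3, rate = 0.045))
  effects <- switch(name,
    lung = list(
      list(variable = "age", beta = 0.025, center = 70),
      list(variable = "dep", beta = 0.06, center = 3),
      # irregular trend: improvement only after the midpoint of the window
      list(variable = "year", beta = -0.035,
           fun = function(y) pmax(y - year0, 0)),
      list(variable = "dep", beta = 0.05, center = 3, tdep = TRUE)),
    colon = list(
      list(variable = "age", beta = 0.02, center = 70),
      list(variable = "dep", beta = 0.05, center = 3),
      list(variable = "year", beta = -0.015, center = year0)),
    breast = list(
      list(variable = "age", beta = 0.022, center = 62),
      list(variable = "dep", beta = 0.05, center = 3),
      list(variable = "year", beta = -0.02, center = year0)))
  age <- if (name == "breast") {
    list(mean = 62, sd = 12, min = 15, max = 99)
  } else {
    list(mean = 70, sd = 10, min = 15, max = 99)
  }
  registry_scenario(n = n, life_table = life_table, years = years, age = age,
                    sex = sex, baseline = base, effects = effects,
                    censor_date = censor_date, seed = seed)
}
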