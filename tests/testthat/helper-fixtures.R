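# shared fixtures, built in code at test time

# flat life table: one constant annual rate everywhere
flat_life_table <- function(rate = 0.1, ages = 20:99, years = 2000:2020,
                            sex = "m", stratum = "all") {
  grid <- expand.grid(age = ages, year = years, sex = sex, stratum = stratum,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rate <- rate
  life_table(grid)
}

# censored exponential survival data with no background mortality; times
# below one day are rounded up to one day (the registry convention the
# fitters apply), so d / sum(t) is well defined on the same scale
sim_exponential <- function(n, rate = 0.3, cens_max = 8, seed = 1) {
  set.seed(seed)
  t <- stats::rexp(n, rate)
  cens <- stats::runif(n, 0, cens_max)
  tibble::tibble(time = pmax(pmin(t, cens), 1 / 365.25),
                 status = as.integer(t <= cens))
}

# Weibull excess times with a proportional linear covariate effect, lamP = 0
sim_ph_linear <- function(n, beta = 0.5, shape = 1.2, rate = 0.25,
                          cens_max = 6, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  u <- stats::runif(n)
  tE <- ((-log(u)) / (rate * exp(beta * x)))^(1 / shape)
  cens <- stats::runif(n, 0.5, cens_max)
  tibble::tibble(time = pmin(tE, cens), status = as.integer(tE <= cens), x = x)
}

# hand-built constant-hazard eh_fit: lambda_E = rate at all times, no data
const_hazard_fit <- function(rate, var_log = 0) {
  spec <- eh_spec(baseline_df = 0)
  frame <- list(spec = spec, baseline = NULL, terms = list())
  structure(list(spec = spec, frame = frame,
                 coef = c(`(Intercept)` = log(rate)),
                 vcov = matrix(var_log, 1, 1,
                               dimnames = list("(Intercept)", "(Intercept)")),
                 loglik = NA_real_, n = 0L, n_events = 0L, p = 1L,
                 AIC = NA_real_, BIC = NA_real_, nodes = 20,
                 convergence = list(code = 0)),
            class = "eh_fit")
}

# independent truncated-power restricted cubic spline (textbook oracle)
rcs_oracle <- function(v, knots) {
  K <- length(knots)
  kK <- knots[K]; kK1 <- knots[K - 1]
  p3 <- function(x) pmax(x, 0)^3
  cols <- list(v)
  for (j in seq_len(K - 2)) {
    kj <- knots[j]
    cols[[j + 1]] <- p3(v - kj) - p3(v - kK1) * (kK - kj) / (kK - kK1) +
      p3(v - kK) * (kK1 - kj) / (kK - kK1)
  }
  do.call(cbind, cols)
}

# toy life-table file on disk
write_toy_lt <- function(path, drop_row = FALSE, bad_rate = FALSE) {
  df <- expand.grid(age = c(70, 71), year = c(2010, 2011),
                    sex = "m", stratum = "all",
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$rate <- c(0.010, 0.012, 0.011, 0.013)
  if (bad_rate) df$rate[1] <- -0.01
  if (drop_row) df <- df[-2, ]
  utils::write.csv(df, path, row.names = FALSE)
  path
}
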