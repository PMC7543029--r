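#' Specify an excess hazard model
#'
#' An excess hazard model decomposes observed mortality as
#' \eqn{\lambda(t,x) = \lambda_E(t,x) + \lambda_P(a+t, y+t, z)}: the excess
#' (cancer-related) hazard plus the expected population hazard from a life
#' table. The excess hazard is modelled as
#' \deqn{\lambda_E(t,x) = \lambda_0(t) \exp\big(\sum_k \beta_k(t) g_k(x)\big)}
#' with \eqn{\log \lambda_0(t)} a restricted cubic spline in \eqn{\log t},
#' covariate effects \eqn{g_k} linear, spline or categorical (dummy) coded,
#' and time-dependent effects entering as \eqn{\beta \cdot \log(t)} multipliers.
#'
#' @param baseline_df Number of spline columns for the log baseline hazard on
#'   the log-time scale: `0` gives a constant (exponential) baseline, `1` a
#'   log-linear (Weibull-type) baseline, `3` (the default) a restricted cubic
#'   spline with two internal knots at the tertiles of the uncensored event
#'   times.
#' @param effects A list of [eh_effect()] terms.
#' @param interactions A list of [eh_interaction()] terms; each interaction's
#'   main effects must be present in `effects` (hierarchy).
#' @return An object of class `eh_spec`.
#' @examples
#' eh_spec(effects = list(eh_effect("age"), eh_effect("dep", form = "categorical")))
#' @export
eh_spec <- function(baseline_df = 3, effects = list(), interactions = list()) {
  stopifnot(is.numeric(baseline_df), baseline_df >= 0, baseline_df == round(baseline_df))
  effects <- lapply(effects, function(e) {
    if (!inherits(e, "eh_effect")) stop("effects must be built with eh_effect()", call. = FALSE)
    e
  })
  vars <- vapply(effects, `[[`, "", "variable")
  if (anyDuplicated(vars)) {
    stop("duplicate effect for variable: ", vars[duplicated(vars)][1], call. = FALSE)
  }
  for (ia in interactions) {
    if (!inherits(ia, "eh_interaction")) {
      stop("interactions must be built with eh_interaction()", call. = FALSE)
    }
    absent <- setdiff(c(ia$var1, ia$var2), vars)
    if (length(absent) > 0) {
      stop("interaction ", ia$var1, ":", ia$var2,
           " requires main effect(s) for: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
  }
  ikeys <- vapply(interactions, function(ia) paste(sort(c(ia$var1, ia$var2)), collapse = ":"), "")
  if (anyDuplicated(ikeys)) {
    stop("duplicate interaction: ", ikeys[duplicated(ikeys)][1], call. = FALSE)
  }
  structure(list(baseline_df = as.integer(baseline_df),
                 effects = effects, interactions = interactions),
            class = "eh_spec")
}

#' Describe one covariate effect
#'
#' @param variable Column name in the patient data.
#' @param form `"linear"` or `"spline"` for continuous variables,
#'   `"categorical"` for factors (dummy coding, first level as reference).
#' @param df Spline degrees of freedom when `form = "spline"` (default 3).
#' @param tdep Logical; if `TRUE` the effect is time-dependent, multiplying
#'   the covariate coding by `log(t)` in addition to the proportional part.
#' @return An `eh_effect` object.
#' @export
eh_effect <- function(variable, form = c("linear", "spline", "categorical"),
                      df = 3, tdep = FALSE) {
  form <- match.arg(form)
  structure(list(variable = variable, form = form,
                 df = as.integer(df), tdep = isTRUE(tdep)),
            class = "eh_effect")
}

#' Describe a pairwise interaction effect
#'
#' The interaction multiplies the linear/dummy codings of the two variables;
#' `tdep = TRUE` additionally multiplies by `log(t)`.
#'
#' @param var1,var2 Variable names; their main effects must be in the spec.
#' @param tdep Logical; time-dependent interaction.
#' @return An `eh_interaction` object.
#' @export
eh_interaction <- function(var1, var2, tdep = FALSE) {
  structure(list(var1 = var1, var2 = var2, tdep = isTRUE(tdep)),
            class = "eh_interaction")
}

# canonical single-line rendering; used for caching/deduplication in selection
#' @export
format.eh_spec <- function(x, ...) {
  eff <- vapply(x$effects, function(e) {
    paste0(e$variable, "[", e$form,
           if (e$form == "spline") paste0(e$df), "]",
           if (e$tdep) "*log(t)" else "")
  }, "")
  ia <- vapply(x$interactions, function(i) {
    paste0(paste(sort(c(i$var1, i$var2)), collapse = ":"),
           if (i$tdep) "*log(t)" else "")
  }, "")
  paste0("bs(", x$baseline_df, ") ", paste(sort(eff), collapse = " + "),
         if (length(ia)) paste0(" + ", paste(sort(ia), collapse = " + ")) else "")
}

#' @export
print.eh_spec <- function(x, ...) {
  cat("<eh_spec>", format(x), "\n")
  invisible(x)
}

# 20-node Gauss-Legendre rule on [-1, 1], cached
gl_rule <- local({
  cache <- list()
  function(n = 20) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- pracma::gaussLegendre(n, -1, 1)
    }
    cache[[key]]
  }
})

## ---- model frame: knots, centers, factor levels resolved against data ----

# one day, in years: events recorded at t = 0 are shifted here
EH_MIN_TIME <- 1 / 365.25

eh_check_data <- function(data, spec, need_lifetable_keys = FALSE) {
  if (!all(c("time", "status") %in% names(data))) {
    stop("patient data must have 'time' and 'status' columns", call. = FALSE)
  }
  if (any(!data$status %in% c(0, 1))) stop("status must be 0/1", call. = FALSE)
  if (any(data$time < 0)) stop("follow-up times must be positive", call. = FALSE)
  vars <- vapply(spec$effects, `[[`, "", "variable")
  absent <- setdiff(vars, names(data))
  if (length(absent) > 0) {
    stop("data lacks model variables: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  if (need_lifetable_keys) {
    keys <- setdiff(c("age", "year", "sex"), names(data))
    if (length(keys) > 0) {
      stop("life-table lookup needs data columns: ", paste(keys, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# resolve knots, centers and factor levels on the training data
eh_frame <- function(spec, data) {
  t <- pmax(data$time, EH_MIN_TIME)
  ev <- t[data$status == 1]

  baseline <- if (spec$baseline_df >= 2) {
    if (length(ev) == 0) {
      stop("cannot place baseline knots with zero events", call. = FALSE)
    }
    place_knots(ev, df = spec$baseline_df, scale = "log")
  } else if (spec$baseline_df == 1) {
    # pure log-linear baseline: no internal knots, boundaries immaterial
    new_spline_basis(numeric(0), c(0, 1), "log")
  } else NULL

  terms <- lapply(spec$effects, function(e) {
    x <- data[[e$variable]]
    if (e$form == "categorical") {
      lev <- if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
      list(effect = e, levels = lev)
    } else {
      if (!is.numeric(x)) {
        stop(sprintf("variable '%s' must be numeric for a %s effect",
                     e$variable, e$form), call. = FALSE)
      }
      basis <- if (e$form == "spline") place_knots(x, df = e$df, scale = "identity") else NULL
      list(effect = e, center = mean(x), basis = basis)
    }
  })
  list(spec = spec, baseline = baseline, terms = terms)
}

# covariate-level (time-free) coding of one term; returns a column matrix
eh_term_columns <- function(term, data) {
  e <- term$effect
  x <- data[[e$variable]]
  if (e$form == "categorical") {
    xc <- as.character(x)
    unknown <- setdiff(unique(xc), term$levels)
    if (length(unknown) > 0) {
      stop(sprintf("variable '%s' has unseen level(s): %s",
                   e$variable, paste(unknown, collapse = ", ")), call. = FALSE)
    }
    lev <- term$levels
    m <- matrix(0, nrow = length(xc), ncol = length(lev) - 1L)
    if (ncol(m) > 0) {
      for (j in seq_along(lev)[-1]) m[, j - 1L] <- as.numeric(xc == lev[j])
      colnames(m) <- paste0(e$variable, lev[-1])
    }
    m
  } else if (e$form == "spline") {
    m <- rcs_eval(term$basis, x)
    m <- sweep(m, 2, rcs_eval(term$basis, term$center)[1, ])
    colnames(m) <- paste0(e$variable, "_s", seq_len(ncol(m)))
    m
  } else {
    m <- matrix(x - term$center, ncol = 1)
    colnames(m) <- e$variable
    m
  }
}

# linear/dummy coding used inside interactions (splines reduce to linear)
eh_interaction_columns <- function(frame, ia, data) {
  coding <- function(v) {
    term <- frame$terms[[match(v, vapply(frame$terms, function(tt) tt$effect$variable, ""))]]
    e <- term$effect
    if (e$form == "categorical") {
      eh_term_columns(term, data)
    } else {
      m <- matrix(data[[v]] - term$center, ncol = 1)
      colnames(m) <- v
      m
    }
  }
  a <- coding(ia$var1); b <- coding(ia$var2)
  out <- matrix(0, nrow = nrow(data), ncol = ncol(a) * ncol(b))
  nm <- character(ncol(out))
  k <- 0
  for (i in seq_len(ncol(a))) {
    for (j in seq_len(ncol(b))) {
      k <- k + 1
      out[, k] <- a[, i] * b[, j]
      nm[k] <- paste0(colnames(a)[i], ":", colnames(b)[j])
    }
  }
  colnames(out) <- nm
  out
}

# split covariate-level design into proportional and time-dependent blocks
eh_covariate_blocks <- function(frame, data) {
  prop <- list(); td <- list()
  for (term in frame$terms) {
    m <- eh_term_columns(term, data)
    if (ncol(m) == 0) next
    prop[[length(prop) + 1]] <- m
    if (term$effect$tdep) {
      mt <- m
      colnames(mt) <- paste0(colnames(m), ":log(t)")
      td[[length(td) + 1]] <- mt
    }
  }
  for (ia in frame$spec$interactions) {
    m <- eh_interaction_columns(frame, ia, data)
    if (ia$tdep) {
      colnames(m) <- paste0(colnames(m), ":log(t)")
      td[[length(td) + 1]] <- m
    } else {
      prop[[length(prop) + 1]] <- m
    }
  }
  bind <- function(lst) if (length(lst)) do.call(cbind, lst) else
    matrix(0, nrow = nrow(data), ncol = 0)
  list(prop = bind(prop), td = bind(td))
}

# full design matrix at given times: [1 | B(log t) | X_prop | X_td * log t]
# rows of `blocks` are indexed by `idx` to align with `t`
eh_design <- function(frame, blocks, idx, t) {
  logt <- log(pmax(t, EH_MIN_TIME))
  n <- length(t)
  B <- if (!is.null(frame$baseline)) rcs_eval(frame$baseline, logt) else
    matrix(0, nrow = n, ncol = 0)
  if (ncol(B) > 0) colnames(B) <- paste0("bs", seq_len(ncol(B)), "(log t)")
  cbind(`(Intercept)` = rep(1, n), B,
        blocks$prop[idx, , drop = FALSE],
        blocks$td[idx, , drop = FALSE] * logt)
}

#' Log excess hazard for given patients and times
#'
#' Evaluates \eqn{\log \lambda_E(t, x)} under a fitted model: the spline
#' baseline in `log(t)` plus proportional effects and time-dependent effects
#' contributing \eqn{\beta g(x) \log(t)}.
#'
#' @param fit An [fit_excess_hazard()] result.
#' @param newdata Patient data frame (one row per subject).
#' @param t Time(s) since diagnosis in years, `> 0`; either length 1 or
#'   `nrow(newdata)`.
#' @return Numeric vector of log hazards, one per row of `newdata`.
#' @export
log_excess_hazard <- function(fit, newdata, t) {
  stopifnot(inherits(fit, "eh_fit"))
  if (any(t <= 0)) stop("t must be positive (log-time undefined at 0)", call. = FALSE)
  newdata <- tibble::as_tibble(newdata)
  n <- nrow(newdata)
  t <- rep_len(t, n)
  blocks <- eh_covariate_blocks(fit$frame, newdata)
  Z <- eh_design(fit$frame, blocks, seq_len(n), t)
  drop(Z %*% fit$coef)
}

#' Cumulative excess hazard
#'
#' \eqn{\Lambda_E(t) = \int_0^t \lambda_E(u)\,du} by Gauss-Legendre
#' quadrature (20 nodes per integral).
#'
#' @inheritParams log_excess_hazard
#' @param nodes Number of quadrature nodes.
#' @return Numeric vector, one value per row of `newdata`.
#' @export
cumulative_excess_hazard <- function(fit, newdata, t, nodes = 20) {
  stopifnot(inherits(fit, "eh_fit"))
  newdata <- tibble::as_tibble(newdata)
  n <- nrow(newdata)
  t <- rep_len(t, n)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  blocks <- eh_covariate_blocks(fit$frame, newdata)
  q <- eh_quad_design(fit$frame, blocks, t, nodes)
  lam <- exp(drop(q$Z %*% fit$coef))
  if (any(!is.finite(lam))) {
    bad <- which(!is.finite(lam))[1]
    stop(sprintf("non-finite excess hazard at quadrature node t = %.6g", q$u[bad]),
         call. = FALSE)
  }
  as.numeric(rowsum(lam * q$w, q$idx, reorder = TRUE))
}

# quadrature design: for each subject i with upper limit t_i, nodes
# u_ik = t_i/2 (x_k + 1) and weights w_ik = t_i/2 w_k
eh_quad_design <- function(frame, blocks, t, nodes = 20) {
  n <- length(t)
  rule <- gl_rule(nodes)
  u <- as.vector(outer(rule$x + 1, t / 2))        # nodes fastest, subject-major
  idx <- rep(seq_len(n), each = nodes)
  w <- rep(t / 2, each = nodes) * rep(rule$w, times = n)
  u <- pmax(u, .Machine$double.xmin)
  Z <- eh_design(frame, blocks, idx, u)
  list(Z = Z, w = w, idx = idx, u = u)
}

## ---- likelihood ----

# internal: precompute everything the optimizer touches
eh_likelihood_parts <- function(frame, data, table, nodes = 20) {
  t <- pmax(data$time, EH_MIN_TIME)
  delta <- as.numeric(data$status)
  blocks <- eh_covariate_blocks(frame, data)
  Ze <- eh_design(frame, blocks, seq_len(nrow(data)), t)
  q <- eh_quad_design(frame, blocks, t, nodes)
  lp <- if (is.null(table)) rep(0, nrow(data)) else
    expected_hazard(table, data$age, data$year, data$sex, lt_stratum(data), t = t)
  list(Ze = Ze, Zq = q$Z, wq = q$w, qidx = q$idx, delta = delta, lp = lp,
       t = t, p = ncol(Ze))
}

lt_stratum <- function(data) {
  if ("stratum" %in% names(data)) data$stratum else rep("all", nrow(data))
}

# exp with a cap: keeps the optimiser's line searches finite far from the
# optimum without affecting any plausible parameter region
exp_cap <- function(eta) exp(pmin(eta, 500))

eh_ll <- function(theta, parts) {
  lam_e <- exp_cap(drop(parts$Ze %*% theta))
  lam_q <- exp_cap(drop(parts$Zq %*% theta))
  obs <- parts$lp + lam_e
  if (any(obs[parts$delta == 1] <= 0)) return(-Inf)
  sum(parts$delta * log(obs)) - sum(parts$wq * lam_q)
}

eh_ll_grad <- function(theta, parts) {
  lam_e <- exp_cap(drop(parts$Ze %*% theta))
  lam_q <- exp_cap(drop(parts$Zq %*% theta))
  r <- parts$delta * lam_e / (parts$lp + lam_e)
  drop(crossprod(parts$Ze, r) - crossprod(parts$Zq, parts$wq * lam_q))
}

eh_ll_hessian <- function(theta, parts) {
  lam_e <- exp_cap(drop(parts$Ze %*% theta))
  lam_q <- exp_cap(drop(parts$Zq %*% theta))
  r <- parts$delta * lam_e * parts$lp / (parts$lp + lam_e)^2
  # delta * d/deta [lam/(lp+lam)] = delta * lam * lp / (lp+lam)^2; when lp=0
  # the event term is linear in eta and contributes nothing
  He <- crossprod(parts$Ze * sqrt(pmax(r, 0)))
  Hq <- crossprod(parts$Zq * sqrt(parts$wq * lam_q))
  He - Hq
}

#' Log-likelihood of an excess hazard model at given parameters
#'
#' \deqn{L = \sum_i \delta_i \log\{\lambda_P(t_i) + \lambda_E(t_i)\} - \Lambda_E(t_i)}
#' With `table = NULL` (\eqn{\lambda_P \equiv 0}) this reduces to the standard
#' parametric survival log-likelihood.
#'
#' @param data Patient data frame with `time`, `status`, model covariates and
#'   (when `table` is supplied) life-table keys `age`, `year`, `sex` and
#'   optionally `stratum`.
#' @param spec An [eh_spec()].
#' @param params Numeric parameter vector in design-column order
#'   (intercept, baseline spline, proportional effects, time-dependent effects).
#' @param table A [life_table()] or `NULL` for \eqn{\lambda_P \equiv 0}.
#' @param nodes Gauss-Legendre nodes per cumulative-hazard integral.
#' @return The scalar log-likelihood.
#' @export
eh_log_likelihood <- function(data, spec, params, table = NULL, nodes = 20) {
  data <- tibble::as_tibble(data)
  eh_check_data(data, spec, need_lifetable_keys = !is.null(table))
  frame <- eh_frame(spec, data)
  parts <- eh_likelihood_parts(frame, data, table, nodes)
  if (length(params) != parts$p) {
    stop(sprintf("params has length %d but the design has %d columns",
                 length(params), parts$p), call. = FALSE)
  }
  eh_ll(params, parts)
}

## ---- fitting ----

#' Fit a flexible parametric excess hazard model
#'
#' Maximises the excess hazard log-likelihood
#' \eqn{\sum_i \delta_i \log(\lambda_P + \lambda_E) - \Lambda_E} by
#' quasi-Newton (BFGS) with analytic gradients; the parameter covariance is
#' the inverse observed information at the optimum. Continuous covariates are
#' centered at their sample means internally (recorded in the model frame and
#' applied to new data at prediction time).
#'
#' @inheritParams eh_log_likelihood
#' @param nodes Gauss-Legendre nodes per cumulative-hazard integral.
#' @param control Passed to [stats::optim()]; sensible defaults applied.
#' @return An object of class `eh_fit` with elements `coef`, `vcov`,
#'   `loglik`, `AIC`, `BIC`, `n`, `n_events`, `p`, `frame`, `spec`,
#'   `convergence`.
#' @export
fit_excess_hazard <- function(data, spec, table = NULL, nodes = 20, control = list()) {
  data <- tibble::as_tibble(data)
  eh_check_data(data, spec, need_lifetable_keys = !is.null(table))
  if (sum(data$status) == 0) {
    stop("cannot fit an excess hazard model with zero events", call. = FALSE)
  }
  frame <- eh_frame(spec, data)
  parts <- eh_likelihood_parts(frame, data, table, nodes)

  # full-rank check over event-time and quadrature rows
  qr_all <- qr(rbind(parts$Ze, parts$Zq))
  if (qr_all$rank < parts$p) {
    keep <- qr_all$pivot[seq_len(qr_all$rank)]
    bad <- colnames(parts$Ze)[setdiff(seq_len(parts$p), keep)]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  # start at the null exponential rate for the intercept, zeros elsewhere
  theta0 <- rep(0, parts$p)
  theta0[1] <- log(sum(parts$delta) / sum(parts$t))
  ctrl <- utils::modifyList(list(maxit = 1000, reltol = 1e-12), control)
  negll <- function(th) {
    v <- eh_ll(th, parts)
    if (!is.finite(v)) 1e10 else -v
  }
  opt <- stats::optim(theta0, fn = negll,
                      gr = function(th) -eh_ll_grad(th, parts),
                      method = "BFGS", control = ctrl)
  if (opt$convergence != 0) {
    stop("excess hazard fit did not converge (optim code ", opt$convergence,
         "): ", paste(opt$message, collapse = " "), call. = FALSE)
  }
  # Newton polishing: BFGS stops on relative function change; a few Newton
  # steps with the analytic Hessian push the gradient to machine precision
  theta <- opt$par
  for (it in seq_len(8)) {
    g <- eh_ll_grad(theta, parts)
    if (sqrt(sum(g^2)) < 1e-10) break
    H <- eh_ll_hessian(theta, parts)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- theta - step
    if (!is.finite(eh_ll(cand, parts)) || eh_ll(cand, parts) < eh_ll(theta, parts) - 1e-8) break
    theta <- cand
  }
  opt$par <- theta
  opt$value <- -eh_ll(theta, parts)
  grad <- eh_ll_grad(opt$par, parts)
  H <- eh_ll_hessian(opt$par, parts)
  vcov <- tryCatch(solve(-H), error = function(e) {
    stop("observed information is singular at the optimum", call. = FALSE)
  })
  vcov <- (vcov + t(vcov)) / 2
  names(opt$par) <- colnames(parts$Ze)
  dimnames(vcov) <- list(names(opt$par), names(opt$par))

  ll <- -opt$value
  d <- sum(parts$delta)
  p <- parts$p
  structure(list(spec = frame$spec, frame = frame,
                 coef = opt$par, vcov = vcov,
                 loglik = ll, n = nrow(data), n_events = d, p = p,
                 AIC = -2 * ll + 2 * p, BIC = -2 * ll + p * log(d),
                 nodes = nodes,
                 convergence = list(code = opt$convergence,
                                    iterations = opt$counts,
                                    grad_norm = sqrt(sum(grad^2)))),
            class = "eh_fit")
}

#' @export
print.eh_fit <- function(x, ...) {
  cat("Excess hazard model:", format(x$spec), "\n")
  cat(sprintf("  n = %d, events = %d, p = %d\n", x$n, x$n_events, x$p))
  cat(sprintf("  logLik = %.3f, AIC = %.3f, BIC = %.3f\n", x$loglik, x$AIC, x$BIC))
  invisible(x)
}

#' @export
logLik.eh_fit <- function(object, ...) {
  structure(object$loglik, df = object$p, nobs = object$n, class = "logLik")
}

#' @export
coef.eh_fit <- function(object, ...) object$coef

#' @export
vcov.eh_fit <- function(object, ...) object$vcov

#' @importFrom stats coef vcov logLik predict
NULL

#' Tidy an excess hazard fit
#'
#' @param x An `eh_fit`.
#' @param conf.level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return A tibble with one row per model parameter: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.eh_fit <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coef / se
  q <- stats::qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                 std.error = unname(se), statistic = unname(z),
                 p.value = unname(2 * stats::pnorm(-abs(z))),
                 conf.low = unname(x$coef - q * se),
                 conf.high = unname(x$coef + q * se))
}

#' One-row model summary
#'
#' @param x An `eh_fit`.
#' @param ... Unused.
#' @return A tibble with `logLik`, `AIC`, `BIC`, `p`, `n`, `n_events`.
#' @export
glance.eh_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$AIC, BIC = x$BIC,
                 p = x$p, n = x$n, n_events = x$n_events)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

## ---- prediction ----

# per-subject hazard, cumulative hazard and delta-method variances on a grid
# of times; returns n x T matrices
eh_predict_quantities <- function(fit, newdata, times, se = TRUE) {
  newdata <- tibble::as_tibble(newdata)
  n <- nrow(newdata)
  if (any(times <= 0)) stop("prediction times must be positive", call. = FALSE)
  blocks <- eh_covariate_blocks(fit$frame, newdata)
  Tn <- length(times)
  haz <- cum <- var_haz <- var_cum <- matrix(NA_real_, n, Tn)
  for (j in seq_len(Tn)) {
    tj <- rep(times[j], n)
    Z <- eh_design(fit$frame, blocks, seq_len(n), tj)
    lam <- exp(drop(Z %*% fit$coef))
    haz[, j] <- lam
    q <- eh_quad_design(fit$frame, blocks, tj, fit$nodes)
    lamq <- exp(drop(q$Z %*% fit$coef))
    cum[, j] <- as.numeric(rowsum(lamq * q$w, q$idx, reorder = TRUE))
    if (se) {
      # var(lambda) = lambda^2 z' V z ; var(Lambda) = g' V g, g = int lam z du
      var_haz[, j] <- lam^2 * rowSums((Z %*% fit$vcov) * Z)
      G <- rowsum((lamq * q$w) * q$Z, q$idx, reorder = TRUE)
      var_cum[, j] <- rowSums((G %*% fit$vcov) * G)
    }
  }
  list(hazard = haz, cum_hazard = cum,
       var_hazard = if (se) var_haz else NULL,
       var_cum_hazard = if (se) var_cum else NULL,
       times = times)
}

#' Predict net survival from a fitted excess hazard model
#'
#' Individual net survival is \eqn{S_{E,i}(t) = \exp\{-\Lambda_{E,i}(t)\}};
#' the cohort curve is the mean of the individual curves,
#' \eqn{S_E(t) = N^{-1}\sum_i S_{E,i}(t)}. Variances are delta-method
#' transforms of the parameter covariance.
#'
#' @param fit An [fit_excess_hazard()] result.
#' @param newdata Patient data frame.
#' @param times Positive prediction times (years).
#' @param type `"cohort"` for the cohort mean curve, `"individual"` for
#'   per-subject curves.
#' @param se Logical; compute delta-method variances.
#' @return A tibble. For `type = "cohort"`: columns `time`, `estimate`,
#'   `variance`, `provenance`; class `ns_curve`. For `type = "individual"`:
#'   columns `.row`, `time`, `hazard`, `cum_hazard`, `survival`,
#'   `var_hazard`, `var_cum_hazard`.
#' @export
predict_net_survival <- function(fit, newdata, times,
                                 type = c("cohort", "individual"), se = TRUE) {
  stopifnot(inherits(fit, "eh_fit"))
  type <- match.arg(type)
  pq <- eh_predict_quantities(fit, newdata, times, se = se)
  surv <- exp(-pq$cum_hazard)
  if (type == "individual") {
    n <- nrow(surv)
    out <- tibble::tibble(
      .row = rep(seq_len(n), times = length(times)),
      time = rep(times, each = n),
      hazard = as.vector(pq$hazard),
      cum_hazard = as.vector(pq$cum_hazard),
      survival = as.vector(surv))
    if (se) {
      out$var_hazard <- as.vector(pq$var_hazard)
      out$var_cum_hazard <- as.vector(pq$var_cum_hazard)
    }
    return(out)
  }
  est <- colMeans(surv)
  vr <- if (se) {
    # delta method through the cohort mean: grad = -(1/N) sum_i S_i dLambda_i
    # approximate with per-subject var(Lambda) and perfect correlation bound
    colMeans(surv^2 * pq$var_cum_hazard)
  } else NA_real_
  new_ns_curve(times, est, vr, provenance = "model")
}

# shared light-weight curve container (see pohar_perme.R for the estimator)
new_ns_curve <- function(time, estimate, variance = NA_real_,
                         provenance = "model", extra = NULL) {
  out <- tibble::tibble(time = time, estimate = estimate,
                        variance = rep_len(variance, length(time)))
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  out$provenance <- provenance
  class(out) <- c("ns_curve", class(out))
  out
}
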