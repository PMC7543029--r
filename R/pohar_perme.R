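#' Pohar-Perme non-parametric net survival
#'
#' Consistent non-parametric estimation of net survival. Each patient's
#' contribution to the event, at-risk and expected-mortality counting
#' processes is weighted by the inverse of their expected (population)
#' survival probability \eqn{1/S_{P,i}(t)}, correcting the informative
#' removal of patients by other-cause death. The estimator is
#' \eqn{\hat S_E(t) = \exp\{-\hat\Lambda_E(t)\}} with
#' \deqn{\hat\Lambda_E(t) = \int_0^t
#'   \frac{\sum_i w_i(u)\,dN_i(u) - \sum_i w_i(u) Y_i(u) \lambda_{P,i}(u)\,du}
#'        {\sum_i w_i(u) Y_i(u)}}
#' The expected-mortality term is accumulated exactly over the
#' piecewise-constant life-table cells:
#' \eqn{\int_a^b w_i \lambda_{P,i}\,du = 1/S_{P,i}(b) - 1/S_{P,i}(a)}.
#'
#' @name pohar_perme
NULL

# per-patient expected-survival paths; returns a list of lp_path objects
pp_lp_paths <- function(data, table, tmax) {
  lapply(seq_len(nrow(data)), function(i) {
    lp_path(table, data$age[i], data$year[i], data$sex[i], lt_stratum(data)[i],
            tmax = max(tmax, data$time[i]) + 1e-9)
  })
}

# core weighted estimator on (entry, exit, status) with weights measured on
# the follow-up clock; `paths` may be NULL for lambda_P = 0. Event times are
# processed in blocks so each patient's weight path is evaluated by one
# vectorised call per block.
pp_core <- function(entry, exit, status, paths, time_grid, block = 256L) {
  stopifnot(length(entry) == length(exit))
  n <- length(exit)
  grid_max <- max(time_grid)
  ev_times <- sort(unique(exit[status == 1]))
  ev_times <- ev_times[ev_times <= grid_max]
  E <- length(ev_times)

  # weight of patient i at time t: 1 / S_P,i(t) = exp(Lambda_P,i(t))
  wmat <- function(ids, tt) {
    if (is.null(paths)) {
      matrix(1, nrow = length(ids), ncol = length(tt))
    } else {
      m <- vapply(ids, function(i) exp(lp_path_cum(paths[[i]], tt)),
                  numeric(length(tt)))
      if (!is.matrix(m)) m <- matrix(m, nrow = length(tt))
      t(m)
    }
  }
  # cumulative weighted expected deaths of patient i by time t:
  # exp(Lambda_P(t*)) with t* clamped to the patient's at-risk interval
  cmat <- function(ids, tt) {
    if (is.null(paths)) {
      matrix(0, nrow = length(ids), ncol = length(tt))
    } else {
      m <- vapply(ids, function(i) {
        tc <- pmin(pmax(tt, entry[i]), exit[i])
        exp(lp_path_cum(paths[[i]], tc))
      }, numeric(length(tt)))
      if (!is.matrix(m)) m <- matrix(m, nrow = length(tt))
      t(m)
    }
  }

  dLam <- dV <- n_risk <- n_event <- numeric(E)
  truncated <- FALSE
  prev <- 0
  b0 <- 1
  while (b0 <= E) {
    b1 <- min(b0 + block - 1L, E)
    tb <- ev_times[b0:b1]
    cand <- which(entry < tb[length(tb)] & exit > prev)
    if (length(cand) == 0) { truncated <- TRUE; break }
    W <- wmat(cand, tb)
    Cl <- cmat(cand, tb)
    Cp <- cmat(cand, prev)[, 1]
    R <- outer(entry[cand], tb, `<`) & outer(exit[cand], tb, `>=`)
    denom <- colSums(W * R)
    ED <- colSums(Cl - cbind(Cp, Cl[, -ncol(Cl), drop = FALSE]))
    for (j in seq_along(tb)) {
      if (denom[j] <= 0) { truncated <- TRUE; break }
      dying <- which(exit[cand] == tb[j] & status[cand] == 1)
      wd <- W[dying, j]
      k <- b0 + j - 1L
      dLam[k] <- (sum(wd) - ED[j]) / denom[j]
      dV[k] <- sum(wd^2) / denom[j]^2
      n_risk[k] <- sum(R[, j])
      n_event[k] <- length(dying)
    }
    if (truncated) break
    prev <- tb[length(tb)]
    b0 <- b1 + 1L
  }
  if (truncated) {
    E <- sum(n_risk > 0)
    ev_times <- ev_times[seq_len(E)]
    dLam <- dLam[seq_len(E)]; dV <- dV[seq_len(E)]
    n_risk <- n_risk[seq_len(E)]; n_event <- n_event[seq_len(E)]
  }
  steps <- tibble::tibble(time = ev_times, cum_hazard = cumsum(dLam),
                          var_cum_hazard = cumsum(dV),
                          n_risk = n_risk, n_event = n_event)

  # grid evaluation: step value at the last event <= tg, plus the
  # expected-death correction accrued continuously on (last event, tg]
  eval_at <- function(tg) {
    k <- if (nrow(steps) == 0) 0L else findInterval(tg, steps$time)
    base_L <- if (k > 0) steps$cum_hazard[k] else 0
    base_V <- if (k > 0) steps$var_cum_hazard[k] else 0
    last <- if (k > 0) steps$time[k] else 0
    extra <- 0
    if (!is.null(paths) && tg > last) {
      contrib <- which(entry < tg & exit > last)
      if (length(contrib) > 0) {
        at_risk <- which(entry < tg & exit >= tg)
        denom <- if (length(at_risk) > 0) sum(wmat(at_risk, tg)) else 0
        if (denom > 0) {
          extra <- sum(cmat(contrib, tg)[, 1] - cmat(contrib, last)[, 1]) / denom
        }
      }
    }
    c(base_L - extra, base_V)
  }
  vals <- vapply(time_grid, eval_at, numeric(2))
  list(cum_hazard = vals[1, ], var_cum_hazard = vals[2, ],
       steps = steps, truncated = truncated)
}

#' Cohort Pohar-Perme estimator
#'
#' @param data Patient data frame with `time` (years of follow-up), `status`
#'   (1 = died, 0 = censored) and, when `table` is supplied, the life-table
#'   keys `age`, `year`, `sex` and optionally `stratum`.
#' @param table A [life_table()], or `NULL` for \eqn{\lambda_P \equiv 0}
#'   (the estimator then reduces to `exp(-`Nelson-Aalen`)`).
#' @param time_grid Times (years) at which to report the curve.
#' @return An `ns_curve` tibble: `time`, `estimate`, `variance`,
#'   `provenance = "pp-cohort"`, plus `n_risk`/`n_event` step counts as the
#'   `steps` attribute. The variance is a Poisson-type variance of the
#'   weighted increments, delta-method transformed to the survival scale.
#' @export
pp_cohort <- function(data, table = NULL, time_grid) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) stop("no patients", call. = FALSE)
  if (any(time_grid < 0)) stop("time_grid must be non-negative", call. = FALSE)
  time <- pmax(data$time, EH_MIN_TIME)
  paths <- if (is.null(table)) NULL else pp_lp_paths(data, table, max(time_grid))
  res <- pp_core(entry = rep(0, nrow(data)), exit = time, status = data$status,
                 paths = paths, time_grid = time_grid)
  est <- exp(-res$cum_hazard)
  out <- new_ns_curve(time_grid, est, est^2 * res$var_cum_hazard,
                      provenance = "pp-cohort")
  attr(out, "steps") <- res$steps
  attr(out, "truncated") <- res$truncated
  out
}

#' Period-approach Pohar-Perme estimator
#'
#' Restricts each patient's contribution to the person-time whose calendar
#' date falls inside `window`: left truncation at window entry, censoring at
#' window exit. Patients whose only-year diagnosis dates are integers are
#' placed at mid-year.
#'
#' @inheritParams pp_cohort
#' @param window Calendar window `c(start, end)` (decimal years, half-open
#'   `[start, end)`), e.g. `c(2010, 2011)` for the single calendar year 2010.
#' @return An `ns_curve` tibble with `provenance = "pp-period"`.
#' @export
pp_period <- function(data, table = NULL, window, time_grid) {
  data <- tibble::as_tibble(data)
  stopifnot(length(window) == 2, window[2] > window[1])
  diag_date <- ifelse(data$year == floor(data$year), data$year + 0.5, data$year)
  time <- pmax(data$time, EH_MIN_TIME)
  entry <- pmax(0, window[1] - diag_date)
  exit_cal <- pmin(time, window[2] - diag_date)
  keep <- exit_cal > entry & exit_cal > 0
  if (!any(keep)) stop("no person-time falls inside the period window", call. = FALSE)
  status <- ifelse(time <= exit_cal, data$status, 0)
  sub <- data[keep, , drop = FALSE]
  paths <- if (is.null(table)) NULL else pp_lp_paths(sub, table, max(time_grid))
  res <- pp_core(entry = entry[keep], exit = pmin(time, exit_cal)[keep],
                 status = status[keep], paths = paths, time_grid = time_grid)
  est <- exp(-res$cum_hazard)
  out <- new_ns_curve(time_grid, est, est^2 * res$var_cum_hazard,
                      provenance = "pp-period")
  attr(out, "steps") <- res$steps
  attr(out, "truncated") <- res$truncated
  out
}

#' Plot net survival curves
#'
#' @param object An `ns_curve` tibble (or several bound by rows with
#'   distinct `provenance` values).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ns_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$estimate,
                                       colour = .data$provenance)) +
    ggplot2::geom_step(data = ~ dplyr::filter(.x, grepl("^pp", .data$provenance))) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, !grepl("^pp", .data$provenance))) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years since diagnosis", y = "Net survival",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
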