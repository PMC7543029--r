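#' Prediction accuracy: integrated square difference and RMISD
#'
#' Predictions are compared with a reference net survival curve by the
#' integrated square difference over a horizon,
#' \eqn{ISD = \int_0^H (\hat S(u) - S(u))^2 du}, approximated by 20-node
#' Gauss-Legendre quadrature, and summarised across patient groups by the
#' root mean integrated square difference
#' \eqn{RMISD = \sqrt{G^{-1} \sum_g ISD_g}}.
#'
#' @name evaluation
NULL

# coerce a curve argument to an evaluator function of time.
# - functions are used as-is (smooth model curves, closed-form truth)
# - ns_curve/step tibbles are evaluated by right-continuous step
#   interpolation from S(0) = 1, for non-parametric estimates
as_survfun <- function(curve, horizon = NULL) {
  if (is.function(curve)) return(curve)
  if (is.data.frame(curve)) {
    if (!all(c("time", "estimate") %in% names(curve))) {
      stop("curve data frames need 'time' and 'estimate' columns", call. = FALSE)
    }
    if (!is.null(horizon) && max(curve$time) < horizon) {
      stop(sprintf(
        "reference curve ends at t = %.4g, before the %.4g-year horizon",
        max(curve$time), horizon), call. = FALSE)
    }
    ord <- order(curve$time)
    tt <- curve$time[ord]; ss <- curve$estimate[ord]
    f <- stats::stepfun(tt, c(1, ss), right = FALSE)
    return(function(u) f(u))
  }
  stop("curves must be functions or data frames", call. = FALSE)
}

#' Integrated square difference between two net survival curves
#'
#' @param predicted,reference Either a function of time returning survival,
#'   or a curve data frame with `time` and `estimate` columns (evaluated as a
#'   right-continuous step function, the convention for non-parametric
#'   estimates).
#' @param horizon Upper integration limit in years (lower limit 0).
#' @param nodes Gauss-Legendre node count (default 20).
#' @return The scalar ISD, `>= 0`.
#' @export
isd <- function(predicted, reference, horizon, nodes = 20) {
  stopifnot(horizon > 0)
  fp <- as_survfun(predicted, horizon)
  fr <- as_survfun(reference, horizon)
  rule <- gl_rule(nodes)
  u <- (rule$x + 1) * horizon / 2
  w <- rule$w * horizon / 2
  sum(w * (fp(u) - fr(u))^2)
}

#' Root mean integrated square difference
#'
#' @param group_isds Numeric vector of per-group ISD values.
#' @return `sqrt(mean(group_isds))`.
#' @export
rmisd <- function(group_isds) {
  stopifnot(length(group_isds) >= 1)
  if (any(group_isds < 0)) stop("ISD values must be non-negative", call. = FALSE)
  sqrt(mean(group_isds))
}

#' Default age bands for grouped evaluation
#'
#' @return A function cutting ages into the bands 15-44, 45-54, 55-64,
#'   65-74, 75-99.
#' @export
age_bands <- function() {
  breaks <- c(15, 45, 55, 65, 75, 100)
  labels <- c("15-44", "45-54", "55-64", "65-74", "75-99")
  function(age) cut(age, breaks = breaks, labels = labels, right = FALSE)
}

#' Grouped RMISD evaluation at one or more horizons
#'
#' @param predicted Named list of predicted curves (functions or curve data
#'   frames), one per group.
#' @param reference Named list of reference curves covering at least the
#'   groups in `predicted`.
#' @param horizons Numeric horizons in years (default `c(1, 5)`).
#' @param nodes Gauss-Legendre nodes per integral.
#' @return A tibble with columns `horizon`, `group`, `isd` plus an `rmisd`
#'   summary row per horizon stored in the `rmisd` attribute (tibble
#'   `horizon`, `rmisd`, `n_groups`).
#' @export
evaluate_at_horizons <- function(predicted, reference, horizons = c(1, 5),
                                 nodes = 20) {
  stopifnot(length(predicted) >= 1)
  if (is.null(names(predicted)) || is.null(names(reference))) {
    stop("predicted and reference must be named lists of group curves", call. = FALSE)
  }
  orphans <- setdiff(names(predicted), names(reference))
  if (length(orphans) > 0) {
    stop("groups missing from the reference set: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  summaries <- list()
  for (h in horizons) {
    vals <- vapply(names(predicted), function(g) {
      isd(predicted[[g]], reference[[g]], horizon = h, nodes = nodes)
    }, 0)
    rows[[length(rows) + 1]] <- tibble::tibble(
      horizon = h, group = names(predicted), isd = unname(vals))
    summaries[[length(summaries) + 1]] <- tibble::tibble(
      horizon = h, rmisd = rmisd(vals), n_groups = length(vals))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "rmisd") <- dplyr::bind_rows(summaries)
  class(out) <- c("evaluation_report", class(out))
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(attr(x, "rmisd"))
  NextMethod()
}
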