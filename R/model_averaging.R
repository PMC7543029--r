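#' Multi-model inference: criterion weights and model-averaged predictions
#'
#' The retained models are combined by their information-criterion weights.
#' With \eqn{\Delta_m = XIC_m - XIC_{min}}, the likelihood of model m given
#' the data is \eqn{\exp(-\Delta_m/2)}, and the weights are the normalised
#' model likelihoods. Averaging acts on predicted quantities — the excess
#' hazard and the cumulative excess hazard — never on parameters.
#'
#' @name model_averaging
NULL

#' Criterion (Akaike/Schwarz) weights of a model set
#'
#' \eqn{w_m = \exp(-\Delta_m/2) / \sum_n \exp(-\Delta_n/2)}.
#'
#' @param set A `model_set` (from [select_models()] or [model_set()]).
#' @return Numeric vector of weights, summing to 1, best model first.
#' @export
xic_weights <- function(set) {
  stopifnot(inherits(set, "model_set"))
  w <- exp(-set$delta / 2)
  w / sum(w)
}

#' Evidence ratio between two retained models
#'
#' \eqn{e_{m,n} = w_m / w_n = \exp\{(\Delta_n - \Delta_m)/2\}}: the weight of
#' evidence for model `m` over model `n`. For the minimum-criterion model
#' against one whose criterion is larger by 2, 4 or 8 the ratio is about
#' 2.7, 7.4 and 54.6.
#'
#' @param set A `model_set`.
#' @param m,n Indices of the two models in the set (best model is 1).
#' @return The scalar evidence ratio.
#' @export
evidence_ratio <- function(set, m = 1, n = 2) {
  stopifnot(inherits(set, "model_set"))
  k <- length(set$models)
  if (m < 1 || m > k || n < 1 || n > k) {
    stop("model indices must lie in 1..", k, call. = FALSE)
  }
  exp((set$delta[n] - set$delta[m]) / 2)
}

#' Unconditional variance of a model-averaged estimate
#'
#' Combines within-model variance and between-model spread:
#' \deqn{\widehat{var} = \Big[\sum_m w_m
#'   \sqrt{\widehat{var}(\hat\theta_m) + (\hat\theta_m - \hat\theta_{MA})^2}
#'   \Big]^2}
#' It assumes perfect pairwise correlation of the model deviations, making
#' the estimate conservative.
#'
#' @param weights Model weights (summing to 1).
#' @param estimates Per-model estimates of the same quantity.
#' @param variances Per-model (within-model) variances, all `>= 0`.
#' @param averaged Optional model-averaged estimate; defaults to
#'   `sum(weights * estimates)`.
#' @return The scalar unconditional variance.
#' @export
unconditional_variance <- function(weights, estimates, variances, averaged = NULL) {
  stopifnot(length(weights) == length(estimates),
            length(weights) == length(variances))
  if (any(variances < 0)) stop("variances must be non-negative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1", call. = FALSE)
  if (is.null(averaged)) averaged <- sum(weights * estimates)
  sum(weights * sqrt(variances + (estimates - averaged)^2))^2
}

#' Model-averaged excess hazard, cumulative hazard and net survival
#'
#' For each subject and prediction time: the averaged excess hazard
#' \eqn{\hat\lambda_{i,MA}(t) = \sum_m w_m \hat\lambda_{i,m}(t)} and averaged
#' cumulative hazard \eqn{\hat\Lambda_{i,MA}(t) = \sum_m w_m
#' \hat\Lambda_{i,m}(t)}; individual net survival
#' \eqn{\hat S_{i,MA}(t) = \exp\{-\hat\Lambda_{i,MA}(t)\}}; cohort net
#' survival as the mean of the individual survival curves. The hazard-scale
#' unconditional variance combines within-model delta-method variances with
#' the between-model spread.
#'
#' @param set A `model_set` whose models can all predict for `newdata`.
#' @param newdata Patient data frame.
#' @param times Positive prediction times (years); monthly spacing up to the
#'   horizon of interest is the conventional grid.
#' @param se Logical; compute the unconditional variance of the averaged
#'   hazard and the averaged delta-method variance of the cumulative hazard.
#' @return An object of class `averaged_prediction`: list with `individual`
#'   (tibble: `.row`, `time`, `hazard`, `cum_hazard`, `survival`,
#'   `var_hazard`), `cohort` (an `ns_curve` tibble with
#'   `provenance = "model-averaged"`), `weights` and `times`.
#' @export
average_predictions <- function(set, newdata, times, se = TRUE) {
  stopifnot(inherits(set, "model_set"))
  if (any(times <= 0)) stop("prediction times must be positive", call. = FALSE)
  newdata <- tibble::as_tibble(newdata)
  w <- xic_weights(set)
  M <- length(set$models)
  n <- nrow(newdata); Tn <- length(times)

  preds <- lapply(set$models, eh_predict_quantities,
                  newdata = newdata, times = times, se = se)
  acc <- function(field) {
    out <- matrix(0, n, Tn)
    for (m in seq_len(M)) out <- out + w[m] * preds[[m]][[field]]
    out
  }
  haz_ma <- acc("hazard")
  cum_ma <- acc("cum_hazard")
  surv_ma <- exp(-cum_ma)

  var_ma <- NULL
  if (se) {
    # unconditional variance on the hazard scale, elementwise over (i, t)
    inner <- matrix(0, n, Tn)
    for (m in seq_len(M)) {
      inner <- inner + w[m] * sqrt(pmax(preds[[m]]$var_hazard, 0) +
                                     (preds[[m]]$hazard - haz_ma)^2)
    }
    var_ma <- inner^2
  }

  individual <- tibble::tibble(
    .row = rep(seq_len(n), times = Tn),
    time = rep(times, each = n),
    hazard = as.vector(haz_ma),
    cum_hazard = as.vector(cum_ma),
    survival = as.vector(surv_ma))
  if (se) individual$var_hazard <- as.vector(var_ma)

  cohort_est <- colMeans(surv_ma)
  cohort_var <- if (se) {
    vc <- matrix(0, n, Tn)
    for (m in seq_len(M)) vc <- vc + w[m] * preds[[m]]$var_cum_hazard
    colMeans(surv_ma^2 * vc)
  } else NA_real_
  cohort <- new_ns_curve(times, cohort_est, cohort_var,
                         provenance = "model-averaged")

  structure(list(individual = individual, cohort = cohort,
                 weights = w, times = times),
            class = "averaged_prediction")
}

#' @export
print.averaged_prediction <- function(x, ...) {
  cat(sprintf("<averaged_prediction> %d model(s), %d subject(s), %d time(s)\n",
              length(x$weights), max(x$individual$.row), length(x$times)))
  invisible(x)
}

#' @export
autoplot.averaged_prediction <- function(object, ...) {
  autoplot(object$cohort, ...)
}
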