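#' Study designs: predict the last diagnosis year, project the next
#'
#' The experimental design mirrors registry practice: follow-up is
#' artificially censored at a cut-off date; models are selected on cohorts
#' diagnosed within a calendar window ending at the cut-off; net survival is
#' predicted for patients diagnosed in the last window year (who contributed
#' only their first months of follow-up) and projected for patients diagnosed
#' the year after (who contributed nothing); predictions are then evaluated
#' against a reference — the known truth for synthetic cohorts, or a
#' Pohar-Perme estimate computed from the full (post-cut-off) follow-up.
#'
#' @param windows List of diagnosis-year windows `c(first, last)`; every
#'   window must end at `prediction_year`.
#' @param censor_date Decimal calendar date ending follow-up for fitting and
#'   selection (e.g. `2011` for 31 December 2010).
#' @param prediction_year Last diagnosis year inside each window.
#' @param projection_year Out-of-sample diagnosis year (`prediction_year + 1`
#'   by convention).
#' @param criterion `"AIC"` or `"BIC"`.
#' @param algorithm Selection algorithm (see [select_models()]).
#' @param horizons Evaluation horizons in years.
#' @return A `study_design` object.
#' @export
study_design <- function(windows = list(c(2005, 2010), c(1990, 2010)),
                         censor_date = 2011,
                         prediction_year = 2010, projection_year = 2011,
                         criterion = c("AIC", "BIC"),
                         algorithm = c("adapted", "interaction-first"),
                         horizons = c(1, 5)) {
  criterion <- match.arg(criterion)
  algorithm <- match.arg(algorithm)
  for (w in windows) {
    stopifnot(length(w) == 2, w[1] <= w[2])
    if (prediction_year < w[1] || prediction_year > w[2]) {
      stop("prediction year must lie inside every window", call. = FALSE)
    }
    if (projection_year >= w[1] && projection_year <= w[2]) {
      stop("projection year must lie outside every window", call. = FALSE)
    }
    if (censor_date < w[2]) {
      stop("the censoring date must end the windows", call. = FALSE)
    }
  }
  structure(list(windows = windows, censor_date = censor_date,
                 prediction_year = prediction_year,
                 projection_year = projection_year,
                 criterion = criterion, algorithm = algorithm,
                 horizons = horizons),
            class = "study_design")
}

#' Artificially censor follow-up at a calendar date
#'
#' Truncates each record's follow-up at `censor_date` minus its diagnosis
#' date, setting `status = 0` for records still alive at the cut-off.
#'
#' @param data Patient data with decimal `year` (diagnosis date), `time`,
#'   `status`.
#' @param censor_date Decimal calendar date.
#' @return The censored tibble (records diagnosed after the cut-off are
#'   dropped).
#' @export
artificially_censor <- function(data, censor_date) {
  data <- tibble::as_tibble(data)
  avail <- censor_date - data$year
  out <- data[avail > 0, , drop = FALSE]
  avail <- avail[avail > 0]
  cut <- out$time > avail
  out$status[cut] <- 0L
  out$time[cut] <- avail[cut]
  out
}

# hard leakage guard: nothing entering fit/selection may carry follow-up
# beyond the cut-off
assert_no_leakage <- function(data, censor_date, what = "fit") {
  beyond <- data$year + data$time > censor_date + 1e-9
  if (any(beyond)) {
    stop(sprintf(
      "%d record(s) with follow-up beyond the censoring date %.3f entered %s: design leakage",
      sum(beyond), censor_date, what), call. = FALSE)
  }
  invisible(TRUE)
}

# group labels: age band x deprivation quintile (drops empty groups)
study_groups <- function(data, bands = age_bands()) {
  paste0(as.character(bands(data$age)), "|dep", data$dep)
}

# model-averaged cohort survival of a set of patients, as a function of time
ma_cohort_fun <- function(set, members) {
  function(u) {
    u <- pmax(u, EH_MIN_TIME)
    average_predictions(set, members, times = u, se = FALSE)$cohort$estimate
  }
}

model_cohort_fun <- function(fit, members) {
  function(u) {
    u <- pmax(u, EH_MIN_TIME)
    pq <- eh_predict_quantities(fit, members, times = u, se = FALSE)
    colMeans(exp(-pq$cum_hazard))
  }
}

truth_cohort_fun <- function(scenario, members) {
  function(u) {
    vapply(u, function(tt) mean(true_net_survival(scenario, members, tt)), 0)
  }
}

#' Run the full prediction/projection study
#'
#' Per window: artificially censors follow-up, selects the model set,
#' model-averages predictions for the prediction-year and projection-year
#' cohorts, fits the pre-selected simple (all linear, all proportional)
#' comparison model, computes the period-approach Pohar-Perme arm, and
#' evaluates every arm's grouped net survival curves against the reference by
#' RMISD at the design horizons.
#'
#' @param data Full patient data (follow-up as actually observed, i.e.
#'   beyond the cut-off when available).
#' @param table A [life_table()] (or `NULL` for no background mortality).
#' @param design A [study_design()].
#' @param base_spec The simple all-linear proportional [eh_spec()]; also the
#'   root of the stepwise search.
#' @param scenario Optional [registry_scenario()]; when supplied the
#'   reference curves are the scenario's exact truth, otherwise Pohar-Perme
#'   estimates from the post-cut-off follow-up.
#' @param interactions,spline_df,max_branches Passed to [select_models()].
#' @param bands Age banding function for evaluation groups
#'   (default [age_bands()]).
#' @param period_window Calendar window of the period arm; default the single
#'   prediction year.
#' @return A `study_result`: per-window results (`model_set`, arm curves,
#'   `evaluation` tibbles for prediction and projection cohorts) and a run
#'   `manifest` (configuration, cohort sizes, retained-model counts,
#'   collected warnings).
#' @export
run_study <- function(data, table, design, base_spec, scenario = NULL,
                      interactions = "none", spline_df = 3, max_branches = 16,
                      bands = age_bands(),
                      period_window = c(design$prediction_year,
                                        design$prediction_year + 1)) {
  stopifnot(inherits(design, "study_design"))
  data <- tibble::as_tibble(data)
  warn_log <- character(0)
  results <- list()

  pred_cohort <- data[floor(data$year) == design$prediction_year, , drop = FALSE]
  proj_cohort <- data[floor(data$year) == design$projection_year, , drop = FALSE]
  if (nrow(pred_cohort) == 0) stop("no patients in the prediction year", call. = FALSE)

  horizon_max <- max(design$horizons)
  ref_fun <- function(members) {
    if (!is.null(scenario)) {
      truth_cohort_fun(scenario, members)
    } else {
      grid <- sort(unique(c((gl_rule(20)$x + 1) * horizon_max / 2,
                            design$horizons)))
      pp_cohort(members, table, time_grid = grid)
    }
  }

  evaluate_arm <- function(curve_fun_by_group, ref_by_group) {
    evaluate_at_horizons(curve_fun_by_group, ref_by_group,
                         horizons = design$horizons)
  }

  for (w in design$windows) {
    wname <- paste0(w[1], "-", w[2])
    fit_data <- data[floor(data$year) >= w[1] & floor(data$year) <= w[2], , drop = FALSE]
    fit_data <- artificially_censor(fit_data, design$censor_date)
    assert_no_leakage(fit_data, design$censor_date, what = paste0("window ", wname))
    if (any(floor(fit_data$year) == design$projection_year)) {
      stop("projection-year patients entered the fitting data: design leakage",
           call. = FALSE)
    }

    set <- withCallingHandlers(
      select_models(fit_data, base_spec, table,
                    criterion = design$criterion, algorithm = design$algorithm,
                    interactions = interactions, spline_df = spline_df,
                    max_branches = max_branches),
      warning = function(cnd) {
        warn_log <<- c(warn_log, conditionMessage(cnd))
        invokeRestart("muffleWarning")
      })
    simple_fit <- fit_excess_hazard(fit_data, base_spec, table)

    arms_for <- function(cohort) {
      groups <- split(cohort, study_groups(cohort, bands))
      groups <- groups[vapply(groups, nrow, 0L) > 0]
      ref <- lapply(groups, ref_fun)
      list(
        groups = names(groups),
        ma = evaluate_arm(lapply(groups, function(g) ma_cohort_fun(set, g)), ref),
        simple = evaluate_arm(lapply(groups, function(g) model_cohort_fun(simple_fit, g)), ref))
    }

    pred_eval <- arms_for(pred_cohort)
    proj_eval <- arms_for(proj_cohort)

    period_curve <- tryCatch(
      pp_period(fit_data, table, window = period_window,
                time_grid = sort(unique(c((gl_rule(20)$x + 1) * horizon_max / 2,
                                          design$horizons)))),
      error = function(e) {
        warn_log <<- c(warn_log, paste("period arm failed:", conditionMessage(e)))
        NULL
      })

    monthly <- seq(1 / 12, 5, by = 1 / 12)
    results[[wname]] <- list(
      window = w,
      model_set = set,
      averaged_prediction = average_predictions(set, pred_cohort, monthly, se = FALSE),
      averaged_projection = if (nrow(proj_cohort) > 0)
        average_predictions(set, proj_cohort, monthly, se = FALSE) else NULL,
      simple_fit = simple_fit,
      period_curve = period_curve,
      evaluation_prediction = pred_eval,
      evaluation_projection = proj_eval)
  }

  manifest <- list(
    design = unclass(design),
    base_spec = format(base_spec),
    n_total = nrow(data),
    n_prediction = nrow(pred_cohort),
    n_projection = nrow(proj_cohort),
    models_retained = vapply(results, function(r) length(r$model_set$models), 0L),
    warnings = warn_log,
    package_version = as.character(utils::packageVersion("netmma")))

  structure(list(windows = results, manifest = manifest),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  for (nm in names(x$windows)) {
    r <- x$windows[[nm]]
    rm_ma <- attr(r$evaluation_prediction$ma, "rmisd")
    cat(sprintf("  window %s: %d model(s); prediction RMISD (model-averaged): %s\n",
                nm, length(r$model_set$models),
                paste(sprintf("%.4f@%gy", rm_ma$rmisd, rm_ma$horizon),
                      collapse = ", ")))
  }
  invisible(x)
}

## ---- delimited text IO ----

#' Read patient records from delimited text
#'
#' Comma- or tab-delimited (autodetected) with a header. Standard columns:
#' `age`, `sex`, `dep`, `year`, `time`, `status` and optionally `stratum`,
#' `stage`, `emergency`, `screen`, `perfstatus`; `col_map` renames
#' nonstandard headers.
#'
#' @param path File path.
#' @param col_map Named character vector, standard name -> file column.
#' @param day_counts If `TRUE`, `time` is in days and is converted to years
#'   at 365.25 days/year.
#' @return A tibble of patient records.
#' @export
read_patients <- function(path, col_map = NULL, day_counts = FALSE) {
  if (!file.exists(path)) stop("patient file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      src <- col_map[[std]]
      if (!src %in% names(raw)) {
        stop(sprintf("mapped column '%s' (for '%s') not found", src, std),
             call. = FALSE)
      }
      names(raw)[names(raw) == src] <- std
    }
  }
  out <- tibble::as_tibble(raw)
  if (day_counts && "time" %in% names(out)) out$time <- out$time / 365.25
  out
}

#' Write a net survival curve to delimited text
#'
#' @param curve An `ns_curve` tibble.
#' @param path Output path (comma-delimited).
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
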