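#' Information-criterion model selection retaining all near-minimal models
#'
#' Stepwise search over functional forms of an excess hazard model. Starting
#' from the simplest model (every variable linear when continuous, every
#' effect proportional), more complex versions of each variable's effect are
#' tried one at a time: non-linearity (restricted cubic spline) and
#' time-dependency (a `log(t)` multiplier), then pairwise interactions. At
#' each comparison the two candidates' criterion values (AIC or BIC,
#' generically "XIC") are contrasted: if they differ by more than the
#' retention threshold (default 2) only the smaller is kept; if they are
#' within the threshold both are kept and expanded further. The result is the
#' set of models whose criterion lies within the threshold of the minimum —
#' models with comparable support from the data.
#'
#' @name model_selection
NULL

# one-step complexity moves for a single variable, respecting hierarchy
#' Enumerate one-step complexity upgrades for a variable
#'
#' Legal moves are: `linear -> spline(df)` for continuous variables,
#' `proportional -> time-dependent` for any effect, adding a pairwise
#' interaction between two main-effect variables, and making an existing
#' interaction time-dependent.
#'
#' @param spec An [eh_spec()].
#' @param variable A variable named in the spec's effects, or an interaction
#'   label `"a:b"`.
#' @param spline_df Spline degrees of freedom used for the non-linearity move.
#' @return A list of `eh_spec` objects (possibly empty).
#' @export
candidate_upgrades <- function(spec, variable, spline_df = 3) {
  vars <- vapply(spec$effects, `[[`, "", "variable")
  out <- list()
  if (grepl(":", variable, fixed = TRUE)) {
    pair <- sort(strsplit(variable, ":", fixed = TRUE)[[1]])
    ikeys <- vapply(spec$interactions,
                    function(i) paste(sort(c(i$var1, i$var2)), collapse = ":"), "")
    k <- match(paste(pair, collapse = ":"), ikeys)
    if (is.na(k)) {
      if (!all(pair %in% vars)) {
        stop("interaction ", variable, " needs both main effects in the spec",
             call. = FALSE)
      }
      s <- spec
      s$interactions <- c(s$interactions, list(eh_interaction(pair[1], pair[2])))
      out <- c(out, list(eh_spec(s$baseline_df, s$effects, s$interactions)))
    } else if (!spec$interactions[[k]]$tdep) {
      s <- spec
      s$interactions[[k]]$tdep <- TRUE
      out <- c(out, list(eh_spec(s$baseline_df, s$effects, s$interactions)))
    }
    return(out)
  }
  k <- match(variable, vars)
  if (is.na(k)) stop("variable '", variable, "' is not in the spec", call. = FALSE)
  e <- spec$effects[[k]]
  if (e$form == "linear") {
    s <- spec
    s$effects[[k]] <- eh_effect(e$variable, "spline", df = spline_df, tdep = e$tdep)
    out <- c(out, list(eh_spec(s$baseline_df, s$effects, s$interactions)))
  }
  if (!e$tdep) {
    s <- spec
    s$effects[[k]]$tdep <- TRUE
    out <- c(out, list(eh_spec(s$baseline_df, s$effects, s$interactions)))
  }
  out
}

# fit cache keyed by the canonical spec string
sel_fit_cached <- function(spec, data, table, cache_env, log) {
  key <- format(spec)
  if (!is.null(cache_env$fits[[key]])) return(cache_env$fits[[key]])
  fit <- tryCatch(fit_excess_hazard(data, spec, table),
                  error = function(e) e)
  cache_env$fits[[key]] <- fit
  fit
}

sel_xic <- function(fit, criterion) {
  if (inherits(fit, "error")) Inf else fit[[criterion]]
}

#' Select the set of near-minimal information-criterion models
#'
#' @param data Patient data frame (see [fit_excess_hazard()]).
#' @param base_spec The starting [eh_spec()]: all effects linear (when
#'   continuous) and proportional.
#' @param table A [life_table()] or `NULL`.
#' @param criterion `"AIC"` or `"BIC"`.
#' @param threshold Retention threshold on the criterion difference
#'   (default 2).
#' @param algorithm `"adapted"` scans variables in order of decreasing
#'   single-upgrade criterion improvement over the base model;
#'   `"interaction-first"` follows the Royston-Sauerbrei ordering (variables
#'   in the order given, main effects settled before interactions are
#'   scanned). Both scan interactions after main effects.
#' @param interactions Candidate interactions to scan: `"none"` (default),
#'   `"all"` (all pairs of main-effect variables), or a list of two-element
#'   character vectors.
#' @param spline_df Spline df used for non-linearity upgrades.
#' @param max_branches Cap on simultaneously open branches; the worst-XIC
#'   branch beyond the cap is pruned with a warning.
#' @return An object of class `model_set`: list with `models` (the retained
#'   `eh_fit`s, best first), `criterion`, `xic` (criterion values), `delta`,
#'   `weights` (normalised `exp(-delta/2)`), `threshold` and `log` (the
#'   comparison history as a tibble).
#' @export
select_models <- function(data, base_spec, table = NULL,
                          criterion = c("AIC", "BIC"), threshold = 2,
                          algorithm = c("adapted", "interaction-first"),
                          interactions = "none", spline_df = 3,
                          max_branches = 16) {
  criterion <- match.arg(criterion)
  algorithm <- match.arg(algorithm)
  data <- tibble::as_tibble(data)
  cache <- new.env(parent = emptyenv())
  cache$fits <- list()
  log <- list()
  note <- function(stage, a, b, xa, xb, kept) {
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = stage, current = a, candidate = b,
      xic_current = xa, xic_candidate = xb, kept = kept)
  }

  base_fit <- sel_fit_cached(base_spec, data, table, cache, log)
  if (inherits(base_fit, "error")) {
    stop("base model failed to fit: ", conditionMessage(base_fit), call. = FALSE)
  }

  vars <- vapply(base_spec$effects, `[[`, "", "variable")
  # variable schedule
  if (algorithm == "adapted") {
    improvement <- vapply(vars, function(v) {
      ups <- candidate_upgrades(base_spec, v, spline_df)
      if (length(ups) == 0) return(-Inf)
      xics <- vapply(ups, function(s)
        sel_xic(sel_fit_cached(s, data, table, cache, log), criterion), 0)
      sel_xic(base_fit, criterion) - min(xics)
    }, 0)
    schedule <- vars[order(-improvement)]
  } else {
    schedule <- vars
  }
  ia_schedule <- character(0)
  if (identical(interactions, "all")) {
    if (length(vars) >= 2) {
      cmb <- utils::combn(sort(vars), 2)
      ia_schedule <- apply(cmb, 2, paste, collapse = ":")
    }
  } else if (is.list(interactions)) {
    ia_schedule <- vapply(interactions, function(p) paste(sort(p), collapse = ":"), "")
  }
  full_schedule <- c(schedule, ia_schedule)

  # expand one branch through the schedule; branching at comparisons within
  # the threshold
  branches <- list(base_spec)
  for (item in full_schedule) {
    repeat {
      old_keys <- sort(vapply(branches, format, ""))
      new_branches <- list()
      for (spec in branches) {
        cur_fit <- sel_fit_cached(spec, data, table, cache, log)
        cur_xic <- sel_xic(cur_fit, criterion)
        ups <- tryCatch(candidate_upgrades(spec, item, spline_df),
                        error = function(e) list())
        advanced <- FALSE
        for (u in ups) {
          u_fit <- sel_fit_cached(u, data, table, cache, log)
          u_xic <- sel_xic(u_fit, criterion)
          if (inherits(u_fit, "error")) {
            warning("candidate '", format(u), "' failed to fit and was pruned: ",
                    conditionMessage(u_fit), call. = FALSE)
            note(item, format(spec), format(u), cur_xic, u_xic, "candidate-failed")
            next
          }
          if (u_xic < cur_xic - threshold) {
            # candidate clearly better: it replaces the current branch
            note(item, format(spec), format(u), cur_xic, u_xic, "candidate")
            new_branches <- c(new_branches, list(u))
            advanced <- TRUE
          } else if (abs(u_xic - cur_xic) <= threshold) {
            note(item, format(spec), format(u), cur_xic, u_xic, "both")
            new_branches <- c(new_branches, list(u))
          } else {
            note(item, format(spec), format(u), cur_xic, u_xic, "current")
          }
        }
        if (!advanced) new_branches <- c(new_branches, list(spec))
      }
      # deduplicate by canonical string
      keys <- vapply(new_branches, format, "")
      branches <- new_branches[!duplicated(keys)]
      if (length(branches) > max_branches) {
        xics <- vapply(branches, function(s)
          sel_xic(sel_fit_cached(s, data, table, cache, log), criterion), 0)
        ord <- order(xics, vapply(branches, format, ""))
        dropped <- branches[ord][-seq_len(max_branches)]
        for (dspec in dropped) {
          warning("branch cap reached; pruning branch ", format(dspec), call. = FALSE)
        }
        branches <- branches[ord][seq_len(max_branches)]
      }
      if (identical(sort(vapply(branches, format, "")), old_keys)) break
    }
  }

  # final set: frontier models within threshold of the minimum
  keys <- vapply(branches, format, "")
  fits <- lapply(branches, sel_fit_cached, data = data, table = table,
                 cache_env = cache, log = log)
  ok <- !vapply(fits, inherits, TRUE, "error")
  fits <- fits[ok]; keys <- keys[ok]
  xic <- vapply(fits, `[[`, 0, criterion)
  ord <- order(xic, keys)
  fits <- fits[ord]; xic <- xic[ord]
  keep <- (xic - xic[1]) <= threshold
  fits <- fits[keep]; xic <- xic[keep]
  delta <- xic - xic[1]
  w <- exp(-delta / 2); w <- w / sum(w)

  structure(list(models = fits, criterion = criterion, xic = xic,
                 delta = delta, weights = w, threshold = threshold,
                 algorithm = algorithm,
                 log = dplyr::bind_rows(log)),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("<model_set> %d model(s) retained by %s (threshold %.3g)\n",
              length(x$models), x$criterion, x$threshold))
  print(tidy(x))
  invisible(x)
}

#' Tidy a model set
#'
#' @param x A `model_set`.
#' @param ... Unused.
#' @return A tibble with one row per retained model: `model`, `xic`, `delta`,
#'   `weight`, `p`, `logLik`.
#' @export
tidy.model_set <- function(x, ...) {
  tibble::tibble(model = vapply(x$models, function(f) format(f$spec), ""),
                 xic = x$xic, delta = x$delta, weight = x$weights,
                 p = vapply(x$models, `[[`, 0L, "p"),
                 logLik = vapply(x$models, `[[`, 0, "loglik"))
}

#' Build a model set directly from fitted models
#'
#' Bypasses the stepwise search: useful for combining externally chosen fits
#' or for constructing sets with known criterion differences.
#'
#' @param fits A list of `eh_fit` objects (or any objects with the criterion
#'   field).
#' @param criterion `"AIC"` or `"BIC"`.
#' @param xic Optional numeric criterion values overriding the fits' own.
#' @return A `model_set`.
#' @export
model_set <- function(fits, criterion = c("AIC", "BIC"), xic = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(xic)) xic <- vapply(fits, `[[`, 0, criterion)
  stopifnot(length(xic) == length(fits), all(is.finite(xic)))
  ord <- order(xic)
  fits <- fits[ord]; xic <- xic[ord]
  delta <- xic - xic[1]
  w <- exp(-delta / 2); w <- w / sum(w)
  structure(list(models = fits, criterion = criterion, xic = xic,
                 delta = delta, weights = w, threshold = NA_real_,
                 algorithm = "manual", log = NULL),
            class = "model_set")
}
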