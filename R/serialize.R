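#' Serialize fitted models to structured text
#'
#' Fitted excess hazard models (parameters, knots, covariance, fit metrics
#' and the spec) round-trip through JSON so selection and averaging runs can
#' be resumed without refitting. Requires the jsonlite package.
#'
#' @name serialize
NULL

spec_to_list <- function(spec) {
  list(baseline_df = spec$baseline_df,
       effects = lapply(spec$effects, unclass),
       interactions = lapply(spec$interactions, unclass))
}

spec_from_list <- function(x) {
  eh_spec(x$baseline_df,
          effects = lapply(x$effects, function(e)
            eh_effect(e$variable, e$form, df = e$df, tdep = e$tdep)),
          interactions = lapply(x$interactions, function(i)
            eh_interaction(i$var1, i$var2, tdep = i$tdep)))
}

basis_to_list <- function(b) {
  if (is.null(b)) return(NULL)
  list(internal_knots = b$internal_knots, boundary_knots = b$boundary_knots,
       scale = b$scale)
}

basis_from_list <- function(x) {
  if (is.null(x) || length(x) == 0) return(NULL)
  new_spline_basis(x$internal_knots, x$boundary_knots, x$scale)
}

#' Write a fitted excess hazard model to JSON
#'
#' @param fit An `eh_fit`.
#' @param path Output path.
#' @export
write_eh_fit <- function(fit, path) {
  stopifnot(inherits(fit, "eh_fit"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the jsonlite package is required for model serialization", call. = FALSE)
  }
  obj <- list(
    spec = spec_to_list(fit$spec),
    baseline_basis = basis_to_list(fit$frame$baseline),
    terms = lapply(fit$frame$terms, function(tm) {
      list(effect = unclass(tm$effect), levels = tm$levels,
           center = tm$center, basis = basis_to_list(tm$basis))
    }),
    coef = as.list(stats::setNames(unname(fit$coef), names(fit$coef))),
    vcov = unname(as.matrix(fit$vcov)),
    loglik = fit$loglik, n = fit$n, n_events = fit$n_events, p = fit$p,
    AIC = fit$AIC, BIC = fit$BIC, nodes = fit$nodes,
    convergence = fit$convergence)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a fitted excess hazard model from JSON
#'
#' @param path Path written by [write_eh_fit()].
#' @return An `eh_fit`.
#' @export
read_eh_fit <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the jsonlite package is required for model serialization", call. = FALSE)
  }
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) if (is.null(x) || length(x) == 0) numeric(0) else
    vapply(x, as.numeric, 0)
  chr <- function(x) if (is.null(x) || length(x) == 0) NULL else
    vapply(x, as.character, "")
  from_basis <- function(b) {
    if (is.null(b)) return(NULL)
    new_spline_basis(num(b$internal_knots), num(b$boundary_knots),
                     as.character(b$scale))
  }
  spec <- eh_spec(
    as.integer(obj$spec$baseline_df),
    effects = lapply(obj$spec$effects, function(e)
      eh_effect(e$variable, e$form, df = e$df, tdep = isTRUE(e$tdep))),
    interactions = lapply(obj$spec$interactions, function(i)
      eh_interaction(i$var1, i$var2, tdep = isTRUE(i$tdep))))
  terms <- lapply(obj$terms, function(tm) {
    e <- eh_effect(tm$effect$variable, tm$effect$form,
                   df = tm$effect$df, tdep = isTRUE(tm$effect$tdep))
    list(effect = e, levels = chr(tm$levels),
         center = if (is.null(tm$center)) NULL else as.numeric(tm$center),
         basis = from_basis(tm$basis))
  })
  frame <- list(spec = spec, baseline = from_basis(obj$baseline_basis),
                terms = terms)
  coef <- num(obj$coef)
  names(coef) <- names(obj$coef)
  p <- length(coef)
  vcov <- matrix(unlist(lapply(obj$vcov, num)), nrow = p, byrow = TRUE)
  dimnames(vcov) <- list(names(coef), names(coef))
  structure(list(spec = spec, frame = frame, coef = coef, vcov = vcov,
                 loglik = as.numeric(obj$loglik), n = as.integer(obj$n),
                 n_events = as.integer(obj$n_events),
                 p = as.integer(obj$p), AIC = as.numeric(obj$AIC),
                 BIC = as.numeric(obj$BIC), nodes = as.integer(obj$nodes),
                 convergence = obj$convergence),
            class = "eh_fit")
}
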