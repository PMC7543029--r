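#' Restricted cubic spline bases
#'
#' Builds the restricted (natural) cubic spline basis used for the log
#' baseline excess hazard and for non-linear covariate effects. A basis of
#' `df` degrees of freedom has `df - 1` internal knots plus two boundary
#' knots, and is linear beyond the boundary knots.
#'
#' @name spline_basis
NULL

# type-1 (inverse empirical CDF) quantile: smallest order statistic x_(k)
# with k >= n * p
quantile_type1 <- function(x, probs) {
  xs <- sort(x)
  n <- length(xs)
  idx <- pmax(1L, pmin(n, as.integer(ceiling(n * probs - 1e-9))))
  xs[idx]
}

#' Place spline knots on an event-time distribution
#'
#' Internal knots are placed at equally spaced empirical percentiles of the
#' uncensored event times (for `df = 3`, the 33.33rd and 66.67th percentiles,
#' i.e. the tertiles), boundary knots at the minimum and maximum uncensored
#' event time. Percentile probabilities are rounded to four decimals and
#' resolved by the inverse empirical CDF (type-1 quantile), so knot placement
#' is deterministic. `df = 1` yields a pure linear basis with no internal
#' knots.
#'
#' @param event_times Positive event (death) times of uncensored subjects, on
#'   the original time scale.
#' @param df Degrees of freedom (number of basis columns), integer >= 1.
#' @param scale Working scale of the basis: `"log"` (knots and evaluation on
#'   `log(t)`; the default for baseline hazards) or `"identity"` (e.g. for a
#'   covariate such as age).
#' @return An object of class `spline_basis` with fields `internal_knots`,
#'   `boundary_knots`, `scale` and `df`.
#' @export
place_knots <- function(event_times, df = 3, scale = c("log", "identity")) {
  scale <- match.arg(scale)
  if (!is.numeric(df) || df < 1 || df != round(df)) {
    stop("df must be a positive integer", call. = FALSE)
  }
  df <- as.integer(df)
  v <- event_times[is.finite(event_times)]
  if (scale == "log") {
    if (any(v <= 0)) stop("event times must be positive on the log scale", call. = FALSE)
    v <- log(v)
  }
  if (length(unique(v)) < df + 1) {
    stop(sprintf("need at least %d distinct event times for df = %d, got %d",
                 df + 1, df, length(unique(v))), call. = FALSE)
  }
  boundary <- range(v)
  internal <- numeric(0)
  if (df > 1) {
    probs <- round(seq_len(df - 1) / df, 4)
    internal <- quantile_type1(v, probs)
    internal <- internal[internal > boundary[1] & internal < boundary[2]]
    dropped <- (df - 1) - length(unique(internal))
    if (dropped > 0) {
      warning(sprintf("heavy ties collapsed %d internal knot(s); basis df reduced to %d",
                      dropped, length(unique(internal)) + 1L), call. = FALSE)
    }
    internal <- unique(internal)
  }
  new_spline_basis(internal, boundary, scale)
}

new_spline_basis <- function(internal, boundary, scale) {
  structure(list(internal_knots = as.numeric(internal),
                 boundary_knots = as.numeric(boundary),
                 scale = scale,
                 df = length(internal) + 1L),
            class = "spline_basis")
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf("<spline_basis> df = %d, scale = %s\n", x$df, x$scale))
  cat("  boundary knots:", format(x$boundary_knots, digits = 5), "\n")
  if (length(x$internal_knots)) {
    cat("  internal knots:", format(x$internal_knots, digits = 5), "\n")
  }
  invisible(x)
}

#' Evaluate a restricted cubic spline basis
#'
#' Returns the `df` basis columns at values `v` on the working scale (callers
#' supply `log(t)` themselves when `scale = "log"`). The basis uses the
#' truncated-power restricted cubic form: column 1 is the working variable
#' itself; column `j + 1` is
#' \deqn{(v-k_j)_+^3 - (v-k_{K-1})_+^3 \frac{k_K-k_j}{k_K-k_{K-1}}
#'       + (v-k_K)_+^3 \frac{k_{K-1}-k_j}{k_K-k_{K-1}}}
#' over the full knot sequence \eqn{k_1 < \dots < k_K} (boundaries included),
#' which is twice continuously differentiable everywhere and linear outside
#' the boundary knots.
#'
#' @param basis A [place_knots()] result (or `new_spline_basis()`).
#' @param v Numeric vector of working-scale values.
#' @return A numeric matrix with `length(v)` rows and `basis$df` columns.
#' @export
rcs_eval <- function(basis, v) {
  stopifnot(inherits(basis, "spline_basis"))
  v <- as.numeric(v)
  out <- matrix(0, nrow = length(v), ncol = basis$df)
  colnames(out) <- paste0("rcs", seq_len(basis$df))
  out[, 1] <- v
  if (basis$df == 1L) return(out)
  knots <- sort(c(basis$boundary_knots, basis$internal_knots))
  K <- length(knots)
  kK <- knots[K]; kK1 <- knots[K - 1]
  pos3 <- function(x) pmax(x, 0)^3
  for (j in seq_len(K - 2)) {
    kj <- knots[j]
    out[, j + 1] <- pos3(v - kj) -
      pos3(v - kK1) * (kK - kj) / (kK - kK1) +
      pos3(v - kK) * (kK1 - kj) / (kK - kK1)
  }
  out
}
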