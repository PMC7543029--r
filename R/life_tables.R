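#' Population life tables
#'
#' A life table stores background ("expected") mortality rates for the general
#' population on a complete grid of single year of age x calendar year x sex x
#' stratum (e.g. deprivation quintile). It supplies the expected hazard
#' \eqn{\lambda_P(a+t, y+t, z)} and expected survival \eqn{S_P(t)} terms of the
#' excess hazard decomposition \eqn{\lambda = \lambda_E + \lambda_P}.
#'
#' @param data A data frame with columns `age` (integer years), `year`
#'   (integer calendar year), `sex`, `stratum` and `rate` (annual mortality
#'   hazard, events per person-year). Additional columns are ignored.
#' @param rate_type Either `"hazard"` (the `rate` column holds annual hazards,
#'   the default) or `"qx"` (annual death probabilities, converted via
#'   `rate = -log(1 - qx)`).
#'
#' @return An object of class `life_table`: a tibble of rates plus metadata
#'   attributes (`age_range`, `year_range`, `strata`, `sexes`).
#'
#' @details The grid must be complete: every combination of age, year, sex and
#'   stratum within the observed ranges must be present exactly once. Rates are
#'   treated as piecewise constant within one age x calendar-year cell.
#'   Attained age is clamped at the table maximum; attained calendar year is
#'   never extrapolated.
#'
#' @export
life_table <- function(data, rate_type = c("hazard", "qx")) {
  rate_type <- match.arg(rate_type)
  required <- c("age", "year", "sex", "stratum", "rate")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("life table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tab <- tibble::as_tibble(data[required])
  tab$age <- as.integer(tab$age)
  tab$year <- as.integer(tab$year)
  tab$sex <- as.character(tab$sex)
  tab$stratum <- as.character(tab$stratum)
  tab$rate <- as.numeric(tab$rate)
  if (anyNA(tab$rate) || any(!is.finite(tab$rate))) {
    stop("life table rates must be finite numbers", call. = FALSE)
  }
  if (rate_type == "qx") {
    if (any(tab$rate >= 1)) {
      stop("qx values must be < 1 to convert to hazards", call. = FALSE)
    }
    tab$rate <- -log(1 - tab$rate)
  }
  if (any(tab$rate < 0)) {
    bad <- which(tab$rate < 0)[1]
    stop(sprintf("negative mortality rate at age %d, year %d (%s, stratum %s)",
                 tab$age[bad], tab$year[bad], tab$sex[bad], tab$stratum[bad]),
         call. = FALSE)
  }

  ages <- range(tab$age)
  years <- range(tab$year)
  sexes <- sort(unique(tab$sex))
  strata <- sort(unique(tab$stratum))

  # complete-grid invariant: one row per cell, no holes
  full <- expand.grid(age = seq(ages[1], ages[2]), year = seq(years[1], years[2]),
                      sex = sexes, stratum = strata,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) paste(d$age, d$year, d$sex, d$stratum, sep = "\r")
  have <- key(tab)
  if (anyDuplicated(have)) {
    dup <- tab[duplicated(have), ][1, ]
    stop(sprintf("duplicate life-table cell: age %d, year %d, sex %s, stratum %s",
                 dup$age, dup$year, dup$sex, dup$stratum), call. = FALSE)
  }
  absent <- setdiff(key(full), have)
  if (length(absent) > 0) {
    parts <- strsplit(absent[1], "\r", fixed = TRUE)[[1]]
    stop(sprintf(
      "life-table grid has %d missing cell(s); first missing: age %s, year %s, sex %s, stratum %s",
      length(absent), parts[1], parts[2], parts[3], parts[4]), call. = FALSE)
  }

  # dense array lookup: [age, year, sex:stratum]
  grp <- paste(tab$sex, tab$stratum, sep = "\r")
  groups <- sort(unique(grp))
  arr <- array(NA_real_,
               dim = c(ages[2] - ages[1] + 1, years[2] - years[1] + 1, length(groups)),
               dimnames = list(NULL, NULL, groups))
  arr[cbind(tab$age - ages[1] + 1L, tab$year - years[1] + 1L, match(grp, groups))] <- tab$rate

  structure(tab,
            class = c("life_table", class(tab)),
            age_range = ages, year_range = years,
            sexes = sexes, strata = strata, rate_array = arr)
}

#' @export
print.life_table <- function(x, ...) {
  ar <- attr(x, "age_range"); yr <- attr(x, "year_range")
  cat(sprintf("<life_table> ages %d-%d, years %d-%d, %d sex(es), %d stratum(a)\n",
              ar[1], ar[2], yr[1], yr[2],
              length(attr(x, "sexes")), length(attr(x, "strata"))))
  NextMethod()
}

#' Read a population life table from delimited text
#'
#' Reads a comma- or tab-delimited file (autodetected from the header line)
#' with columns `age`, `year`, `sex`, `stratum`, `rate`. Nonstandard headers
#' are renamed through `col_map`.
#'
#' @param path Path to the file.
#' @param col_map Named character vector mapping standard names to the file's
#'   column names, e.g. `c(age = "agex", rate = "mx")`. Unmapped standard
#'   names are looked up verbatim.
#' @param rate_type Passed to [life_table()]: `"hazard"` or `"qx"`.
#' @return A [life_table()] object.
#' @export
read_life_table <- function(path, col_map = NULL, rate_type = c("hazard", "qx")) {
  if (!file.exists(path)) stop("life-table file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      src <- col_map[[std]]
      if (!src %in% names(raw)) {
        stop(sprintf("mapped column '%s' (for '%s') not found in %s", src, std, path),
             call. = FALSE)
      }
      names(raw)[names(raw) == src] <- std
    }
  }
  life_table(raw, rate_type = match.arg(rate_type))
}

# resolve the rate-array slab for sex/stratum, with helpful errors
lt_group_index <- function(table, sex, stratum) {
  arr <- attr(table, "rate_array")
  groups <- dimnames(arr)[[3]]
  g <- paste(as.character(sex), as.character(stratum), sep = "\r")
  idx <- match(g, groups)
  if (anyNA(idx)) {
    bad <- strsplit(g[which(is.na(idx))[1]], "\r", fixed = TRUE)[[1]]
    stop(sprintf("life table has no cells for sex '%s', stratum '%s'", bad[1], bad[2]),
         call. = FALSE)
  }
  idx
}

#' Expected (background) mortality hazard at attained age and year
#'
#' Looks up \eqn{\lambda_P(a+t, y+t, z)}: the annual mortality hazard of the
#' life-table cell containing attained age `floor(age + t)` and attained
#' calendar year `floor(year + t)`. Attained age above the table maximum uses
#' the maximum-age row (clamping); attained calendar year outside the table is
#' an error (no extrapolation over calendar time).
#'
#' @param table A [life_table()].
#' @param age Age at diagnosis in years (vectorised).
#' @param year Calendar year (possibly fractional) at diagnosis (vectorised).
#' @param sex,stratum Life-table keys (vectorised).
#' @param t Years since diagnosis (vectorised).
#' @return Numeric vector of per-year hazards.
#' @export
expected_hazard <- function(table, age, year, sex, stratum, t = 0) {
  stopifnot(inherits(table, "life_table"))
  n <- max(length(age), length(year), length(sex), length(stratum), length(t))
  age <- rep_len(age, n); year <- rep_len(year, n); t <- rep_len(t, n)
  sex <- rep_len(sex, n); stratum <- rep_len(stratum, n)
  ar <- attr(table, "age_range"); yr <- attr(table, "year_range")
  att_age <- pmin(floor(age + t), ar[2])   # clamp at max tabulated age
  att_age <- pmax(att_age, ar[1])
  att_year <- floor(year + t)
  if (any(att_year < yr[1] | att_year > yr[2])) {
    bad <- att_year[att_year < yr[1] | att_year > yr[2]][1]
    stop(sprintf("attained calendar year %d outside life-table range %d-%d",
                 bad, yr[1], yr[2]), call. = FALSE)
  }
  arr <- attr(table, "rate_array")
  gi <- lt_group_index(table, sex, stratum)
  arr[cbind(att_age - ar[1] + 1, att_year - yr[1] + 1, gi)]
}

# Cumulative expected hazard from diagnosis to each t, integrating exactly
# over the piecewise-constant cells crossed. Cell boundaries occur where the
# attained age or attained year crosses an integer, i.e. at the same set of
# offsets u with age+u or year+u integer.
cum_expected_hazard_one <- function(table, age, year, sex, stratum, t) {
  if (t <= 0) return(0)
  # breakpoints where floor(age+u) or floor(year+u) changes
  b1 <- setdiff(seq(ceiling(age + 1e-12), age + t + 1, by = 1) - age, 0)
  b2 <- setdiff(seq(ceiling(year + 1e-12), year + t + 1, by = 1) - year, 0)
  cuts <- sort(unique(c(b1[b1 > 0 & b1 < t], b2[b2 > 0 & b2 < t], t)))
  lo <- c(0, cuts[-length(cuts)])
  mid <- (lo + cuts) / 2
  rates <- expected_hazard(table, age, year, sex, stratum, t = mid)
  sum(rates * (cuts - lo))
}

#' Expected (background) survival probability
#'
#' \eqn{S_P(t) = \exp(-\int_0^t \lambda_P(a+u, y+u, z)\,du)}, the probability
#' that a general-population individual matched on the life-table keys
#' survives `t` years past diagnosis. The integral is exact over the
#' piecewise-constant life-table cells crossed.
#'
#' @inheritParams expected_hazard
#' @return Numeric vector of survival probabilities; `1` at `t = 0`,
#'   non-increasing in `t`.
#' @export
expected_survival <- function(table, age, year, sex, stratum, t) {
  stopifnot(inherits(table, "life_table"))
  n <- max(length(age), length(year), length(sex), length(stratum), length(t))
  age <- rep_len(age, n); year <- rep_len(year, n); t <- rep_len(t, n)
  sex <- rep_len(sex, n); stratum <- rep_len(stratum, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- exp(-cum_expected_hazard_one(table, age[i], year[i], sex[i], stratum[i], t[i]))
  }
  out
}

# Per-patient cumulative expected hazard path: breakpoints (offsets u from
# diagnosis where the life-table cell changes), the constant rate on each
# segment, and the cumulative hazard at each breakpoint. Evaluating
# Lambda_P(t) or inverting Lambda_P(t) = E is then linear interpolation.
lp_path <- function(table, age, year, sex, stratum, tmax) {
  ar <- attr(table, "age_range"); yr <- attr(table, "year_range")
  b1 <- seq(ceiling(age + 1e-12), age + tmax + 1, by = 1) - age
  b2 <- seq(ceiling(year + 1e-12), year + tmax + 1, by = 1) - year
  cuts <- sort(unique(c(b1[b1 > 0 & b1 < tmax], b2[b2 > 0 & b2 < tmax], tmax)))
  lo <- c(0, cuts[-length(cuts)])
  mid <- (lo + cuts) / 2
  rates <- expected_hazard(table, age, year, sex, stratum, t = mid)
  cum <- c(0, cumsum(rates * (cuts - lo)))
  list(breaks = c(0, cuts), rates = rates, cum = cum)
}

# Lambda_P(t) for a path, vectorised over t in [0, tmax]
lp_path_cum <- function(path, t) {
  i <- findInterval(pmin(t, path$breaks[length(path$breaks)]), path$breaks,
                    rightmost.closed = TRUE)
  i <- pmax(pmin(i, length(path$rates)), 1)
  path$cum[i] + path$rates[i] * (pmax(t, 0) - path$breaks[i])
}

# smallest t with Lambda_P(t) >= e, or Inf if the path never accumulates e
lp_path_invert <- function(path, e) {
  k <- length(path$cum)
  if (e >= path$cum[k]) {
    # beyond tabulated horizon: treat last rate as continuing (caller censors)
    last_rate <- path$rates[length(path$rates)]
    if (last_rate <= 0) return(Inf)
    return(path$breaks[k] + (e - path$cum[k]) / last_rate)
  }
  i <- findInterval(e, path$cum, rightmost.closed = FALSE)
  i <- max(i, 1)
  if (path$rates[i] <= 0) return(path$breaks[i + 1])
  path$breaks[i] + (e - path$cum[i]) / path$rates[i]
}
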