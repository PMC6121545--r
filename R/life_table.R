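#' Construct and validate a life table
#'
#' A life table is a tibble with one row per integer age carrying `q_all`,
#' the annual probability of death from all causes, and optionally
#' `cvd_fatality`, the probability that an incident cardiovascular event in
#' that year is fatal. Ages must be contiguous, probabilities in \[0, 1\], and
#' the terminal age must have `q_all = 1` so every cohort closes out.
#' A non-monotone `q_all` above age 30 triggers a warning (real period tables
#' are monotone there) but is not an error.
#'
#' @param data A data frame with columns `age`, `q_all` and optionally
#'   `cvd_fatality`.
#' @return A tibble of class `life_table`.
#' @export
life_table <- function(data) {
  if (!all(c("age", "q_all") %in% names(data))) {
    stop("a life table needs columns `age` and `q_all`", call. = FALSE)
  }
  lt <- tibble::as_tibble(data)
  if (anyNA(lt$age) || anyNA(lt$q_all)) stop("life table contains missing values", call. = FALSE)
  if (any(lt$age != as.integer(lt$age))) stop("`age` must be integer years", call. = FALSE)
  lt$age <- as.integer(lt$age)
  if (is.unsorted(lt$age, strictly = TRUE)) stop("`age` must be strictly increasing", call. = FALSE)
  if (nrow(lt) > 1 && any(diff(lt$age) != 1)) stop("ages must be contiguous (step of 1 year)", call. = FALSE)
  if (any(lt$q_all < 0 | lt$q_all > 1)) {
    bad <- lt$age[which(lt$q_all < 0 | lt$q_all > 1)[1]]
    stop("`q_all` outside [0, 1] at age ", bad, call. = FALSE)
  }
  if (lt$q_all[nrow(lt)] != 1) {
    stop("terminal row must have q_all = 1 (age ", lt$age[nrow(lt)], " has q_all = ",
      lt$q_all[nrow(lt)], ")",
      call. = FALSE
    )
  }
  if ("cvd_fatality" %in% names(lt)) {
    if (any(is.na(lt$cvd_fatality) | lt$cvd_fatality < 0 | lt$cvd_fatality > 1)) {
      stop("`cvd_fatality` must lie in [0, 1] with no missing values", call. = FALSE)
    }
  }
  adult <- lt$q_all[lt$age >= 30]
  if (length(adult) > 1 && any(diff(adult) < 0)) {
    warning("`q_all` is not non-decreasing above age 30; check the table", call. = FALSE)
  }
  class(lt) <- c("life_table", class(lt))
  lt
}

#' Read a life table from CSV
#'
#' Expects a header with columns `age`, `q_all` and optionally `cvd_fatality`;
#' validation is as in [life_table()].
#'
#' @param path CSV file path.
#' @return A validated `life_table` tibble.
#' @export
read_life_table <- function(path) {
  # base read.csv: correctly rounded double parsing, so round trips are
  # bit-exact
  df <- utils::read.csv(path, check.names = TRUE)
  life_table(df)
}

#' @rdname read_life_table
#' @param table A `life_table` to write.
#' @export
write_life_table <- function(table, path) {
  out <- tibble::as_tibble(unclass(table))
  # full 17-significant-digit output so a write/read round trip is bit-exact
  for (col in setdiff(names(out), "age")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Look up annual all-cause mortality at an age
#'
#' Exact row lookup; ages beyond the table's terminal age return 1 (the
#' terminal row is absorbing), ages below the table's coverage are an error.
#'
#' @param table A `life_table`.
#' @param age Integer age(s) in years.
#' @return Annual probability of death, vectorised over `age`.
#' @export
mortality_at <- function(table, age) {
  if (any(age < table$age[1])) {
    stop("age below life-table coverage (first age is ", table$age[1], ")", call. = FALSE)
  }
  idx <- pmin(age - table$age[1] + 1, nrow(table))
  table$q_all[idx]
}

cvd_fatality_at <- function(table, age, default = 0.10) {
  if (!"cvd_fatality" %in% names(table)) {
    return(rep(default, length(age)))
  }
  idx <- pmin(pmax(age - table$age[1] + 1, 1), nrow(table))
  table$cvd_fatality[idx]
}

#' Generate a synthetic Gompertz life table
#'
#' Annual mortality follows a Gompertz law,
#' `q(age) = 1 - exp(-a * exp(b * age))`, with the terminal age forced to
#' `q = 1`. The defaults (`a = 2e-5`, `b = 0.10`, terminal age 110) give an
#' undiscounted life expectancy at age 41 of about 39.5 years, in line with a
#' contemporary US period life table; the result is a synthetic stand-in, not
#' an official table. A constant CVD case-fatality column is attached.
#'
#' @param a Baseline hazard scale, positive.
#' @param b Log-hazard slope per year of age, positive.
#' @param max_age Terminal age (q_all set to 1 there).
#' @param min_age First age covered.
#' @param cvd_fatality Constant probability that a CVD event is fatal in its
#'   cycle; use `NULL` to omit the column.
#' @return A `life_table` tibble covering `min_age:max_age`.
#' @examples
#' lt <- gompertz_life_table()
#' mortality_at(lt, 41)
#' @export
gompertz_life_table <- function(a = 2e-5, b = 0.10, max_age = 110, min_age = 0,
                                cvd_fatality = 0.10) {
  if (a <= 0 || b <= 0) stop("Gompertz parameters `a` and `b` must be > 0", call. = FALSE)
  if (max_age <= min_age) stop("`max_age` must exceed `min_age`", call. = FALSE)
  ages <- min_age:max_age
  q <- 1 - exp(-a * exp(b * ages))
  q[length(q)] <- 1
  df <- tibble::tibble(age = ages, q_all = q)
  if (!is.null(cvd_fatality)) df$cvd_fatality <- cvd_fatality
  life_table(df)
}

#' Survival curve and life expectancy from a life table
#'
#' `survival_curve()` returns the probability of being alive at the *start*
#' of each age, conditional on being alive at `from`; `life_expectancy()`
#' integrates it (with a half-year correction for deaths within the year).
#'
#' @param table A `life_table`.
#' @param from Age at which survival is conditioned (default: first age).
#' @return `survival_curve()`: a tibble with `age` and `surv`;
#'   `life_expectancy()`: expected remaining years of life at `from`.
#' @export
survival_curve <- function(table, from = table$age[1]) {
  keep <- table$age >= from
  q <- table$q_all[keep]
  tibble::tibble(
    age = table$age[keep],
    surv = c(1, cumprod(1 - q))[seq_along(q)]
  )
}

#' @rdname survival_curve
#' @export
life_expectancy <- function(table, from = table$age[1]) {
  sc <- survival_curve(table, from)
  q <- mortality_at(table, sc$age)
  # person-years: survivors of the year count 1, deaths count 1/2
  sum(sc$surv * (1 - q) + sc$surv * q * 0.5)
}
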