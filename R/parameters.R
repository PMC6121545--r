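#' Default age-banded annual risk of a first-or-recurrent CVD event
#'
#' Ten-year age bands with the annual probability of a cardiovascular disease
#' (CVD) event for a person with no prior history, together with its standard
#' error (beta-distributed in the probabilistic analysis). The published bands
#' start at 35; the first band is extended down to age 18 so that cohorts
#' starting before 35 (as in the one-way sensitivity analysis on baseline age)
#' remain covered, carrying the youngest published risk.
#'
#' @return A tibble with columns `age_low`, `age_high`, `mean`, `se`.
#' @export
default_cvd_risk <- function() {
  tibble::tibble(
    age_low  = c(18, 45, 55, 65, 75, 85),
    age_high = c(44, 54, 64, 74, 84, Inf),
    mean     = c(0.0015, 0.0071, 0.0149, 0.0266, 0.0478, 0.0681),
    se       = c(0.0004, 0.0018, 0.0037, 0.0067, 0.0120, 0.0170)
  )
}

#' Assemble the model parameter set
#'
#' Builds the full parameter set for the noise cost-effectiveness model:
#' age-banded CVD risk, relative risks for prior CVD and for noise exposure,
#' the annual probability of a generalized anxiety disorder episode, event
#' costs (2016 US dollars), utilities and disutilities, cohort settings, and
#' exposure (flight-delay) costs per noise-exposed person. Every stochastic
#' parameter carries a sampling distribution (beta for probabilities and
#' utilities, gamma for costs, log-normal for relative risks) used by
#' [sample_parameters()].
#'
#' Defaults are the base-case values of the underlying noise-health analysis;
#' pass named arguments to override any of them.
#'
#' @param ... Named overrides for any field, e.g. `discount_rate = 0`,
#'   `rr_anx_noise = 1`. Unknown names are an error.
#' @param cvd_risk Age-banded risk table as produced by [default_cvd_risk()].
#' @return An object of class `cea_parameters` (a validated named list).
#' @examples
#' p <- cea_parameters()
#' p$rr_cvd_noise
#' cea_parameters(discount_rate = 0)$discount_rate
#' @export
cea_parameters <- function(..., cvd_risk = default_cvd_risk()) {
  params <- list(
    cvd_risk = cvd_risk,
    rr_cvd_prior = 1.965,
    p_anxiety_base = 0.18,
    rr_anx_cvd = 1.66,
    rr_cvd_noise = 1.14,
    rr_anx_noise = 1.79,
    anxiety_odds_ratio = 2.0,
    cost_cvd_direct = 23229,
    cost_cvd_indirect = 12837,
    cost_anx_direct = 2814,
    cost_anx_indirect = 313,
    exposure_op_cost_pp = 1516,
    exposure_prod_loss_pp = 238,
    disutil_cvd_event = 0.283,
    disutil_anxiety = 0.16,
    u_prior_cvd = 0.844,
    u_no_cvd = 1.0,
    cvd_prevalence_init = 0.35,
    cvd_case_fatality = NULL, # NULL = use the life table's cvd_fatality column
    prior_cvd_mortality_multiplier = 1.0,
    start_age = 41,
    discount_rate = 0.03,
    population_60db = 83807,
    population_65db = NA_real_
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(params))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    params[names(dots)] <- dots
  }
  params <- structure(params, class = "cea_parameters")
  validate_parameters(params)
  params
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("<cea_parameters>\n")
  cat(sprintf(
    "  start age %d, discount rate %.1f%%, initial CVD prevalence %.2f\n",
    as.integer(x$start_age), 100 * x$discount_rate, x$cvd_prevalence_init
  ))
  cat(sprintf(
    "  noise RRs: CVD %.3g, anxiety %.3g; exposure cost $%s/person-year\n",
    x$rr_cvd_noise, x$rr_anx_noise,
    format(x$exposure_op_cost_pp + x$exposure_prod_loss_pp, big.mark = ",")
  ))
  cat(sprintf("  CVD risk bands: %d (ages %d-%s)\n",
    nrow(x$cvd_risk), as.integer(min(x$cvd_risk$age_low)),
    if (is.infinite(max(x$cvd_risk$age_high))) "open" else max(x$cvd_risk$age_high)
  ))
  invisible(x)
}

#' Validate a parameter set
#'
#' Checks every structural invariant: probabilities and utilities in \[0, 1\],
#' costs non-negative, relative risks positive, contiguous non-overlapping CVD
#' age bands that cover the starting age.
#'
#' @param params A `cea_parameters` object.
#' @return `params`, invisibly; errors name the offending field.
#' @export
validate_parameters <- function(params) {
  fail <- function(field, msg) {
    stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
  }
  cr <- params$cvd_risk
  if (!all(c("age_low", "age_high", "mean", "se") %in% names(cr))) {
    fail("cvd_risk", "must have columns age_low, age_high, mean, se")
  }
  if (is.unsorted(cr$age_low, strictly = TRUE)) fail("cvd_risk", "bands must be in ascending age order")
  if (nrow(cr) > 1 && any(cr$age_low[-1] != cr$age_high[-nrow(cr)] + 1)) {
    fail("cvd_risk", "bands must be contiguous and non-overlapping")
  }
  if (any(cr$mean <= 0 | cr$mean >= 1)) fail("cvd_risk", "band probabilities must lie in (0, 1)")
  for (f in c("p_anxiety_base", "cvd_prevalence_init")) {
    v <- params[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) fail(f, "must be a probability in [0, 1]")
  }
  for (f in c("disutil_cvd_event", "disutil_anxiety", "u_prior_cvd", "u_no_cvd")) {
    v <- params[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) fail(f, "utilities/disutilities must lie in [0, 1]")
  }
  if (!is.null(params$cvd_case_fatality)) {
    v <- params$cvd_case_fatality
    if (!is.numeric(v) || v < 0 || v > 1) fail("cvd_case_fatality", "must be a probability in [0, 1]")
  }
  for (f in c(
    "cost_cvd_direct", "cost_cvd_indirect", "cost_anx_direct", "cost_anx_indirect",
    "exposure_op_cost_pp", "exposure_prod_loss_pp"
  )) {
    v <- params[[f]]
    if (!is.numeric(v) || v < 0) fail(f, "costs must be >= 0")
  }
  for (f in c("rr_cvd_prior", "rr_anx_cvd", "rr_cvd_noise", "rr_anx_noise",
              "anxiety_odds_ratio", "prior_cvd_mortality_multiplier")) {
    v <- params[[f]]
    if (!is.numeric(v) || v <= 0) fail(f, "relative risks must be > 0")
  }
  if (params$discount_rate < 0) fail("discount_rate", "must be >= 0")
  if (params$start_age < min(cr$age_low) ||
      params$start_age > max(cr$age_high)) {
    fail("start_age", sprintf(
      "age %s is outside CVD risk coverage [%s, %s]",
      params$start_age, min(cr$age_low), max(cr$age_high)
    ))
  }
  invisible(params)
}

# Distribution catalogue: which fields are stochastic and how each is fitted.
# CVD risk bands are handled separately (one beta per band).
parameter_families <- function() {
  tibble::tribble(
    ~parameter,              ~family,     ~se,   ~ci_low, ~ci_high,
    "p_anxiety_base",        "beta",      0.0070, NA,      NA,
    "rr_cvd_prior",          "lognormal", NA,     1.67,    2.30,
    "rr_anx_cvd",            "lognormal", NA,     1.49,    1.82,
    "rr_cvd_noise",          "lognormal", NA,     1.08,    1.20,
    "rr_anx_noise",          "lognormal", NA,     1.00,    3.06,
    "cost_cvd_direct",       "gamma",     5807,   NA,      NA,
    "cost_cvd_indirect",     "gamma",     3209,   NA,      NA,
    "cost_anx_direct",       "gamma",     704,    NA,      NA,
    "cost_anx_indirect",     "gamma",     78,     NA,      NA,
    "exposure_op_cost_pp",   "gamma",     379,    NA,      NA,
    "exposure_prod_loss_pp", "gamma",     59,     NA,      NA,
    "disutil_cvd_event",     "beta",      0.0130, NA,      NA,
    "disutil_anxiety",       "beta",      0.04,   NA,      NA,
    "u_prior_cvd",           "beta",      0.0096, NA,      NA
  )
}

#' Tabulate the parameter set with its sampling distributions
#'
#' @param params A `cea_parameters` object.
#' @return A tibble with one row per stochastic scalar (plus one row per CVD
#'   age band) and columns `parameter`, `family`, `mean`, `se`, `ci_low`,
#'   `ci_high`.
#' @export
parameter_table <- function(params) {
  validate_parameters(params)
  fam <- parameter_families()
  scalars <- fam |>
    dplyr::mutate(mean = purrr::map_dbl(.data$parameter, ~ params[[.x]])) |>
    dplyr::select("parameter", "family", "mean", "se", "ci_low", "ci_high")
  bands <- params$cvd_risk |>
    dplyr::mutate(
      parameter = cvd_band_names(params$cvd_risk),
      family = "beta", ci_low = NA_real_, ci_high = NA_real_
    ) |>
    dplyr::select("parameter", "family", "mean", "se", "ci_low", "ci_high")
  dplyr::bind_rows(bands, scalars)
}

cvd_band_names <- function(cvd_risk) {
  hi <- ifelse(is.infinite(cvd_risk$age_high), "up", as.character(cvd_risk$age_high))
  paste0("cvd_risk_", cvd_risk$age_low, "_", hi)
}

#' Draw parameter sets for probabilistic sensitivity analysis
#'
#' Samples every stochastic parameter independently from its fitted
#' distribution: beta shapes matched to the published mean and standard error,
#' gamma likewise, and log-normal parameters taken from the published 95%
#' confidence interval. Fixed fields (utility of the healthy state, cohort
#' settings, populations) are not drawn. Draws are reproducible for a given
#' `seed` and leave the caller's RNG state untouched.
#'
#' @param params A `cea_parameters` object supplying means and distributions.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return A tibble with `n` rows, one column per stochastic parameter
#'   (CVD band columns first), plus a `draw` index column.
#' @examples
#' draws <- sample_parameters(cea_parameters(), n = 100, seed = 1)
#' colMeans(draws[, c("p_anxiety_base", "cost_cvd_direct")])
#' @export
sample_parameters <- function(params, n, seed) {
  validate_parameters(params)
  stopifnot(n >= 1)
  tab <- parameter_table(params)
  draw_one <- function(parameter, family, mean, se, ci_low, ci_high) {
    switch(family,
      beta = {
        sh <- beta_params_from_moments(mean, se)
        stats::rbeta(n, sh$alpha, sh$beta)
      },
      gamma = {
        sh <- gamma_params_from_moments(mean, se)
        stats::rgamma(n, shape = sh$shape, scale = sh$scale)
      },
      lognormal = {
        lp <- lognormal_params_from_ci(mean, ci_low, ci_high)
        if (lp$sigma == 0) rep(exp(lp$mu), n) else stats::rlnorm(n, lp$mu, lp$sigma)
      },
      stop("unsupported distribution family: ", family, call. = FALSE)
    )
  }
  draws <- withr::with_seed(seed, purrr::pmap(tab, draw_one))
  names(draws) <- tab$parameter
  dplyr::bind_cols(tibble::tibble(draw = seq_len(n)), tibble::as_tibble(draws))
}

#' Replace fields of a parameter set
#'
#' Convenience wrapper used by the one-way sensitivity analysis: returns a
#' revalidated copy with the named fields pinned. CVD band columns (as named
#' in [parameter_table()]) address individual rows of the risk table.
#'
#' @param params A `cea_parameters` object.
#' @param ... Named values to pin.
#' @return A new `cea_parameters` object.
#' @export
set_parameters <- function(params, ...) {
  dots <- list(...)
  band_names <- cvd_band_names(params$cvd_risk)
  for (nm in names(dots)) {
    if (nm %in% band_names) {
      params$cvd_risk$mean[match(nm, band_names)] <- dots[[nm]]
    } else if (nm %in% names(params)) {
      params[[nm]] <- dots[[nm]]
    } else {
      stop("unknown parameter: ", nm, call. = FALSE)
    }
  }
  validate_parameters(params)
  params
}

#' Read / write a parameter set as YAML
#'
#' The on-disk format is a flat mapping of field names to values, with the
#' CVD risk table under `cvd_risk` as parallel lists. A default file
#' reproducing the base case ships at
#' `system.file("extdata", "parameters.yaml", package = "flightnoise")`.
#'
#' @param path File path.
#' @return For `read_parameters()`, a `cea_parameters` object.
#' @export
read_parameters <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$cvd_risk)) stop("parameter file is missing `cvd_risk`", call. = FALSE)
  cvd <- tibble::as_tibble(raw$cvd_risk) |>
    dplyr::mutate(age_high = ifelse(.data$age_high < 0, Inf, .data$age_high))
  raw$cvd_risk <- NULL
  null_fields <- vapply(raw, is.null, logical(1))
  args <- raw[!null_fields]
  do.call(cea_parameters, c(args, list(cvd_risk = cvd)))
}

#' @rdname read_parameters
#' @param params A `cea_parameters` object to serialise.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  out <- unclass(params)
  out$cvd_risk <- as.list(params$cvd_risk |>
    dplyr::mutate(age_high = ifelse(is.infinite(.data$age_high), -1, .data$age_high)))
  out$population_65db <- if (is.na(out$population_65db)) NULL else out$population_65db
  yaml::write_yaml(out, path)
  invisible(path)
}
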