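#' Incremental cost-effectiveness of one arm against another
#'
#' Computes incremental cost, incremental QALYs, the ICER and the dominance
#' class of `reference` relative to `comparator`. When the reference is
#' cheaper and more effective it is *dominant* (cost-saving); costlier and
#' less effective, *dominated*; in the trade-off quadrants the ICER is the
#' ratio of increments. A negative ratio is never reported as a bare ICER:
#' the dominance class carries the interpretation and `icer` keeps the raw
#' signed ratio for table comparability.
#'
#' @param reference,comparator One-row tibbles with columns `cost` and
#'   `qalys`, as returned by [discounted_totals()].
#' @return An object of class `cea_result`.
#' @examples
#' icer(
#'   tibble::tibble(arm = "a", cost = 667461, qalys = 18.7),
#'   tibble::tibble(arm = "b", cost = 656173, qalys = 17.6)
#' )
#' @export
icer <- function(reference, comparator) {
  stopifnot(
    is.finite(reference$cost), is.finite(reference$qalys),
    is.finite(comparator$cost), is.finite(comparator$qalys)
  )
  dc <- reference$cost - comparator$cost
  dq <- reference$qalys - comparator$qalys
  dominance <- if (dc < 0 && dq > 0) {
    "dominant"
  } else if (dc > 0 && dq < 0) {
    "dominated"
  } else if (dq == 0) {
    if (dc < 0) "dominant" else if (dc > 0) "dominated" else "equivalent"
  } else {
    "tradeoff"
  }
  ratio <- if (dq != 0) dc / dq else NA_real_
  structure(
    list(
      arms = dplyr::bind_rows(reference, comparator),
      inc_cost = dc,
      inc_qalys = dq,
      icer = ratio,
      dominance = dominance
    ),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>\n")
  ref <- x$arms$arm[1]
  cmp <- x$arms$arm[2]
  cat(sprintf("  %s vs %s\n", ref, cmp))
  for (i in 1:2) {
    cat(sprintf(
      "  %-12s cost $%s, QALYs %.2f\n", x$arms$arm[i],
      format(round(x$arms$cost[i]), big.mark = ","), x$arms$qalys[i]
    ))
  }
  cat(sprintf(
    "  incremental: $%s, %.3f QALYs (%s)\n",
    format(round(x$inc_cost), big.mark = ","), x$inc_qalys, x$dominance
  ))
  if (x$dominance == "tradeoff") {
    cat(sprintf("  ICER: $%s/QALY\n", format(round(x$icer), big.mark = ",")))
  }
  invisible(x)
}

#' Run the deterministic base case
#'
#' Runs the cohort model for both policy arms on a shared parameter set and
#' life table, and returns their incremental comparison (limited use as the
#' reference, year-round use as the comparator).
#'
#' @param params A `cea_parameters` object.
#' @param table A `life_table`.
#' @param ... Passed to [run_cohort()] (`anxiety_once`, `half_cycle`).
#' @return A `cea_result`.
#' @examples
#' res <- run_cea(cea_parameters(), gompertz_life_table())
#' glance(res)
#' @export
run_cea <- function(params, table, ...) {
  arms <- build_arms(params)
  lim <- discounted_totals(run_cohort(params, arms$limited, table, ...))
  yr <- discounted_totals(run_cohort(params, arms$year_round, table, ...))
  icer(lim, yr)
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` parameter sets with [sample_parameters()] and runs both
#' arms on each shared draw (vectorised, so 10,000 draws complete in
#' seconds). The exposure cost of the limited arm is the drawn per-person
#' operating cost plus productivity loss; the year-round arm's event
#' probabilities carry the drawn noise relative risks.
#'
#' @param params A `cea_parameters` object.
#' @param table A `life_table`.
#' @param n_draws Number of Monte Carlo draws (the headline analysis uses
#'   10,000).
#' @param seed Integer seed; results are bit-reproducible given the seed.
#' @param anxiety_once,half_cycle Passed to the cohort engine.
#' @return A tibble of class `cea_psa` with one row per draw: arm costs and
#'   QALYs, `inc_cost`, `inc_qaly`.
#' @examples
#' psa <- run_psa(cea_parameters(), gompertz_life_table(), n_draws = 50, seed = 1)
#' summary(psa$inc_qaly)
#' @export
run_psa <- function(params, table, n_draws = 10000, seed = 1,
                    anxiety_once = FALSE, half_cycle = FALSE) {
  stopifnot(n_draws >= 1)
  draws <- sample_parameters(params, n = n_draws, seed = seed)
  arm_lim <- arm_spec("limited",
    rr_cvd_exposure = 1, rr_anx_exposure = 1,
    exposure_cost_pp = draws$exposure_op_cost_pp + draws$exposure_prod_loss_pp
  )
  arm_yr <- arm_spec("year_round",
    rr_cvd_exposure = draws$rr_cvd_noise,
    rr_anx_exposure = draws$rr_anx_noise,
    exposure_cost_pp = 0
  )
  res_lim <- cohort_engine(engine_context(params, arm_lim, draws, anxiety_once, half_cycle), table)
  res_yr <- cohort_engine(engine_context(params, arm_yr, draws, anxiety_once, half_cycle), table)
  out <- tibble::tibble(
    draw = draws$draw,
    cost_limited = res_lim$cost,
    qaly_limited = res_lim$qaly,
    cost_year_round = res_yr$cost,
    qaly_year_round = res_yr$qaly,
    inc_cost = res_lim$cost - res_yr$cost,
    inc_qaly = res_lim$qaly - res_yr$qaly
  )
  class(out) <- c("cea_psa", class(out))
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay (WTP) value, the probability that the
#' reference arm is cost-effective: the fraction of PSA draws with positive
#' net monetary benefit, `NMB(w) = w * inc_qaly - inc_cost`. This rule
#' handles all four quadrants of the cost-effectiveness plane; at `w = 0` it
#' reduces to the fraction of cost-saving draws.
#'
#' @param psa A `cea_psa` tibble from [run_psa()].
#' @param wtp Vector of WTP thresholds in $/QALY (default $0 to $200,000 in
#'   $1,000 steps).
#' @return A tibble with columns `wtp` and `prob_cost_effective`.
#' @export
ceac <- function(psa, wtp = seq(0, 200000, by = 1000)) {
  if (!nrow(psa)) stop("empty PSA sample", call. = FALSE)
  if (!length(wtp)) stop("empty WTP grid", call. = FALSE)
  tibble::tibble(
    wtp = wtp,
    prob_cost_effective = vapply(
      wtp,
      function(w) mean(w * psa$inc_qaly - psa$inc_cost > 0),
      numeric(1)
    )
  )
}

#' Summarise a probabilistic sensitivity analysis
#'
#' Headline quantities of the PSA: the fraction of draws in which the
#' reference arm is cost-saving (less costly, more effective), the fraction
#' of trade-off draws (costlier and more effective) whose ICER falls below
#' $100,000/QALY, and the acceptability probabilities at $0, $50,000 and
#' $100,000 per QALY.
#'
#' @param psa A `cea_psa` tibble.
#' @param icer_threshold Threshold for the trade-off ICER fraction (default
#'   $100,000/QALY).
#' @return A one-row tibble.
#' @export
psa_summary <- function(psa, icer_threshold = 1e5) {
  cs <- psa$inc_cost < 0 & psa$inc_qaly > 0
  tradeoff_below <- psa$inc_cost > 0 & psa$inc_qaly > 0 &
    psa$inc_cost / psa$inc_qaly < icer_threshold
  cc <- ceac(psa, wtp = c(0, 50000, 100000))
  tibble::tibble(
    n_draws = nrow(psa),
    p_cost_saving = mean(cs),
    p_icer_below_threshold = mean(tradeoff_below),
    ceac_at_0 = cc$prob_cost_effective[1],
    ceac_at_50k = cc$prob_cost_effective[2],
    ceac_at_100k = cc$prob_cost_effective[3]
  )
}

#' One-way (tornado) sensitivity analysis
#'
#' `one_way()` pins a single parameter at each end of a range, reruns the
#' deterministic base case, and reports the two signed cost-per-QALY ratios
#' sorted ascending (a negative value marks a cost-saving end).
#' `tornado_analysis()` does this for a whole table of ranges and sorts rows
#' by descending ICER spread, the conventional tornado ordering.
#'
#' @param params A `cea_parameters` object (base-case values).
#' @param table A `life_table`.
#' @param parameter Parameter name as in [parameter_table()] (CVD band rows
#'   use their `cvd_risk_*` names).
#' @param low,high Range ends in parameter space, `low <= high`.
#' @return A one-row tibble: `parameter`, `low`, `high`, `icer_min`,
#'   `icer_max`, `dominance_min`, `dominance_max`, `spread`.
#' @export
one_way <- function(params, table, parameter, low, high) {
  if (low > high) stop("`low` must be <= `high`", call. = FALSE)
  run_at <- function(value) {
    p <- do.call(set_parameters, c(list(params), stats::setNames(list(value), parameter)))
    run_cea(p, table)
  }
  res <- lapply(c(low, high), run_at)
  ratios <- vapply(res, function(r) r$icer, numeric(1))
  doms <- vapply(res, function(r) r$dominance, character(1))
  ord <- order(ratios)
  tibble::tibble(
    parameter = parameter,
    low = low, high = high,
    icer_min = ratios[ord[1]], icer_max = ratios[ord[2]],
    dominance_min = doms[ord[1]], dominance_max = doms[ord[2]],
    spread = abs(ratios[ord[2]] - ratios[ord[1]])
  )
}

#' @rdname one_way
#' @param ranges A tibble with columns `parameter`, `low`, `high`
#'   (default [default_owsa_ranges()]).
#' @export
tornado_analysis <- function(params, table, ranges = default_owsa_ranges()) {
  rows <- purrr::pmap(
    ranges[c("parameter", "low", "high")],
    function(parameter, low, high) one_way(params, table, parameter, low, high)
  )
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(dplyr::desc(.data$spread))
  class(out) <- c("cea_tornado", class(out))
  attr(out, "base_icer") <- run_cea(params, table)$icer
  out
}

#' Default one-way sensitivity ranges
#'
#' The ranges conventionally explored for this model: published confidence
#' intervals for the relative risks, +/-25% for costs and event
#' probabilities, +/-0.10 absolute for utilities and disutilities, 0-5% for
#' the discount rate, and +/-10 years of baseline age.
#'
#' @return A tibble with columns `parameter`, `low`, `high`.
#' @export
default_owsa_ranges <- function() {
  tibble::tribble(
    ~parameter,              ~low,   ~high,
    "rr_anx_noise",          1.00,   3.06,
    "p_anxiety_base",        0.08,   0.28,
    "exposure_op_cost_pp",   1137,   1895,
    "disutil_anxiety",       0.06,   0.26,
    "rr_cvd_noise",          1.00,   1.18,
    "cost_anx_direct",       2111,   3518,
    "cost_cvd_direct",       17422,  29036,
    "rr_anx_cvd",            1.49,   1.82,
    "cvd_prevalence_init",   0.25,   0.45,
    "start_age",             31,     51,
    "exposure_prod_loss_pp", 178.5,  297.5,
    "cost_cvd_indirect",     9628,   16046,
    "disutil_cvd_event",     0.18,   0.38,
    "u_prior_cvd",           0.74,   0.94,
    "cost_anx_indirect",     235,    391,
    "rr_cvd_prior",          1.7,    2.3,
    "discount_rate",         0.00,   0.05
  )
}

#' Scenario analysis at a stricter exposure threshold
#'
#' Restricts the exposed population to those above a higher noise threshold
#' (e.g. 65 dB DNL instead of 60): the same annual delay-cost totals are then
#' spread over fewer people, raising the per-person exposure cost, while the
#' health model is unchanged.
#'
#' @param params A `cea_parameters` object.
#' @param table A `life_table`.
#' @param population Exposed population under the stricter threshold.
#' @param total_op,total_prod Annual incremental operating-cost and
#'   productivity-loss totals in dollars; by default the base-case per-person
#'   values scaled back up by the 60 dB population.
#' @return A `cea_result`.
#' @export
scenario_population <- function(params, table, population,
                                total_op = params$exposure_op_cost_pp * params$population_60db,
                                total_prod = params$exposure_prod_loss_pp * params$population_60db) {
  if (population <= 0) stop("`population` must be > 0", call. = FALSE)
  p <- set_parameters(params,
    exposure_op_cost_pp = per_person(total_op, population),
    exposure_prod_loss_pp = per_person(total_prod, population)
  )
  run_cea(p, table)
}
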