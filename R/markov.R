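#' Specify a comparison arm
#'
#' An arm bundles what differs between the two routing policies: the relative
#' risks that chronic noise exposure applies to cardiovascular (CVD) and
#' anxiety event probabilities, and the annual flight-delay cost borne per
#' exposed person. Under the limited policy residents are unexposed
#' (both multipliers 1) but society pays the delay costs; under the
#' year-round policy the noise multipliers apply and the delay cost is zero.
#'
#' @param label Arm label, `"limited"` or `"year_round"`.
#' @param rr_cvd_exposure Multiplier on the annual CVD event probability.
#' @param rr_anx_exposure Multiplier on the annual anxiety probability.
#' @param exposure_cost_pp Annual delay cost per alive person, dollars.
#' @return A list of class `arm_spec`.
#' @export
arm_spec <- function(label, rr_cvd_exposure = 1, rr_anx_exposure = 1,
                     exposure_cost_pp = 0) {
  if (any(rr_cvd_exposure <= 0) || any(rr_anx_exposure <= 0)) {
    stop("exposure multipliers must be positive", call. = FALSE)
  }
  if (any(exposure_cost_pp < 0)) stop("`exposure_cost_pp` must be >= 0", call. = FALSE)
  structure(
    list(
      label = label,
      rr_cvd_exposure = rr_cvd_exposure,
      rr_anx_exposure = rr_anx_exposure,
      exposure_cost_pp = exposure_cost_pp
    ),
    class = "arm_spec"
  )
}

#' Build the two policy arms from a parameter set
#'
#' @param params A `cea_parameters` object.
#' @return A list with `limited` (no noise multipliers, full delay cost,
#'   the sum of per-person operating cost and productivity loss) and
#'   `year_round` (noise multipliers from `rr_cvd_noise`/`rr_anx_noise`,
#'   zero delay cost).
#' @export
build_arms <- function(params) {
  list(
    limited = arm_spec("limited",
      rr_cvd_exposure = 1, rr_anx_exposure = 1,
      exposure_cost_pp = params$exposure_op_cost_pp + params$exposure_prod_loss_pp
    ),
    year_round = arm_spec("year_round",
      rr_cvd_exposure = params$rr_cvd_noise,
      rr_anx_exposure = params$rr_anx_noise,
      exposure_cost_pp = 0
    )
  )
}

band_index <- function(cvd_risk, age) {
  if (any(age < cvd_risk$age_low[1])) {
    stop("age ", min(age), " is below CVD risk coverage (first band starts at ",
      cvd_risk$age_low[1], ")",
      call. = FALSE
    )
  }
  findInterval(age, cvd_risk$age_low)
}

#' Annual CVD event probability for a person
#'
#' The age-banded base risk multiplied by the prior-CVD relative risk (if the
#' person has a CVD history) and the arm's noise exposure multiplier, capped
#' at 1.
#'
#' @param age Age in years (vectorised).
#' @param has_prior Logical: prior history of CVD?
#' @param arm An `arm_spec`.
#' @param params A `cea_parameters` object.
#' @return Annual event probability.
#' @export
cvd_event_prob <- function(age, has_prior, arm, params) {
  base <- params$cvd_risk$mean[band_index(params$cvd_risk, age)]
  mult <- ifelse(has_prior, params$rr_cvd_prior, 1) * arm$rr_cvd_exposure
  pmin(base * mult, 1)
}

#' Annual anxiety disorder probability for a person
#'
#' Base annual probability multiplied by the prior-CVD anxiety relative risk
#' (if applicable) and the arm's noise exposure multiplier, capped at 1.
#'
#' @inheritParams cvd_event_prob
#' @return Annual event probability.
#' @export
anxiety_event_prob <- function(has_prior, arm, params) {
  mult <- ifelse(has_prior, params$rr_anx_cvd, 1) * arm$rr_anx_exposure
  pmin(params$p_anxiety_base * mult, 1)
}

# Build the (possibly vectorised) engine context. `draws` is an optional
# tibble from sample_parameters(); drawn columns override base values, and the
# arm's multipliers/costs may themselves be vectors of the same length.
engine_context <- function(params, arm, draws = NULL,
                           anxiety_once = FALSE, half_cycle = FALSE) {
  validate_parameters(params)
  get <- function(field) {
    if (!is.null(draws) && field %in% names(draws)) draws[[field]] else params[[field]]
  }
  band_cols <- cvd_band_names(params$cvd_risk)
  if (!is.null(draws) && all(band_cols %in% names(draws))) {
    band_risk <- as.matrix(draws[band_cols])
  } else {
    band_risk <- matrix(params$cvd_risk$mean, nrow = 1)
  }
  list(
    start_age = params$start_age,
    bands = params$cvd_risk,
    band_risk = band_risk,
    rr_cvd_prior = get("rr_cvd_prior"),
    p_anx = get("p_anxiety_base"),
    rr_anx_cvd = get("rr_anx_cvd"),
    rr_cvd_exp = arm$rr_cvd_exposure,
    rr_anx_exp = arm$rr_anx_exposure,
    exposure = arm$exposure_cost_pp,
    cost_cvd = get("cost_cvd_direct") + get("cost_cvd_indirect"),
    cost_anx = get("cost_anx_direct") + get("cost_anx_indirect"),
    du_cvd = get("disutil_cvd_event"),
    du_anx = get("disutil_anxiety"),
    u0 = get("u_no_cvd"),
    u1 = get("u_prior_cvd"),
    prev = params$cvd_prevalence_init,
    r = params$discount_rate,
    cf_override = params$cvd_case_fatality,
    prior_mult = params$prior_cvd_mortality_multiplier,
    anxiety_once = anxiety_once,
    half_cycle = half_cycle
  )
}

# Core cohort recursion. All per-draw quantities are vectors of a common
# length m (scalars recycle); ages advance one cycle per year from start_age
# to the life table's terminal age. Four alive compartments track CVD history
# crossed with anxiety history (the anxiety split only fills when
# anxiety_once = TRUE). Returns totals, and the full per-cycle trace when
# trace = TRUE (m must be 1 for a trace).
cohort_engine <- function(ctx, lt, trace = FALSE) {
  max_age <- lt$age[nrow(lt)]
  if (ctx$start_age < lt$age[1]) {
    stop("start age ", ctx$start_age, " is below life-table coverage", call. = FALSE)
  }
  ages <- ctx$start_age:max_age
  m <- max(
    nrow(ctx$band_risk), length(ctx$rr_cvd_prior), length(ctx$p_anx),
    length(ctx$rr_cvd_exp), length(ctx$exposure)
  )
  if (trace && m > 1) stop("trace output requires scalar (non-vectorised) parameters", call. = FALSE)
  one <- rep(1, m)

  n0a <- one * (1 - ctx$prev)
  n0b <- one * 0
  n1a <- one * ctx$prev
  n1b <- one * 0
  dead <- one * 0

  tot_cost <- tot_qaly <- tot_cost_ud <- tot_qaly_ud <- one * 0
  if (trace) rec <- vector("list", length(ages))

  bi <- band_index(ctx$bands, ages)
  q_all_vec <- mortality_at(lt, ages)
  cf_vec <- if (is.null(ctx$cf_override)) cvd_fatality_at(lt, ages) else NULL

  for (t in seq_along(ages)) {
    age <- ages[t]
    q0 <- q_all_vec[t]
    qp <- pmin(q_all_vec[t] * ctx$prior_mult, 1)
    cf <- if (is.null(cf_vec)) ctx$cf_override else cf_vec[t]

    base <- if (nrow(ctx$band_risk) == 1) ctx$band_risk[1, bi[t]] else ctx$band_risk[, bi[t]]
    p_ev0 <- pmin(base * ctx$rr_cvd_exp, 1)
    p_ev1 <- pmin(base * ctx$rr_cvd_prior * ctx$rr_cvd_exp, 1)
    p_anx0 <- pmin(ctx$p_anx * ctx$rr_anx_exp, 1)
    p_anx1 <- pmin(ctx$p_anx * ctx$rr_anx_cvd * ctx$rr_anx_exp, 1)

    n0 <- n0a + n0b
    n1 <- n1a + n1b
    alive <- n0 + n1

    # event incidence (events are resolved before death within the cycle, so
    # fractions with a fatal event still accrue that event's cost/disutility)
    e0a <- n0a * p_ev0; e0b <- n0b * p_ev0
    e1a <- n1a * p_ev1; e1b <- n1b * p_ev1
    ev_total <- e0a + e0b + e1a + e1b
    anx_total <- n0a * p_anx0 + n1a * p_anx1 # anxiety-naive compartments only
    anx_only <- n0a * p_anx0 * (1 - p_ev0) + n1a * p_anx1 * (1 - p_ev1)

    # transitions: survivors of an event carry a CVD history; death combines
    # background mortality with event case fatality
    s_ev0 <- (1 - q0) * (1 - cf)
    s_ev1 <- (1 - qp) * (1 - cf)
    surv0a_stay <- (n0a - e0a) * (1 - q0)
    surv0b_stay <- (n0b - e0b) * (1 - q0)
    surv0a_ev <- e0a * s_ev0
    surv0b_ev <- e0b * s_ev0
    surv1a <- (n1a - e1a) * (1 - qp) + e1a * s_ev1
    surv1b <- (n1b - e1b) * (1 - qp) + e1b * s_ev1

    if (ctx$anxiety_once) {
      new_n0a <- surv0a_stay * (1 - p_anx0)
      new_n0b <- surv0b_stay + surv0a_stay * p_anx0
      # event survivors from state 0 join state 1, keeping their anxiety split
      new_n1a <- surv1a * (1 - p_anx1) + surv0a_ev * (1 - p_anx0)
      new_n1b <- surv1b + surv1a * p_anx1 + surv0b_ev + surv0a_ev * p_anx0
    } else {
      new_n0a <- surv0a_stay
      new_n0b <- surv0b_stay
      new_n1a <- surv1a + surv0a_ev
      new_n1b <- surv1b + surv0b_ev
    }
    new_alive <- new_n0a + new_n0b + new_n1a + new_n1b

    if (ctx$half_cycle) {
      w0 <- (n0 + new_n0a + new_n0b) / 2
      w1 <- (n1 + new_n1a + new_n1b) / 2
      w_alive <- (alive + new_alive) / 2
    } else {
      w0 <- n0; w1 <- n1; w_alive <- alive
    }

    util <- w0 * ctx$u0 + w1 * ctx$u1 - ctx$du_cvd * ev_total - ctx$du_anx * anx_only
    cost <- ev_total * ctx$cost_cvd + anx_total * ctx$cost_anx + w_alive * ctx$exposure
    disc <- (1 + ctx$r)^(-(t - 1))

    tot_cost_ud <- tot_cost_ud + cost
    tot_qaly_ud <- tot_qaly_ud + util
    tot_cost <- tot_cost + cost * disc
    tot_qaly <- tot_qaly + util * disc

    if (trace) {
      rec[[t]] <- tibble::tibble(
        cycle = t - 1, age = age,
        n_no_prior_cvd = n0, n_prior_cvd = n1, n_dead = dead,
        cvd_events = ev_total, anxiety_events = anx_total,
        cost = cost, qaly = util,
        cost_disc = cost * disc, qaly_disc = util * disc
      )
    }

    dead <- dead + (alive - new_alive)
    n0a <- new_n0a; n0b <- new_n0b; n1a <- new_n1a; n1b <- new_n1b
  }

  out <- list(
    cost = tot_cost, qaly = tot_qaly,
    cost_undisc = tot_cost_ud, qaly_undisc = tot_qaly_ud
  )
  if (trace) out$trace <- dplyr::bind_rows(rec)
  out
}

#' Run the cohort model for one arm
#'
#' Propagates a cohort (a unit mass of exposed persons starting at
#' `params$start_age`, of whom `cvd_prevalence_init` begin with a CVD
#' history) through annual cycles until the life table's terminal age. Each
#' cycle applies CVD event incidence (age-banded base risk times prior-CVD
#' and exposure multipliers), recurrent anxiety episodes, and death from
#' background mortality combined with CVD case fatality. Rewards accrue on
#' start-of-cycle occupancy: state utilities minus event disutilities (CVD
#' disutility takes precedence when CVD and anxiety co-occur in a cycle), and
#' costs for events plus the arm's per-person exposure cost on the alive
#' fraction. Costs and QALYs are discounted at `discount_rate` with the first
#' cycle undiscounted.
#'
#' @param params A `cea_parameters` object.
#' @param arm An `arm_spec` (see [build_arms()]).
#' @param table A `life_table` covering the start age through a terminal age.
#' @param anxiety_once If `TRUE`, anxiety can strike each person at most once
#'   in a lifetime; the default treats it as a memoryless annual event.
#' @param half_cycle If `TRUE`, state-occupancy rewards use the mean of
#'   start- and end-of-cycle occupancy (half-cycle correction). Default off.
#' @return A tibble of class `markov_trace` with one row per cycle and
#'   attributes `arm` and `totals`.
#' @examples
#' params <- cea_parameters()
#' lt <- gompertz_life_table(min_age = 41)
#' tr <- run_cohort(params, build_arms(params)$limited, lt)
#' discounted_totals(tr)
#' @export
run_cohort <- function(params, arm, table, anxiety_once = FALSE, half_cycle = FALSE) {
  ctx <- engine_context(params, arm, NULL, anxiety_once, half_cycle)
  res <- cohort_engine(ctx, table, trace = TRUE)
  tr <- res$trace
  occ_sum <- tr$n_no_prior_cvd + tr$n_prior_cvd + tr$n_dead
  bad <- which(abs(occ_sum - 1) > 1e-12)
  if (length(bad)) {
    stop("occupancy not conserved at cycle ", tr$cycle[bad[1]], call. = FALSE)
  }
  structure(
    tr,
    class = c("markov_trace", class(tr)),
    arm = arm$label,
    totals = list(
      cost = res$cost, qaly = res$qaly,
      cost_undisc = res$cost_undisc, qaly_undisc = res$qaly_undisc
    )
  )
}

#' Discounted lifetime totals of a trace
#'
#' @param trace A `markov_trace` from [run_cohort()].
#' @return A one-row tibble with `arm`, discounted `cost` and `qalys`, and
#'   their undiscounted counterparts.
#' @export
discounted_totals <- function(trace) {
  tot <- attr(trace, "totals")
  tibble::tibble(
    arm = attr(trace, "arm"),
    cost = tot$cost,
    qalys = tot$qaly,
    cost_undisc = tot$cost_undisc,
    qalys_undisc = tot$qaly_undisc
  )
}
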