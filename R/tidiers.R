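#' Tidy a cost-effectiveness result
#'
#' Returns one row per arm plus an `incremental` row, in the spirit of
#' broom's `tidy()` methods.
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @return A tibble with columns `arm`, `cost`, `qalys`.
#' @method tidy cea_result
#' @export
tidy.cea_result <- function(x, ...) {
  dplyr::bind_rows(
    x$arms[c("arm", "cost", "qalys")],
    tibble::tibble(arm = "incremental", cost = x$inc_cost, qalys = x$inc_qalys)
  )
}

#' Glance at a cost-effectiveness result
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @return A one-row tibble: `inc_cost`, `inc_qalys`, `icer`, `dominance`.
#' @method glance cea_result
#' @export
glance.cea_result <- function(x, ...) {
  tibble::tibble(
    inc_cost = x$inc_cost,
    inc_qalys = x$inc_qalys,
    icer = x$icer,
    dominance = x$dominance
  )
}

#' Tidy a probabilistic sensitivity analysis
#'
#' Summary statistics of the incremental quantities across draws.
#'
#' @param x A `cea_psa` tibble.
#' @param ... Unused.
#' @return A tibble with one row per quantity (`inc_cost`, `inc_qaly`):
#'   mean, standard deviation and central 95% interval.
#' @method tidy cea_psa
#' @export
tidy.cea_psa <- function(x, ...) {
  x |>
    tidyr::pivot_longer(c("inc_cost", "inc_qaly"),
      names_to = "quantity", values_to = "value"
    ) |>
    dplyr::group_by(.data$quantity) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      q025 = stats::quantile(.data$value, 0.025),
      q975 = stats::quantile(.data$value, 0.975),
      .groups = "drop"
    )
}

#' Glance at a probabilistic sensitivity analysis
#'
#' @param x A `cea_psa` tibble.
#' @param ... Unused.
#' @return The one-row summary of [psa_summary()].
#' @method glance cea_psa
#' @export
glance.cea_psa <- function(x, ...) {
  psa_summary(x)
}
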