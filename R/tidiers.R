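#' Tidy a network-cost result
#'
#' One row per facility level: sampled cost, outpatient capture, and
#' extrapolated cost.
#'
#' @param x A `phc_network_cost` from [network_total()] or
#'   [national_rollup()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy phc_network_cost
#' @export
tidy.phc_network_cost <- function(x, ...) {
  x$per_level |>
    mutate(sub_county = x$sub_county, .before = 1)
}

#' Glance at a network-cost result
#'
#' @param x A `phc_network_cost`.
#' @param ... Unused.
#' @return One-row tibble: `sub_county`, `network_total`, `population`,
#'   `actual_pc`.
#' @method glance phc_network_cost
#' @export
glance.phc_network_cost <- function(x, ...) {
  tibble(sub_county = x$sub_county, network_total = x$network_total,
         population = x$population, actual_pc = x$actual_pc)
}

#' Tidy a normative-cost result
#'
#' One row per service: loaded unit cost, population in need, and total.
#'
#' @param x A `phc_normative` from [normative_subcounty()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy phc_normative
#' @export
tidy.phc_normative <- function(x, ...) x$per_service

#' Glance at a normative-cost result
#'
#' @param x A `phc_normative`.
#' @param ... Unused.
#' @return One-row tibble: `n_services`, `population`, `normative_total`,
#'   `normative_pc`.
#' @method glance phc_normative
#' @export
glance.phc_normative <- function(x, ...) {
  tibble(n_services = nrow(x$per_service), population = x$population,
         normative_total = x$normative_total, normative_pc = x$normative_pc)
}

#' Tidy a tornado (one-way sensitivity) result
#'
#' One row per perturbed parameter, widest output swing first.
#'
#' @param x A `phc_tornado` from [one_way()].
#' @param ... Unused.
#' @return A tibble of bars.
#' @method tidy phc_tornado
#' @export
tidy.phc_tornado <- function(x, ...) x$bars

#' Glance at a tornado result
#'
#' @param x A `phc_tornado`.
#' @param ... Unused.
#' @return One-row tibble: `base`, `best_case`, `worst_case`, and
#'   `n_parameters`.
#' @method glance phc_tornado
#' @export
glance.phc_tornado <- function(x, ...) {
  tibble(base = x$base, best_case = x$best_case, worst_case = x$worst_case,
         n_parameters = nrow(x$bars))
}
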