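#' Financial resource gap between actual and normative costs
#'
#' The resource gap is the normative minus the actual per-capita cost — the
#' additional annual financing per person needed to deliver the full service
#' package at universal coverage. The required-investment multiple is
#' normative over actual; a multiple below 1 (negative gap) means current
#' spending already exceeds the normative requirement.
#'
#' @param actual_pc Actual cost per capita (USD/person/year, > 0),
#'   vectorised.
#' @param normative_pc Normative cost per capita (USD/person/year).
#' @param label Optional label(s) (e.g. sub-county names).
#' @param digits Decimal places for the reported multiple. Default 1.
#' @return Tibble of class `phc_gap`: `actual_pc`, `normative_pc`, `gap_pc`,
#'   `investment_multiple`, and `multiple_reported` (e.g. `"1.6 times"`).
#' @export
#' @examples
#' resource_gap(26.6, 41.7)  # gap 15.1, "1.6 times"
resource_gap <- function(actual_pc, normative_pc, label = NULL, digits = 1) {
  if (any(actual_pc <= 0)) abort("`actual_pc` must be > 0.")
  out <- tibble(
    actual_pc = actual_pc,
    normative_pc = normative_pc,
    gap_pc = normative_pc - actual_pc,
    investment_multiple = normative_pc / actual_pc
  ) |>
    mutate(multiple_reported = paste0(
      format(round_half_up(.data$investment_multiple, digits), nsmall = digits),
      " times"
    ))
  if (!is.null(label)) out <- bind_cols(tibble(label = label), out)
  class(out) <- c("phc_gap", class(out))
  out
}

#' Perturbation specification for one-way sensitivity analysis
#'
#' Relative low/high perturbations per parameter, as signed fractions. The
#' defaults are the uncertainty ranges of the study design: clinical labor
#' costs +/-20% (salary reporting uncertainty, ghost workers), drugs +/-30%
#' and medical supplies +/-20% (supply-database inaccuracies), indirect
#' costs +/-30%, and population +/-5% (work-plan figures).
#'
#' @param ... Named perturbations, each a length-2 numeric `c(low, high)`
#'   with `low < 0 < high`, overriding or extending the defaults.
#' @return A named list of class `phc_sensitivity_spec`.
#' @export
#' @examples
#' sensitivity_spec()
#' sensitivity_spec(drugs = c(-0.5, 0.5))
sensitivity_spec <- function(...) {
  spec <- list(
    clinical_labor = c(low = -0.20, high = 0.20),
    drugs = c(low = -0.30, high = 0.30),
    medical_supplies = c(low = -0.20, high = 0.20),
    indirect = c(low = -0.30, high = 0.30),
    population = c(low = -0.05, high = 0.05)
  )
  over <- list(...)
  for (nm in names(over)) {
    p <- as.numeric(over[[nm]])
    if (length(p) != 2 || !(p[1] < 0 && p[2] > 0)) {
      abort(paste0("Perturbation for `", nm, "` must be c(low, high) with low < 0 < high."))
    }
    spec[[nm]] <- c(low = p[1], high = p[2])
  }
  structure(spec, class = "phc_sensitivity_spec")
}

base_multipliers <- function(spec) {
  stats::setNames(rep(1, length(spec)), names(spec))
}

#' One-way and scenario sensitivity analysis
#'
#' Evaluates a per-capita cost model at the base point, at each parameter's
#' low and high perturbation with all others held at base (one-way bars),
#' and at combined best- and worst-case scenarios. Cost parameters and the
#' population move in opposite directions in the scenarios: since per-capita
#' cost divides by population, the worst case pairs all costs at their high
#' perturbation with population at its low, and the best case the reverse.
#' Bars are ordered by descending width for tornado display.
#'
#' @param model A function taking a named numeric vector of multipliers (one
#'   per parameter in `spec`, 1 = base) and returning the per-capita cost.
#' @param spec A [sensitivity_spec()].
#' @return An object of class `phc_tornado`: `bars` (tibble `parameter`,
#'   `low_input`, `high_input`, `low_output`, `high_output`, `width`,
#'   ordered widest first), `base`, `best_case`, `worst_case`.
#' @export
#' @examples
#' # single-facility world: costs (100, 50, 10, 40), population 100
#' m <- function(mult) {
#'   costs <- c(clinical_labor = 100, drugs = 50,
#'              medical_supplies = 10, indirect = 40)
#'   sum(costs * mult[names(costs)]) / (100 * mult["population"])
#' }
#' tor <- one_way(m, sensitivity_spec())
#' tor$base        # 2.00
#' tor$worst_case  # 2.6211
one_way <- function(model, spec = sensitivity_spec()) {
  stopifnot(is.function(model), inherits(spec, "phc_sensitivity_spec"))
  base_m <- base_multipliers(spec)
  eval_at <- function(mult, where) {
    out <- tryCatch(model(mult), error = function(e) {
      abort(paste0("Model evaluation failed at ", where, ": ",
                   conditionMessage(e)))
    })
    if (!is.finite(out)) abort(paste0("Model returned a non-finite value at ", where, "."))
    out
  }
  base <- eval_at(base_m, "the base point")
  bars <- purrr::imap(spec, function(p, nm) {
    lo <- hi <- base_m
    lo[nm] <- 1 + p[["low"]]
    hi[nm] <- 1 + p[["high"]]
    tibble(
      parameter = nm,
      low_input = 1 + p[["low"]],
      high_input = 1 + p[["high"]],
      low_output = eval_at(lo, paste0(nm, " low")),
      high_output = eval_at(hi, paste0(nm, " high"))
    )
  }) |>
    purrr::list_rbind() |>
    mutate(width = abs(.data$high_output - .data$low_output)) |>
    arrange(desc(.data$width))
  is_pop <- names(spec) == "population"
  best_m <- 1 + vapply(spec, `[[`, numeric(1), "low")
  best_m[is_pop] <- 1 + vapply(spec[is_pop], `[[`, numeric(1), "high")
  worst_m <- 1 + vapply(spec, `[[`, numeric(1), "high")
  worst_m[is_pop] <- 1 + vapply(spec[is_pop], `[[`, numeric(1), "low")
  structure(
    list(bars = bars, base = base,
         best_case = eval_at(best_m, "the best-case scenario"),
         worst_case = eval_at(worst_m, "the worst-case scenario")),
    class = "phc_tornado"
  )
}

#' @export
print.phc_tornado <- function(x, ...) {
  cat("<phc_tornado> base ", format(x$base, digits = 4),
      "; scenario range [", format(x$best_case, digits = 4), ", ",
      format(x$worst_case, digits = 4), "]\n", sep = "")
  print(x$bars)
  invisible(x)
}

#' Sensitivity model for the actual cost per capita
#'
#' Builds the deterministic per-capita model perturbed in a one-way
#' analysis: each cost-category multiplier scales that category in every
#' sampled facility (aggregate perturbation, not per-facility noise), the
#' extrapolation re-runs, and the population multiplier scales the
#' denominator.
#'
#' @param frame A [subcounty_frame()], or a list of frames with
#'   `national_universe_op` and `national_population` for the national
#'   model.
#' @param national_universe_op,national_population See [national_rollup()];
#'   only for the national model.
#' @return A function of a named multiplier vector, suitable for
#'   [one_way()].
#' @export
actual_pc_model <- function(frame, national_universe_op = NULL,
                            national_population = NULL) {
  function(mult) {
    scale_frame <- function(fr) {
      fac <- fr$facilities
      for (cat in intersect(phc_cost_categories(), names(mult))) {
        fac[[cat]] <- fac[[cat]] * mult[[cat]]
      }
      fr$facilities <- fac
      fr
    }
    pop_mult <- if ("population" %in% names(mult)) mult[["population"]] else 1
    if (inherits(frame, "phc_subcounty")) {
      fr <- scale_frame(frame)
      fr$population <- fr$population * pop_mult
      network_total(fr)$actual_pc
    } else {
      frames <- lapply(frame, scale_frame)
      national_rollup(frames, national_universe_op,
                      national_population * pop_mult)$actual_pc
    }
  }
}

#' Sensitivity model for the normative cost per capita
#'
#' Cost-category multipliers scale the corresponding normative ingredients:
#' `clinical_labor` scales human-resource line costs, `drugs` scales drug
#' lines, `medical_supplies` scales diagnostic and reagent lines, and
#' `indirect` scales the overhead loading term (the added overhead, not the
#' direct cost). `population` scales the population in need and the
#' per-capita denominator together, so it is inert for the normative
#' per-capita — retained for symmetry with the actual-cost model.
#'
#' @param catalog An [stp_catalog()].
#' @param population Sub-county (or national) population.
#' @param overheads Overhead rates, see [normative_subcounty()].
#' @param shares,nonclinical_share Passed to [normative_subcounty()].
#' @return A function of a named multiplier vector for [one_way()].
#' @export
normative_pc_model <- function(catalog, population, overheads, shares = NULL,
                               nonclinical_share = 0.30) {
  kind_map <- c(drug = "drugs", diagnostic = "medical_supplies",
                reagent = "medical_supplies", human_resource = "clinical_labor")
  function(mult) {
    cat2 <- catalog
    m <- mult[kind_map[cat2$lines$kind]]
    m[is.na(m)] <- 1
    cat2$lines$unit_cost <- cat2$lines$unit_cost * m
    res <- normative_subcounty(cat2, population, overheads, shares,
                               nonclinical_share)
    if ("indirect" %in% names(mult)) {
      # scale the overhead component (loaded - direct) of every service
      psl <- res$per_service_level |>
        mutate(loaded_unit_cost = .data$direct_unit_cost +
                 (.data$loaded_unit_cost - .data$direct_unit_cost) *
                 mult[["indirect"]])
      per_service <- psl |>
        group_by(.data$service_id) |>
        summarise(unit_cost = sum(.data$share * .data$loaded_unit_cost),
                  .groups = "drop") |>
        left_join(select(cat2$services, "service_id", "need_rate"),
                  by = "service_id")
      total <- sum(population_in_need(res$population, per_service$need_rate) *
                     per_service$unit_cost)
      total / res$population
    } else {
      res$normative_pc
    }
  }
}
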