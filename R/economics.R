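#' Discounted sum of a per-cycle stream
#'
#' Present value of a reward stream with rewards accrued at cycle start:
#' `sum(stream[k] / (1 + rate)^(k - 1))`, the first cycle undiscounted.
#' Effects are discounted at 1.5% and costs at 4% per year in the
#' discounted analyses; a rate of 0 returns the plain sum.
#'
#' @param stream Numeric vector, one value per cycle.
#' @param rate Annual discount rate (>= 0).
#' @return The discounted sum.
#' @examples
#' discounted_sum(c(1, 1, 1), 0.04) # 1 + 1/1.04 + 1/1.04^2
#' @export
discounted_sum <- function(stream, rate = 0) {
  if (rate < 0) stop("discount rate must be non-negative", call. = FALSE)
  if (length(stream) == 0L) return(0)
  sum(stream / (1 + rate)^(seq_along(stream) - 1L))
}

# Occupancy rows used for rewards: cycles 0..horizon-1 (one year each).
reward_rows <- function(trace) {
  trace[-nrow(trace), , drop = FALSE]
}

#' Lifetime years free of end-organ damage from a trace
#'
#' YFEOD counts time spent in the asymptomatic, signs/symptoms and
#' recovery states: per cycle, the summed occupancy of those three states,
#' accumulated (optionally discounted) over the horizon.
#'
#' @param trace A `cohort_trace`.
#' @param rate Annual discount rate for effects (0 = undiscounted).
#' @return Lifetime YFEOD in years.
#' @export
yfeod_from_trace <- function(trace, rate = 0) {
  occ <- reward_rows(trace)
  discounted_sum(rowSums(occ[, yfeod_states(), drop = FALSE]), rate)
}

#' Lifetime QALYs from a trace
#'
#' With 1-year cycles the mean state utility is the number of QALYs a
#' patient generates per cycle, so lifetime QALYs are the per-cycle sum of
#' occupancy times utility, discount-summed. Death contributes 0.
#'
#' @inheritParams yfeod_from_trace
#' @param strategy A [strategy_spec] providing the utility table.
#' @param tariff Which EQ-5D value set to use, `"UK"` or `"NL"`.
#' @return Lifetime QALYs.
#' @export
qalys_from_trace <- function(trace, strategy, tariff = "UK", rate = 0) {
  u <- utility_vector(strategy, tariff)
  discounted_sum(as.numeric(reward_rows(trace) %*% u), rate)
}

# Length-8 utility vector for a tariff; dead = 0; errors if any alive state
# reachable in principle has no utility row.
utility_vector <- function(strategy, tariff = "UK") {
  ut <- strategy$utilities
  ut <- ut[ut$tariff == tariff, ]
  u <- stats::setNames(rep(NA_real_, 8L), gd_states())
  u[ut$state] <- ut$mean_u
  u["dead"] <- 0
  if (anyNA(u)) {
    stop(sprintf("missing %s-tariff utility for state(s): %s", tariff,
                 paste(names(u)[is.na(u)], collapse = ", ")), call. = FALSE)
  }
  u
}

# Per-state annual cost vectors. `medical` = hospital + out-of-hospital
# (+ ERT medication in ERT arms, never in asymptomatic, scaled by the
# multiplier); `production` = production-loss component, applied only
# within the productive age window when the scenario enables it.
state_cost_vectors <- function(strategy, ert_cost_multiplier = NULL) {
  co <- strategy$costs
  comp_vec <- function(component) {
    rows <- co[co$component == component, ]
    v <- stats::setNames(numeric(8L), gd_states())
    v[rows$state] <- rows$mean_annual
    v
  }
  medical <- comp_vec("hospital") + comp_vec("out_of_hospital")
  if (!is.null(strategy$ert_dosing) && strategy$label != "no_ert") {
    mult <- ert_cost_multiplier %||% strategy$ert_cost_multiplier
    ed <- strategy$ert_dosing
    ert <- stats::setNames(numeric(8L), gd_states())
    ert[ed$state] <- ed$vials_per_year * strategy$ert_vial_unit_cost * mult
    ert["asymptomatic"] <- 0 # patients are untreated before symptom onset
    medical <- medical + ert
  }
  list(medical = medical, production = comp_vec("production_loss"))
}

#' Lifetime costs from a trace
#'
#' Per cycle, occupancy times per-state annual cost: hospital plus
#' out-of-hospital care for all arms, plus ERT medication (vials per year
#' times vial unit cost times the scenario's cost multiplier) in ERT arms
#' for symptomatic states, plus production loss when the scenario includes
#' it and the cohort age falls in the productive window. Discount-summed at
#' the cost rate. All costs are 2009 euros.
#'
#' @inheritParams qalys_from_trace
#' @param scenario A [scenario_spec]; controls the ERT cost multiplier and
#'   whether production-loss costs are included.
#' @param config A [model_config] (productive age window).
#' @param rate Annual discount rate for costs.
#' @return Lifetime costs in euros.
#' @export
costs_from_trace <- function(trace, strategy, scenario = scenario_spec(),
                             config = model_config(), rate = 0) {
  cv <- state_cost_vectors(strategy, scenario$ert_cost_multiplier)
  occ <- reward_rows(trace)
  stream <- as.numeric(occ %*% cv$medical)
  if (isTRUE(scenario$include_production_loss)) {
    ages <- seq_len(nrow(occ)) - 1L
    win <- ages >= config$productive_age_window[1] &
      ages <= config$productive_age_window[2]
    stream[win] <- stream[win] + as.numeric(occ[win, , drop = FALSE] %*%
                                              cv$production)
  }
  discounted_sum(stream, rate)
}

#' Scenario definition
#'
#' The four analysis scenarios vary three levers on top of the base case:
#' whether human-capital production-loss costs are added to the medical
#' costs (within ages 25-64), the ERT medication cost multiplier (0.75 for
#' the 25% price-reduction scenario), and, for the historical scenarios,
#' the 1991 starting distribution over disease states together with the
#' historical ERT transition set.
#'
#' @param name Scenario label.
#' @param ert_cost_multiplier Multiplier on ERT medication costs; `NULL`
#'   keeps each strategy's own multiplier.
#' @param include_production_loss Add production-loss costs?
#' @param start_distribution Optional named start vector overriding each
#'   arm's default (historical scenarios).
#' @param ert_strategy Which ERT parameter set the intervention arm uses
#'   (`"ert_base"` or `"ert_historical"`).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(name = "base",
                          ert_cost_multiplier = NULL,
                          include_production_loss = FALSE,
                          start_distribution = NULL,
                          ert_strategy = "ert_base") {
  structure(list(name = name,
                 ert_cost_multiplier = ert_cost_multiplier,
                 include_production_loss = include_production_loss,
                 start_distribution = start_distribution,
                 ert_strategy = ert_strategy),
            class = "scenario_spec")
}

#' Lifetime outcomes for one arm
#'
#' @inheritParams costs_from_trace
#' @param discounted Apply the differential discount rates (effects at
#'   `config$discount_effects`, costs at `config$discount_costs`)?
#' @param tariff EQ-5D tariff for QALYs.
#' @return A one-row data frame: strategy, scenario, discounted flag,
#'   yfeod, qalys, costs.
#' @export
outcome_summary <- function(trace, strategy, config = model_config(),
                            scenario = scenario_spec(), tariff = "UK",
                            discounted = FALSE) {
  re <- if (discounted) config$discount_effects else 0
  rc <- if (discounted) config$discount_costs else 0
  data.frame(strategy = attr(trace, "strategy"),
             scenario = scenario$name,
             discounted = discounted,
             yfeod = yfeod_from_trace(trace, re),
             qalys = qalys_from_trace(trace, strategy, tariff, re),
             costs = costs_from_trace(trace, strategy, scenario, config, rc))
}

#' Incremental cost-effectiveness result
#'
#' Pairwise comparison of an intervention against a comparator: effect and
#' cost differences and their ratios (euro per YFEOD gained, euro per QALY
#' gained). When the signs disagree the ratio is replaced by a dominance
#' flag: `"dominant"` (more effect, lower cost) or `"dominated"` (less
#' effect, higher cost); a zero effect difference leaves the ratio
#' undefined.
#'
#' @param intervention,comparator One-row data frames from
#'   [outcome_summary] computed under the same scenario and discounting.
#' @return A list of class `incremental_result` with elements
#'   `delta_yfeod`, `delta_qalys`, `delta_costs`, `icer_per_yfeod`,
#'   `icer_per_qaly`, `dominance` (`"none"`, `"dominant"`, `"dominated"`).
#' @export
icer <- function(intervention, comparator) {
  stopifnot(identical(intervention$scenario, comparator$scenario),
            identical(intervention$discounted, comparator$discounted))
  dy <- intervention$yfeod - comparator$yfeod
  dq <- intervention$qalys - comparator$qalys
  dc <- intervention$costs - comparator$costs
  dominance <- if (dq > 0 && dc < 0) {
    "dominant"
  } else if (dq < 0 && dc > 0) {
    "dominated"
  } else {
    "none"
  }
  ratio <- function(de) if (de == 0) NA_real_ else dc / de
  structure(list(delta_yfeod = dy, delta_qalys = dq, delta_costs = dc,
                 icer_per_yfeod = ratio(dy), icer_per_qaly = ratio(dq),
                 dominance = dominance,
                 discounted = intervention$discounted,
                 scenario = intervention$scenario),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("<incremental_result '%s'%s>\n", x$scenario,
              if (x$discounted) ", discounted" else ""))
  cat(sprintf("  dYFEOD %.2f, dQALY %.2f, dCosts %.0f\n",
              x$delta_yfeod, x$delta_qalys, x$delta_costs))
  if (x$dominance == "none") {
    cat(sprintf("  ICER %.0f €/YFEOD, %.0f €/QALY\n",
                x$icer_per_yfeod, x$icer_per_qaly))
  } else {
    cat(sprintf("  %s\n", x$dominance))
  }
  invisible(x)
}

#' Run a full scenario (both arms, discounted and undiscounted)
#'
#' Evaluates the ERT arm named by the scenario and the `no_ert` comparator
#' on the deterministic cohort engine, then summarizes lifetime YFEOD,
#' QALYs and costs and their increments the way the scenario tables of a
#' cost-utility report are laid out.
#'
#' @param scenario A [scenario_spec].
#' @param strategies Named list of [strategy_spec] objects containing at
#'   least `no_ert` and the scenario's ERT arm.
#' @inheritParams run_cohort
#' @param tariff EQ-5D tariff.
#' @return A list with `summaries` (data frame, one row per arm x
#'   discounting) and `incremental` (named list of `incremental_result`,
#'   keys `undiscounted` and `discounted`).
#' @export
run_scenario <- function(scenario, strategies, config, life_table,
                         tariff = "UK") {
  ert_lab <- scenario$ert_strategy
  if (!all(c("no_ert", ert_lab) %in% names(strategies))) {
    stop(sprintf("strategies must include 'no_ert' and '%s'", ert_lab),
         call. = FALSE)
  }
  if (grepl("historical", scenario$name) &&
      is.null(scenario$start_distribution)) {
    stop("historical scenario requires a start distribution", call. = FALSE)
  }
  arms <- list(ert = strategies[[ert_lab]], no_ert = strategies[["no_ert"]])
  traces <- lapply(arms, function(s) {
    run_cohort(s, config, life_table,
               start_distribution = scenario$start_distribution)
  })
  summaries <- list()
  incremental <- list()
  for (disc in c(FALSE, TRUE)) {
    os <- mapply(function(trace, s) {
      outcome_summary(trace, s, config, scenario, tariff, discounted = disc)
    }, traces, arms, SIMPLIFY = FALSE)
    summaries[[length(summaries) + 1L]] <- do.call(rbind, os)
    incremental[[if (disc) "discounted" else "undiscounted"]] <-
      icer(os$ert, os$no_ert)
  }
  list(summaries = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
       incremental = incremental)
}
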