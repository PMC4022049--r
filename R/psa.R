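#' Draw one sampled parameter set for the PSA
#'
#' Second-order uncertainty: every annual transition probability is drawn
#' from its beta distribution. In `all_parameters` mode, state utilities,
#' cost components and ERT vial rates are additionally drawn from
#' triangular distributions (mode at the point estimate, support at the
#' 95% confidence limits); the same sampled utility and cost tables are
#' applied to both arms within a draw, since treated and untreated
#' patients share utilities and non-ERT costs in a given disease state.
#' Parameters with no stored uncertainty (missing shapes or limits) stay
#' at their point estimates.
#'
#' @param strategies Named list of [strategy_spec] objects.
#' @param mode `"transitions_only"` or `"all_parameters"`.
#' @return A named list of `strategy_spec` with sampled values.
#' @export
sample_parameters <- function(strategies, mode = c("transitions_only",
                                                   "all_parameters")) {
  mode <- match.arg(mode)
  sampled <- strategies

  for (lab in names(sampled)) {
    tr <- sampled[[lab]]$transitions
    ok <- !is.na(tr$alpha) & !is.na(tr$beta)
    if (any(ok)) {
      tr$mean_p[ok] <- stats::rbeta(sum(ok), tr$alpha[ok], tr$beta[ok])
      tr$alpha[ok] <- NA_real_ # shapes no longer describe the drawn value
      tr$beta[ok] <- NA_real_
    }
    sampled[[lab]]$transitions <- tr
  }

  if (mode == "all_parameters") {
    first <- sampled[[1L]]
    ut <- first$utilities
    has <- !is.na(ut$lcl) & !is.na(ut$ucl)
    if (any(has)) {
      ut$mean_u[has] <- mapply(function(m, lo, hi) {
        sample_triangular(1L, m, lo, hi)
      }, ut$mean_u[has], ut$lcl[has], ut$ucl[has])
      ut$mean_u <- pmin(pmax(ut$mean_u, UTILITY_FLOOR), 1)
    }
    co <- first$costs
    hasc <- !is.na(co$lcl) & !is.na(co$ucl)
    if (any(hasc)) {
      co$mean_annual[hasc] <- mapply(function(m, lo, hi) {
        sample_triangular(1L, m, max(lo, 0), hi)
      }, co$mean_annual[hasc], co$lcl[hasc], co$ucl[hasc])
    }
    ed <- first$ert_dosing
    if (!is.null(ed) && all(c("lcl", "ucl") %in% names(ed))) {
      hasd <- !is.na(ed$lcl) & !is.na(ed$ucl)
      ed$vials_per_year[hasd] <- mapply(function(m, lo, hi) {
        sample_triangular(1L, m, lo, hi)
      }, ed$vials_per_year[hasd], ed$lcl[hasd], ed$ucl[hasd])
    }
    for (lab in names(sampled)) {
      sampled[[lab]]$utilities <- ut
      sampled[[lab]]$costs <- co
      if (!is.null(sampled[[lab]]$ert_dosing)) sampled[[lab]]$ert_dosing <- ed
    }
  }
  sampled
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: for each of `n_draws`
#' second-order draws a sampled parameter set is evaluated on both arms
#' and the incremental costs and effects recorded. With
#' `method = "microsim"` each arm is evaluated as the mean over
#' `n_trials` first-order patient trajectories (patient heterogeneity),
#' using common random numbers across arms within a draw; with
#' `method = "cohort"` the deterministic cohort trace is used (second-order
#' uncertainty only).
#'
#' @inheritParams run_scenario
#' @param mode Passed to [sample_parameters].
#' @param n_draws,n_trials Second-order draws and first-order trials per
#'   draw; default to the values in `config`.
#' @param method `"microsim"` or `"cohort"`.
#' @param discounted Evaluate outcomes discounted?
#' @param common_random_numbers Reuse the same first-order uniforms for
#'   both arms within a draw (variance reduction)?
#' @param scenario Scenario evaluated (default base case).
#' @return A data frame of class `psa_result` with columns `draw`,
#'   `delta_cost`, `delta_qaly`, `delta_yfeod`, and attributes `mode`,
#'   `method`, `n_trials`.
#' @export
run_psa <- function(strategies, config, life_table,
                    mode = c("transitions_only", "all_parameters"),
                    n_draws = config$psa_draws,
                    n_trials = config$psa_trials,
                    method = c("microsim", "cohort"),
                    tariff = "UK", discounted = FALSE,
                    common_random_numbers = TRUE,
                    scenario = scenario_spec()) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  ert_lab <- scenario$ert_strategy
  arms <- c(ert_lab, "no_ert")
  out <- data.frame(draw = seq_len(n_draws), delta_cost = NA_real_,
                    delta_qaly = NA_real_, delta_yfeod = NA_real_)

  for (d in seq_len(n_draws)) {
    sampled <- sample_parameters(strategies[arms], mode)
    u <- NULL
    if (method == "microsim" && common_random_numbers) {
      u <- matrix(stats::runif(n_trials * config$horizon_years),
                  n_trials, config$horizon_years)
    }
    eval_arm <- function(s) {
      trace <- if (method == "cohort") {
        run_cohort(s, config, life_table,
                   start_distribution = scenario$start_distribution,
                   quiet = TRUE)
      } else {
        trace_from_trajectories(run_microsimulation(
          s, config, life_table, n_patients = n_trials,
          start_distribution = scenario$start_distribution, u = u))
      }
      re <- if (discounted) config$discount_effects else 0
      rc <- if (discounted) config$discount_costs else 0
      c(cost = costs_from_trace(trace, s, scenario, config, rc),
        qaly = qalys_from_trace(trace, s, tariff, re),
        yfeod = yfeod_from_trace(trace, re))
    }
    ert <- eval_arm(sampled[[ert_lab]])
    ref <- eval_arm(sampled[["no_ert"]])
    out$delta_cost[d] <- ert["cost"] - ref["cost"]
    out$delta_qaly[d] <- ert["qaly"] - ref["qaly"]
    out$delta_yfeod[d] <- ert["yfeod"] - ref["yfeod"]
  }
  structure(out, class = c("psa_result", "data.frame"),
            mode = mode, method = method, n_trials = n_trials,
            discounted = discounted)
}

#' Cost-effectiveness plane quadrant shares
#'
#' Fractions of PSA draws in each quadrant of the incremental cost /
#' incremental effect plane. Boundary points (a zero difference) count
#' toward the positive side.
#'
#' @param result A `psa_result`.
#' @param effect `"qaly"` or `"yfeod"`.
#' @return Named numeric vector over `upper_right` (more effect, more
#'   cost), `upper_left`, `lower_right`, `lower_left`, summing to 1.
#' @export
quadrant_shares <- function(result, effect = c("qaly", "yfeod")) {
  effect <- match.arg(effect)
  de <- result[[paste0("delta_", effect)]]
  dc <- result$delta_cost
  n <- length(de)
  if (n == 0L) stop("empty PSA result", call. = FALSE)
  c(upper_right = sum(de >= 0 & dc >= 0),
    upper_left = sum(de < 0 & dc >= 0),
    lower_right = sum(de >= 0 & dc < 0),
    lower_left = sum(de < 0 & dc < 0)) / n
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `lambda` on the grid, the probability
#' that the intervention is cost-effective: the fraction of draws with
#' positive net monetary benefit `lambda * delta_effect - delta_cost`.
#'
#' @inheritParams quadrant_shares
#' @param wtp_grid Increasing willingness-to-pay grid (euro per unit
#'   effect).
#' @return A data frame of class `ceac_curve` with columns `wtp` and
#'   `probability`.
#' @export
ceac <- function(result, wtp_grid = seq(0, 1e7, by = 1e4),
                 effect = c("qaly", "yfeod")) {
  effect <- match.arg(effect)
  if (nrow(result) == 0L) stop("empty PSA result", call. = FALSE)
  de <- result[[paste0("delta_", effect)]]
  dc <- result$delta_cost
  prob <- vapply(wtp_grid, function(l) mean(l * de - dc > 0), numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = prob),
            class = c("ceac_curve", "data.frame"), effect = effect)
}

#' Willingness-to-pay at a given acceptability
#'
#' Reads the CEAC "backwards": the willingness-to-pay at which the
#' probability of cost-effectiveness first reaches `q`, linearly
#' interpolated between the bracketing grid points. If the curve never
#' reaches `q` the highest grid value is returned with a warning; if it
#' starts at or above `q`, the lowest.
#'
#' @param curve A `ceac_curve`.
#' @param q Target probability in `[0, 1]`.
#' @return Willingness-to-pay in euro per unit effect.
#' @export
wtp_at_probability <- function(curve, q) {
  p <- curve$probability
  w <- curve$wtp
  hit <- which(p >= q)
  if (length(hit) == 0L) {
    warning("curve never reaches the target probability; returning max WTP",
            call. = FALSE)
    return(w[length(w)])
  }
  i <- hit[1L]
  if (i == 1L) return(w[1L])
  # linear interpolation on the rising segment
  w[i - 1L] + (q - p[i - 1L]) / (p[i] - p[i - 1L]) * (w[i] - w[i - 1L])
}
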