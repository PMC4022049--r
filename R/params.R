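#' Strategy parameter set
#'
#' A `strategy_spec` bundles everything the cohort engine needs for one
#' treatment arm: the annual disease transition table, per-state utilities
#' (UK and/or NL tariff), per-state annual cost components, ERT dosing,
#' excess mortality in the malignancy state, and the starting distribution
#' over states.
#'
#' @param label Strategy label, one of `"no_ert"`, `"ert_base"`,
#'   `"ert_historical"`.
#' @param transitions Data frame with columns `from`, `to`, `mean_p` and
#'   optionally `lcl`, `ucl`, `alpha`, `beta`, `source_label`. One row per
#'   allowed annual transition between alive states.
#' @param utilities Data frame with columns `state`, `tariff` (`"UK"` or
#'   `"NL"`), `mean_u` and optionally `lcl`, `ucl`. The `dead` state is
#'   fixed at utility 0 and must not appear.
#' @param costs Data frame with columns `state`, `component` (one of
#'   `"hospital"`, `"out_of_hospital"`, `"production_loss"`), `mean_annual`
#'   and optionally `lcl`, `ucl`, in 2009 euros per patient-year. ERT
#'   medication costs are derived from `ert_dosing`, not listed here.
#' @param ert_dosing Data frame with columns `state`, `vials_per_year` and
#'   optionally `lcl`, `ucl` (vials of 400 IU). Ignored for `no_ert`.
#' @param start_distribution Named numeric vector over states summing to 1.
#'   Unnamed states default to 0.
#' @param malignancy_excess_mortality Additional annual death probability
#'   applied in the malignancy state on top of background mortality.
#' @param ert_vial_unit_cost Euro per vial of 400 IU (2009 price level).
#' @param ert_cost_multiplier Scale factor in `[0, 1]` on ERT medication
#'   costs (the 25% price-reduction scenario uses 0.75).
#' @return An object of class `strategy_spec`.
#' @export
strategy_spec <- function(label,
                          transitions,
                          utilities,
                          costs,
                          ert_dosing = NULL,
                          start_distribution = c(asymptomatic = 1),
                          malignancy_excess_mortality = 0,
                          ert_vial_unit_cost = 1985,
                          ert_cost_multiplier = 1) {
  spec <- structure(
    list(label = label,
         transitions = as.data.frame(transitions),
         utilities = as.data.frame(utilities),
         costs = as.data.frame(costs),
         ert_dosing = if (is.null(ert_dosing)) NULL else as.data.frame(ert_dosing),
         start_distribution = expand_start_distribution(start_distribution),
         malignancy_excess_mortality = malignancy_excess_mortality,
         ert_vial_unit_cost = ert_vial_unit_cost,
         ert_cost_multiplier = ert_cost_multiplier),
    class = "strategy_spec")
  validate_strategy_spec(spec)
}

# Pad a (possibly partial) named start vector to all eight states.
expand_start_distribution <- function(x) {
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("start_distribution must be a named vector", call. = FALSE)
  }
  assert_states(names(x), "start_distribution state")
  full <- stats::setNames(numeric(8L), gd_states())
  full[names(x)] <- x
  full
}

#' @rdname strategy_spec
#' @param spec A `strategy_spec` to validate.
#' @export
validate_strategy_spec <- function(spec) {
  stopifnot(inherits(spec, "strategy_spec"))
  lab <- spec$label
  if (!lab %in% c("no_ert", "ert_base", "ert_historical")) {
    stop(sprintf("unknown strategy label '%s'", lab), call. = FALSE)
  }

  tr <- spec$transitions
  need <- c("from", "to", "mean_p")
  if (!all(need %in% names(tr))) {
    stop("transitions needs columns from, to, mean_p", call. = FALSE)
  }
  assert_states(tr$from, "transition 'from'")
  assert_states(tr$to, "transition 'to'")
  if (any(tr$from == "dead")) {
    stop("dead is absorbing: no transitions out of dead", call. = FALSE)
  }
  if (any(tr$from == tr$to)) {
    stop("self-transitions are implicit; remove rows with from == to",
         call. = FALSE)
  }
  bad <- which(!is.finite(tr$mean_p) | tr$mean_p < 0 | tr$mean_p > 1)
  if (length(bad) > 0L) {
    stop(sprintf("transition row %d (%s -> %s): mean_p outside [0, 1]",
                 bad[1], tr$from[bad[1]], tr$to[bad[1]]), call. = FALSE)
  }
  if (dup <- anyDuplicated(tr[, c("from", "to")])) {
    stop(sprintf("duplicated transition row: %s -> %s",
                 tr$from[dup], tr$to[dup]), call. = FALSE)
  }
  if (all(c("alpha", "beta") %in% names(tr))) {
    has <- which(!is.na(tr$alpha) & !is.na(tr$beta))
    if (any(tr$alpha[has] <= 0 | tr$beta[has] <= 0)) {
      stop("beta shape parameters must be positive", call. = FALSE)
    }
    m <- tr$alpha[has] / (tr$alpha[has] + tr$beta[has])
    off <- has[abs(m - tr$mean_p[has]) > 1e-9]
    if (length(off) > 0L) {
      stop(sprintf(paste0("transition row %s -> %s: alpha/(alpha+beta) ",
                          "does not reproduce mean_p"),
                   tr$from[off[1]], tr$to[off[1]]), call. = FALSE)
    }
  }
  if (lab == "no_ert" && any(tr$to == "recovery" & tr$mean_p > 0)) {
    stop("recovery is reachable only under ERT: no_ert has a transition into recovery",
         call. = FALSE)
  }

  ut <- spec$utilities
  if (!all(c("state", "tariff", "mean_u") %in% names(ut))) {
    stop("utilities needs columns state, tariff, mean_u", call. = FALSE)
  }
  assert_states(ut$state, "utility state")
  if (any(ut$state == "dead")) {
    stop("the utility of dead is fixed at 0 and is not configurable",
         call. = FALSE)
  }
  if (!all(ut$tariff %in% c("UK", "NL"))) {
    stop("utility tariff must be 'UK' or 'NL'", call. = FALSE)
  }
  if (any(ut$mean_u < UTILITY_FLOOR | ut$mean_u > 1)) {
    stop(sprintf("utilities must lie in [%s, 1]", UTILITY_FLOOR), call. = FALSE)
  }
  if (all(c("lcl", "ucl") %in% names(ut))) {
    has <- !is.na(ut$lcl) & !is.na(ut$ucl)
    if (any(ut$lcl[has] > ut$mean_u[has] | ut$mean_u[has] > ut$ucl[has])) {
      stop("utility confidence limits must bracket the mean", call. = FALSE)
    }
  }

  co <- spec$costs
  if (!all(c("state", "component", "mean_annual") %in% names(co))) {
    stop("costs needs columns state, component, mean_annual", call. = FALSE)
  }
  assert_states(co$state, "cost state")
  if (!all(co$component %in% c("hospital", "out_of_hospital", "production_loss"))) {
    stop("cost component must be hospital, out_of_hospital or production_loss",
         call. = FALSE)
  }
  bad <- which(!is.finite(co$mean_annual) | co$mean_annual < 0)
  if (length(bad) > 0L) {
    stop(sprintf("cost row %d (%s, %s): negative or missing annual cost",
                 bad[1], co$state[bad[1]], co$component[bad[1]]),
         call. = FALSE)
  }

  sd <- spec$start_distribution
  if (abs(sum(sd) - 1) > 1e-12) {
    stop(sprintf("start_distribution sums to %.6f, not 1", sum(sd)),
         call. = FALSE)
  }
  if (any(sd < 0)) stop("start_distribution has negative mass", call. = FALSE)

  if (!is.null(spec$ert_dosing)) {
    ed <- spec$ert_dosing
    if (!all(c("state", "vials_per_year") %in% names(ed))) {
      stop("ert_dosing needs columns state, vials_per_year", call. = FALSE)
    }
    assert_states(ed$state, "ert_dosing state")
    if (any(ed$vials_per_year < 0)) {
      stop("vials_per_year must be non-negative", call. = FALSE)
    }
    if (any(ed$state == "asymptomatic" & ed$vials_per_year > 0)) {
      stop("ERT is not dosed in the asymptomatic state", call. = FALSE)
    }
  }

  m <- spec$malignancy_excess_mortality
  if (!is.finite(m) || m < 0 || m > 1) {
    stop("malignancy_excess_mortality must be an annual probability in [0, 1]",
         call. = FALSE)
  }
  if (spec$ert_vial_unit_cost <= 0) {
    stop("ert_vial_unit_cost must be positive", call. = FALSE)
  }
  if (spec$ert_cost_multiplier < 0) {
    stop("ert_cost_multiplier must be non-negative", call. = FALSE)
  }
  spec
}

#' @export
print.strategy_spec <- function(x, ...) {
  cat(sprintf("<strategy_spec '%s'>\n", x$label))
  cat(sprintf("  %d transitions, %d utility rows, %d cost rows\n",
              nrow(x$transitions), nrow(x$utilities), nrow(x$costs)))
  st <- x$start_distribution[x$start_distribution > 0]
  cat("  start:", paste(sprintf("%s=%g", names(st), st), collapse = ", "), "\n")
  invisible(x)
}

#' Model run configuration
#'
#' Defaults follow the evaluation design: a closed cohort followed from
#' birth over an 85-year horizon in 1-year cycles, effects discounted at
#' 1.5% and costs at 4% per year, a productive-age window of 25-64 years
#' for production-loss costing, and a probabilistic sensitivity analysis of
#' 1,000 second-order draws each evaluated with 100 first-order trials over
#' a willingness-to-pay grid up to 10,000,000 euro per QALY.
#'
#' @param horizon_years Number of 1-year model cycles.
#' @param discount_effects,discount_costs Annual discount rates.
#' @param productive_age_window Inclusive age interval (years) in which
#'   production-loss costs accrue.
#' @param wtp_grid Strictly increasing willingness-to-pay grid (euro per
#'   unit effect).
#' @param psa_draws,psa_trials Second-order draws and first-order trials
#'   per draw.
#' @param seed Base RNG seed.
#' @return An object of class `model_config`.
#' @export
model_config <- function(horizon_years = 85,
                         discount_effects = 0.015,
                         discount_costs = 0.04,
                         productive_age_window = c(25, 64),
                         wtp_grid = seq(0, 1e7, by = 1e4),
                         psa_draws = 1000,
                         psa_trials = 100,
                         seed = 1L) {
  if (horizon_years < 1) stop("horizon_years must be >= 1", call. = FALSE)
  if (discount_effects < 0 || discount_costs < 0) {
    stop("discount rates must be non-negative", call. = FALSE)
  }
  if (length(productive_age_window) != 2L ||
      productive_age_window[1] > productive_age_window[2]) {
    stop("productive_age_window must be an ordered age pair", call. = FALSE)
  }
  if (any(diff(wtp_grid) <= 0)) {
    stop("wtp_grid must be strictly increasing", call. = FALSE)
  }
  if (psa_draws < 1 || psa_trials < 1) {
    stop("psa_draws and psa_trials must be >= 1", call. = FALSE)
  }
  structure(list(horizon_years = as.integer(horizon_years),
                 cycle_years = 1,
                 discount_effects = discount_effects,
                 discount_costs = discount_costs,
                 productive_age_window = productive_age_window,
                 wtp_grid = wtp_grid,
                 psa_draws = as.integer(psa_draws),
                 psa_trials = as.integer(psa_trials),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(paste0("<model_config> horizon %d y, discounting %.1f%%/%.1f%% ",
                     "(effects/costs), PSA %d x %d\n"),
              x$horizon_years, 100 * x$discount_effects,
              100 * x$discount_costs, x$psa_draws, x$psa_trials))
  invisible(x)
}

#' Read a parameter fixture
#'
#' Loads a run configuration plus one `strategy_spec` per strategy from a
#' fixture directory holding `transitions.csv` (strategy, from, to, mean_p,
#' lcl, ucl, alpha, beta, source_label), `utilities.csv` (state, tariff,
#' mean_u, lcl, ucl), `costs.csv` (state, component, mean_annual, lcl,
#' ucl), `ert_dosing.csv` (state, vials_per_year, lcl, ucl) and
#' `start_distribution.csv` (strategy, state, fraction). Utility, cost and
#' dosing tables are shared across strategies (treated and untreated
#' patients are assumed to have equal utilities and non-ERT costs within a
#' disease state). Missing beta shapes are fitted from the confidence
#' limits with [fit_beta_from_ci] where limits are available.
#'
#' @param config_path Path to a YAML file whose top-level keys mirror
#'   [model_config] arguments, plus an optional `strategies:` block with
#'   per-strategy scalars (`malignancy_excess_mortality`,
#'   `ert_vial_unit_cost`, `ert_cost_multiplier`).
#' @param fixture_dir Directory with the five CSV files.
#' @return A list with elements `config` (a `model_config`) and
#'   `strategies` (named list of `strategy_spec`).
#' @seealso [write_parameters()] for the inverse, [gaucher_fixture()] for
#'   the packaged fixture.
#' @export
load_parameters <- function(config_path, fixture_dir) {
  if (!file.exists(config_path)) {
    stop(sprintf("config file not found: %s", config_path), call. = FALSE)
  }
  raw <- yaml::read_yaml(config_path)
  strat_conf <- raw$strategies
  raw$strategies <- NULL
  if (!is.null(raw$wtp_max)) {
    step <- if (is.null(raw$wtp_step)) 1e4 else raw$wtp_step
    raw$wtp_grid <- seq(0, raw$wtp_max, by = step)
    raw$wtp_max <- raw$wtp_step <- NULL
  }
  known <- names(formals(model_config))
  config <- do.call(model_config, raw[intersect(names(raw), known)])

  read_fix <- function(name) {
    path <- file.path(fixture_dir, name)
    if (!file.exists(path)) {
      stop(sprintf("fixture file not found: %s", path), call. = FALSE)
    }
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  tr <- read_fix("transitions.csv")
  ut <- read_fix("utilities.csv")
  co <- read_fix("costs.csv")
  ed <- read_fix("ert_dosing.csv")
  sd <- read_fix("start_distribution.csv")

  if (!all(c("alpha", "beta") %in% names(tr))) tr$alpha <- tr$beta <- NA_real_
  fit_needed <- which(is.na(tr$alpha) & !is.na(tr$lcl) & !is.na(tr$ucl) &
                        tr$mean_p > 0 & tr$mean_p < 1)
  for (i in fit_needed) {
    f <- fit_beta_from_ci(tr$mean_p[i], tr$lcl[i], tr$ucl[i])
    tr$alpha[i] <- f$alpha
    tr$beta[i] <- f$beta
  }

  strategies <- list()
  for (lab in unique(tr$strategy)) {
    sdl <- sd[sd$strategy == lab, ]
    if (nrow(sdl) == 0L) {
      stop(sprintf("no start_distribution rows for strategy '%s'", lab),
           call. = FALSE)
    }
    sc <- if (!is.null(strat_conf)) strat_conf[[lab]] else NULL
    strategies[[lab]] <- strategy_spec(
      label = lab,
      transitions = tr[tr$strategy == lab,
                       setdiff(names(tr), "strategy"), drop = FALSE],
      utilities = ut,
      costs = co,
      ert_dosing = if (lab == "no_ert") NULL else ed,
      start_distribution = stats::setNames(sdl$fraction, sdl$state),
      malignancy_excess_mortality =
        if (!is.null(sc$malignancy_excess_mortality))
          sc$malignancy_excess_mortality else 0,
      ert_vial_unit_cost =
        if (!is.null(sc$ert_vial_unit_cost)) sc$ert_vial_unit_cost else 1985,
      ert_cost_multiplier =
        if (!is.null(sc$ert_cost_multiplier)) sc$ert_cost_multiplier else 1)
  }
  list(config = config, strategies = strategies)
}

#' Write strategy specs to a fixture directory
#'
#' Inverse of [load_parameters]: serializes a named list of
#' `strategy_spec` objects to the five fixture CSVs so that loading them
#' back reproduces the parameter values exactly.
#'
#' @param strategies Named list of `strategy_spec` objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_parameters <- function(strategies, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  first <- strategies[[1]]

  tr <- do.call(rbind, lapply(strategies, function(s) {
    cbind(strategy = s$label, s$transitions)
  }))
  for (col in c("lcl", "ucl", "alpha", "beta", "source_label")) {
    if (!col %in% names(tr)) tr[[col]] <- NA
  }
  utils::write.csv(tr, file.path(dir, "transitions.csv"), row.names = FALSE)
  utils::write.csv(first$utilities, file.path(dir, "utilities.csv"),
                   row.names = FALSE)
  utils::write.csv(first$costs, file.path(dir, "costs.csv"),
                   row.names = FALSE)
  ed <- NULL
  for (s in strategies) if (!is.null(s$ert_dosing)) ed <- s$ert_dosing
  if (is.null(ed)) {
    ed <- data.frame(state = character(), vials_per_year = numeric(),
                     lcl = numeric(), ucl = numeric())
  }
  utils::write.csv(ed, file.path(dir, "ert_dosing.csv"), row.names = FALSE)
  sd <- do.call(rbind, lapply(strategies, function(s) {
    data.frame(strategy = s$label,
               state = names(s$start_distribution),
               fraction = unname(s$start_distribution))
  }))
  utils::write.csv(sd, file.path(dir, "start_distribution.csv"),
                   row.names = FALSE)
  invisible(dir)
}
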