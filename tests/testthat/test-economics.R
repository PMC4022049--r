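test_that("discounting follows the cycle-start convention", {
  expect_equal(discounted_sum(c(2, 3, 4), 0), 9)
  expect_equal(discounted_sum(c(1, 1, 1), 0.04),
               1 + 1 / 1.04 + 1 / 1.04^2, tolerance = 1e-12)
  expect_error(discounted_sum(1:3, -0.1), "non-negative")
  # discounted never exceeds undiscounted for non-negative streams
  set.seed(81)
  s <- runif(20, 0, 5)
  expect_lte(discounted_sum(s, 0.04), sum(s))
})

test_that("trivial cohorts give closed-form lifetime outcomes", {
  cfg <- model_config()
  idle <- toy_strategy(u = 0.93)
  trace <- run_cohort(idle, cfg, flat_life_table(0))
  expect_equal(yfeod_from_trace(trace), 85)
  expect_equal(qalys_from_trace(trace, idle), 85 * 0.93)

  # a cohort starting (and stuck) in splenectomy accrues no YFEOD
  stuck <- toy_strategy(start = c(splenectomy = 1))
  tr2 <- run_cohort(stuck, cfg, flat_life_table(0))
  expect_equal(yfeod_from_trace(tr2), 0)

  # a cohort dying after its first cycle accrues one cycle of utility
  dead <- toy_strategy(start = c(malignancy = 1), excess = 1)
  dead$utilities$mean_u[dead$utilities$state == "malignancy"] <- 0.15
  tr3 <- run_cohort(dead, cfg, flat_life_table(0))
  expect_equal(tr3[2, "dead"], 1)
  expect_equal(qalys_from_trace(tr3, dead), 0.15)
  expect_equal(yfeod_from_trace(tr3), 0)
})

test_that("costing applies component rules per state, arm and scenario", {
  cfg <- model_config()
  asympt <- toy_strategy(hospital = 1470)
  trace <- run_cohort(asympt, cfg, flat_life_table(0))
  expect_equal(costs_from_trace(trace, asympt, scenario_spec(), cfg),
               85 * 1470)

  # ERT multiplier 0 removes exactly the medication component
  ert <- strategy_spec("ert_base",
                       data.frame(from = "asymptomatic",
                                  to = "signs_symptoms", mean_p = 0.2),
                       toy_utilities(), toy_costs(hospital = 1000),
                       ert_dosing = data.frame(state = "signs_symptoms",
                                               vials_per_year = 76))
  tre <- run_cohort(ert, cfg, flat_life_table(0))
  no_med <- ert
  no_med$ert_dosing <- NULL
  expect_equal(
    costs_from_trace(tre, ert, scenario_spec(ert_cost_multiplier = 0), cfg),
    costs_from_trace(tre, no_med, scenario_spec(), cfg))
  # and the multiplier is monotone in ERT-arm costs
  c_half <- costs_from_trace(tre, ert,
                             scenario_spec(ert_cost_multiplier = 0.5), cfg)
  c_full <- costs_from_trace(tre, ert, scenario_spec(), cfg)
  expect_lt(c_half, c_full)

  # production loss only accrues inside the productive age window
  prod <- toy_strategy(start = c(splenectomy = 1))
  prod$costs$mean_annual[prod$costs$component == "production_loss" &
                           prod$costs$state == "splenectomy"] <- 13698
  trp <- run_cohort(prod, cfg, flat_life_table(0))
  base_cost <- costs_from_trace(trp, prod, scenario_spec(), cfg)
  with_pl <- costs_from_trace(
    trp, prod, scenario_spec(include_production_loss = TRUE), cfg)
  expect_equal(with_pl - base_cost, 40 * 13698) # ages 25..64 inclusive
})

test_that("ICERs satisfy the ratio identity and dominance rules", {
  mk <- function(y, q, c) data.frame(strategy = "x", scenario = "base",
                                     discounted = FALSE, yfeod = y,
                                     qalys = q, costs = c)
  r <- icer(mk(12, 2, 200), mk(10, 0, 100))
  expect_equal(r$icer_per_qaly, 50)
  expect_equal(r$icer_per_yfeod, 50)
  expect_equal(r$icer_per_qaly, r$delta_costs / r$delta_qalys,
               tolerance = 1e-9)
  expect_equal(r$dominance, "none")

  expect_equal(icer(mk(1, 1, -10), mk(0, 0, 0))$dominance, "dominant")
  expect_equal(icer(mk(0, -1, 10), mk(0, 0, 0))$dominance, "dominated")
  expect_true(is.na(icer(mk(5, 1, 50), mk(5, 1, 20))$icer_per_yfeod))
})

test_that("scenario runs respect their levers", {
  sc_base <- run_scenario(fx$scenarios$base, fx$strategies, fx$config,
                          fx$life_table)
  same <- run_scenario(scenario_spec("ert_cost_reduction",
                                     ert_cost_multiplier = 1),
                       fx$strategies, fx$config, fx$life_table)
  expect_equal(same$incremental$undiscounted$delta_costs,
               sc_base$incremental$undiscounted$delta_costs)

  red <- run_scenario(fx$scenarios$ert_cost_reduction, fx$strategies,
                      fx$config, fx$life_table)
  expect_lt(red$incremental$undiscounted$icer_per_qaly,
            sc_base$incremental$undiscounted$icer_per_qaly)
  # effects are untouched by the price lever
  expect_equal(red$incremental$undiscounted$delta_qalys,
               sc_base$incremental$undiscounted$delta_qalys)

  pl <- run_scenario(fx$scenarios$production_loss, fx$strategies,
                     fx$config, fx$life_table)
  base_noert <- sc_base$summaries[sc_base$summaries$strategy == "no_ert" &
                                    !sc_base$summaries$discounted, ]
  pl_noert <- pl$summaries[pl$summaries$strategy == "no_ert" &
                             !pl$summaries$discounted, ]
  expect_gt(pl_noert$costs, base_noert$costs)
  expect_equal(pl_noert$yfeod, base_noert$yfeod)

  expect_error(run_scenario(scenario_spec("historical_I",
                                          ert_strategy = "ert_historical"),
                            fx$strategies, fx$config, fx$life_table),
               "start distribution")

  # discounted totals never exceed undiscounted ones
  s <- sc_base$summaries
  for (arm in unique(s$strategy)) {
    expect_lte(s$yfeod[s$strategy == arm & s$discounted],
               s$yfeod[s$strategy == arm & !s$discounted])
    expect_lte(s$costs[s$strategy == arm & s$discounted],
               s$costs[s$strategy == arm & !s$discounted])
  }
})

test_that("tariff choice moves QALYs only; utilities act monotonically", {
  cfg <- fx$config
  s <- fx$strategies$no_ert
  trace <- run_cohort(s, cfg, fx$life_table)
  uk <- outcome_summary(trace, s, cfg, tariff = "UK")
  nl <- outcome_summary(trace, s, cfg, tariff = "NL")
  expect_equal(uk$yfeod, nl$yfeod)
  expect_equal(uk$costs, nl$costs)
  expect_false(isTRUE(all.equal(uk$qalys, nl$qalys)))

  bumped <- s
  i <- which(bumped$utilities$state == "splenectomy" &
               bumped$utilities$tariff == "UK")
  bumped$utilities$mean_u[i] <- bumped$utilities$mean_u[i] + 0.05
  expect_gte(qalys_from_trace(trace, bumped, "UK"),
             qalys_from_trace(trace, s, "UK"))
})
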