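make_episodes <- function(time, event, state = "signs_symptoms") {
  data.frame(patient_id = seq_along(time), state = state,
             start_age = 20, end_age = 20 + time, end_event = event)
}

test_that("cumulative incidence reduces to the empirical CDF without competition", {
  ep <- make_episodes(c(1, 2, 3, 4, 6, 6, 6, 6, 6, 6),
                      c(rep("transition_to:splenectomy", 4),
                        rep("censored", 6)))
  cv <- cumulative_incidence_competing(ep, "signs_symptoms", "splenectomy")
  expect_equal(max(cv$cif), 0.4, tolerance = 1e-12)
  expect_true(all(diff(cv$cif) >= -1e-12))
})

test_that("competing events reduce the cause-specific cumulative incidence", {
  # 10 at risk; year 1: one competing event; year 2: one event of interest.
  # Hand oracle: CIF_interest(2) = (9/10) * (1/9) = 0.10.
  ep <- make_episodes(c(1, 2, rep(3, 8)),
                      c("transition_to:bone_complication",
                        "transition_to:splenectomy",
                        rep("censored", 8)))
  cv <- cumulative_incidence_competing(ep, "signs_symptoms", "splenectomy")
  expect_equal(cv$cif[cv$time == 2], 0.9 * (1 / 9), tolerance = 1e-12)

  # all censored: identically zero
  ep0 <- make_episodes(rep(5, 6), rep("censored", 6))
  cv0 <- cumulative_incidence_competing(ep0, "signs_symptoms", "splenectomy")
  expect_true(all(cv0$cif == 0))

  expect_error(cumulative_incidence_competing(ep, "malignancy",
                                              "splenectomy"),
               "no episodes")
})

test_that("destination incidences and the event-free fraction conserve mass", {
  set.seed(31)
  n <- 60
  time <- round(rexp(n, 0.3), 2) + 0.1
  event <- sample(c("transition_to:splenectomy",
                    "transition_to:bone_complication", "death", "censored"),
                  n, replace = TRUE)
  ep <- make_episodes(time, event)
  dests <- c("splenectomy", "bone_complication", "dead")
  curves <- lapply(dests, function(d) {
    cumulative_incidence_competing(ep, "signs_symptoms", d)
  })
  total <- Reduce(`+`, lapply(curves, function(cv) cv$cif))
  expect_equal(total + attr(curves[[1]], "event_free"),
               rep(1, length(total)), tolerance = 1e-9)
})

test_that("competing-risk curves agree with an independent implementation", {
  skip_if_not_installed("cmprsk")
  set.seed(32)
  n <- 80
  time <- rexp(n, 0.25) + 0.05 # continuous times, no ties
  event <- sample(c("transition_to:splenectomy", "death", "censored"), n,
                  replace = TRUE, prob = c(0.4, 0.3, 0.3))
  ep <- make_episodes(time, event)
  cv <- cumulative_incidence_competing(ep, "signs_symptoms", "splenectomy")
  code <- ifelse(event == "censored", 0, ifelse(event == "death", 2, 1))
  ci <- cmprsk::cuminc(time, code, cencode = 0)
  ref <- stats::stepfun(ci$`1 1`$time, c(0, ci$`1 1`$est))
  # cuminc reports staircase coordinates; read just past each jump
  expect_equal(cv$cif, ref(cv$time + 1e-9), tolerance = 1e-8)
})

test_that("the reading rule picks the median crossing or the 4-at-risk point", {
  curve <- structure(
    data.frame(time = 1:10,
               cif = c(0.05, 0.1, 0.2, 0.3, 0.42, 0.55, 0.6, 0.62, 0.63,
                       0.63),
               n_risk = c(20, 18, 16, 14, 12, 10, 8, 6, 4, 3)),
    class = c("cif_curve", "data.frame"))
  ts <- transition_summary(curve)
  expect_equal(ts$rule, "median")
  expect_equal(ts$p_cum, 0.5)
  expect_equal(ts$t_ref, 6)

  flat <- curve
  flat$cif <- c(0.05, 0.1, 0.15, 0.2, 0.22, 0.25, 0.27, 0.29, 0.30, 0.30)
  ts2 <- transition_summary(flat)
  expect_equal(ts2$rule, "at_risk")
  expect_equal(ts2$t_ref, 9)
  expect_equal(ts2$p_cum, 0.30)

  zero <- curve
  zero$cif <- 0
  ts3 <- transition_summary(zero)
  expect_equal(ts3$p_cum, 0)
  expect_equal(annualize_transition(ts3$p_cum, ts3$t_ref), 0)

  tiny <- flat # never crosses 0.5
  tiny$n_risk <- 3
  expect_equal(transition_summary(tiny)$rule, "insufficient")
})

test_that("the Markov correction inverts multi-year compounding exactly", {
  expect_equal(annualize_transition(0, 7), 0)
  expect_equal(annualize_transition(0.75, 2), 0.5, tolerance = 1e-12)
  expect_equal(annualize_transition(0.5, 3), 1 - 0.5^(1 / 3),
               tolerance = 1e-12)
  expect_warning(p1 <- annualize_transition(1, 5), "instantaneous")
  expect_equal(p1, 1)
  expect_error(annualize_transition(0.5, 0), "positive")

  set.seed(41)
  P <- runif(1000, 0, 0.999)
  t <- runif(1000, 0.2, 40)
  p <- annualize_transition(P, t)
  expect_equal(1 - (1 - p)^t, P, tolerance = 1e-12)
  expect_equal(annualize_linear(0.3, 6), 0.05)
})

test_that("state utilities use two-stage averaging over patients", {
  rec <- data.frame(patient_id = 1, age = 30,
                    state_at_observation = "splenectomy",
                    utility = c(0.8, 0.9), tariff = "UK")
  r <- mean_state_utility(rec, "splenectomy", bootstrap_reps = 50)
  expect_equal(r$mean_u, 0.85)
  expect_false(r$ci_available)

  rec2 <- rbind(
    data.frame(patient_id = 1, age = 30,
               state_at_observation = "splenectomy",
               utility = rep(0.8, 10), tariff = "UK"),
    data.frame(patient_id = 2, age = 30,
               state_at_observation = "splenectomy",
               utility = rep(0.9, 2), tariff = "UK"))
  r2 <- mean_state_utility(rec2, "splenectomy", bootstrap_reps = 500)
  expect_equal(r2$mean_u, 0.85) # not the pooled-observation mean 0.8167

  # duplicating one patient's observations leaves the mean unchanged
  dup <- rbind(rec2, rec2[rec2$patient_id == 1, ])
  expect_equal(mean_state_utility(dup, "splenectomy",
                                  bootstrap_reps = 50)$mean_u, 0.85)
})

test_that("BCa intervals cover the truth in repeated simulations", {
  set.seed(43)
  hits <- 0L
  for (i in 1:40) {
    pats <- 25
    pm <- rnorm(pats, 0.8, 0.05)
    rec <- data.frame(patient_id = rep(seq_len(pats), each = 3),
                      age = 30, state_at_observation = "splenectomy",
                      utility = rep(pm, each = 3) + rnorm(3 * pats, 0, 0.02),
                      tariff = "UK")
    r <- mean_state_utility(rec, "splenectomy", bootstrap_reps = 400)
    if (r$lcl <= 0.8 && 0.8 <= r$ucl) hits <- hits + 1L
  }
  expect_gte(hits, 32L) # ~95% nominal; allow Monte Carlo slack
})

test_that("ERT dosing is episode-weighted, then averaged over patients", {
  one <- data.frame(patient_id = 1, state = "signs_symptoms",
                    episode_start_age = 20, episode_end_age = 22,
                    vials_per_month = 6)
  r <- annual_ert_cost(one, "signs_symptoms")
  expect_equal(r$vials_per_year, 72)
  expect_equal(r$annual_cost, 72 * 1985)

  split <- data.frame(patient_id = 1, state = "signs_symptoms",
                      episode_start_age = c(20, 20.5),
                      episode_end_age = c(20.5, 21),
                      vials_per_month = c(4, 8))
  expect_equal(annual_ert_cost(split, "signs_symptoms")$annual_cost,
               72 * 1985)

  # a cross-patient mean of ~76.14 vials/year prices at ~151,147 euro
  mean76 <- data.frame(patient_id = 1:2, state = "signs_symptoms",
                       episode_start_age = 20, episode_end_age = 21,
                       vials_per_month = c(70, 82.2893) / 12)
  expect_equal(annual_ert_cost(mean76, "signs_symptoms")$annual_cost,
               151147, tolerance = 1)

  zero_len <- data.frame(patient_id = 1:2, state = "signs_symptoms",
                         episode_start_age = 20,
                         episode_end_age = c(21, 20),
                         vials_per_month = c(6, 99))
  expect_warning(rz <- annual_ert_cost(zero_len, "signs_symptoms"),
                 "zero total")
  expect_equal(rz$vials_per_year, 72)
})

test_that("hospital costs are product-sums annualized per patient then averaged", {
  ep <- data.frame(patient_id = 1, state = "splenectomy", start_age = 30,
                   end_age = 31, end_event = "censored")
  pr <- data.frame(patient_id = 1, age = 30.5, state = "splenectomy",
                   unit_cost = c(500, 970), count = 1)
  expect_equal(annual_hospital_cost(pr, ep, "splenectomy")$mean_annual, 1470)

  ep2 <- ep; ep2$end_age <- 32
  pr2 <- data.frame(patient_id = 1, age = 31, state = "splenectomy",
                    unit_cost = 2000, count = 1)
  expect_equal(annual_hospital_cost(pr2, ep2, "splenectomy")$mean_annual,
               1000)

  # brute-force double-mean oracle on a random multi-patient set
  set.seed(51)
  n <- 12
  ep3 <- data.frame(patient_id = 1:n, state = "splenectomy", start_age = 30,
                    end_age = 30 + runif(n, 0.5, 4), end_event = "censored")
  pr3 <- data.frame(patient_id = sample(1:n, 40, replace = TRUE),
                    age = 31, state = "splenectomy",
                    unit_cost = runif(40, 10, 900),
                    count = sample(1:3, 40, replace = TRUE))
  fu <- ep3$end_age - ep3$start_age
  per <- vapply(1:n, function(i) {
    sum(pr3$unit_cost[pr3$patient_id == i] * pr3$count[pr3$patient_id == i]) /
      fu[i]
  }, numeric(1))
  expect_equal(annual_hospital_cost(pr3, ep3, "splenectomy")$mean_annual,
               mean(per), tolerance = 1e-12)
})

test_that("out-of-hospital costs annualize quarterly volumes by a factor 4", {
  one <- data.frame(patient_id = 1, age = 30, state = "signs_symptoms",
                    visits = 1, unit_cost = 28)
  expect_equal(annual_outpatient_cost(one, "signs_symptoms")$mean_annual,
               112)
  none <- data.frame(patient_id = 1:3, age = 30, state = "signs_symptoms",
                     visits = 0, unit_cost = 28)
  expect_equal(annual_outpatient_cost(none, "signs_symptoms")$mean_annual, 0)

  set.seed(52)
  many <- data.frame(patient_id = sample(1:6, 40, replace = TRUE),
                     age = 30, state = "signs_symptoms",
                     visits = rpois(40, 2), unit_cost = runif(40, 20, 90))
  oracle <- mean(tapply(many$visits * many$unit_cost, many$patient_id,
                        mean) * 4)
  expect_equal(annual_outpatient_cost(many, "signs_symptoms")$mean_annual,
               oracle, tolerance = 1e-12)
})

test_that("production loss follows the human-capital rules", {
  base <- data.frame(patient_id = 1:3, state = "splenectomy",
                     employed = c(TRUE, FALSE, FALSE),
                     disabled_due_to_gd = c(FALSE, FALSE, TRUE),
                     hours_per_workday = c(8, NA, NA),
                     workdays_per_week = c(5, NA, NA),
                     sick_days_per_fortnight = c(1, 0, 0))
  r <- annual_production_loss(base, "splenectomy")
  # employed: 1 day/fortnight * 26 * 8 h * 30 euro = 6,240
  # disabled: 52 weeks * 5 d * 8 h * 30 euro = 62,400; other: 0
  expect_equal(r$mean_annual, mean(c(6240, 0, 62400)))

  not_working <- base[2, ]
  expect_equal(annual_production_loss(not_working, "splenectomy",
                                      hourly_cost = 30)$mean_annual, 0)
})

test_that("calibrate flags missing data instead of fabricating zeros", {
  empty <- list(
    episodes = data.frame(patient_id = integer(), state = character(),
                          start_age = numeric(), end_age = numeric(),
                          end_event = character()),
    eq5d = data.frame(patient_id = integer(), age = numeric(),
                      state_at_observation = character(),
                      utility = numeric(), tariff = character()),
    doses = data.frame(patient_id = integer(), state = character(),
                       episode_start_age = numeric(),
                       episode_end_age = numeric(),
                       vials_per_month = numeric()),
    procedures = data.frame(patient_id = integer(), age = numeric(),
                            state = character(), unit_cost = numeric(),
                            count = integer()),
    outpatient = data.frame(patient_id = integer(), age = numeric(),
                            state = character(), visits = integer(),
                            unit_cost = numeric()),
    work = data.frame(patient_id = integer(), state = character(),
                      employed = logical(), disabled_due_to_gd = logical(),
                      hours_per_workday = numeric(),
                      workdays_per_week = numeric(),
                      sick_days_per_fortnight = numeric()))
  cal <- calibrate(empty, bootstrap_reps = 10)
  expect_equal(nrow(cal$transitions), 0L)
  expect_true(all(is.na(cal$utilities$mean_u)))
  expect_true(all(is.na(cal$costs$mean_annual)))

  single <- empty
  single$episodes <- data.frame(patient_id = 1, state = "signs_symptoms",
                                start_age = 20, end_age = 25,
                                end_event = "censored")
  single$eq5d <- data.frame(patient_id = 1, age = 21,
                            state_at_observation = "signs_symptoms",
                            utility = c(0.8, 0.9), tariff = "UK")
  cal1 <- calibrate(single, bootstrap_reps = 10, tariffs = "UK")
  row <- cal1$utilities[cal1$utilities$state == "signs_symptoms", ]
  expect_equal(row$mean_u, 0.85)
  expect_false(row$ci_available)
})
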