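#' Specify a synthetic registry cohort
#'
#' Describes a simulated patient registry with known ground truth, used to
#' exercise and validate the whole calibration-to-model pipeline without
#' any real patient data. Patients enter the registry at a random integer
#' age, in a disease state drawn from `entry_state_probs` (a prevalent-mix
#' registry, as when a national cohort is enrolled at the moment a therapy
#' becomes available), and are then followed for `follow_up_years` under
#' the annual transition probabilities of `truth`, with background
#' mortality from `life_table` plus the malignancy excess. Event times are
#' jittered uniformly within their cycle year so that observed episode
#' durations are real-valued.
#'
#' @param n_patients Number of patients.
#' @param truth A [strategy_spec] providing the generating transition
#'   probabilities, utilities, costs and dosing.
#' @param follow_up_years Administrative censoring horizon (years).
#' @param eq5d_noise_sd SD of the observation noise added to the state
#'   mean utility (clipped to the tariff range).
#' @param obs_rate Probability that a scheduled quarterly EQ-5D
#'   observation is actually completed.
#' @param dose_cv Between-patient coefficient of variation (log scale) of
#'   the vials-per-month rate.
#' @param p_employed Probability a patient in a state has paid work.
#' @param censoring_rate Fraction of patients censored uniformly before
#'   the end of follow-up (loss to follow-up).
#' @param entry_state_probs Named probabilities over alive states for the
#'   state at registry entry; recovery mass is moved to signs/symptoms
#'   when `truth` has no path into recovery.
#' @param entry_age_range Integer age range at entry (inclusive).
#' @param life_table Background mortality; defaults to the synthetic
#'   schedule of [make_synthetic_life_table].
#' @param seed RNG seed.
#' @return A list of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_patients,
                                  truth,
                                  follow_up_years = 20,
                                  eq5d_noise_sd = 0.05,
                                  obs_rate = 0.95,
                                  dose_cv = 0.3,
                                  p_employed = 0.6,
                                  censoring_rate = 0.1,
                                  entry_state_probs = c(
                                    asymptomatic = 0.18,
                                    signs_symptoms = 0.22,
                                    recovery = 0.10,
                                    splenectomy = 0.14,
                                    bone_complication = 0.14,
                                    multiple_complications = 0.14,
                                    malignancy = 0.08),
                                  entry_age_range = c(10L, 50L),
                                  life_table = make_synthetic_life_table(),
                                  seed = 1L) {
  stopifnot(inherits(truth, "strategy_spec"),
            n_patients >= 0, follow_up_years > 0,
            eq5d_noise_sd >= 0, obs_rate >= 0, obs_rate <= 1,
            censoring_rate >= 0, censoring_rate <= 1)
  assert_states(names(entry_state_probs), "entry state")
  if (!any(truth$transitions$to == "recovery" & truth$transitions$mean_p > 0) &&
      "recovery" %in% names(entry_state_probs)) {
    entry_state_probs["signs_symptoms"] <-
      entry_state_probs["signs_symptoms"] + entry_state_probs["recovery"]
    entry_state_probs <- entry_state_probs[names(entry_state_probs) != "recovery"]
  }
  entry_state_probs <- entry_state_probs / sum(entry_state_probs)
  structure(list(n_patients = as.integer(n_patients), truth = truth,
                 follow_up_years = follow_up_years,
                 eq5d_noise_sd = eq5d_noise_sd, obs_rate = obs_rate,
                 dose_cv = dose_cv, p_employed = p_employed,
                 censoring_rate = censoring_rate,
                 entry_state_probs = entry_state_probs,
                 entry_age_range = as.integer(entry_age_range),
                 life_table = life_table, seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

# Internal costing constants linking truth cost tables to record-level
# generating processes (cost per hospital procedure, per out-of-hospital
# visit, productivity valuation). Shared with truth_report.
SYNTH_PROC_UNIT <- 35   # euro per hospital procedure
SYNTH_VISIT_UNIT <- 35  # euro per out-of-hospital visit
SYNTH_HOURLY <- 30      # euro per hour of lost production
SYNTH_HOURS_PER_DAY <- 8
SYNTH_DAYS_PER_WEEK <- 5

# Per-state work profile implied by a truth production-loss cost: half the
# cost from sick leave among the employed, half from permanent
# GD-attributable work disability.
synth_work_profile <- function(cost, p_employed) {
  fte_loss <- 52 * SYNTH_DAYS_PER_WEEK * SYNTH_HOURS_PER_DAY * SYNTH_HOURLY
  sick_unit <- 26 * SYNTH_HOURS_PER_DAY * SYNTH_HOURLY
  if (cost <= 0) {
    return(list(p_disabled = 0, sick_days = 0))
  }
  list(p_disabled = min(0.9, 0.5 * cost / fte_loss),
       sick_days = min(13, 0.5 * cost / (p_employed * sick_unit)))
}

#' Simulate a patient-level registry
#'
#' Generates the six registry record sets the calibration consumes:
#' state episodes, quarterly EQ-5D utilities (UK and NL tariffs), ERT dose
#' episodes, hospital procedure logs, quarterly out-of-hospital visit
#' counts, and per-state work/sick-leave records. All randomness is
#' governed by `spec$seed`; the same spec reproduces the same registry.
#'
#' @param spec A [synthetic_cohort_spec].
#' @return A list of class `synthetic_registry` with data frames
#'   `episodes`, `eq5d`, `doses`, `procedures`, `outpatient`, `work`, and
#'   the generating `truth` echoed back.
#' @export
simulate_registry <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  set.seed(spec$seed)
  truth <- spec$truth
  states <- gd_states()

  # annual disease transition probability matrix (alive rows)
  p <- matrix(0, 8L, 8L, dimnames = list(states, states))
  tr <- truth$transitions
  p[cbind(state_index(tr$from), state_index(tr$to))] <- tr$mean_p
  out <- rowSums(p)
  if (any(out > 1)) p[out > 1, ] <- p[out > 1, , drop = FALSE] / out[out > 1]

  u_mean <- list(
    UK = tryCatch(utility_vector(truth, "UK"), error = function(e) NULL),
    NL = tryCatch(utility_vector(truth, "NL"), error = function(e) NULL))
  dose_rate <- stats::setNames(numeric(8L), states) # vials/month
  if (!is.null(truth$ert_dosing) && truth$label != "no_ert") {
    dose_rate[truth$ert_dosing$state] <- truth$ert_dosing$vials_per_year / 12
  }
  cost_of <- function(component) {
    rows <- truth$costs[truth$costs$component == component, ]
    v <- stats::setNames(numeric(8L), states)
    v[rows$state] <- rows$mean_annual
    v
  }
  hosp_cost <- cost_of("hospital")
  outp_cost <- cost_of("out_of_hospital")
  prod_cost <- cost_of("production_loss")
  proc_rate <- hosp_cost / SYNTH_PROC_UNIT      # procedures / year
  visit_rate <- outp_cost / SYNTH_VISIT_UNIT / 4 # visits / quarter

  episodes <- list(); eq5d <- list(); doses <- list()
  procedures <- list(); outpatient <- list(); work <- list()

  n <- spec$n_patients
  if (n > 0L) {
    entry_age <- sample(seq.int(spec$entry_age_range[1],
                                spec$entry_age_range[2]), n, replace = TRUE)
    entry_state <- sample(names(spec$entry_state_probs), n, replace = TRUE,
                          prob = spec$entry_state_probs)
    cens <- rep(spec$follow_up_years, n)
    lost <- stats::runif(n) < spec$censoring_rate
    cens[lost] <- stats::runif(sum(lost), 0, spec$follow_up_years)
    dose_mult <- stats::rlnorm(n, meanlog = -spec$dose_cv^2 / 2,
                               sdlog = spec$dose_cv)
  }

  for (i in seq_len(n)) {
    s <- state_index(entry_state[i])
    t_start <- 0 # years since registry entry, start of current episode
    repeat {
      # annual cycles measured from state entry, so that every entrant
      # into a state faces the same sojourn-time law; the event is placed
      # uniformly within its cycle year
      ev <- NULL
      j <- 0L
      repeat {
        tj <- t_start + j # start of the (j+1)-th year in the state
        if (tj >= cens[i]) { ev <- list(type = "censored"); break }
        age <- floor(entry_age[i] + tj)
        q <- life_table_q(spec$life_table, age)
        if (states[s] == "malignancy") {
          q <- min(1, q + truth$malignancy_excess_mortality)
        }
        r <- stats::runif(1)
        if (r < q) {
          ev <- list(type = "death", time = tj + stats::runif(1))
          break
        }
        r2 <- stats::runif(1)
        cp <- cumsum(p[s, ])
        if (r2 < cp[8L]) {
          dest <- findInterval(r2, cp, left.open = TRUE) + 1L
          ev <- list(type = "transition", dest = dest,
                     time = tj + stats::runif(1))
          break
        }
        j <- j + 1L
      }
      t_end <- switch(ev$type,
                      censored = cens[i],
                      min(ev$time, cens[i]))
      if (t_end <= t_start) t_end <- t_start + 1e-6
      censored_here <- ev$type == "censored" || ev$time > cens[i]
      end_event <- if (censored_here) {
        "censored"
      } else if (ev$type == "death") {
        "death"
      } else {
        paste0("transition_to:", states[ev$dest])
      }
      episodes[[length(episodes) + 1L]] <- data.frame(
        patient_id = i, state = states[s],
        start_age = entry_age[i] + t_start, end_age = entry_age[i] + t_end,
        end_event = end_event)

      # quarterly EQ-5D observations during the episode
      first_q <- ceiling(t_start * 4) / 4
      qt <- if (first_q <= t_end - 1e-9) {
        seq(first_q, t_end - 1e-9, by = 0.25)
      } else {
        numeric(0)
      }
      if (length(qt) > 0L && spec$obs_rate > 0) {
        seen <- stats::runif(length(qt)) < spec$obs_rate
        qt <- qt[seen]
        for (tar in c("UK", "NL")) {
          um <- u_mean[[tar]]
          if (!is.null(um) && length(qt) > 0L) {
            uu <- pmin(pmax(um[s] + stats::rnorm(length(qt),
                                                 sd = spec$eq5d_noise_sd),
                            UTILITY_FLOOR), 1)
            eq5d[[length(eq5d) + 1L]] <- data.frame(
              patient_id = i, age = entry_age[i] + qt,
              state_at_observation = states[s], utility = uu, tariff = tar)
          }
        }
        # out-of-hospital visit counts share the quarterly schedule
        if (length(qt) > 0L) {
          outpatient[[length(outpatient) + 1L]] <- data.frame(
            patient_id = i, age = entry_age[i] + qt,
            state = states[s],
            visits = stats::rpois(length(qt), visit_rate[s]),
            unit_cost = SYNTH_VISIT_UNIT)
        }
      }

      dur <- t_end - t_start
      if (proc_rate[s] > 0 && dur > 0) {
        cnt <- stats::rpois(1L, proc_rate[s] * dur)
        if (cnt > 0L) {
          procedures[[length(procedures) + 1L]] <- data.frame(
            patient_id = i, age = entry_age[i] + t_start + dur / 2,
            state = states[s], unit_cost = SYNTH_PROC_UNIT, count = cnt)
        }
      }

      if (dose_rate[s] > 0 && dur > 0) {
        # split into two dose episodes to exercise episode-length weighting
        cut <- t_start + dur * stats::runif(1, 0.3, 0.7)
        wig <- stats::runif(1, -0.1, 0.1)
        base <- dose_rate[s] * dose_mult[i]
        doses[[length(doses) + 1L]] <- data.frame(
          patient_id = i, state = states[s],
          episode_start_age = entry_age[i] + c(t_start, cut),
          episode_end_age = entry_age[i] + c(cut, t_end),
          vials_per_month = base * c(1 + wig, 1 - wig))
      }

      if (ev$type != "transition" || censored_here) break
      s <- ev$dest
      t_start <- ev$time
    }
  }

  # one work record per patient per visited state
  ep <- if (length(episodes) > 0L) {
    do.call(rbind, episodes)
  } else {
    data.frame(patient_id = integer(), state = character(),
               start_age = numeric(), end_age = numeric(),
               end_event = character())
  }
  if (nrow(ep) > 0L) {
    ps <- unique(ep[, c("patient_id", "state")])
    for (j in seq_len(nrow(ps))) {
      st <- ps$state[j]
      prof <- synth_work_profile(prod_cost[st], spec$p_employed)
      employed <- stats::runif(1) < spec$p_employed
      disabled <- !employed && stats::runif(1) < prof$p_disabled /
        max(1e-12, 1 - spec$p_employed)
      sick <- 0
      hrs <- NA_real_; days <- NA_real_
      if (employed) {
        hrs <- pmin(12, pmax(4, stats::rnorm(1, SYNTH_HOURS_PER_DAY, 0.5)))
        days <- SYNTH_DAYS_PER_WEEK
        jit <- min(prof$sick_days, 1)
        sick <- prof$sick_days + stats::runif(1, -jit, jit)
      }
      work[[length(work) + 1L]] <- data.frame(
        patient_id = ps$patient_id[j], state = st, employed = employed,
        disabled_due_to_gd = disabled, hours_per_workday = hrs,
        workdays_per_week = days, sick_days_per_fortnight = sick)
    }
  }

  bind <- function(lst, proto) {
    if (length(lst) == 0L) proto else do.call(rbind, lst)
  }
  structure(list(
    episodes = ep,
    eq5d = bind(eq5d, data.frame(patient_id = integer(), age = numeric(),
                                 state_at_observation = character(),
                                 utility = numeric(), tariff = character())),
    doses = bind(doses, data.frame(patient_id = integer(), state = character(),
                                   episode_start_age = numeric(),
                                   episode_end_age = numeric(),
                                   vials_per_month = numeric())),
    procedures = bind(procedures, data.frame(patient_id = integer(),
                                             age = numeric(),
                                             state = character(),
                                             unit_cost = numeric(),
                                             count = integer())),
    outpatient = bind(outpatient, data.frame(patient_id = integer(),
                                             age = numeric(),
                                             state = character(),
                                             visits = integer(),
                                             unit_cost = numeric())),
    work = bind(work, data.frame(patient_id = integer(), state = character(),
                                 employed = logical(),
                                 disabled_due_to_gd = logical(),
                                 hours_per_workday = numeric(),
                                 workdays_per_week = numeric(),
                                 sick_days_per_fortnight = numeric())),
    truth = truth), class = "synthetic_registry")
}

#' Ground-truth parameters in calibration-result form
#'
#' Returns the generating parameters of a synthetic cohort in the same
#' schema [calibrate] emits, for field-by-field recovery comparison.
#'
#' @param spec A [synthetic_cohort_spec].
#' @return A list of class `calibration_result` with the truth transition
#'   table, utilities, ERT dosing and per-state annual costs.
#' @export
truth_report <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  truth <- spec$truth
  structure(list(
    transitions = truth$transitions[, c("from", "to", "mean_p")],
    utilities = truth$utilities,
    ert_dosing = truth$ert_dosing,
    costs = truth$costs,
    diagnostics = NULL), class = "calibration_result")
}

#' Write / read a registry as CSV files
#'
#' @param registry A `synthetic_registry` (or compatible list of record
#'   data frames).
#' @param dir Directory for `episodes.csv`, `eq5d.csv`, `doses.csv`,
#'   `procedures.csv`, `outpatient.csv`, `work.csv`.
#' @return `write_registry` returns `dir` invisibly; `read_registry`
#'   returns the list of data frames.
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("episodes", "eq5d", "doses", "procedures", "outpatient",
               "work")) {
    utils::write.csv(registry[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_registry
#' @export
read_registry <- function(dir) {
  out <- lapply(c(episodes = "episodes", eq5d = "eq5d", doses = "doses",
                  procedures = "procedures", outpatient = "outpatient",
                  work = "work"),
                function(nm) {
                  utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                                  stringsAsFactors = FALSE)
                })
  class(out) <- "synthetic_registry"
  out
}
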