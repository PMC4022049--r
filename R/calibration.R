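#' Competing-risk cumulative incidence for one transition
#'
#' Estimates the cumulative incidence of moving from `from_state` to
#' `to_state` as a function of time since entering `from_state`,
#' accounting for competing destinations (including death) that preclude
#' the transition of interest. The estimator is the Aalen-Johansen
#' cumulative incidence function (the standard competing-risk correction
#' of Kaplan-Meier), computed through [survival::survfit] on the
#' multi-state endpoint; `naive_km = TRUE` instead returns the
#' complement of the single-endpoint Kaplan-Meier (which ignores
#' competing risks) for sensitivity comparison.
#'
#' @param episodes Data frame of episode records with columns
#'   `patient_id`, `state`, `start_age`, `end_age`, `end_event` (one of
#'   `"censored"`, `"death"`, `"transition_to:<state>"`).
#' @param from_state,to_state State labels.
#' @param naive_km Use 1 - KM instead of the competing-risk estimator.
#' @return A data frame of class `cif_curve` with columns `time` (years
#'   since state entry), `cif`, `n_risk`, plus attributes `from`, `to`,
#'   `n_patients` and `event_free` (the event-free fraction at each step).
#'   Zero rows if no episode ever leaves `from_state`.
#' @export
cumulative_incidence_competing <- function(episodes, from_state, to_state,
                                           naive_km = FALSE) {
  assert_states(c(from_state, to_state))
  ep <- episodes[episodes$state == from_state, , drop = FALSE]
  if (nrow(ep) == 0L) {
    stop(sprintf("no episodes start in state '%s'", from_state),
         call. = FALSE)
  }
  time <- ep$end_age - ep$start_age
  if (any(time < 0)) stop("episode with end_age < start_age", call. = FALSE)
  dest <- ifelse(ep$end_event == "censored", "censored",
                 ifelse(ep$end_event == "death", "dead",
                        sub("^transition_to:", "", ep$end_event)))
  if (naive_km) {
    status <- as.integer(dest == to_state)
    fit <- survival::survfit(survival::Surv(time, status) ~ 1)
    curve <- data.frame(time = fit$time, cif = 1 - fit$surv,
                        n_risk = fit$n.risk)
    ef <- fit$surv
  } else if (all(dest == "censored")) {
    # no events at all: the incidence curve is identically zero
    ord <- order(time)
    curve <- data.frame(time = time[ord], cif = 0,
                        n_risk = rev(seq_along(time)))
    return(structure(curve, class = c("cif_curve", "data.frame"),
                     from = from_state, to = to_state,
                     n_patients = length(unique(ep$patient_id)),
                     event_free = rep(1, length(time))))
  } else {
    lev <- c("censored", setdiff(unique(dest), "censored"))
    if (!to_state %in% lev) lev <- c(lev, to_state)
    evf <- factor(dest, levels = lev)
    fit <- survival::survfit(survival::Surv(time, evf) ~ 1)
    col <- match(to_state, fit$states)
    curve <- data.frame(time = fit$time,
                        cif = fit$pstate[, col],
                        n_risk = fit$n.risk[, 1L])
    ef <- fit$pstate[, match("(s0)", fit$states)]
  }
  structure(curve, class = c("cif_curve", "data.frame"),
            from = from_state, to = to_state,
            n_patients = length(unique(ep$patient_id)), event_free = ef)
}

#' Cumulative proportion and reference time from a CIF curve
#'
#' Applies the study's reading rule to a cumulative incidence curve: if
#' the curve reaches 50%, the cumulative proportion is 0.5 at the first
#' time it does (the median rule); otherwise the curve is read at the
#' last step at which at least `min_at_risk` patients are still at risk.
#'
#' @param curve A `cif_curve` from [cumulative_incidence_competing].
#' @param min_at_risk Minimum risk-set size for the fallback reading
#'   point.
#' @return A list with `p_cum`, `t_ref`, and `rule` (`"median"`,
#'   `"at_risk"`, or `"insufficient"` when the risk set never reaches
#'   `min_at_risk`, in which case `p_cum` and `t_ref` are `NA`).
#' @export
transition_summary <- function(curve, min_at_risk = 4) {
  if (nrow(curve) == 0L) {
    return(list(p_cum = NA_real_, t_ref = NA_real_, rule = "insufficient"))
  }
  hit <- which(curve$cif >= 0.5)
  if (length(hit) > 0L) {
    return(list(p_cum = 0.5, t_ref = curve$time[hit[1L]], rule = "median"))
  }
  ok <- which(curve$n_risk >= min_at_risk)
  if (length(ok) == 0L) {
    return(list(p_cum = NA_real_, t_ref = NA_real_, rule = "insufficient"))
  }
  i <- ok[length(ok)]
  list(p_cum = curve$cif[i], t_ref = curve$time[i], rule = "at_risk")
}

#' Convert a cumulative proportion to an annual probability
#'
#' The Markov correction: a cumulative transition proportion `P_cum`
#' observed over `t_ref` years is converted to the constant per-cycle
#' probability `p` whose `t_ref`-fold compounding reproduces it,
#' `p = 1 - (1 - P_cum)^(1/t_ref)`. `annualize_linear` returns the naive
#' ratio `P_cum / t_ref` as a diagnostic only.
#'
#' @param p_cum Cumulative proportion in `[0, 1]`.
#' @param t_ref Reference time in years (> 0).
#' @return Annual transition probability.
#' @examples
#' annualize_transition(0.75, 2) # 0.5
#' @export
annualize_transition <- function(p_cum, t_ref) {
  if (any(t_ref <= 0)) stop("t_ref must be positive", call. = FALSE)
  if (any(p_cum < 0 | p_cum > 1)) {
    stop("p_cum must lie in [0, 1]", call. = FALSE)
  }
  if (any(p_cum == 1)) {
    warning("cumulative proportion of 1: instantaneous transition",
            call. = FALSE)
  }
  1 - (1 - p_cum)^(1 / t_ref)
}

#' @rdname annualize_transition
#' @export
annualize_linear <- function(p_cum, t_ref) {
  if (any(t_ref <= 0)) stop("t_ref must be positive", call. = FALSE)
  p_cum / t_ref
}

#' Mean state utility with BCa bootstrap interval
#'
#' Two-stage averaging: utilities are first averaged per patient within
#' the state (so patients with many observations do not dominate), then
#' averaged over patients. The 95% confidence interval is obtained by
#' bias-corrected and accelerated (BCa) bootstrap resampling of
#' *patients*. With a single contributing patient the mean is returned
#' and the interval flagged unavailable.
#'
#' @param records EQ-5D records: `patient_id`, `state_at_observation`,
#'   `utility`, `tariff`.
#' @param state State label.
#' @param tariff `"UK"` or `"NL"`.
#' @param bootstrap_reps BCa replicates.
#' @return A list with `state`, `tariff`, `mean_u`, `lcl`, `ucl`,
#'   `n_patients`, `ci_available`.
#' @export
mean_state_utility <- function(records, state, tariff = "UK",
                               bootstrap_reps = 2000) {
  assert_states(state)
  rec <- records[records$state_at_observation == state &
                   records$tariff == tariff, , drop = FALSE]
  if (nrow(rec) == 0L) {
    stop(sprintf("no %s-tariff observations in state '%s'", tariff, state),
         call. = FALSE)
  }
  pm <- tapply(rec$utility, rec$patient_id, mean)
  est <- mean(pm)
  n <- length(pm)
  lcl <- ucl <- NA_real_
  ci_ok <- FALSE
  if (n > 1L && stats::var(pm) > 0) {
    b <- boot::boot(as.numeric(pm), function(x, i) mean(x[i]),
                    R = bootstrap_reps)
    ci <- tryCatch(boot::boot.ci(b, type = "bca"), error = function(e) NULL)
    if (!is.null(ci)) {
      lcl <- ci$bca[4L]
      ucl <- ci$bca[5L]
      ci_ok <- TRUE
    }
  }
  list(state = state, tariff = tariff, mean_u = est, lcl = lcl, ucl = ucl,
       n_patients = n, ci_available = ci_ok)
}

#' Mean yearly ERT volume and cost per disease state
#'
#' (i) the vials-per-month rate is averaged per patient within the state,
#' weighting dose episodes by their length; (ii) these per-patient rates
#' are averaged over patients; (iii) the overall mean is multiplied by 12
#' and by the vial unit cost. Patients whose dose episodes have zero
#' total length are excluded with a warning.
#'
#' @param records Dose records: `patient_id`, `state`,
#'   `episode_start_age`, `episode_end_age`, `vials_per_month`.
#' @param state State label.
#' @param vial_unit_cost Euro per vial of 400 IU.
#' @return A list with `state`, `vials_per_year`, `annual_cost`,
#'   `n_patients`.
#' @export
annual_ert_cost <- function(records, state, vial_unit_cost = 1985) {
  assert_states(state)
  if (vial_unit_cost <= 0) stop("vial_unit_cost must be positive",
                                call. = FALSE)
  rec <- records[records$state == state, , drop = FALSE]
  if (nrow(rec) == 0L) {
    return(list(state = state, vials_per_year = NA_real_,
                annual_cost = NA_real_, n_patients = 0L))
  }
  len <- rec$episode_end_age - rec$episode_start_age
  if (any(len < 0)) stop("dose episode with negative length", call. = FALSE)
  per_patient <- vapply(split(seq_len(nrow(rec)), rec$patient_id),
                        function(ix) {
                          w <- len[ix]
                          if (sum(w) <= 0) return(NA_real_)
                          sum(rec$vials_per_month[ix] * w) / sum(w)
                        }, numeric(1))
  if (anyNA(per_patient)) {
    warning("patient(s) with zero total dose-episode length excluded",
            call. = FALSE)
    per_patient <- per_patient[!is.na(per_patient)]
  }
  vials_year <- mean(per_patient) * 12
  list(state = state, vials_per_year = vials_year,
       annual_cost = vials_year * vial_unit_cost,
       n_patients = length(per_patient))
}

#' Mean yearly hospital costs per disease state
#'
#' Product-sum costing: each patient's procedures in the state are valued
#' at their unit costs, totalled, and divided by that patient's years of
#' follow-up in the state (from the episode records); the per-patient
#' annual costs are then averaged over patients. Patients with zero
#' follow-up time in the state are excluded with a warning.
#'
#' @param procedures Procedure records: `patient_id`, `state`,
#'   `unit_cost`, `count`.
#' @param episodes Episode records giving follow-up time per patient per
#'   state.
#' @param state State label.
#' @return A list with `state`, `mean_annual`, `n_patients`.
#' @export
annual_hospital_cost <- function(procedures, episodes, state) {
  assert_states(state)
  ep <- episodes[episodes$state == state, , drop = FALSE]
  if (nrow(ep) == 0L) {
    return(list(state = state, mean_annual = NA_real_, n_patients = 0L))
  }
  fu <- tapply(ep$end_age - ep$start_age, ep$patient_id, sum)
  if (any(fu <= 0)) {
    warning("patient(s) with zero follow-up in state excluded",
            call. = FALSE)
    fu <- fu[fu > 0]
  }
  pr <- procedures[procedures$state == state, , drop = FALSE]
  spent <- tapply(pr$unit_cost * pr$count, pr$patient_id, sum)
  total <- stats::setNames(numeric(length(fu)), names(fu))
  common <- intersect(names(spent), names(fu))
  total[common] <- spent[common]
  list(state = state, mean_annual = mean(total / fu),
       n_patients = length(fu))
}

#' Mean yearly out-of-hospital costs per disease state
#'
#' Quarterly visit counts are valued at their unit costs, averaged per
#' patient per quarter, multiplied by 4 for a yearly estimate, and
#' averaged over patients.
#'
#' @param records Quarterly out-of-hospital records: `patient_id`,
#'   `state`, `visits`, `unit_cost`.
#' @param state State label.
#' @return A list with `state`, `mean_annual`, `n_patients`.
#' @export
annual_outpatient_cost <- function(records, state) {
  assert_states(state)
  rec <- records[records$state == state, , drop = FALSE]
  if (nrow(rec) == 0L) {
    return(list(state = state, mean_annual = NA_real_, n_patients = 0L))
  }
  q_cost <- rec$visits * rec$unit_cost
  per_patient <- tapply(q_cost, rec$patient_id, mean) * 4
  list(state = state, mean_annual = mean(per_patient),
       n_patients = length(per_patient))
}

#' Mean yearly production-loss costs per disease state
#'
#' Human-capital costing. For patients with paid work, sick-leave days
#' per two-week period are multiplied by 26 and by the overall mean
#' working hours per day; for patients with permanent work disability due
#' to the disease, a full working year is lost (52 weeks times the
#' overall mean workdays per week times mean hours per day); patients
#' without paid work for unrelated reasons contribute zero. Hours are
#' valued at `hourly_cost` and the per-patient yearly losses averaged
#' over patients in the state. The overall means of hours per workday and
#' workdays per week are taken over all employed patients in the record
#' set, across states.
#'
#' @param records Work records: `patient_id`, `state`, `employed`,
#'   `disabled_due_to_gd`, `hours_per_workday`, `workdays_per_week`,
#'   `sick_days_per_fortnight`.
#' @param state State label.
#' @param hourly_cost Euro per hour of lost production.
#' @return A list with `state`, `mean_annual`, `n_patients`.
#' @export
annual_production_loss <- function(records, state, hourly_cost = 30) {
  assert_states(state)
  if (hourly_cost <= 0) stop("hourly_cost must be positive", call. = FALSE)
  emp <- records[records$employed %in% TRUE, , drop = FALSE]
  mean_hours <- mean(emp$hours_per_workday, na.rm = TRUE)
  mean_days <- mean(emp$workdays_per_week, na.rm = TRUE)
  rec <- records[records$state == state, , drop = FALSE]
  if (nrow(rec) == 0L) {
    return(list(state = state, mean_annual = NA_real_, n_patients = 0L))
  }
  loss <- numeric(nrow(rec))
  is_emp <- rec$employed %in% TRUE
  is_dis <- !is_emp & rec$disabled_due_to_gd %in% TRUE
  loss[is_emp] <- rec$sick_days_per_fortnight[is_emp] * 26 * mean_hours *
    hourly_cost
  loss[is_dis] <- 52 * mean_days * mean_hours * hourly_cost
  list(state = state, mean_annual = mean(loss), n_patients = nrow(rec))
}

#' Calibrate model parameters from a patient-level registry
#'
#' Orchestrates the full estimation: annual transition probabilities from
#' episode records (competing-risk cumulative incidence, the 50% /
#' 4-at-risk reading rule, and the Markov annualization), state utilities
#' with BCa bootstrap intervals, ERT dosing, and per-state annual cost
#' components. Beta shape parameters for each transition are formed from
#' the point estimate and the number of patients ever at risk
#' (`alpha = p * n`, `beta = (1 - p) * n`). States or transitions without
#' data are flagged as missing, never silently zero.
#'
#' @param registry A list with data frames `episodes`, `eq5d`, `doses`,
#'   `procedures`, `outpatient`, `work` (e.g. from [simulate_registry] or
#'   [read_registry]).
#' @param vial_unit_cost Euro per ERT vial.
#' @param bootstrap_reps BCa replicates for utility intervals.
#' @param tariffs Tariffs to calibrate utilities for.
#' @return A list of class `calibration_result` with elements
#'   `transitions`, `utilities`, `ert_dosing`, `costs`, `diagnostics`.
#' @export
calibrate <- function(registry, vial_unit_cost = 1985,
                      bootstrap_reps = 2000, tariffs = c("UK", "NL")) {
  ep <- registry$episodes
  states <- alive_states()

  # --- transitions ---------------------------------------------------
  trans <- list()
  for (f in states) {
    epf <- ep[ep$state == f, , drop = FALSE]
    if (nrow(epf) == 0L) next
    dests <- unique(sub("^transition_to:", "",
                        epf$end_event[startsWith(epf$end_event,
                                                 "transition_to:")]))
    for (d in dests) {
      curve <- cumulative_incidence_competing(ep, f, d)
      ts <- transition_summary(curve)
      p_hat <- if (ts$rule == "insufficient") {
        NA_real_
      } else {
        annualize_transition(ts$p_cum, ts$t_ref)
      }
      n <- attr(curve, "n_patients")
      trans[[length(trans) + 1L]] <- data.frame(
        from = f, to = d, mean_p = p_hat,
        alpha = if (!is.na(p_hat) && p_hat > 0) p_hat * n else NA_real_,
        beta = if (!is.na(p_hat) && p_hat > 0) (1 - p_hat) * n else NA_real_,
        n_patients = n, p_cum = ts$p_cum, t_ref = ts$t_ref, rule = ts$rule)
    }
  }
  transitions <- if (length(trans) > 0L) {
    do.call(rbind, trans)
  } else {
    data.frame(from = character(), to = character(), mean_p = numeric(),
               alpha = numeric(), beta = numeric(), n_patients = integer(),
               p_cum = numeric(), t_ref = numeric(), rule = character())
  }

  # --- utilities -----------------------------------------------------
  utilities <- list()
  for (tar in tariffs) {
    for (s in states) {
      res <- tryCatch(mean_state_utility(registry$eq5d, s, tar,
                                         bootstrap_reps),
                      error = function(e) NULL)
      utilities[[length(utilities) + 1L]] <- data.frame(
        state = s, tariff = tar,
        mean_u = if (is.null(res)) NA_real_ else res$mean_u,
        lcl = if (is.null(res)) NA_real_ else res$lcl,
        ucl = if (is.null(res)) NA_real_ else res$ucl,
        n_patients = if (is.null(res)) 0L else res$n_patients,
        ci_available = if (is.null(res)) FALSE else res$ci_available)
    }
  }
  utilities <- do.call(rbind, utilities)

  # --- costs and dosing ---------------------------------------------
  dose <- lapply(states, function(s) {
    r <- annual_ert_cost(registry$doses, s, vial_unit_cost)
    data.frame(state = s, vials_per_year = r$vials_per_year,
               annual_cost = r$annual_cost, n_patients = r$n_patients)
  })
  ert_dosing <- do.call(rbind, dose)

  costs <- list()
  for (s in states) {
    h <- annual_hospital_cost(registry$procedures, ep, s)
    o <- annual_outpatient_cost(registry$outpatient, s)
    p <- annual_production_loss(registry$work, s)
    costs[[length(costs) + 1L]] <- data.frame(
      state = s,
      component = c("hospital", "out_of_hospital", "production_loss"),
      mean_annual = c(h$mean_annual, o$mean_annual, p$mean_annual),
      n_patients = c(h$n_patients, o$n_patients, p$n_patients))
  }
  costs <- do.call(rbind, costs)

  structure(list(transitions = transitions, utilities = utilities,
                 ert_dosing = ert_dosing, costs = costs,
                 diagnostics = list(
                   n_patients = length(unique(ep$patient_id)),
                   missing = costs$state[is.na(costs$mean_annual)])),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %d transitions, %d utility rows\n",
              nrow(x$transitions), nrow(x$utilities)))
  invisible(x)
}
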