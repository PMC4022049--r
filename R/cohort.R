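#' Build the annual transition matrix at a given age
#'
#' Assembles the row-stochastic 8x8 matrix for one model cycle. Within a
#' cycle, survival is evaluated first: every alive state carries the
#' background annual death probability `q(age)` from the life table (the
#' malignancy state adds its excess mortality, capped at 1), and disease
#' transitions apply conditionally on surviving the cycle. If the annual
#' disease transition probabilities out of a state sum to more than 1 they
#' are rescaled proportionally (preserving relative risks) with a warning.
#'
#' @param strategy A [strategy_spec].
#' @param age Integer age at the start of the cycle.
#' @param life_table A [read_life_table] life table.
#' @param quiet Suppress the rescaling warning (used internally by the PSA
#'   where rescaling may recur across draws).
#' @return An 8x8 matrix with rows and columns named by [gd_states()],
#'   rows summing to 1.
#' @export
transition_matrix <- function(strategy, age, life_table, quiet = FALSE) {
  states <- gd_states()
  n <- length(states)
  dis <- matrix(0, n, n, dimnames = list(states, states))
  tr <- strategy$transitions
  dis[cbind(state_index(tr$from), state_index(tr$to))] <- tr$mean_p
  out <- rowSums(dis)
  over <- which(out > 1)
  if (length(over) > 0L) {
    if (!quiet) {
      warning(sprintf("outgoing probabilities exceed 1 in: %s; rescaled",
                      paste(states[over], collapse = ", ")), call. = FALSE)
    }
    dis[over, ] <- dis[over, , drop = FALSE] / out[over]
    out[over] <- 1
  }
  diag(dis) <- diag(dis) + (1 - out)

  q <- rep(life_table_q(life_table, age), n)
  q[states == "malignancy"] <- min(1, q[states == "malignancy"] +
                                     strategy$malignancy_excess_mortality)
  m <- dis * (1 - q)
  m[, "dead"] <- m[, "dead"] + q
  m["dead", ] <- 0
  m["dead", "dead"] <- 1
  m
}

# Array of per-cycle matrices for ages 0..horizon-1 (or offset start).
transition_matrices <- function(strategy, horizon, life_table, quiet = FALSE) {
  states <- gd_states()
  arr <- array(0, dim = c(8L, 8L, horizon),
               dimnames = list(states, states, NULL))
  for (k in seq_len(horizon)) {
    arr[, , k] <- transition_matrix(strategy, k - 1L, life_table,
                                    quiet = quiet || k > 1L)
  }
  arr
}

#' Run the deterministic cohort model
#'
#' Propagates the starting occupancy vector through `horizon_years` annual
#' cycles by vector-matrix products. Cycle `k` spans ages `[k, k + 1)`;
#' the trace records occupancy at the start of each cycle (rows `0 ..
#' horizon`), and rewards in the economics layer accrue at cycle start
#' with no half-cycle correction.
#'
#' @inheritParams transition_matrix
#' @param config A [model_config].
#' @param start_distribution Optional override of the strategy's starting
#'   occupancy (used by the historical scenarios).
#' @return A `cohort_trace`: numeric matrix of occupancy fractions with
#'   `horizon + 1` rows (cycles) and 8 state columns, carrying the strategy
#'   label and start vector as attributes.
#' @export
run_cohort <- function(strategy, config, life_table,
                       start_distribution = NULL, quiet = FALSE) {
  horizon <- config$horizon_years
  start <- if (is.null(start_distribution)) {
    strategy$start_distribution
  } else {
    expand_start_distribution(start_distribution)
  }
  if (abs(sum(start) - 1) > 1e-12) {
    stop("start distribution must sum to 1", call. = FALSE)
  }
  arr <- transition_matrices(strategy, horizon, life_table, quiet = quiet)
  occ <- matrix(0, horizon + 1L, 8L,
                dimnames = list(0:horizon, gd_states()))
  occ[1L, ] <- start
  v <- start
  for (k in seq_len(horizon)) {
    v <- as.numeric(v %*% arr[, , k])
    occ[k + 1L, ] <- v
  }
  new_cohort_trace(occ, strategy$label, start)
}

new_cohort_trace <- function(occ, label, start) {
  structure(occ, class = c("cohort_trace", "matrix", "array"),
            strategy = label, start = start)
}

#' @rdname run_cohort
#' @param trace Object to validate.
#' @export
validate_cohort_trace <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  sums <- rowSums(trace)
  if (any(abs(sums - 1) > 1e-10)) {
    stop("cohort trace rows must sum to 1 (mass conservation)", call. = FALSE)
  }
  if (any(diff(trace[, "dead"]) < -1e-12)) {
    stop("occupancy of dead must be non-decreasing", call. = FALSE)
  }
  invisible(trace)
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace '%s'> %d cycles\n", attr(x, "strategy"),
              nrow(x) - 1L))
  cat(sprintf("  final: alive %.3f, dead %.3f\n",
              1 - x[nrow(x), "dead"], x[nrow(x), "dead"]))
  invisible(x)
}

#' Write a cohort trace to CSV
#'
#' One row per cycle with the cycle index, age at cycle start, the eight
#' occupancy fractions and a row-sum check column.
#'
#' @param trace A `cohort_trace`.
#' @param path Output CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(cycle = seq_len(nrow(trace)) - 1L)
  df$age <- df$cycle
  df <- cbind(df, as.data.frame(unclass(trace), row.names = FALSE))
  df$row_sum <- rowSums(trace)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Simulate individual patient trajectories
#'
#' First-order microsimulation: each simulated patient steps through the
#' same per-age matrices as [run_cohort], drawing the next state each
#' cycle. With `u` supplied (a `n_patients x horizon` matrix of uniforms)
#' the trajectories are a deterministic function of `u`, which the PSA uses
#' to apply common random numbers across treatment arms.
#'
#' @inheritParams run_cohort
#' @param n_patients Number of simulated individuals.
#' @param u Optional uniform variates, dimension `n_patients x horizon`.
#' @return Integer matrix `n_patients x (horizon + 1)` of state indices
#'   into [gd_states()], class `patient_trajectories`.
#' @export
run_microsimulation <- function(strategy, config, life_table, n_patients,
                                start_distribution = NULL, u = NULL,
                                quiet = TRUE) {
  horizon <- config$horizon_years
  start <- if (is.null(start_distribution)) {
    strategy$start_distribution
  } else {
    expand_start_distribution(start_distribution)
  }
  arr <- transition_matrices(strategy, horizon, life_table, quiet = quiet)
  if (is.null(u)) {
    u <- matrix(stats::runif(n_patients * horizon), n_patients, horizon)
  }
  traj <- matrix(0L, n_patients, horizon + 1L)
  # Starting states: inverse-CDF on the start distribution using an extra
  # uniform column would change RNG layout; draw directly.
  traj[, 1L] <- sample.int(8L, n_patients, replace = TRUE, prob = start)
  cum <- array(0, dim = dim(arr))
  for (k in seq_len(horizon)) {
    cum[, , k] <- t(apply(arr[, , k], 1L, cumsum))
  }
  for (k in seq_len(horizon)) {
    cur <- traj[, k]
    nxt <- cur
    for (s in unique(cur)) {
      idx <- which(cur == s)
      nxt[idx] <- findInterval(u[idx, k], cum[s, , k],
                               left.open = TRUE) + 1L
    }
    traj[, k + 1L] <- nxt
  }
  structure(traj, class = c("patient_trajectories", "matrix", "array"),
            strategy = strategy$label)
}

#' Empirical occupancy trace from simulated trajectories
#'
#' @param trajectories A `patient_trajectories` matrix from
#'   [run_microsimulation].
#' @return A `cohort_trace` of empirical occupancy fractions.
#' @export
trace_from_trajectories <- function(trajectories) {
  if (is.null(dim(trajectories)) || nrow(trajectories) == 0L) {
    stop("no trajectories supplied", call. = FALSE)
  }
  n <- nrow(trajectories)
  occ <- t(apply(trajectories, 2L, tabulate, nbins = 8L)) / n
  dimnames(occ) <- list(seq_len(ncol(trajectories)) - 1L, gd_states())
  new_cohort_trace(occ, attr(trajectories, "strategy") %||% "unknown",
                   occ[1L, ])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
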