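# Shared test objects. The packaged fixture is loaded once; toy model
# pieces are built in code.

fx <- gaucher_fixture()

# A flat life table with constant annual death probability q.
flat_life_table <- function(q = 0, max_age = 85) {
  validate_life_table(data.frame(age = 0:max_age, qx = q), horizon = max_age)
}

# Minimal utility/cost tables covering all alive states.
toy_utilities <- function(u = 0.93) {
  data.frame(state = alive_states(), tariff = "UK", mean_u = u,
             lcl = NA_real_, ucl = NA_real_)
}

toy_costs <- function(hospital = 0, out_of_hospital = 0, production = 0) {
  rbind(data.frame(state = alive_states(), component = "hospital",
                   mean_annual = hospital),
        data.frame(state = alive_states(), component = "out_of_hospital",
                   mean_annual = out_of_hospital),
        data.frame(state = alive_states(), component = "production_loss",
                   mean_annual = production))
}

# A strategy with an arbitrary transition table and flat utilities/costs.
toy_strategy <- function(transitions =
                           data.frame(from = character(), to = character(),
                                      mean_p = numeric()),
                         label = "no_ert", u = 0.93, hospital = 0,
                         start = c(asymptomatic = 1), excess = 0, ...) {
  strategy_spec(label = label, transitions = transitions,
                utilities = toy_utilities(u),
                costs = toy_costs(hospital = hospital),
                start_distribution = start,
                malignancy_excess_mortality = excess, ...)
}

# Random chain on the first k alive states (+ dead), used for the
# engine-vs-matrix-power checks.
random_chain_strategy <- function(k = 4, p_death_path = TRUE) {
  sts <- c(utils::head(alive_states(), k - 1L), "dead")
  from <- rep(sts[-k], each = k - 1L)
  to <- unlist(lapply(seq_len(k - 1L), function(i) sts[-i]))
  keep <- if (p_death_path) rep(TRUE, length(from)) else to != "dead"
  from <- from[keep]; to <- to[keep]
  p <- stats::runif(length(from), 0, 0.25)
  # keep outgoing sums below 1
  for (f in unique(from)) {
    ix <- from == f
    s <- sum(p[ix])
    if (s > 0.9) p[ix] <- p[ix] * 0.9 / s
  }
  tr <- data.frame(from = from, to = to, mean_p = p)
  tr <- tr[tr$to != "recovery", , drop = FALSE] # label no_ert: no recovery
  start <- stats::setNames(c(1, numeric(k - 2L)), sts[-k])
  toy_strategy(tr, start = start)
}

# Explicit dense transition matrix of a strategy at a given age (built
# independently of transition_matrix, for oracle comparisons).
oracle_matrix <- function(strategy, q) {
  sts <- gd_states()
  m <- matrix(0, 8, 8, dimnames = list(sts, sts))
  tr <- strategy$transitions
  for (i in seq_len(nrow(tr))) m[tr$from[i], tr$to[i]] <- tr$mean_p[i]
  diag(m) <- diag(m) + 1 - rowSums(m)
  qs <- rep(q, 8)
  qs[sts == "malignancy"] <- min(1, q + strategy$malignancy_excess_mortality)
  out <- m * (1 - qs)
  out[, "dead"] <- out[, "dead"] + qs
  out["dead", ] <- 0; out["dead", "dead"] <- 1
  out
}
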