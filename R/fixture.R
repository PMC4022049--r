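#' Packaged base-case parameter fixture
#'
#' The package ships a complete parameter fixture under
#' `inst/extdata/basecase/`. The utility, cost and ERT dosing tables are
#' transcriptions of the published per-state means and 95% confidence
#' limits (2009 euros). The transition tables and the life table are
#' **synthetic placeholders**: the study's transition probabilities and
#' the national background-mortality table it used are published only in
#' supplementary material that is not redistributed here, so the fixture
#' carries a plausible set (marked `synthetic_placeholder` in its
#' `source_label` column) and a [make_synthetic_life_table] schedule.
#' Model outputs obtained with the packaged fixture therefore illustrate
#' the machinery; they are not a reproduction of the published estimates.
#'
#' @return `gaucher_fixture_dir()` returns the fixture directory path.
#'   `gaucher_fixture()` loads everything: a list with `config`,
#'   `strategies`, `life_table` and `scenarios`.
#' @export
gaucher_fixture_dir <- function() {
  system.file("extdata", "basecase", package = "gauchercea", mustWork = TRUE)
}

#' @rdname gaucher_fixture_dir
#' @export
gaucher_fixture <- function() {
  dir <- gaucher_fixture_dir()
  pars <- load_parameters(file.path(dir, "config.yaml"), dir)
  c(pars,
    list(life_table = read_life_table(file.path(dir,
                                                "lifetable_synthetic.csv")),
         scenarios = load_scenarios(dir)))
}

#' Standard analysis scenarios
#'
#' Builds the five scenario definitions: the base case, production-loss
#' inclusion, 25% ERT cost reduction, and the two historical variants
#' whose starting distributions over disease states (the prevalent cohort
#' when ERT entered the market) are read from the fixture's
#' `start_distribution.csv` rows labelled `historical_I` and
#' `historical_II`.
#'
#' @param fixture_dir Fixture directory (defaults to the packaged one).
#' @return Named list of [scenario_spec] objects.
#' @export
load_scenarios <- function(fixture_dir = gaucher_fixture_dir()) {
  sd <- utils::read.csv(file.path(fixture_dir, "start_distribution.csv"),
                        stringsAsFactors = FALSE)
  hist_start <- function(label) {
    rows <- sd[sd$strategy == label, ]
    if (nrow(rows) == 0L) return(NULL)
    stats::setNames(rows$fraction, rows$state)
  }
  list(
    base = scenario_spec("base"),
    production_loss = scenario_spec("production_loss",
                                    include_production_loss = TRUE),
    ert_cost_reduction = scenario_spec("ert_cost_reduction",
                                       ert_cost_multiplier = 0.75),
    historical_I = scenario_spec("historical_I",
                                 start_distribution = hist_start("historical_I"),
                                 ert_strategy = "ert_historical"),
    historical_II = scenario_spec("historical_II",
                                  start_distribution = hist_start("historical_II"),
                                  ert_strategy = "ert_historical"))
}
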