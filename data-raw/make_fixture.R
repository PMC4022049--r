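# Generates inst/extdata/basecase/ fixture CSVs. Utilities/costs/dosing are
# transcriptions of the printed per-state tables; transitions + life table
# are synthetic placeholders (see R/fixture.R docs).
dir <- "inst/extdata/basecase"
dir.create(dir, recursive = TRUE, showWarnings = FALSE)

tr_no <- data.frame(
  strategy = "no_ert",
  from = c("asymptomatic", "signs_symptoms", "signs_symptoms",
           "signs_symptoms", "splenectomy", "splenectomy",
           "bone_complication", "bone_complication",
           "multiple_complications"),
  to = c("signs_symptoms", "splenectomy", "bone_complication", "malignancy",
         "multiple_complications", "malignancy",
         "multiple_complications", "malignancy", "malignancy"),
  mean_p = c(0.040, 0.025, 0.020, 0.003, 0.040, 0.008, 0.050, 0.005, 0.012))

tr_ert <- data.frame(
  strategy = "ert_base",
  from = c("asymptomatic", "signs_symptoms", "signs_symptoms",
           "signs_symptoms", "signs_symptoms", "recovery", "recovery",
           "recovery", "splenectomy", "splenectomy", "bone_complication",
           "bone_complication", "multiple_complications"),
  to = c("signs_symptoms", "recovery", "splenectomy", "bone_complication",
         "malignancy", "splenectomy", "bone_complication", "malignancy",
         "multiple_complications", "malignancy", "multiple_complications",
         "malignancy", "malignancy"),
  mean_p = c(0.040, 0.180, 0.008, 0.010, 0.002, 0.004, 0.008, 0.002,
             0.020, 0.005, 0.025, 0.004, 0.008))

tr_hist <- tr_ert
tr_hist$strategy <- "ert_historical"

tr <- rbind(tr_no, tr_ert, tr_hist)
tr$lcl <- round(0.6 * tr$mean_p, 6)
tr$ucl <- round(1.5 * tr$mean_p, 6)
tr$alpha <- NA_real_ # fitted at load from the confidence limits
tr$beta <- NA_real_
tr$source_label <- "synthetic_placeholder"
write.csv(tr, file.path(dir, "transitions.csv"), row.names = FALSE)

ut <- rbind(
  data.frame(state = "asymptomatic", tariff = c("UK", "NL"),
             mean_u = 0.93, lcl = 0.89, ucl = 0.97),
  data.frame(state = "signs_symptoms", tariff = c("UK", "NL"),
             mean_u = c(0.8716, 0.8897), lcl = c(0.8177, 0.8410),
             ucl = c(0.9225, 0.9349)),
  data.frame(state = "recovery", tariff = c("UK", "NL"),
             mean_u = c(0.8716, 0.8897), lcl = c(0.8177, 0.8410),
             ucl = c(0.9225, 0.9349)),
  data.frame(state = "splenectomy", tariff = c("UK", "NL"),
             mean_u = c(0.7532, 0.7781), lcl = c(0.6768, 0.6990),
             ucl = c(0.8215, 0.8626)),
  data.frame(state = "bone_complication", tariff = c("UK", "NL"),
             mean_u = c(0.8614, 0.8882), lcl = c(0.7530, 0.8027),
             ucl = c(0.9685, 0.9707)),
  data.frame(state = "multiple_complications", tariff = c("UK", "NL"),
             mean_u = c(0.7323, 0.7981), lcl = c(0.6601, 0.7430),
             ucl = c(0.8202, 0.8638)),
  data.frame(state = "malignancy", tariff = c("UK", "NL"),
             mean_u = c(0.15, 0.364), lcl = NA_real_, ucl = NA_real_))
write.csv(ut, file.path(dir, "utilities.csv"), row.names = FALSE)

st <- c("asymptomatic", "signs_symptoms", "recovery", "splenectomy",
        "bone_complication", "multiple_complications", "malignancy")
co <- rbind(
  data.frame(state = st, component = "hospital",
             mean_annual = c(1470, 2887, 3055, 4836, 4337, 2194, 27523),
             lcl = c(455, 1974, 1708, 2544, 1590, 1652, 4786),
             ucl = c(2152, 3885, 4858, 7145, 9313, 2826, 51722)),
  data.frame(state = st, component = "out_of_hospital",
             mean_annual = c(0, 121, 641, 299, 449, 245, 56),
             lcl = c(NA, 31, 229, 8, 51, 97, NA),
             ucl = c(NA, 272, 1097, 589, 939, 421, NA)),
  data.frame(state = st, component = "production_loss",
             mean_annual = c(0, 0, 0, 13698, 10002, 10615, 73057),
             lcl = c(NA, 0, 0, 0, 0, 0, NA),
             ucl = c(NA, 0, 0, 27396, 20004, 21230, NA)))
write.csv(co, file.path(dir, "costs.csv"), row.names = FALSE)

ed <- data.frame(
  state = c("signs_symptoms", "recovery", "splenectomy",
            "bone_complication", "multiple_complications", "malignancy"),
  vials_per_year = c(76, 63, 78, 102, 86, 130),
  lcl = c(62, 49, 50, 75, 70, 68),
  ucl = c(91, 75, 111, 132, 102, 209))
write.csv(ed, file.path(dir, "ert_dosing.csv"), row.names = FALSE)

sd <- rbind(
  data.frame(strategy = c("no_ert", "ert_base", "ert_historical"),
             state = "asymptomatic", fraction = 1),
  data.frame(strategy = "historical_I",
             state = c("signs_symptoms", "splenectomy", "bone_complication",
                       "multiple_complications", "malignancy"),
             fraction = c(0.35, 0.25, 0.20, 0.15, 0.05)),
  data.frame(strategy = "historical_II",
             state = c("signs_symptoms", "splenectomy", "bone_complication",
                       "multiple_complications", "malignancy"),
             fraction = c(0.20, 0.25, 0.20, 0.25, 0.10)))
write.csv(sd, file.path(dir, "start_distribution.csv"), row.names = FALSE)

source("R/lifetable.R")
lt <- make_synthetic_life_table()
write.csv(as.data.frame(lt), file.path(dir, "lifetable_synthetic.csv"),
          row.names = FALSE)

writeLines(c(
  "horizon_years: 85",
  "discount_effects: 0.015",
  "discount_costs: 0.04",
  "productive_age_window: [25, 64]",
  "wtp_max: 10000000",
  "wtp_step: 10000",
  "psa_draws: 1000",
  "psa_trials: 100",
  "seed: 1",
  "strategies:",
  "  no_ert:",
  "    malignancy_excess_mortality: 0.10",
  "  ert_base:",
  "    malignancy_excess_mortality: 0.10",
  "    ert_vial_unit_cost: 1985",
  "    ert_cost_multiplier: 1.0",
  "  ert_historical:",
  "    malignancy_excess_mortality: 0.10",
  "    ert_vial_unit_cost: 1985",
  "    ert_cost_multiplier: 1.0"),
  file.path(dir, "config.yaml"))

cat("fixture written to", dir, "\n")
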