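#' Life tables
#'
#' Background mortality enters the model as a period life table: one row
#' per integer age with the annual probability of death `qx`. The packaged
#' fixture ships a *synthetic* life table generated by
#' [make_synthetic_life_table()] (a Gompertz-Makeham schedule with added
#' infant mortality), standing in for a national statistics-office table.
#'
#' @param path CSV file with header `age,qx`.
#' @param horizon Highest age the table must cover.
#' @return A data frame of class `life_table` with columns `age` and `qx`.
#' @export
read_life_table <- function(path, horizon = 85) {
  if (!file.exists(path)) {
    stop(sprintf("life table not found: %s", path), call. = FALSE)
  }
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_life_table(lt, horizon)
}

#' @rdname read_life_table
#' @param lt Data frame with columns `age` and `qx`.
#' @export
validate_life_table <- function(lt, horizon = 85) {
  if (!all(c("age", "qx") %in% names(lt))) {
    stop("life table needs columns age and qx", call. = FALSE)
  }
  lt <- lt[order(lt$age), c("age", "qx")]
  if (!identical(as.integer(lt$age), seq.int(0L, max(lt$age)))) {
    stop("life table ages must be contiguous integers starting at 0",
         call. = FALSE)
  }
  if (max(lt$age) < horizon) {
    stop(sprintf("life table must cover ages 0..%d", horizon), call. = FALSE)
  }
  if (any(!is.finite(lt$qx) | lt$qx < 0 | lt$qx > 1)) {
    stop("all qx must be probabilities in [0, 1]", call. = FALSE)
  }
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' @rdname read_life_table
#' @param age Integer age(s); values beyond the table reuse the last row.
#' @export
life_table_q <- function(lt, age) {
  idx <- pmin(as.integer(age), max(lt$age)) + 1L
  lt$qx[idx]
}

#' Generate a synthetic period life table
#'
#' A Gompertz-Makeham hazard `h(x) = a + b * exp(c * x)` converted to
#' annual death probabilities `qx = 1 - exp(-h(x))`, with a separate infant
#' mortality term at age 0. Default parameters give a low-mortality
#' western-European-like schedule (life expectancy around 80 years); the
#' table is synthetic and is not transcribed from any national source.
#'
#' @param max_age Highest age in the table.
#' @param a Makeham (age-independent) hazard component.
#' @param b,cc Gompertz level and log-slope.
#' @param q0 Infant mortality (annual death probability at age 0).
#' @return A `life_table` data frame.
#' @export
make_synthetic_life_table <- function(max_age = 85, a = 2e-4, b = 3e-5,
                                      cc = 0.095, q0 = 0.004) {
  age <- 0:max_age
  h <- a + b * exp(cc * age)
  qx <- 1 - exp(-h)
  qx[1] <- q0
  validate_life_table(data.frame(age = age, qx = qx), horizon = max_age)
}
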