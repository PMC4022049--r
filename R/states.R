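#' Disease states of the Gaucher model
#'
#' The model distinguishes eight mutually exclusive states: `asymptomatic`,
#' `signs_symptoms` (any signs/symptoms, organomegaly and/or cytopenia),
#' `recovery` (reachable only from `signs_symptoms` and only under enzyme
#' replacement therapy, since splenectomy and bone complications are
#' irreversible), `splenectomy`, `bone_complication` (a single bone
#' complication), `multiple_complications`, `malignancy` (multiple
#' myeloma/amyloidosis or hepatocellular carcinoma) and the absorbing state
#' `dead`.
#'
#' @return `gd_states()` returns the character vector of the eight state
#'   names, in canonical order (`dead` last). `yfeod_states()` returns the
#'   subset of states counted as free of end-organ damage: `asymptomatic`,
#'   `signs_symptoms` and `recovery`.
#' @export
gd_states <- function() {
  c("asymptomatic", "signs_symptoms", "recovery", "splenectomy",
    "bone_complication", "multiple_complications", "malignancy", "dead")
}

#' @rdname gd_states
#' @export
yfeod_states <- function() {
  c("asymptomatic", "signs_symptoms", "recovery")
}

#' @rdname gd_states
#' @export
alive_states <- function() {
  setdiff(gd_states(), "dead")
}

# Validate state labels, returning them invisibly; `what` names the field in
# error messages.
assert_states <- function(x, what = "state") {
  bad <- setdiff(unique(as.character(x)), gd_states())
  if (length(bad) > 0L) {
    stop(sprintf("unknown %s label(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# Integer index of states in canonical order.
state_index <- function(x) {
  assert_states(x)
  match(as.character(x), gd_states())
}

# Lowest EQ-5D tariff value (UK time-trade-off value set floor).
UTILITY_FLOOR <- -0.594
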