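#' CGM glucose trace
#'
#' Container for one patient's continuous glucose monitoring (CGM) record:
#' glucose concentrations in mmol/L on a regular 5-minute grid, split into
#' whole days of 288 samples. Values must be finite and strictly positive;
#' the vector length must be a whole multiple of 288.
#'
#' @param values Numeric vector of glucose concentrations (mmol/L), length a
#'   multiple of 288.
#' @param patient_id Character scalar identifying the patient.
#' @return An object of class `glucose_trace`: a list with elements
#'   `patient_id`, `values`, `n_days`, `day_length` (288) and
#'   `sampling_interval_min` (5).
#' @examples
#' tr <- glucose_trace(rep(6, 2 * 288), "P001")
#' tr$n_days
#' @export
glucose_trace <- function(values, patient_id = "unknown") {
  if (!is.numeric(values)) {
    rlang::abort("`values` must be numeric (mmol/L).", class = "cgmboost_data_error")
  }
  values <- as.double(values)
  if (length(values) == 0 || length(values) %% 288L != 0L) {
    rlang::abort(
      sprintf("trace length (%d) must be a positive multiple of 288 samples/day", length(values)),
      class = "cgmboost_data_error"
    )
  }
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    rlang::abort(
      sprintf("non-finite or non-positive glucose value at sample %d (%.3g mmol/L)", bad[1], values[bad[1]]),
      class = "cgmboost_data_error"
    )
  }
  structure(
    list(
      patient_id = as.character(patient_id),
      values = values,
      n_days = length(values) %/% 288L,
      day_length = 288L,
      sampling_interval_min = 5
    ),
    class = "glucose_trace"
  )
}

#' @export
print.glucose_trace <- function(x, ...) {
  cat(sprintf(
    "<glucose_trace> patient %s: %d day(s) x 288 samples (5-min grid), range %.1f-%.1f mmol/L\n",
    x$patient_id, x$n_days, min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Split a trace into its day-curves
#'
#' @param trace A [glucose_trace()].
#' @return A list of numeric vectors, one 288-sample day each.
#' @export
trace_days <- function(trace) {
  stopifnot(inherits(trace, "glucose_trace"))
  split(trace$values, rep(seq_len(trace$n_days), each = trace$day_length))
}
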