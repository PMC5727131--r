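# Plain-text I/O for CGM traces, labels and feature tables.
#
# Trace CSV: columns patient_id, day (1-based), slot (0..287),
# glucose_mmol_per_L. A timestamp column may replace day/slot.
# Labels CSV: patient_id, label with "T1D"/"T2D" mapped to +1/-1.
# Feature CSV: patient_id, the 17 feature columns, label.

label_to_int <- function(x) {
  if (is.numeric(x)) {
    if (!all(x %in% c(-1, 1))) {
      rlang::abort("numeric labels must be +1 (type 1) or -1 (type 2)",
                   class = "cgmboost_data_error")
    }
    return(as.integer(x))
  }
  x <- toupper(as.character(x))
  if (!all(x %in% c("T1D", "T2D"))) {
    rlang::abort("labels must be \"T1D\"/\"T2D\" (or +1/-1)", class = "cgmboost_data_error")
  }
  ifelse(x == "T1D", 1L, -1L)
}

label_to_chr <- function(x) ifelse(x == 1, "T1D", "T2D")

#' Read CGM traces from a delimited text file
#'
#' Expects columns `patient_id`, `glucose_mmol_per_L` and either `day` +
#' `slot` (slot in 0..287) or a `timestamp` column (POSIXct-parsable or
#' minutes); with timestamps the grid is inferred from the first sample and
#' must be strictly increasing on the 5-minute grid. Values are partitioned
#' into complete 288-sample days; a trailing partial day is dropped with a
#' warning. Days with interior gaps are rejected (the whole trace is dropped
#' with a warning) unless `impute = TRUE`, in which case gap runs of at most
#' `max_gap_run` samples are filled by linear interpolation.
#'
#' @param path CSV file path.
#' @param impute Impute short interior gaps by linear interpolation
#'   (default `FALSE`: strict rejection).
#' @param max_gap_run Longest gap run (samples) that may be imputed
#'   (default 3, i.e. 15 minutes).
#' @return Tibble with columns `patient_id`, `n_days` and `trace` (list of
#'   [glucose_trace()]).
#' @export
read_cgm_traces <- function(path, impute = FALSE, max_gap_run = 3) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("trace file not found: %s", path), class = "cgmboost_data_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"patient_id" %in% names(raw) || !"glucose_mmol_per_L" %in% names(raw)) {
    rlang::abort("trace file needs columns patient_id and glucose_mmol_per_L",
                 class = "cgmboost_data_error")
  }
  bad <- which(!is.finite(raw$glucose_mmol_per_L) | raw$glucose_mmol_per_L <= 0)
  if (length(bad)) {
    rlang::abort(
      sprintf("invalid glucose value %.4g at data row %d",
              raw$glucose_mmol_per_L[bad[1]], bad[1]),
      class = "cgmboost_data_error"
    )
  }
  if (!all(c("day", "slot") %in% names(raw))) {
    if (!"timestamp" %in% names(raw)) {
      rlang::abort("trace file needs day+slot columns or a timestamp column",
                   class = "cgmboost_data_error")
    }
    raw <- dplyr::group_by(raw, .data$patient_id)
    raw <- dplyr::mutate(raw, .mins = time_to_minutes(.data$timestamp))
    if (any(vapply(split(raw$.mins, raw$patient_id),
                   function(m) any(diff(m) <= 0), logical(1)))) {
      rlang::abort("non-monotone timestamps within a patient", class = "cgmboost_data_error")
    }
    raw <- dplyr::mutate(raw,
      .idx = round((.data$.mins - .data$.mins[1]) / 5),
      day = as.integer(.data$.idx %/% 288 + 1),
      slot = as.integer(.data$.idx %% 288)
    )
    raw <- dplyr::ungroup(raw)
  }
  if (any(raw$slot < 0 | raw$slot > 287)) {
    rlang::abort("slot values must lie in 0..287", class = "cgmboost_data_error")
  }
  out <- list()
  for (pid in unique(raw$patient_id)) {
    g <- raw[raw$patient_id == pid, ]
    if (anyDuplicated(g[, c("day", "slot")])) {
      rlang::abort(sprintf("duplicate (day, slot) sample for patient %s", pid),
                   class = "cgmboost_data_error")
    }
    days <- sort(unique(g$day))
    day_vecs <- list()
    rejected <- FALSE
    for (d in days) {
      gd <- g[g$day == d, ]
      v <- rep(NA_real_, 288)
      v[gd$slot + 1L] <- gd$glucose_mmol_per_L
      n_miss <- sum(is.na(v))
      if (n_miss == 0) {
        day_vecs[[length(day_vecs) + 1L]] <- v
        next
      }
      if (d == max(days)) {
        rlang::warn(sprintf("patient %s: dropping trailing partial day %d (%d/288 samples)",
                            pid, d, 288 - n_miss))
        next
      }
      runs <- rle(is.na(v))
      longest <- max(runs$lengths[runs$values])
      interior <- !is.na(v[1]) && !is.na(v[288])
      if (impute && longest <= max_gap_run && interior) {
        ok <- which(!is.na(v))
        v <- stats::approx(ok, v[ok], xout = seq_len(288))$y
        day_vecs[[length(day_vecs) + 1L]] <- v
      } else {
        rlang::warn(sprintf(
          "patient %s rejected: day %d has %d missing sample(s) (longest run %d)",
          pid, d, n_miss, longest))
        rejected <- TRUE
        break
      }
    }
    if (rejected || length(day_vecs) == 0) next
    out[[length(out) + 1L]] <- tibble::tibble(
      patient_id = pid,
      n_days = length(day_vecs),
      trace = list(glucose_trace(unlist(day_vecs), pid))
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(patient_id = character(), n_days = integer(), trace = list()))
  }
  dplyr::bind_rows(out)
}

time_to_minutes <- function(ts) {
  if (inherits(ts, c("POSIXct", "POSIXt"))) return(as.numeric(ts) / 60)
  if (is.numeric(ts)) return(as.numeric(ts))
  p <- as.POSIXct(ts, tz = "UTC")
  if (anyNA(p)) {
    rlang::abort("unparseable timestamps", class = "cgmboost_data_error")
  }
  as.numeric(p) / 60
}

#' Write CGM traces to the long CSV format
#'
#' @param cohort Tibble with `patient_id` and `trace` columns (list of
#'   [glucose_trace()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cgm_traces <- function(cohort, path) {
  stopifnot(is.data.frame(cohort), all(c("patient_id", "trace") %in% names(cohort)))
  long <- purrr::map2(cohort$patient_id, cohort$trace, function(pid, tr) {
    tibble::tibble(
      patient_id = pid,
      day = rep(seq_len(tr$n_days), each = 288L),
      slot = rep(0:287, tr$n_days),
      glucose_mmol_per_L = tr$values
    )
  })
  readr::write_csv(dplyr::bind_rows(long), path, progress = FALSE)
  invisible(path)
}

#' Write / read a cohort's labels
#'
#' Labels are stored as the strings `"T1D"` (+1) / `"T2D"` (-1).
#'
#' @param cohort Tibble with `patient_id` and `label` columns.
#' @param path CSV path.
#' @return `write_labels()`: `path` invisibly. `read_labels()`: tibble with
#'   `patient_id` and integer `label` in {+1, -1}.
#' @export
write_labels <- function(cohort, path) {
  stopifnot(all(c("patient_id", "label") %in% names(cohort)))
  readr::write_csv(
    tibble::tibble(patient_id = cohort$patient_id, label = label_to_chr(cohort$label)),
    path, progress = FALSE
  )
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("label file not found: %s", path), class = "cgmboost_data_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("patient_id", "label") %in% names(raw))) {
    rlang::abort("label file needs columns patient_id and label", class = "cgmboost_data_error")
  }
  tibble::tibble(patient_id = as.character(raw$patient_id), label = label_to_int(raw$label))
}

#' Write / read a labeled feature table
#'
#' One row per patient: `patient_id`, the 17 feature columns in canonical
#' order, and `label` (written as `"T1D"`/`"T2D"`). Round-trips losslessly.
#'
#' @param features Tibble as produced by [extract_feature_table()].
#' @param path CSV path.
#' @return `write_feature_table()`: `path` invisibly. `read_feature_table()`:
#'   the feature tibble with integer labels in {+1, -1}.
#' @export
write_feature_table <- function(features, path) {
  missing_cols <- setdiff(feature_names(), names(features))
  if (length(missing_cols)) {
    rlang::abort(paste0("feature table lacks columns: ", paste(missing_cols, collapse = ", ")),
                 class = "cgmboost_data_error")
  }
  out <- features[, c("patient_id", feature_names())]
  out$label <- if ("label" %in% names(features)) label_to_chr(features$label) else NA_character_
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("feature file not found: %s", path), class = "cgmboost_data_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("patient_id", feature_names()), names(raw))
  if (length(missing_cols)) {
    rlang::abort(paste0("feature file lacks columns: ", paste(missing_cols, collapse = ", ")),
                 class = "cgmboost_data_error")
  }
  out <- raw[, c("patient_id", feature_names())]
  out$patient_id <- as.character(out$patient_id)
  if ("label" %in% names(raw) && !all(is.na(raw$label))) {
    out$label <- label_to_int(raw$label)
  }
  tibble::as_tibble(out)
}
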