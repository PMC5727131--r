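#' Glucose target-range thresholds
#'
#' The upper threshold (mu) is the glucose target-range ceiling used by the
#' threshold-dependent features (excess AUC, TH/TL excursion counts,
#' HL/LL/WL time percentages); it is typically swept over 7-11 mmol/L.
#' The lower threshold defaults to the standard 3.9 mmol/L hypoglycemia
#' cut-off.
#'
#' @param upper Upper threshold in mmol/L (mu). Any positive value.
#' @param lower Lower threshold in mmol/L; must satisfy `0 < lower < upper`.
#' @return An object of class `threshold_config`.
#' @examples
#' threshold_config(7)
#' @export
threshold_config <- function(upper = 7, lower = 3.9) {
  if (!is.numeric(upper) || length(upper) != 1 || !is.finite(upper) ||
      !is.numeric(lower) || length(lower) != 1 || !is.finite(lower)) {
    rlang::abort("thresholds must be finite numeric scalars", class = "cgmboost_config_error")
  }
  if (!(0 < lower && lower < upper)) {
    rlang::abort(
      sprintf("need 0 < lower (%.3g) < upper (%.3g) mmol/L", lower, upper),
      class = "cgmboost_config_error"
    )
  }
  structure(list(upper = as.double(upper), lower = as.double(lower)),
            class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat(sprintf("<threshold_config> upper %.2f mmol/L, lower %.2f mmol/L\n", x$upper, x$lower))
  invisible(x)
}

parse_time_of_day <- function(x, what) {
  if (is.numeric(x)) {
    m <- as.double(x)
  } else if (is.character(x) && grepl("^\\d{1,2}:\\d{2}$", x)) {
    p <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
    m <- p[1] * 60 + p[2]
  } else {
    rlang::abort(sprintf("%s must be \"HH:MM\" or minutes after midnight", what),
                 class = "cgmboost_config_error")
  }
  if (!is.finite(m) || m < 0 || m >= 1440) {
    rlang::abort(sprintf("%s out of range [0, 1440) minutes", what),
                 class = "cgmboost_config_error")
  }
  m
}

#' Meal schedule for meal-window glucose means
#'
#' Defines the clock times of the three meals and the pre-/post-meal windows
#' over which the six meal-window means are computed. A sample belongs to the
#' pre-meal window when its slot midpoint lies in `[meal - pre_window, meal)`
#' and to the post-meal window when it lies in `(meal, meal + post_window]`.
#' Windows must fall inside the day and must not overlap.
#'
#' @param breakfast,lunch,dinner Meal times, `"HH:MM"` strings or minutes
#'   after midnight. Defaults 07:30, 12:00, 18:00.
#' @param pre_window Minutes before each meal (default 30).
#' @param post_window Minutes after each meal (default 120).
#' @return An object of class `meal_schedule` with meal times in minutes.
#' @examples
#' meal_schedule(breakfast = "08:00")
#' @export
meal_schedule <- function(breakfast = "07:30", lunch = "12:00", dinner = "18:00",
                          pre_window = 30, post_window = 120) {
  meals <- c(
    breakfast = parse_time_of_day(breakfast, "breakfast"),
    lunch = parse_time_of_day(lunch, "lunch"),
    dinner = parse_time_of_day(dinner, "dinner")
  )
  if (!is.numeric(pre_window) || pre_window <= 0 || !is.numeric(post_window) || post_window <= 0) {
    rlang::abort("pre_window and post_window must be positive minutes",
                 class = "cgmboost_config_error")
  }
  if (is.unsorted(meals, strictly = TRUE)) {
    rlang::abort("meals must be ordered breakfast < lunch < dinner",
                 class = "cgmboost_config_error")
  }
  # windows: [meal - pre, meal) and (meal, meal + post]
  lo <- meals - pre_window
  hi <- meals + post_window
  if (lo[1] < 0 || hi[3] > 1440) {
    rlang::abort("meal windows must lie within the day", class = "cgmboost_config_error")
  }
  if (any(hi[-3] > lo[-1])) {
    rlang::abort("meal windows overlap; shrink pre/post windows or move meals",
                 class = "cgmboost_config_error")
  }
  structure(
    list(meals = meals, pre_window = as.double(pre_window),
         post_window = as.double(post_window)),
    class = "meal_schedule"
  )
}

#' @export
print.meal_schedule <- function(x, ...) {
  fmt <- function(m) sprintf("%02d:%02d", m %/% 60, m %% 60)
  cat(sprintf(
    "<meal_schedule> breakfast %s, lunch %s, dinner %s (pre %g min, post %g min)\n",
    fmt(x$meals[1]), fmt(x$meals[2]), fmt(x$meals[3]), x$pre_window, x$post_window
  ))
  invisible(x)
}
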