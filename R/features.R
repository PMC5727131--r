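# Stage 1: glycemic-variability features from one CGM day-curve.
# All per-day operations take a complete 288-sample day vector (mmol/L).

DAY_LEN <- 288L
SLOT_MIN <- 5

#' Canonical names of the 17 glycemic features
#'
#' Order: seven period means (whole day, pre/post x breakfast/lunch/dinner),
#' SDBG, LAGE, MODD, excess AUC, MAGE, TH, TL, HL, LL, WL.
#'
#' @return Character vector of length 17.
#' @export
feature_names <- function() {
  c("mean_day",
    "mean_pre_breakfast", "mean_pre_lunch", "mean_pre_dinner",
    "mean_post_breakfast", "mean_post_lunch", "mean_post_dinner",
    "sdbg", "lage", "modd", "auc", "mage",
    "th", "tl", "hl", "ll", "wl")
}

check_day <- function(day) {
  if (!is.numeric(day) || length(day) != DAY_LEN || anyNA(day) || any(!is.finite(day))) {
    rlang::abort("a complete day of 288 finite glucose values is required",
                 class = "cgmboost_data_error")
  }
  as.double(day)
}

#' Whole-day mean glucose
#'
#' @param day Numeric vector of 288 glucose values (mmol/L).
#' @return Mean glucose over the day, mmol/L.
#' @export
daily_mean <- function(day) mean(check_day(day))

# slot midpoints in minutes after midnight: slot s covers [5s, 5s+5)
slot_midpoints <- function() (seq_len(DAY_LEN) - 1) * SLOT_MIN + SLOT_MIN / 2

#' Pre- and post-meal window means
#'
#' Arithmetic mean of the samples whose slot midpoint falls in
#' `[meal - pre_window, meal)` (pre) and `(meal, meal + post_window]` (post),
#' for each of the three meals.
#'
#' @inheritParams daily_mean
#' @param meals A [meal_schedule()].
#' @return Named numeric vector of six means (mmol/L):
#'   `mean_pre_breakfast`, `mean_pre_lunch`, `mean_pre_dinner`,
#'   `mean_post_breakfast`, `mean_post_lunch`, `mean_post_dinner`.
#' @export
window_means <- function(day, meals = meal_schedule()) {
  day <- check_day(day)
  stopifnot(inherits(meals, "meal_schedule"))
  mid <- slot_midpoints()
  out <- numeric(6)
  nm <- character(6)
  for (j in 1:3) {
    m <- meals$meals[j]
    pre <- mid >= m - meals$pre_window & mid < m
    post <- mid > m & mid <= m + meals$post_window
    if (!any(pre) || !any(post)) {
      rlang::abort(sprintf("empty %s window: no slot midpoint inside it", names(meals$meals)[j]),
                   class = "cgmboost_config_error")
    }
    out[j] <- mean(day[pre])
    out[j + 3] <- mean(day[post])
    nm[j] <- paste0("mean_pre_", names(meals$meals)[j])
    nm[j + 3] <- paste0("mean_post_", names(meals$meals)[j])
  }
  stats::setNames(out, nm)
}

#' Standard deviation of blood glucose (SDBG)
#'
#' Population form: `sqrt(mean((x - mean(x))^2))` with divisor n = 288,
#' not the n - 1 sample form.
#'
#' @inheritParams daily_mean
#' @return SDBG in mmol/L.
#' @export
sdbg <- function(day) {
  day <- check_day(day)
  sqrt(mean((day - mean(day))^2))
}

#' Large amplitude of glucose excursions (LAGE)
#'
#' Daily maximum minus daily minimum.
#'
#' @inheritParams daily_mean
#' @return LAGE in mmol/L.
#' @export
lage <- function(day) {
  day <- check_day(day)
  max(day) - min(day)
}

#' Mean of daily differences (MODD)
#'
#' Inter-day variability: the mean absolute difference between time-matched
#' samples of two days from the same patient. The printed definition sums the
#' 288 paired differences and divides by 287; that form is the default, with
#' `denominator = 288` available as an escape hatch.
#'
#' @param day1,day2 Two complete 288-sample days from the same patient.
#' @param denominator Either 287 (as printed, default) or 288.
#' @return MODD in mmol/L.
#' @export
modd <- function(day1, day2, denominator = 287) {
  day1 <- check_day(day1)
  day2 <- check_day(day2)
  if (!denominator %in% c(287, 288)) {
    rlang::abort("`denominator` must be 287 or 288", class = "cgmboost_config_error")
  }
  sum(abs(day1 - day2)) / denominator
}

#' Excess area under/over the glucose curve (AUC)
#'
#' Area of the curve above the upper threshold plus area below the lower
#' threshold, in mmol/L*h. Integration is trapezoidal on the slot-midpoint
#' grid extended to the day boundaries by constant continuation, so the
#' integral covers the full 24 h (for a constant excess `c` it equals
#' `24 * c` exactly).
#'
#' @inheritParams daily_mean
#' @param thresholds A [threshold_config()].
#' @return Excess AUC in mmol/L*h; 0 when the curve stays inside the range.
#' @export
auc_excess <- function(day, thresholds = threshold_config()) {
  day <- check_day(day)
  stopifnot(inherits(thresholds, "threshold_config"))
  t_h <- c(0, slot_midpoints() / 60, 24)
  area <- function(excess) {
    pracma::trapz(t_h, c(excess[1], excess, excess[DAY_LEN]))
  }
  area(pmax(day - thresholds$upper, 0)) + area(pmax(thresholds$lower - day, 0))
}

# Collapse runs of equal consecutive values to the run's midpoint sample so
# that strict sign-change extrema are well defined on plateaus.
collapse_plateaus <- function(day) {
  r <- rle(day)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  list(values = r$values, index = (starts + ends) %/% 2L)
}

# Interior local extrema of a day-curve after plateau collapse.
# Returns values, indices into the original day, and type (+1 max / -1 min).
local_extrema <- function(day) {
  cp <- collapse_plateaus(day)
  v <- cp$values
  n <- length(v)
  if (n < 3) {
    return(list(values = numeric(0), index = integer(0), type = integer(0)))
  }
  s <- sign(diff(v)) # nonzero everywhere after collapse
  turn <- which(s[-1] != s[-(n - 1)]) + 1L # positions 2..n-1 in collapsed series
  list(
    values = v[turn],
    index = cp$index[turn],
    type = as.integer(-s[turn]) # rising then falling (-1 after +1) => max (+1)
  )
}

#' Mean amplitude of glycemic excursions (MAGE)
#'
#' Four-step procedure on one day-curve:
#' 1. collect all interior local extrema (runs of equal values are collapsed
#'    to their midpoint sample first);
#' 2. find the first extreme point whose absolute difference to *both*
#'    adjacent extrema exceeds the day's SDBG;
#' 3. starting from that point, take the amplitudes `|ep_i - ep_(i+1)|` of
#'    all consecutive extrema pairs and keep those exceeding the SDBG (each
#'    qualifying pair counted once);
#' 4. return the mean of the kept amplitudes.
#'
#' Returns 0 for monotone days, days with fewer than two extrema, or when no
#' extreme point passes step 2.
#'
#' @inheritParams daily_mean
#' @return MAGE in mmol/L.
#' @export
mage <- function(day) {
  day <- check_day(day)
  ext <- local_extrema(day)$values
  k <- length(ext)
  if (k < 2) return(0)
  sd_day <- sdbg(day)
  amps <- abs(diff(ext))
  # step 2: a point with both neighbours further away than one SD
  valid_start <- which(amps[-(k - 1)] > sd_day & amps[-1] > sd_day)
  if (length(valid_start) == 0) return(0)
  keep <- amps[amps > sd_day]
  if (length(keep) == 0) return(0)
  mean(keep)
}

#' High/low excursion counts (TH, TL)
#'
#' In the default `"peaks"` mode, TH is the number of local maxima above the
#' upper threshold and TL the number of local minima below the lower
#' threshold (episode-peak counting). In `"crossings"` mode, TH/TL count
#' maximal runs of samples above/below the respective threshold instead.
#'
#' @inheritParams auc_excess
#' @param mode `"peaks"` (default) or `"crossings"`.
#' @return Named integer vector `c(th = ..., tl = ...)`.
#' @export
excursion_counts <- function(day, thresholds = threshold_config(), mode = c("peaks", "crossings")) {
  day <- check_day(day)
  stopifnot(inherits(thresholds, "threshold_config"))
  mode <- match.arg(mode)
  if (mode == "peaks") {
    ext <- local_extrema(day)
    th <- sum(ext$type == 1L & ext$values > thresholds$upper)
    tl <- sum(ext$type == -1L & ext$values < thresholds$lower)
  } else {
    runs_above <- rle(day > thresholds$upper)
    runs_below <- rle(day < thresholds$lower)
    th <- sum(runs_above$values)
    tl <- sum(runs_below$values)
  }
  c(th = as.integer(th), tl = as.integer(tl))
}

#' Time-in-range percentages (HL, LL, WL)
#'
#' Percentage of the day's samples above the upper limit (HL), below the
#' lower limit (LL) and within limits (WL = 100 - HL - LL).
#'
#' @inheritParams auc_excess
#' @return Named numeric vector `c(hl = ..., ll = ..., wl = ...)`, percent.
#' @export
time_percentages <- function(day, thresholds = threshold_config()) {
  day <- check_day(day)
  stopifnot(inherits(thresholds, "threshold_config"))
  hl <- 100 * sum(day > thresholds$upper) / DAY_LEN
  ll <- 100 * sum(day < thresholds$lower) / DAY_LEN
  c(hl = hl, ll = ll, wl = 100 - hl - ll)
}

#' Extract the 17 glycemic features from a trace
#'
#' Per-day features are computed on each complete day and averaged across
#' days; MODD is computed on each consecutive day pair and averaged. The
#' trace must have at least two days (MODD needs a day pair).
#'
#' @param trace A [glucose_trace()] with `n_days >= 2`.
#' @param thresholds A [threshold_config()].
#' @param meals A [meal_schedule()].
#' @param modd_denominator 287 (default) or 288, see [modd()].
#' @param th_tl_mode `"peaks"` (default) or `"crossings"`, see
#'   [excursion_counts()].
#' @return A one-row tibble with `patient_id` and the 17 features in
#'   canonical order (see [feature_names()]).
#' @examples
#' tr <- glucose_trace(rep(6, 2 * 288), "P001")
#' extract_features(tr, threshold_config(7))
#' @export
extract_features <- function(trace, thresholds = threshold_config(),
                             meals = meal_schedule(),
                             modd_denominator = 287,
                             th_tl_mode = c("peaks", "crossings")) {
  stopifnot(inherits(trace, "glucose_trace"))
  th_tl_mode <- match.arg(th_tl_mode)
  if (trace$n_days < 2) {
    rlang::abort(
      sprintf("trace %s has %d day(s); MODD requires at least 2 complete days",
              trace$patient_id, trace$n_days),
      class = "cgmboost_data_error"
    )
  }
  days <- trace_days(trace)
  per_day <- vapply(days, function(d) {
    c(mean_day = daily_mean(d),
      window_means(d, meals),
      sdbg = sdbg(d),
      lage = lage(d),
      auc = auc_excess(d, thresholds),
      mage = mage(d),
      excursion_counts(d, thresholds, th_tl_mode),
      time_percentages(d, thresholds))
  }, numeric(16))
  agg <- rowMeans(per_day)
  modds <- vapply(seq_len(trace$n_days - 1L), function(i) {
    modd(days[[i]], days[[i + 1L]], denominator = modd_denominator)
  }, numeric(1))
  out <- c(agg[1:9], modd = mean(modds), agg[10:16])
  names(out) <- c(names(agg)[1:9], "modd", names(agg)[10:16])
  out <- out[feature_names()]
  tibble::as_tibble(c(list(patient_id = trace$patient_id), as.list(out)))
}

#' Feature table for a labeled cohort
#'
#' Maps [extract_features()] over a cohort tibble (columns `patient_id`,
#' `label`, `trace`) and returns the samples-by-features table used by the
#' boosting stage.
#'
#' @param cohort Tibble with columns `patient_id`, `label` (+1 type 1 /
#'   -1 type 2) and `trace` (list of [glucose_trace()] objects), as returned
#'   by [simulate_cohort()] or assembled from [read_cgm_traces()] plus labels.
#' @inheritParams extract_features
#' @return Tibble with `patient_id`, the 17 feature columns and `label`.
#' @export
extract_feature_table <- function(cohort, thresholds = threshold_config(),
                                  meals = meal_schedule(),
                                  modd_denominator = 287,
                                  th_tl_mode = c("peaks", "crossings")) {
  stopifnot(is.data.frame(cohort), all(c("patient_id", "trace") %in% names(cohort)))
  th_tl_mode <- match.arg(th_tl_mode)
  feats <- purrr::map(cohort$trace, extract_features,
    thresholds = thresholds, meals = meals,
    modd_denominator = modd_denominator, th_tl_mode = th_tl_mode
  )
  out <- dplyr::bind_rows(feats)
  out$patient_id <- cohort$patient_id
  if ("label" %in% names(cohort)) out$label <- cohort$label
  out
}
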