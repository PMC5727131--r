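# Seeded simulator of labeled CGM cohorts with type-1/type-2 glycemic
# phenotypes. A day-curve is baseline + circadian drift + three meal-locked
# excursions + optional hypoglycemic dips and brief hyperglycemic spikes +
# white noise, clipped to the sensor range [2, 25] mmol/L.

class_param <- function(x, label) {
  # class-paired parameters are length-2 vectors c(t1d = ..., t2d = ...)
  if (length(x) == 1) return(as.double(x))
  unname(x[if (label == 1) "t1d" else "t2d"])
}

#' Configuration of the synthetic CGM cohort generator
#'
#' Class-paired parameters are length-2 named vectors `c(t1d = , t2d = )`.
#' The default phenotype contrast follows textbook CGM physiology: type 1
#' shows larger meal excursions and more hypoglycemic dips at a lower
#' baseline; type 2 a higher baseline with blunted excursions.
#'
#' Two presets are provided. `"default"` is the contrast above.
#' `"threshold_structured"` makes the two classes share baseline and meal
#' excursions and differ only in the rate of brief spikes into the
#' 7-9 mmol/L band (both classes stay below 10 mmol/L), so the class signal
#' is concentrated in the threshold-dependent features at upper thresholds
#' of 7-8 mmol/L and vanishes from them at 10-11 mmol/L.
#'
#' @param n_per_class Patients per class, `c(t1d = , t2d = )` (default
#'   525 + 525).
#' @param n_days Days per patient, >= 2 (default 2).
#' @param baseline_mean Per-class baseline glucose (mmol/L).
#' @param baseline_sd Between-patient SD of the baseline (mmol/L).
#' @param excursion_amplitude Per-class meal-excursion amplitude (mmol/L).
#' @param amplitude_cv Log-scale between-patient coefficient of variation of
#'   the amplitude.
#' @param meal_peak_min Minutes after a meal at which the excursion peaks.
#' @param meal_width_min Gaussian width (SD, minutes) of a meal excursion.
#' @param circadian_amplitude Amplitude of the slow sinusoidal drift (mmol/L).
#' @param hypo_rate Per-class rate of hypoglycemic dips (events/day).
#' @param hypo_depth Mean dip depth (mmol/L).
#' @param hypo_width_min Gaussian width (SD, minutes) of a dip.
#' @param spike_rate Per-class rate of brief hyperglycemic spikes
#'   (events/day; 0 in the default preset).
#' @param spike_height Mean spike height above baseline (mmol/L).
#' @param spike_width_min Gaussian width (SD, minutes) of a spike.
#' @param wave_amp_range Range `c(min, max)` of a per-patient glycemic
#'   instability oscillation amplitude (mmol/L), drawn uniformly and
#'   identically for both classes; `c(0, 0)` disables it. In the structured
#'   preset this shared oscillation dominates the dispersion features so the
#'   class contrast stays confined to the threshold band.
#' @param wave_period_min Period of the instability oscillation (minutes).
#' @param noise_sd Measurement noise SD (mmol/L).
#' @param clip Sensor dynamic range, mmol/L (default `c(2, 25)`).
#' @param meals A [meal_schedule()] fixing meal clock times.
#' @param seed Master seed; per-patient substreams are derived from it.
#' @param preset `"default"` or `"threshold_structured"` (overridden by any
#'   explicitly supplied argument).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_per_class = c(t1d = 525, t2d = 525),
                              n_days = 2,
                              baseline_mean = c(t1d = 7.0, t2d = 8.5),
                              baseline_sd = 0.5,
                              excursion_amplitude = c(t1d = 4.5, t2d = 2.0),
                              amplitude_cv = 0.15,
                              meal_peak_min = 75,
                              meal_width_min = 40,
                              circadian_amplitude = 0.4,
                              hypo_rate = c(t1d = 0.5, t2d = 0.05),
                              hypo_depth = 3.0,
                              hypo_width_min = 25,
                              spike_rate = c(t1d = 0, t2d = 0),
                              spike_height = 3.2,
                              spike_width_min = 15,
                              wave_amp_range = c(0, 0),
                              wave_period_min = 180,
                              noise_sd = 0.3,
                              clip = c(2, 25),
                              meals = meal_schedule(),
                              seed = 1L,
                              preset = c("default", "threshold_structured")) {
  preset <- match.arg(preset)
  if (preset == "threshold_structured") {
    # class contrast concentrated in brief spikes into the 7-9 mmol/L band;
    # a shared instability oscillation swamps the dispersion features
    if (missing(baseline_mean)) baseline_mean <- c(t1d = 4.7, t2d = 4.7)
    if (missing(baseline_sd)) baseline_sd <- 0.3
    if (missing(excursion_amplitude)) excursion_amplitude <- c(t1d = 1.0, t2d = 1.0)
    if (missing(circadian_amplitude)) circadian_amplitude <- 0.3
    if (missing(hypo_rate)) hypo_rate <- c(t1d = 0, t2d = 0)
    if (missing(spike_rate)) spike_rate <- c(t1d = 3, t2d = 0.3)
    if (missing(spike_height)) spike_height <- 3.2 # peaks ~8, below 10 even on a wave crest
    if (missing(wave_amp_range)) wave_amp_range <- c(0.4, 1.5) # crests stay below 7
  }
  pair <- function(x, what) {
    if (length(x) == 1) x <- c(t1d = unname(x), t2d = unname(x))
    if (length(x) != 2 || is.null(names(x)) || !setequal(names(x), c("t1d", "t2d"))) {
      rlang::abort(sprintf("%s must be a scalar or c(t1d = , t2d = )", what),
                   class = "cgmboost_config_error")
    }
    x[c("t1d", "t2d")]
  }
  cfg <- list(
    n_per_class = pair(n_per_class, "n_per_class"),
    n_days = as.integer(n_days),
    baseline_mean = pair(baseline_mean, "baseline_mean"),
    baseline_sd = as.double(baseline_sd),
    excursion_amplitude = pair(excursion_amplitude, "excursion_amplitude"),
    amplitude_cv = as.double(amplitude_cv),
    meal_peak_min = as.double(meal_peak_min),
    meal_width_min = as.double(meal_width_min),
    circadian_amplitude = as.double(circadian_amplitude),
    hypo_rate = pair(hypo_rate, "hypo_rate"),
    hypo_depth = as.double(hypo_depth),
    hypo_width_min = as.double(hypo_width_min),
    spike_rate = pair(spike_rate, "spike_rate"),
    spike_height = as.double(spike_height),
    spike_width_min = as.double(spike_width_min),
    wave_amp_range = as.double(wave_amp_range),
    wave_period_min = as.double(wave_period_min),
    noise_sd = as.double(noise_sd),
    clip = as.double(clip),
    meals = meals,
    seed = as.integer(seed),
    preset = preset
  )
  if (cfg$n_days < 2) {
    rlang::abort("`n_days` must be >= 2 (MODD needs a day pair)",
                 class = "cgmboost_config_error")
  }
  rates <- c(cfg$baseline_sd, cfg$amplitude_cv, cfg$hypo_rate, cfg$spike_rate,
             cfg$noise_sd, cfg$circadian_amplitude, cfg$wave_amp_range)
  if (length(cfg$wave_amp_range) != 2 || cfg$wave_amp_range[1] > cfg$wave_amp_range[2] ||
      cfg$wave_period_min <= 0) {
    rlang::abort("wave_amp_range must be c(min, max) with min <= max and a positive period",
                 class = "cgmboost_config_error")
  }
  if (any(rates < 0) || any(cfg$n_per_class < 1)) {
    rlang::abort("rates/SDs must be >= 0 and n_per_class >= 1",
                 class = "cgmboost_config_error")
  }
  if (length(cfg$clip) != 2 || cfg$clip[1] <= 0 || cfg$clip[1] >= cfg$clip[2]) {
    rlang::abort("`clip` must be c(low, high) with 0 < low < high",
                 class = "cgmboost_config_error")
  }
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> preset %s: %d + %d patients x %d days; baseline %.1f/%.1f, amplitude %.1f/%.1f mmol/L; seed %d\n",
    x$preset, x$n_per_class[1], x$n_per_class[2], x$n_days,
    x$baseline_mean[1], x$baseline_mean[2],
    x$excursion_amplitude[1], x$excursion_amplitude[2], x$seed
  ))
  invisible(x)
}

#' Remove the class contrast from a simulation config
#'
#' Replaces every class-paired parameter by its class average, so the two
#' classes are drawn from identical distributions (a no-signal null cohort).
#'
#' @param config A [simulation_config()].
#' @return The modified config.
#' @export
zero_contrast <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  for (p in c("baseline_mean", "excursion_amplitude", "hypo_rate", "spike_rate")) {
    config[[p]][] <- mean(config[[p]])
  }
  config
}

# Deterministic per-patient seed derived from the master seed; stays below
# 2^31 so it is a valid R integer seed.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + index * 2654435) %% 2147483647)
}

gaussian_bump <- function(t_min, center, width) {
  exp(-0.5 * ((t_min - center) / width)^2)
}

#' Simulate one CGM trace
#'
#' @param label +1 (type 1) or -1 (type 2).
#' @param config A [simulation_config()].
#' @param seed Integer seed for this patient's substream.
#' @param patient_id Identifier for the resulting trace.
#' @return A [glucose_trace()] with `config$n_days` days.
#' @export
simulate_trace <- function(label, config, seed, patient_id = "sim") {
  stopifnot(inherits(config, "simulation_config"), label %in% c(-1, 1))
  values <- with_seed(seed, {
    t_min <- slot_midpoints()
    base <- stats::rnorm(1, class_param(config$baseline_mean, label), config$baseline_sd)
    amp0 <- class_param(config$excursion_amplitude, label)
    amp <- if (amp0 > 0) amp0 * exp(stats::rnorm(1, 0, config$amplitude_cv)) else 0
    wave_amp <- stats::runif(1, config$wave_amp_range[1], config$wave_amp_range[2])
    days <- lapply(seq_len(config$n_days), function(d) {
      g <- base + config$circadian_amplitude * sin(2 * pi * (t_min - 600) / 1440)
      if (wave_amp > 0) {
        g <- g + wave_amp * sin(2 * pi * (t_min - stats::runif(1, 0, config$wave_period_min)) /
                                  config$wave_period_min)
      }
      for (mt in config$meals$meals) {
        g <- g + amp * stats::runif(1, 0.8, 1.2) *
          gaussian_bump(t_min, mt + config$meal_peak_min, config$meal_width_min)
      }
      n_hypo <- stats::rpois(1, class_param(config$hypo_rate, label))
      for (i in seq_len(n_hypo)) {
        g <- g - max(stats::rnorm(1, config$hypo_depth, 0.5), 0) *
          gaussian_bump(t_min, stats::runif(1, 0, 1440), config$hypo_width_min)
      }
      n_spike <- stats::rpois(1, class_param(config$spike_rate, label))
      for (i in seq_len(n_spike)) {
        g <- g + max(stats::rnorm(1, config$spike_height, 0.3), 0) *
          gaussian_bump(t_min, stats::runif(1, 0, 1440), config$spike_width_min)
      }
      g + stats::rnorm(length(t_min), 0, config$noise_sd)
    })
    pmin(pmax(unlist(days), config$clip[1]), config$clip[2])
  })
  glucose_trace(values, patient_id)
}

#' Simulate a labeled CGM cohort
#'
#' Generates `n_per_class["t1d"]` type-1 and `n_per_class["t2d"]` type-2
#' patients. Each patient uses an independent substream derived from the
#' master seed, so cohorts are reproducible and removing one patient leaves
#' all others unchanged.
#'
#' @param config A [simulation_config()].
#' @return Tibble with columns `patient_id`, `label` (+1/-1) and `trace`
#'   (list of [glucose_trace()]), type 1 first.
#' @examples
#' cfg <- simulation_config(n_per_class = c(t1d = 3, t2d = 3), seed = 7)
#' simulate_cohort(cfg)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n1 <- config$n_per_class["t1d"]
  n2 <- config$n_per_class["t2d"]
  ids <- c(sprintf("T1D_%04d", seq_len(n1)), sprintf("T2D_%04d", seq_len(n2)))
  labels <- c(rep(1L, n1), rep(-1L, n2))
  traces <- purrr::map(seq_along(ids), function(i) {
    simulate_trace(labels[i], config, derive_seed(config$seed, i), ids[i])
  })
  tibble::tibble(patient_id = ids, label = labels, trace = traces)
}
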