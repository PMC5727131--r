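# Programmatic fixtures shared across tests.

# smooth-ish random positive day-curve on the 288-sample grid
random_day <- function() {
  base <- runif(1, 4, 9)
  walk <- cumsum(rnorm(288, 0, 0.15))
  wave <- runif(1, 0, 2.5) * sin(2 * pi * (1:288) / runif(1, 40, 300))
  pmax(base + walk - mean(walk) + wave + rnorm(288, 0, 0.2), 0.5)
}

random_trace <- function(n_days = 2, patient_id = "R") {
  glucose_trace(unlist(replicate(n_days, random_day(), simplify = FALSE)), patient_id)
}

# triangle wave oscillating lo <-> hi with period 2*half slots, starting at lo
triangle_day <- function(lo = 4, hi = 9, half = 24) {
  up <- seq(lo, hi, length.out = half + 1)[-(half + 1)]
  down <- seq(hi, lo, length.out = half + 1)[-(half + 1)]
  rep_len(c(up, down), 288)
}

# XOR pattern: 4 points in 2 features, opposite corners share a label, so no
# single stump separates them. Coordinates are jittered off the exact
# corners: at exact corners every univariate weak learner sits exactly at
# chance (zero edge) and no boosting variant can move at all, and a negative
# point that is extreme on both features forces score(a) = -score(d) for
# every stump combination. With one positive point as the f2 maximum the
# pattern is boostable to zero training error.
xor_data <- function() {
  tibble::tibble(
    f1 = c(0.0, 0.1, 0.9, 1.0),
    f2 = c(0.0, 1.2, 0.1, 1.1),
    label = c(-1, 1, 1, -1)
  )
}

# random labeled feature table (pure noise unless shift > 0)
random_feature_data <- function(n = 40, p = 5, shift = 0) {
  y <- rep(c(1L, -1L), length.out = n)
  X <- matrix(rnorm(n * p), n, p) + shift * y
  d <- tibble::as_tibble(as.data.frame(X))
  names(d) <- paste0("f", seq_len(p))
  d$label <- y
  d
}

small_cohort <- function(n_per_class = 20, seed = 11, ...) {
  simulate_cohort(simulation_config(
    n_per_class = c(t1d = n_per_class, t2d = n_per_class), seed = seed, ...
  ))
}
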