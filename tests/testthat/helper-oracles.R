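# Independent brute-force oracles, coded with explicit loops and scans so
# they share no code path with the package implementations.

oracle_mean <- function(day) {
  s <- 0
  for (x in day) s <- s + x
  s / length(day)
}

oracle_sdbg <- function(day) {
  m <- oracle_mean(day)
  ss <- 0
  for (x in day) ss <- ss + (x - m)^2
  sqrt(ss / length(day))
}

oracle_lage <- function(day) {
  lo <- Inf; hi <- -Inf
  for (x in day) {
    if (x < lo) lo <- x
    if (x > hi) hi <- x
  }
  hi - lo
}

oracle_modd <- function(d1, d2, denominator = 287) {
  s <- 0
  for (i in 1:288) s <- s + abs(d1[i] - d2[i])
  s / denominator
}

# rectangle rule per 5-min slot; equals the package's boundary-extended
# trapezoid by construction, but summed independently
oracle_auc <- function(day, upper, lower) {
  s <- 0
  for (x in day) {
    if (x > upper) s <- s + (x - upper) / 12
    if (x < lower) s <- s + (lower - x) / 12
  }
  s
}

oracle_window_means <- function(day, meal_min, pre = 30, post = 120) {
  pre_vals <- c(); post_vals <- c()
  for (i in 1:288) {
    mid <- (i - 1) * 5 + 2.5
    if (mid >= meal_min - pre && mid < meal_min) pre_vals <- c(pre_vals, day[i])
    if (mid > meal_min && mid <= meal_min + post) post_vals <- c(post_vals, day[i])
  }
  c(pre = mean(pre_vals), post = mean(post_vals))
}

oracle_time_pct <- function(day, upper, lower) {
  hi <- 0; lo <- 0
  for (x in day) {
    if (x > upper) hi <- hi + 1
    if (x < lower) lo <- lo + 1
  }
  c(hl = 100 * hi / 288, ll = 100 * lo / 288, wl = 100 * (288 - hi - lo) / 288)
}

# plateau-collapsed series by explicit scan (values of runs of equals)
oracle_collapse <- function(day) {
  v <- day[1]
  for (i in 2:length(day)) {
    if (day[i] != v[length(v)]) v <- c(v, day[i])
  }
  v
}

# interior turning points of the collapsed series; type +1 max / -1 min
oracle_extrema <- function(day) {
  v <- oracle_collapse(day)
  vals <- c(); type <- c()
  if (length(v) >= 3) {
    for (j in 2:(length(v) - 1)) {
      if (v[j] > v[j - 1] && v[j] > v[j + 1]) {
        vals <- c(vals, v[j]); type <- c(type, 1)
      } else if (v[j] < v[j - 1] && v[j] < v[j + 1]) {
        vals <- c(vals, v[j]); type <- c(type, -1)
      }
    }
  }
  list(values = vals, type = type)
}

oracle_mage <- function(day) {
  ep <- oracle_extrema(day)$values
  k <- length(ep)
  if (k < 2) return(0)
  sd_day <- oracle_sdbg(day)
  start <- NA
  for (j in 2:max(k - 1, 2)) {
    if (j <= k - 1 &&
        abs(ep[j] - ep[j - 1]) > sd_day && abs(ep[j] - ep[j + 1]) > sd_day) {
      start <- j
      break
    }
  }
  if (is.na(start)) return(0)
  total <- 0; count <- 0
  for (j in 1:(k - 1)) {
    a <- abs(ep[j] - ep[j + 1])
    if (a > sd_day) {
      total <- total + a
      count <- count + 1
    }
  }
  if (count == 0) 0 else total / count
}

oracle_counts <- function(day, upper, lower) {
  ex <- oracle_extrema(day)
  th <- 0; tl <- 0
  for (j in seq_along(ex$values)) {
    if (ex$type[j] == 1 && ex$values[j] > upper) th <- th + 1
    if (ex$type[j] == -1 && ex$values[j] < lower) tl <- tl + 1
  }
  c(th = th, tl = tl)
}

# all 17 features of a multi-day trace, composed from the per-day oracles
oracle_features <- function(values, upper, lower,
                            meals = c(breakfast = 450, lunch = 720, dinner = 1080)) {
  n_days <- length(values) / 288
  days <- lapply(1:n_days, function(d) values[((d - 1) * 288 + 1):(d * 288)])
  per_day <- sapply(days, function(d) {
    wb <- oracle_window_means(d, meals[1])
    wl_ <- oracle_window_means(d, meals[2])
    wd <- oracle_window_means(d, meals[3])
    cts <- oracle_counts(d, upper, lower)
    pct <- oracle_time_pct(d, upper, lower)
    c(mean_day = oracle_mean(d),
      mean_pre_breakfast = wb["pre"], mean_pre_lunch = wl_["pre"], mean_pre_dinner = wd["pre"],
      mean_post_breakfast = wb["post"], mean_post_lunch = wl_["post"], mean_post_dinner = wd["post"],
      sdbg = oracle_sdbg(d), lage = oracle_lage(d),
      auc = oracle_auc(d, upper, lower), mage = oracle_mage(d),
      th = cts["th"], tl = cts["tl"], hl = pct["hl"], ll = pct["ll"], wl = pct["wl"])
  })
  agg <- rowMeans(per_day)
  names(agg) <- sub("\\.(pre|post|th|tl|hl|ll|wl)$", "", names(agg))
  modds <- sapply(seq_len(n_days - 1), function(i) oracle_modd(days[[i]], days[[i + 1]]))
  out <- c(agg, modd = mean(modds))
  out[c("mean_day", "mean_pre_breakfast", "mean_pre_lunch", "mean_pre_dinner",
        "mean_post_breakfast", "mean_post_lunch", "mean_post_dinner",
        "sdbg", "lage", "modd", "auc", "mage", "th", "tl", "hl", "ll", "wl")]
}

# Exhaustive decision-stump search by triple loop (feature, cut, polarity).
# Same learner family and tie-break as the trainer: thresholds are midpoints
# of consecutive sorted unique values, first (feature, threshold) minimum wins.
oracle_best_stump <- function(X, y, w) {
  best_err <- Inf
  best <- NULL
  for (f in seq_len(ncol(X))) {
    u <- sort(unique(X[, f]))
    if (length(u) < 2) next
    for (c_i in seq_len(length(u) - 1)) {
      thr <- (u[c_i] + u[c_i + 1]) / 2
      for (pol in c(1, -1)) {
        err <- 0
        for (i in seq_along(y)) {
          h <- pol * (if (X[i, f] > thr) 1 else -1)
          if (h != y[i]) err <- err + w[i]
        }
        if (err < best_err - 1e-15) {
          best_err <- err
          best <- list(err = err, feature = f, threshold = thr, polarity = pol)
        }
      }
    }
  }
  best
}

# Independent Modest AdaBoost over per-feature equal-frequency blocks,
# written with explicit loops; mirrors the published formulation
# (inverted distribution, f = p+(1-pbar+) - p-(1-pbar-)).
oracle_modest <- function(X, y, T, n_bins = 2) {
  m <- nrow(X)
  edges <- list()
  for (f in seq_len(ncol(X))) {
    q <- unique(quantile(X[, f], probs = seq(0, 1, length.out = n_bins + 1),
                         names = FALSE, type = 7))
    edges[[f]] <- unique(q[-c(1, length(q))])
  }
  bin_of <- function(x, f) {
    b <- 1
    for (e in edges[[f]]) if (x > e) b <- b + 1
    b
  }
  w <- rep(1 / m, m)
  rounds <- list()
  for (t in seq_len(T)) {
    wbar <- (1 - w) / sum(1 - w)
    best_gain <- -Inf; best <- NULL
    for (f in seq_len(ncol(X))) {
      nb <- length(edges[[f]]) + 1
      pp <- rep(0, nb); pn <- rep(0, nb); bp <- rep(0, nb); bn <- rep(0, nb)
      for (i in seq_len(m)) {
        b <- bin_of(X[i, f], f)
        if (y[i] == 1) {
          pp[b] <- pp[b] + w[i]; bp[b] <- bp[b] + wbar[i]
        } else {
          pn[b] <- pn[b] + w[i]; bn[b] <- bn[b] + wbar[i]
        }
      }
      out <- pp * (1 - bp) - pn * (1 - bn)
      gain <- 0
      for (i in seq_len(m)) gain <- gain + w[i] * y[i] * out[bin_of(X[i, f], f)]
      if (gain > best_gain + 1e-15) {
        best_gain <- gain
        best <- list(feature = f, out = out)
      }
    }
    if (best_gain <= 0) break
    rounds[[t]] <- best
    for (i in seq_len(m)) {
      w[i] <- w[i] * exp(-y[i] * best$out[bin_of(X[i, best$feature], best$feature)])
    }
    w <- w / sum(w)
  }
  predict_fn <- function(Xn) {
    s <- rep(0, nrow(Xn))
    for (r in rounds) {
      for (i in seq_len(nrow(Xn))) {
        s[i] <- s[i] + r$out[bin_of(Xn[i, r$feature], r$feature)]
      }
    }
    ifelse(s >= 0, 1, -1)
  }
  list(rounds = rounds, predict = predict_fn)
}
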