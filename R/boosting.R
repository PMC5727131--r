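# Stage 2: from-scratch binary AdaBoost ensembles over the feature space.
#
# Four variants share the round structure  (fit weak learner under the
# current sample weights; reweight; normalize) and differ in the weak
# learner and its output:
#   discrete - hard decision stump h in {-1,+1}, alpha_t = 0.5*ln((1-e)/e)
#   real     - per-feature block partition, output 0.5*log(p+/p-) per block,
#              feature chosen to minimize z = 2*sum_j sqrt(p+_j p-_j)
#   gentle   - regression stump fit by weighted least squares of y on g
#   modest   - block outputs damped by the inverted weight distribution:
#              f_j = p+_j(1 - pbar+_j) - p-_j(1 - pbar-_j)

#' Fit an AdaBoost ensemble on a labeled feature table
#'
#' Trains `n_rounds` weak learners on the numeric feature columns of `data`
#' (every numeric column except `label`; `patient_id` is ignored). Labels
#' must be +1 (type 1) / -1 (type 2), or `"T1D"`/`"T2D"`. Weights start at
#' 1/m and are renormalized to sum to 1 after every round. Training is
#' deterministic: stump thresholds are midpoints between consecutive sorted
#' unique feature values, ties in the round objective are broken by lowest
#' feature index then lowest threshold, and block edges (real/modest) are
#' equal-frequency quantiles computed once from the training data.
#'
#' Early stopping: a perfect stump (weighted error 0) is kept with its error
#' floored at 1e-10 for the weight formula and training stops; a round in
#' which no stump beats chance (error exactly 0.5) or a Modest round whose
#' best learner has non-positive weighted margin gain stops training before
#' adding the useless learner.
#'
#' @param data Data frame with a `label` column and the feature columns.
#' @param variant One of `"discrete"`, `"real"`, `"gentle"`, `"modest"`.
#' @param n_rounds Number of boosting rounds T (default 100).
#' @param n_bins Number of blocks per feature for the real/modest variants
#'   (default 8, equal-frequency edges).
#' @return An object of class `boost_model`. Inspect with [tidy()] (one row
#'   per round) and [glance()]; predict with [predict.boost_model()].
#' @examples
#' d <- tibble::tibble(x = c(1, 2, 3, 4), label = c(-1, -1, 1, 1))
#' m <- fit_adaboost(d, "discrete", n_rounds = 3)
#' predict(m, d)
#' @export
fit_adaboost <- function(data, variant = c("discrete", "real", "gentle", "modest"),
                         n_rounds = 100, n_bins = 8) {
  variant <- match.arg(variant)
  if (!is.data.frame(data) || !"label" %in% names(data)) {
    rlang::abort("`data` must be a data frame with a `label` column",
                 class = "cgmboost_data_error")
  }
  y <- label_to_int(data$label)
  feat_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                       c("label", "patient_id"))
  if (length(feat_cols) == 0) {
    rlang::abort("no numeric feature columns found", class = "cgmboost_data_error")
  }
  X <- as.matrix(data[, feat_cols, drop = FALSE])
  storage.mode(X) <- "double"
  m <- nrow(X)
  if (m < 2) rlang::abort("need at least 2 samples", class = "cgmboost_data_error")
  if (any(!is.finite(X))) {
    rlang::abort("features must be finite", class = "cgmboost_data_error")
  }
  if (length(unique(y)) < 2) {
    rlang::abort("both classes (+1/-1) must be present in the training data",
                 class = "cgmboost_data_error")
  }
  if (!is.numeric(n_rounds) || n_rounds < 1) {
    rlang::abort("`n_rounds` must be >= 1", class = "cgmboost_config_error")
  }
  n_rounds <- as.integer(n_rounds)

  fit <- switch(variant,
    discrete = boost_discrete(X, y, n_rounds),
    real = boost_blockwise(X, y, n_rounds, n_bins, modest = FALSE),
    gentle = boost_gentle(X, y, n_rounds),
    modest = boost_blockwise(X, y, n_rounds, n_bins, modest = TRUE)
  )

  model <- structure(
    c(list(variant = variant, feature_names = feat_cols,
           requested_rounds = n_rounds, n_bins = n_bins),
      fit),
    class = "boost_model"
  )
  scores <- predict(model, data, type = "score")
  model$train_error <- mean(sign_pos(scores) != y)
  model
}

# sign with the documented tie rule sign(0) -> +1
sign_pos <- function(s) ifelse(s >= 0, 1L, -1L)

# ---- discrete -------------------------------------------------------------

# Exhaustive weighted-error-minimizing decision stump.
# h(x) = polarity * (+1 if x > threshold else -1).
best_class_stump <- function(X, y, w, ord) {
  m <- nrow(X)
  total_w <- sum(w)
  best <- list(err = Inf, feature = NA_integer_, threshold = NA_real_,
               polarity = NA_integer_)
  for (f in seq_len(ncol(X))) {
    o <- ord[[f]]
    xs <- X[o, f]
    cuts <- which(diff(xs) > 0)
    if (length(cuts) == 0) next
    cpos <- cumsum(w[o] * (y[o] == 1))
    cneg <- cumsum(w[o] * (y[o] == -1))
    # polarity +1: predict -1 on the left block, +1 on the right
    errA <- cpos[cuts] + (cneg[m] - cneg[cuts])
    errB <- total_w - errA
    err <- pmin(errA, errB)
    k <- which.min(err) # first minimum -> lowest threshold
    if (err[k] < best$err - 1e-15) {
      cut <- cuts[k]
      best <- list(
        err = err[k],
        feature = f,
        threshold = (xs[cut] + xs[cut + 1]) / 2,
        polarity = if (errA[k] <= errB[k]) 1L else -1L
      )
    }
  }
  if (!is.finite(best$err)) {
    rlang::abort("all features are constant; no stump can be fit",
                 class = "cgmboost_data_error")
  }
  best
}

stump_predict <- function(x, threshold, polarity) {
  polarity * (2L * (x > threshold) - 1L)
}

boost_discrete <- function(X, y, n_rounds) {
  m <- nrow(X)
  ord <- lapply(seq_len(ncol(X)), function(f) order(X[, f]))
  w <- rep(1 / m, m)
  feature <- integer(0); threshold <- numeric(0); polarity <- integer(0)
  alphas <- numeric(0); eps_seq <- numeric(0)
  stop_reason <- NA_character_
  for (t in seq_len(n_rounds)) {
    st <- best_class_stump(X, y, w, ord)
    eps <- st$err / sum(w)
    if (eps >= 0.5) {
      stop_reason <- sprintf("round %d: no stump beats chance (eps = %.3f)", t, eps)
      break
    }
    eps_eff <- max(eps, 1e-10)
    a <- 0.5 * log((1 - eps_eff) / eps_eff)
    feature <- c(feature, st$feature)
    threshold <- c(threshold, st$threshold)
    polarity <- c(polarity, st$polarity)
    alphas <- c(alphas, a)
    eps_seq <- c(eps_seq, eps)
    h <- stump_predict(X[, st$feature], st$threshold, st$polarity)
    w <- w * exp(-a * y * h)
    w <- w / sum(w)
    if (eps == 0) {
      stop_reason <- sprintf("round %d: perfect stump (eps = 0); stopping", t)
      break
    }
  }
  list(
    n_rounds = length(alphas),
    learners = tibble::tibble(
      round = seq_along(alphas), feature_index = feature,
      threshold = threshold, polarity = polarity
    ),
    alphas = alphas,
    round_stats = tibble::tibble(round = seq_along(alphas), eps = eps_seq, alpha = alphas),
    stop_reason = stop_reason
  )
}

# ---- gentle ---------------------------------------------------------------

# Weighted least-squares regression stump: piecewise-constant fit of y on
# one feature, outputs = weighted mean of y on each side of the cut.
best_reg_stump <- function(X, y, w, ord) {
  m <- nrow(X)
  best <- list(gain = -Inf, feature = NA_integer_, threshold = NA_real_,
               left = NA_real_, right = NA_real_)
  for (f in seq_len(ncol(X))) {
    o <- ord[[f]]
    xs <- X[o, f]
    cuts <- which(diff(xs) > 0)
    if (length(cuts) == 0) next
    cw <- cumsum(w[o])
    cwy <- cumsum(w[o] * y[o])
    lw <- cw[cuts]; ly <- cwy[cuts]
    rw <- cw[m] - lw; ry <- cwy[m] - ly
    # minimizing weighted SSE == maximizing (sum wy)^2 / (sum w) per side
    gain <- ifelse(lw > 0, ly^2 / lw, 0) + ifelse(rw > 0, ry^2 / rw, 0)
    k <- which.max(gain)
    if (gain[k] > best$gain + 1e-15) {
      cut <- cuts[k]
      best <- list(
        gain = gain[k],
        feature = f,
        threshold = (xs[cut] + xs[cut + 1]) / 2,
        left = if (lw[k] > 0) ly[k] / lw[k] else 0,
        right = if (rw[k] > 0) ry[k] / rw[k] else 0
      )
    }
  }
  if (!is.finite(best$gain)) {
    rlang::abort("all features are constant; no stump can be fit",
                 class = "cgmboost_data_error")
  }
  best
}

boost_gentle <- function(X, y, n_rounds) {
  m <- nrow(X)
  ord <- lapply(seq_len(ncol(X)), function(f) order(X[, f]))
  w <- rep(1 / m, m)
  feature <- integer(0); threshold <- numeric(0)
  left <- numeric(0); right <- numeric(0)
  for (t in seq_len(n_rounds)) {
    st <- best_reg_stump(X, y, w / sum(w), ord)
    feature <- c(feature, st$feature)
    threshold <- c(threshold, st$threshold)
    left <- c(left, st$left)
    right <- c(right, st$right)
    h <- ifelse(X[, st$feature] > st$threshold, st$right, st$left)
    w <- w * exp(-y * h)
    w <- w / sum(w)
  }
  list(
    n_rounds = length(feature),
    learners = tibble::tibble(
      round = seq_along(feature), feature_index = feature,
      threshold = threshold, left_value = left, right_value = right
    ),
    alphas = rep(1, length(feature)),
    round_stats = tibble::tibble(round = seq_along(feature)),
    stop_reason = NA_character_
  )
}

# ---- real / modest (block learners) ---------------------------------------

# Equal-frequency interior edges for one feature, computed once from the
# training data; findInterval(x, edges) + 1 maps any value into 1..n_blocks.
block_edges <- function(x, n_bins) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  edges <- qs[-c(1, length(qs))]
  unique(edges)
}

bin_sums <- function(v, bin, n_blocks) {
  out <- numeric(n_blocks)
  s <- rowsum(v, bin)
  out[as.integer(rownames(s))] <- s
  out
}

boost_blockwise <- function(X, y, n_rounds, n_bins, modest) {
  m <- nrow(X)
  p <- ncol(X)
  if (n_bins < 2) rlang::abort("`n_bins` must be >= 2", class = "cgmboost_config_error")
  edges <- lapply(seq_len(p), function(f) block_edges(X[, f], n_bins))
  n_blocks <- vapply(edges, function(e) length(e) + 1L, integer(1))
  bins <- vapply(seq_len(p), function(f) findInterval(X[, f], edges[[f]]) + 1L,
                 integer(m))
  bins <- matrix(bins, nrow = m)
  eps_s <- 1 / (4 * m) # Schapire-Singer smoothing
  w <- rep(1 / m, m)
  pos <- y == 1
  feature <- integer(0); outputs <- list()
  stats_rows <- list()
  stop_reason <- NA_character_
  for (t in seq_len(n_rounds)) {
    if (modest) {
      wbar <- (1 - w) / sum(1 - w)
    }
    best <- NULL
    for (f in seq_len(p)) {
      b <- bins[, f]
      wp <- bin_sums(w * pos, b, n_blocks[f])
      wn <- bin_sums(w * !pos, b, n_blocks[f])
      if (modest) {
        wbp <- bin_sums(wbar * pos, b, n_blocks[f])
        wbn <- bin_sums(wbar * !pos, b, n_blocks[f])
        out <- wp * (1 - wbp) - wn * (1 - wbn)
        crit <- sum(w * y * out[b]) # weighted margin gain, maximized
        better <- is.null(best) || crit > best$crit + 1e-15
      } else {
        out <- 0.5 * log((wp + eps_s) / (wn + eps_s))
        out[wp + wn == 0] <- 0
        crit <- 2 * sum(sqrt(wp * wn)) # z, minimized
        better <- is.null(best) || crit < best$crit - 1e-15
      }
      if (better) best <- list(crit = crit, feature = f, out = out)
    }
    if (modest && best$crit <= 0) {
      stop_reason <- sprintf("round %d: no learner with positive margin gain", t)
      break
    }
    feature <- c(feature, best$feature)
    outputs[[length(outputs) + 1L]] <- best$out
    stats_rows[[length(stats_rows) + 1L]] <-
      if (modest) tibble::tibble(round = t, gain = best$crit)
      else tibble::tibble(round = t, z = best$crit)
    h <- best$out[bins[, best$feature]]
    w <- w * exp(-y * h)
    w <- w / sum(w)
  }
  list(
    n_rounds = length(feature),
    learners = tibble::tibble(
      round = seq_along(feature), feature_index = feature,
      bin_outputs = outputs
    ),
    alphas = rep(1, length(feature)),
    edges = edges,
    round_stats = if (length(stats_rows)) dplyr::bind_rows(stats_rows)
                  else tibble::tibble(round = integer()),
    stop_reason = stop_reason
  )
}

# ---- prediction -----------------------------------------------------------

model_matrix <- function(model, new_data) {
  missing_cols <- setdiff(model$feature_names, names(new_data))
  if (length(missing_cols)) {
    rlang::abort(paste0("new data lacks feature columns: ",
                        paste(missing_cols, collapse = ", ")),
                 class = "cgmboost_data_error")
  }
  X <- as.matrix(new_data[, model$feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

# n x T matrix of per-round weighted weak-learner outputs alpha_t * h_t(x)
contribution_matrix <- function(model, X) {
  Tn <- model$n_rounds
  n <- nrow(X)
  out <- matrix(0, n, max(Tn, 1))
  if (Tn == 0) return(out[, 0, drop = FALSE])
  L <- model$learners
  for (t in seq_len(Tn)) {
    f <- L$feature_index[t]
    x <- X[, f]
    h <- if (model$variant == "discrete") {
      stump_predict(x, L$threshold[t], L$polarity[t])
    } else if (model$variant == "gentle") {
      ifelse(x > L$threshold[t], L$right_value[t], L$left_value[t])
    } else {
      b <- findInterval(x, model$edges[[f]]) + 1L
      L$bin_outputs[[t]][b]
    }
    out[, t] <- model$alphas[t] * h
  }
  out
}

#' Predict with a boosting model
#'
#' The ensemble score is `sum_t alpha_t h_t(g)` (alpha_t = 1 for the real,
#' gentle and modest variants); the class is its sign, with a score of
#' exactly 0 mapped to +1.
#'
#' @param object A `boost_model`.
#' @param new_data Data frame containing the model's feature columns.
#' @param type `"class"` (default, +1/-1) or `"score"` (real-valued).
#' @param ... Unused.
#' @return Numeric vector of labels or scores, one per row of `new_data`.
#' @export
predict.boost_model <- function(object, new_data, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- model_matrix(object, new_data)
  s <- rowSums(contribution_matrix(object, X))
  if (type == "score") s else sign_pos(s)
}

#' Per-round test error of a boosting model
#'
#' Error rate of the truncated ensemble using only the first t learners,
#' for t = 1..T, on a labeled evaluation set.
#'
#' @param model A `boost_model`.
#' @param new_data Data frame with the feature columns and a `label` column.
#' @return Tibble with columns `round` and `error_rate`.
#' @export
staged_errors <- function(model, new_data) {
  stopifnot(inherits(model, "boost_model"))
  if (!"label" %in% names(new_data)) {
    rlang::abort("`new_data` needs a `label` column", class = "cgmboost_data_error")
  }
  y <- label_to_int(new_data$label)
  X <- model_matrix(model, new_data)
  if (model$n_rounds == 0) {
    return(tibble::tibble(round = integer(), error_rate = numeric()))
  }
  contrib <- contribution_matrix(model, X)
  cum <- t(apply(contrib, 1, cumsum))
  if (model$n_rounds == 1) cum <- matrix(contrib, ncol = 1)
  err <- vapply(seq_len(model$n_rounds),
                function(t) mean(sign_pos(cum[, t]) != y), numeric(1))
  tibble::tibble(round = seq_len(model$n_rounds), error_rate = err)
}

#' @export
print.boost_model <- function(x, ...) {
  cat(sprintf(
    "<boost_model> %s AdaBoost: %d round(s) over %d features; training error %.4f\n",
    x$variant, x$n_rounds, length(x$feature_names),
    if (is.null(x$train_error)) NA_real_ else x$train_error
  ))
  if (!is.na(x$stop_reason)) cat("  stopped early:", x$stop_reason, "\n")
  invisible(x)
}

#' Tidy a boosting model
#'
#' One row per boosting round with the learner's feature and parameters
#' (threshold/polarity for discrete, threshold/left/right for gentle,
#' block outputs as a list column for real/modest) plus round statistics.
#'
#' @param x A `boost_model`.
#' @param ... Unused.
#' @return A tibble with one row per round.
#' @exportS3Method generics::tidy
tidy.boost_model <- function(x, ...) {
  out <- x$learners
  out$feature <- x$feature_names[out$feature_index]
  out$alpha <- x$alphas
  extra <- c("round", setdiff(names(x$round_stats), names(out)))
  dplyr::left_join(out, x$round_stats[, extra, drop = FALSE], by = "round")
}

#' Glance at a boosting model
#'
#' @param x A `boost_model`.
#' @param ... Unused.
#' @return One-row tibble: variant, rounds trained/requested, number of
#'   features, training error.
#' @exportS3Method generics::glance
glance.boost_model <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    n_rounds = x$n_rounds,
    requested_rounds = x$requested_rounds,
    n_features = length(x$feature_names),
    train_error = x$train_error,
    stopped_early = !is.na(x$stop_reason)
  )
}

# ---- serialization --------------------------------------------------------

#' Serialize / restore a boosting model as JSON
#'
#' Versioned JSON with the variant, feature names, learners, weights and
#' block edges; numbers are written at full precision so that a restored
#' model reproduces identical predictions.
#'
#' @param model A `boost_model`.
#' @param path JSON file path.
#' @return `write_boost_model()`: `path` invisibly. `read_boost_model()`:
#'   the restored `boost_model`.
#' @export
write_boost_model <- function(model, path) {
  stopifnot(inherits(model, "boost_model"))
  payload <- list(
    format = "cgmboost_model", version = 1L,
    variant = model$variant,
    feature_names = model$feature_names,
    n_rounds = model$n_rounds,
    requested_rounds = model$requested_rounds,
    n_bins = model$n_bins,
    alphas = model$alphas,
    learners = as.list(model$learners),
    edges = model$edges,
    train_error = model$train_error,
    stop_reason = model$stop_reason
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_boost_model
#' @export
read_boost_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(p$format) || p$format != "cgmboost_model") {
    rlang::abort("not a cgmboost model file", class = "cgmboost_data_error")
  }
  L <- p$learners
  num_col <- function(v) if (is.null(v)) NULL else as.numeric(unlist(v))
  learners <- tibble::tibble(
    round = as.integer(unlist(L$round)),
    feature_index = as.integer(unlist(L$feature_index))
  )
  for (col in c("threshold", "left_value", "right_value")) {
    if (!is.null(L[[col]])) learners[[col]] <- num_col(L[[col]])
  }
  if (!is.null(L$polarity)) learners$polarity <- as.integer(unlist(L$polarity))
  if (!is.null(L$bin_outputs)) {
    learners$bin_outputs <- lapply(L$bin_outputs, function(v) as.numeric(unlist(v)))
  }
  n_rounds <- as.integer(p$n_rounds)
  structure(
    list(
      variant = p$variant,
      feature_names = as.character(unlist(p$feature_names)),
      requested_rounds = as.integer(p$requested_rounds),
      n_bins = as.integer(p$n_bins),
      n_rounds = n_rounds,
      learners = learners,
      alphas = as.numeric(unlist(p$alphas)),
      edges = if (!is.null(p$edges)) lapply(p$edges, function(v) as.numeric(unlist(v))),
      round_stats = tibble::tibble(round = seq_len(n_rounds)),
      stop_reason = if (is.null(p$stop_reason)) NA_character_ else p$stop_reason,
      train_error = as.numeric(p$train_error)
    ),
    class = "boost_model"
  )
}
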