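# Evaluation protocols: confusion-matrix metrics, hold-out split,
# stratified k-fold CV and the upper-threshold (mu) sweep.
# Positive class is +1 (type 1 diabetes) throughout.

#' Confusion matrix for binary +1/-1 labels
#'
#' @param truth,predicted Vectors of labels in {+1, -1}, equal length.
#' @return Object of class `confusion_matrix` with integer counts
#'   `tp`, `fn`, `fp`, `tn` (positive class = +1).
#' @examples
#' cm <- confusion_matrix(c(1, 1, -1, -1), c(1, -1, -1, -1))
#' accuracy(cm); mcc(cm)
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- label_to_int(truth)
  predicted <- label_to_int(predicted)
  if (length(truth) != length(predicted)) {
    rlang::abort("truth and predicted must have equal length", class = "cgmboost_data_error")
  }
  if (length(truth) == 0) {
    rlang::abort("empty label vectors", class = "cgmboost_data_error")
  }
  structure(
    list(
      tp = sum(truth == 1 & predicted == 1),
      fn = sum(truth == 1 & predicted == -1),
      fp = sum(truth == -1 & predicted == 1),
      tn = sum(truth == -1 & predicted == -1)
    ),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fn=%d fp=%d tn=%d (acc %.4f, mcc %.4f)\n",
              x$tp, x$fn, x$fp, x$tn, accuracy(x), mcc(x)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(tp = x$tp, fn = x$fn, fp = x$fp, tn = x$tn)
}

#' @exportS3Method generics::glance
glance.confusion_matrix <- function(x, ...) {
  tibble::tibble(acc = accuracy(x), mcc = mcc(x), error_rate = 1 - accuracy(x))
}

check_cm <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  if (n == 0) rlang::abort("empty confusion matrix", class = "cgmboost_data_error")
  n
}

#' Accuracy: (TP + TN) / (P + N)
#'
#' @param cm A [confusion_matrix()].
#' @return Fraction in [0, 1].
#' @export
accuracy <- function(cm) {
  n <- check_cm(cm)
  (cm$tp + cm$tn) / n
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; returns 0 when
#' the denominator is 0 (e.g. a constant prediction), by the standard
#' convention.
#'
#' @param cm A [confusion_matrix()].
#' @return Value in [-1, 1].
#' @export
mcc <- function(cm) {
  check_cm(cm)
  tp <- as.double(cm$tp); fn <- as.double(cm$fn)
  fp <- as.double(cm$fp); tn <- as.double(cm$tn)
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

# Run a block of code under a temporary RNG state so evaluation protocols
# are seeded without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Hold-out train/test evaluation
#'
#' Seeded shuffle of the samples, train on the first `round(train_ratio * n)`
#' rows, evaluate on the rest. The default ratio 2/7 mirrors a 300:750
#' train:test split.
#'
#' @param data Labeled feature table ([extract_feature_table()] output).
#' @param variant Boosting variant, see [fit_adaboost()].
#' @param n_rounds Boosting rounds T (default 100).
#' @param train_ratio Fraction of samples used for training (default 2/7).
#' @param seed Integer seed for the shuffle.
#' @param n_bins Blocks per feature for real/modest variants.
#' @return Object of class `holdout_eval`: metrics tibble (`error_rate`,
#'   `acc`, `mcc`), per-round `staged` errors, the fitted `model`, the
#'   confusion matrix, and the split sizes.
#' @export
holdout_protocol <- function(data, variant = "discrete", n_rounds = 100,
                             train_ratio = 2 / 7, seed = 1, n_bins = 8) {
  stopifnot(is.data.frame(data), "label" %in% names(data))
  n <- nrow(data)
  n_train <- round(train_ratio * n)
  if (n_train < 2 || n_train >= n) {
    rlang::abort(sprintf("degenerate split: %d train / %d test", n_train, n - n_train),
                 class = "cgmboost_config_error")
  }
  perm <- with_seed(seed, sample.int(n))
  train <- data[perm[seq_len(n_train)], , drop = FALSE]
  test <- data[perm[(n_train + 1):n], , drop = FALSE]
  if (length(unique(label_to_int(train$label))) < 2) {
    rlang::abort("training part contains a single class; use another seed",
                 class = "cgmboost_data_error")
  }
  model <- fit_adaboost(train, variant, n_rounds = n_rounds, n_bins = n_bins)
  pred <- predict(model, test)
  cm <- confusion_matrix(test$label, pred)
  structure(
    list(
      metrics = tibble::tibble(
        variant = variant,
        error_rate = 1 - accuracy(cm),
        acc = accuracy(cm),
        mcc = mcc(cm)
      ),
      staged = staged_errors(model, test),
      model = model,
      cm = cm,
      n_train = n_train,
      n_test = n - n_train,
      seed = seed
    ),
    class = "holdout_eval"
  )
}

#' @export
print.holdout_eval <- function(x, ...) {
  cat(sprintf(
    "<holdout_eval> %s: %d train / %d test; error %.4f, ACC %.4f, MCC %.4f\n",
    x$metrics$variant, x$n_train, x$n_test,
    x$metrics$error_rate, x$metrics$acc, x$metrics$mcc
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.holdout_eval <- function(x, ...) x$staged

#' @exportS3Method generics::glance
glance.holdout_eval <- function(x, ...) {
  dplyr::bind_cols(x$metrics, tibble::tibble(n_train = x$n_train, n_test = x$n_test))
}

#' Stratified k-fold cross-validation
#'
#' Seeded, class-stratified partition into k folds; each fold is held out
#' once. Returns the per-fold staged error curves and their mean.
#'
#' @inheritParams holdout_protocol
#' @param k Number of folds (default 5).
#' @return Object of class `cv_eval`: `folds` tibble (fold, round,
#'   error_rate), `mean_curve`, `fold_errors` (final error per fold),
#'   `mean_error`, and the fold assignment.
#' @export
kfold_cv <- function(data, variant = "discrete", n_rounds = 100, k = 5,
                     seed = 1, n_bins = 8) {
  stopifnot(is.data.frame(data), "label" %in% names(data))
  n <- nrow(data)
  if (k < 2 || n < k) {
    rlang::abort("need k >= 2 and n >= k", class = "cgmboost_config_error")
  }
  y <- label_to_int(data$label)
  fold <- integer(n)
  with_seed(seed, {
    for (cl in c(1L, -1L)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  res <- purrr::map(seq_len(k), function(f) {
    train <- data[fold != f, , drop = FALSE]
    test <- data[fold == f, , drop = FALSE]
    if (length(unique(label_to_int(train$label))) < 2 || nrow(test) == 0) {
      rlang::abort(
        sprintf("fold %d leaves a single-class training set; try another seed or smaller k", f),
        class = "cgmboost_data_error"
      )
    }
    model <- fit_adaboost(train, variant, n_rounds = n_rounds, n_bins = n_bins)
    st <- staged_errors(model, test)
    st$fold <- f
    st
  })
  folds <- dplyr::bind_rows(res)
  mean_curve <- dplyr::summarise(
    dplyr::group_by(folds, .data$round),
    error_rate = mean(.data$error_rate), .groups = "drop"
  )
  fold_errors <- vapply(res, function(st) st$error_rate[nrow(st)], numeric(1))
  structure(
    list(
      folds = folds[, c("fold", "round", "error_rate")],
      mean_curve = mean_curve,
      fold_errors = fold_errors,
      mean_error = mean(fold_errors),
      assignment = fold,
      k = k, variant = variant, seed = seed
    ),
    class = "cv_eval"
  )
}

#' @export
print.cv_eval <- function(x, ...) {
  cat(sprintf("<cv_eval> %s, %d folds: per-fold error %s; mean %.4f\n",
              x$variant, x$k, paste(sprintf("%.3f", x$fold_errors), collapse = " "),
              x$mean_error))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cv_eval <- function(x, ...) {
  tibble::tibble(fold = seq_len(x$k), error_rate = x$fold_errors)
}

#' @exportS3Method generics::glance
glance.cv_eval <- function(x, ...) {
  tibble::tibble(variant = x$variant, k = x$k, mean_error = x$mean_error,
                 sd_error = stats::sd(x$fold_errors))
}

#' Upper-threshold (mu) sweep across boosting variants
#'
#' For each upper threshold in `mu`, re-extracts the 17 features from the
#' cohort and runs the hold-out protocol for every variant with the same
#' seed (hence the same split), assembling a (variant x mu) grid of error
#' rate / ACC / MCC plus the per-round test-error curves.
#'
#' @param cohort Labeled cohort tibble (`patient_id`, `label`, `trace`).
#' @param variants Character vector of boosting variants.
#' @param mu Upper thresholds in mmol/L (default `c(7, 8, 9, 10, 11)`).
#' @param lower Lower threshold in mmol/L (default 3.9).
#' @inheritParams holdout_protocol
#' @param meals A [meal_schedule()].
#' @return Object of class `sweep_result`: `grid` tibble (variant, mu,
#'   error_rate, acc, mcc) and `curves` tibble (variant, mu, round,
#'   error_rate).
#' @export
threshold_sweep <- function(cohort, variants = c("discrete", "real", "gentle", "modest"),
                            mu = c(7, 8, 9, 10, 11), lower = 3.9,
                            n_rounds = 100, train_ratio = 2 / 7, seed = 1,
                            n_bins = 8, meals = meal_schedule()) {
  stopifnot(is.data.frame(cohort), all(c("label", "trace") %in% names(cohort)))
  if (is.unsorted(mu, strictly = TRUE)) {
    rlang::abort("`mu` must be strictly ascending", class = "cgmboost_config_error")
  }
  cells <- purrr::map(mu, function(u) {
    feats <- extract_feature_table(cohort, threshold_config(u, lower), meals)
    purrr::map(variants, function(v) {
      ev <- holdout_protocol(feats, v, n_rounds = n_rounds,
                             train_ratio = train_ratio, seed = seed, n_bins = n_bins)
      list(
        grid = dplyr::bind_cols(tibble::tibble(variant = v, mu = u),
                                ev$metrics[, c("error_rate", "acc", "mcc")]),
        curves = dplyr::bind_cols(tibble::tibble(variant = v, mu = u), ev$staged)
      )
    })
  })
  cells <- purrr::flatten(cells)
  structure(
    list(
      grid = dplyr::bind_rows(purrr::map(cells, "grid")),
      curves = dplyr::bind_rows(purrr::map(cells, "curves")),
      mu = mu, variants = variants, seed = seed, n_rounds = n_rounds
    ),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d variant(s) x %d threshold(s), T = %d\n",
              length(x$variants), length(x$mu), x$n_rounds))
  wide <- tidyr::pivot_wider(x$grid[, c("variant", "mu", "error_rate")],
                             names_from = "mu", values_from = "error_rate",
                             names_prefix = "mu_")
  print(wide)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sweep_result <- function(x, ...) x$grid

#' @exportS3Method generics::glance
glance.sweep_result <- function(x, ...) {
  best <- x$grid[which.min(x$grid$error_rate), ]
  tibble::tibble(
    best_variant = best$variant, best_mu = best$mu,
    best_error_rate = best$error_rate, best_acc = best$acc, best_mcc = best$mcc
  )
}
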