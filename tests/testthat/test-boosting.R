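test_that("discrete AdaBoost follows the weighting scheme", {
  # linearly separable 1-D data: one stump suffices, training stops
  d <- tibble::tibble(x = c(1, 2, 3, 10, 11, 12), label = c(-1, -1, -1, 1, 1, 1))
  m <- fit_adaboost(d, "discrete", n_rounds = 50)
  expect_equal(m$train_error, 0)
  expect_equal(m$n_rounds, 1)
  expect_true(grepl("perfect stump", m$stop_reason))
  # alpha follows 0.5*ln((1-eps)/eps) with eps floored at 1e-10
  expect_equal(m$alphas[1], 0.5 * log((1 - 1e-10) / 1e-10))

  # XOR pattern: unsolvable by one stump, solved by boosting within 10
  # rounds, and round-for-round identical to a brute-force stump search
  xd <- xor_data()
  m <- fit_adaboost(xd, "discrete", n_rounds = 10)
  expect_equal(m$train_error, 0)
  X <- as.matrix(xd[, 1:2]); y <- xd$label
  w <- rep(1 / 4, 4)
  for (t in seq_len(m$n_rounds)) {
    o <- oracle_best_stump(X, y, w)
    expect_equal(m$learners$feature_index[t], o$feature)
    expect_equal(m$learners$threshold[t], o$threshold)
    h <- o$polarity * ifelse(X[, o$feature] > o$threshold, 1, -1)
    a <- 0.5 * log((1 - max(o$err, 1e-10)) / max(o$err, 1e-10))
    w <- w * exp(-a * y * h); w <- w / sum(w)
  }

  # alpha_t = 0.5*ln((1-eps_t)/eps_t) holds for every recorded round
  set.seed(61)
  d <- random_feature_data(n = 50, shift = 0.4)
  m <- fit_adaboost(d, "discrete", n_rounds = 20)
  st <- tidy(m)
  expect_equal(st$alpha, 0.5 * log((1 - st$eps) / st$eps), tolerance = 1e-12)
  expect_true(all(st$eps < 0.5)) # polarity flip rules out eps > 0.5
})

test_that("round-1 discrete model equals the exhaustive best stump", {
  set.seed(71)
  for (i in 1:5) {
    d <- random_feature_data(n = 25, p = 3, shift = 0.3)
    m <- fit_adaboost(d, "discrete", n_rounds = 1)
    X <- as.matrix(d[, 1:3])
    o <- oracle_best_stump(X, d$label, rep(1 / 25, 25))
    expect_equal(m$learners$feature_index[1], o$feature)
    expect_equal(m$learners$threshold[1], o$threshold)
    expect_equal(m$learners$polarity[1], o$polarity)
    expect_equal(tidy(m)$eps[1], o$err, tolerance = 1e-12)
  }
})

test_that("discrete training error respects the classical bounds", {
  set.seed(81)
  for (i in 1:3) {
    d <- random_feature_data(n = 60, p = 4, shift = 0.25)
    m <- fit_adaboost(d, "discrete", n_rounds = 30)
    eps <- tidy(m)$eps
    bound <- cumprod(2 * sqrt(eps * (1 - eps)))
    staged <- staged_errors(m, d)$error_rate
    expect_true(all(staged <= bound + 1e-12))
    gamma <- 0.5 - eps
    expect_lte(m$train_error, exp(-2 * sum(gamma^2)) + 1e-12)
  }
})

test_that("sample weights stay a distribution through every round", {
  set.seed(91)
  d <- random_feature_data(n = 30, p = 3, shift = 0.2)
  for (v in c("discrete", "real", "gentle", "modest")) {
    # re-run training with an instrumented copy of the update rule:
    # reconstruct weights from the model and verify normalization
    m <- fit_adaboost(d, v, n_rounds = 15)
    X <- as.matrix(d[, 1:3])
    y <- d$label
    w <- rep(1 / nrow(d), nrow(d))
    contrib <- cgmboost:::contribution_matrix(m, X)
    for (t in seq_len(m$n_rounds)) {
      w <- w * exp(-y * contrib[, t])
      w <- w / sum(w)
      expect_equal(sum(w), 1, tolerance = 1e-12)
      expect_true(all(w >= 0))
    }
  }
})

test_that("Real AdaBoost block outputs and z follow the block formulas", {
  # 1 feature, 2 equal-frequency blocks, perfectly separable
  d <- tibble::tibble(x = c(1, 2, 8, 9), label = c(-1, -1, 1, 1))
  m <- fit_adaboost(d, "real", n_rounds = 1, n_bins = 2)
  eps_s <- 1 / (4 * 4)
  # left block: all weight 0.5 on class -1; right block mirrored
  expect_equal(m$learners$bin_outputs[[1]],
               c(0.5 * log(eps_s / (0.5 + eps_s)), 0.5 * log((0.5 + eps_s) / eps_s)))
  expect_equal(m$train_error, 0)
  # z = 2*sum_j sqrt(p+ p-) = 0 for pure blocks
  expect_equal(tidy(m)$z[1], 0)

  # a block with equal weighted class mass outputs exactly 0
  d2 <- tibble::tibble(x = c(1, 1, 9, 9), label = c(-1, 1, -1, 1))
  m2 <- fit_adaboost(d2, "real", n_rounds = 1, n_bins = 2)
  expect_equal(m2$learners$bin_outputs[[1]], c(0, 0))

  # z_t matches an independent recomputation on random data
  set.seed(101)
  d3 <- random_feature_data(n = 40, p = 3, shift = 0.3)
  m3 <- fit_adaboost(d3, "real", n_rounds = 10, n_bins = 4)
  X <- as.matrix(d3[, 1:3]); y <- d3$label
  w <- rep(1 / 40, 40)
  for (t in seq_len(m3$n_rounds)) {
    f <- m3$learners$feature_index[t]
    b <- findInterval(X[, f], m3$edges[[f]]) + 1L
    nb <- length(m3$edges[[f]]) + 1L
    z <- 2 * sum(sqrt(
      vapply(1:nb, function(j) sum(w[b == j & y == 1]), 0) *
      vapply(1:nb, function(j) sum(w[b == j & y == -1]), 0)
    ))
    expect_equal(tidy(m3)$z[t], z, tolerance = 1e-12)
    h <- m3$learners$bin_outputs[[t]][b]
    w <- w * exp(-y * h); w <- w / sum(w)
  }
})

test_that("Gentle AdaBoost fits weighted least-squares stumps", {
  # weighted means of a constant target are that constant on both sides
  X <- matrix(c(1, 2, 3, 4), ncol = 1)
  st <- cgmboost:::best_reg_stump(X, c(1, 1, 1, 1), rep(0.25, 4),
                                  list(order(X[, 1])))
  expect_equal(st$left, 1)
  expect_equal(st$right, 1)

  # two points with weights (w, 1-w) split between them: outputs (+1, -1)
  for (wgt in c(0.2, 0.5, 0.9)) {
    st <- cgmboost:::best_reg_stump(matrix(c(0, 1), ncol = 1), c(1, -1),
                                    c(wgt, 1 - wgt), list(1:2))
    expect_equal(st$left, 1)
    expect_equal(st$right, -1)
  }

  # exponential loss sum_i D1(i) exp(-y_i F_t(x_i)) is non-increasing in t
  set.seed(111)
  for (i in 1:3) {
    d <- random_feature_data(n = 30, p = 4, shift = 0)
    m <- fit_adaboost(d, "gentle", n_rounds = 25)
    X <- as.matrix(d[, 1:4])
    contrib <- cgmboost:::contribution_matrix(m, X)
    Fmat <- t(apply(contrib, 1, cumsum))
    loss <- colMeans(exp(-d$label * Fmat))
    expect_true(all(diff(loss) <= 1e-12))
  }
})

test_that("Modest AdaBoost damps by the inverted distribution", {
  # symmetric class mass under D and Dbar in every block -> output 0,
  # no positive margin gain, training stops without learners
  d <- tibble::tibble(x = c(1, 1, 9, 9), label = c(-1, 1, -1, 1))
  m <- fit_adaboost(d, "modest", n_rounds = 5, n_bins = 2)
  expect_equal(m$n_rounds, 0)
  expect_true(grepl("margin gain", m$stop_reason))

  # hand-computed round-1 outputs on a pure 4-point set, 2 blocks:
  # left block all -1 (mass 1/2), right all +1; Dbar = D here, so
  # f = p+(1-pbar+) - p-(1-pbar-) = c(-0.25, 0.25)
  dp <- tibble::tibble(x = c(1, 2, 8, 9), label = c(-1, -1, 1, 1))
  mp <- fit_adaboost(dp, "modest", n_rounds = 1, n_bins = 2)
  expect_equal(mp$learners$bin_outputs[[1]], c(-0.25, 0.25))
  expect_equal(mp$train_error, 0)

  # block outputs bounded in [-1, 1] every round
  set.seed(121)
  d2 <- random_feature_data(n = 40, p = 4, shift = 0.3)
  m2 <- fit_adaboost(d2, "modest", n_rounds = 20)
  for (out in m2$learners$bin_outputs) {
    expect_true(all(out >= -1 & out <= 1))
  }

  # dual-implementation cross-check on the XOR set (4 blocks so each block
  # isolates one point and the learner has an edge)
  xd <- xor_data()
  m3 <- fit_adaboost(xd, "modest", n_rounds = 8, n_bins = 4)
  ref <- oracle_modest(as.matrix(xd[, 1:2]), xd$label, T = 8, n_bins = 4)
  expect_equal(length(ref$rounds), m3$n_rounds)
  expect_equal(predict(m3, xd), ref$predict(as.matrix(xd[, 1:2])))
  for (t in seq_len(m3$n_rounds)) {
    expect_equal(m3$learners$feature_index[t], ref$rounds[[t]]$feature)
    expect_equal(m3$learners$bin_outputs[[t]], ref$rounds[[t]]$out, tolerance = 1e-12)
  }
})

test_that("prediction is the signed weighted vote with sign(0) -> +1", {
  d <- tibble::tibble(x = c(1, 2, 8, 9), label = c(-1, -1, 1, 1))
  m <- fit_adaboost(d, "discrete", n_rounds = 1)
  expect_equal(predict(m, tibble::tibble(x = c(0, 100))), c(-1L, 1L))

  # hand-built two-stump model whose votes cancel exactly -> score 0 -> +1
  m0 <- m
  m0$n_rounds <- 2L
  m0$learners <- tibble::tibble(
    round = 1:2, feature_index = c(1L, 1L),
    threshold = c(5, 5), polarity = c(1L, -1L)
  )
  m0$alphas <- c(1, 1)
  expect_equal(predict(m0, tibble::tibble(x = 3), type = "score"), 0)
  expect_equal(predict(m0, tibble::tibble(x = 3)), 1L)

  # score equals the learner-by-learner sum for every variant
  set.seed(131)
  d2 <- random_feature_data(n = 30, p = 3, shift = 0.2)
  newd <- random_feature_data(n = 10, p = 3)
  for (v in c("discrete", "real", "gentle", "modest")) {
    mv <- fit_adaboost(d2, v, n_rounds = 12)
    s <- rowSums(cgmboost:::contribution_matrix(mv, as.matrix(newd[, 1:3])))
    expect_equal(predict(mv, newd, type = "score"), s, tolerance = 1e-12)
  }

  expect_error(predict(m, tibble::tibble(z = 1)), class = "cgmboost_data_error")
})

test_that("staged errors are consistent with full prediction", {
  set.seed(141)
  d <- random_feature_data(n = 40, p = 3, shift = 0.3)
  test <- random_feature_data(n = 20, p = 3, shift = 0.3)
  m1 <- fit_adaboost(d, "gentle", n_rounds = 1)
  st1 <- staged_errors(m1, test)
  expect_equal(nrow(st1), 1)
  expect_equal(st1$error_rate, mean(predict(m1, test) != test$label))

  m <- fit_adaboost(d, "gentle", n_rounds = 15)
  st <- staged_errors(m, test)
  expect_equal(nrow(st), 15)
  expect_equal(st$error_rate[15], mean(predict(m, test) != test$label))
})

test_that("training is deterministic and errors on degenerate input", {
  set.seed(151)
  d <- random_feature_data(n = 30, p = 4, shift = 0.2)
  for (v in c("discrete", "real", "gentle", "modest")) {
    expect_identical(fit_adaboost(d, v, n_rounds = 10), fit_adaboost(d, v, n_rounds = 10))
  }
  expect_error(fit_adaboost(dplyr::mutate(d, label = 1L), "discrete"),
               class = "cgmboost_data_error")
  expect_error(fit_adaboost(d[1, ], "discrete"), class = "cgmboost_data_error")
  const <- tibble::tibble(x = rep(1, 6), label = rep(c(1L, -1L), 3))
  expect_error(fit_adaboost(const, "discrete"), class = "cgmboost_data_error")
})

test_that("models serialize to JSON and back with identical predictions", {
  set.seed(161)
  d <- random_feature_data(n = 30, p = 3, shift = 0.3)
  newd <- random_feature_data(n = 15, p = 3)
  for (v in c("discrete", "real", "gentle", "modest")) {
    m <- fit_adaboost(d, v, n_rounds = 8)
    path <- withr::local_tempfile(fileext = ".json")
    write_boost_model(m, path)
    m2 <- read_boost_model(path)
    expect_equal(m2$variant, m$variant)
    expect_equal(predict(m2, newd, type = "score"),
                 predict(m, newd, type = "score"), tolerance = 1e-12)
    expect_equal(predict(m2, newd), predict(m, newd))
  }
})
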