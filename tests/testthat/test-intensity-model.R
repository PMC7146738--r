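test_that("train/test split follows the rounding and determinism contract", {
  d30 <- make_dataset(21, n_samples = 30)
  sp <- split_dataset(d30, 0.7, seed = 5)
  expect_equal(nrow(sp$train$samples), 21)
  expect_equal(nrow(sp$test$samples), 9)

  d31 <- make_dataset(21, n_samples = 31)
  sp31 <- split_dataset(d31, 0.7, seed = 5)  # round(21.7) = 22
  expect_equal(nrow(sp31$train$samples), 22)
  expect_equal(nrow(sp31$test$samples), 9)

  sp2 <- split_dataset(d30, 0.7, seed = 5)
  expect_identical(sp$train$samples, sp2$train$samples)
  expect_identical(sp$test$samples, sp2$test$samples)

  # disjoint partition covering the dataset
  key <- function(s) paste(s$conc_a_mg_m3, s$conc_b_mg_m3)
  expect_length(intersect(key(sp$train$samples), key(sp$test$samples)), 0)
  expect_setequal(c(key(sp$train$samples), key(sp$test$samples)),
                  key(d30$samples))

  expect_error(split_dataset(d30, 1.0, seed = 1), "train_fraction")
  expect_error(split_dataset(d30, 0, seed = 1), "train_fraction")
})

test_that("R^2 and MAE match brute-force formula evaluations", {
  for (s in 1:5) {
    obs <- withr::with_seed(s, stats::rnorm(20, 4, 1.5))
    pred <- withr::with_seed(100 + s, obs + stats::rnorm(20, 0, 0.5))
    r2_naive <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
    mae_naive <- sum(abs(obs - pred)) / length(obs)
    expect_equal(r_squared(obs, pred), r2_naive, tolerance = 1e-10)
    expect_equal(mae(obs, pred), mae_naive, tolerance = 1e-10)
    expect_equal(mae(obs, pred), mae(pred, obs), tolerance = 1e-14)
  }
  expect_identical(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0, tolerance = 1e-14)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5, tolerance = 1e-12)
  expect_identical(mae(c(1, 2), c(2, 2)), 0.5)
  expect_identical(mae(c(1, 2), c(1, 2)), 0)
  expect_error(r_squared(c(2, 2), c(1, 2)), "all equal")
  expect_error(r_squared(1, 1), "at least 2")
  expect_error(mae(1:3, 1:2), "equal length")
  expect_error(mae(numeric(0), numeric(0)), "empty")
})

test_that("grid search selects the CV-MAE argmin with the stated tie-break", {
  d <- make_dataset(31, n_samples = 30)
  sp <- split_dataset(d, 0.7, seed = 2)
  train <- sp$train

  # degenerate single-cell grid
  g1 <- hyperparameter_grid(c_values = 4, gamma_values = 0.25)
  m1 <- fit_intensity_model(train, g1, cv_folds = 5, seed = 9)
  expect_equal(nrow(m1$cv_table), 1)
  expect_equal(m1$selected_c, 4)
  expect_equal(m1$selected_gamma, 0.25)

  # naive oracle: independent CV loop over a 3x3 grid
  for (cv_seed in c(9, 77)) {
    grid <- small_grid()
    m <- fit_intensity_model(train, grid, cv_folds = 10, seed = cv_seed)

    x <- log(as.matrix(train$samples[, c("conc_a_mg_m3", "conc_b_mg_m3")]))
    y <- train$samples$oi
    n <- nrow(x)
    xs <- scale(x, colMeans(x), apply(x, 2, stats::sd))
    perm <- withr::with_seed(cv_seed, sample.int(n))
    sizes <- rep(n %/% 10, 10) + c(rep(1L, n %% 10), rep(0L, 10 - n %% 10))
    fold <- integer(n)
    fold[perm] <- rep(seq_len(10), times = sizes)
    naive <- expand.grid(c = grid$c_values, gamma = grid$gamma_values)
    naive$cv_mae <- NA_real_
    for (j in seq_len(nrow(naive))) {
      pred <- numeric(n)
      for (k in 1:10) {
        h <- fold == k
        f <- e1071::svm(x = xs[!h, , drop = FALSE], y = y[!h],
                        type = "eps-regression", kernel = "radial",
                        cost = naive$c[j], gamma = naive$gamma[j],
                        epsilon = 0.1, scale = FALSE)
        pred[h] <- stats::predict(f, xs[h, , drop = FALSE])
      }
      naive$cv_mae[j] <- mean(abs(pred - y))
    }
    naive <- naive[order(naive$c, naive$gamma), ]
    best <- naive[order(naive$cv_mae, naive$c, naive$gamma), ][1, ]
    expect_equal(m$selected_c, best$c)
    expect_equal(m$selected_gamma, best$gamma)
    merged <- merge(m$cv_table, naive, by = c("c", "gamma"))
    expect_equal(merged$cv_mae.x, merged$cv_mae.y, tolerance = 1e-10)
  }
})

test_that("noiseless smooth targets are learned nearly exactly", {
  d <- make_dataset(5, rho_max = 0, noise_sigma = 0, n_samples = 60)
  m <- fit_intensity_model(d, cv_folds = 10, seed = 3)
  pred <- predict_oi(m, d$samples$conc_a_mg_m3, d$samples$conc_b_mg_m3)
  expect_lte(mae(d$samples$oi, pred), 0.05)
  # epsilon-tube property: training points recovered within 2*eps + 0.05
  expect_lt(max(abs(pred - d$samples$oi)), 2 * m$epsilon + 0.05)
  ev <- evaluate_model(m, d, d)
  expect_gte(ev$r2_train, 0.99)
  expect_identical(ev$r2_train, ev$r2_test)
  expect_identical(ev$mae_train, ev$mae_test)
})

test_that("prediction is deterministic and survives persistence", {
  d <- make_dataset(6, n_samples = 30)
  sp <- split_dataset(d, 0.7, seed = 4)
  m <- fit_intensity_model(sp$train, small_grid(), cv_folds = 5, seed = 8)

  probe_a <- conc_from_lnoav(seq(1, 7, length.out = 100), get_odorant("EA"))
  probe_b <- conc_from_lnoav(seq(7, 1, length.out = 100), get_odorant("BA"))
  p1 <- predict_oi(m, probe_a, probe_b)
  expect_identical(p1, predict_oi(m, probe_a, probe_b))

  path <- withr::local_tempfile(fileext = ".rds")
  save_intensity_model(m, path)
  m2 <- load_intensity_model(path)
  expect_identical(p1, predict_oi(m2, probe_a, probe_b))

  expect_error(predict_oi(m, -1, 1), "positive")
  expect_error(predict_oi(list(), 1, 1), "fitted intensity_model")
})

test_that("fit refuses degenerate inputs", {
  d <- make_dataset(7, n_samples = 12)
  expect_error(fit_intensity_model(d, small_grid(), cv_folds = 13, seed = 1),
               "exceeds the training size")
  const <- panel_dataset(
    get_odorant("EA"), get_odorant("BA"),
    tibble::tibble(conc_a_mg_m3 = rep(1, 10),
                   conc_b_mg_m3 = seq(1, 2, length.out = 10),
                   oi = seq(2, 4, length.out = 10), source = "measured"))
  expect_error(fit_intensity_model(const, small_grid(), cv_folds = 5,
                                   seed = 1),
               "zero variance")
})

test_that("training and held-out accuracy stay close across seeds", {
  gaps <- vapply(1:10, function(s) {
    d <- make_dataset(100 + s)
    sp <- split_dataset(d, 0.7, seed = 200 + s)
    m <- fit_intensity_model(sp$train, cv_folds = 10, seed = 300 + s)
    ev <- evaluate_model(m, sp$train, sp$test)
    ev$r2_train - ev$r2_test
  }, numeric(1))
  expect_lte(stats::median(gaps), 0.1)
  expect_gte(mean(gaps <= 0.2), 0.8)
})
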