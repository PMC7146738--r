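# Per-pair odor-intensity predictor: eps-SVR with an RBF kernel, the two
# raw component concentrations as features (z-scored on training stats),
# and (C, gamma) selected by seeded k-fold cross-validated MAE.

#' Hyperparameter grid for the RBF-SVR search
#'
#' Defaults are the canonical log2 lattice for RBF-SVR grid search:
#' `C` in `2^(-5), 2^(-3), ..., 2^15` and `gamma` in
#' `2^(-15), 2^(-13), ..., 2^3`. The insensitive-tube half-width
#' `epsilon` is fixed (not searched); only `C` and `gamma` are optimized.
#'
#' @param c_values Positive penalty values `C`, ascending.
#' @param gamma_values Positive RBF widths `gamma`, ascending.
#' @param epsilon Insensitive-tube half-width, OIRS units.
#' @return An object of class `hyperparameter_grid`.
#' @export
hyperparameter_grid <- function(c_values = 2^seq(-5, 15, by = 2),
                                gamma_values = 2^seq(-15, 3, by = 2),
                                epsilon = 0.1) {
  if (length(c_values) == 0 || length(gamma_values) == 0) {
    stop("hyperparameter grids must be non-empty")
  }
  if (any(c_values <= 0) || any(gamma_values <= 0) || epsilon < 0) {
    stop("C and gamma must be positive; epsilon must be >= 0")
  }
  structure(list(c_values = sort(c_values),
                 gamma_values = sort(gamma_values),
                 epsilon = epsilon),
            class = "hyperparameter_grid")
}

subset_dataset <- function(dataset, idx) {
  panel_dataset(dataset$odorant_a, dataset$odorant_b,
                dataset$samples[idx, , drop = FALSE],
                provenance = dataset$provenance)
}

#' Randomly split a dataset into training and test parts
#'
#' The training size is `round(train_fraction * n)` (ties to even); the
#' partition is a seeded draw without replacement, and each part keeps
#' the original row order.
#'
#' @param dataset A [panel_dataset()] with at least 4 samples.
#' @param train_fraction Fraction in `(0, 1)` assigned to training.
#' @param seed Integer seed for the partition.
#' @return A list with elements `train` and `test`, both `panel_dataset`.
#' @export
split_dataset <- function(dataset, train_fraction = 0.7, seed) {
  stopifnot(inherits(dataset, "panel_dataset"))
  n <- nrow(dataset$samples)
  if (n < 4) stop("dataset must contain at least 4 samples")
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("train_fraction must lie strictly inside (0, 1)")
  }
  n_train <- round(train_fraction * n)
  if (n_train < 1 || n_train >= n) {
    stop("split leaves an empty training or test set (n = ", n,
         ", train_fraction = ", train_fraction, ")")
  }
  train_idx <- sort(withr::with_seed(seed, sample.int(n, n_train)))
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = subset_dataset(dataset, train_idx),
       test = subset_dataset(dataset, test_idx))
}

# Seeded fold assignment: shuffle indices, then contiguous blocks whose
# sizes differ by at most one. Returns a fold id per original index.
make_cv_folds <- function(n, k, seed) {
  if (k < 2) stop("cv_folds must be >= 2")
  if (k > n) stop("cv_folds (", k, ") exceeds the training size (", n, ")")
  perm <- withr::with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold_of_perm <- rep(seq_len(k), times = sizes)
  folds <- integer(n)
  folds[perm] <- fold_of_perm
  folds
}

feature_matrix <- function(dataset) {
  as.matrix(dataset$samples[, c("conc_a_mg_m3", "conc_b_mg_m3")])
}

apply_transform <- function(x, transform) {
  switch(transform,
         log = log(x),
         identity = x,
         stop("unknown feature transform: ", transform))
}

svr_fit <- function(x, y, cost, gamma, epsilon) {
  e1071::svm(x = x, y = y, type = "eps-regression", kernel = "radial",
             cost = cost, gamma = gamma, epsilon = epsilon, scale = FALSE)
}

#' Fit the per-pair SVR odor-intensity model
#'
#' Features are the two component concentrations (mg/m3), by default
#' ln-transformed and then standardized with the training set's mean and
#' standard deviation (odorant concentrations span orders of magnitude
#' and perceived intensity follows log-concentration, so the RBF kernel
#' operates on the log scale; set `feature_transform = "identity"` to
#' standardize the raw concentrations instead).
#' The target is the panel odor intensity. For every `(C, gamma)` cell of
#' the grid, the mean absolute error over all held-out samples of a
#' seeded `cv_folds`-fold cross-validation is computed; the cell with the
#' minimal CV MAE is selected (ties broken towards smaller `C`, then
#' smaller `gamma`), and the final predictor is refit on the full
#' training set at that cell.
#'
#' @param train A [panel_dataset()] of training samples.
#' @param grid A [hyperparameter_grid()].
#' @param cv_folds Number of cross-validation folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param feature_transform `"log"` (default) or `"identity"`, applied
#'   to the concentrations before standardization.
#' @return An object of class `intensity_model` carrying the fitted
#'   predictor, scaler statistics, selected hyperparameters, and the full
#'   per-cell CV table.
#' @export
fit_intensity_model <- function(train, grid = hyperparameter_grid(),
                                cv_folds = 10, seed,
                                feature_transform = c("log", "identity")) {
  stopifnot(inherits(train, "panel_dataset"),
            inherits(grid, "hyperparameter_grid"))
  feature_transform <- match.arg(feature_transform)
  x <- apply_transform(feature_matrix(train), feature_transform)
  y <- train$samples$oi
  n <- nrow(x)
  if (cv_folds > n) {
    stop("cv_folds (", cv_folds, ") exceeds the training size (", n, ")")
  }
  center <- colMeans(x)
  scale_sd <- apply(x, 2, stats::sd)
  if (any(scale_sd == 0)) {
    stop("degenerate feature: a concentration column has zero variance")
  }
  xs <- scale(x, center = center, scale = scale_sd)

  folds <- make_cv_folds(n, cv_folds, seed)
  # Rows ordered C-major, gamma-minor, both ascending, so the first
  # minimum realises the tie-break (smaller C, then smaller gamma).
  cells <- expand.grid(gamma = grid$gamma_values, c = grid$c_values,
                       KEEP.OUT.ATTRS = FALSE)[, c("c", "gamma")]
  cv_mae <- vapply(seq_len(nrow(cells)), function(j) {
    pred <- numeric(n)
    for (k in seq_len(cv_folds)) {
      hold <- folds == k
      fit <- svr_fit(xs[!hold, , drop = FALSE], y[!hold],
                     cost = cells$c[j], gamma = cells$gamma[j],
                     epsilon = grid$epsilon)
      pred[hold] <- stats::predict(fit, xs[hold, , drop = FALSE])
    }
    mean(abs(pred - y))
  }, numeric(1))

  best <- which.min(cv_mae)
  cv_table <- tibble::tibble(c = cells$c, gamma = cells$gamma,
                             cv_mae = cv_mae)
  final <- svr_fit(xs, y, cost = cells$c[best], gamma = cells$gamma[best],
                   epsilon = grid$epsilon)
  structure(list(
    pair = c(train$odorant_a$abbreviation, train$odorant_b$abbreviation),
    feature_transform = feature_transform,
    scaler_stats = list(center = center, scale = scale_sd),
    selected_c = cells$c[best],
    selected_gamma = cells$gamma[best],
    epsilon = grid$epsilon,
    cv_table = cv_table,
    cv_folds = as.integer(cv_folds),
    predictor = final,
    train_digest = sprintf("n=%d, cv_seed=%s", n, format(seed))
  ), class = "intensity_model")
}

#' @export
print.intensity_model <- function(x, ...) {
  cat(sprintf("RBF-SVR odor-intensity model for %s + %s\n",
              x$pair[1], x$pair[2]))
  cat(sprintf("  selected C = %g, gamma = %g (epsilon = %g), %d-fold CV\n",
              x$selected_c, x$selected_gamma, x$epsilon, x$cv_folds))
  cat(sprintf("  CV MAE at selected cell: %.4f OIRS (%s)\n",
              min(x$cv_table$cv_mae), x$train_digest))
  invisible(x)
}

#' Predict mixture odor intensity from component concentrations
#'
#' @param model A fitted [fit_intensity_model()] result.
#' @param conc_a,conc_b Component concentrations in mg/m3 (vectors of
#'   equal length), strictly positive.
#' @return Predicted odor intensity in OIRS units.
#' @export
predict_oi <- function(model, conc_a, conc_b) {
  if (!inherits(model, "intensity_model") || is.null(model$predictor)) {
    stop("model must be a fitted intensity_model")
  }
  if (any(conc_a <= 0) || any(conc_b <= 0)) {
    stop("concentrations must be strictly positive")
  }
  x <- apply_transform(cbind(conc_a_mg_m3 = conc_a, conc_b_mg_m3 = conc_b),
                       model$feature_transform)
  xs <- scale(x, center = model$scaler_stats$center,
              scale = model$scaler_stats$scale)
  as.numeric(stats::predict(model$predictor, xs))
}

#' Persist a fitted intensity model
#' @param model An `intensity_model`.
#' @param path Destination file.
#' @export
save_intensity_model <- function(model, path) {
  stopifnot(inherits(model, "intensity_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Reload a persisted intensity model
#' @param path File written by [save_intensity_model()].
#' @return The `intensity_model`.
#' @export
load_intensity_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "intensity_model")) {
    stop("file does not contain an intensity_model")
  }
  model
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return Dimensionless; 1 for a perfect fit, 0 for the mean predictor.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length")
  }
  if (length(observed) < 2) stop("need at least 2 observations")
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) stop("observed values are all equal; R^2 is undefined")
  1 - sum((observed - predicted)^2) / tss
}

#' Mean absolute error
#'
#' @param observed,predicted Numeric vectors of equal length (>= 1).
#' @return MAE in the units of the inputs (OIRS for intensities).
#' @export
mae <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length")
  }
  if (length(observed) == 0) stop("empty input")
  mean(abs(observed - predicted))
}

#' Evaluate a fitted model on the training and test splits
#'
#' Computes R^2 and MAE between panel and predicted intensity on each
#' split; never refits.
#'
#' @param model A fitted `intensity_model`.
#' @param train,test The two [panel_dataset()] splits.
#' @return An `evaluation_report` list with `r2_train`, `r2_test`,
#'   `mae_train`, `mae_test`, `n_train`, `n_test`.
#' @export
evaluate_model <- function(model, train, test) {
  pred_tr <- predict_oi(model, train$samples$conc_a_mg_m3,
                        train$samples$conc_b_mg_m3)
  pred_te <- predict_oi(model, test$samples$conc_a_mg_m3,
                        test$samples$conc_b_mg_m3)
  structure(list(
    r2_train = r_squared(train$samples$oi, pred_tr),
    r2_test = r_squared(test$samples$oi, pred_te),
    mae_train = mae(train$samples$oi, pred_tr),
    mae_test = mae(test$samples$oi, pred_te),
    n_train = nrow(train$samples),
    n_test = nrow(test$samples)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Model evaluation (n_train = %d, n_test = %d)\n",
              x$n_train, x$n_test))
  cat(sprintf("  R^2: train %.3f, test %.3f\n", x$r2_train, x$r2_test))
  cat(sprintf("  MAE: train %.3f, test %.3f OIRS\n",
              x$mae_train, x$mae_test))
  invisible(x)
}
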