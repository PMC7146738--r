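test_that("interaction statistics follow their defining identities", {
  expect_equal(oi_sum(3, 3, "ester"), 3.00, tolerance = 1e-12)
  expect_equal(oi_sum(1, 2, "aromatic"), 3.21, tolerance = 1e-12)
  expect_equal(oi_sum(1.82 / 1.76, 1.82 / 1.76, "aldehyde"), 0,
               tolerance = 1e-12)

  expect_identical(oi_reduction(3, 3), 0)
  expect_identical(oi_reduction(4, 3), 1)
  expect_identical(oi_reduction(2, 2.5), -0.5)  # synergism sign

  expect_identical(oi_reduction_ratio(4, 3), 0.25)
  expect_identical(oi_reduction_ratio(5, 5), 0)
  expect_identical(oi_reduction_ratio(2, 0), 1)
  expect_error(oi_reduction_ratio(0, 1), "undefined")

  expect_identical(mixing_ratio(2, 2), 0.5)
  expect_identical(mixing_ratio(3, 1), 0.75)
  expect_identical(mixing_ratio(0, 5), 0)
  expect_error(mixing_ratio(-3, 1), "must be > 0")

  # Reduction and ratio are consistent: ratio * OI_sum = reduction
  s <- withr::with_seed(1, stats::runif(50, 0.5, 8))
  m <- withr::with_seed(2, stats::runif(50, 0, 8))
  expect_equal(oi_reduction_ratio(s, m) * s, oi_reduction(s, m),
               tolerance = 1e-12)
})

test_that("surface grid has the stated geometry, identities, and mask", {
  d <- make_dataset(12, n_samples = 30)
  truth <- truth_predictor(ester_pair, rho_max = 0.35)
  surf <- simulate_interaction_surface(truth, d, resolution = 50,
                                       min_oi_sum = 2)
  expect_equal(dim(surf$oi_mix), c(50, 50))
  expect_equal(dim(surf$oi_sum), c(50, 50))
  expect_equal(dim(surf$mask), c(50, 50))

  la <- ln_oav(d$samples$conc_a_mg_m3, "EA")
  lb <- ln_oav(d$samples$conc_b_mg_m3, "BA")
  expect_equal(range(surf$axis_a), range(la), tolerance = 1e-12)
  expect_equal(range(surf$axis_b), range(lb), tolerance = 1e-12)
  expect_true(all(diff(surf$axis_a) > 0))

  # elementwise identity and exact mask rule
  expect_identical(surf$oi_reduction, surf$oi_sum - surf$oi_mix)
  expect_identical(surf$mask, surf$oi_sum < 2)
  # the grid reaches below the OI_sum floor, so some cells are masked
  expect_gt(sum(surf$mask), 0)

  # oi_sum on the grid agrees with an independent law evaluation
  i <- c(1, 17, 50); j <- c(3, 25, 44)
  expect_equal(surf$oi_sum[cbind(i, j)],
               oi_from_lnoav(surf$axis_a[i], "ester") +
                 oi_from_lnoav(surf$axis_b[j], "ester"),
               tolerance = 1e-12)

  expect_error(simulate_interaction_surface(truth, d, resolution = 1),
               "resolution")
})

test_that("additive oracle makes every interaction statistic vanish", {
  d <- make_dataset(13, rho_max = 0, noise_sigma = 0, n_samples = 30)
  stub <- additive_oi_predictor("EA", "BA")
  surf <- simulate_interaction_surface(stub, d, resolution = 40,
                                       min_oi_sum = 2)
  expect_lt(max(abs(surf$oi_reduction[!surf$mask])), 1e-9)
  for (support in c(TRUE, FALSE)) {
    sc <- ratio_scatter(d, surf, within_support = support)
    expect_lt(max(abs(sc$oi_reduction_ratio)), 1e-9)
  }
  su <- summarize_surface(ratio_scatter(d, surf))
  expect_lt(abs(su$peak_ratio), 1e-9)
})

test_that("scatter bookkeeping: row counts, ranges, and mask exclusion", {
  d <- make_dataset(14, n_samples = 30)
  m <- fit_intensity_model(split_dataset(d, 0.7, seed = 3)$train,
                           small_grid(), cv_folds = 5, seed = 4)
  surf <- simulate_interaction_surface(m, d, resolution = 30,
                                       min_oi_sum = 2)
  full <- ratio_scatter(d, surf, within_support = FALSE)
  expect_equal(nrow(full),
               nrow(d$samples) + sum(!surf$mask) - attr(full, "n_dropped"))
  expect_true(all(full$x_a > 0 & full$x_a < 1))
  expect_true(all(is.finite(full$oi_reduction_ratio)))
  expect_setequal(unique(full$source), c("measured", "predicted"))

  sc <- ratio_scatter(d, surf, within_support = TRUE)
  expect_lt(sum(sc$source == "predicted"), sum(!surf$mask))
  expect_equal(sum(sc$source == "measured"), nrow(d$samples))

  expect_error(
    ratio_scatter(make_dataset(14, pair = c("PA", "VA")), surf),
    "different odorant pairs")
})

test_that("summary recovers the generator ground truth from a clean scatter", {
  d <- make_dataset(9, rho_max = 0.35, noise_sigma = 0, n_samples = 60)
  truth <- truth_predictor(ester_pair, rho_max = 0.35)
  surf <- simulate_interaction_surface(truth, d, resolution = 50,
                                       min_oi_sum = 2)
  su <- summarize_surface(ratio_scatter(d, surf))
  expect_lt(abs(su$peak_ratio - 0.35), 0.02)
  expect_lt(abs(su$peak_x_a - 0.5), 0.05)
  expect_lt(abs(su$intensity_ratio_correlation), 0.5)

  # duplication invariance of the summary's peak
  sc <- ratio_scatter(d, surf)
  su2 <- summarize_surface(rbind(sc, sc))
  expect_identical(su2$peak_ratio, su$peak_ratio)
  expect_identical(su2$peak_x_a, su$peak_x_a)

  expect_error(summarize_surface(sc[1:5, ]), "at least 10")
})
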