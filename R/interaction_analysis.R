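# Interaction statistics (OI_sum, OI reduction, OI reduction ratio,
# mixing ratio), model-densified interaction surfaces on the lnOAV
# plane, and the ratio-scatter / summary products.

#' Additive (no-interaction) odor intensity of a binary mixture
#'
#' `OI_sum = OI_a + OI_b`, each component intensity from its family's
#' psychophysical law. No clamping.
#'
#' @param lnoav_a,lnoav_b Component lnOAVs.
#' @param family_a,family_b Chemical family of each component.
#' @return OI_sum in OIRS units.
#' @export
#' @examples
#' oi_sum(3, 3, "ester")          # 1.5 + 1.5
#' oi_sum(1, 2, "aromatic")       # 1.07 + 2.14
oi_sum <- function(lnoav_a, lnoav_b, family_a, family_b = family_a) {
  oi_from_lnoav(lnoav_a, family_a) + oi_from_lnoav(lnoav_b, family_b)
}

#' Odor-intensity reduction of a mixture
#'
#' `OI reduction = OI_sum - OI_mix`; positive values indicate antagonism
#' (the mixture smells weaker than the additive expectation), negative
#' values synergism.
#'
#' @param oi_sum_val Additive intensity, OIRS units.
#' @param oi_mix_val Measured or predicted mixture intensity, OIRS units.
#' @return OI reduction in OIRS units.
#' @export
oi_reduction <- function(oi_sum_val, oi_mix_val) {
  oi_sum_val - oi_mix_val
}

#' Odor-intensity reduction ratio
#'
#' `(OI_sum - OI_mix) / OI_sum`: 0 for an additive mixture, 1 for
#' complete suppression, negative for synergism.
#'
#' @inheritParams oi_reduction
#' @return Dimensionless reduction ratio.
#' @export
oi_reduction_ratio <- function(oi_sum_val, oi_mix_val) {
  if (any(oi_sum_val == 0)) {
    stop("OI reduction ratio is undefined where OI_sum = 0")
  }
  (oi_sum_val - oi_mix_val) / oi_sum_val
}

#' Mixing ratio of a binary mixture
#'
#' `x_a = lnOAV_a / (lnOAV_a + lnOAV_b)`, the composition coordinate at
#' which the interaction degree is analyzed; `x_a + x_b = 1`.
#'
#' @param lnoav_a,lnoav_b Component lnOAVs with positive sum.
#' @return Mixing ratio(s).
#' @export
mixing_ratio <- function(lnoav_a, lnoav_b) {
  total <- lnoav_a + lnoav_b
  if (any(total <= 0)) {
    stop("lnoav_a + lnoav_b must be > 0 for the mixing ratio to be defined")
  }
  lnoav_a / total
}

# A "model" may be a fitted intensity_model or a plain function
# (conc_a, conc_b) -> OI, e.g. the additive oracle used in tests.
predict_mixture_oi <- function(model, conc_a, conc_b) {
  if (is.function(model)) {
    as.numeric(model(conc_a, conc_b))
  } else {
    predict_oi(model, conc_a, conc_b)
  }
}

#' Exact additive predictor for a pair (no-interaction oracle)
#'
#' Returns a function `(conc_a, conc_b) -> OI_sum` computed exactly from
#' the psychophysical laws; useful as a null model in which every
#' interaction statistic must vanish.
#'
#' @param odorant_a,odorant_b Abbreviations or one-row registry entries.
#' @param registry Odorant registry.
#' @return A function of two concentration vectors.
#' @export
additive_oi_predictor <- function(odorant_a, odorant_b,
                                  registry = default_odorant_registry()) {
  oa <- resolve_odorant(odorant_a, registry)
  ob <- resolve_odorant(odorant_b, registry)
  function(conc_a, conc_b) {
    oi_sum(ln_oav(conc_a, oa), ln_oav(conc_b, ob), oa$family, ob$family)
  }
}

dataset_lnoavs <- function(dataset) {
  list(a = ln_oav(dataset$samples$conc_a_mg_m3, dataset$odorant_a),
       b = ln_oav(dataset$samples$conc_b_mg_m3, dataset$odorant_b))
}

#' Densify the composition space with model predictions
#'
#' Builds a `resolution x resolution` grid of lnOAV values spanning each
#' component's observed range in `dataset`, converts every cell to
#' concentrations, scores it with the model to obtain `OI_mix`, computes
#' the additive `OI_sum` and `OI reduction = OI_sum - OI_mix`, and masks
#' cells whose `OI_sum` falls below `min_oi_sum` (low-intensity samples
#' carry too much olfactory evaluation error to interpret). Anchors carry
#' the measured samples and the unmasked grid predictions for plotting.
#'
#' @param model A fitted `intensity_model`, or a function
#'   `(conc_a, conc_b) -> OI`.
#' @param dataset The [panel_dataset()] supplying the axis bounds and the
#'   measured anchor points.
#' @param resolution Number of grid points per axis (>= 2).
#' @param min_oi_sum Masking threshold on `OI_sum`, OIRS units.
#' @return An object of class `interaction_surface` with monotone axes
#'   `axis_a`, `axis_b`, matrices `oi_mix`, `oi_sum`, `oi_reduction`,
#'   logical `mask` (`TRUE` = excluded), and an `anchors` tibble.
#' @export
simulate_interaction_surface <- function(model, dataset, resolution = 50,
                                         min_oi_sum = 2.0) {
  stopifnot(inherits(dataset, "panel_dataset"))
  if (resolution < 2) stop("resolution must be >= 2")
  if (!is.function(model) && !inherits(model, "intensity_model")) {
    stop("model must be a fitted intensity_model or a prediction function")
  }
  ln <- dataset_lnoavs(dataset)
  axis_a <- seq(min(ln$a), max(ln$a), length.out = resolution)
  axis_b <- seq(min(ln$b), max(ln$b), length.out = resolution)
  fam_a <- dataset$odorant_a$family
  fam_b <- dataset$odorant_b$family

  grid_a <- rep(axis_a, times = resolution)       # row index varies fastest
  grid_b <- rep(axis_b, each = resolution)
  conc_a <- conc_from_lnoav(grid_a, dataset$odorant_a)
  conc_b <- conc_from_lnoav(grid_b, dataset$odorant_b)
  mix <- predict_mixture_oi(model, conc_a, conc_b)
  add <- oi_sum(grid_a, grid_b, fam_a, fam_b)

  dim_ <- c(resolution, resolution)
  oi_mix_m <- matrix(mix, nrow = resolution)      # [i, j] = (axis_a[i], axis_b[j])
  oi_sum_m <- matrix(add, nrow = resolution)
  mask <- oi_sum_m < min_oi_sum

  anchors <- rbind(
    tibble::tibble(lnoav_a = ln$a, lnoav_b = ln$b,
                   oi = dataset$samples$oi, source = "measured"),
    tibble::tibble(lnoav_a = grid_a[!as.vector(mask)],
                   lnoav_b = grid_b[!as.vector(mask)],
                   oi = mix[!as.vector(mask)], source = "predicted")
  )

  structure(list(
    pair = c(dataset$odorant_a$abbreviation, dataset$odorant_b$abbreviation),
    families = c(fam_a, fam_b),
    axis_a = axis_a, axis_b = axis_b,
    oi_mix = oi_mix_m, oi_sum = oi_sum_m,
    oi_reduction = oi_sum_m - oi_mix_m,
    mask = mask, min_oi_sum = min_oi_sum,
    anchors = anchors
  ), class = "interaction_surface")
}

#' @export
print.interaction_surface <- function(x, ...) {
  cat(sprintf("Interaction surface for %s + %s: %d x %d lnOAV grid\n",
              x$pair[1], x$pair[2], length(x$axis_a), length(x$axis_b)))
  cat(sprintf("  lnOAV_a in [%.2f, %.2f], lnOAV_b in [%.2f, %.2f]\n",
              min(x$axis_a), max(x$axis_a), min(x$axis_b), max(x$axis_b)))
  cat(sprintf("  %d / %d cells masked (OI_sum < %g)\n",
              sum(x$mask), length(x$mask), x$min_oi_sum))
  invisible(x)
}

#' Reduction-ratio scatter over measured samples and grid predictions
#'
#' One row per measured sample and per unmasked surface cell: the mixing
#' ratio `x_a`, the reduction ratio, and the mixture intensity `OI_mix`
#' (the color variable of the scatter). Rows with non-positive `OI_sum`
#' (undefined ratio) are dropped; their count is kept in the
#' `n_dropped` attribute.
#'
#' With `within_support = TRUE` (the default) the predicted rows are
#' restricted to grid cells whose total lnOAV and mixing ratio both lie
#' inside the ranges observed in the measured data. The fitted model is
#' only trusted for mixtures similar to those it was trained on; the
#' rectangular lnOAV grid, by contrast, reaches compositions (e.g. both
#' components simultaneously at their individual maxima) far outside the
#' measured design, where predictions are extrapolation.
#'
#' @param dataset The measured [panel_dataset()].
#' @param surface The [simulate_interaction_surface()] result for the
#'   same pair.
#' @param within_support Keep predicted rows only inside the measured
#'   composition support (default TRUE).
#' @return A tibble with columns `x_a`, `oi_reduction_ratio`, `oi_mix`,
#'   `source`, and attribute `n_dropped`.
#' @export
ratio_scatter <- function(dataset, surface, within_support = TRUE) {
  stopifnot(inherits(dataset, "panel_dataset"),
            inherits(surface, "interaction_surface"))
  if (!identical(surface$pair,
                 c(dataset$odorant_a$abbreviation,
                   dataset$odorant_b$abbreviation))) {
    stop("surface and dataset refer to different odorant pairs")
  }
  ln <- dataset_lnoavs(dataset)
  s_meas <- oi_sum(ln$a, ln$b, dataset$odorant_a$family,
                   dataset$odorant_b$family)
  meas <- tibble::tibble(
    x_a = mixing_ratio(ln$a, ln$b),
    s = s_meas,
    oi_mix = dataset$samples$oi,
    source = "measured"
  )

  res <- length(surface$axis_a)
  grid_a <- rep(surface$axis_a, times = length(surface$axis_b))
  grid_b <- rep(surface$axis_b, each = res)
  keep <- !as.vector(surface$mask)
  if (within_support) {
    total_obs <- range(ln$a + ln$b)
    x_obs <- range(mixing_ratio(ln$a, ln$b))
    total_g <- grid_a + grid_b
    x_g <- ifelse(total_g > 0, grid_a / total_g, NA_real_)
    keep <- keep & !is.na(x_g) &
      total_g >= total_obs[1] & total_g <= total_obs[2] &
      x_g >= x_obs[1] & x_g <= x_obs[2]
  }
  pred <- tibble::tibble(
    x_a = mixing_ratio(grid_a[keep], grid_b[keep]),
    s = as.vector(surface$oi_sum)[keep],
    oi_mix = as.vector(surface$oi_mix)[keep],
    source = "predicted"
  )

  rows <- rbind(meas, pred)
  ok <- rows$s > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) with OI_sum <= 0 dropped from the scatter")
  }
  rows <- rows[ok, ]
  out <- tibble::tibble(
    x_a = rows$x_a,
    oi_reduction_ratio = oi_reduction_ratio(rows$s, rows$oi_mix),
    oi_mix = rows$oi_mix,
    source = rows$source
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Summarize a reduction-ratio scatter
#'
#' Locates the peak reduction ratio and its mixing ratio, and measures
#' the Spearman rank correlation between the reduction ratio and the
#' mixture intensity over all rows (the intensity-independence check:
#' under a purely ratio-driven interaction this correlation is near
#' zero). The peak is read off the model-predicted rows when any are
#' present: the densified surface is the de-noised estimate of the
#' interaction pattern, whereas individual measured readings carry panel
#' noise that would bias a maximum upward.
#'
#' @param scatter A [ratio_scatter()] tibble with at least 10 rows.
#' @return A `surface_summary` list: `peak_ratio`, `peak_x_a`,
#'   `intensity_ratio_correlation`, `n_points`.
#' @export
summarize_surface <- function(scatter) {
  if (nrow(scatter) < 10) {
    stop("need at least 10 scatter rows to summarize, got ", nrow(scatter))
  }
  peak_rows <- if (any(scatter$source == "predicted")) {
    scatter[scatter$source == "predicted", ]
  } else {
    scatter
  }
  i <- which.max(peak_rows$oi_reduction_ratio)
  structure(list(
    peak_ratio = peak_rows$oi_reduction_ratio[i],
    peak_x_a = peak_rows$x_a[i],
    intensity_ratio_correlation =
      stats::cor(scatter$oi_reduction_ratio, scatter$oi_mix,
                 method = "spearman"),
    n_points = nrow(scatter)
  ), class = "surface_summary")
}

#' @export
print.surface_summary <- function(x, ...) {
  cat("Interaction summary\n")
  cat(sprintf("  peak reduction ratio %.3f at x_a = %.3f (n = %d)\n",
              x$peak_ratio, x$peak_x_a, x$n_points))
  cat(sprintf("  rank correlation(ratio, OI_mix) = %.3f\n",
              x$intensity_ratio_correlation))
  invisible(x)
}
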