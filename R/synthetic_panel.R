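# Synthetic sensory-panel generator: binary-mixture datasets with a known
# interaction ground truth, so the whole analysis pipeline is testable
# without measured olfactometry data.

default_rho_max <- function(family) {
  # Aromatic pairs show weaker antagonism than esters/aldehydes.
  if (family == "aromatic") 0.15 else 0.35
}

# Total-lnOAV range over which the additive intensity of a same-family
# pair spans 2--7 OIRS: for OI_sum(T) = slope * T + 2 * intercept this is
# T in [(2 - 2 i)/s, (7 - 2 i)/s]. Keeps panel readings in the reliable
# band (below 2 OIRS the olfactory evaluation error grows; 8 is the
# scale ceiling).
default_lnoav_range <- function(family) {
  law <- law_for_family(family)
  c((2 - 2 * law$intercept) / law$slope,
    (7 - 2 * law$intercept) / law$slope)
}

#' Configuration of the synthetic panel generator
#'
#' Defines the ground-truth interaction, panel noise, and mixture design
#' used to emulate an olfactometry dataset for one binary pair. The
#' ground-truth mixture intensity is
#' `OI_sum * (1 - rho(x_a))` with `rho(x) = rho_max * (4 x (1-x))^shape_p`:
#' antagonism is maximal (`rho_max`) at the equal-lnOAV mixing ratio
#' `x_a = 0.5` and vanishes for pure components. `rho_max < 0` emulates
#' synergism.
#'
#' @param odorant_a,odorant_b Abbreviations of the two components; they
#'   must belong to the same chemical family.
#' @param seed Integer seed; mandatory, so every dataset is reproducible.
#' @param rho_max Peak true reduction ratio in `(-1, 1)`; positive values
#'   mean antagonism. Default 0.35 for ester/aldehyde pairs, 0.15 for
#'   aromatic pairs.
#' @param shape_p Exponent (>= 0) of the symmetric ratio kernel.
#' @param noise_sigma Standard deviation of panel noise, OIRS units.
#'   Default 0.3, near the accepted ~0.4 OIRS olfactory evaluation error.
#' @param n_samples Number of mixture samples (>= 4).
#' @param x_levels Target mixing ratios `x_a = lnOAV_a / (lnOAV_a +
#'   lnOAV_b)` of the design; all in `(0, 1)`. Levels are allocated in a
#'   balanced cycle over the samples, as in designed mixture experiments.
#' @param total_lnoav_range Range `[low, high]`, `low < high`, of the
#'   total `T = lnOAV_a + lnOAV_b` sampled uniformly. The default
#'   (`NULL`) inverts the pair's psychophysical law so that the additive
#'   intensity `OI_sum` spans 2--7 OIRS, the band where panel readings
#'   are reliable.
#' @param min_oi_sum Samples whose additive intensity `OI_sum` falls below
#'   this OIRS level are redrawn (default 2.0, the low-intensity exclusion
#'   used throughout the analysis).
#' @param oi_clip Length-2 numeric `[lo, hi]` clipping the noisy panel
#'   reading to the physical OIRS scale (default `c(0, 8)`), or `NULL`
#'   to disable clipping.
#' @param registry Odorant registry.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(odorant_a = "EA", odorant_b = "BA", seed,
                             rho_max = NULL, shape_p = 1,
                             noise_sigma = 0.3, n_samples = 30,
                             x_levels = seq(0.1, 0.9, by = 0.1),
                             total_lnoav_range = NULL,
                             min_oi_sum = 2.0, oi_clip = c(0, 8),
                             registry = default_odorant_registry()) {
  oa <- get_odorant(odorant_a, registry)
  ob <- get_odorant(odorant_b, registry)
  if (oa$family != ob$family) {
    stop("both odorants must belong to the same family (got ",
         oa$family, " and ", ob$family, ")")
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 ||
      !is.finite(seed)) {
    stop("an explicit integer seed is required")
  }
  if (is.null(rho_max)) rho_max <- default_rho_max(oa$family)
  if (!is.numeric(rho_max) || abs(rho_max) >= 1) {
    stop("rho_max must lie in (-1, 1), got ", rho_max)
  }
  if (shape_p < 0) stop("shape_p must be >= 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (n_samples < 4) stop("n_samples must be >= 4")
  if (any(x_levels <= 0) || any(x_levels >= 1)) {
    stop("x_levels must lie strictly inside (0, 1)")
  }
  if (is.null(total_lnoav_range)) {
    total_lnoav_range <- default_lnoav_range(oa$family)
  }
  if (length(total_lnoav_range) != 2 ||
      total_lnoav_range[1] >= total_lnoav_range[2]) {
    stop("total_lnoav_range must be [low, high] with low < high")
  }
  if (!is.null(oi_clip) &&
      (length(oi_clip) != 2 || oi_clip[1] >= oi_clip[2])) {
    stop("oi_clip must be NULL or [lo, hi] with lo < hi")
  }
  structure(list(
    odorant_a = oa$abbreviation, odorant_b = ob$abbreviation,
    family = oa$family, rho_max = rho_max, shape_p = shape_p,
    noise_sigma = noise_sigma, n_samples = as.integer(n_samples),
    x_levels = x_levels, total_lnoav_range = total_lnoav_range,
    min_oi_sum = min_oi_sum, oi_clip = oi_clip,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic panel generator config\n")
  cat(sprintf("  pair: %s + %s (%s)\n", x$odorant_a, x$odorant_b, x$family))
  cat(sprintf("  ground truth: rho_max = %g, shape_p = %g\n",
              x$rho_max, x$shape_p))
  cat(sprintf("  noise_sigma = %g OIRS, n_samples = %d, seed = %d\n",
              x$noise_sigma, x$n_samples, x$seed))
  cat(sprintf("  x_levels: %s\n", paste(x$x_levels, collapse = ", ")))
  cat(sprintf("  total lnOAV in [%g, %g], OI_sum >= %g, clip %s\n",
              x$total_lnoav_range[1], x$total_lnoav_range[2], x$min_oi_sum,
              if (is.null(x$oi_clip)) "disabled"
              else sprintf("[%g, %g]", x$oi_clip[1], x$oi_clip[2])))
  invisible(x)
}

#' Ground-truth reduction ratio at a mixing ratio
#'
#' `rho(x_a) = rho_max * (4 x_a (1 - x_a))^shape_p`: symmetric about 0.5,
#' zero at the pure components, and equal to `rho_max` at `x_a = 0.5`.
#'
#' @param x_a Mixing ratio(s) in `[0, 1]`.
#' @param rho_max Peak reduction ratio in `(-1, 1)`.
#' @param shape_p Kernel exponent >= 0.
#' @return Dimensionless reduction ratio(s).
#' @export
#' @examples
#' true_reduction_ratio(0.5, 0.35, 1)   # 0.35
#' true_reduction_ratio(0.25, 0.4, 1)   # 0.3
true_reduction_ratio <- function(x_a, rho_max, shape_p = 1) {
  if (!is.numeric(rho_max) || length(rho_max) != 1 || abs(rho_max) >= 1) {
    stop("rho_max must lie in (-1, 1), got ", rho_max)
  }
  if (any(x_a < 0 | x_a > 1)) stop("x_a must lie in [0, 1]")
  rho_max * (4 * x_a * (1 - x_a))^shape_p
}

#' Ground-truth mixture odor intensity
#'
#' `OI_mix_true = OI_sum * (1 - rho(x_a))`, where `OI_sum` is the additive
#' intensity of the two components and `x_a = lnOAV_a / (lnOAV_a +
#' lnOAV_b)`. With `rho_max = 0` the mixture is exactly additive.
#'
#' @param lnoav_a,lnoav_b Component lnOAVs; their sum must be positive.
#' @param family_a,family_b Chemical family of each component.
#' @inheritParams true_reduction_ratio
#' @return Ground-truth mixture intensity, OIRS units.
#' @export
true_mixture_oi <- function(lnoav_a, lnoav_b, family_a, family_b = family_a,
                            rho_max, shape_p = 1) {
  total <- lnoav_a + lnoav_b
  if (any(total <= 0)) {
    stop("lnoav_a + lnoav_b must be > 0 for the mixing ratio to be defined")
  }
  s <- oi_sum(lnoav_a, lnoav_b, family_a, family_b)
  x_a <- lnoav_a / total
  s * (1 - true_reduction_ratio(x_a, rho_max, shape_p))
}

#' Construct a binary-mixture panel dataset
#'
#' @param odorant_a,odorant_b One-row registry entries of the components.
#' @param samples Tibble with columns `conc_a_mg_m3`, `conc_b_mg_m3`, `oi`,
#'   `source` (each `"measured"` or `"predicted"`).
#' @param provenance Free-text provenance (config digest or file path).
#' @return An object of class `panel_dataset`.
#' @export
panel_dataset <- function(odorant_a, odorant_b, samples, provenance = "") {
  required <- c("conc_a_mg_m3", "conc_b_mg_m3", "oi", "source")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0) {
    stop("samples is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (odorant_a$family != odorant_b$family) {
    stop("both odorants must belong to the same family")
  }
  if (any(samples$conc_a_mg_m3 <= 0) || any(samples$conc_b_mg_m3 <= 0)) {
    stop("all concentrations must be strictly positive")
  }
  if (!all(samples$source %in% c("measured", "predicted"))) {
    stop("sample source must be 'measured' or 'predicted'")
  }
  structure(list(
    odorant_a = odorant_a, odorant_b = odorant_b,
    samples = tibble::as_tibble(samples)[required],
    provenance = provenance
  ), class = "panel_dataset")
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf("Binary-mixture panel dataset: %s + %s (%s), %d samples\n",
              x$odorant_a$abbreviation, x$odorant_b$abbreviation,
              x$odorant_a$family, nrow(x$samples)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  print(x$samples, ...)
  invisible(x)
}

config_digest <- function(config) {
  sprintf(paste0("generator(%s+%s, rho_max=%g, shape_p=%g, sigma=%g, n=%d, ",
                 "T=[%g,%g], min_oi_sum=%g, seed=%d)"),
          config$odorant_a, config$odorant_b, config$rho_max, config$shape_p,
          config$noise_sigma, config$n_samples, config$total_lnoav_range[1],
          config$total_lnoav_range[2], config$min_oi_sum, config$seed)
}

#' Generate a synthetic binary-mixture panel dataset
#'
#' Allocates the target mixing ratios `x_levels` to the `n_samples`
#' design points in a balanced cycle (every ratio level is replicated as
#' evenly as possible, as in designed sensory mixture experiments), then
#' draws each point's total `T = lnOAV_a + lnOAV_b` uniformly from
#' `total_lnoav_range`. Points whose additive intensity `OI_sum` falls
#' below `min_oi_sum` have their `T` rejected and redrawn. Each design
#' point is converted to concentrations through the odor thresholds, the
#' ground-truth mixture intensity is computed, Gaussian panel noise is
#' added, and the reading is clipped to the OIRS scale. Identical config
#' (including seed) gives a bit-identical dataset.
#'
#' @param config A [generator_config()].
#' @param registry Odorant registry.
#' @return A [panel_dataset()] with `source = "measured"` samples.
#' @export
generate_panel_dataset <- function(config,
                                   registry = default_odorant_registry()) {
  stopifnot(inherits(config, "generator_config"))
  oa <- get_odorant(config$odorant_a, registry)
  ob <- get_odorant(config$odorant_b, registry)
  n <- config$n_samples
  max_draws <- 1000L * n
  lo <- config$total_lnoav_range[1]
  hi <- config$total_lnoav_range[2]
  x <- rep(config$x_levels, length.out = n)

  withr::with_seed(config$seed, {
    tt <- stats::runif(n, lo, hi)
    s <- oi_sum(x * tt, (1 - x) * tt, oa$family, ob$family)
    draws <- n
    bad <- s < config$min_oi_sum
    while (any(bad)) {
      if (draws >= max_draws) {
        stop("design region empty: could not satisfy OI_sum >= ",
             config$min_oi_sum, " after ", max_draws, " draws")
      }
      k <- sum(bad)
      draws <- draws + k
      tt[bad] <- stats::runif(k, lo, hi)
      s[bad] <- oi_sum(x[bad] * tt[bad], (1 - x[bad]) * tt[bad],
                       oa$family, ob$family)
      bad <- s < config$min_oi_sum
    }
    noise <- stats::rnorm(n, 0, config$noise_sigma)
  })

  la <- x * tt
  lb <- (1 - x) * tt
  mix_true <- true_mixture_oi(la, lb, oa$family, ob$family,
                              config$rho_max, config$shape_p)
  oi <- mix_true + noise
  if (!is.null(config$oi_clip)) {
    oi <- pmin(pmax(oi, config$oi_clip[1]), config$oi_clip[2])
  }

  samples <- tibble::tibble(
    conc_a_mg_m3 = conc_from_lnoav(la, oa),
    conc_b_mg_m3 = conc_from_lnoav(lb, ob),
    oi = oi,
    source = "measured"
  )
  panel_dataset(oa, ob, samples, provenance = config_digest(config))
}
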