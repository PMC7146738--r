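# Odorant registry and the deterministic conversions between chemical
# concentration, log odor activity value (lnOAV), and odor intensity (OI)
# on the 1-butanol OIRS scale.

#' Family-specific OI--lnOAV psychophysical laws
#'
#' Each chemical family maps lnOAV (natural log of the odor activity value,
#' i.e. concentration over odor threshold) to odor intensity on the OIRS
#' scale through an affine law `OI = slope * lnOAV + intercept`:
#' esters `1.40 * lnOAV - 2.70`, aldehydes `1.76 * lnOAV - 1.82`, and
#' aromatic hydrocarbons `1.07 * lnOAV` (intercept stored explicitly as 0
#' so the three families share one affine form).
#'
#' @return A tibble with columns `family`, `slope` (OIRS units per lnOAV
#'   unit) and `intercept` (OIRS units).
#' @export
#' @examples
#' psychophysical_laws()
psychophysical_laws <- function() {
  tibble::tibble(
    family    = c("ester", "aldehyde", "aromatic"),
    slope     = c(1.40, 1.76, 1.07),
    intercept = c(-2.70, -1.82, 0.00)
  )
}

#' Valid chemical families
#' @return Character vector of the three supported families.
#' @export
odor_families <- function() c("ester", "aldehyde", "aromatic")

#' Default odorant registry
#'
#' Nine odorants (three esters, three aldehydes, three aromatic
#' hydrocarbons) with their panel-measured odor detection thresholds in
#' mg/m3. The registry ships as a CSV data file
#' (`system.file("extdata", "odorants.csv", package = "odormix")`).
#' Note: the CAS number stored for n-heptaldehyde, 117-71-7, follows the
#' source table as printed; the commonly listed CAS for that compound is
#' 111-71-7. CAS strings are opaque identifiers here, never validated.
#'
#' @return A tibble with columns `abbreviation`, `name`, `cas`, `family`,
#'   `threshold_mg_m3`.
#' @export
#' @examples
#' default_odorant_registry()
default_odorant_registry <- function() {
  path <- system.file("extdata", "odorants.csv", package = "odormix",
                      mustWork = TRUE)
  read_odorant_registry(path)
}

#' Read an odorant registry CSV
#'
#' @param path CSV file with header
#'   `abbreviation,name,cas,family,threshold_mg_m3`.
#' @return A validated registry tibble.
#' @export
read_odorant_registry <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    abbreviation = "character", name = "character", cas = "character",
    family = "character", threshold_mg_m3 = "numeric"
  ))
  required <- c("abbreviation", "name", "cas", "family", "threshold_mg_m3")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("registry is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$abbreviation)) {
    stop("registry abbreviations must be unique")
  }
  bad_fam <- setdiff(unique(df$family), odor_families())
  if (length(bad_fam) > 0) {
    stop("unknown odor family in registry: ", paste(bad_fam, collapse = ", "))
  }
  if (any(!is.finite(df$threshold_mg_m3)) || any(df$threshold_mg_m3 <= 0)) {
    stop("odor thresholds must be finite and strictly positive")
  }
  tibble::as_tibble(df[required])
}

#' Look up an odorant by abbreviation
#'
#' @param abbreviation Odorant abbreviation, e.g. `"EA"`.
#' @param registry Registry tibble; defaults to the built-in registry.
#' @return A one-row tibble.
#' @export
get_odorant <- function(abbreviation, registry = default_odorant_registry()) {
  i <- match(abbreviation, registry$abbreviation)
  if (is.na(i)) {
    stop("unknown odorant abbreviation: '", abbreviation, "'")
  }
  registry[i, ]
}

# Accept either a one-row registry entry or an abbreviation string.
resolve_odorant <- function(odorant, registry = default_odorant_registry()) {
  if (is.character(odorant) && length(odorant) == 1) {
    return(get_odorant(odorant, registry))
  }
  if (is.data.frame(odorant) && nrow(odorant) == 1 &&
      all(c("threshold_mg_m3", "family") %in% names(odorant))) {
    return(odorant)
  }
  stop("odorant must be an abbreviation or a one-row registry entry")
}

#' Log odor activity value of a concentration
#'
#' lnOAV = ln(C / C_thr), the natural log of the odor activity value
#' (concentration over the odorant's detection threshold).
#'
#' @param concentration Concentration(s) in mg/m3; strictly positive.
#' @param odorant Odorant abbreviation or one-row registry entry.
#' @param registry Registry used to resolve abbreviations.
#' @return lnOAV value(s), dimensionless.
#' @export
#' @examples
#' ln_oav(0.276, "EA")         # at threshold: 0
#' ln_oav(2.53 * exp(1), "B")  # one log-unit above threshold: 1
ln_oav <- function(concentration, odorant,
                   registry = default_odorant_registry()) {
  od <- resolve_odorant(odorant, registry)
  thr <- od$threshold_mg_m3
  if (!is.finite(thr) || thr <= 0) {
    stop("odor threshold must be > 0, got ", thr)
  }
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    bad <- concentration[!is.finite(concentration) | concentration <= 0][1]
    stop("concentration must be > 0 mg/m3, got ", bad)
  }
  log(concentration / thr)
}

#' Concentration from lnOAV (inverse of [ln_oav()])
#'
#' @param lnoav lnOAV value(s).
#' @inheritParams ln_oav
#' @return Concentration(s) in mg/m3.
#' @export
conc_from_lnoav <- function(lnoav, odorant,
                            registry = default_odorant_registry()) {
  od <- resolve_odorant(odorant, registry)
  thr <- od$threshold_mg_m3
  if (!is.finite(thr) || thr <= 0) {
    stop("odor threshold must be > 0, got ", thr)
  }
  thr * exp(lnoav)
}

law_for_family <- function(family) {
  laws <- psychophysical_laws()
  i <- match(family, laws$family)
  if (anyNA(i)) {
    stop("no psychophysical law registered for family: ",
         paste(unique(family[is.na(i)]), collapse = ", "))
  }
  laws[i, ]
}

#' Odor intensity from lnOAV
#'
#' Evaluates the family's affine law `OI = slope * lnOAV + intercept`.
#' No clamping is applied: below the law's root the value is negative,
#' and downstream stages decide how to treat sub-threshold intensities.
#'
#' @param lnoav lnOAV value(s).
#' @param family Chemical family (`"ester"`, `"aldehyde"`, `"aromatic"`);
#'   recycled against `lnoav`.
#' @return Odor intensity in OIRS units.
#' @export
#' @examples
#' oi_from_lnoav(3, "ester")     # 1.40 * 3 - 2.70 = 1.5
#' oi_from_lnoav(0, "aromatic")  # 0
oi_from_lnoav <- function(lnoav, family) {
  law <- law_for_family(family)
  law$slope * lnoav + law$intercept
}

#' lnOAV from odor intensity (inverse of [oi_from_lnoav()])
#'
#' @param oi Odor intensity in OIRS units.
#' @inheritParams oi_from_lnoav
#' @return lnOAV value(s).
#' @export
lnoav_from_oi <- function(oi, family) {
  law <- law_for_family(family)
  if (any(law$slope == 0)) {
    stop("psychophysical law has zero slope; cannot invert")
  }
  (oi - law$intercept) / law$slope
}
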