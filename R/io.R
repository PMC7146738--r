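# CSV readers/writers for datasets, surfaces and scatters. All files are
# comma-separated UTF-8 with a header row and '.' as decimal separator.

#' Write a panel dataset to CSV
#'
#' Header: `odorant_a,odorant_b,conc_a_mg_m3,conc_b_mg_m3,oi,source`.
#'
#' @param dataset A [panel_dataset()].
#' @param path Destination CSV file.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "panel_dataset"))
  df <- data.frame(
    odorant_a = dataset$odorant_a$abbreviation,
    odorant_b = dataset$odorant_b$abbreviation,
    conc_a_mg_m3 = dataset$samples$conc_a_mg_m3,
    conc_b_mg_m3 = dataset$samples$conc_b_mg_m3,
    oi = dataset$samples$oi,
    source = dataset$samples$source
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a panel dataset from CSV
#'
#' Expects the header written by [write_dataset()]; all rows must name
#' the same odorant pair, resolvable in the registry. Malformed rows are
#' rejected with their file line number (header = line 1).
#'
#' @param path CSV file.
#' @param registry Odorant registry used to resolve abbreviations.
#' @return A [panel_dataset()].
#' @export
read_dataset <- function(path, registry = default_odorant_registry()) {
  required <- c("odorant_a", "odorant_b", "conc_a_mg_m3", "conc_b_mg_m3",
                "oi", "source")
  header <- strsplit(gsub("\"", "", readLines(path, n = 1)), ",")[[1]]
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    stop("dataset file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- utils::read.csv(path, colClasses = c(
    odorant_a = "character", odorant_b = "character",
    conc_a_mg_m3 = "numeric", conc_b_mg_m3 = "numeric",
    oi = "numeric", source = "character"
  ))
  if (nrow(df) == 0) {
    stop("dataset file '", path, "' contains a header but no samples")
  }
  line <- seq_len(nrow(df)) + 1L   # header occupies line 1
  fail <- function(rows, what) {
    stop("dataset file '", path, "': ", what, " on line ",
         paste(line[rows], collapse = ", "))
  }
  for (ab in c("odorant_a", "odorant_b")) {
    unknown <- !(df[[ab]] %in% registry$abbreviation)
    if (any(unknown)) fail(which(unknown), paste("unknown", ab))
  }
  if (length(unique(df$odorant_a)) != 1 || length(unique(df$odorant_b)) != 1) {
    stop("dataset file '", path, "' mixes more than one odorant pair")
  }
  for (cc in c("conc_a_mg_m3", "conc_b_mg_m3")) {
    bad <- !is.finite(df[[cc]]) | df[[cc]] <= 0
    if (any(bad)) fail(which(bad), paste("non-positive", cc))
  }
  bad_oi <- !is.finite(df$oi)
  if (any(bad_oi)) fail(which(bad_oi), "non-finite oi")
  bad_src <- !(df$source %in% c("measured", "predicted"))
  if (any(bad_src)) fail(which(bad_src), "invalid source")

  panel_dataset(
    get_odorant(df$odorant_a[1], registry),
    get_odorant(df$odorant_b[1], registry),
    tibble::tibble(conc_a_mg_m3 = df$conc_a_mg_m3,
                   conc_b_mg_m3 = df$conc_b_mg_m3,
                   oi = df$oi, source = df$source),
    provenance = path
  )
}

#' Export an interaction surface as a long-format CSV
#'
#' Header: `lnoav_a,lnoav_b,conc_a_mg_m3,conc_b_mg_m3,oi_mix,oi_sum,`
#' `oi_reduction,masked`; one row per grid cell.
#'
#' @param surface An [simulate_interaction_surface()] result.
#' @param path Destination CSV file.
#' @param registry Odorant registry (for the lnOAV-to-concentration
#'   conversion of the grid axes).
#' @export
write_surface_csv <- function(surface, path,
                              registry = default_odorant_registry()) {
  stopifnot(inherits(surface, "interaction_surface"))
  df <- surface_long(surface)
  oa <- get_odorant(surface$pair[1], registry)
  ob <- get_odorant(surface$pair[2], registry)
  df$conc_a_mg_m3 <- conc_from_lnoav(df$lnoav_a, oa)
  df$conc_b_mg_m3 <- conc_from_lnoav(df$lnoav_b, ob)
  df <- df[, c("lnoav_a", "lnoav_b", "conc_a_mg_m3", "conc_b_mg_m3",
               "oi_mix", "oi_sum", "oi_reduction", "masked")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a ratio scatter as CSV
#'
#' Header: `x_a,oi_reduction_ratio,oi_mix,source`.
#'
#' @param scatter A [ratio_scatter()] tibble.
#' @param path Destination CSV file.
#' @export
write_scatter_csv <- function(scatter, path) {
  utils::write.csv(
    as.data.frame(scatter[, c("x_a", "oi_reduction_ratio", "oi_mix",
                              "source")]),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
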