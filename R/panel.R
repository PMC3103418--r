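#' Default geographic region set
#'
#' The seven continental areas of the HGDP panel, used as the shipped default
#' region vocabulary. A custom region set can be supplied to [read_panel()]
#' and [as_pop_panel()].
#'
#' @return Character vector of seven region names.
#' @export
default_regions <- function() {
  c("Africa", "Middle_East", "Europe", "Central_South_Asia",
    "East_Asia", "America", "Oceania")
}

#' Construct and validate a population panel
#'
#' A population panel maps each sample to exactly one population, each
#' population to exactly one geographic region, and (optionally) each
#' population to a latitude/longitude used for geographic distances.
#'
#' @param df data.frame with columns `sample`, `population`, `region` and
#'   optionally `lat`, `lon` (decimal degrees).
#' @param regions allowed region names; defaults to the seven HGDP areas.
#' @return A `pop_panel` object (a validated data.frame).
#' @export
as_pop_panel <- function(df, regions = default_regions()) {
  need <- c("sample", "population", "region")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_gd("panel is missing column(s): ", paste(miss, collapse = ", "))
  if (!"lat" %in% names(df)) df$lat <- NA_real_
  if (!"lon" %in% names(df)) df$lon <- NA_real_
  df <- df[, c("sample", "population", "region", "lat", "lon")]
  for (col in need) df[[col]] <- as.character(df[[col]])
  df$lat <- as.numeric(df$lat)
  df$lon <- as.numeric(df$lon)

  if (any(is.na(df$sample) | df$sample == ""))
    stop_gd("panel contains empty sample ids")
  dup <- df$sample[duplicated(df$sample)]
  if (length(dup))
    stop_gd("duplicate sample id(s) in panel: ", paste(unique(dup), collapse = ", "))
  if (any(is.na(df$population) | df$population == ""))
    stop_gd("sample(s) with missing population: ",
            paste(df$sample[is.na(df$population) | df$population == ""], collapse = ", "))
  bad <- setdiff(unique(df$region), regions)
  if (length(bad))
    stop_gd("unknown region(s): ", paste(bad, collapse = ", "),
            " (allowed: ", paste(regions, collapse = ", "), ")")

  map <- unique(df[, c("population", "region")])
  dup_pop <- map$population[duplicated(map$population)]
  if (length(dup_pop))
    stop_gd("population(s) assigned to more than one region: ",
            paste(unique(dup_pop), collapse = ", "))
  if (length(unique(df$population)) < 2L)
    stop_gd("panel must contain at least 2 populations")

  ok <- is.na(df$lat) | (df$lat >= -90 & df$lat <= 90)
  if (!all(ok)) stop_gd("latitude out of [-90, 90] for sample(s): ",
                        paste(df$sample[!ok], collapse = ", "))
  ok <- is.na(df$lon) | (df$lon >= -180 & df$lon <= 180)
  if (!all(ok)) stop_gd("longitude out of [-180, 180] for sample(s): ",
                        paste(df$sample[!ok], collapse = ", "))

  # one coordinate per population
  crd <- unique(df[, c("population", "lat", "lon")])
  dup_crd <- crd$population[duplicated(crd$population)]
  if (length(dup_crd))
    stop_gd("population(s) with inconsistent coordinates: ",
            paste(unique(dup_crd), collapse = ", "))

  rownames(df) <- NULL
  structure(df, regions = regions, class = c("pop_panel", "data.frame"))
}

#' Read a population panel from TSV
#'
#' @param path TSV file with header columns `sample`, `population`, `region`,
#'   and optionally `lat`, `lon`. Lines starting with `#` are ignored.
#' @inheritParams as_pop_panel
#' @return A `pop_panel`.
#' @export
read_panel <- function(path, regions = default_regions()) {
  if (!file.exists(path)) stop_gd("panel file not found: ", path)
  as_pop_panel(read_tsv_gd(path), regions = regions)
}

#' Write a population panel to TSV
#'
#' @param panel a `pop_panel`.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  write_tsv_gd(as.data.frame(panel), path, digits = 10)
}

#' @export
print.pop_panel <- function(x, ...) {
  cat(sprintf("pop_panel: %d samples, %d populations, %d regions\n",
              nrow(x), length(unique(x$population)), length(unique(x$region))))
  invisible(x)
}

# populations in stable (first appearance) order
panel_populations <- function(panel) unique(panel$population)

panel_regions_used <- function(panel) unique(panel$region)

# population -> region named vector
panel_pop_region <- function(panel) {
  map <- unique(panel[, c("population", "region")])
  stats::setNames(map$region, map$population)
}

# population -> c(lat, lon)
panel_pop_coords <- function(panel) {
  crd <- unique(as.data.frame(panel)[, c("population", "lat", "lon")])
  if (any(is.na(crd$lat) | is.na(crd$lon)))
    stop_gd("coordinates missing for population(s): ",
            paste(crd$population[is.na(crd$lat) | is.na(crd$lon)], collapse = ", "))
  rownames(crd) <- crd$population
  crd[, c("lat", "lon")]
}
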