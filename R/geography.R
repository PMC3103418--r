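#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km (via
#' [geosphere::distHaversine()]). Vectorised over coordinates.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees.
#' @return distance(s) in km.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  for (v in list(lat1, lat2))
    if (any(!is.finite(v) | v < -90 | v > 90)) stop_gd("latitude out of [-90, 90]")
  for (v in list(lon1, lon2))
    if (any(!is.finite(v) | v < -180 | v > 180)) stop_gd("longitude out of [-180, 180]")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Default inter-regional migration waypoints
#'
#' Obligatory land-route waypoints used when routing distances between
#' populations of different regions, in the style of classic human-migration
#' distance work (e.g. routes through Cairo, Istanbul, Phnom Penh, Anadyr and
#' Prince Rupert). This set is a literature-standard reconstruction and is
#' fully user-overridable via the `waypoints` argument of
#' [population_distances()] or a waypoint TSV.
#'
#' @return data.frame: region_a, region_b, waypoints (semicolon-separated
#'   `lat,lon` pairs, ordered from the region_a side to the region_b side).
#' @export
default_waypoints <- function() {
  cairo <- "30.0,31.2"; istanbul <- "41.0,28.9"
  phnom_penh <- "11.5,104.9"; anadyr <- "64.0,177.0"; prince_rupert <- "54.3,-130.3"
  w <- rbind(
    c("Africa", "Europe", paste(cairo, istanbul, sep = ";")),
    c("Africa", "Middle_East", cairo),
    c("Africa", "Central_South_Asia", cairo),
    c("Africa", "East_Asia", cairo),
    c("Africa", "Oceania", paste(cairo, phnom_penh, sep = ";")),
    c("Africa", "America", paste(cairo, anadyr, prince_rupert, sep = ";")),
    c("Europe", "East_Asia", istanbul),
    c("Europe", "Central_South_Asia", istanbul),
    c("Europe", "Oceania", paste(istanbul, phnom_penh, sep = ";")),
    c("Europe", "America", paste(anadyr, prince_rupert, sep = ";")),
    c("Middle_East", "Oceania", phnom_penh),
    c("Middle_East", "America", paste(anadyr, prince_rupert, sep = ";")),
    c("Central_South_Asia", "Oceania", phnom_penh),
    c("Central_South_Asia", "America", paste(anadyr, prince_rupert, sep = ";")),
    c("East_Asia", "Oceania", phnom_penh),
    c("East_Asia", "America", paste(anadyr, prince_rupert, sep = ";")),
    c("Oceania", "America", paste(phnom_penh, anadyr, prince_rupert, sep = ";")),
    # land-contiguous Eurasian pairs: explicit direct routes
    c("Middle_East", "Europe", ""),
    c("Middle_East", "Central_South_Asia", ""),
    c("Middle_East", "East_Asia", ""),
    c("Central_South_Asia", "East_Asia", ""))
  data.frame(region_a = w[, 1], region_b = w[, 2], waypoints = w[, 3],
             stringsAsFactors = FALSE)
}

#' Read a waypoint table from TSV
#'
#' @param path TSV with columns `region_a`, `region_b`, `waypoints`
#'   (semicolon-separated `lat,lon` pairs).
#' @return waypoint data.frame.
#' @export
read_waypoints <- function(path) {
  df <- read_tsv_gd(path)
  need <- c("region_a", "region_b", "waypoints")
  if (!all(need %in% names(df)))
    stop_gd("waypoint table needs columns: ", paste(need, collapse = ", "))
  df
}

parse_waypoints <- function(s) {
  if (is.na(s) || !nzchar(s)) return(matrix(numeric(0), 0, 2))
  parts <- strsplit(strsplit(s, ";")[[1]], ",")
  m <- t(vapply(parts, function(p) as.numeric(trimws(p)), numeric(2)))
  colnames(m) <- c("lat", "lon")
  m
}

# ordered waypoint matrix for a region pair, or NULL when not configured
lookup_waypoints <- function(waypoints, ra, rb) {
  hit <- which(waypoints$region_a == ra & waypoints$region_b == rb)
  if (length(hit)) return(parse_waypoints(waypoints$waypoints[hit[1]]))
  hit <- which(waypoints$region_a == rb & waypoints$region_b == ra)
  if (length(hit)) {
    m <- parse_waypoints(waypoints$waypoints[hit[1]])
    return(m[rev(seq_len(nrow(m))), , drop = FALSE])
  }
  NULL
}

#' Waypoint-routed distance between two points
#'
#' Sum of great-circle legs through an ordered set of obligatory waypoints;
#' with no waypoints this is the direct haversine distance.
#'
#' @param lat1,lon1,lat2,lon2 endpoint coordinates (decimal degrees).
#' @param waypoint_coords matrix with columns `lat`, `lon` (possibly 0 rows).
#' @return distance in km.
#' @export
waypoint_distance <- function(lat1, lon1, lat2, lon2,
                              waypoint_coords = matrix(numeric(0), 0, 2)) {
  pts <- rbind(c(lat1, lon1), waypoint_coords, c(lat2, lon2))
  sum(great_circle_km(pts[-nrow(pts), 1], pts[-nrow(pts), 2],
                      pts[-1, 1], pts[-1, 2]))
}

#' Pairwise population distance matrix
#'
#' Same-region pairs use the direct great-circle distance; pairs in different
#' regions are routed through the configured obligatory waypoints. A region
#' pair without a waypoint entry falls back to the direct distance with a
#' warning.
#'
#' @param panel a `pop_panel` with coordinates for every population.
#' @param waypoints waypoint data.frame (see [default_waypoints()]), or
#'   `NULL` for direct distances everywhere.
#' @return symmetric matrix of km, zero diagonal, populations in panel order.
#' @export
population_distances <- function(panel, waypoints = default_waypoints()) {
  crd <- panel_pop_coords(panel)
  pops <- rownames(crd)
  reg <- panel_pop_region(panel)[pops]
  K <- length(pops)
  D <- matrix(0, K, K, dimnames = list(pops, pops))
  missing_pairs <- character(0)
  for (i in seq_len(K - 1)) for (j in seq((i + 1), K)) {
    wp <- matrix(numeric(0), 0, 2)
    if (!is.null(waypoints) && reg[i] != reg[j]) {
      found <- lookup_waypoints(waypoints, reg[i], reg[j])
      if (is.null(found)) {
        missing_pairs <- c(missing_pairs, paste(reg[i], reg[j], sep = "-"))
      } else wp <- found
    }
    D[i, j] <- D[j, i] <- waypoint_distance(crd$lat[i], crd$lon[i],
                                            crd$lat[j], crd$lon[j], wp)
  }
  if (length(missing_pairs))
    warning("no waypoint route for region pair(s) ",
            paste(unique(missing_pairs), collapse = ", "),
            "; direct distance used", call. = FALSE)
  D
}

#' Regression of pairwise F_ST on geographic distance
#'
#' Ordinary least squares of pairwise theta on pairwise km, per SNP and
#' pooled over all SNP-pair observations (isolation by distance). Pairs with
#' `NA` theta are dropped pairwise.
#'
#' @param fst_pairs named list of per-SNP pairwise theta matrices
#'   ([fst_matrices()] `$population`).
#' @param dist distance matrix from [population_distances()] (same
#'   population set).
#' @param pooled also fit the pooled regression (default `TRUE`).
#' @return data.frame: snp (or `"pooled"`), slope (theta per km), intercept,
#'   r_squared, p_value, n_pairs.
#' @export
ibd_regression <- function(fst_pairs, dist, pooled = TRUE) {
  pops <- rownames(dist)
  ut <- upper.tri(dist)
  km_all <- dist[ut]
  na_row <- function(label, n) data.frame(snp = label, slope = NA_real_,
                                          intercept = NA_real_,
                                          r_squared = NA_real_,
                                          p_value = NA_real_, n_pairs = n,
                                          stringsAsFactors = FALSE)
  fit_one <- function(theta, km, label, strict = TRUE) {
    ok <- !is.na(theta) & !is.na(km)
    theta <- theta[ok]; km <- km[ok]
    if (length(theta) < 3L) {
      if (strict)
        stop_gd("need at least 3 pairs with defined theta and distance (", label, ")")
      warning("fewer than 3 defined pairs for ", label, "; fit skipped",
              call. = FALSE)
      return(na_row(label, length(theta)))
    }
    if (length(unique(km)) < 2L)
      stop_gd("degenerate design: all distances equal (", label, ")")
    fit <- stats::lm(theta ~ km)
    sm <- summary(fit)
    r2 <- sm$r.squared
    pv <- sm$coefficients[2, 4]
    if (stats::var(theta) == 0) { r2 <- 0; pv <- 1 }  # flat response
    data.frame(snp = label,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = r2,
               p_value = pv,
               n_pairs = length(theta),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(names(fst_pairs), function(s) {
    m <- fst_pairs[[s]][pops, pops]
    fit_one(m[ut], km_all, s, strict = length(fst_pairs) == 1L)
  })
  if (pooled) {
    theta_all <- unlist(lapply(fst_pairs, function(m) m[pops, pops][ut]),
                        use.names = FALSE)
    km_rep <- rep(km_all, length(fst_pairs))
    rows <- c(rows, list(fit_one(theta_all, km_rep, "pooled")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
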