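# Isoline extraction and great-circle point-to-line distances.
#
# Contours come from grDevices::contourLines() (linear interpolation on the
# cell-centre lattice, the same contouring the field's GIS/R workflows use);
# land cells are NA and are simply skipped by the contouring. Distances are
# computed by densifying each polyline to <= 1 km vertex spacing and taking
# the haversine minimum, which bounds the error by the densification step
# and avoids committing to any map projection.

#' Extract isolines from a gridded field
#'
#' @param lon,lat Ascending cell-centre coordinate vectors.
#' @param z Matrix (`length(lon)` x `length(lat)`), NA treated as missing.
#' @param level Contour level.
#' @param min_length_km Polylines with geodesic length below this are
#'   dropped (used for the ice edge, where short speckle contours are
#'   eliminated; keep 0 for isobaths and coastlines).
#' @return A `contour_set`: list with `level`, `lines` (each a list with
#'   `lon`, `lat` vertex vectors), and `lengths_km`. A level outside the
#'   data range yields an empty set, not an error.
#' @export
extract_contours <- function(lon, lat, z, level, min_length_km = 0) {
  stopifnot(length(lon) == nrow(z), length(lat) == ncol(z))
  if (sum(!is.na(z)) < 4)
    stop("grid must contain at least 2x2 non-missing cells")
  # contourLines warns on flat fields; an absent level is simply empty here
  cl <- suppressWarnings(grDevices::contourLines(lon, lat, z, levels = level))
  lines <- lapply(cl, function(p) list(lon = p$x, lat = p$y))
  lengths_km <- vapply(lines, polyline_length_km, numeric(1))
  keep <- lengths_km >= min_length_km
  structure(
    list(level = level, lines = lines[keep], lengths_km = lengths_km[keep]),
    class = "contour_set"
  )
}

#' Geodesic length of a lon/lat polyline
#'
#' @param line List with `lon` and `lat` vertex vectors.
#' @return Length in km (0 for fewer than 2 vertices).
#' @export
polyline_length_km <- function(line) {
  n <- length(line$lon)
  if (n < 2) return(0)
  sum(gc_distance_km(line$lon[-n], line$lat[-n], line$lon[-1], line$lat[-1]))
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("contour_set: level %g, %d polyline(s), total %.1f km\n",
              x$level, length(x$lines), sum(x$lengths_km)))
  invisible(x)
}

# Densify a contour set to <= spacing_km between consecutive vertices;
# returns a 2-column matrix (lon, lat) of all vertices, cached on the set.
densify_contours <- function(contours, spacing_km = 1) {
  cached <- attr(contours, "densified")
  if (!is.null(cached) && isTRUE(attr(cached, "spacing_km") == spacing_km))
    return(cached)
  pieces <- lapply(contours$lines, function(ln) {
    n <- length(ln$lon)
    if (n == 1) return(cbind(ln$lon, ln$lat))
    seg_len <- gc_distance_km(ln$lon[-n], ln$lat[-n], ln$lon[-1], ln$lat[-1])
    out_lon <- vector("list", n - 1L)
    out_lat <- vector("list", n - 1L)
    for (i in seq_len(n - 1L)) {
      k <- max(1L, ceiling(seg_len[i] / spacing_km))
      f <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
      # linear interpolation in lon/lat is adequate at km scales
      out_lon[[i]] <- ln$lon[i] + f * (ln$lon[i + 1L] - ln$lon[i])
      out_lat[[i]] <- ln$lat[i] + f * (ln$lat[i + 1L] - ln$lat[i])
    }
    cbind(c(unlist(out_lon), ln$lon[n]), c(unlist(out_lat), ln$lat[n]))
  })
  dens <- do.call(rbind, pieces)
  attr(dens, "spacing_km") <- spacing_km
  dens
}

#' Shortest great-circle distance from points to a contour set
#'
#' Minimum haversine distance from each point to the densified polylines.
#' An empty contour set returns NA for every point (propagated downstream
#' as a missing covariate).
#'
#' @param lon,lat Point coordinates (vectorized).
#' @param contours A [extract_contours()] result.
#' @param spacing_km Densification spacing; the reported distance is exact
#'   to within roughly half this value.
#' @return Distances in km.
#' @export
distance_to_lines <- function(lon, lat, contours, spacing_km = 1) {
  stopifnot(inherits(contours, "contour_set"))
  n <- length(lon)
  if (length(contours$lines) == 0) return(rep(NA_real_, n))
  dens <- densify_contours(contours, spacing_km)
  vlam <- deg2rad(dens[, 1]); vphi <- deg2rad(dens[, 2])
  cosvphi <- cos(vphi)
  out <- numeric(n)
  block <- max(1L, floor(4e6 / nrow(dens)))
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    plam <- deg2rad(lon[s:e]); pphi <- deg2rad(lat[s:e])
    # haversine 'a' term, points x vertices
    sp <- sin(outer(pphi, vphi, "-") / 2)^2
    sl <- sin(outer(plam, vlam, "-") / 2)^2
    a <- sp + outer(cos(pphi), cosvphi) * sl
    a <- pmin(pmax(a, 0), 1)
    out[s:e] <- 2 * EARTH_RADIUS_KM * asin(sqrt(apply(a, 1, min)))
  }
  out
}

#' Ice-edge contours for one day
#'
#' The ice edge is the `level`% concentration isoline of that day's grid;
#' polylines shorter than `min_length_km` (speckle) are eliminated.
#'
#' @param env An `env_stack`.
#' @param date Date of the ice layer.
#' @param level Edge concentration, % (default 10).
#' @param min_length_km Minimum retained polyline length (default 50).
#' @return A `contour_set`.
#' @export
ice_edge_contours <- function(env, date, level = 10, min_length_km = 50) {
  d <- env_day_index(env, date)
  extract_contours(env$lon, env$lat, env$ice[, , d], level, min_length_km)
}

#' Depth isobath contours
#'
#' @param env An `env_stack`.
#' @param depth_m Isobath depth (default 1000 m). All polylines are kept.
#' @return A `contour_set`.
#' @export
isobath_contours <- function(env, depth_m = 1000) {
  extract_contours(env$lon, env$lat, env$depth, depth_m, 0)
}

#' Coastline derived from the land mask
#'
#' The coastline is the 0.5 isoline of the 0/1 land indicator, i.e. the
#' midline between land and sea cell centres.
#'
#' @param env An `env_stack`.
#' @return A `contour_set`.
#' @export
coastline_contours <- function(env) {
  extract_contours(env$lon, env$lat, env$land + 0, 0.5, 0)
}
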