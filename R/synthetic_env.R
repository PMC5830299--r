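# Synthetic environment generator: a shelf sea with an advancing ice field.
#
# The generated stack emulates the inputs the pipeline expects from passive
# microwave ice products (daily % concentration grids with a land mask) and a
# global bathymetry grid: an ice concentration field that is high in the
# north and falls off southward through a logistic ramp whose 10% level
# advances south at a configurable rate, over a shallow shelf that drops off
# through a monotone slope crossing 1000 m.

#' Configuration for the synthetic environment
#'
#' @param lon_range,lat_range Extent in decimal degrees (2-vectors, min/max).
#' @param cell Cell size in degrees (> 0).
#' @param n_days Number of daily ice layers (>= 1).
#' @param start_date First ice layer date (`Date`).
#' @param ice_advance_km_day Southward advance rate of the 10% ice contour,
#'   km/day. 0 freezes the field.
#' @param ice_gradient_km Width of the north-to-south concentration ramp, km.
#' @param ice_max_conc Concentration plateau in the pack interior, % (0-100].
#' @param ice_edge_start_lat Latitude of the 10% contour on day 1, degrees.
#' @param shelf_depth_m Depth of the shallow shelf, m.
#' @param slope_lat Latitude at which the continental slope is centred.
#' @param slope_width_km Width of the slope ramp, km.
#' @param max_depth_m Abyssal depth south of the slope, m.
#' @param coast_lat Cells north of this latitude are land.
#' @param coast_lon Cells east of this longitude are land.
#' @param noise_sd Optional seeded Gaussian noise on ice concentration, %.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return A list of class `env_config`.
#' @export
env_config <- function(lon_range = c(-180, -160), lat_range = c(54, 68.5),
                       cell = 0.25, n_days = 60,
                       start_date = as.Date("2005-11-01"),
                       ice_advance_km_day = 12, ice_gradient_km = 120,
                       ice_max_conc = 100, ice_edge_start_lat = 66,
                       shelf_depth_m = 60, slope_lat = 56.5,
                       slope_width_km = 80, max_depth_m = 3500,
                       coast_lat = 67.5, coast_lon = -161,
                       noise_sd = 5, seed = 1L) {
  cfg <- list(
    lon_range = lon_range, lat_range = lat_range, cell = cell,
    n_days = as.integer(n_days), start_date = as.Date(start_date),
    ice_advance_km_day = ice_advance_km_day,
    ice_gradient_km = ice_gradient_km, ice_max_conc = ice_max_conc,
    ice_edge_start_lat = ice_edge_start_lat,
    shelf_depth_m = shelf_depth_m, slope_lat = slope_lat,
    slope_width_km = slope_width_km, max_depth_m = max_depth_m,
    coast_lat = coast_lat, coast_lon = coast_lon,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  if (!is.numeric(cell) || cell <= 0) stop("invalid config: cell size must be > 0")
  if (cfg$n_days < 1) stop("invalid config: n_days must be >= 1")
  if (ice_max_conc <= 0 || ice_max_conc > 100)
    stop("invalid config: ice_max_conc must be in (0, 100]")
  if (noise_sd < 0) stop("invalid config: noise_sd must be >= 0")
  structure(cfg, class = "env_config")
}

KM_PER_DEG_LAT <- 111.195  # spherical Earth, R = 6371 km

#' Build a synthetic environment stack
#'
#' Produces daily ice-concentration grids with a monotone north-to-south
#' gradient whose 10% level moves south at the configured rate, a bathymetry
#' grid with a shallow shelf and a slope crossing 1000 m, and a land mask
#' with a derived coastline. Deterministic given `cfg$seed`.
#'
#' @param cfg An [env_config()].
#' @return An `env_stack`: list with cell-centre coordinate vectors
#'   `lon`/`lat`, lower-left corner `lon0`/`lat0`, `cell`, `dates`,
#'   3-D array `ice` (lon x lat x day, % in \[0,100\], NA on land), matrix
#'   `depth` (m positive down, NA on land), logical matrix `land`.
#' @export
make_environment <- function(cfg) {
  stopifnot(inherits(cfg, "env_config"))
  lon0 <- cfg$lon_range[1]; lat0 <- cfg$lat_range[1]
  nlon <- floor((cfg$lon_range[2] - lon0) / cfg$cell + 1e-9)
  nlat <- floor((cfg$lat_range[2] - lat0) / cfg$cell + 1e-9)
  if (nlon * nlat <= 1) stop("invalid config: degenerate extent (<= 1 cell)")
  lon <- lon0 + (seq_len(nlon) - 0.5) * cfg$cell
  lat <- lat0 + (seq_len(nlat) - 0.5) * cfg$cell

  land <- outer(lon, lat, function(x, y) y > cfg$coast_lat | x > cfg$coast_lon)

  sw <- cfg$slope_width_km / KM_PER_DEG_LAT
  # shelf deepens toward the break (0.7x..1.5x the nominal shelf depth)
  # with a gentle longitudinal ripple, then drops through the slope
  lat_n <- cfg$lat_range[2]
  shelf_frac <- pmin(1, pmax(0, (lat_n - lat) / (lat_n - cfg$slope_lat)))
  depth_profile <- cfg$shelf_depth_m * (0.7 + 0.8 * shelf_frac) +
    (cfg$max_depth_m - cfg$shelf_depth_m) *
    stats::plogis((cfg$slope_lat - lat) / sw)
  ripple <- 0.15 * cfg$shelf_depth_m * sin(2 * pi * (lon - lon0) / 10)
  depth <- outer(ripple, depth_profile, `+`)
  depth[land] <- NA_real_

  w <- cfg$ice_gradient_km / KM_PER_DEG_LAT
  # place the logistic midpoint so that the 10% level starts at the
  # configured latitude: conc = max * plogis((lat - mid)/w)
  mid0 <- cfg$ice_edge_start_lat - w * stats::qlogis(10 / cfg$ice_max_conc)
  dates <- cfg$start_date + seq_len(cfg$n_days) - 1L
  ice <- array(NA_real_, dim = c(nlon, nlat, cfg$n_days))
  set.seed(cfg$seed)
  for (d in seq_len(cfg$n_days)) {
    mid <- mid0 - cfg$ice_advance_km_day * (d - 1L) / KM_PER_DEG_LAT
    prof <- cfg$ice_max_conc * stats::plogis((lat - mid) / w)
    layer <- matrix(rep(prof, each = nlon), nlon, nlat)
    if (cfg$noise_sd > 0)
      layer <- layer + matrix(stats::rnorm(nlon * nlat, 0, cfg$noise_sd), nlon, nlat)
    layer <- pmin(pmax(layer, 0), 100)
    layer[layer < 1] <- 0  # open water reports 0, as microwave products do
    layer[land] <- NA_real_
    ice[, , d] <- layer
  }

  structure(list(
    lon = lon, lat = lat, lon0 = lon0, lat0 = lat0, cell = cfg$cell,
    dates = dates, ice = ice, depth = depth, land = land, cfg = cfg
  ), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf(
    "env_stack: %d x %d cells (%.3g deg), %d daily ice layers (%s .. %s)\n",
    length(x$lon), length(x$lat), x$cell, length(x$dates),
    format(min(x$dates)), format(max(x$dates))
  ))
  cat(sprintf("  land fraction: %.2f\n", mean(x$land)))
  invisible(x)
}

# Cell indices for points; errors when a point is outside the extent.
env_cell_index <- function(env, lon, lat) {
  ix <- floor((lon - env$lon0) / env$cell) + 1L
  iy <- floor((lat - env$lat0) / env$cell) + 1L
  # points exactly on the upper edge of the extent belong to the last cell
  ix[lon == env$lon0 + length(env$lon) * env$cell] <- length(env$lon)
  iy[lat == env$lat0 + length(env$lat) * env$cell] <- length(env$lat)
  bad <- ix < 1L | ix > length(env$lon) | iy < 1L | iy > length(env$lat)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("point outside grid extent: lon=%.4f lat=%.4f", lon[i], lat[i]))
  }
  cbind(ix, iy)
}

env_day_index <- function(env, date) {
  d <- match(as.Date(date), env$dates)
  if (anyNA(d))
    stop(sprintf("missing layer: no ice grid for date %s",
                 format(as.Date(date)[which(is.na(d))[1]])))
  d
}

#' Sample a raster layer at point locations
#'
#' Returns the value of the containing grid cell (no interpolation), matching
#' how covariates are read "directly from the raster cell". Land cells carry
#' NA for `ice` and `depth`.
#'
#' @param env An `env_stack`.
#' @param lon,lat Point coordinates (vectorized).
#' @param layer `"ice"`, `"depth"` or `"land"`.
#' @param date Required for the dated `ice` layer (scalar or vector).
#' @return Numeric (or logical for `"land"`) vector of cell values.
#' @export
sample_raster <- function(env, lon, lat, layer = c("ice", "depth", "land"),
                          date = NULL) {
  layer <- match.arg(layer)
  idx <- env_cell_index(env, lon, lat)
  if (layer == "land") return(env$land[idx])
  if (layer == "depth") return(env$depth[idx])
  if (is.null(date)) stop("missing layer: ice sampling requires a date")
  d <- env_day_index(env, date)
  if (length(d) == 1L) d <- rep(d, nrow(idx))
  env$ice[cbind(idx, d)]
}

#' Is a point on land?
#'
#' @inheritParams sample_raster
#' @return Logical vector.
#' @export
on_land <- function(env, lon, lat) {
  sample_raster(env, lon, lat, layer = "land")
}
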