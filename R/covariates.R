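# Habitat covariates for case and control locations.
#
# Per location: distance to coast, seafloor depth, distance to the 1000 m
# isobath (shelf break), distance to the same-day ice edge (10% contour,
# speckle < 50 km removed), ice concentration at the cell, and the binary
# sea_ice indicator. Ice layers are resolved by UTC calendar date with no
# temporal interpolation; case and control rows for the same animal and
# timestamp therefore share layers, preserving the temporal matching.

# Cache of static contours and per-day ice edges for one env stack.
covariate_context <- function(env, edge_level = 10, edge_min_km = 50,
                              isobath_m = 1000) {
  ctx <- new.env(parent = emptyenv())
  ctx$coast <- coastline_contours(env)
  ctx$isobath <- isobath_contours(env, isobath_m)
  ctx$edges <- list()
  ctx$edge_level <- edge_level
  ctx$edge_min_km <- edge_min_km
  ctx
}

get_ice_edge <- function(env, ctx, date) {
  key <- format(as.Date(date))
  if (is.null(ctx$edges[[key]]))
    ctx$edges[[key]] <- ice_edge_contours(env, date, ctx$edge_level,
                                          ctx$edge_min_km)
  ctx$edges[[key]]
}

# Covariates for a vector of same-day points. Returns natural-scale columns
# understood by rsf_design_matrix()/rsf_score().
point_covariates <- function(env, lon, lat, date, sex, ctx = NULL,
                             ice_threshold = 0) {
  if (is.null(ctx)) ctx <- covariate_context(env)
  edge <- get_ice_edge(env, ctx, date)
  ice <- sample_raster(env, lon, lat, "ice", date = date)
  data.frame(
    sex = rep_len(sex, length(lon)),
    d2coast = distance_to_lines(lon, lat, ctx$coast),
    depth_m = sample_raster(env, lon, lat, "depth"),
    d21kiso = distance_to_lines(lon, lat, ctx$isobath),
    d2ice = distance_to_lines(lon, lat, edge),
    ice_conc = ice,
    sea_ice = ifelse(ice > ice_threshold, "yes", "no"),
    stringsAsFactors = FALSE
  )
}

#' Build the case-control covariate table
#'
#' One row per location per track: replicate 0 holds the observed (case)
#' locations, replicates 1..n the simulated control tracks. Distance
#' covariates use the same-day ice edge and the static isobath/coastline;
#' square-root and quadratic columns are appended. Rows with any missing
#' covariate (e.g. a day whose grid has no ice edge) are flagged
#' `complete = FALSE` and skipped by the fitting code; their count is
#' recorded in the `n_incomplete` attribute.
#'
#' @param cases Named list of observed `seal_track`s (each with a `sex`
#'   attribute).
#' @param controls List of simulated control tracks (data frames with
#'   `animal_id`, `replicate`, `timestamp`, `lon`, `lat`), e.g. from
#'   [simulate_ensemble()].
#' @param env An `env_stack` covering all dates and positions.
#' @param ice_threshold Concentration above which `sea_ice = "yes"`
#'   (default 0).
#' @param edge_level,edge_min_km Ice-edge contour level (%) and minimum
#'   retained contour length (km).
#' @param isobath_m Shelf-break isobath depth (m).
#' @param max_missing_fraction Error out when more than this fraction of
#'   rows lack a resolvable ice layer.
#' @return Data frame of covariate rows with columns `animal_id`,
#'   `replicate`, `timestamp`, `case`, `sex`, `lon`, `lat`, the six natural
#'   covariates, transforms `sqrt_*` / `ice_conc2`, and `complete`.
#' @export
build_covariate_table <- function(cases, controls, env, ice_threshold = 0,
                                  edge_level = 10, edge_min_km = 50,
                                  isobath_m = 1000,
                                  max_missing_fraction = 0.05) {
  sexes <- vapply(cases, function(tr) attr(tr, "sex") %||% "F", character(1))
  names(sexes) <- vapply(cases, function(tr) tr$animal_id[1], character(1))
  case_df <- do.call(rbind, lapply(cases, function(tr) {
    data.frame(animal_id = tr$animal_id, replicate = 0L,
               timestamp = tr$timestamp, lon = tr$lon, lat = tr$lat,
               stringsAsFactors = FALSE)
  }))
  ctl_df <- do.call(rbind, lapply(controls, function(tr) {
    data.frame(animal_id = tr$animal_id, replicate = as.integer(tr$replicate),
               timestamp = tr$timestamp, lon = tr$lon, lat = tr$lat,
               stringsAsFactors = FALSE)
  }))
  all_df <- rbind(case_df, ctl_df)
  rownames(all_df) <- NULL
  all_df$case <- as.integer(all_df$replicate == 0L)
  all_df$sex <- unname(sexes[all_df$animal_id])
  all_df$date <- as.Date(all_df$timestamp, tz = "UTC")

  covered <- all_df$date %in% env$dates
  if (mean(!covered) > max_missing_fraction)
    stop(sprintf("coverage error: %.1f%% of rows have no ice layer",
                 100 * mean(!covered)))

  ctx <- covariate_context(env, edge_level, edge_min_km, isobath_m)
  cov_cols <- c("d2coast", "depth_m", "d21kiso", "d2ice", "ice_conc",
                "sea_ice")
  for (cc in cov_cols) all_df[[cc]] <- NA
  all_df$sea_ice <- NA_character_
  for (dch in unique(format(all_df$date[covered]))) {
    d <- as.Date(dch)
    i <- which(covered & all_df$date == d)
    pc <- point_covariates(env, all_df$lon[i], all_df$lat[i], d,
                           sex = all_df$sex[i], ctx = ctx,
                           ice_threshold = ice_threshold)
    for (cc in cov_cols) all_df[[cc]][i] <- pc[[cc]]
  }
  all_df$sqrt_d2coast <- sqrt(all_df$d2coast)
  all_df$sqrt_depth_m <- sqrt(all_df$depth_m)
  all_df$sqrt_d21kiso <- sqrt(all_df$d21kiso)
  all_df$sqrt_d2ice <- sqrt(all_df$d2ice)
  all_df$ice_conc2 <- all_df$ice_conc^2
  all_df$complete <- stats::complete.cases(
    all_df[, c(cov_cols, "sex")])
  attr(all_df, "n_incomplete") <- sum(!all_df$complete)
  all_df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
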