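# Synthetic seal tracks with known habitat selection.
#
# Selection is operationalized as a biased random walk: at each step M
# candidate endpoints are proposed from the movement kernel and one is
# chosen with probability proportional to exp(truth . x(endpoint)), where x
# are the same transformed covariates the inference module uses. With truth
# all zero this collapses to the unweighted kernel; M couples the strength
# of realized selection to the truth coefficients (M = 20 by default).

#' Movement kernel parameters for the synthetic generator
#'
#' A drifting correlated walk: each bearing pulls toward the drift heading
#' (south by default, emulating seals following the advancing ice) while
#' retaining persistence on the deviation from it; speeds are lognormal and
#' capped; fix intervals are gamma-distributed (irregular, as Argos
#' sampling is).
#'
#' @param drift_bearing Mean heading, degrees true (180 = south).
#' @param persistence Fraction of the previous deviation from drift kept at
#'   the next step, in \[0, 1).
#' @param bearing_sd Innovation SD on bearings, degrees.
#' @param speed_meanlog,speed_sdlog Lognormal swim-speed parameters (km/h).
#' @param max_speed_kmh Speed cap, km/h.
#' @param mean_gap_h Mean inter-fix interval, hours.
#' @param gap_shape Gamma shape of the interval distribution (mean fixed at
#'   `mean_gap_h`; larger = more regular).
#' @return A list of class `movement_params`.
#' @export
movement_params <- function(drift_bearing = 180, persistence = 0.6,
                            bearing_sd = 40, speed_meanlog = log(1.2),
                            speed_sdlog = 0.5, max_speed_kmh = 8,
                            mean_gap_h = 6, gap_shape = 4) {
  stopifnot(persistence >= 0, persistence < 1, bearing_sd > 0,
            max_speed_kmh > 0, mean_gap_h > 0, gap_shape > 0)
  structure(list(drift_bearing = drift_bearing, persistence = persistence,
                 bearing_sd = bearing_sd, speed_meanlog = speed_meanlog,
                 speed_sdlog = speed_sdlog, max_speed_kmh = max_speed_kmh,
                 mean_gap_h = mean_gap_h, gap_shape = gap_shape),
            class = "movement_params")
}

# signed angular difference a - b wrapped to (-180, 180]
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

draw_kernel_bearing <- function(prev_bearing, move, n = 1) {
  dev <- ang_diff(prev_bearing, move$drift_bearing)
  (move$drift_bearing + move$persistence * dev +
     stats::rnorm(n, 0, move$bearing_sd)) %% 360
}

draw_kernel_speed <- function(move, n = 1) {
  pmin(stats::rlnorm(n, move$speed_meanlog, move$speed_sdlog),
       move$max_speed_kmh)
}

# softmax choice among candidates; isolated so its frequencies can be
# checked against exp-weighted probabilities directly
softmax_choose <- function(scores) {
  w <- exp(scores - max(scores))
  sample.int(length(w), 1L, prob = w)
}

# deterministic per-(animal, replicate) seed fan-out, kept below 2^31
derive_seed <- function(master, a, r = 0L) {
  as.integer((as.double(master) * 48271 + a * 9973 + r * 101 + 7) %% 2147483647)
}

#' Simulate tracks with known selection
#'
#' Each animal starts near the northern coast of the synthetic shelf and
#' walks for `n_steps` irregular intervals; every step picks among `m`
#' kernel candidates with probability proportional to
#' `exp(truth . x(endpoint))`. Candidates on land (or off-grid) are
#' redrawn; after `retries` rounds a step-generation error names the animal
#' and time.
#'
#' @param env An `env_stack`.
#' @param truth Named coefficient vector over the RSF vocabulary (see
#'   [rsf_single_effects()]); empty or all-zero means no selection.
#' @param move A [movement_params()].
#' @param n_animals Number of animals.
#' @param n_steps Steps per animal.
#' @param m Candidates per step (default 20).
#' @param retries Land-redraw rounds per candidate before failing.
#' @param seed Master RNG seed.
#' @param diagnostics Keep per-step candidate covariates (for generator
#'   verification).
#' @return Named list of `seal_track` data frames (columns `animal_id`,
#'   `timestamp` (UTC), `lon`, `lat`; attribute `sex`). With
#'   `diagnostics = TRUE` each track has attribute `candidates`, a data
#'   frame of all candidate endpoints' covariates with `chosen` flags.
#' @export
make_selective_tracks <- function(env, truth = numeric(0),
                                  move = movement_params(),
                                  n_animals = 5, n_steps = 60, m = 20,
                                  retries = 50, seed = 1L,
                                  diagnostics = FALSE) {
  stopifnot(inherits(env, "env_stack"), m >= 1)
  ctx <- covariate_context(env)
  cfg <- env$cfg
  tracks <- list()
  for (a in seq_len(n_animals)) {
    set.seed(derive_seed(seed, a))
    sex <- sample(c("F", "M"), 1)
    id <- sprintf("sim%02d", a)
    # start at sea just south of the coast, west of the eastern land edge
    lon_hi <- min(cfg$coast_lon, cfg$lon_range[2])
    repeat {
      start_lat <- min(cfg$coast_lat, cfg$lat_range[2]) -
        stats::runif(1, 0.5, 1.5)
      start_lon <- stats::runif(1, cfg$lon_range[1] + 2, lon_hi - 2)
      if (!env$land[env_cell_index(env, start_lon, start_lat)]) break
    }
    gaps <- stats::rgamma(n_steps, shape = move$gap_shape,
                          rate = move$gap_shape / move$mean_gap_h)
    ts <- as.POSIXct(paste(env$dates[1], "00:00:00"), tz = "UTC") +
      round(cumsum(c(stats::runif(1, 0, 6 * 3600), gaps * 3600)))
    lon <- numeric(n_steps + 1L); lat <- numeric(n_steps + 1L)
    lon[1] <- start_lon; lat[1] <- start_lat
    prev_b <- move$drift_bearing
    diag_rows <- if (diagnostics) vector("list", n_steps) else NULL
    for (s in seq_len(n_steps)) {
      elapsed_h <- gaps[s]
      day <- as.Date(ts[s + 1L], tz = "UTC")
      cand_lon <- numeric(m); cand_lat <- numeric(m); cand_b <- numeric(m)
      for (j in seq_len(m)) {
        ok <- FALSE
        for (r in seq_len(retries)) {
          b <- draw_kernel_bearing(prev_b, move)
          v <- draw_kernel_speed(move)
          dest <- gc_destination(lon[s], lat[s], b, v * elapsed_h)
          if (in_extent(env, dest$lon, dest$lat) &&
              !env$land[env_cell_index(env, dest$lon, dest$lat)]) {
            cand_lon[j] <- dest$lon; cand_lat[j] <- dest$lat; cand_b[j] <- b
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop(sprintf(
            "step generation failed: all candidates on land for animal %s at %s",
            id, format(ts[s + 1L], tz = "UTC")))
      }
      active <- length(truth) > 0 && any(truth != 0)
      x <- if (active || diagnostics)
        point_covariates(env, cand_lon, cand_lat, day, sex = sex, ctx = ctx)
      scores <- if (active) rsf_score(truth, x) else rep(0, m)
      pick <- softmax_choose(scores)
      lon[s + 1L] <- cand_lon[pick]; lat[s + 1L] <- cand_lat[pick]
      prev_b <- cand_b[pick]
      if (diagnostics) {
        x$step <- s
        x$chosen <- seq_len(m) == pick
        diag_rows[[s]] <- x
      }
    }
    tr <- data.frame(animal_id = id, timestamp = ts, lon = lon, lat = lat,
                     lq = "3", stringsAsFactors = FALSE)
    attr(tr, "sex") <- sex
    class(tr) <- c("seal_track", "data.frame")
    if (diagnostics) attr(tr, "candidates") <- do.call(rbind, diag_rows)
    tracks[[id]] <- tr
  }
  tracks
}

in_extent <- function(env, lon, lat) {
  lon >= env$lon0 & lon <= env$lon0 + length(env$lon) * env$cell &
    lat >= env$lat0 & lat <= env$lat0 + length(env$lat) * env$cell
}

#' Default Argos location-quality error scales
#'
#' Isotropic per-class positional error SDs in km. The Argos system does
#' not publish exact magnitudes for these classes; these are conventional
#' order-of-magnitude values (classes 3..0, A, B).
#'
#' @return Named numeric vector (km).
#' @export
argos_class_sd <- function() {
  c("3" = 0.25, "2" = 0.5, "1" = 1.5, "0" = 5, "A" = 8, "B" = 15)
}

#' Add Argos-style observation error to a track
#'
#' Assigns each location a quality class drawn from `class_mix` and
#' perturbs the position with isotropic Gaussian noise at the class SD. The
#' true coordinates are retained as `lon_true`/`lat_true` for diagnostics.
#'
#' @param track A `seal_track`.
#' @param class_mix Named proportions over classes 3,2,1,0,A,B (must sum
#'   to 1).
#' @param class_sd Named per-class SD in km (default [argos_class_sd()]).
#' @param seed RNG seed.
#' @return The track with `lq` reassigned, coordinates perturbed, and
#'   truth columns appended.
#' @export
add_argos_error <- function(track,
                            class_mix = c("3" = 0.05, "2" = 0.08, "1" = 0.12,
                                          "0" = 0.15, "A" = 0.25, "B" = 0.35),
                            class_sd = argos_class_sd(), seed = 1L) {
  if (abs(sum(class_mix) - 1) > 1e-8)
    stop("invalid config: class_mix proportions must sum to 1")
  if (any(class_sd < 0)) stop("invalid config: negative class sd")
  set.seed(seed)
  n <- nrow(track)
  lq <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
  sd_km <- unname(class_sd[lq])
  east_km <- stats::rnorm(n, 0, sd_km)
  north_km <- stats::rnorm(n, 0, sd_km)
  out <- track
  out$lon_true <- track$lon
  out$lat_true <- track$lat
  out$lq <- lq
  out$lat <- track$lat + north_km / KM_PER_DEG_LAT
  out$lon <- normalize_lon(
    track$lon + east_km / (KM_PER_DEG_LAT * cos(deg2rad(track$lat))))
  out
}

#' Simulate independent case-control covariate rows
#'
#' A row-level stand-in for the full track pipeline, used for calibration
#' and recovery checks where independence between rows is required. Control
#' rows are i.i.d. draws from an availability distribution; case rows are
#' importance-resampled from availability with weight
#' `exp(truth . x)`, so the case-vs-control logistic slope on each term
#' equals the truth coefficient. Cases are drawn once and shared by every
#' replicate, mirroring the matched design (observed track fixed, 20
#' simulated control sets).
#'
#' @param truth Named coefficient vector over the RSF vocabulary.
#' @param n_case Case rows (shared across replicates).
#' @param n_rep Number of control replicates.
#' @param n_control Control rows per replicate (default `n_case`).
#' @param seed RNG seed.
#' @param availability Function `n -> data.frame` of covariate rows;
#'   default [default_availability()].
#' @param pool_factor Availability pool size for case resampling, as a
#'   multiple of `n_case`.
#' @return Covariate table with `replicate` (0 = case) and `case` columns.
#' @export
simulate_rsf_rows <- function(truth, n_case, n_rep, n_control = n_case,
                              seed = 1L, availability = default_availability,
                              pool_factor = 10) {
  set.seed(as.integer(seed))
  pool <- availability(max(2L, as.integer(pool_factor * n_case)))
  w <- exp(rsf_score(truth, pool) - max(rsf_score(truth, pool)))
  cases <- pool[sample.int(nrow(pool), n_case, replace = TRUE, prob = w), ,
                drop = FALSE]
  cases$replicate <- 0L
  cases$case <- 1L
  ctl <- lapply(seq_len(n_rep), function(r) {
    d <- availability(n_control)
    d$replicate <- r
    d$case <- 0L
    d
  })
  out <- do.call(rbind, c(list(cases), ctl))
  rownames(out) <- NULL
  out
}

#' Default availability distribution for row-level simulation
#'
#' Marginals chosen to look like a shelf sea in freeze-up: distances in the
#' tens-to-hundreds of km, shelf depths, a mixed open-water/ice
#' concentration field.
#'
#' @param n Number of rows.
#' @return Covariate data frame (natural scales).
#' @export
default_availability <- function(n) {
  ice_conc <- ifelse(stats::runif(n) < 0.25, 0,
                     100 * stats::rbeta(n, 1.2, 0.8))
  data.frame(
    sex = sample(c("F", "M"), n, replace = TRUE),
    d2coast = stats::rgamma(n, shape = 2, scale = 60),
    depth_m = 20 + stats::rgamma(n, shape = 2, scale = 40),
    d21kiso = stats::rgamma(n, shape = 2, scale = 150),
    d2ice = abs(stats::rnorm(n, 0, 80)),
    ice_conc = ice_conc,
    sea_ice = ifelse(ice_conc > 0, "yes", "no"),
    stringsAsFactors = FALSE
  )
}
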