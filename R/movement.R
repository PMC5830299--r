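# Null movement model: correlated random walk on binned absolute bearings
# with a variance-stabilized speed distribution, fitted to the pooled steps
# of all included animals and used to simulate temporally matched control
# tracks.
#
# Bearings are first-order Markov on 10-degree bins (any directional drift
# in the data, e.g. the southerly push of animals following advancing ice,
# is inherited by the simulations rather than hard-coded). Speeds are capped
# and modelled on a fourth-root scale: Argos positional error inflates
# apparent speeds over short intervals and skews the raw distribution badly,
# and the fourth root is a standard variance-stabilizer for such
# heavy-tailed positive rates. Steps spanning more than `max_gap_h` are
# excluded from fitting (they say little about swimming speed) but the
# matched timestamps are still simulated as a single draw.

#' Decompose a track into movement steps
#'
#' Sequential movement vectors: elapsed time, initial great-circle bearing,
#' great-circle length, and speed = length / elapsed. Coincident positions
#' give length 0 and bearing 0 by convention.
#'
#' @param track A `seal_track` (>= 2 locations, strictly increasing
#'   timestamps).
#' @return Data frame of n-1 steps: `animal_id`, `t0`, `t1`, `elapsed_h`,
#'   `bearing`, `length_km`, `speed_kmh`.
#' @export
decompose_steps <- function(track) {
  n <- nrow(track)
  if (n < 2) stop("track must have at least 2 locations")
  dt <- as.numeric(difftime(track$timestamp[-1], track$timestamp[-n],
                            units = "hours"))
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  len <- gc_distance_km(track$lon[-n], track$lat[-n],
                        track$lon[-1], track$lat[-1])
  brg <- gc_bearing_deg(track$lon[-n], track$lat[-n],
                        track$lon[-1], track$lat[-1])
  data.frame(animal_id = track$animal_id[-n], t0 = track$timestamp[-n],
             t1 = track$timestamp[-1], elapsed_h = dt, bearing = brg,
             length_km = len, speed_kmh = len / dt,
             stringsAsFactors = FALSE)
}

#' Fit the null correlated-random-walk model
#'
#' Estimates a first-order transition table over binned absolute bearings
#' (additive smoothing so no row is degenerate) and a marginal -- or
#' optionally previous-bin-conditioned -- distribution of capped,
#' fourth-root-transformed speeds, pooled across animals.
#'
#' @param steps Pooled steps from [decompose_steps()] (all included
#'   animals).
#' @param n_bearing_bins Number of bearing bins (default 36 x 10 degrees).
#' @param n_speed_bins Number of speed bins on the transformed scale.
#' @param max_speed_kmh Speed cap before transformation (km/h).
#' @param max_gap_h Steps longer than this are excluded from fitting.
#' @param min_steps Minimum usable steps.
#' @param smooth Additive (Laplace) smoothing count per cell.
#' @param condition_speed Condition the speed distribution on the previous
#'   speed bin (full bivariate transition) instead of the marginal.
#' @return A `crw_model`: bin edges, transition/marginal tables, transform
#'   spec, fit metadata.
#' @export
fit_movement_model <- function(steps, n_bearing_bins = 36, n_speed_bins = 20,
                               max_speed_kmh = 8, max_gap_h = 72,
                               min_steps = 100, smooth = 0.5,
                               condition_speed = FALSE) {
  use <- steps[steps$elapsed_h <= max_gap_h, , drop = FALSE]
  if (nrow(use) < min_steps)
    stop(sprintf("insufficient data: %d usable steps < %d required",
                 nrow(use), min_steps))
  if (all(use$speed_kmh == 0)) stop("degenerate data: all speeds are zero")

  b_edges <- seq(0, 360, length.out = n_bearing_bins + 1L)
  speed <- pmin(use$speed_kmh, max_speed_kmh)
  ts_speed <- speed^(1 / 4)
  s_edges <- seq(0, max_speed_kmh^(1 / 4), length.out = n_speed_bins + 1L)

  b_bin <- findInterval(use$bearing %% 360, b_edges,
                        rightmost.closed = TRUE, all.inside = TRUE)
  s_bin <- findInterval(ts_speed, s_edges,
                        rightmost.closed = TRUE, all.inside = TRUE)

  # transitions between consecutive steps of the same animal
  same <- use$animal_id[-nrow(use)] == use$animal_id[-1]
  from_b <- b_bin[-nrow(use)][same]; to_b <- b_bin[-1][same]
  b_trans <- matrix(smooth, n_bearing_bins, n_bearing_bins)
  for (k in seq_along(from_b))
    b_trans[from_b[k], to_b[k]] <- b_trans[from_b[k], to_b[k]] + 1
  b_trans <- b_trans / rowSums(b_trans)
  b_marg <- tabulate(b_bin, n_bearing_bins) + smooth
  b_marg <- b_marg / sum(b_marg)

  s_marg <- tabulate(s_bin, n_speed_bins) + smooth
  s_marg <- s_marg / sum(s_marg)
  s_trans <- NULL
  if (condition_speed) {
    from_s <- s_bin[-nrow(use)][same]; to_s <- s_bin[-1][same]
    s_trans <- matrix(smooth, n_speed_bins, n_speed_bins)
    for (k in seq_along(from_s))
      s_trans[from_s[k], to_s[k]] <- s_trans[from_s[k], to_s[k]] + 1
    s_trans <- s_trans / rowSums(s_trans)
  }

  structure(list(
    bearing_edges = b_edges, bearing_trans = b_trans, bearing_marg = b_marg,
    speed_edges = s_edges, speed_marg = s_marg, speed_trans = s_trans,
    transform = list(name = "fourthroot", power = 1 / 4,
                     max_speed_kmh = max_speed_kmh),
    meta = list(n_steps = nrow(use), n_excluded_gap = nrow(steps) - nrow(use),
                n_animals = length(unique(use$animal_id)),
                max_gap_h = max_gap_h, smooth = smooth,
                condition_speed = condition_speed)
  ), class = "crw_model")
}

#' @export
print.crw_model <- function(x, ...) {
  cat(sprintf(
    "crw_model: %d bearing bins (Markov), %d speed bins (%s), %d steps from %d animals\n",
    length(x$bearing_edges) - 1L, length(x$speed_edges) - 1L,
    if (is.null(x$speed_trans)) "marginal" else "Markov",
    x$meta$n_steps, x$meta$n_animals))
  invisible(x)
}

# one (bearing, speed) draw; prev_b/prev_s are bin indices or NA
draw_model_step <- function(model, prev_b = NA, prev_s = NA) {
  nb <- length(model$bearing_marg)
  pb <- if (is.na(prev_b)) model$bearing_marg else model$bearing_trans[prev_b, ]
  b_bin <- sample.int(nb, 1L, prob = pb)
  bearing <- stats::runif(1, model$bearing_edges[b_bin],
                          model$bearing_edges[b_bin + 1L])
  ns <- length(model$speed_marg)
  ps <- if (is.null(model$speed_trans) || is.na(prev_s)) model$speed_marg
        else model$speed_trans[prev_s, ]
  s_bin <- sample.int(ns, 1L, prob = ps)
  ts <- stats::runif(1, model$speed_edges[s_bin], model$speed_edges[s_bin + 1L])
  list(bearing = bearing, speed = ts^(1 / model$transform$power),
       b_bin = b_bin, s_bin = s_bin)
}

#' Simulate one temporally matched control track
#'
#' Starts at the template's first observed position and, for each observed
#' inter-fix interval, draws a bearing (conditioned on the previous bearing
#' bin) and a speed from the fitted model, advancing along the geodesic by
#' speed x elapsed. Draws landing on land (or off-grid) are redrawn; after
#' `retries` failures a simulation-stuck error reports the context. The
#' output timestamps are exactly the template's.
#'
#' @param model A `crw_model`.
#' @param template The observed `seal_track`.
#' @param env An `env_stack` (land mask and extent).
#' @param replicate Replicate index (recorded, and folded into the seed).
#' @param seed Master seed; the draw stream is `(seed, animal, replicate)`
#'   specific.
#' @param retries Redraw budget per interval.
#' @return A `sim_track` data frame: `animal_id`, `replicate`, `timestamp`,
#'   `lon`, `lat`.
#' @export
simulate_track <- function(model, template, env, replicate = 1L, seed = 1L,
                           retries = 50) {
  n <- nrow(template)
  if (n < 2) stop("template must have at least 2 locations")
  a_key <- sum(utf8ToInt(template$animal_id[1]))
  set.seed(derive_seed(seed, a_key, replicate))
  lon <- numeric(n); lat <- numeric(n)
  lon[1] <- template$lon[1]; lat[1] <- template$lat[1]
  dt <- as.numeric(difftime(template$timestamp[-1], template$timestamp[-n],
                            units = "hours"))
  prev_b <- NA; prev_s <- NA
  for (i in seq_len(n - 1L)) {
    placed <- FALSE
    for (r in seq_len(retries)) {
      d <- draw_model_step(model, prev_b, prev_s)
      dest <- gc_destination(lon[i], lat[i], d$bearing, d$speed * dt[i])
      if (in_extent(env, dest$lon, dest$lat) &&
          !env$land[env_cell_index(env, dest$lon, dest$lat)]) {
        lon[i + 1L] <- dest$lon; lat[i + 1L] <- dest$lat
        prev_b <- d$b_bin; prev_s <- d$s_bin
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf(
        "simulation stuck: %d redraws on land for %s replicate %d at %s",
        retries, template$animal_id[1], replicate,
        format(template$timestamp[i + 1L], tz = "UTC")))
  }
  out <- data.frame(animal_id = template$animal_id[1],
                    replicate = as.integer(replicate),
                    timestamp = template$timestamp, lon = lon, lat = lat,
                    stringsAsFactors = FALSE)
  class(out) <- c("sim_track", "data.frame")
  out
}

#' Simulate the full control ensemble
#'
#' `n_rep` temporally matched control tracks per template (20 by default,
#' giving 340 tracks for 17 templates), with replicate-indexed seeds.
#'
#' @param model A `crw_model`.
#' @param tracks Named list of observed `seal_track` templates.
#' @param env An `env_stack`.
#' @param n_rep Replicates per template.
#' @param seed Master seed.
#' @param retries Redraw budget per interval.
#' @return Flat list of `sim_track`s, named `<animal>.<replicate>`.
#' @export
simulate_ensemble <- function(model, tracks, env, n_rep = 20, seed = 1L,
                              retries = 50) {
  out <- list()
  for (tr in tracks) {
    for (r in seq_len(n_rep)) {
      s <- simulate_track(model, tr, env, replicate = r, seed = seed,
                          retries = retries)
      out[[paste0(tr$animal_id[1], ".", r)]] <- s
    }
  }
  out
}
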