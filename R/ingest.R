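# Ingest of Argos-style location tables: location-quality filtering, land
# removal against the study-area grid, Bering Sea entry determination, and
# per-animal summaries.
#
# Quality filtering keeps LQ in {3,2,1,0,A} and drops the worst classes
# (B and Z); no speed/turning-angle filter is applied -- LQ filtering plus
# land removal is the whole rule. Land is judged by the cell of the same
# grid that defines the study area.

LQ_LEVELS <- c("3", "2", "1", "0", "A", "B", "Z")
LQ_KEEP <- c("3", "2", "1", "0", "A")

#' Filter raw Argos locations for one animal
#'
#' Drops the worst quality classes (B, Z), removes locations whose grid
#' cell is land, deduplicates shared timestamps (first kept), and sorts by
#' time. Counts removed per reason are attached as the `filter_report`
#' attribute.
#'
#' @param raw Data frame with `animal_id`, `timestamp` (POSIXct UTC),
#'   `lon`, `lat`, `lq` for a single animal.
#' @param env An `env_stack` whose land mask covers the locations; a point
#'   outside the grid extent is an error naming the point.
#' @param sex Optional sex ("F"/"M") recorded as a track attribute.
#' @return A `seal_track` data frame.
#' @export
filter_locations <- function(raw, env, sex = NA_character_) {
  stopifnot(all(c("animal_id", "timestamp", "lon", "lat", "lq") %in%
                  names(raw)))
  if (length(unique(raw$animal_id)) > 1)
    stop("filter_locations expects a single animal; see ingest_tracks()")
  bad_lq <- !(raw$lq %in% LQ_LEVELS)
  if (any(bad_lq))
    stop(sprintf("unknown location quality class '%s'",
                 raw$lq[which(bad_lq)[1]]))
  n0 <- nrow(raw)
  out <- raw[raw$lq %in% LQ_KEEP, , drop = FALSE]
  n_lq <- n0 - nrow(out)
  out$lon <- normalize_lon(out$lon)
  land <- if (nrow(out)) on_land(env, out$lon, out$lat) else logical(0)
  n_land <- sum(land)
  out <- out[!land, , drop = FALSE]
  out <- out[order(out$timestamp), , drop = FALSE]
  dup <- duplicated(out$timestamp)
  n_dup <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- list(n_input = n0, n_lq_removed = n_lq,
                                     n_land_removed = n_land,
                                     n_duplicate_removed = n_dup)
  attr(out, "sex") <- sex
  class(out) <- c("seal_track", "data.frame")
  out
}

#' Ingest and filter a multi-animal location table
#'
#' Splits a raw table by animal, applies [filter_locations()], and attaches
#' sex from a metadata table.
#'
#' @param raw Location data frame (multiple animals).
#' @param metadata Data frame keyed by `animal_id` with a `sex` column.
#' @param env An `env_stack`.
#' @return Named list of `seal_track`s.
#' @export
ingest_tracks <- function(raw, metadata, env) {
  ids <- unique(raw$animal_id)
  out <- lapply(ids, function(id) {
    sex <- if (id %in% metadata$animal_id)
      metadata$sex[match(id, metadata$animal_id)] else NA_character_
    filter_locations(raw[raw$animal_id == id, , drop = FALSE], env, sex = sex)
  })
  names(out) <- ids
  out
}

#' Date of entry into the Bering Sea
#'
#' The entry date is the date of the *last* southward crossing of the
#' boundary parallel (65 deg 45 min N = 65.75 by default) observed in the
#' track: the date of the first location at or south of the boundary whose
#' predecessor was north of it. A track that lies entirely south of the
#' boundary is taken to have entered before tracking began (its first
#' date). `NA` when the track never reaches the boundary's south side.
#'
#' @param track A filtered `seal_track`.
#' @param boundary_lat Boundary latitude, decimal degrees.
#' @return A `Date`, or `NA`.
#' @export
bering_entry_date <- function(track, boundary_lat = 65.75) {
  if (nrow(track) == 0) stop("empty track")
  s <- track$lat <= boundary_lat
  if (all(s)) return(as.Date(track$timestamp[1], tz = "UTC"))
  n <- nrow(track)
  cross <- which(!s[-n] & s[-1]) + 1L  # indices of south-side arrivals
  if (length(cross) == 0) return(as.Date(NA))
  as.Date(track$timestamp[max(cross)], tz = "UTC")
}

# index of the first location of the final southern residence, or NA
last_entry_index <- function(track, boundary_lat = 65.75) {
  s <- track$lat <= boundary_lat
  if (all(s)) return(1L)
  n <- nrow(track)
  cross <- which(!s[-n] & s[-1]) + 1L
  if (length(cross) == 0) return(NA_integer_)
  max(cross)
}

#' Inclusion rule for the selection analysis
#'
#' A track is included iff it entered the Bering Sea (has an entry date)
#' and remained south of the boundary from that entry until its last
#' transmission.
#'
#' @inheritParams bering_entry_date
#' @return List with `include` (logical) and `reason` (character).
#' @export
include_for_rsf <- function(track, boundary_lat = 65.75) {
  if (nrow(track) == 0) stop("empty track")
  k <- last_entry_index(track, boundary_lat)
  if (is.na(k))
    return(list(include = FALSE, reason = "never entered the Bering Sea"))
  lat_after <- track$lat[k:nrow(track)]
  if (any(lat_after > boundary_lat))
    return(list(include = FALSE,
                reason = "left the Bering Sea after entry"))
  list(include = TRUE, reason = sprintf("entered %s and remained",
                                        format(bering_entry_date(track,
                                                                 boundary_lat))))
}

#' Per-animal track summaries
#'
#' Duration (whole days, last minus first transmission date), number of
#' distinct calendar dates with a location, and distinct location-dates on
#' the Bering Sea side of the boundary, plus cohort mean/min/max duration.
#'
#' @param tracks Named list of `seal_track`s.
#' @param boundary_lat Boundary latitude.
#' @return List with `per_animal` (data frame) and `cohort`
#'   (mean/min/max duration).
#' @export
summarize_tracks <- function(tracks, boundary_lat = 65.75) {
  per <- do.call(rbind, lapply(tracks, function(tr) {
    dates <- as.Date(tr$timestamp, tz = "UTC")
    k <- last_entry_index(tr, boundary_lat)
    bering_days <- if (is.na(k)) 0L else
      length(unique(dates[seq(k, nrow(tr))][tr$lat[seq(k, nrow(tr))] <=
                                              boundary_lat]))
    data.frame(animal_id = tr$animal_id[1],
               duration_days = as.integer(max(dates) - min(dates)),
               days_with_location = length(unique(dates)),
               bering_location_days = bering_days,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(per_animal = per,
       cohort = c(mean = mean(per$duration_days),
                  min = min(per$duration_days),
                  max = max(per$duration_days)))
}
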