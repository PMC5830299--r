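# Independent oracles and small fixture builders shared across the suite.
# Everything here is deliberately written without reusing the package's
# internal code paths (brute force, closed forms, linear scans).

# Newton-Raphson maximizer of the exact Bernoulli-logit log-likelihood;
# independent of glm()/glm.fit().
newton_logistic <- function(X, y, tol = 1e-10, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(X, y - p))
    H <- crossprod(X * (p * (1 - p)), X)
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# linear-scan oracle for the last southward boundary crossing
scan_last_south_crossing <- function(lat, dates, boundary) {
  idx <- NA_integer_
  for (i in seq_len(length(lat) - 1)) {
    if (lat[i] > boundary && lat[i + 1] <= boundary) idx <- i + 1L
  }
  if (is.na(idx)) as.Date(NA) else dates[idx]
}

# independent containment check for model-term hierarchy
oracle_contains <- function(a, b) {
  fa <- strsplit(a, ":", fixed = TRUE)[[1]]
  fb <- strsplit(b, ":", fixed = TRUE)[[1]]
  (length(fb) > length(fa) && all(fa %in% fb)) ||
    (a == "ice_conc" && b == "ice_conc^2")
}

# small fast synthetic world shared by several tests
small_env <- function(n_days = 20, advance = 12, noise = 0, seed = 1) {
  make_environment(env_config(
    lon_range = c(-176, -164), lat_range = c(58, 68.5), cell = 0.5,
    n_days = n_days, ice_advance_km_day = advance,
    ice_edge_start_lat = 66, noise_sd = noise, seed = seed
  ))
}

# hand-built track data frame
mk_track <- function(lat, lon = NULL, start = "2005-11-02 00:00:00",
                     gap_h = 6, id = "t1", lq = "3", sex = "F") {
  n <- length(lat)
  if (is.null(lon)) lon <- rep(-170, n)
  tr <- data.frame(
    animal_id = id,
    timestamp = as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * gap_h * 3600,
    lon = lon, lat = lat, lq = rep_len(lq, n),
    stringsAsFactors = FALSE
  )
  attr(tr, "sex") <- sex
  class(tr) <- c("seal_track", "data.frame")
  tr
}

# core columns only, attributes and classes stripped, for content equality
strip_track <- function(x) {
  cols <- intersect(c("animal_id", "timestamp", "lon", "lat", "lq"), names(x))
  out <- as.data.frame(lapply(unclass(x)[cols], identity),
                       stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

expect_track_equal <- function(a, b) {
  expect_equal(a$timestamp, b$timestamp)
  expect_equal(a$lon, b$lon)
  expect_equal(a$lat, b$lat)
}
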