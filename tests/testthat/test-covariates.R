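# Raster sampling, contour extraction/filtering, point-to-line distances,
# and the assembled case-control covariate table.

test_that("raster sampling returns the containing cell, no interpolation", {
  env <- small_env()
  ix <- 8L; iy <- 5L
  stored <- env$ice[ix, iy, 3]
  expect_equal(sample_raster(env, env$lon[ix], env$lat[iy], "ice",
                             date = env$dates[3]), stored)
  # a point just inside the cell's west/south boundary still maps to it
  eps <- 1e-9
  lon_edge <- env$lon0 + (ix - 1) * env$cell
  lat_edge <- env$lat0 + (iy - 1) * env$cell
  expect_equal(sample_raster(env, lon_edge + eps, lat_edge + eps, "ice",
                             date = env$dates[3]), stored)
  # index arithmetic oracle for the cell one west
  expect_equal(sample_raster(env, lon_edge - eps, lat_edge + eps, "ice",
                             date = env$dates[3]), env$ice[ix - 1L, iy, 3])
  expect_error(sample_raster(env, env$lon[1], env$lat[1], "ice",
                             date = as.Date("1999-01-01")), "missing layer")
  expect_error(sample_raster(env, 0, 0, "depth"), "outside grid")
  # land cells are flagged by NA values and the land layer
  land_idx <- which(env$land, arr.ind = TRUE)[1, ]
  expect_true(on_land(env, env$lon[land_idx[1]], env$lat[land_idx[2]]))
  expect_true(is.na(sample_raster(env, env$lon[land_idx[1]],
                                  env$lat[land_idx[2]], "depth")))
})

test_that("short ice-edge contours are eliminated, isobaths keep all", {
  # one long meridional ice tongue and one single-cell speckle whose
  # contour ring is ~44 km, below the 50 km threshold
  lon <- seq(-175, -165, by = 0.1); lat <- seq(58, 66, by = 0.1)
  z <- outer(lon, lat, function(x, y) ifelse(x < -171, 80, 0))
  z[which.min(abs(lon + 166.2)), which.min(abs(lat - 59.2))] <- 80
  cs <- extract_contours(lon, lat, z, level = 10, min_length_km = 50)
  expect_equal(length(cs$lines), 1)
  cs_all <- extract_contours(lon, lat, z, level = 10, min_length_km = 0)
  expect_equal(length(cs_all$lines), 2)
  expect_true(min(cs_all$lengths_km) < 50)

  # uniform 5% field: the 10% level does not exist
  u <- matrix(5, length(lon), length(lat))
  expect_equal(length(extract_contours(lon, lat, u, 10)$lines), 0)
  expect_error(extract_contours(lon, lat, matrix(NA_real_, length(lon),
                                                 length(lat)), 10),
               "2x2")
})

test_that("contour length of a circular patch matches 2*pi*r", {
  lon <- seq(-174, -166, by = 0.2); lat <- seq(58, 62, by = 0.2)
  ctr <- c(-170, 60)
  d <- outer(lon, lat, function(x, y)
    sealrsf::gc_distance_km(x, y, ctr[1], ctr[2]))
  # linear cone: the 10% level is r = 180 km (pmax would drop dim)
  z <- matrix(pmax(0, 100 - 0.5 * d), nrow(d))
  cs <- extract_contours(lon, lat, z, level = 10)
  expect_equal(length(cs$lines), 1)
  expect_equal(cs$lengths_km, 2 * pi * 180, tolerance = 0.05)
})

test_that("point-to-line distance matches closed forms and brute force", {
  # straight meridional edge at -170; offset 1 degree of longitude at 60N
  edge <- structure(list(level = 10,
                         lines = list(list(lon = c(-170, -170),
                                           lat = c(58, 62))),
                         lengths_km = 444.8), class = "contour_set")
  expect_equal(distance_to_lines(-169, 60, edge),
               gc_distance_km(-169, 60, -170, 60), tolerance = 0.01)
  expect_equal(distance_to_lines(-169, 60, edge), 55.6, tolerance = 0.002)
  # a point on a vertex is at distance 0
  expect_equal(distance_to_lines(-170, 58, edge), 0)

  # brute-force minimum over 100 m densified vertices on random points
  set.seed(31)
  plon <- runif(20, -172, -168); plat <- runif(20, 58.5, 61.5)
  fine_lat <- seq(58, 62, by = 0.1 / 111.195)
  brute <- vapply(seq_along(plon), function(i)
    min(gc_distance_km(plon[i], plat[i], -170, fine_lat)), numeric(1))
  expect_equal(distance_to_lines(plon, plat, edge), brute, tolerance = 2e-3)

  # invariance under vertex-order reversal and polyline splitting
  rev_edge <- edge
  rev_edge$lines[[1]] <- lapply(edge$lines[[1]], rev)
  split_edge <- structure(list(level = 10, lines = list(
    list(lon = c(-170, -170), lat = c(58, 60)),
    list(lon = c(-170, -170), lat = c(60, 62))),
    lengths_km = c(222.4, 222.4)), class = "contour_set")
  expect_equal(distance_to_lines(plon, plat, edge),
               distance_to_lines(plon, plat, rev_edge), tolerance = 1e-9)
  # splitting shifts the densified vertex lattice; equal to within spacing
  expect_lt(max(abs(distance_to_lines(plon, plat, edge) -
                      distance_to_lines(plon, plat, split_edge))), 0.05)

  empty <- structure(list(level = 10, lines = list(),
                          lengths_km = numeric(0)), class = "contour_set")
  expect_true(is.na(distance_to_lines(-170, 60, empty)))
})

test_that("d2ice decreases toward the edge on a half-plane field", {
  env <- small_env(n_days = 5, advance = 0)
  edge <- ice_edge_contours(env, env$dates[1], min_length_km = 0)
  lat_grid <- seq(67.2, 66.2, by = -0.2)  # inside the ice, approaching the edge
  d <- distance_to_lines(rep(-170, length(lat_grid)), lat_grid, edge)
  expect_true(all(diff(d) < 0))
})

test_that("the covariate table is matched, partitioned, and self-consistent", {
  env <- small_env(n_days = 25)
  trs <- make_selective_tracks(env, n_animals = 3, n_steps = 40, seed = 41)
  st <- do.call(rbind, lapply(trs, decompose_steps))
  m <- fit_movement_model(st, min_steps = 100)
  ens <- simulate_ensemble(m, trs, env, n_rep = 4, seed = 42)
  rows <- build_covariate_table(trs, ens, env)

  # one row per location per replicate: 3 animals x 41 fixes x (1 + 4)
  expect_equal(nrow(rows), 3 * 41 * 5)
  counts <- table(rows$animal_id, rows$replicate)
  expect_true(all(counts == 41))
  expect_equal(unique(rows$case[rows$replicate == 0]), 1L)
  expect_equal(unique(rows$case[rows$replicate > 0]), 0L)

  # temporal matching survives into the covariates: control timestamps are
  # exactly the case timestamps for each animal
  for (a in unique(rows$animal_id)) {
    tc <- rows$timestamp[rows$animal_id == a & rows$replicate == 0]
    for (r in 1:4)
      expect_identical(rows$timestamp[rows$animal_id == a &
                                        rows$replicate == r], tc)
  }

  # transforms are definitional
  expect_equal(rows$sqrt_d2ice, sqrt(rows$d2ice))
  expect_equal(rows$sqrt_d2coast, sqrt(rows$d2coast))
  expect_equal(rows$ice_conc2, rows$ice_conc^2)
  expect_true(all(rows$d2coast >= 0 & rows$d21kiso >= 0 & rows$d2ice >= 0,
                  na.rm = TRUE))
  expect_true(all(rows$ice_conc >= 0 & rows$ice_conc <= 100, na.rm = TRUE))
  # the sea-ice binary is the concentration threshold
  expect_equal(rows$sea_ice == "yes", rows$ice_conc > 0)
})

test_that("open water 30 km from the edge reads as no-ice at 30 km", {
  # sharp-edged field: 80% ice north of 63N, open water south; the 10%
  # isoline interpolates to 1/8 of a cell north of the southern centre row
  lon <- seq(-175, -165, by = 0.1); lat <- seq(60, 66, by = 0.1)
  z <- outer(lon, lat, function(x, y) ifelse(y >= 63, 80, 0))
  edge <- extract_contours(lon, lat, z, level = 10)
  i_south <- max(which(lat < 63))
  edge_lat <- lat[i_south] + 0.125 * 0.1
  expect_equal(mean(unlist(lapply(edge$lines, `[[`, "lat"))), edge_lat,
               tolerance = 1e-9)
  pt_lat <- edge_lat - 30 / 111.195  # 30 km south of the isoline
  conc <- z[match(-170, lon), findInterval(pt_lat, lat)]
  expect_equal(conc, 0)  # open water cell
  expect_equal(ifelse(conc > 0, "yes", "no"), "no")
  expect_equal(distance_to_lines(-170, pt_lat, edge), 30, tolerance = 0.01)
})
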