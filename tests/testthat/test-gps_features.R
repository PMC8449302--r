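test_that("segment speeds and states follow the haversine closed form", {
  # 0.01 degrees of latitude, 5 minutes apart: 6371 * 0.01 * pi/180 km
  fixes <- tibble::tibble(
    t = as.POSIXct("2019-07-29 08:00:00", tz = "UTC") + c(0, 300),
    lat = c(41.90, 41.91), lon = c(-87.65, -87.65)
  )
  track <- label_stationary(fixes)
  d_exp <- 6371 * 0.01 * pi / 180
  expect_equal(track$seg_km[2], d_exp, tolerance = 1e-6)
  expect_equal(track$speed_kmh[2], d_exp * 12, tolerance = 1e-6)
  expect_equal(track$state, c("transition", "transition"))  # first inherits

  still <- make_track(list(c(41.9, -87.65)), n_each = 20)
  ts <- label_stationary(still)
  expect_true(all(ts$state == "stationary"))
  expect_true(all(ts$speed_kmh == 0))

  expect_warning(one <- label_stationary(still[1, ]), "fewer than 2")
  expect_equal(one$state, "stationary")
})

test_that("total distance matches an independent pairwise-haversine oracle", {
  set.seed(31)
  for (rep in 1:5) {
    pts <- lapply(1:6, function(i) c(41.9 + rnorm(1, 0, 0.02),
                                     -87.65 + rnorm(1, 0, 0.02)))
    track <- label_stationary(make_track(pts, n_each = 3))
    feats <- compute_gps_features(track, cluster_locations(track, seed = 1))
    seg <- which(track$state == "transition" & !track$gap_before &
                   !is.na(track$seg_km))
    seg <- seg[seg > 1]
    oracle <- sum(oracle_haversine_km(track$lat[seg - 1], track$lon[seg - 1],
                                      track$lat[seg], track$lon[seg]))
    expect_equal(feats$total_distance, oracle, tolerance = 1e-9)
  }
})

test_that("location clustering recovers separated blobs and dwell accounting", {
  one <- label_stationary(make_track(list(c(41.9, -87.65)), n_each = 12))
  cl1 <- cluster_locations(one)
  expect_equal(cl1$k, 1L)
  expect_equal(sum(cl1$clusters$dwell_min), 5 * 12)

  set.seed(5)
  two <- label_stationary(make_track(
    list(c(41.90, -87.65), c(41.945, -87.65)), n_each = 10))  # ~5 km apart
  cl2 <- cluster_locations(two, max_cluster_radius_m = 500)
  expect_equal(cl2$k, 2L)
  # stationary fixes partition across the clusters (transition fixes NA)
  stat_assign <- cl2$assignment[two$state == "stationary"]
  expect_true(all(!is.na(stat_assign)))
  expect_setequal(unique(stat_assign), 1:2)

  # three blobs >= 2 km apart: k = 3 and assignment = brute-force nearest
  blobs <- list(c(41.90, -87.65), c(41.92, -87.65), c(41.90, -87.62))
  set.seed(7)
  jit <- function(p) lapply(1:8, function(i) p + rnorm(2, 0, 0.0004))
  track3 <- label_stationary(make_track(do.call(c, lapply(blobs, jit)),
                                        n_each = 1))
  cl3 <- cluster_locations(track3, max_cluster_radius_m = 500)
  expect_equal(cl3$k, 3L)
  stat_idx <- which(track3$state == "stationary")
  for (i in stat_idx) {
    d <- oracle_haversine_km(track3$lat[i], track3$lon[i],
                             cl3$clusters$lat, cl3$clusters$lon)
    expect_equal(cl3$assignment[i], which.min(d))
  }
})

test_that("entropy features obey their closed forms and bounds", {
  # 10 + 11 fixes: the fix arriving at the second blob is a transition fix,
  # leaving 10 stationary fixes (equal dwell) in each cluster
  two <- label_stationary(make_track(
    list(c(41.90, -87.65), c(41.945, -87.65)), n_each = c(10, 11)))
  cl <- cluster_locations(two)
  f <- compute_gps_features(two, cl)
  expect_equal(f$entropy, log(2), tolerance = 1e-10)  # equal dwell
  expect_equal(f$normalized_entropy, 1.0, tolerance = 1e-10)

  one <- label_stationary(make_track(list(c(41.9, -87.65)), n_each = 12))
  f1 <- compute_gps_features(one, cluster_locations(one))
  expect_equal(f1$entropy, 0)
  expect_equal(f1$normalized_entropy, 0)   # defined 0 at k = 1
  expect_equal(f1$total_distance, 0)
  expect_equal(f1$avg_velocity, 0)

  set.seed(11)
  for (rep in 1:5) {
    pts <- lapply(1:4, function(i) c(41.9 + rnorm(1, 0, 0.03),
                                     -87.65 + rnorm(1, 0, 0.03)))
    tr <- label_stationary(make_track(pts, n_each = sample(2:12, 1)))
    cl <- cluster_locations(tr, seed = rep)
    f <- compute_gps_features(tr, cl)
    expect_gte(f$entropy, 0)
    expect_lte(f$entropy, log(max(f$n_clusters, 1)) + 1e-12)
    expect_gte(f$normalized_entropy, 0)
    expect_lte(f$normalized_entropy, 1 + 1e-12)
    expect_gte(f$total_distance, 0)
  }
})

test_that("distance is invariant under translation and zero without transitions", {
  pts <- list(c(41.90, -87.65), c(41.93, -87.61), c(41.88, -87.70))
  tr <- label_stationary(make_track(pts, n_each = 5))
  f <- compute_gps_features(tr, cluster_locations(tr))
  shifted <- make_track(lapply(pts, function(p) p + c(0, 10)), n_each = 5)
  ts <- label_stationary(shifted)
  fs <- compute_gps_features(ts, cluster_locations(ts))
  expect_equal(fs$total_distance, f$total_distance, tolerance = 1e-9)

  no_trans <- tr[tr$state == "stationary", ]
  f0 <- compute_gps_features(label_stationary(no_trans),
                             cluster_locations(label_stationary(no_trans)))
  expect_equal(f0$total_distance, 0)
  expect_equal(f0$avg_velocity, 0)
})

test_that("Lomb energy equals the least-squares sinusoid fit", {
  set.seed(17)
  t <- sort(runif(200, 0, 24 * 14))
  y <- sin(2 * pi * t / 24) + rnorm(200, 0, 0.5)
  for (p in c(23.5, 24, 24.5, 30)) {
    expect_equal(lomb_energy(t, y, p), oracle_sinusoid_energy(t, y, p),
                 tolerance = 1e-9)
  }
})

test_that("circadian movement detects a 24 h location rhythm", {
  set.seed(23)
  n_days <- 14
  t <- seq(0, n_days * 24 - 0.25, by = 0.25)            # 15-min cadence, hours
  lat <- 41.9 + 0.01 * sin(2 * pi * t / 24) + rnorm(length(t), 0, 0.001)
  fixes <- tibble::tibble(
    t = as.POSIXct("2019-07-29", tz = "UTC") + t * 3600,
    lat = lat, lon = -87.65)
  track <- label_stationary(fixes)
  cl <- cluster_locations(track, seed = 1)
  f_rhythmic <- compute_gps_features(track, cl)

  # destroy the rhythm by permuting the coordinate series in time
  shuf <- fixes
  shuf$lat <- sample(lat)
  ts <- label_stationary(shuf)
  f_shuffled <- compute_gps_features(ts, cluster_locations(ts, seed = 1))
  expect_gt(f_rhythmic$circadian_movement, f_shuffled$circadian_movement)
})

test_that("gps features are deterministic and empty input is all missing", {
  set.seed(3)
  pts <- lapply(1:5, function(i) c(41.9 + rnorm(1, 0, 0.02),
                                   -87.65 + rnorm(1, 0, 0.02)))
  tr <- label_stationary(make_track(pts, n_each = 4))
  f1 <- compute_gps_features(tr, cluster_locations(tr, seed = 9))
  f2 <- compute_gps_features(tr, cluster_locations(tr, seed = 9))
  expect_identical(f1, f2)

  empty <- tr[0, ]
  fe <- compute_gps_features(empty, cluster_locations(empty))
  expect_true(all(is.na(fe)))
})
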