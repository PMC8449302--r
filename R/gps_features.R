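# GPS mobility features: stationary labeling, incremental location clustering,
# and the seven window-level movement features (location variance, cluster
# count, entropy, normalized entropy, circadian movement, distance, velocity).

# great-circle distance in km on a 6371-km sphere
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000) / 1000
}

#' Label GPS fixes as stationary or in transition
#'
#' Each fix gets the speed of the segment arriving at it (haversine distance
#' to the previous fix divided by elapsed time); a fix is stationary when that
#' speed is at or below `speed_threshold_kmh`. The first fix inherits the
#' second fix's state. Segments longer than `max_gap_min` are flagged as gaps:
#' no distance is accumulated across them downstream.
#'
#' @param fixes Tibble with columns `t` (POSIXct, strictly increasing), `lat`,
#'   `lon` (degrees WGS84).
#' @param speed_threshold_kmh Stationary/transition speed cut, km/h.
#' @param max_gap_min Sampling gaps longer than this (minutes) break segments.
#' @return The input tibble with added columns `speed_kmh`, `state`
#'   (`"stationary"`/`"transition"`) and `gap_before` (logical).
#' @export
label_stationary <- function(fixes, speed_threshold_kmh = 1, max_gap_min = 30) {
  stopifnot(all(c("t", "lat", "lon") %in% names(fixes)))
  n <- nrow(fixes)
  if (n < 2) {
    warning("fewer than 2 fixes: labeling everything stationary with zero speed")
    return(dplyr::mutate(fixes,
      speed_kmh = 0, state = "stationary", gap_before = FALSE
    ))
  }
  tt <- as.numeric(fixes$t)
  if (is.unsorted(tt, strictly = TRUE)) {
    stop("GPS fixes must be strictly increasing in time")
  }
  dt_h <- diff(tt) / 3600
  d_km <- haversine_km(
    fixes$lat[-n], fixes$lon[-n],
    fixes$lat[-1], fixes$lon[-1]
  )
  speed <- c(NA_real_, d_km / dt_h)
  speed[1] <- speed[2]
  gap <- c(FALSE, dt_h * 60 > max_gap_min)
  state <- ifelse(speed <= speed_threshold_kmh, "stationary", "transition")
  state[1] <- state[2]
  dplyr::mutate(fixes,
    speed_kmh = speed, state = state, gap_before = gap,
    seg_km = c(NA_real_, d_km)
  )
}

# project lat/lon degrees to local meters around a reference point
.to_local_m <- function(lat, lon, lat0 = mean(lat), lon0 = mean(lon)) {
  cbind(
    x = (lon - lon0) * 111320 * cos(lat0 * pi / 180),
    y = (lat - lat0) * 111320
  )
}

#' Cluster stationary fixes into visited places
#'
#' k-means on the stationary fixes (in a local metric projection), with k
#' incremented from 1 until every fix lies within `max_cluster_radius_m` of
#' its assigned centroid. Dwell time credits 5 minutes per member fix
#' (the nominal sampling cadence).
#'
#' @param track Output of [label_stationary()].
#' @param max_cluster_radius_m Maximum member-to-centroid distance, meters.
#' @param seed RNG seed for the k-means restarts (deterministic result).
#' @param nstart Restarts per k.
#' @param fix_interval_min Sampling cadence used for dwell credit.
#' @return List with `clusters` (tibble: `cluster`, `lat`, `lon`, `n_fixes`,
#'   `dwell_min`), `assignment` (integer per track row, `NA` for transition
#'   fixes) and `k`.
#' @export
cluster_locations <- function(track, max_cluster_radius_m = 500, seed = 1,
                              nstart = 10, fix_interval_min = 5) {
  idx <- which(track$state == "stationary")
  empty <- list(
    clusters = tibble::tibble(
      cluster = integer(), lat = numeric(), lon = numeric(),
      n_fixes = integer(), dwell_min = numeric()
    ),
    assignment = rep(NA_integer_, nrow(track)), k = 0L
  )
  if (length(idx) == 0) return(empty)
  lat <- track$lat[idx]
  lon <- track$lon[idx]
  lat0 <- mean(lat); lon0 <- mean(lon)
  xy <- .to_local_m(lat, lon, lat0, lon0)
  k_max <- nrow(unique(xy))
  fit <- with_preserved_seed(seed, {
    for (k in seq_len(k_max)) {
      km <- suppressWarnings(stats::kmeans(xy, centers = k, nstart = nstart, iter.max = 100))
      dmax <- max(sqrt(rowSums((xy - km$centers[km$cluster, , drop = FALSE])^2)))
      if (dmax <= max_cluster_radius_m || k == k_max) break
    }
    km
  })
  k <- nrow(fit$centers)
  # order clusters by dwell (descending) for stable, meaningful indices
  ord <- order(-tabulate(fit$cluster, k), fit$centers[, "y"], fit$centers[, "x"])
  relabel <- match(seq_len(k), ord)
  cl <- relabel[fit$cluster]
  centers <- fit$centers[ord, , drop = FALSE]
  assignment <- rep(NA_integer_, nrow(track))
  assignment[idx] <- cl
  counts <- tabulate(cl, k)
  list(
    clusters = tibble::tibble(
      cluster = seq_len(k),
      lat = lat0 + centers[, "y"] / 111320,
      lon = lon0 + centers[, "x"] / (111320 * cos(lat0 * pi / 180)),
      n_fixes = counts,
      dwell_min = counts * fix_interval_min
    ),
    assignment = assignment,
    k = as.integer(k)
  )
}

#' Lomb periodogram spectral energy for an unevenly sampled series
#'
#' Classic Lomb least-squares periodogram (tau-shifted form). For a centered
#' series the reported energy at each frequency equals half the regression sum
#' of squares of the least-squares sinusoid fit at that frequency.
#'
#' @param t Sample times (hours).
#' @param y Values.
#' @param period_hours Periods (hours) at which to evaluate.
#' @return Numeric vector of spectral energies, one per period.
#' @export
lomb_energy <- function(t, y, period_hours) {
  yc <- y - mean(y)
  vapply(period_hours, function(p) {
    w <- 2 * pi / p
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau))
    st <- sin(w * (t - tau))
    0.5 * (sum(yc * ct)^2 / sum(ct^2) + sum(yc * st)^2 / sum(st^2))
  }, numeric(1))
}

#' Compute the seven GPS mobility features over a window
#'
#' * `location_variance`: `log(var(lat) + var(lon) + eps)` over stationary
#'   fixes (log-degrees-squared).
#' * `n_clusters`: number of visited location clusters.
#' * `entropy`: `-sum(p_i * log(p_i))` over per-cluster dwell fractions, nats.
#' * `normalized_entropy`: `entropy / log(k)`, defined 0 when `k = 1`.
#' * `circadian_movement`: `log(E_lat + E_lon + eps)` where `E` is Lomb
#'   spectral energy summed over periods 23.5-24.5 h.
#' * `total_distance`: summed haversine km over transition segments (gap
#'   segments excluded).
#' * `avg_velocity`: distance-weighted mean speed over transition segments,
#'   km/h; 0 when there are none.
#'
#' @param track Output of [label_stationary()].
#' @param clusters Output of [cluster_locations()] on the same track.
#' @param eps Guard added inside logs so single-location traces stay finite.
#' @param circadian_band Period band (hours) for the circadian energy.
#' @param n_freq Number of period grid points across the band.
#' @return One-row tibble with the seven features (all `NA` for an empty
#'   track).
#' @export
compute_gps_features <- function(track, clusters, eps = 1e-10,
                                 circadian_band = c(23.5, 24.5), n_freq = 25) {
  na_row <- tibble::tibble(
    location_variance = NA_real_, n_clusters = NA_real_, entropy = NA_real_,
    normalized_entropy = NA_real_, circadian_movement = NA_real_,
    total_distance = NA_real_, avg_velocity = NA_real_
  )
  if (nrow(track) == 0) return(na_row)

  stat <- track$state == "stationary"
  lat_s <- if (any(stat)) track$lat[stat] else track$lat
  lon_s <- if (any(stat)) track$lon[stat] else track$lon
  location_variance <- log(stats::var(lat_s) + stats::var(lon_s) + eps)
  if (length(lat_s) < 2) location_variance <- log(eps)

  k <- clusters$k
  if (k >= 1) {
    p <- clusters$clusters$dwell_min / sum(clusters$clusters$dwell_min)
    p <- p[p > 0]
    entropy <- -sum(p * log(p))
    normalized_entropy <- if (k > 1) entropy / log(k) else 0
  } else {
    entropy <- NA_real_
    normalized_entropy <- NA_real_
  }

  # circadian energy of the coordinate series near the 24 h period
  if (nrow(track) >= 3) {
    th <- (as.numeric(track$t) - as.numeric(track$t[1])) / 3600
    periods <- seq(circadian_band[1], circadian_band[2], length.out = n_freq)
    energy <- sum(lomb_energy(th, track$lat, periods)) +
      sum(lomb_energy(th, track$lon, periods))
    circadian_movement <- log(energy + eps)
  } else {
    circadian_movement <- log(eps)
  }

  trans_seg <- which(track$state == "transition" & !track$gap_before &
                       !is.na(track$seg_km))
  trans_seg <- trans_seg[trans_seg > 1]
  if (length(trans_seg) > 0) {
    d <- track$seg_km[trans_seg]
    v <- track$speed_kmh[trans_seg]
    total_distance <- sum(d)
    avg_velocity <- if (total_distance > 0) sum(d * v) / total_distance else 0
  } else {
    total_distance <- 0
    avg_velocity <- 0
  }

  tibble::tibble(
    location_variance = location_variance,
    n_clusters = as.numeric(k),
    entropy = entropy,
    normalized_entropy = normalized_entropy,
    circadian_movement = circadian_movement,
    total_distance = total_distance,
    avg_velocity = avg_velocity
  )
}
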