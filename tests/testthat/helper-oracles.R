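# Independent oracles and small fixture builders used across test files.

# ANCOVA route to the repeated-measures correlation: design-matrix least
# squares with participant factor + shared slope, decomposed via anova().
# Deliberately distinct from the package's per-participant-centering path.
oracle_rmcorr <- function(x, y, id) {
  fit <- lm(y ~ factor(id) + x)
  an <- anova(fit)
  ss_x <- an["x", "Sum Sq"]
  ss_res <- an["Residuals", "Sum Sq"]
  r <- sign(coef(fit)[["x"]]) * sqrt(ss_x / (ss_x + ss_res))
  list(r = r, p = an["x", "Pr(>F)"], dof = an["Residuals", "Df"])
}

# least-squares sinusoid fit energy: for centered data this equals the
# tau-shifted Lomb periodogram energy exactly
oracle_sinusoid_energy <- function(t, y, period) {
  w <- 2 * pi / period
  yc <- y - mean(y)
  fit <- lm(yc ~ 0 + cos(w * t) + sin(w * t))
  sum(fitted(fit)^2) / 2
}

# plain haversine, written out (not geosphere), R = 6371 km
oracle_haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

# adjusted Rand index from the contingency table
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# a 5-min-cadence track visiting the given (lat, lon) waypoints, n fixes
# each (n_each recycled across waypoints)
make_track <- function(waypoints, n_each = 10,
                       t0 = as.POSIXct("2019-07-29 08:00:00", tz = "UTC")) {
  n_each <- rep(n_each, length.out = length(waypoints))
  lat <- rep(vapply(waypoints, `[`, numeric(1), 1), n_each)
  lon <- rep(vapply(waypoints, `[`, numeric(1), 2), n_each)
  tibble::tibble(t = t0 + (seq_along(lat) - 1) * 300, lat = lat, lon = lon)
}

# assessments tibble with given totals on a measure's schedule (NA = missing,
# row dropped); baseline items optional
make_assessments <- function(pid, measure, totals, weeks = NULL) {
  if (is.null(weeks)) weeks <- checkin_weeks(measure)
  keep <- !is.na(totals)
  tibble::tibble(participant_id = pid, week = as.integer(weeks[keep]),
                 measure = measure, total = as.integer(totals[keep]),
                 items = vector("list", sum(keep)))
}

# complete feature-window grid with constant (or supplied) group values
make_windows <- function(pids, weeks = checkin_weeks("PHQ8", baseline = TRUE),
                         value = 0) {
  grid <- expand.grid(participant_id = pids, week = as.integer(weeks),
                      side = c("preceding", "proceeding"),
                      stringsAsFactors = FALSE)
  w <- tibble::as_tibble(grid)
  w$valid_days <- 14L
  for (g in names(feature_groups())) w[[g]] <- value
  w
}
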