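# Standardize base sensor features across the full sample and average them
# into the 14 unit-weighted feature groups, evaluated over the 2-week windows
# adjacent to each assessment check-in.

#' Feature-group membership
#'
#' The 14 unit-weighted sensor feature groups and their base features:
#' GPS-derived `locations` (cluster count, location variance), `time`
#' (entropy, normalized entropy, circadian movement) and `transitions`
#' (distance, velocity); six semantic-location dwell groups; `calls` and
#' `texts` communication composites; and the three app-use categories.
#' Group values are unweighted means of member z-scores.
#'
#' @return Named list mapping group name to base-feature names.
#' @export
feature_groups <- function() {
  list(
    locations   = c("n_clusters", "location_variance"),
    time        = c("entropy", "normalized_entropy", "circadian_movement"),
    transitions = c("total_distance", "avg_velocity"),
    home        = "sem_home",
    work        = "sem_work",
    shopping    = "sem_shopping",
    social      = "sem_social",
    religious   = "sem_religious",
    exercise    = "sem_exercise",
    calls       = c("calls_n_in", "calls_n_out", "calls_duration"),
    texts       = c("sms_n_in", "sms_n_out", "sms_length"),
    apps_active      = "app_active",
    apps_information = "app_information",
    apps_social      = "app_social"
  )
}

#' @rdname feature_groups
#' @export
base_feature_names <- function() unname(unlist(feature_groups()))

#' Study days covered by a check-in's sensor window
#'
#' A check-in at week `w` falls on study day `7 * w`. Its preceding window is
#' the 14 days ending the day before the check-in; its proceeding window is
#' the 14 days starting on the check-in day.
#'
#' @param checkin_week Integer study week of the check-in.
#' @param side `"preceding"` or `"proceeding"`.
#' @param window_days_n Window length in days.
#' @return Integer vector of study days (day 0 = first study day).
#' @export
#' @examples
#' window_days(6, "preceding")   # days 28..41 for a check-in on day 42
window_days <- function(checkin_week, side = c("preceding", "proceeding"),
                        window_days_n = 14) {
  side <- match.arg(side)
  d <- 7L * as.integer(checkin_week)
  if (side == "preceding") seq(d - window_days_n, d - 1L) else seq(d, d + window_days_n - 1L)
}

#' Assemble the base features of one participant window
#'
#' Communication, app and semantic features are means of daily values over
#' the window days that have sensor coverage; GPS features are computed once
#' over the whole window and passed in. A window with fewer than
#' `min_valid_days` covered days is missing (all base features `NA`).
#'
#' @param checkin_week,side Window anchor, as in [window_days()].
#' @param daily Tibble of daily records with a `study_day` column and the
#'   daily base-feature columns (`sem_*`, `calls_*`, `sms_*`, `app_*`);
#'   one row per day with sensor coverage.
#' @param gps One-row tibble of window-level GPS features
#'   ([compute_gps_features()]), or `NULL`.
#' @param min_valid_days Minimum covered days for a usable window.
#' @return One-row tibble: `week`, `side`, `valid_days` and every base
#'   feature.
#' @export
build_window <- function(checkin_week, side, daily, gps = NULL, min_valid_days = 7) {
  span <- window_days(checkin_week, side)
  rows <- daily[daily$study_day %in% span, , drop = FALSE]
  valid_days <- nrow(rows)
  daily_feats <- setdiff(base_feature_names(),
                         unlist(feature_groups()[c("locations", "time", "transitions")]))
  gps_feats <- c("n_clusters", "location_variance", "entropy",
                 "normalized_entropy", "circadian_movement",
                 "total_distance", "avg_velocity")
  out <- tibble::tibble(week = as.integer(checkin_week), side = side,
                        valid_days = as.integer(valid_days))
  if (valid_days < min_valid_days) {
    for (f in base_feature_names()) out[[f]] <- NA_real_
    return(out)
  }
  for (f in gps_feats) out[[f]] <- if (is.null(gps)) NA_real_ else gps[[f]]
  for (f in daily_feats) out[[f]] <- mean(rows[[f]], na.rm = TRUE)
  out
}

#' Standardize base features across the full sample
#'
#' Mean-centers each base feature to unit variance (denominator `n - 1`)
#' across all participant windows jointly. Missing entries stay missing; a
#' zero-variance feature standardizes to all zeros with a warning.
#'
#' @param windows Tibble of windows with base-feature columns.
#' @param features Columns to standardize.
#' @return List: `windows` (standardized) and `scaling` (tibble of `feature`,
#'   `mean`, `sd` for reproducibility).
#' @export
standardize_features <- function(windows, features = base_feature_names()) {
  features <- intersect(features, names(windows))
  scaling <- tibble::tibble(feature = features, mean = NA_real_, sd = NA_real_)
  for (i in seq_along(features)) {
    x <- windows[[features[i]]]
    mu <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      warning("feature '", features[i], "' has zero variance; standardized to 0")
      z <- ifelse(is.na(x), NA_real_, 0)
      s <- 0
    } else {
      z <- (x - mu) / s
    }
    windows[[features[i]]] <- z
    scaling$mean[i] <- mu
    scaling$sd[i] <- s
  }
  list(windows = windows, scaling = scaling)
}

#' Average standardized base features into feature groups
#'
#' Each group value is the unweighted mean of its member z-scores; members
#' that are missing are dropped from the mean, and a group with every member
#' missing is missing.
#'
#' @param windows Tibble of standardized windows.
#' @param groups Group membership, as [feature_groups()].
#' @return `windows` with one added column per group.
#' @export
aggregate_groups <- function(windows, groups = feature_groups()) {
  unknown <- setdiff(unlist(groups), names(windows))
  if (length(unknown) > 0) {
    stop("unknown base features in group definition: ", paste(unknown, collapse = ", "))
  }
  for (g in names(groups)) {
    m <- as.matrix(windows[, groups[[g]], drop = FALSE])
    v <- rowMeans(m, na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    windows[[g]] <- v
  }
  windows
}

#' Extract standardized feature-group windows from a cohort
#'
#' Runs the full sensor-feature pipeline: per participant, label stationary
#' fixes, cluster visited locations over the study, propagate semantic
#' labels, build daily records, compute window-level GPS features, then
#' standardize every base feature across the full sample and aggregate into
#' the 14 feature groups.
#'
#' @param bundle A cohort bundle ([load_cohort()] or [generate_cohort()]).
#' @param speed_threshold_kmh,max_cluster_radius_m,match_radius_m,min_valid_days
#'   Pipeline tuning knobs (see the respective functions).
#' @param category_map App-to-category map ([read_app_category_map()]).
#' @param weeks Check-in weeks to build windows for; default is the union of
#'   the post-baseline schedules.
#' @param seed Seed for the location-clustering restarts.
#' @return List: `windows` (tibble with `participant_id`, `week`, `side`,
#'   `valid_days` and one column per feature group), `base` (raw base
#'   features) and `scaling`.
#' @export
extract_feature_windows <- function(bundle,
                                    speed_threshold_kmh = 1,
                                    max_cluster_radius_m = 500,
                                    match_radius_m = 200,
                                    min_valid_days = 7,
                                    category_map = read_app_category_map(),
                                    weeks = checkin_weeks("PHQ8"),
                                    seed = 1) {
  start_date <- bundle$start_date
  pids <- bundle$participants$participant_id
  rows <- vector("list", length(pids))
  for (i in seq_along(pids)) {
    pid <- pids[i]
    tz_off <- bundle$participants$tz_offset_hours[i]
    gps <- dplyr::filter(bundle$gps, .data$participant_id == pid)
    comm <- dplyr::filter(bundle$comm, .data$participant_id == pid)
    apps <- dplyr::filter(bundle$apps, .data$participant_id == pid)
    labels <- dplyr::filter(bundle$semantic_labels, .data$participant_id == pid)

    if (nrow(gps) >= 2) {
      track <- label_stationary(gps, speed_threshold_kmh)
      cl <- cluster_locations(track, max_cluster_radius_m,
                              seed = (seed + 7919L * i) %% .Machine$integer.max)
      labeled <- propagate_semantic_labels(labels, cl$clusters, match_radius_m)
      sem <- daily_semantic_durations(track, cl$assignment, labeled, tz_off)
      covered <- sort(unique(local_date(gps$t, tz_off)))
    } else {
      track <- NULL
      sem <- daily_semantic_durations(
        tibble::tibble(t = as.POSIXct(character(0), tz = "UTC"),
                       lat = numeric(0), lon = numeric(0),
                       speed_kmh = numeric(0), state = character(0),
                       gap_before = logical(0), seg_km = numeric(0)),
        integer(0), tibble::tibble(cluster = integer(0), category = character(0)))
      covered <- as.Date(character(0))
    }
    names(sem)[-1] <- paste0("sem_", names(sem)[-1])
    comm_daily <- daily_comm_aggregates(comm, tz_off, dates = covered)
    app_daily <- daily_app_durations(apps, category_map, tz_off)

    daily <- tibble::tibble(date = covered) |>
      dplyr::left_join(sem, by = "date") |>
      dplyr::left_join(comm_daily, by = "date") |>
      dplyr::left_join(app_daily, by = "date")
    daily[is.na(daily)] <- 0
    daily$study_day <- as.integer(daily$date - start_date)

    prows <- list()
    for (w in weeks) {
      for (side in c("preceding", "proceeding")) {
        span <- window_days(w, side)
        gps_row <- NULL
        if (!is.null(track)) {
          in_span <- as.integer(local_date(track$t, tz_off) - start_date) %in% span
          sub <- track[in_span, , drop = FALSE]
          if (nrow(sub) >= 2) {
            sub$gap_before[1] <- FALSE
            sub$seg_km[1] <- NA_real_
            sub_cl <- cluster_locations(
              sub, max_cluster_radius_m,
              seed = (seed + 7919L * i + 131L * w +
                        as.integer(side == "proceeding")) %% .Machine$integer.max)
            gps_row <- compute_gps_features(sub, sub_cl)
          }
        }
        row <- build_window(w, side, daily, gps_row, min_valid_days)
        row <- dplyr::bind_cols(tibble::tibble(participant_id = pid), row)
        prows[[length(prows) + 1]] <- row
      }
    }
    rows[[i]] <- dplyr::bind_rows(prows)
  }
  base <- dplyr::bind_rows(rows)
  std <- standardize_features(base)
  windows <- aggregate_groups(std$windows)
  keep <- c("participant_id", "week", "side", "valid_days", names(feature_groups()))
  list(windows = windows[, keep], base = base, scaling = std$scaling)
}
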