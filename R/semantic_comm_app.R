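# Daily aggregates from the non-movement streams: semantic-location dwell
# minutes (labels propagated from assessment weeks), call/SMS sums, and
# app-category foreground minutes.

#' Semantic location categories
#' @return Character vector of the recognized categories.
#' @export
semantic_categories <- function() {
  c("home", "work", "shopping", "social", "religious", "exercise", "other")
}

#' App-use categories
#' @return Character vector of the app categories used for feature grouping
#'   (`other` collects unmapped apps and is excluded from the feature groups).
#' @export
app_categories <- function() c("active", "information", "social", "other")

#' Read an app-to-category map
#'
#' The map is a YAML file keyed by app id with values in [app_categories()].
#' The packaged default covers the usual exemplars (messaging/email/maps are
#' active, video and browsers are information consumption, social media are
#' social).
#'
#' @param path YAML file; default is the map shipped with the package.
#' @return Named character vector, app id -> category.
#' @export
read_app_category_map <- function(path = system.file("extdata", "app_categories.yaml",
                                                     package = "laggedsense")) {
  raw <- yaml::read_yaml(path)
  map <- vapply(raw, as.character, character(1))
  bad <- setdiff(unique(map), app_categories())
  if (length(bad) > 0) {
    stop("unknown app categories in map: ", paste(bad, collapse = ", "))
  }
  map
}

# local calendar day of UTC timestamps given a fixed participant UTC offset
local_date <- function(t, tz_offset_hours = 0) {
  as.Date(as.POSIXct(as.numeric(t) + tz_offset_hours * 3600,
                     origin = "1970-01-01", tz = "UTC"))
}

#' Propagate semantic labels to location clusters
#'
#' Participants label the places they visit during assessment weeks; those
#' labeled centroids are carried to every location cluster by nearest
#' neighbor: a cluster takes the category of the closest labeled centroid
#' within `match_radius_m`, otherwise `"other"`. Ties are broken by smallest
#' distance, then lexicographically by category.
#'
#' @param label_map Tibble with `lat`, `lon`, `category`.
#' @param clusters Cluster tibble (from [cluster_locations()]`$clusters`).
#' @param match_radius_m Maximum centroid-to-label distance, meters.
#' @return `clusters` with an added `category` column.
#' @export
propagate_semantic_labels <- function(label_map, clusters, match_radius_m = 200) {
  if (nrow(clusters) == 0) {
    return(dplyr::mutate(clusters, category = character(0)))
  }
  if (is.null(label_map) || nrow(label_map) == 0) {
    warning("empty semantic label map: all clusters labeled 'other'")
    return(dplyr::mutate(clusters, category = "other"))
  }
  bad <- setdiff(unique(label_map$category), semantic_categories())
  if (length(bad) > 0) stop("unknown semantic categories: ", paste(bad, collapse = ", "))
  lab <- label_map[order(label_map$category), ]   # lexicographic tie-break
  category <- vapply(seq_len(nrow(clusters)), function(i) {
    d <- haversine_km(clusters$lat[i], clusters$lon[i], lab$lat, lab$lon) * 1000
    j <- which.min(d)   # first minimum = smallest distance, then lexicographic
    if (d[j] <= match_radius_m) lab$category[j] else "other"
  }, character(1))
  dplyr::mutate(clusters, category = category)
}

#' Daily minutes per semantic-location category
#'
#' Credits 5 minutes (one sampling interval) per stationary fix to the
#' category of its location cluster, bucketed by local day. Dwell episodes
#' shorter than three consecutive fixes in the same cluster are credited to
#' no category, a conservative enforcement of the more-than-10-minutes visit
#' rule. Runs are broken by cluster changes, transition fixes and sampling
#' gaps.
#'
#' @param track Output of [label_stationary()].
#' @param assignment Integer cluster id per track row ([cluster_locations()]).
#' @param labeled_clusters Cluster tibble with a `category` column
#'   ([propagate_semantic_labels()]).
#' @param tz_offset_hours Participant UTC offset for local-day bucketing.
#' @param min_run_fixes Minimum consecutive fixes for an episode to count.
#' @param fix_interval_min Minutes credited per fix.
#' @return Tibble: `date` plus one minutes column per category in
#'   [semantic_categories()].
#' @export
daily_semantic_durations <- function(track, assignment, labeled_clusters,
                                     tz_offset_hours = 0, min_run_fixes = 3,
                                     fix_interval_min = 5) {
  cats <- semantic_categories()
  empty <- tibble::as_tibble(c(list(date = as.Date(character(0))),
                               setNames(rep(list(numeric(0)), length(cats)), cats)))
  n <- nrow(track)
  if (n == 0) return(empty)
  a <- assignment
  # break runs at assignment change, NA, or sampling gap
  brk <- c(TRUE, (a[-1] != a[-n]) | is.na(a[-1]) | is.na(a[-n]) | track$gap_before[-1])
  run_id <- cumsum(brk)
  keep <- !is.na(a)
  if (!any(keep)) return(empty)
  df <- tibble::tibble(
    run = run_id[keep], cluster = a[keep],
    date = local_date(track$t[keep], tz_offset_hours)
  )
  run_len <- table(df$run)
  df <- df[df$run %in% as.integer(names(run_len)[run_len >= min_run_fixes]), ]
  if (nrow(df) == 0) return(empty)
  df$category <- labeled_clusters$category[match(df$cluster, labeled_clusters$cluster)]
  out <- df |>
    dplyr::count(.data$date, .data$category) |>
    dplyr::mutate(minutes = .data$n * fix_interval_min, n = NULL) |>
    tidyr::pivot_wider(names_from = "category", values_from = "minutes",
                       values_fill = 0)
  for (cat in setdiff(cats, names(out))) out[[cat]] <- 0
  out[, c("date", cats)]
}

#' Daily communication aggregates
#'
#' Sums incoming/outgoing call and SMS counts, call seconds and message
#' characters per local day.
#'
#' @param events Tibble with `t`, `kind` (`"call"`/`"sms"`), `direction`
#'   (`"incoming"`/`"outgoing"`), `magnitude` (seconds or characters).
#' @param tz_offset_hours Participant UTC offset.
#' @param dates Optional vector of dates to complete with zero rows (days
#'   with sensor coverage but no events).
#' @return Tibble: `date`, `calls_n_in`, `calls_n_out`, `calls_duration`,
#'   `sms_n_in`, `sms_n_out`, `sms_length`.
#' @export
daily_comm_aggregates <- function(events, tz_offset_hours = 0, dates = NULL) {
  cols <- c("calls_n_in", "calls_n_out", "calls_duration",
            "sms_n_in", "sms_n_out", "sms_length")
  if (nrow(events) == 0) {
    out <- tibble::as_tibble(c(list(date = as.Date(character(0))),
                               setNames(rep(list(numeric(0)), 6), cols)))
  } else {
    out <- events |>
      dplyr::mutate(date = local_date(.data$t, tz_offset_hours)) |>
      dplyr::group_by(.data$date) |>
      dplyr::summarise(
        calls_n_in    = sum(.data$kind == "call" & .data$direction == "incoming"),
        calls_n_out   = sum(.data$kind == "call" & .data$direction == "outgoing"),
        calls_duration = sum(.data$magnitude[.data$kind == "call"]),
        sms_n_in      = sum(.data$kind == "sms" & .data$direction == "incoming"),
        sms_n_out     = sum(.data$kind == "sms" & .data$direction == "outgoing"),
        sms_length    = sum(.data$magnitude[.data$kind == "sms"]),
        .groups = "drop"
      )
  }
  if (!is.null(dates)) {
    missing_dates <- setdiff(as.character(dates), as.character(out$date))
    if (length(missing_dates) > 0) {
      fill <- tibble::as_tibble(c(list(date = as.Date(missing_dates)),
                                  setNames(rep(list(0), 6), cols)))
      out <- dplyr::arrange(dplyr::bind_rows(out, fill), .data$date)
    }
  }
  out
}

#' Daily app-use minutes per category
#'
#' Foreground apps are sampled every 5 minutes; each sample credits one
#' sampling interval to its app's category. Apps missing from the map fall
#' into `"other"`, which is excluded from the three app feature groups.
#'
#' @param samples Tibble with `t`, `app_id`.
#' @param category_map Named character vector app id -> category
#'   ([read_app_category_map()]).
#' @param tz_offset_hours Participant UTC offset.
#' @param fix_interval_min Minutes credited per sample.
#' @return Tibble: `date`, `app_active`, `app_information`, `app_social`,
#'   `app_other`.
#' @export
daily_app_durations <- function(samples, category_map, tz_offset_hours = 0,
                                fix_interval_min = 5) {
  cols <- paste0("app_", app_categories())
  if (nrow(samples) == 0) {
    return(tibble::as_tibble(c(list(date = as.Date(character(0))),
                               setNames(rep(list(numeric(0)), 4), cols))))
  }
  cat <- unname(category_map[samples$app_id])
  cat[is.na(cat)] <- "other"
  out <- tibble::tibble(
    date = local_date(samples$t, tz_offset_hours),
    category = paste0("app_", cat)
  ) |>
    dplyr::count(.data$date, .data$category) |>
    dplyr::mutate(minutes = .data$n * fix_interval_min, n = NULL) |>
    tidyr::pivot_wider(names_from = "category", values_from = "minutes",
                       values_fill = 0)
  for (col in setdiff(cols, names(out))) out[[col]] <- 0
  out[, c("date", cols)]
}
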