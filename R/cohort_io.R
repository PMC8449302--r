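# Cohort file layout: one directory per participant holding one UTF-8 CSV
# per stream (gps.csv, comm.csv, apps.csv, assessments.csv,
# semantic_labels.csv), a top-level participants.csv with demographics, and
# study.yaml with the study start date. Timestamps are ISO-8601 UTC; local
# days are derived from the per-participant tz_offset_hours column.

.iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

.empty_streams <- function() {
  t0 <- as.POSIXct(character(0), tz = "UTC")
  list(
    gps = tibble::tibble(participant_id = character(0), t = t0,
                         lat = numeric(0), lon = numeric(0)),
    comm = tibble::tibble(participant_id = character(0), t = t0,
                          kind = character(0), direction = character(0),
                          magnitude = integer(0)),
    apps = tibble::tibble(participant_id = character(0), t = t0,
                          app_id = character(0)),
    semantic_labels = tibble::tibble(participant_id = character(0),
                                     lat = numeric(0), lon = numeric(0),
                                     category = character(0), week = integer(0)),
    assessments = tibble::tibble(participant_id = character(0),
                                 week = integer(0), measure = character(0),
                                 total = integer(0), items = list())
  )
}

#' Construct a cohort bundle
#'
#' The in-memory cohort container: a list of tidy tibbles (`participants`,
#' `gps`, `comm`, `apps`, `semantic_labels`, `assessments`, each keyed by
#' `participant_id`) plus the study `start_date`.
#'
#' @param participants,gps,comm,apps,semantic_labels,assessments Component
#'   tibbles.
#' @param start_date First study day (`Date`).
#' @return A `cohort_bundle`.
#' @export
new_cohort_bundle <- function(participants, gps, comm, apps, semantic_labels,
                              assessments, start_date) {
  structure(list(
    participants = participants, gps = gps, comm = comm, apps = apps,
    semantic_labels = semantic_labels, assessments = assessments,
    start_date = as.Date(start_date)
  ), class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle> ", nrow(x$participants), " participants, start ",
      format(x$start_date), "\n", sep = "")
  cat("  gps fixes: ", nrow(x$gps), "; comm events: ", nrow(x$comm),
      "; app samples: ", nrow(x$apps), "; assessments: ",
      nrow(x$assessments), "\n", sep = "")
  invisible(x)
}

# schema validation; returns a tibble report (zero rows = clean)
.validate_streams <- function(pid, streams) {
  probs <- list()
  add <- function(file, row, problem) {
    probs[[length(probs) + 1]] <<- tibble::tibble(
      participant_id = pid, file = file, row = as.integer(row),
      problem = problem)
  }
  g <- streams$gps
  bad <- which(g$lat < -90 | g$lat > 90 | g$lon < -180 | g$lon > 180)
  for (r in bad) add("gps.csv", r, "lat/lon out of bounds")
  if (nrow(g) > 1 && is.unsorted(as.numeric(g$t), strictly = TRUE)) {
    add("gps.csv", which(diff(as.numeric(g$t)) <= 0)[1] + 1L,
        "timestamps not strictly increasing")
  }
  cm <- streams$comm
  for (r in which(cm$magnitude < 0)) add("comm.csv", r, "negative magnitude")
  for (r in which(!cm$kind %in% c("call", "sms"))) add("comm.csv", r, "bad kind")
  for (r in which(!cm$direction %in% c("incoming", "outgoing"))) {
    add("comm.csv", r, "bad direction")
  }
  sl <- streams$semantic_labels
  for (r in which(!sl$category %in% semantic_categories())) {
    add("semantic_labels.csv", r, "unknown category")
  }
  a <- streams$assessments
  info <- measure_info()
  for (r in seq_len(nrow(a))) {
    j <- match(a$measure[r], info$measure)
    if (is.na(j)) { add("assessments.csv", r, "unknown measure"); next }
    if (!is.na(a$total[r]) && (a$total[r] < 0 || a$total[r] > info$total_max[j])) {
      add("assessments.csv", r, "total out of range")
    }
    it <- a$items[[r]]
    if (!is.null(it) && !is.na(a$total[r]) && sum(it) != a$total[r]) {
      add("assessments.csv", r, "items do not sum to total")
    }
  }
  if (length(probs) == 0) {
    tibble::tibble(participant_id = character(0), file = character(0),
                   row = integer(0), problem = character(0))
  } else dplyr::bind_rows(probs)
}

.read_stream <- function(path, cols) {
  if (!file.exists(path)) {
    stop("missing stream file: ", path)
  }
  x <- readr::read_csv(path, col_types = cols, progress = FALSE)
  required <- names(cols$cols)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x
}

#' Load a cohort from its directory layout
#'
#' Reads and validates every stream. Schema problems (out-of-bounds
#' coordinates, unsorted timestamps, impossible scores, items not summing to
#' totals) are collected into a per-row report; with `strict = TRUE`
#' (default) any problem raises an error naming the file and row, otherwise
#' the report is attached as `attr(bundle, "validation_report")` and rows
#' are kept, never silently dropped.
#'
#' @param root Cohort directory.
#' @param strict Raise on validation problems?
#' @return A `cohort_bundle`.
#' @export
load_cohort <- function(root, strict = TRUE) {
  t_iso <- readr::col_datetime(format = "%Y-%m-%dT%H:%M:%SZ")
  meta_path <- file.path(root, "study.yaml")
  start_date <- if (file.exists(meta_path)) {
    as.Date(yaml::read_yaml(meta_path)$start_date)
  } else as.Date("2019-07-29")
  ppath <- file.path(root, "participants.csv")
  if (!file.exists(ppath)) {
    warning("no participants.csv under ", root, ": empty cohort")
    e <- .empty_streams()
    return(new_cohort_bundle(
      tibble::tibble(participant_id = character(0), age = integer(0),
                     gender = character(0), race = character(0),
                     tz_offset_hours = numeric(0)),
      e$gps, e$comm, e$apps, e$semantic_labels, e$assessments, start_date))
  }
  participants <- .read_stream(ppath, readr::cols(
    participant_id = readr::col_character(), age = readr::col_integer(),
    gender = readr::col_character(), race = readr::col_character(),
    tz_offset_hours = readr::col_double()))
  if (anyDuplicated(participants$participant_id)) {
    stop("duplicate participant ids in participants.csv")
  }
  acc <- .empty_streams()
  reports <- list()
  for (pid in participants$participant_id) {
    pdir <- file.path(root, pid)
    # lat/lon come in as text and convert via strtod, which (unlike the csv
    # parser) is correctly rounded, keeping round trips bit-exact
    num <- function(x) {
      for (dc in intersect(c("lat", "lon"), names(x))) {
        x[[dc]] <- as.numeric(x[[dc]])
      }
      x
    }
    streams <- list(
      gps = num(.read_stream(file.path(pdir, "gps.csv"), readr::cols(
        t = t_iso, lat = readr::col_character(),
        lon = readr::col_character()))),
      comm = .read_stream(file.path(pdir, "comm.csv"), readr::cols(
        t = t_iso, kind = readr::col_character(),
        direction = readr::col_character(), magnitude = readr::col_integer())),
      apps = .read_stream(file.path(pdir, "apps.csv"), readr::cols(
        t = t_iso, app_id = readr::col_character())),
      semantic_labels = num(.read_stream(file.path(pdir, "semantic_labels.csv"),
        readr::cols(lat = readr::col_character(),
                    lon = readr::col_character(),
                    category = readr::col_character(),
                    week = readr::col_integer()))),
      assessments = .read_stream(file.path(pdir, "assessments.csv"),
        readr::cols(week = readr::col_integer(),
                    measure = readr::col_character(),
                    total = readr::col_integer(),
                    items = readr::col_character()))
    )
    streams$assessments$items <- lapply(streams$assessments$items, function(s) {
      if (is.na(s) || s == "") NULL else as.integer(strsplit(s, ";")[[1]])
    })
    reports[[pid]] <- .validate_streams(pid, streams)
    for (nm in names(streams)) {
      acc[[nm]] <- dplyr::bind_rows(
        acc[[nm]],
        dplyr::mutate(streams[[nm]], participant_id = pid, .before = 1))
    }
  }
  report <- dplyr::bind_rows(reports)
  if (strict && nrow(report) > 0) {
    stop("cohort validation failed (", nrow(report), " problem(s)); first: ",
         report$participant_id[1], "/", report$file[1], " row ",
         report$row[1], ": ", report$problem[1])
  }
  bundle <- new_cohort_bundle(participants, acc$gps, acc$comm, acc$apps,
                              acc$semantic_labels, acc$assessments, start_date)
  attr(bundle, "validation_report") <- report
  bundle
}

#' Save a cohort to the directory layout
#'
#' Writes the CSV layout read by [load_cohort()]; a saved-then-reloaded
#' bundle reproduces every stream exactly. Ground-truth group memberships
#' attached by [generate_cohort()] are written to `ground_truth.csv`.
#'
#' @param bundle A `cohort_bundle`.
#' @param root Target directory (created if needed).
#' @return `root`, invisibly.
#' @export
save_cohort <- function(bundle, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(start_date = format(bundle$start_date)),
                   file.path(root, "study.yaml"))
  readr::write_csv(bundle$participants, file.path(root, "participants.csv"),
                   progress = FALSE)
  for (pid in bundle$participants$participant_id) {
    pdir <- file.path(root, pid)
    dir.create(pdir, showWarnings = FALSE)
    wr <- function(x, name, tcol = "t") {
      x <- x[x$participant_id == pid, setdiff(names(x), "participant_id"),
             drop = FALSE]
      if (tcol %in% names(x)) x[[tcol]] <- .iso8601(x[[tcol]])
      # %.17g text guarantees bit-exact double round trips
      for (dc in intersect(c("lat", "lon"), names(x))) {
        x[[dc]] <- sprintf("%.17g", x[[dc]])
      }
      readr::write_csv(x, file.path(pdir, name), progress = FALSE)
    }
    wr(bundle$gps, "gps.csv")
    wr(bundle$comm, "comm.csv")
    wr(bundle$apps, "apps.csv")
    sl <- bundle$semantic_labels
    wr(sl[, c("participant_id", "lat", "lon", "category", "week")],
       "semantic_labels.csv")
    a <- bundle$assessments[bundle$assessments$participant_id == pid, ]
    a$items <- vapply(a$items, function(v) {
      if (is.null(v)) "" else paste(v, collapse = ";")
    }, character(1))
    readr::write_csv(a[, c("week", "measure", "total", "items")],
                     file.path(pdir, "assessments.csv"), progress = FALSE)
  }
  truth <- attr(bundle, "truth")
  if (!is.null(truth)) {
    readr::write_csv(truth$group, file.path(root, "ground_truth.csv"),
                     progress = FALSE)
  }
  invisible(root)
}

#' Demographic summary of a cohort
#'
#' Participant count, mean/SD age, and category counts with percentages
#' (half-up, one decimal) for gender and race.
#'
#' @param bundle A `cohort_bundle`.
#' @return List with `n`, `age_mean`, `age_sd` and a `categories` tibble
#'   (`variable`, `level`, `count`, `total`, `percent`).
#' @export
cohort_summary <- function(bundle) {
  p <- bundle$participants
  n <- nrow(p)
  cats <- if (n == 0) {
    tibble::tibble(variable = character(0), level = character(0),
                   count = integer(0), total = integer(0),
                   percent = numeric(0))
  } else {
    dplyr::bind_rows(lapply(c("gender", "race"), function(v) {
      tab <- table(p[[v]])
      tibble::tibble(variable = v, level = names(tab),
                     count = as.integer(tab), total = n,
                     percent = round_half_up(100 * as.integer(tab) / n, 1))
    }))
  }
  list(
    n = n,
    age_mean = if (n > 0) mean(p$age) else NA_real_,
    age_sd = if (n > 1) stats::sd(p$age) else NA_real_,
    categories = cats
  )
}
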