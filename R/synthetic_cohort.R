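# Synthetic cohort generator: four latent symptom-profile groups, 3-weekly
# symptom trajectories with an AR(1) person process, daily behavior driven by
# a latent behavioral-activation state, and a tunable lagged coupling in
# which behavior change precedes symptom change. Used to validate the whole
# analysis pipeline with known ground truth.

#' Simulation configuration
#'
#' All generative choices are explicit configuration. The defaults describe a
#' 16-week cohort with four symptom-profile groups weighted like the
#' qualitative profiles the clustering step is expected to find (minimal
#' symptoms; depression with social anxiety; depression with anxiety;
#' multiple comorbidities), an AR(1) check-in-level symptom process, a daily
#' latent behavioral state with strong week-scale persistence, and no
#' behavior-symptom coupling until one is asked for.
#'
#' `coupling_rho` is the target correlation between the standardized change
#' in the latent behavioral state averaged over the 2-week window preceding
#' each check-in and the symptom change across consecutive check-ins; the
#' coupling weight is calibrated from the AR process variance so the target
#' is hit exactly in expectation. `reverse_coupling_rho` plays the symmetric
#' role for symptom change preceding sensor change (window-level generator
#' only) and defaults to 0, enabling directional-specificity tests.
#'
#' @param n_participants Cohort size.
#' @param group_weights Four probabilities, summing to 1.
#' @param group_profiles Tibble of per-group baseline total-score means/SDs
#'   (columns `phq8_mean`, `phq8_sd`, `gad7_mean`, `gad7_sd`, `spin_mean`,
#'   `spin_sd`).
#' @param ar_coef AR(1) coefficient of the check-in-level symptom process.
#' @param sigma_symptom Marginal SD of the symptom process (scale points).
#' @param coupling_rho Target lagged behavior-to-symptom change correlation.
#' @param reverse_coupling_rho Target symptom-to-subsequent-behavior change
#'   correlation.
#' @param coupling_group Feature group carrying the coupling.
#' @param ar_daily AR(1) coefficient of the daily latent behavioral state.
#' @param feature_noise_sd SD of measurement noise added to window-level
#'   feature-group values (z units).
#' @param n_anchors Anchor locations per participant (first is home).
#' @param gps_noise_m GPS jitter SD, meters.
#' @param assessment_missing_rate Marginal post-baseline assessment dropout
#'   rate.
#' @param missing_severity_slope Logistic slope of dropout on standardized
#'   baseline PHQ-8 (dropout is missing-not-at-random when positive).
#' @param sensor_missing_day_rate Probability a whole sensor day is dropped.
#' @param tz_offset_hours Participant UTC offset.
#' @param start_date First study day.
#' @param seed RNG seed (Mersenne-Twister; identical seed, identical cohort).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_participants = 200,
                       group_weights = c(88, 71, 69, 54) / 282,
                       group_profiles = default_group_profiles(),
                       ar_coef = 0.6,
                       sigma_symptom = 2.5,
                       coupling_rho = 0,
                       reverse_coupling_rho = 0,
                       coupling_group = "locations",
                       ar_daily = 0.9,
                       feature_noise_sd = 0.2,
                       n_anchors = 4,
                       gps_noise_m = 30,
                       assessment_missing_rate = 0,
                       missing_severity_slope = 1,
                       sensor_missing_day_rate = 0,
                       tz_offset_hours = 0,
                       start_date = as.Date("2019-07-29"),
                       seed = 1) {
  if (length(group_weights) != 4 || abs(sum(group_weights) - 1) > 1e-8 ||
      any(group_weights < 0)) {
    stop("group_weights must be 4 nonnegative probabilities summing to 1")
  }
  if (abs(coupling_rho) >= 1 || abs(reverse_coupling_rho) >= 1) {
    stop("coupling magnitudes must be < 1")
  }
  rates <- c(assessment_missing_rate, sensor_missing_day_rate)
  if (any(rates < 0 | rates > 1)) stop("missingness rates must lie in [0, 1]")
  if (!coupling_group %in% names(feature_groups())) {
    stop("unknown coupling_group: ", coupling_group)
  }
  structure(list(
    n_participants = as.integer(n_participants),
    group_weights = group_weights, group_profiles = group_profiles,
    ar_coef = ar_coef, sigma_symptom = sigma_symptom,
    coupling_rho = coupling_rho, reverse_coupling_rho = reverse_coupling_rho,
    coupling_group = coupling_group, ar_daily = ar_daily,
    feature_noise_sd = feature_noise_sd, n_anchors = as.integer(n_anchors),
    gps_noise_m = gps_noise_m,
    assessment_missing_rate = assessment_missing_rate,
    missing_severity_slope = missing_severity_slope,
    sensor_missing_day_rate = sensor_missing_day_rate,
    tz_offset_hours = tz_offset_hours, start_date = start_date,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_group_profiles <- function() {
  tibble::tibble(
    group = 1:4,
    group_name = c("minimal_symptom", "depression_social_anxiety",
                   "depression_anxiety", "multiple_comorbidities"),
    phq8_mean = c(3, 12, 15, 18), phq8_sd = c(2, 2.5, 2.5, 2.5),
    gad7_mean = c(3, 5, 12, 15),  gad7_sd = c(2, 2, 2.5, 2.5),
    spin_mean = c(10, 38, 14, 46), spin_sd = c(5, 6, 5, 7)
  )
}

n_study_days <- function() 112L   # 16 weeks

# distribute a total across items with a per-item cap, uniformly over
# unit-score slots
.split_total <- function(total, n_items, item_max) {
  slots <- sample(rep(seq_len(n_items), item_max))
  tabulate(slots[seq_len(total)], n_items)
}

# stationary AR(1) path with unit marginal variance
.ar1_path <- function(n, phi) {
  e <- rnorm(n)
  v <- c(e[1], sqrt(1 - phi^2) * e[-1])
  as.numeric(stats::filter(v, phi, method = "recursive"))
}

# n independent stationary AR(1) rows, vectorized across rows
.ar1_matrix <- function(nrow, ncol, phi) {
  e <- matrix(rnorm(nrow * ncol), nrow, ncol)
  x <- matrix(0, nrow, ncol)
  s <- sqrt(1 - phi^2)
  x[, 1] <- e[, 1]
  for (t in seq_len(ncol)[-1]) x[, t] <- phi * x[, t - 1] + s * e[, t]
  x
}

# participants, group memberships, and baseline item-level scores
.sim_population <- function(config) {
  n <- config$n_participants
  pids <- sprintf("p%04d", seq_len(n))
  group <- sample(1:4, n, replace = TRUE, prob = config$group_weights)
  participants <- tibble::tibble(
    participant_id = pids,
    age = as.integer(pmin(pmax(round(rnorm(n, 39, 12)), 18), 75)),
    gender = sample(c("female", "male", "nonbinary"), n, replace = TRUE,
                    prob = c(0.79, 0.19, 0.02)),
    race = sample(c("white", "black", "asian", "other"), n, replace = TRUE,
                  prob = c(0.80, 0.08, 0.06, 0.06)),
    tz_offset_hours = config$tz_offset_hours
  )
  info <- measure_info()
  prof <- config$group_profiles
  base_totals <- matrix(NA_real_, n, 3, dimnames = list(pids, info$measure))
  items_all <- vector("list", n * 3)
  for (j in seq_len(3)) {
    m <- info$measure[j]
    mu <- prof[[paste0(tolower(m), "_mean")]][group]
    s <- prof[[paste0(tolower(m), "_sd")]][group]
    totals <- pmin(pmax(round(rnorm(n, mu, s)), 0), info$total_max[j])
    base_totals[, j] <- totals
    for (i in seq_len(n)) {
      items_all[[(j - 1) * n + i]] <-
        as.integer(.split_total(totals[i], info$n_items[j], info$item_max[j]))
    }
  }
  baseline <- tibble::tibble(
    participant_id = rep(pids, 3), week = 0L,
    measure = rep(info$measure, each = n),
    total = as.integer(base_totals), items = items_all
  )
  list(participants = participants, group = group,
       baseline = baseline, base_totals = base_totals)
}

# symptom totals at every scheduled check-in, coupled to the latent window
# means: dS over a pair = lambda * z(dW_pre) + AR(1) increment, with lambda
# calibrated so corr(dS, z) = coupling_rho
.sim_assessments <- function(config, pop, W_pre) {
  info <- measure_info()
  n <- config$n_participants
  pids <- pop$participants$participant_id
  rho <- config$coupling_rho
  out <- list(pop$baseline)
  for (j in seq_len(3)) {
    m <- info$measure[j]
    sched <- checkin_weeks(m)
    J <- length(sched)
    # standardized preceding-window latent changes, pooled across the cohort
    dW <- W_pre[, as.character(sched[-1]), drop = FALSE] -
      W_pre[, as.character(sched[-J]), drop = FALSE]
    z <- (dW - mean(dW)) / stats::sd(dW)
    sd_de <- config$sigma_symptom * sqrt(2 * (1 - config$ar_coef))
    lambda <- if (rho == 0) 0 else sd_de * rho / sqrt(1 - rho^2)
    e <- config$sigma_symptom * .ar1_matrix(n, J, config$ar_coef)
    cum <- cbind(0, t(apply(z, 1, cumsum)))
    S <- pop$base_totals[, m] + e + lambda * cum
    S <- pmin(pmax(round(S), 0), info$total_max[j])
    out[[length(out) + 1]] <- tibble::tibble(
      participant_id = rep(pids, J), week = rep(sched, each = n),
      measure = m, total = as.integer(S), items = vector("list", n * J)
    )
  }
  dplyr::bind_rows(out)
}

# mean of the daily latent state over each check-in's preceding window,
# clipped to the study period
.window_means <- function(B, weeks, side) {
  days <- seq_len(ncol(B)) - 1L
  m <- vapply(weeks, function(w) {
    span <- intersect(window_days(w, side), days)
    rowMeans(B[, span + 1L, drop = FALSE])
  }, numeric(nrow(B)))
  m <- matrix(m, nrow = nrow(B))
  colnames(m) <- as.character(weeks)
  m
}

#' Generate one participant-day GPS trace
#'
#' 288 fixes at 5-minute cadence. The day starts at the home anchor; each
#' non-home anchor is visited with probability increasing in the behavioral
#' state `B_t`, with travel interpolated over a few fixes and dwell episodes
#' of at least 30 minutes. Gaussian jitter of `gps_noise_m` meters is added
#' to every fix, so visited-anchor count and traveled distance increase in
#' `B_t` in expectation.
#'
#' @param anchors Tibble with `lat`, `lon` (row 1 = home).
#' @param B_t Behavioral-activation scalar for the day.
#' @param gps_noise_m Jitter SD, meters.
#' @param date Local calendar date of the day.
#' @param tz_offset_hours Participant UTC offset.
#' @return Tibble `t` (POSIXct UTC), `lat`, `lon` with 288 rows.
#' @export
generate_gps_day <- function(anchors, B_t, gps_noise_m = 30,
                             date = as.Date("2019-07-29"), tz_offset_hours = 0) {
  stopifnot(nrow(anchors) >= 1)
  n_slots <- 288L
  loc <- matrix(rep(c(anchors$lat[1], anchors$lon[1]), each = n_slots), ncol = 2)
  n_other <- nrow(anchors) - 1
  if (n_other > 0) {
    visit <- runif(n_other) < stats::plogis(-0.2 + 0.9 * B_t)
    cursor <- 84L   # ~07:00, leave earlier parts of the day at home
    for (a in which(visit) + 1L) {
      travel <- sample(2:4, 1)
      dwell <- sample(6:24, 1)
      need <- 2L * travel + dwell
      if (cursor + need > n_slots - 12L) break
      frac <- seq_len(travel) / (travel + 1)
      out_lat <- anchors$lat[1] + frac * (anchors$lat[a] - anchors$lat[1])
      out_lon <- anchors$lon[1] + frac * (anchors$lon[a] - anchors$lon[1])
      idx <- cursor + seq_len(need)
      loc[idx, 1] <- c(out_lat, rep(anchors$lat[a], dwell), rev(out_lat))
      loc[idx, 2] <- c(out_lon, rep(anchors$lon[a], dwell), rev(out_lon))
      cursor <- cursor + need + sample(3:12, 1)   # pause at home between trips
    }
  }
  jit <- gps_noise_m / 111320
  lat <- loc[, 1] + rnorm(n_slots, 0, jit)
  lon <- loc[, 2] + rnorm(n_slots, 0, jit / cos(mean(loc[, 1]) * pi / 180))
  t0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") - tz_offset_hours * 3600
  tibble::tibble(t = t0 + (seq_len(n_slots) - 1L) * 300, lat = lat, lon = lon)
}

# full event streams for one participant across the study
.sim_streams <- function(config, pid, anchors, B) {
  days <- seq_len(n_study_days()) - 1L
  dates <- config$start_date + days
  gps <- vector("list", length(days))
  comm <- vector("list", length(days))
  apps <- vector("list", length(days))
  app_pool <- list(
    active = c("com.app.messenger", "com.app.mail", "com.app.maps"),
    information = c("com.app.video", "com.app.browser"),
    social = c("com.app.facegram", "com.app.snapbook"),
    other = c("com.app.misc")
  )
  cat_prob <- c(active = 0.35, information = 0.3, social = 0.25, other = 0.1)
  for (d in seq_along(days)) {
    b <- B[d]
    gps[[d]] <- generate_gps_day(anchors, b, config$gps_noise_m, dates[d],
                                 config$tz_offset_hours)
    n_call <- rpois(2, exp(0.0 + 0.25 * b))
    n_sms <- rpois(2, exp(1.2 + 0.30 * b))
    n_ev <- sum(n_call) + sum(n_sms)
    if (n_ev > 0) {
      secs <- sort(sample.int(86400L, n_ev))
      t0 <- as.POSIXct(paste(dates[d], "00:00:00"), tz = "UTC") -
        config$tz_offset_hours * 3600
      comm[[d]] <- tibble::tibble(
        t = t0 + secs,
        kind = rep(c("call", "call", "sms", "sms"), c(n_call, n_sms)),
        direction = rep(c("incoming", "outgoing", "incoming", "outgoing"),
                        c(n_call, n_sms)),
        magnitude = as.integer(c(round(stats::rexp(sum(n_call), 1 / 120)),
                                 1L + rpois(sum(n_sms), 40)))
      )
    }
    use <- which(runif(288) < stats::plogis(-1 + 0.3 * b))
    if (length(use) > 0) {
      cat <- sample(names(cat_prob), length(use), replace = TRUE, prob = cat_prob)
      t0 <- as.POSIXct(paste(dates[d], "00:00:00"), tz = "UTC") -
        config$tz_offset_hours * 3600
      apps[[d]] <- tibble::tibble(
        t = t0 + (use - 1L) * 300L + 150L,
        app_id = unname(vapply(cat, function(cc) sample(app_pool[[cc]], 1),
                               character(1)))
      )
    }
  }
  list(
    gps = dplyr::bind_rows(gps) |> dplyr::mutate(participant_id = pid, .before = 1),
    comm = dplyr::bind_rows(comm) |> dplyr::mutate(participant_id = pid, .before = 1),
    apps = dplyr::bind_rows(apps) |> dplyr::mutate(participant_id = pid, .before = 1)
  )
}

#' Generate a complete synthetic cohort with raw event streams
#'
#' Produces a cohort bundle with 16 weeks of GPS, communication and app
#' streams per participant, semantic labels for the participant's anchor
#' locations, the full assessment schedule, and group/latent-state ground
#' truth attached as `attr(bundle, "truth")`. The daily behavioral state
#' drives mobility (anchors visited, distance traveled), communication and
#' app-use volumes, and — through `coupling_rho` — subsequent symptom change.
#' Missingness is injected last via [inject_missingness()].
#'
#' Identical configuration (including seed) yields an identical bundle.
#'
#' @param config A [sim_config()].
#' @return A cohort bundle (see [load_cohort()] for the layout).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$reverse_coupling_rho != 0) {
    stop("reverse coupling is supported by generate_window_cohort() only")
  }
  bundle <- with_preserved_seed(config$seed, {
    pop <- .sim_population(config)
    n <- config$n_participants
    B <- .ar1_matrix(n, n_study_days(), config$ar_daily)
    weeks_all <- checkin_weeks("PHQ8", baseline = TRUE)
    W_pre <- .window_means(B, weeks_all, "preceding")
    assessments <- .sim_assessments(config, pop, W_pre)

    anchors <- vector("list", n)
    labels <- vector("list", n)
    cats <- c("work", "shopping", "social", "exercise", "religious")
    for (i in seq_len(n)) {
      lat0 <- 41.9 + rnorm(1, 0, 0.05)
      lon0 <- -87.65 + rnorm(1, 0, 0.05)
      k <- config$n_anchors
      dist_km <- runif(k - 1, 0.5, 3)
      bearing <- runif(k - 1, 0, 2 * pi)
      anchors[[i]] <- tibble::tibble(
        lat = c(lat0, lat0 + dist_km * cos(bearing) / 111.32),
        lon = c(lon0, lon0 + dist_km * sin(bearing) /
                  (111.32 * cos(lat0 * pi / 180)))
      )
      cat_i <- c("home", sample(cats, k - 1, replace = k - 1 > length(cats)))
      labels[[i]] <- tibble::tibble(
        participant_id = pop$participants$participant_id[i],
        lat = anchors[[i]]$lat, lon = anchors[[i]]$lon,
        category = cat_i, week = 0L
      )
    }
    streams <- lapply(seq_len(n), function(i) {
      .sim_streams(config, pop$participants$participant_id[i], anchors[[i]],
                   B[i, ])
    })
    bundle <- new_cohort_bundle(
      participants = pop$participants,
      gps = dplyr::bind_rows(lapply(streams, `[[`, "gps")),
      comm = dplyr::bind_rows(lapply(streams, `[[`, "comm")),
      apps = dplyr::bind_rows(lapply(streams, `[[`, "apps")),
      semantic_labels = dplyr::bind_rows(labels),
      assessments = assessments,
      start_date = config$start_date
    )
    attr(bundle, "truth") <- list(
      group = tibble::tibble(
        participant_id = pop$participants$participant_id,
        group = pop$group,
        group_name = config$group_profiles$group_name[pop$group]
      ),
      coupling_rho = config$coupling_rho,
      coupling_group = config$coupling_group,
      latent_B = B
    )
    bundle
  })
  inject_missingness(bundle, config)
}

#' Generate a window-level synthetic cohort
#'
#' The fast companion of [generate_cohort()]: instead of raw event streams it
#' emits standardized feature-group values per participant window directly,
#' each group driven by its own latent daily behavioral process plus
#' measurement noise, with the coupled group's latent window means driving
#' symptom change exactly as in the full generator. This is the scale at
#' which the lagged coupling is defined, so Monte-Carlo calibration studies
#' of the inference chain (change pairs, rmcorr, FDR) run on this path;
#' the raw-stream path is validated separately.
#'
#' Supports `reverse_coupling_rho`: symptom changes feed the coupled group's
#' subsequent proceeding-window values with the symmetric calibration.
#'
#' @param config A [sim_config()].
#' @return List: `windows` (feature-group windows), `assessments`,
#'   `participants`, `truth`.
#' @export
generate_window_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  out <- with_preserved_seed(config$seed, {
    pop <- .sim_population(config)
    n <- config$n_participants
    pids <- pop$participants$participant_id
    weeks <- checkin_weeks("PHQ8", baseline = TRUE)
    gnames <- names(feature_groups())
    W_pre_list <- list()
    vals <- list()
    for (g in gnames) {
      Bg <- .ar1_matrix(n, n_study_days(), config$ar_daily)
      for (side in c("preceding", "proceeding")) {
        W <- .window_means(Bg, weeks, side)
        # windows falling wholly outside the study period are missing
        W[is.nan(W)] <- NA_real_
        Wz <- (W - mean(W, na.rm = TRUE)) / stats::sd(W, na.rm = TRUE)
        obs <- Wz + rnorm(length(Wz), 0, config$feature_noise_sd)
        dim(obs) <- dim(W); dimnames(obs) <- dimnames(W)
        vals[[paste(g, side)]] <- obs
        if (g == config$coupling_group && side == "preceding") W_pre_list$W <- W
      }
    }
    assessments <- .sim_assessments(config, pop, W_pre_list$W)

    # symptom-to-subsequent-sensor coupling on the coupled group's
    # proceeding windows
    rr <- config$reverse_coupling_rho
    if (rr != 0) {
      sched <- checkin_weeks("PHQ8")
      S <- matrix(NA_real_, n, length(sched))
      a <- assessments[assessments$measure == "PHQ8", ]
      for (j in seq_along(sched)) {
        S[, j] <- a$total[match(paste(pids, sched[j]), paste(a$participant_id, a$week))]
      }
      dS <- S[, -1, drop = FALSE] - S[, -ncol(S), drop = FALSE]
      zS <- (dS - mean(dS)) / stats::sd(dS)
      key <- paste(config$coupling_group, "proceeding")
      obs <- vals[[key]]
      dobs <- obs[, as.character(sched[-1])] - obs[, as.character(sched[-length(sched)])]
      lam_r <- stats::sd(dobs, na.rm = TRUE) * rr / sqrt(1 - rr^2)
      cum <- cbind(0, t(apply(zS, 1, cumsum)))
      obs[, as.character(sched)] <- obs[, as.character(sched)] + lam_r * cum
      vals[[key]] <- obs
    }

    grid <- expand.grid(i = seq_len(n), week = weeks,
                        side = c("preceding", "proceeding"),
                        stringsAsFactors = FALSE)
    windows <- tibble::tibble(
      participant_id = pids[grid$i],
      week = as.integer(grid$week),
      side = grid$side,
      valid_days = 14L
    )
    for (g in gnames) {
      v <- numeric(nrow(grid))
      for (side in c("preceding", "proceeding")) {
        sel <- grid$side == side
        m <- vals[[paste(g, side)]]
        v[sel] <- m[cbind(grid$i[sel], match(as.character(grid$week[sel]),
                                             colnames(m)))]
      }
      windows[[g]] <- v
    }
    list(
      windows = windows, assessments = assessments,
      participants = pop$participants,
      truth = list(
        group = tibble::tibble(participant_id = pids, group = pop$group,
                               group_name = config$group_profiles$group_name[pop$group]),
        coupling_rho = config$coupling_rho,
        reverse_coupling_rho = config$reverse_coupling_rho,
        coupling_group = config$coupling_group
      )
    )
  })
  if (config$assessment_missing_rate > 0) {
    out$assessments <- .drop_assessments(out$assessments, out$participants,
                                         config)
  }
  out
}

# MNAR assessment dropout: logistic in standardized baseline PHQ-8 severity
.drop_assessments <- function(assessments, participants, config) {
  rate <- config$assessment_missing_rate
  if (rate >= 1) {
    return(assessments[assessments$week == 0, , drop = FALSE])
  }
  base <- assessments[assessments$measure == "PHQ8" & assessments$week == 0, ]
  z <- as.numeric(scale(base$total[match(participants$participant_id,
                                         base$participant_id)]))
  z[is.na(z)] <- 0
  p_i <- stats::plogis(stats::qlogis(rate) + config$missing_severity_slope * z)
  # recenter so the marginal rate matches the configured rate
  p_i <- p_i * rate / mean(p_i)
  p_i <- pmin(p_i, 1)
  names(p_i) <- participants$participant_id
  post <- assessments$week > 0
  drop <- post & (runif(nrow(assessments)) <
                    p_i[assessments$participant_id])
  assessments[!drop, , drop = FALSE]
}

#' Inject missingness into a complete cohort bundle
#'
#' Removes post-baseline assessments with probability increasing in baseline
#' PHQ-8 severity (logistic link with configurable slope, recentered so the
#' marginal rate matches `assessment_missing_rate`) — missing not at random —
#' and removes whole sensor days (all GPS/communication/app rows of a
#' participant-day) at `sensor_missing_day_rate`.
#'
#' @param bundle A complete cohort bundle.
#' @param config The [sim_config()] holding the rates.
#' @param seed Seed for the dropout draws; defaults to a stream derived from
#'   the config seed.
#' @return The thinned bundle.
#' @export
inject_missingness <- function(bundle, config, seed = config$seed + 1000003L) {
  if (config$assessment_missing_rate == 0 && config$sensor_missing_day_rate == 0) {
    return(bundle)
  }
  with_preserved_seed(seed, {
    if (config$assessment_missing_rate > 0) {
      bundle$assessments <- .drop_assessments(bundle$assessments,
                                              bundle$participants, config)
    }
    if (config$sensor_missing_day_rate > 0) {
      # one draw per participant-day, shared by all three streams so whole
      # sensor days disappear together
      pd <- expand.grid(participant_id = bundle$participants$participant_id,
                        day = seq_len(n_study_days()) - 1L,
                        stringsAsFactors = FALSE)
      dropped <- paste(pd$participant_id, pd$day)[
        runif(nrow(pd)) < config$sensor_missing_day_rate]
      for (stream in c("gps", "comm", "apps")) {
        s <- bundle[[stream]]
        if (nrow(s) == 0) next
        day <- as.integer(local_date(s$t, config$tz_offset_hours) -
                            bundle$start_date)
        bundle[[stream]] <- s[!paste(s$participant_id, day) %in% dropped, ,
                              drop = FALSE]
      }
    }
    bundle
  })
}
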