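# The core inference: lagged change pairs in both temporal directions,
# repeated-measures correlation (ANCOVA with participant intercepts and one
# shared slope), Benjamini-Hochberg correction, and the supporting power and
# missingness calculations.

#' Build lagged change pairs for one symptom measure
#'
#' Consecutive post-baseline check-ins form change pairs: six PHQ-8 check-ins
#' yield five pairs per participant, five GAD-7/SPIN check-ins yield four.
#' For each pair and feature group this returns the symptom change
#' `dSx = Sx2 - Sx1`, the preceding-window sensor change
#' `dSn = Sn2 - Sn1` (sensing strictly before each symptom report) and the
#' proceeding-window change `dSn_prime` (sensing strictly after). If exactly
#' one assessment of a pair is missing it is replaced by the participant's
#' mean of observed scores on that measure (baseline included); pairs with
#' both assessments missing are dropped, as are directions whose sensor
#' window is missing. Participants with fewer than two observed assessments
#' contribute no pairs.
#'
#' @param assessments Assessment tibble.
#' @param windows Feature-window tibble ([extract_feature_windows()]`$windows`
#'   or [generate_window_cohort()]`$windows`).
#' @param measure `"PHQ8"`, `"GAD7"` or `"SPIN"`.
#' @param groups Feature-group column names present in `windows`.
#' @return Long tibble: `participant_id`, `pair`, `week1`, `week2`, `dSx`,
#'   `n_filled` (0-1 mean-filled assessments in the pair), `group`, `dSn`,
#'   `dSn_prime`.
#' @export
build_change_pairs <- function(assessments, windows, measure,
                               groups = names(feature_groups())) {
  stopifnot(measure %in% measure_info()$measure)
  groups <- intersect(groups, names(windows))
  sched <- checkin_weeks(measure)
  J <- length(sched)
  meas <- assessments[assessments$measure == measure, , drop = FALSE]
  n_obs_pid <- tapply(!is.na(meas$total), meas$participant_id, sum)
  pids <- sort(names(n_obs_pid)[n_obs_pid >= 2])
  empty <- tibble::tibble(
    participant_id = character(0), pair = integer(0), week1 = integer(0),
    week2 = integer(0), dSx = numeric(0), n_filled = integer(0),
    group = character(0), dSn = numeric(0), dSn_prime = numeric(0))
  if (length(pids) == 0) return(empty)
  n <- length(pids)
  fill_mean <- tapply(meas$total, meas$participant_id, mean, na.rm = TRUE)[pids]
  Tm <- matrix(NA_real_, n, J)
  hit <- meas$participant_id %in% pids & meas$week %in% sched
  Tm[cbind(match(meas$participant_id[hit], pids),
           match(meas$week[hit], sched))] <- meas$total[hit]
  s1 <- Tm[, -J, drop = FALSE]; s2 <- Tm[, -1, drop = FALSE]
  n_filled <- is.na(s1) + is.na(s2)
  fm <- matrix(fill_mean, n, J - 1)
  s1[is.na(s1)] <- fm[is.na(s1)]
  s2[is.na(s2)] <- fm[is.na(s2)]
  kept <- which(n_filled < 2, arr.ind = TRUE)
  if (nrow(kept) == 0) return(empty)

  side_mat <- function(side, g) {
    w <- windows[windows$side == side & windows$participant_id %in% pids &
                   windows$week %in% sched, , drop = FALSE]
    m <- matrix(NA_real_, n, J)
    m[cbind(match(w$participant_id, pids), match(w$week, sched))] <- w[[g]]
    m
  }
  K <- nrow(kept)
  ii <- kept[, 1]; jj <- kept[, 2]
  blocks <- lapply(groups, function(g) {
    pre <- side_mat("preceding", g)
    pro <- side_mat("proceeding", g)
    dSn <- (pre[, -1, drop = FALSE] - pre[, -J, drop = FALSE])[kept]
    dSnp <- (pro[, -1, drop = FALSE] - pro[, -J, drop = FALSE])[kept]
    tibble::tibble(
      participant_id = pids[ii], pair = jj,
      week1 = sched[jj], week2 = sched[jj + 1],
      dSx = s2[kept] - s1[kept], n_filled = n_filled[kept],
      group = g, dSn = dSn, dSn_prime = dSnp
    )
  })
  dplyr::bind_rows(blocks)
}

#' Repeated-measures correlation
#'
#' The common within-participant association: an ANCOVA of `y` on `x` with a
#' separate intercept per participant and one shared slope, which reduces to
#' the pooled association of within-participant-centered values. The
#' coefficient is `sign(slope) * sqrt(SS_x / (SS_x + SS_residual))`;
#' inference uses `dof = N - n - 1` (observations minus participants minus
#' the slope) with a two-sided t test. `dof_nk = n * (k_bar - 1)` — the
#' participant-count times mean-observations-minus-one convention — is
#' reported alongside for comparability.
#'
#' Participants contributing fewer than two complete observations are
#' excluded; at least two participants must remain.
#'
#' @param x,y Numeric vectors of paired observations.
#' @param participant Participant id per observation.
#' @return One-row tibble: `r_rm`, `p_raw`, `slope`, `n_participants`,
#'   `n_obs`, `dof_inference`, `dof_nk`. All `NA` (with a warning where
#'   informative) when the statistic is undefined.
#' @export
rmcorr <- function(x, y, participant) {
  na_row <- tibble::tibble(
    r_rm = NA_real_, p_raw = NA_real_, slope = NA_real_,
    n_participants = NA_integer_, n_obs = NA_integer_,
    dof_inference = NA_integer_, dof_nk = NA_integer_
  )
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]; participant <- as.character(participant)[ok]
  counts <- table(participant)
  keep <- participant %in% names(counts)[counts >= 2]
  x <- x[keep]; y <- y[keep]; participant <- participant[keep]
  n <- length(unique(participant))
  N <- length(x)
  if (n < 2) return(na_row)
  xc <- x - stats::ave(x, participant)
  yc <- y - stats::ave(y, participant)
  ssx <- sum(xc^2)
  if (ssx == 0) {
    warning("x is constant within every participant; rmcorr undefined")
    return(na_row)
  }
  slope <- sum(xc * yc) / ssx
  ss_effect <- slope^2 * ssx
  ss_res <- sum((yc - slope * xc)^2)
  if (ss_effect + ss_res == 0) {
    warning("y is constant within every participant; rmcorr undefined")
    return(na_row)
  }
  r <- sign(slope) * sqrt(ss_effect / (ss_effect + ss_res))
  dof <- N - n - 1L
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt(dof / (1 - r^2))
    2 * stats::pt(-abs(tstat), dof)
  }
  tibble::tibble(
    r_rm = r, p_raw = p, slope = slope,
    n_participants = as.integer(n), n_obs = as.integer(N),
    dof_inference = as.integer(dof), dof_nk = as.integer(N - n)
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p values controlling the false discovery rate, capped at
#' 1. The running minimum from the largest p downward can (and does) produce
#' tied adjusted values. Missing p values stay missing and do not count
#' toward the family size.
#'
#' @param p Numeric vector of raw p values in \[0, 1\] (NA allowed).
#' @return Adjusted p values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Run the full lagged repeated-measures correlation analysis
#'
#' For every symptom measure, analysis frame (full sample plus each symptom
#' cluster), feature group and temporal direction, estimates the
#' repeated-measures correlation of lagged changes and applies
#' Benjamini-Hochberg correction within each measure x frame x direction
#' family of feature groups. Direction `"sensor->symptom"` correlates
#' preceding-window sensor changes with subsequent symptom changes
#' (`x = dSn`, `y = dSx`); `"symptom->sensor"` correlates symptom changes
#' with subsequent proceeding-window sensor changes (`x = dSx`,
#' `y = dSn_prime`).
#'
#' @param windows Feature-window tibble.
#' @param assessments Assessment tibble.
#' @param clusters Optional tibble `participant_id`, `cluster_name`
#'   ([assign_clusters()]`$assignments`); the full sample is always analyzed.
#' @param measures Symptom measures to analyze.
#' @param groups Feature-group columns.
#' @param alpha,trend Corrected-p thresholds for the significance and trend
#'   flags.
#' @return Tibble with one row per measure x frame x group x direction:
#'   `measure`, `frame`, `group`, `direction`, the [rmcorr()] columns,
#'   `p_bh`, `sig` (`p_bh < alpha`), `trend` (`p_bh < trend`).
#' @export
run_lagged_analysis <- function(windows, assessments, clusters = NULL,
                                measures = c("PHQ8", "GAD7", "SPIN"),
                                groups = names(feature_groups()),
                                alpha = 0.05, trend = 0.1) {
  groups <- intersect(groups, names(windows))
  frames <- list(full_sample = unique(windows$participant_id))
  if (!is.null(clusters)) {
    for (cn in sort(unique(clusters$cluster_name))) {
      frames[[cn]] <- clusters$participant_id[clusters$cluster_name == cn]
    }
  }
  out <- list()
  for (m in measures) {
    pairs <- build_change_pairs(assessments, windows, m, groups)
    for (fr in names(frames)) {
      sub <- pairs[pairs$participant_id %in% frames[[fr]], , drop = FALSE]
      for (dir in c("sensor->symptom", "symptom->sensor")) {
        res <- dplyr::bind_rows(lapply(groups, function(g) {
          gp <- sub[sub$group == g, , drop = FALSE]
          stat <- if (dir == "sensor->symptom") {
            rmcorr(gp$dSn, gp$dSx, gp$participant_id)
          } else {
            rmcorr(gp$dSx, gp$dSn_prime, gp$participant_id)
          }
          dplyr::bind_cols(
            tibble::tibble(measure = m, frame = fr, group = g, direction = dir),
            stat
          )
        }))
        res$p_bh <- bh_adjust(res$p_raw)
        out[[length(out) + 1]] <- res
      }
    }
  }
  res <- dplyr::bind_rows(out)
  res$sig <- !is.na(res$p_bh) & res$p_bh < alpha
  res$trend <- !is.na(res$p_bh) & res$p_bh < trend
  res
}

#' Sample size for detecting a correlation
#'
#' Normal-approximation sample size for a two-sided test of a correlation
#' via the Fisher z transform:
#' `n = trunc(((z_{1-alpha/2} + z_power) / atanh(rho))^2)`. The optional
#' small-sample correction adds 3 and rounds up instead.
#'
#' @param rho Target correlation magnitude, `0 < |rho| < 1`.
#' @param alpha Two-sided type-I error rate.
#' @param power Target power.
#' @param fisher_correction Apply the `+3` small-sample correction?
#' @return Required number of participants (integer).
#' @export
#' @examples
#' power_sample_size(0.2, 0.05, 0.90)   # 255
power_sample_size <- function(rho, alpha = 0.05, power = 0.90,
                              fisher_correction = FALSE) {
  if (rho == 0) stop("rho = 0 is undetectable at any sample size")
  if (abs(rho) >= 1 || alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("require 0 < |rho| < 1 and alpha, power in (0, 1)")
  }
  raw <- ((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / atanh(abs(rho)))^2
  if (fisher_correction) as.integer(ceiling(raw) + 3) else as.integer(trunc(raw))
}

#' Assessment missingness summary
#'
#' Missing over possible post-baseline assessments per measure (possible =
#' participants x scheduled post-baseline check-ins), with the percentage to
#' two decimals, plus the mean baseline severity of participants with at
#' least one missing assessment against the cohort mean (missingness in this
#' design is expected to lean toward higher-severity participants).
#'
#' @param bundle A cohort bundle.
#' @return Tibble: `measure`, `missing`, `possible`, `percent`,
#'   `mean_baseline_missing`, `mean_baseline_all`.
#' @export
summarize_missingness <- function(bundle) {
  a <- bundle$assessments
  n <- nrow(bundle$participants)
  dplyr::bind_rows(lapply(measure_info()$measure, function(m) {
    sched <- checkin_weeks(m)
    possible <- n * length(sched)
    obs <- a[a$measure == m & a$week %in% sched & !is.na(a$total), ]
    missing <- possible - nrow(obs)
    base <- a[a$measure == m & a$week == 0 & !is.na(a$total), ]
    n_obs_per <- table(factor(obs$participant_id,
                              levels = bundle$participants$participant_id))
    any_missing <- names(n_obs_per)[n_obs_per < length(sched)]
    tibble::tibble(
      measure = m, missing = missing, possible = possible,
      percent = round_half_up(100 * missing / possible, 2),
      mean_baseline_missing = mean(base$total[base$participant_id %in% any_missing]),
      mean_baseline_all = mean(base$total)
    )
  }))
}
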