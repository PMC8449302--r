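test_that("change pairs follow the schedule: 6 check-ins give 5 pairs, 5 give 4", {
  pids <- c("a", "b")
  windows <- make_windows(pids, value = 0.1)
  windows$locations <- seq_len(nrow(windows)) / 10   # something non-constant
  assess <- dplyr::bind_rows(
    lapply(pids, function(p) dplyr::bind_rows(
      make_assessments(p, "PHQ8", c(10, 11, 12, 13, 14, 15)),
      make_assessments(p, "GAD7", c(5, 6, 7, 8, 9)),
      make_assessments(p, "SPIN", c(20, 21, 22, 23, 24)))))
  phq <- build_change_pairs(assess, windows, "PHQ8")
  gad <- build_change_pairs(assess, windows, "GAD7")
  spin <- build_change_pairs(assess, windows, "SPIN")
  expect_equal(nrow(phq), 2 * 5 * length(feature_groups()))
  expect_equal(nrow(gad), 2 * 4 * length(feature_groups()))
  expect_equal(nrow(spin), 2 * 4 * length(feature_groups()))
  expect_equal(sort(unique(phq$week1)), c(1, 4, 7, 10, 13))
  loc <- phq[phq$participant_id == "a" & phq$group == "locations", ]
  expect_equal(loc$dSx, rep(1, 5))
})

test_that("a single missing assessment is filled with the within-person mean", {
  windows <- make_windows("a", value = 0)
  assess <- make_assessments("a", "PHQ8", c(10, NA, 14, 12, 10, 14))
  pairs <- build_change_pairs(assess, windows, "PHQ8",
                              groups = "locations")
  # fill value is the mean of observed scores: (10+14+12+10+14)/5 = 12
  expect_equal(nrow(pairs), 5)
  expect_equal(pairs$dSx[pairs$pair == 1], 12 - 10)
  expect_equal(pairs$dSx[pairs$pair == 2], 14 - 12)
  expect_equal(pairs$n_filled[pairs$pair %in% 1:2], c(1, 1))

  # both members missing: the pair is dropped, not double-filled
  assess2 <- make_assessments("a", "PHQ8", c(10, NA, NA, 12, 10, 14))
  pairs2 <- build_change_pairs(assess2, windows, "PHQ8", groups = "locations")
  expect_false(2 %in% pairs2$pair)
  expect_equal(nrow(pairs2), 4)

  # fewer than two observed assessments: no pairs at all
  assess3 <- make_assessments("a", "PHQ8", c(10, NA, NA, NA, NA, NA))
  expect_equal(nrow(build_change_pairs(assess3, windows, "PHQ8")), 0)
})

test_that("pairs with a missing sensor window drop per direction", {
  windows <- make_windows("a", value = 0.5)
  windows$locations[windows$week == 4 & windows$side == "preceding"] <- NA
  assess <- make_assessments("a", "PHQ8", c(10, 11, 12, 13, 14, 15))
  pairs <- build_change_pairs(assess, windows, "PHQ8", groups = "locations")
  expect_true(is.na(pairs$dSn[pairs$pair == 1]))       # uses week-4 preceding
  expect_true(is.na(pairs$dSn[pairs$pair == 2]))
  expect_false(any(is.na(pairs$dSn_prime)))            # proceeding intact
  expect_false(any(is.na(pairs$dSn[pairs$pair >= 3])))
})

test_that("rmcorr recovers perfect within-person association with signs", {
  x <- c(1, 2, 3, 11, 12, 13)
  id <- rep(c("p", "q"), each = 3)
  up <- rmcorr(x, x + rep(c(100, -50), each = 3), id)
  expect_equal(up$r_rm, 1)
  down <- rmcorr(x, -x + rep(c(100, -50), each = 3), id)
  expect_equal(down$r_rm, -1)
  expect_equal(up$dof_inference, 6 - 2 - 1)
  expect_equal(up$dof_nk, 6 - 2)
})

test_that("rmcorr matches the ANCOVA least-squares oracle to 1e-10", {
  set.seed(73)
  for (rep in 1:20) {
    n_id <- sample(3:10, 1)
    k <- sample(2:6, 1)
    id <- rep(seq_len(n_id), each = k)
    x <- rnorm(n_id * k)
    y <- runif(1, -1, 1) * x + rep(rnorm(n_id, sd = 3), each = k) + rnorm(n_id * k)
    mine <- rmcorr(x, y, id)
    oracle <- oracle_rmcorr(x, y, id)
    expect_equal(mine$r_rm, oracle$r, tolerance = 1e-10)
    expect_equal(mine$p_raw, oracle$p, tolerance = 1e-10)
    expect_equal(mine$dof_inference, oracle$dof)
  }
})

test_that("rmcorr is invariant to per-participant shifts and filters sparse ids", {
  set.seed(79)
  id <- rep(1:5, each = 4)
  x <- rnorm(20); y <- 0.4 * x + rnorm(20)
  base <- rmcorr(x, y, id)
  shift <- rmcorr(x + rep(rnorm(5, sd = 50), each = 4),
                  y + rep(rnorm(5, sd = 50), each = 4), id)
  expect_equal(shift$r_rm, base$r_rm, tolerance = 1e-12)

  # a participant with a single observation contributes nothing
  with_single <- rmcorr(c(x, 99), c(y, 99), c(id, 6))
  expect_equal(with_single$r_rm, base$r_rm, tolerance = 1e-12)
  expect_equal(with_single$n_participants, 5L)

  expect_warning(const <- rmcorr(rep(rep(1, 4), 3), rnorm(12), rep(1:3, each = 4)),
                 "constant")
  expect_true(is.na(const$r_rm))
  expect_true(is.na(rmcorr(1:3, 1:3, c(1, 2, 3))$r_rm))  # all ids singletons
})

test_that("BH adjustment reproduces the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)               # m = 1: unchanged
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.3, 0.9)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))      # monotone in sorted order
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  withna <- bh_adjust(c(0.01, NA, 0.02))
  expect_true(is.na(withna[2]))
  expect_equal(withna[c(1, 3)], bh_adjust(c(0.01, 0.02)))
  expect_error(bh_adjust(c(0.5, 1.2)), "must lie")
})

test_that("the analysis table is deterministic and BH families are per direction", {
  wc <- generate_window_cohort(sim_config(n_participants = 40, seed = 101,
                                          coupling_rho = -0.3))
  r1 <- run_lagged_analysis(wc$windows, wc$assessments, measures = "PHQ8")
  r2 <- run_lagged_analysis(wc$windows, wc$assessments, measures = "PHQ8")
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 2 * length(feature_groups()))
  for (dir in unique(r1$direction)) {
    fam <- r1[r1$direction == dir, ]
    expect_equal(fam$p_bh, bh_adjust(fam$p_raw))
    expect_true(all(fam$p_bh >= fam$p_raw, na.rm = TRUE))
  }
})

test_that("clustered analysis reports every frame and flags significance", {
  wc <- generate_window_cohort(sim_config(n_participants = 60, seed = 103,
                                          coupling_rho = -0.5))
  items <- baseline_item_matrix(wc$assessments)
  cl <- assign_clusters(items, k = 4, n_init = 10, seed = 5)
  res <- run_lagged_analysis(wc$windows, wc$assessments, cl$assignments,
                             measures = "PHQ8")
  expect_setequal(unique(res$frame),
                  c("full_sample", sort(unique(cl$assignments$cluster_name))))
  full_loc <- res[res$frame == "full_sample" & res$group == "locations" &
                    res$direction == "sensor->symptom", ]
  expect_true(full_loc$sig)
  expect_true(full_loc$trend)
})

test_that("sample-size formula matches the printed design and its limits", {
  expect_equal(power_sample_size(0.2, 0.05, 0.90), 255L)
  expect_equal(power_sample_size(-0.2, 0.05, 0.90), 255L)   # magnitude only
  expect_equal(power_sample_size(0.2, 0.05, 0.90, fisher_correction = TRUE),
               259L)
  # monotone decreasing in |rho|
  ns <- vapply(c(0.1, 0.2, 0.4, 0.8, 0.99), power_sample_size, integer(1))
  expect_true(all(diff(ns) < 0))
  expect_error(power_sample_size(0), "undetectable")
  expect_error(power_sample_size(1.2), "require")
})

test_that("missingness summary arithmetic and MNAR severity report", {
  n <- 282
  pids <- sprintf("p%04d", seq_len(n))
  mk <- function(measure, n_miss, base_mean) {
    sched <- checkin_weeks(measure)
    rows <- expand.grid(participant_id = pids, week = sched,
                        stringsAsFactors = FALSE)
    rows <- rows[order(rows$participant_id), ]
    # drop the earliest rows, so missingness concentrates in few participants
    rows <- rows[setdiff(seq_len(nrow(rows)), seq_len(n_miss)), ]
    dplyr::bind_rows(
      tibble::tibble(participant_id = pids, week = 0L, measure = measure,
                     total = as.integer(round(base_mean)),
                     items = vector("list", n)),
      tibble::tibble(participant_id = rows$participant_id,
                     week = as.integer(rows$week), measure = measure,
                     total = 10L, items = vector("list", nrow(rows))))
  }
  bundle <- list(
    participants = tibble::tibble(participant_id = pids),
    assessments = dplyr::bind_rows(mk("PHQ8", 277, 11), mk("GAD7", 104, 10),
                                   mk("SPIN", 104, 25)))
  ms <- summarize_missingness(bundle)
  expect_equal(ms$percent[ms$measure == "PHQ8"], 16.37)
  expect_equal(ms$missing[ms$measure == "PHQ8"], 277)
  expect_equal(ms$possible[ms$measure == "PHQ8"], 1692)
  expect_equal(ms$percent[ms$measure == "GAD7"], 7.38)
  expect_equal(ms$percent[ms$measure == "SPIN"], 7.38)

  complete <- list(participants = bundle$participants,
                   assessments = dplyr::bind_rows(mk("PHQ8", 0, 10),
                                                  mk("GAD7", 0, 10),
                                                  mk("SPIN", 0, 10)))
  expect_equal(summarize_missingness(complete)$percent, rep(0, 3))
})
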