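# k-means clustering of participants on baseline item-level symptom scores
# (PHQ-8, GAD-7, SPIN), with elbow-based selection of k.

#' Baseline item matrix
#'
#' Assembles the participant x item matrix of baseline (week 0) item scores:
#' 8 PHQ-8 + 7 GAD-7 + 17 SPIN items. Participants missing any baseline item
#' vector are excluded with a warning.
#'
#' @param assessments Assessment tibble (`participant_id`, `week`, `measure`,
#'   `total`, `items` list-column).
#' @return Numeric matrix with participant ids as row names.
#' @export
baseline_item_matrix <- function(assessments) {
  info <- measure_info()
  base <- dplyr::filter(assessments, .data$week == 0)
  pids <- sort(unique(base$participant_id))
  rows <- lapply(pids, function(pid) {
    v <- unlist(lapply(info$measure, function(m) {
      r <- base[base$participant_id == pid & base$measure == m, ]
      if (nrow(r) != 1 || is.null(r$items[[1]])) return(NULL)
      it <- r$items[[1]]
      if (length(it) != info$n_items[info$measure == m]) return(NULL)
      it
    }))
    if (length(v) == sum(info$n_items)) v else NULL
  })
  ok <- !vapply(rows, is.null, logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " participant(s) excluded for missing baseline items")
  }
  m <- do.call(rbind, rows[ok])
  rownames(m) <- pids[ok]
  colnames(m) <- unlist(lapply(seq_len(nrow(info)), function(i) {
    paste0(tolower(info$measure[i]), "_", seq_len(info$n_items[i]))
  }))
  m
}

#' Scan k-means inertia over a range of k
#'
#' Best-of-`n_init` k-means within-cluster sum of squares for each candidate
#' number of clusters, deterministic under the seed.
#'
#' @param item_matrix Baseline item matrix ([baseline_item_matrix()]).
#' @param k_range Candidate values of k.
#' @param n_init Random restarts per k.
#' @param seed RNG seed.
#' @return Tibble with `k` and `inertia`.
#' @export
scan_k <- function(item_matrix, k_range = 1:8, n_init = 50, seed = 1) {
  stopifnot(max(k_range) <= nrow(item_matrix))
  with_preserved_seed(seed, {
    inertia <- vapply(k_range, function(k) {
      suppressWarnings(stats::kmeans(item_matrix, centers = k, nstart = n_init,
                                     iter.max = 100))$tot.withinss
    }, numeric(1))
    tibble::tibble(k = as.integer(k_range), inertia = inertia)
  })
}

#' Elbow choice of k
#'
#' Operationalizes the elbow heuristic as the k with the largest second
#' difference of the inertia curve (the sharpest bend).
#'
#' @param scan Output of [scan_k()] over at least three consecutive k.
#' @return Integer k.
#' @export
elbow_k <- function(scan) {
  stopifnot(nrow(scan) >= 3)
  d2 <- diff(scan$inertia, differences = 2)
  scan$k[which.max(d2) + 1L]
}

# canonical profile names for the four-cluster solution, assigned from the
# per-cluster mean totals: lowest PHQ-8 is the minimal-symptom group, highest
# is multiple comorbidities, and the middle two split on relative SPIN vs
# GAD-7 elevation
.name_clusters <- function(means) {
  k <- nrow(means)
  nm <- paste0("cluster_", seq_len(k))
  if (k == 4) {
    nm[1] <- "minimal_symptom"
    nm[4] <- "multiple_comorbidities"
    mid <- c(2L, 3L)
    rel_spin <- means$spin[mid] / 68 - means$gad7[mid] / 21
    nm[mid[which.max(rel_spin)]] <- "depression_social_anxiety"
    nm[mid[which.min(rel_spin)]] <- "depression_anxiety"
  }
  nm
}

#' Assign participants to symptom-profile clusters
#'
#' k-means on the baseline item matrix. Cluster indices are relabeled in
#' ascending order of mean PHQ-8 total so the solution is reproducible up to
#' content, not initialization; for `k = 4` the clusters get the canonical
#' profile names (minimal symptom, depression and social anxiety, depression
#' and anxiety, multiple comorbidities).
#'
#' @inheritParams scan_k
#' @param k Number of clusters.
#' @return List: `assignments` (tibble `participant_id`, `cluster`,
#'   `cluster_name`), `centroids` (k x items), `means` (per-cluster mean
#'   totals per measure), `k`, `inertia`.
#' @export
assign_clusters <- function(item_matrix, k = 4, n_init = 50, seed = 1) {
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(item_matrix)) stop("k exceeds the number of participants")
  fit <- with_preserved_seed(seed, suppressWarnings(
    stats::kmeans(item_matrix, centers = k, nstart = n_init, iter.max = 100)
  ))
  info <- measure_info()
  idx <- split(seq_len(nrow(info)), info$measure)
  cols <- lapply(info$measure, function(m) {
    which(grepl(paste0("^", tolower(m), "_"), colnames(item_matrix)))
  })
  names(cols) <- info$measure
  means <- tibble::tibble(
    cluster = seq_len(k),
    phq8 = vapply(seq_len(k), function(c) sum(fit$centers[c, cols$PHQ8]), numeric(1)),
    gad7 = vapply(seq_len(k), function(c) sum(fit$centers[c, cols$GAD7]), numeric(1)),
    spin = vapply(seq_len(k), function(c) sum(fit$centers[c, cols$SPIN]), numeric(1))
  )
  ord <- order(means$phq8)
  relabel <- match(seq_len(k), ord)
  means <- means[ord, ]
  means$cluster <- seq_len(k)
  means$cluster_name <- .name_clusters(means)
  cl <- relabel[fit$cluster]
  list(
    assignments = tibble::tibble(
      participant_id = rownames(item_matrix),
      cluster = cl,
      cluster_name = means$cluster_name[cl]
    ),
    centroids = fit$centers[ord, , drop = FALSE],
    means = means,
    k = as.integer(k),
    inertia = fit$tot.withinss
  )
}
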