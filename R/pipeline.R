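#' Modularity trajectory of a recovery study
#'
#' Runs the network arm of the pipeline over every session of a recovery
#' study: builds the region-level functional network per day, takes the
#' spectral partition of the day-1 network (the reference parcellation), and
#' evaluates modularity of every day's network under that fixed partition.
#' Optionally a per-day greedy modularity-maximizing partition is evaluated
#' alongside.
#'
#' @param study A [simulate_recovery()] `recovery_study`, or a named list of
#'   `calcium_dataset`s keyed by day.
#' @param k Number of communities for the day-1 spectral partition.
#' @param params A [modularity_params()] object.
#' @param per_day_partition Also report modularity under a per-day greedy
#'   partition (default `FALSE`).
#' @param seed Seed for the spectral k-means.
#' @return Data frame with one row per day: `day`, `modularity` (fixed day-1
#'   partition), optional `modularity_refit`, `mean_connectivity`,
#'   `strong_ratio`. The day-1 partition is attached as attribute
#'   `partition`.
#' @export
recovery_modularity <- function(study, k = 3L, params = modularity_params(),
                                per_day_partition = FALSE, seed = 1L) {
  sessions <- if (inherits(study, "recovery_study")) study$sessions else study
  days <- as.numeric(names(sessions))
  nets <- lapply(sessions, region_network)
  part <- spectral_partition(nets[[1]], k = k, seed = seed)
  out <- data.frame(
    day = days,
    modularity = vapply(nets, function(nt) {
      common <- intersect(names(part$membership), nt$nodes)
      sub <- subset_network(nt, common)
      network_modularity(sub, list(membership = part$membership[common]),
                         params)
    }, numeric(1)),
    mean_connectivity = vapply(nets, mean_connectivity, numeric(1)),
    strong_ratio = vapply(nets, strong_ratio, numeric(1)))
  if (per_day_partition) {
    out$modularity_refit <- vapply(nets, function(nt) {
      network_modularity(nt, greedy_partition(nt, params), params)
    }, numeric(1))
  }
  rownames(out) <- NULL
  attr(out, "partition") <- part
  out
}

subset_network <- function(net, nodes) {
  idx <- match(nodes, net$nodes)
  structure(list(w = net$w[idx, idx, drop = FALSE], nodes = nodes,
                 level = net$level), class = "functional_network")
}

#' Responsive-neuron and decoding trajectories of a recovery study
#'
#' Per-day responsive-neuron detection, regional counts and decoding
#' accuracy, plus the temporally normalized region-by-day distribution of
#' responsive neurons.
#'
#' @param study A `recovery_study`.
#' @param det A [detection_params()] object.
#' @param folds,seed Cross-validation folds and seed for decoding.
#' @return List with `summary` (data frame: `day`, `n_responsive`,
#'   `accuracy`), `region_counts` (regions x days matrix) and
#'   `region_normalized` (same, each region scaled to its peak day).
#' @export
recovery_function <- function(study, det = detection_params(), folds = 4L,
                              seed = 1L) {
  sessions <- study$sessions
  days <- names(sessions)
  counts <- NULL; nresp <- numeric(0); acc <- numeric(0)
  for (d in days) {
    ds <- sessions[[d]]
    rs <- detect_responsive(ds, det)
    counts <- cbind(counts, region_counts(rs, ds))
    nresp <- c(nresp, sum(rs$union))
    acc <- c(acc, decoding_accuracy(trial_features(ds), folds = folds,
                                    seed = seed)$accuracy)
  }
  colnames(counts) <- days
  list(summary = data.frame(day = as.numeric(days), n_responsive = nresp,
                            accuracy = acc),
       region_counts = counts,
       region_normalized = region_time_normalize(counts))
}

#' Cross-modal lag analysis of a recovery study
#'
#' The longitudinal arm of the pipeline: normalizes both morphology
#' modalities to the day-1 baseline average, averages across animals,
#' interpolates to daily resolution, and scans the sliding-window
#' lag-correlation grid with the first modality's window fixed at day 1.
#'
#' @param study A `recovery_study`, or a tidy morphology data frame.
#' @param fixed_modality,sliding_modality Modality names (defaults:
#'   microglial intensity fixed, neuronal intensity sliding).
#' @param widths,max_lag Grid controls passed to [lag_correlation()].
#' @return A [lag_correlation()] result.
#' @export
recovery_lag_analysis <- function(study,
                                  fixed_modality = "microglial_intensity",
                                  sliding_modality = "neuronal_intensity",
                                  widths = c(7, 14, 21, 28, 35),
                                  max_lag = 20) {
  morph <- if (inherits(study, "recovery_study")) study$morphology else study
  norm <- normalize_to_baseline(morph, baseline_day = min(morph$day))
  daily_mean <- function(mod) {
    sel <- norm[norm$modality == mod, ]
    agg <- stats::aggregate(value ~ day, data = sel, FUN = mean)
    interpolate_daily(agg$day, agg$value)
  }
  lag_correlation(daily_mean(fixed_modality), daily_mean(sliding_modality),
                  widths = widths, max_lag = max_lag)
}
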