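#' Detection parameters for stimulus-responsive neurons
#'
#' @param stim_window Stimulus window length in seconds (default 2, the
#'   stimulus duration).
#' @param baseline_window Pre-stimulus baseline length in seconds; defaults
#'   to the stimulus window length.
#' @param k_sd Threshold multiplier on the baseline SD (default 3).
#' @param baseline_mode `"pooled"` (baseline statistics from the pooled
#'   pre-stimulus windows of all trials, the default) or `"per_orientation"`
#'   (pooled over that orientation's trials only).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(stim_window = 2, baseline_window = stim_window,
                             k_sd = 3,
                             baseline_mode = c("pooled", "per_orientation")) {
  if (stim_window <= 0) stop("stim_window must be positive")
  if (baseline_window <= 0) stop("baseline_window must be positive")
  if (k_sd <= 0) stop("k_sd must be positive")
  structure(list(stim_window = stim_window,
                 baseline_window = baseline_window, k_sd = k_sd,
                 baseline_mode = match.arg(baseline_mode)),
            class = "detection_params")
}

#' Per-trial stimulus and baseline frame windows
#'
#' Frame convention, used throughout the package: 0-based, half-open,
#' floor rounding. A trial with onset `t` seconds at rate `r` Hz occupies
#' stimulus frames `[floor(t * r), floor((t + stim_window) * r))` and
#' baseline frames of the `baseline_window` seconds immediately before the
#' onset, same convention.
#'
#' @param schedule A [build_schedule()] stimulus schedule.
#' @param frame_rate Imaging rate in Hz.
#' @param params A [detection_params()] object.
#' @return Data frame, one row per trial: `orientation`, `stim_start`,
#'   `stim_end`, `base_start`, `base_end` (0-based half-open frame bounds).
#' @examples
#' sched <- build_schedule(session_params(), seed = 1)
#' head(trial_windows(sched, 20, detection_params()))
#' @export
trial_windows <- function(schedule, frame_rate, params = detection_params()) {
  stopifnot(inherits(schedule, "stim_schedule"),
            inherits(params, "detection_params"))
  on <- schedule$onset
  if (min(on) < params$baseline_window)
    stop("baseline window does not fit before the first onset")
  data.frame(
    orientation = schedule$orientation,
    stim_start = floor(on * frame_rate),
    stim_end = floor((on + params$stim_window) * frame_rate),
    base_start = floor((on - params$baseline_window) * frame_rate),
    base_end = floor(on * frame_rate))
}

#' Detect stimulus-responsive neurons
#'
#' A neuron is responsive to an orientation when its mean dF/F over all of
#' that orientation's stimulus windows strictly exceeds its baseline mean
#' plus `k_sd` baseline standard deviations. Baseline statistics are taken
#' over the pooled pre-stimulus windows (population SD, divide-by-N); ties
#' at the threshold are not responsive, so a constant trace is never
#' responsive.
#'
#' @param dataset A [simulate_session()] `calcium_dataset` (or compatible
#'   list).
#' @param params A [detection_params()] object.
#' @return An object of class `responsive_set`: list with `flags` (logical
#'   n_neurons x n_orientations matrix), `union` (responsive to at least one
#'   orientation), `baseline_mean`, `baseline_sd`, and `params`.
#' @export
detect_responsive <- function(dataset, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  traces <- dataset$traces
  if (anyNA(traces)) stop("traces contain missing values")
  w <- trial_windows(dataset$schedule, dataset$frame_rate, params)
  n_frames <- ncol(traces)
  if (max(w$stim_end) > n_frames) stop("trial windows outside recording")
  oris <- attr(dataset$schedule, "orientations")

  frames_of <- function(start, end) {
    unique(unlist(mapply(function(s, e) (s + 1L):e, start, end,
                         SIMPLIFY = FALSE)))
  }
  pooled_base <- frames_of(w$base_start, w$base_end)
  if (length(pooled_base) < 2) stop("need at least 2 baseline frames")

  base_stats <- function(frames) {
    b <- traces[, frames, drop = FALSE]
    mu <- rowMeans(b)
    sigma <- sqrt(rowMeans((b - mu)^2))   # population (divide-by-N) SD
    list(mu = mu, sigma = sigma)
  }
  pooled <- base_stats(pooled_base)

  flags <- sapply(oris, function(th) {
    sel <- w$orientation == th
    stim <- frames_of(w$stim_start[sel], w$stim_end[sel])
    st <- if (params$baseline_mode == "per_orientation")
      base_stats(frames_of(w$base_start[sel], w$base_end[sel])) else pooled
    rowMeans(traces[, stim, drop = FALSE]) > st$mu + params$k_sd * st$sigma
  })
  dim(flags) <- c(nrow(traces), length(oris))
  colnames(flags) <- as.character(oris)
  structure(list(flags = flags, union = apply(flags, 1, any),
                 baseline_mean = pooled$mu, baseline_sd = pooled$sigma,
                 params = params),
            class = "responsive_set")
}

#' Count responsive neurons per brain region
#'
#' @param rset A [detect_responsive()] `responsive_set`.
#' @param dataset The `calcium_dataset` the set was computed from.
#' @param regions Optional `region_map`; defaults to the dataset's map.
#' @return Named integer vector, one count per region (including zeros);
#'   the counts sum to the size of the responsive union.
#' @export
region_counts <- function(rset, dataset, regions = dataset$region_map) {
  stopifnot(inherits(rset, "responsive_set"), inherits(regions, "region_map"))
  ids <- factor(dataset$region[rset$union],
                levels = regions$rects$id)
  out <- as.integer(table(ids))
  names(out) <- regions$rects$name
  out
}

#' Temporally normalize regional responsive-neuron counts
#'
#' Each region's day-series is divided by that region's maximum across days,
#' putting every region on a common `[0, 1]` scale so its temporal pattern
#' can be compared across regions. All-zero regions stay zero.
#'
#' @param counts Numeric matrix, regions x days (counts >= 0).
#' @return Matrix of the same shape with values in `[0, 1]`; each region
#'   with any nonzero count attains 1 at its peak day.
#' @export
region_time_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  mx <- apply(counts, 1, max)
  mx[mx == 0] <- 1
  sweep(counts, 1, mx, `/`)
}

#' @export
print.responsive_set <- function(x, ...) {
  cat(sprintf("<responsive_set> %d / %d neurons responsive (union)\n",
              sum(x$union), length(x$union)))
  invisible(x)
}
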