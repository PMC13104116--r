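#' Simulate a calcium-imaging session
#'
#' Generates a `calcium_dataset` emulating mesoscale dF/F recordings of
#' layer-2/3 neurons on a parcellated cortical sheet during drifting-grating
#' stimulation. Truly responsive neurons receive a boxcar stimulus drive
#' scaled by a von Mises orientation-tuning curve on the doubled angle
#' (period 180 degrees); the drive is convolved with a unit-gain exponential
#' calcium kernel. Community structure is injected through shared smoothed
#' Gaussian factors: one per community (`within_amplitude`) and one global
#' (`between_amplitude`), both expressed as their SD contribution to the
#' final trace. White observation noise is added last.
#'
#' @param params A [session_params()] object.
#' @param schedule A [build_schedule()] result consistent with `params`.
#' @param regions A [make_atlas()] region map on which neurons are placed.
#' @param seed Integer seed; the full dataset is reproducible given the seed.
#' @param community Optional integer vector (0-based, length `n_neurons`)
#'   overriding the default region-aligned community assignment, in which
#'   each region belongs wholly to one of `n_communities` contiguous blocks.
#' @return An object of class `calcium_dataset`: list with `traces`
#'   (n_neurons x n_frames dF/F matrix), `frame_rate`, `positions`
#'   (n_neurons x 2, micrometres), `region` (0-based region id per neuron),
#'   `region_map`, `schedule`, and `ground_truth` (list with `preferred`
#'   orientation, logical `responsive`, 0-based `community`).
#' @examples
#' p <- session_params(n_neurons = 20, n_sets = 1, reps_per_set = 2)
#' ds <- simulate_session(p, build_schedule(p, seed = 1),
#'                        make_atlas(K = 4), seed = 1)
#' dim(ds$traces)
#' @export
simulate_session <- function(params, schedule, regions, seed = 1L,
                             community = NULL) {
  stopifnot(inherits(params, "session_params"),
            inherits(schedule, "stim_schedule"),
            inherits(regions, "region_map"))
  if (params$noise_sd <= 0) stop("noise_sd must be positive")
  if (params$decay_tau <= 0) stop("decay_tau must be positive")
  set.seed(seed)
  n <- params$n_neurons
  rate <- params$frame_rate
  dur <- attr(schedule, "stim_duration")
  n_frames <- floor((max(schedule$onset) + dur + params$isi_range[2]) * rate)

  positions <- cbind(stats::runif(n, 0, regions$width),
                     stats::runif(n, 0, regions$height))
  region <- region_lookup(regions, positions[, 1], positions[, 2])

  if (is.null(community)) {
    # contiguous blocks of regions share a community
    K <- regions$n_regions
    region_comm <- as.integer(floor(seq_len(K) - 1) * params$n_communities / K)
    community <- region_comm[region + 1L]
  } else {
    community <- as.integer(community)
    if (length(community) != n) stop("community must have length n_neurons")
  }

  preferred <- sample(params$orientations, n, replace = TRUE)
  responsive <- stats::runif(n) < params$responsive_fraction

  # stimulus drive, boxcar per trial scaled by tuning
  drive <- matrix(0, n, n_frames)
  if (params$response_amplitude != 0 && any(responsive)) {
    idx_resp <- which(responsive)
    for (t in seq_len(nrow(schedule))) {
      fr <- stim_frames(schedule$onset[t], dur, rate)
      if (max(fr) > n_frames) stop("trial window outside recording")
      g <- tuning_curve(schedule$orientation[t], preferred[idx_resp],
                        params$kappa)
      drive[idx_resp, fr] <- drive[idx_resp, fr] +
        params$response_amplitude * g
    }
  }
  a <- exp(-1 / (rate * params$decay_tau))
  traces <- drive
  nz <- which(rowSums(abs(drive)) > 0)
  for (i in nz) traces[i, ] <- ca_filter(drive[i, ], a)

  if (params$within_amplitude > 0) {
    for (c_id in unique(community)) {
      f <- smooth_factor(n_frames, a)
      members <- community == c_id
      traces[members, ] <- sweep(traces[members, , drop = FALSE], 2,
                                 params$within_amplitude * f, `+`)
    }
  }
  if (params$between_amplitude > 0) {
    g <- smooth_factor(n_frames, a)
    traces <- sweep(traces, 2, params$between_amplitude * g, `+`)
  }
  traces <- traces + matrix(stats::rnorm(n * n_frames, 0, params$noise_sd),
                            n, n_frames)

  structure(list(
    traces = traces, frame_rate = rate, positions = positions,
    region = region, region_map = regions, schedule = schedule,
    ground_truth = list(preferred = preferred, responsive = responsive,
                        community = community)),
    class = "calcium_dataset")
}

#' Von Mises orientation tuning on the doubled angle
#'
#' `exp(kappa * (cos(2 * dtheta) - 1))`, equal to 1 at the preferred
#' orientation and decaying with angular distance on a 180-degree period.
#' As `kappa -> Inf` the curve tends to an indicator of the preferred
#' orientation.
#'
#' @param theta Stimulus orientation(s), degrees.
#' @param preferred Preferred orientation(s), degrees.
#' @param kappa Concentration (>= 0); `Inf` allowed.
#' @return Tuning gain in `(0, 1]` (exactly `0`/`1` when `kappa = Inf`).
#' @export
tuning_curve <- function(theta, preferred, kappa) {
  d <- (theta - preferred) * pi / 180
  if (is.infinite(kappa)) {
    as.numeric(cos(2 * d) >= 1 - 1e-12)
  } else {
    exp(kappa * (cos(2 * d) - 1))
  }
}

# unit-steady-state-gain exponential (AR(1)) calcium filter
ca_filter <- function(x, a) {
  (1 - a) * as.numeric(stats::filter(x, a, method = "recursive"))
}

# smoothed white noise rescaled to unit SD (a shared latent factor)
smooth_factor <- function(n_frames, a) {
  f <- as.numeric(stats::filter(stats::rnorm(n_frames), a,
                                method = "recursive"))
  s <- stats::sd(f)
  if (s == 0) return(rep(0, n_frames))
  (f - mean(f)) / s
}

# half-open stimulus frame window [floor(onset*rate), floor((onset+dur)*rate)),
# returned 1-based for matrix indexing
stim_frames <- function(onset, dur, rate) {
  lo <- floor(onset * rate)
  hi <- floor((onset + dur) * rate)
  if (hi <= lo) stop("empty stimulus window")
  (lo + 1L):hi
}

#' @export
print.calcium_dataset <- function(x, ...) {
  cat(sprintf(
    "<calcium_dataset> %d neurons x %d frames @ %g Hz, %d trials, %d regions\n",
    nrow(x$traces), ncol(x$traces), x$frame_rate, nrow(x$schedule),
    x$region_map$n_regions))
  invisible(x)
}
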