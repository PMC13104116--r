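#' Session parameters for the synthetic calcium generator
#'
#' Collects every knob of a simulated drifting-grating session. Defaults
#' follow the recording protocol emulated throughout the package: 20 Hz
#' imaging, four grating orientations (0/45/90/135 degrees) presented in
#' random order, three stimulus sets of eight repeats per orientation, 2 s
#' stimuli separated by 8-10 s inter-stimulus intervals.
#'
#' @param n_neurons Number of simulated layer-2/3 neurons.
#' @param frame_rate Imaging rate in Hz (> 0).
#' @param orientations Grating orientations in degrees.
#' @param n_sets Number of stimulus sets.
#' @param reps_per_set Repeats of each orientation within a set.
#' @param stim_duration Stimulus duration in seconds.
#' @param isi_range Length-2 numeric, inter-stimulus interval bounds in
#'   seconds; ISIs are drawn uniformly from this range.
#' @param kappa Von Mises concentration of orientation tuning on the doubled
#'   angle (period 180 degrees). Larger values give sharper tuning; 2 gives
#'   neurons that respond preferentially but not exclusively to one
#'   orientation.
#' @param response_amplitude Peak stimulus drive of a responsive neuron at
#'   its preferred orientation (dF/F units).
#' @param responsive_fraction Fraction of neurons that are truly
#'   stimulus-responsive, in `[0, 1]`. Applied per region.
#' @param n_communities Number of functional communities.
#' @param within_amplitude SD contribution of the community-shared factor to
#'   each trace (dF/F units).
#' @param between_amplitude SD contribution of the global factor shared by
#'   all neurons.
#' @param noise_sd SD of white observation noise added to each trace (> 0).
#' @param decay_tau Calcium-kernel exponential decay constant in seconds
#'   (> 0); the default 0.7 s approximates a fast genetically encoded
#'   calcium indicator.
#' @return A list of class `session_params`.
#' @export
session_params <- function(n_neurons = 200L,
                           frame_rate = 20,
                           orientations = c(0, 45, 90, 135),
                           n_sets = 3L,
                           reps_per_set = 8L,
                           stim_duration = 2,
                           isi_range = c(8, 10),
                           kappa = 2,
                           response_amplitude = 1,
                           responsive_fraction = 0.5,
                           n_communities = 3L,
                           within_amplitude = 0.15,
                           between_amplitude = 0.05,
                           noise_sd = 0.1,
                           decay_tau = 0.7) {
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (length(isi_range) != 2 || isi_range[1] > isi_range[2])
    stop("isi_range must be c(lo, hi) with lo <= hi")
  if (responsive_fraction < 0 || responsive_fraction > 1)
    stop("responsive_fraction must be in [0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (decay_tau <= 0) stop("decay_tau must be positive")
  if (n_sets < 1 || reps_per_set < 1) stop("n_sets and reps_per_set must be >= 1")
  structure(list(
    n_neurons = as.integer(n_neurons), frame_rate = frame_rate,
    orientations = orientations, n_sets = as.integer(n_sets),
    reps_per_set = as.integer(reps_per_set), stim_duration = stim_duration,
    isi_range = isi_range, kappa = kappa,
    response_amplitude = response_amplitude,
    responsive_fraction = responsive_fraction,
    n_communities = as.integer(n_communities),
    within_amplitude = within_amplitude,
    between_amplitude = between_amplitude,
    noise_sd = noise_sd, decay_tau = decay_tau), class = "session_params")
}

#' Build a randomized drifting-grating stimulus schedule
#'
#' Produces `length(orientations) * n_sets * reps_per_set` trials. Within
#' each set the orientation order is randomized; inter-stimulus intervals
#' are drawn uniformly from `isi_range`. The first onset is preceded by one
#' full ISI so that a pre-stimulus baseline window always fits.
#'
#' @param params A [session_params()] object.
#' @param seed Integer seed; the schedule is reproducible given the seed.
#' @return An object of class `stim_schedule`: a data frame with columns
#'   `onset` (s), `orientation` (deg), `isi` (s, the interval preceding the
#'   trial) and attributes `stim_duration` and `orientations`.
#' @examples
#' sched <- build_schedule(session_params(), seed = 1)
#' nrow(sched)            # 96 trials
#' table(sched$orientation)
#' @export
build_schedule <- function(params, seed = 1L) {
  stopifnot(inherits(params, "session_params"))
  set.seed(seed)
  n_ori <- length(params$orientations)
  per_set <- rep(params$orientations, params$reps_per_set)
  ori <- unlist(lapply(seq_len(params$n_sets), function(s) sample(per_set)))
  n_trials <- length(ori)
  isi <- stats::runif(n_trials, params$isi_range[1], params$isi_range[2])
  onset <- cumsum(isi + c(0, rep(params$stim_duration, n_trials - 1)))
  out <- data.frame(onset = onset, orientation = ori, isi = isi)
  attr(out, "stim_duration") <- params$stim_duration
  attr(out, "orientations") <- params$orientations
  class(out) <- c("stim_schedule", "data.frame")
  out
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf("<stim_schedule> %d trials, %d orientations, stim %gs\n",
              nrow(x), length(attr(x, "orientations")),
              attr(x, "stim_duration")))
  invisible(x)
}
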