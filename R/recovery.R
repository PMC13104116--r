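#' Define a post-operative recovery scenario
#'
#' A scenario bundles everything needed to simulate one longitudinal study:
#' calcium sessions at each post-operative timepoint (with per-day parameter
#' overrides encoding a designed network trajectory) and per-animal
#' morphology intensity series with a controllable cross-modal lag.
#'
#' The latent morphology trajectory is a Gaussian bump over days (microglial
#' activation rising to a peak and decaying) plus a small set of smooth
#' sinusoidal fluctuations shared by all animals — the day-to-day structure
#' that makes a lagged copy identifiable. The neuronal-intensity trajectory
#' is the microglial trajectory delayed by `lag_days`; per-animal
#' measurement noise is expressed relative to the latent trajectory's SD.
#'
#' @param days Session timepoints (post-operative days), strictly increasing
#'   within `[1, 56]`. Default `c(1, 4, 7, 10, 14, 21, 28, 56)`.
#' @param session Base [session_params()] shared by all days.
#' @param day_overrides Named list: `day_overrides[["21"]]` is a list of
#'   `session_params` fields overriding the base on day 21.
#' @param trough_day If non-`NULL`, convenience override generator: the
#'   global (between-community) coupling follows a Gaussian bump peaking at
#'   `trough_day` (SD 6 days, baseline `between_base`, peak amplitude
#'   `between_peak`), which produces a modularity trough at that day.
#' @param between_base,between_peak Baseline and added peak global-coupling
#'   SD used by `trough_day`.
#' @param n_animals Animals per morphology modality (default 3).
#' @param peak_day,amplitude,sigma,base Microglial latent bump parameters:
#'   peak day (default 10), bump amplitude, Gaussian SD in days, baseline
#'   intensity.
#' @param lag_days Cross-modal structural lag in days (>= 0; default 5): the
#'   neuronal trajectory is the microglial one delayed by this many days.
#'   The delayed peak must stay inside the 56-day window.
#' @param wiggle_amplitude Total amplitude of the shared smooth fluctuations,
#'   as a fraction of `amplitude` (default 0.25).
#' @param noise_sd Per-animal, per-day measurement noise SD as a fraction of
#'   the latent trajectory SD (default 0.05).
#' @param morpho_days Days at which morphology is measured (default daily,
#'   `1:56`, emulating the continuous post-interpolation series; a sparse
#'   vector emulates sparse imaging).
#' @param seed Integer seed from which all scenario randomness flows.
#' @return A list of class `recovery_scenario`.
#' @export
recovery_scenario <- function(days = c(1, 4, 7, 10, 14, 21, 28, 56),
                              session = session_params(),
                              day_overrides = list(),
                              trough_day = NULL,
                              between_base = 0.05, between_peak = 0.5,
                              n_animals = 3L,
                              peak_day = 10, amplitude = 2, sigma = 6,
                              base = 1,
                              lag_days = 5,
                              wiggle_amplitude = 0.25,
                              noise_sd = 0.05,
                              morpho_days = 1:56,
                              seed = 1L) {
  if (any(diff(days) <= 0) || min(days) < 1 || max(days) > 56)
    stop("days must be strictly increasing within [1, 56]")
  if (lag_days < 0) stop("lag_days must be >= 0")
  if (peak_day + lag_days > 56)
    stop("lag pushes the delayed trajectory peak outside [1, 56]")
  if (!is.null(trough_day)) {
    for (d in days) {
      ov <- day_overrides[[as.character(d)]] %||% list()
      ov$between_amplitude <- between_base +
        between_peak * exp(-(d - trough_day)^2 / (2 * 6^2))
      day_overrides[[as.character(d)]] <- ov
    }
  }
  structure(list(days = days, session = session,
                 day_overrides = day_overrides, n_animals = as.integer(n_animals),
                 peak_day = peak_day, amplitude = amplitude, sigma = sigma,
                 base = base, lag_days = lag_days,
                 wiggle_amplitude = wiggle_amplitude, noise_sd = noise_sd,
                 morpho_days = morpho_days, seed = as.integer(seed)),
            class = "recovery_scenario")
}

# latent morphology trajectory: bump + shared smooth fluctuations,
# analytic in day (defined for all real days, so delayed evaluation before
# day 1 is well-posed)
latent_trajectory <- function(scenario, wiggle) {
  force(scenario); force(wiggle)
  function(d) {
    v <- scenario$base +
      scenario$amplitude * exp(-(d - scenario$peak_day)^2 /
                                 (2 * scenario$sigma^2))
    for (j in seq_along(wiggle$a))
      v <- v + wiggle$a[j] * sin(2 * pi * d / wiggle$period[j] + wiggle$phase[j])
    v
  }
}

#' Simulate a full recovery study
#'
#' Generates one calcium session per timepoint (parameters from the scenario
#' base with per-day overrides, fresh schedule and noise each day) and the
#' per-animal longitudinal morphology series with the injected cross-modal
#' lag. All randomness derives from the scenario seed.
#'
#' @param scenario A [recovery_scenario()].
#' @param regions Optional `region_map` shared by all sessions; defaults to
#'   a 19-region atlas.
#' @param sessions If `FALSE`, generate only the morphology series (fast
#'   path for longitudinal-only analyses).
#' @return An object of class `recovery_study`: list with `sessions` (named
#'   by day), `morphology` (tidy data frame: `animal`, `modality`, `day`,
#'   `value`), `scenario`, and `latent` (the noise-free latent trajectory
#'   function, for scoring).
#' @export
simulate_recovery <- function(scenario, regions = make_atlas(19),
                              sessions = TRUE) {
  stopifnot(inherits(scenario, "recovery_scenario"))
  set.seed(scenario$seed)
  n_wig <- 4L
  wiggle <- list(
    a = stats::runif(n_wig, 0.3, 1) *
      scenario$wiggle_amplitude * scenario$amplitude,
    period = stats::runif(n_wig, 8, 30),
    phase = stats::runif(n_wig, 0, 2 * pi))
  B <- latent_trajectory(scenario, wiggle)
  sd_latent <- stats::sd(B(1:56))
  noise <- scenario$noise_sd * sd_latent

  morph <- do.call(rbind, lapply(seq_len(scenario$n_animals), function(a) {
    md <- scenario$morpho_days
    rbind(
      data.frame(animal = paste0("A", a), modality = "microglial_intensity",
                 day = md,
                 value = B(md) + stats::rnorm(length(md), 0, noise)),
      data.frame(animal = paste0("A", a), modality = "neuronal_intensity",
                 day = md,
                 value = B(md - scenario$lag_days) +
                   stats::rnorm(length(md), 0, noise)))
  }))

  session_list <- list()
  if (sessions) for (i in seq_along(scenario$days)) {
    d <- scenario$days[i]
    p <- scenario$session
    ov <- scenario$day_overrides[[as.character(d)]]
    for (nm in names(ov)) p[[nm]] <- ov[[nm]]
    class(p) <- "session_params"
    day_seed <- (scenario$seed * 131L + i * 7919L) %% 2147483629L
    sched <- build_schedule(p, seed = day_seed)
    session_list[[as.character(d)]] <- simulate_session(p, sched, regions,
                                                        seed = day_seed + 1L)
  }
  structure(list(sessions = session_list, morphology = morph,
                 scenario = scenario, latent = B),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf(
    "<recovery_study> %d sessions (days %s), %d animals, lag %g d\n",
    length(x$sessions), paste(x$scenario$days, collapse = ","),
    x$scenario$n_animals, x$scenario$lag_days))
  invisible(x)
}
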