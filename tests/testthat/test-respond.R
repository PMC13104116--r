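make_sched <- function(onsets, oris, dur = 2, isi = 8) {
  out <- data.frame(onset = onsets, orientation = oris,
                    isi = rep(isi, length(onsets)))
  attr(out, "stim_duration") <- dur
  attr(out, "orientations") <- sort(unique(oris))
  class(out) <- c("stim_schedule", "data.frame")
  out
}

make_ds <- function(traces, sched, rate = 20) {
  n <- nrow(traces)
  atlas <- make_atlas(2, width = 100, height = 100)
  structure(list(traces = traces, frame_rate = rate,
                 positions = cbind(rep(25, n), rep(50, n)),
                 region = rep(0L, n), region_map = atlas,
                 schedule = sched, ground_truth = NULL),
            class = "calcium_dataset")
}

test_that("trial windows follow the 0-based half-open floor convention", {
  sched <- make_sched(10, 0)
  w <- trial_windows(sched, 20, detection_params())
  expect_equal(w$stim_start, 200)
  expect_equal(w$stim_end, 240)
  expect_equal(w$base_start, 160)
  expect_equal(w$base_end, 200)
  w1 <- trial_windows(make_sched(3.5, 0), 1,
                      detection_params(stim_window = 2, baseline_window = 1))
  expect_equal(c(w1$stim_start, w1$stim_end), c(3, 5))
  expect_error(trial_windows(make_sched(1, 0), 20, detection_params()),
               "baseline")
})

test_that("constant traces are never responsive (strict threshold, zero SD)", {
  sched <- make_sched(c(10, 22), c(0, 90))
  traces <- matrix(1, 3, 500)
  rs <- detect_responsive(make_ds(traces, sched))
  expect_false(any(rs$flags))
  expect_equal(rs$baseline_sd, rep(0, 3))
})

test_that("a constructed supra-threshold response is detected for its orientation only", {
  sched <- make_sched(c(10, 22, 34, 46), c(0, 90, 0, 90))
  set.seed(1)
  tr <- matrix(rnorm(2 * 1200, 0, 0.1), 2, 1200)
  w <- trial_windows(sched, 20, detection_params())
  mu <- rowMeans(tr); sdv <- apply(tr, 1, sd)
  # neuron 1: lift stimulus frames of orientation 0 well above mu + 4 sd
  for (i in which(w$orientation == 0))
    tr[1, (w$stim_start[i] + 1):w$stim_end[i]] <- mu[1] + 6 * sdv[1]
  rs <- detect_responsive(make_ds(tr, sched))
  expect_true(rs$flags[1, "0"])
  expect_false(rs$flags[1, "90"])
  expect_false(any(rs$flags[2, ]))
  expect_equal(rs$union, c(TRUE, FALSE))
})

test_that("detection on i.i.d. noise fires well below 1% per orientation", {
  p <- session_params(n_neurons = 1000, response_amplitude = 0,
                      within_amplitude = 0, between_amplitude = 0,
                      noise_sd = 1)
  ds <- simulate_session(p, build_schedule(p, seed = 1), make_atlas(4),
                         seed = 1)
  rs <- detect_responsive(ds)
  expect_lt(max(colMeans(rs$flags)), 0.01)
})

test_that("detection is shift-invariant and scale-equivariant", {
  sched <- make_sched(c(10, 22, 34, 46), c(0, 90, 0, 90))
  set.seed(2)
  tr <- matrix(rnorm(5 * 1200), 5, 1200)
  w <- trial_windows(sched, 20, detection_params())
  for (i in which(w$orientation == 0))
    tr[2, (w$stim_start[i] + 1):w$stim_end[i]] <- 5
  base <- detect_responsive(make_ds(tr, sched))
  shifted <- detect_responsive(make_ds(tr + 100, sched))
  scaled <- detect_responsive(make_ds(tr * 3.7, sched))
  expect_identical(base$flags, shifted$flags)
  expect_identical(base$flags, scaled$flags)
})

test_that("raising the threshold multiplier never adds responsive neurons", {
  p <- session_params(n_neurons = 100, n_sets = 1, reps_per_set = 2,
                      responsive_fraction = 0.5, response_amplitude = 0.3,
                      noise_sd = 0.3)
  ds <- simulate_session(p, build_schedule(p, seed = 3), make_atlas(4),
                         seed = 3)
  prev <- detect_responsive(ds, detection_params(k_sd = 1))$flags
  for (k in c(2, 3, 5)) {
    cur <- detect_responsive(ds, detection_params(k_sd = k))$flags
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("regional counts partition the responsive union", {
  p <- session_params(n_neurons = 120, n_sets = 1, reps_per_set = 2)
  ds <- simulate_session(p, build_schedule(p, seed = 4), make_atlas(19),
                         seed = 4)
  rs <- detect_responsive(ds)
  counts <- region_counts(rs, ds)
  expect_length(counts, 19)
  expect_equal(sum(counts), sum(rs$union))
  # empty union -> all zeros
  rs0 <- rs
  rs0$union[] <- FALSE
  expect_equal(sum(region_counts(rs0, ds)), 0)
})

test_that("temporal normalization scales each region to its peak day", {
  counts <- rbind(r1 = c(2, 4, 8), r2 = c(0, 0, 0), r3 = c(5, 5, 5))
  norm <- region_time_normalize(counts)
  expect_equal(norm["r1", ], c(0.25, 0.5, 1.0), ignore_attr = TRUE)
  expect_equal(norm["r2", ], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(norm["r3", ], c(1, 1, 1), ignore_attr = TRUE)
  single <- region_time_normalize(cbind(c(3, 0)))
  expect_equal(as.vector(single), c(1, 0))
})
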