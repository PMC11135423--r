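test_that("acquisition geometry gives floor(duration/dt)+1 frames in every mode", {
  cases <- list(c(0.6, 90, 151), c(0.7, 90, 129), c(1, 10, 11), c(0.6, 0.6, 2))
  for (cs in cases) {
    acq <- acq_config(frame_interval = cs[1], duration = cs[2],
                      localization_sigma = 0, seed = 1)
    expect_identical(n_frames(acq), as.integer(cs[3]))
    for (spec in list(motion_spec("ballistic", velocity = 1),
                      motion_spec("brownian", D = 0.1),
                      motion_spec("confined", D = 0.1, corral_radius = 0.5))) {
      expect_length(simulate_track(spec, acq, "t")$t, cs[3])
    }
  }
  expect_error(acq_config(frame_interval = -1), "positive")
  expect_error(acq_config(duration = 0.1, frame_interval = 0.6), "duration")
})

test_that("noiseless ballistic track follows the closed form x = x0 + v t", {
  acq <- acq_config(localization_sigma = 0, seed = 42)
  tr <- simulate_track(motion_spec("ballistic", velocity = 1), acq, "b")
  expect_length(tr$x, 151L)
  expect_equal(tr$x, seq(0, 90, by = 0.6), tolerance = 1e-12)
  expect_equal(tr$y, rep(0, 151))

  tr2 <- simulate_track(motion_spec("ballistic", velocity = 0.5), acq, "b2")
  expect_equal(tr2$x[151] - tr2$x[1], 45.0, tolerance = 1e-12)
})

test_that("simulation is deterministic in (spec, acq, seed) and track order", {
  acq <- acq_config(seed = 9)
  spec <- motion_spec("brownian", D = 0.2)
  a <- simulate_track(spec, acq, "id7")
  b <- simulate_track(spec, acq, "id7")
  expect_identical(a, b)
  # a track's stream depends only on (seed, id), not on what was drawn before
  batch <- simulate_tracks(spec, acq, 5)
  expect_identical(batch[["brownian_3"]],
                   simulate_track(spec, acq, "brownian_3"))
  # different seed changes the draw
  acq2 <- acq_config(seed = 10)
  expect_false(identical(simulate_track(spec, acq2, "id7")$x, a$x))
})

test_that("Brownian increments recover the 2-D step variance 4*D*dt", {
  D <- 0.25; dt <- 0.6
  acq <- acq_config(frame_interval = dt, duration = dt * 10000,
                    localization_sigma = 0, seed = 101)
  tracks <- simulate_tracks(motion_spec("brownian", D = D), acq, 10)
  sq <- unlist(lapply(tracks, function(tr) diff(tr$x)^2 + diff(tr$y)^2))
  expect_gte(length(sq), 1e4)
  expected <- 4 * D * dt
  # mean of 1e5 squared steps: check both the 2% band and the 3-SE band
  se <- stats::sd(sq) / sqrt(length(sq))
  expect_lt(abs(mean(sq) - expected), 0.02 * expected)
  expect_lt(abs(mean(sq) - expected), 3 * se)
})

test_that("zero-diffusion Brownian track is stationary at its start position", {
  acq <- acq_config(localization_sigma = 0, seed = 3)
  tr <- simulate_track(motion_spec("brownian", D = 0,
                                   start_position = c(2, -1)), acq, "s")
  expect_true(all(tr$x == 2) && all(tr$y == -1))
})

test_that("confined positions never leave the corral", {
  acq <- acq_config(localization_sigma = 0, seed = 17)
  R <- 0.2
  tracks <- simulate_tracks(motion_spec("confined", D = 0.1,
                                        corral_radius = R), acq, 20)
  for (tr in tracks) {
    r <- sqrt((tr$x - tr$x[1])^2 + (tr$y - tr$y[1])^2)
    expect_lte(max(r), R + 1e-12)
  }
})

test_that("a huge corral reproduces the free Brownian track bit for bit", {
  acq <- acq_config(localization_sigma = 0.02, seed = 23)
  free <- simulate_track(motion_spec("brownian", D = 0.1), acq, "t")
  caged <- simulate_track(motion_spec("confined", D = 0.1,
                                      corral_radius = 1e6), acq, "t")
  expect_identical(free$x, caged$x)
  expect_identical(free$y, caged$y)
})

test_that("confined MSD at large lags stays below the (2R)^2 geometric bound", {
  acq <- acq_config(duration = 600, localization_sigma = 0, seed = 31)
  R <- 0.2
  tr <- simulate_track(motion_spec("confined", D = 0.1, corral_radius = R),
                       acq, "c")
  curve <- compute_msd(tr, max_lag_fraction = 0.25)
  expect_lte(max(curve$msd_um2), (2 * R)^2)
})

test_that("motion_spec validates its parameters", {
  expect_error(motion_spec("confined", D = 0.1, corral_radius = 0), "corral")
  expect_error(motion_spec("brownian", D = -1), ">= 0")
  expect_error(motion_spec("walk"), "arg")
})
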