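test_that("ND and LMD match hand-computed examples", {
  mono <- line_track("m", 6)
  expect_equal(compute_nd(mono), 6)
  expect_equal(compute_lmd(mono), 6)

  oab <- out_and_back_track("o", 3)
  expect_equal(compute_nd(oab), 0)
  expect_equal(compute_lmd(oab), 3)

  retro <- line_track("r", -4)
  expect_equal(compute_nd(retro), 4)

  mix <- trajectory("x", t = (0:2) * 0.6, x = c(0, -2, 1), y = c(0, 0, 0))
  expect_equal(compute_nd(mix), 1)
  expect_equal(compute_lmd(mix), 2)
})

test_that("nd <= lmd and both are translation- and reflection-invariant", {
  set.seed(5)
  for (i in 1:30) {
    tr <- random_track(paste0("d", i), sample(5:60, 1))
    nd <- compute_nd(tr); lmd <- compute_lmd(tr)
    expect_lte(nd, lmd + 1e-9)

    shift <- trajectory("s", tr$t, tr$x + 13.7, tr$y)
    flip <- trajectory("f", tr$t, -tr$x, tr$y)
    expect_equal(compute_nd(shift), nd, tolerance = 1e-12)
    expect_equal(compute_lmd(shift), lmd, tolerance = 1e-12)
    expect_equal(compute_nd(flip), nd, tolerance = 1e-12)
    expect_equal(compute_lmd(flip), lmd, tolerance = 1e-12)
    expect_identical(classify_directionality(nd, lmd),
                     displacement_features(shift)$directionality)
  }
})

test_that("directionality rules and boundary handling follow the published order", {
  thr <- motion_thresholds()
  expect_identical(classify_directionality(6, 6, thr), "directed")
  expect_identical(classify_directionality(0.2, 0.5, thr), "stationary")
  expect_identical(classify_directionality(2, 3, thr), "oscillatory")
  # strict inequalities: exact boundaries fall through to oscillatory
  expect_identical(classify_directionality(5, 5, thr), "oscillatory")
  expect_identical(classify_directionality(0.5, 1, thr), "oscillatory")
  expect_error(classify_directionality(-1, 0, thr), ">= 0")
})

test_that("noiseless fast ballistic tracks are always labelled directed", {
  acq <- acq_config(localization_sigma = 0, seed = 8)
  tracks <- simulate_tracks(motion_spec("ballistic", velocity = 0.3), acq, 20)
  labels <- vapply(tracks, function(tr) displacement_features(tr)$directionality, "")
  expect_true(all(labels == "directed"))  # v*T = 27 um > 5 um
})

test_that("principal-axis projection restores axial displacements of rotated tracks", {
  tr <- line_track("rot", 8, n = 40)
  th <- 0.7
  rot <- trajectory("rot", tr$t, cos(th) * tr$x - sin(th) * tr$y,
                    sin(th) * tr$x + cos(th) * tr$y)
  expect_lt(compute_nd(rot), 8)  # rotated frame under-reads the axial run
  back <- project_axial(rot)
  expect_equal(compute_nd(back), 8, tolerance = 1e-9)
  expect_equal(compute_lmd(back), 8, tolerance = 1e-9)
})
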