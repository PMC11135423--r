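test_that("compute_msd matches hand-enumerated pair averages", {
  tr <- trajectory("t1", t = c(0, 0.6, 1.2), x = c(0, 1, 2), y = c(0, 0, 0))
  curve <- compute_msd(tr, max_lag_fraction = 1)
  expect_equal(curve$lag_s, c(0.6, 1.2))
  expect_equal(curve$msd_um2, c(1.0, 4.0))
  expect_equal(curve$n_pairs, c(2L, 1L))

  zig <- trajectory("t2", t = (0:3) * 0.6, x = c(0, 1, 0, 1), y = rep(0, 4))
  curve2 <- compute_msd(zig, max_lag_fraction = 1)
  # lag 2 pairs are (x3 - x1) = 0 and (x4 - x2) = 0, hence exactly zero
  expect_equal(curve2$msd_um2, c(1.0, 0.0, 1.0))
  expect_equal(curve2$msd_um2, msd_brute_force(zig, 3), tolerance = 1e-15)

  still <- trajectory("t3", t = (0:9) * 0.6, x = rep(2, 10), y = rep(-1, 10))
  expect_true(all(compute_msd(still, 1)$msd_um2 == 0))
})

test_that("compute_msd equals the brute-force pair enumeration on random tracks", {
  set.seed(2024)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    tr <- random_track(paste0("r", i), n)
    frac <- sample(c(0.25, 0.5, 1), 1)
    curve <- compute_msd(tr, max_lag_fraction = frac)
    k_max <- max(1L, floor(frac * (n - 1)))
    expect_length(curve$msd_um2, k_max)
    expect_equal(curve$msd_um2, msd_brute_force(tr, k_max),
                 tolerance = 1e-12)
  }
})

test_that("the 25% lag cap still returns at least one lag on short tracks", {
  tr <- trajectory("s", t = c(0, 0.6, 1.2), x = c(0, 1, 0), y = c(0, 0, 0))
  curve <- compute_msd(tr, max_lag_fraction = 0.25)  # floor(0.25*2) = 0
  expect_length(curve$msd_um2, 1L)
  expect_equal(curve$lag_s, 0.6)
})

test_that("fit_anomalous recovers closed-form generating curves", {
  fit2 <- fit_anomalous(curve_from_function(function(tau) tau^2))
  expect_true(fit2$converged)
  expect_equal(unname(coef(fit2)), c(1, 2, 0), tolerance = 1e-3)

  fit1 <- fit_anomalous(curve_from_function(function(tau) 0.6 * tau))
  expect_equal(fit1$alpha, 1, tolerance = 1e-3)

  fit_b <- fit_anomalous(curve_from_function(function(tau) 0.5 * tau^0.4 + 0.2))
  expect_equal(unname(coef(fit_b)), c(0.5, 0.4, 0.2), tolerance = 1e-3)
})

test_that("degenerate and short curves are reported non-converged", {
  flat <- fit_anomalous(curve_from_function(function(tau) rep(2, length(tau))))
  expect_false(flat$converged)
  expect_identical(classify_alpha(flat), "ambiguous")

  short <- curve_from_function(function(tau) tau, tau = c(0.6, 1.2))
  expect_false(fit_anomalous(short)$converged)
  expect_error(fit_anomalous(curve_from_function(function(tau) tau * NaN)),
               "finite")
})

test_that("fit methods are consistent: predict, residuals, coef", {
  curve <- curve_from_function(function(tau) 0.3 * tau^1.4 + 0.1)
  fit <- fit_anomalous(curve)
  expect_equal(predict(fit), curve$msd_um2, tolerance = 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-6)
  expect_named(coef(fit), c("A", "alpha", "B"))
})

test_that("MSD scales as c^2 under dilation and alpha is scale-invariant", {
  set.seed(7)
  tr <- random_track("sc", 60)
  c2 <- 3.7
  tr_big <- trajectory("sc2", tr$t, tr$x * c2, tr$y * c2)
  a <- compute_msd(tr); b <- compute_msd(tr_big)
  expect_equal(b$msd_um2, a$msd_um2 * c2^2, tolerance = 1e-12)
  fa <- fit_anomalous(a); fb <- fit_anomalous(b)
  expect_equal(fa$alpha, fb$alpha, tolerance = 1e-6)
})

test_that("alpha classification uses strict published inequalities", {
  thr <- motion_thresholds()
  expect_identical(classify_alpha(1.8, thr), "active")
  expect_identical(classify_alpha(1.0, thr), "diffusive")
  expect_identical(classify_alpha(0.3, thr), "confined")
  # gap values and exact boundaries are ambiguous
  for (a in c(0.5, 0.7, 0.9, 1.1, 1.3, 1.5)) {
    expect_identical(classify_alpha(a, thr), "ambiguous")
  }
  expect_identical(classify_alpha(1.5 + 1e-9, thr), "active")
  expect_identical(classify_alpha(0.5 - 1e-9, thr), "confined")
})

test_that("every fit receives exactly one of the four labels", {
  set.seed(11)
  labels <- vapply(1:40, function(i) {
    classify_alpha(fit_anomalous(compute_msd(random_track(paste0("p", i),
                                                          sample(22:80, 1)))))
  }, "")
  expect_true(all(labels %in% c("active", "diffusive", "confined",
                                "ambiguous")))
})
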