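test_that("zone components partition the recording exactly", {
  sim <- simulate_recording(sim_config(n_channels = 2, n_cycles = 5,
                                       jitter = 0.2), seed = 9)
  rec <- sim$recording
  ann <- sim$annotation
  total <- numeric(nrow(rec$samples))
  for (m in seq_len(ann$n_cycles)) {
    for (k in 1:2) total <- total + zone_component(rec, ann, 1, m, k)
  }
  t <- sample_times(rec)
  on_support <- t >= ann$boundaries[1] &
    t <= ann$boundaries[length(ann$boundaries)]
  expect_identical(total[on_support], rec$samples[on_support, 1])
  expect_true(all(total[!on_support] == 0))
})

test_that("zone indicators are 0/1 on half-open windows", {
  ann <- ann5()
  expect_equal(zone_indicator(ann, 1, 1, c(0, 0.25, 0.5, 0.75)),
               c(1, 1, 0, 0))
  expect_equal(zone_indicator(ann, 2, 1, c(0.99, 1.0, 1.74, 1.75)),
               c(0, 1, 1, 0))
  # the final boundary closes the last cycle
  expect_equal(zone_indicator(ann, 2, 2, c(2.4999, 2.5)), c(1, 1))

  # sample-count example: zone (2,1) of [0,0.5,1,1.75,2.5] at 250 Hz
  rec <- multichannel_recording(rep(1, 626), fs = 250)
  comp <- zone_component(rec, ann, 1, 2, 1)
  expect_equal(sum(comp != 0), 188L)

  expect_error(zone_component(rec, ann, 1, 5, 1), "outside")
})

test_that("mean and moment estimators obey their exact reductions", {
  fx <- regular_recording(M = 6L, wave = function(t) rep(4, length(t)))
  rf <- rhythm_interpolant(fx$ann)
  grid <- phase_grid(fx$rec, fx$ann, "zone1")

  # constant c: mean c, initial order 3 = c^3, dispersion 0
  expect_true(all(estimate_mean(fx$rec, rf, grid, 1)$values == 4))
  expect_true(all(estimate_initial_moment(fx$rec, rf, grid, 1, 3)$values == 64))
  expect_true(all(estimate_dispersion(fx$rec, rf, grid, 1)$values == 0))

  # deterministic cyclic signal: zero dispersion at every phase
  fx2 <- regular_recording(M = 5L)
  rf2 <- rhythm_interpolant(fx2$ann)
  g2 <- phase_grid(fx2$rec, fx2$ann, "full")
  expect_equal(max(abs(estimate_dispersion(fx2$rec, rf2, g2, 1)$values)), 0)

  # initial moment of order 1 is the mean
  sim <- simulate_recording(sim_config(n_channels = 1, n_cycles = 8), seed = 3)
  rf3 <- rhythm_interpolant(sim$annotation)
  g3 <- phase_grid(sim$recording, sim$annotation, "zone2")
  expect_identical(estimate_initial_moment(sim$recording, rf3, g3, 1, 1)$values,
                   estimate_mean(sim$recording, rf3, g3, 1)$values)
})

test_that("printed normalizations give d = ((M-1)/M) * central2 exactly", {
  sim <- simulate_recording(sim_config(n_channels = 2, n_cycles = 13,
                                       jitter = 0.15), seed = 17)
  rf <- rhythm_interpolant(sim$annotation)
  M <- sim$annotation$n_cycles
  for (zone in c("zone1", "zone2")) {
    grid <- phase_grid(sim$recording, sim$annotation, zone)
    d <- estimate_dispersion(sim$recording, rf, grid, 2)$values
    c2 <- estimate_central_moment(sim$recording, rf, grid, 2, 2)$values
    expect_equal(d, (M - 1) / M * c2, tolerance = 1e-14)
  }
})

test_that("single-cycle mean equals the first-cycle signal on the grid", {
  # M = 1 is not interpolatable, so use M = 2 and check the n = 0 row logic
  fs <- 250
  ann <- regular_annotation(2L, d = 1)
  x <- rnorm(4 * fs + 1)
  rec <- multichannel_recording(x, fs)
  rf <- rhythm_interpolant(ann)
  grid <- phase_grid(rec, ann, "full")
  X <- align_cycles(rec, rf, grid, 1)
  expect_equal(colMeans(X[1, , drop = FALSE]), x[seq_len(2 * fs)],
               ignore_attr = TRUE)
})

test_that("mixed estimators reduce to plain moments and known covariances", {
  sim <- simulate_recording(
    sim_config(n_channels = 2, n_cycles = 30, jitter = 0, rho = 0,
               mean_profiles = list(1.5, 2.5), sd_profiles = list(1, 1)),
    seed = 29)
  rf <- rhythm_interpolant(sim$annotation)
  grid <- phase_grid(sim$recording, sim$annotation, "zone1")

  # k = 1, M1 = 1: exactly the plain initial moment of the same order
  for (ord in c(1L, 3L)) {
    mi <- estimate_mixed_initial(sim$recording, rf, grid,
                                 channels = 1, exponents = ord)
    expect_equal(mi$values,
                 estimate_initial_moment(sim$recording, rf, grid, 1,
                                         ord)$values,
                 tolerance = 1e-14)
  }

  # constant signals: cross-channel product moment is the product
  fxc <- regular_recording(M = 4L, n_channels = 2L,
                           wave = function(t) rep(3, length(t)))
  rfc <- rhythm_interpolant(fxc$ann)
  gc <- phase_grid(fxc$rec, fxc$ann, "zone1")
  mm <- estimate_mixed_initial(fxc$rec, rfc, gc, channels = c(1, 2),
                               exponents = c(1, 1))
  expect_true(all(mm$values == 9))
  expect_equal(mm$order, 2L)

  # deterministic signal: mixed central moment identically zero
  mc0 <- estimate_mixed_central(fxc$rec, rfc, gc, channels = c(1, 2),
                                exponents = c(1, 1))
  expect_true(all(mc0$values == 0))

  # independent zero-mean channels: |cross moment| within the CLT bound
  sim2 <- simulate_recording(
    sim_config(n_channels = 2, n_cycles = 500, jitter = 0, rho = 0,
               zone_durations = c(0.25, 0.25),
               mean_profiles = list(0, 0), sd_profiles = list(1, 1)),
    seed = 101)
  rf2 <- rhythm_interpolant(sim2$annotation)
  g2 <- phase_grid(sim2$recording, sim2$annotation, "zone1")
  cross <- estimate_mixed_central(sim2$recording, rf2, g2,
                                  channels = c(1, 2), exponents = c(1, 1))
  expect_lt(max(abs(cross$values)), 4 / sqrt(500))

  # shared noise component: covariance recovered
  sim3 <- simulate_recording(
    sim_config(n_channels = 2, n_cycles = 500, jitter = 0, rho = 0,
               zone_durations = c(0.25, 0.25),
               mean_profiles = list(0, 0), sd_profiles = list(1, 1),
               shared_sd = 0.5),
    seed = 67)
  rf3 <- rhythm_interpolant(sim3$annotation)
  g3 <- phase_grid(sim3$recording, sim3$annotation, "zone1")
  cov12 <- estimate_mixed_central(sim3$recording, rf3, g3,
                                  channels = c(1, 2), exponents = c(1, 1))
  expect_equal(mean(cov12$values), 0.25, tolerance = 0.3)
  expect_lt(abs(mean(cov12$values) - 0.25), 0.08)
})

test_that("mixed-moment argument validation", {
  sim <- simulate_recording(sim_config(n_channels = 1, n_cycles = 5), seed = 1)
  rf <- rhythm_interpolant(sim$annotation)
  grid <- phase_grid(sim$recording, sim$annotation, "zone1")
  expect_error(estimate_mixed_initial(sim$recording, rf, grid, 1, 1, M1 = 5),
               "M1")
  expect_error(estimate_mixed_initial(sim$recording, rf, grid, c(1, 1),
                                      c(1, 1), lag_cycles = c(1, 0)),
               "lag_cycles\\[1\\]")
  expect_error(estimate_mixed_initial(sim$recording, rf, grid, c(1, 1),
                                      c(1, 1), lag_cycles = c(0, 2), M1 = 2),
               "M1")
})

test_that("estimates are invariant to re-anchoring the phase grid", {
  # estimates from a grid shifted one cycle forward agree with the original
  # within Monte-Carlo error (the model's shift invariance)
  sim <- simulate_recording(
    sim_config(n_channels = 1, n_cycles = 200, jitter = 0, rho = 0,
               zone_durations = c(0.5, 0.5),
               mean_profiles = list(mean_profile(2, 1, 1), 0),
               sd_profiles = list(1, 1)),
    seed = 77)
  rec <- sim$recording
  ann <- sim$annotation
  rf <- rhythm_interpolant(ann)
  g1 <- phase_grid(rec, ann, "zone1")
  m1 <- estimate_mean(rec, rf, g1, 1)

  # re-anchored: drop cycle 1, start the annotation at cycle 2
  ann2 <- cycle_annotation(ann$boundaries[-(1:2)])
  rf2 <- rhythm_interpolant(ann2)
  g2 <- phase_grid(rec, ann2, "zone1")
  m2 <- estimate_mean(rec, rf2, g2, 1)
  expect_equal(mean(abs(m1$values - m2$values)), 0, tolerance = 0.05)
})
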