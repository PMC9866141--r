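test_that("spectrum of simple estimates has the expected energy layout", {
  # constant estimate: all energy in the DC bin
  sp <- moment_spectrum(fake_estimate(rep(2.5, 100)))
  expect_equal(sp$cumulative_energy_fraction[1], 1)
  expect_equal(sp$magnitudes[1], 2.5)

  # pure tone on bin j: all non-DC energy in that bin
  v <- sin(2 * pi * 7 * (0:199) / 200)
  sp <- moment_spectrum(fake_estimate(v))
  expect_equal(sp$magnitudes[8], 0.5, tolerance = 1e-12)   # |X_j|/P = A/2
  others <- sp$energy[-8]
  expect_lt(sum(others) - sp$energy[1], 1e-20)

  # frequencies start at DC and increase
  expect_equal(sp$frequencies[1], 0)
  expect_true(all(diff(sp$frequencies) > 0))
})

test_that("Parseval: spectral energy equals mean-square grid energy", {
  set.seed(19)
  for (P in c(500L, 501L)) {    # even and odd lengths
    v <- rnorm(P)
    sp <- moment_spectrum(fake_estimate(v))
    expect_equal(sum(sp$energy), mean(v^2), tolerance = 1e-9)
    expect_equal(sp$cumulative_energy_fraction[length(sp$energy)], 1,
                 tolerance = 1e-12)
    expect_true(all(diff(sp$cumulative_energy_fraction) >= -1e-15))
  }
})

test_that("non-uniform phase grids are rejected", {
  est <- fake_estimate(rnorm(50))
  est$phase[10] <- est$phase[10] + 0.001
  expect_error(moment_spectrum(est), "uniform")
})

test_that("Bessel selection keeps the minimal sufficient prefix", {
  # flat 100-bin spectrum at 0.95: K = 95
  flat <- structure(
    list(magnitudes = rep(1, 100), energy = rep(1, 100),
         cumulative_energy_fraction = cumsum(rep(0.01, 100)),
         frequencies = 0:99,
         source = list(kind = "mean", order = 1L, zone = "zone1")),
    class = "spectrum_estimate")
  expect_equal(select_leading(flat, 0.95)$K, 95L)

  # DC-only spectrum: K = 1
  sp <- moment_spectrum(fake_estimate(rep(1, 64)))
  fv <- select_leading(sp, 0.95)
  expect_equal(fv$K, 1L)
  expect_equal(fv$energy_captured, 1)

  # geometric bin energies 2^-j: 1 - 2^-K >= 0.95 first at K = 5
  e <- 2^-(1:30)
  geom <- structure(
    list(magnitudes = sqrt(e), energy = e,
         cumulative_energy_fraction = cumsum(e) / sum(e),
         frequencies = 0:29,
         source = list(kind = "mean", order = 1L, zone = "zone1")),
    class = "spectrum_estimate")
  expect_equal(select_leading(geom, 0.95)$K, 5L)

  expect_error(select_leading(geom, 0), "threshold")
  expect_error(select_leading(geom, 1.2), "threshold")
})

test_that("selection is minimal and monotone in the threshold", {
  set.seed(5)
  sim <- simulate_recording(sim_config(n_channels = 1, n_cycles = 20),
                            seed = 13)
  rf <- rhythm_interpolant(sim$annotation)
  grid <- phase_grid(sim$recording, sim$annotation, "zone2")
  sp <- moment_spectrum(estimate_initial_moment(sim$recording, rf, grid, 1, 2))
  prevK <- 0L
  for (thr in c(0.5, 0.8, 0.9, 0.95, 0.99, 1.0)) {
    fv <- select_leading(sp, thr)
    expect_gte(fv$K, prevK)
    expect_gte(fv$energy_captured, thr - 1e-9)
    if (fv$K > 1L) {
      expect_lt(sp$cumulative_energy_fraction[fv$K - 1L], thr)
    }
    prevK <- fv$K
  }
})

test_that("mean absolute distance matches hand computations", {
  a <- fake_estimate(c(1, 2, 3))
  b <- fake_estimate(c(2, 2, 5))
  expect_equal(mean_absolute_distance(a, b), 1.0)
  expect_equal(mean_absolute_distance(a, a), 0)
  # constant offset delta -> delta
  d <- fake_estimate(c(1, 2, 3) + 0.75)
  expect_equal(mean_absolute_distance(a, d), 0.75)
  # kind mismatch is an error
  expect_error(
    mean_absolute_distance(a, fake_estimate(1:3, kind = "dispersion",
                                            order = 2L)),
    "cannot compare")
  # unequal lengths: resampled onto the shorter grid
  long <- fake_estimate(seq(0, 1, length.out = 9))
  short <- fake_estimate(seq(0, 1, length.out = 5))
  expect_equal(mean_absolute_distance(long, short), 0, tolerance = 1e-12)
})

test_that("MAD is a pseudometric on random estimate triples", {
  set.seed(37)
  for (rep in 1:20) {
    a <- fake_estimate(rnorm(40))
    b <- fake_estimate(rnorm(40))
    c <- fake_estimate(rnorm(40))
    dab <- mean_absolute_distance(a, b)
    dba <- mean_absolute_distance(b, a)
    expect_equal(dab, dba)
    expect_gte(dab, 0)
    expect_lte(dab, mean_absolute_distance(a, c) +
                 mean_absolute_distance(c, b) + 1e-12)
  }
})

test_that("sensitivity report has the documented shape and row order", {
  sim <- simulate_recording(sim_config(n_channels = 3, n_cycles = 12),
                            seed = 21)
  rf <- rhythm_interpolant(sim$annotation)
  rep <- sensitivity_report(sim$recording, rf, sim$annotation)
  expect_equal(dim(rep$time), c(6L, 3L))
  expect_equal(dim(rep$spectral), dim(rep$time))
  expect_equal(rownames(rep$time),
               c("initial4", "central4", "initial3", "initial2",
                 "dispersion", "mean"))
  expect_true(all(rep$time >= 0))
  expect_true(all(rep$spectral >= 0))

  path <- withr::local_tempfile(fileext = ".csv")
  write_sensitivity(rep, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 6L)
  expect_equal(ncol(back), 7L)   # name + 3 time + 3 spectral
})

test_that("feature vectors serialize to JSON faithfully", {
  sp <- moment_spectrum(fake_estimate(sin(2 * pi * (0:99) / 100) + 2))
  fv <- select_leading(sp, 0.95)
  path <- withr::local_tempfile(fileext = ".json")
  write_features(fv, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$K, fv$K)
  expect_equal(back$coefficients, fv$coefficients)
  expect_equal(back$threshold, 0.95)
})
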