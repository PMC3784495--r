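test_that("pink noise is reproducible, exactly scaled and plantable", {
  a <- pink_noise(1024, seed = 3)
  b <- pink_noise(1024, seed = 3)
  expect_identical(a$values, b$values)        # bit reproducible
  expect_false(identical(a$values, pink_noise(1024, seed = 4)$values))
  # realized MSF equals the requested value exactly (rescaling)
  for (beta in c(0, 1, 1.7)) {
    pn <- pink_noise(2048, beta = beta, msf = 0.37, seed = 5)
    expect_equal(mean((pn$values - mean(pn$values))^2), 0.37,
                 tolerance = 1e-9)
  }
  # planted component on zero noise: exact round trip
  pn0 <- pink_noise(512, msf = 0, seed = 1,
                    planted = list(k = 16, amplitude = 1.7, phase = -0.4))
  br <- band_reconstruct(pn0, 16)
  expect_equal(br$amplitude, 1.7, tolerance = 1e-9)
  expect_equal(br$phase, -0.4, tolerance = 1e-9)
  # the caller's RNG stream is untouched
  set.seed(99); r1 <- rnorm(1)
  set.seed(99); invisible(pink_noise(64, seed = 7)); r2 <- rnorm(1)
  expect_identical(r1, r2)
})

test_that("fitted spectral exponents track the generator's beta", {
  # white noise: slope ~ 0; pink noise: slope ~ -1 (30-seed means)
  for (beta in c(0, 1)) {
    slopes <- vapply(1:30, function(s) {
      pn <- pink_noise(16000, beta = beta, seed = 200 + s)
      fit_baseline(power_spectrum(pn), exclude_low = 10)$slope
    }, 0)
    expect_equal(mean(slopes), -beta, tolerance = 0.1)
  }
})

test_that("circular generation produces rotamer-like spectra", {
  # all-zero spec: constant angle
  flat <- synth_circular(256, base = 45, seed = 1)
  expect_equal(flat$angles, rep(45, 256))
  # planted oscillation only: power concentrated at the planted k
  osc <- synth_circular(512, base = 0, seed = 2,
                        planted = list(k = 20, amplitude = 6, phase = 0))
  cd <- circular_density(osc)
  expect_equal(which.max(cd$msf_contrib), 20)
  # jumps only: power concentrated in the lowest components
  jmp <- synth_circular(4096, base = -60, seed = 3,
                        jumps = list(targets = c(-60, 60, 180),
                                     rate = 1.5))
  cdj <- circular_density(jmp)
  expect_gt(sum(cdj$msf_contrib[1:5]), sum(cdj$msf_contrib[20:24]))
  expect_true(all(jmp$angles > -180 & jmp$angles <= 180))
})

test_that("forcing schedules are on-bin triangles without even harmonics", {
  s <- target_schedule(5000, 16, 1)
  expect_equal(s$f0, 0.2)
  ser <- schedule_series(s)
  expect_equal(length(ser$values), 80000)
  # extrema at half-period boundaries
  expect_equal(ser$values[1], 0)
  expect_equal(ser$values[2501], 1)
  expect_equal(max(ser$values), 1)
  # fundamental at component 16 = 0.2 ns^-1
  ff <- forcing_fundamental(s)
  expect_equal(ff$k, 16)
  expect_equal(ff$f0, 0.2)
  expect_equal(ff$amplitude, 4 / pi^2, tolerance = 1e-3)
  # even harmonics of the symmetric triangle vanish
  X <- fft(ser$values - mean(ser$values))
  odd <- Mod(X[16 + 1])
  evens <- Mod(X[c(32, 64) + 1])
  expect_lt(max(evens), 1e-9 * odd)
  expect_error(target_schedule(1001.5, 4, 2), "multiple of dt")
})

test_that("the unforced network obeys equipartition on a single bond", {
  # two beads, one spring: Boltzmann predicts var(|r| - r0) = kT / k_net
  vs <- vapply(1:3, function(s) {
    sp <- toy_network_spec(n_beads = 2, restrained = 1, k_tmd = 0,
                           schedule = target_schedule(1000, 10, 1),
                           integration_dt = 0.25, seed = s)
    sim <- toy_tmd_simulate(sp)
    var(distance_series(sim$traj, c(1, 2))$values[-(1:2000)])
  }, 0)
  kT_over_k <- 0.593 / 2
  # within discretization accuracy of the Euler-Maruyama integrator
  expect_equal(mean(vs), kT_over_k, tolerance = 0.1)
})

test_that("driven networks peak at the forcing frequency and propagate", {
  spec <- toy_network_spec(schedule = target_schedule(2500, 12, 1),
                           seed = 2)
  sim <- toy_tmd_simulate(spec)
  expect_equal(n_frames(sim$traj), 30000)
  # restrained bead: dominant peak (above the first 10 components) at f0
  b <- spec$restrained[3]
  sdb <- power_spectrum_group(lapply(c("x", "y", "z"), function(ax)
    coordinate_series(sim$traj, b, ax)))
  idx <- which.max(sdb$msf_contrib[-(1:10)]) + 10
  expect_equal(sdb$frequencies[idx], spec$schedule$f0)
  # halving the period doubles the peak frequency
  spec2 <- toy_network_spec(schedule = target_schedule(1250, 24, 1),
                            seed = 2)
  sim2 <- toy_tmd_simulate(spec2)
  sdb2 <- power_spectrum_group(lapply(c("x", "y", "z"), function(ax)
    coordinate_series(sim2$traj, b, ax)))
  idx2 <- which.max(sdb2$msf_contrib[-(1:10)]) + 10
  expect_equal(sdb2$frequencies[idx2], 2 * spec$schedule$f0)
  # propagation: beads adjacent to the restrained subset show a larger
  # forcing-frequency excess than distant beads
  dens <- lapply(1:60, function(a) power_spectrum_group(
    lapply(c("x", "y", "z"), function(ax)
      coordinate_series(sim$traj, a, ax)), id = paste0("b", a)))
  tab <- scan_variables(dens, spec$schedule$f0)
  adjacent <- c(24:27, 34:37); distant <- c(1:6, 55:60)
  expect_gt(mean(tab$excess[adjacent]), mean(tab$excess[distant]))
  expect_true(all(tab$flag05[adjacent]))
  # reproducibility of the whole simulation
  sim_b <- toy_tmd_simulate(spec)
  expect_identical(sim$traj$xyz, sim_b$traj$xyz)
})

test_that("benchmark sets carry recoverable planted truth", {
  # very high SNR: the planted subset is recovered exactly, and the
  # four planted phase groups land in their quadrant clusters
  bench <- benchmark_set(n_vars = 24, n_perturbed = 8, snr = 1e6,
                         seed = 7, n = 4096)
  dens <- lapply(bench$series, power_spectrum)
  tab <- scan_variables(dens, bench$f_b)
  expect_equal(tab$flag01, bench$truth$perturbed)
  ass <- lapply(which(bench$truth$perturbed), function(v) {
    variable_phase(band_reconstruct(bench$series[[v]], 16),
                   forcing_phase = 0, id = bench$truth$id[v])
  })
  cl <- quadrant_cluster(phase_table(ass))
  expect_equal(cl$cluster, bench$truth$cluster[bench$truth$perturbed])
  # circular variables are generated when requested
  bench2 <- benchmark_set(n_vars = 6, n_perturbed = 3, seed = 1,
                          n = 1024, n_circular = 2)
  expect_s3_class(bench2$series[[1]], "circular_series")
  expect_s3_class(bench2$series[[6]], "scalar_series")
  # no perturbations: false-positive rate stays near the nominal level
  bench0 <- benchmark_set(n_vars = 60, n_perturbed = 0, seed = 11,
                          n = 4096)
  tab0 <- scan_variables(lapply(bench0$series, power_spectrum),
                         bench0$f_b)
  expect_lte(mean(tab0$flag05), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
})
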