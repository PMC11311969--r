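test_that("the generator is deterministic given the seed", {
  a <- small_synth(seed = 3)
  b <- small_synth(seed = 3)
  expect_equal(a$lipids, b$lipids)
  expect_equal(a$probe, b$probe)
  expect_equal(a$waters, b$waters)
  c <- small_synth(seed = 4)
  expect_false(isTRUE(all.equal(a$probe$tdm_x, c$probe$tdm_x)))
})

test_that("the lateral box area is exactly lipids-per-leaflet times the target APL", {
  p <- synth_params(n_lipids_per_leaflet = 64, apl_target = 52.3,
                    n_waters = 20, n_frames = 2, n_carbons = 2)
  traj <- generate_trajectory(p)
  expect_equal(traj$box$lx[1] * traj$box$ly[1], 64 * 0.523, tolerance = 1e-12)
  expect_error(synth_params(apl_target = 39), "overlap")
})

test_that("a zero cone semiangle freezes the dipole and pins r(t) at 0.4", {
  traj <- generate_trajectory(synth_params(n_lipids_per_leaflet = 4, n_waters = 20,
                                           n_frames = 15, n_carbons = 2,
                                           tdm_cone_semiangle = 0, seed = 9))
  expect_true(all(traj$probe$tdm_z == 1))
  r <- anisotropy_decay(traj, max_lag = 1)$curve$y
  expect_equal(r, rep(0.4, length(r)))
})

test_that("emission tables follow the configured Gaussian wavelength law", {
  p0 <- synth_params(emission_mean = 360, emission_sigma = 0, seed = 5)
  em <- generate_emission_table(p0, 50)
  expect_equal(nrow(em), 50)
  expect_true(all(em$wavelength_nm == 360))

  p1 <- synth_params(emission_mean = 360, emission_sigma = 8, seed = 5)
  big <- generate_emission_table(p1, 10000)
  expect_lt(abs(mean(big$wavelength_nm) - 360), 0.3)   # ~3.7 standard errors
  expect_true(all(big$wavelength_nm > 200))
  expect_error(generate_emission_table(p1, 0), "n_records")
})

test_that("plateau-carbon order parameters hit the generator target within 0.02", {
  p <- synth_params(n_lipids_per_leaflet = 32, scd_plateau_target = -0.25,
                    n_waters = 10, n_frames = 100, seed = 21)
  traj <- generate_trajectory(p)
  for (tail in c("sn1", "sn2")) {
    prof <- deuterium_order_parameters(traj, tail)
    expect_lt(abs(mean(prof$scd[prof$carbon %in% 2:10]) - (-0.25)), 0.02)
  }
})

test_that("the wobbling dipole reproduces the cone-model anisotropy plateau", {
  for (theta_c in c(25, 40)) {
    u <- simulate_dipole_trajectory(3000, 0.05, 2.0, theta_c, seed = theta_c)
    res <- anisotropy_decay(u, max_lag = 60, dt = 0.05)
    ct <- cos(theta_c * pi / 180)
    expect_lt(abs(res$plateau - 0.4 * (ct * (1 + ct) / 2)^2), 0.03)
  }
})

test_that("the water-orientation statistic relaxes with the configured time constant", {
  p <- synth_params(n_lipids_per_leaflet = 16, n_waters = 1500, n_carbons = 2,
                    n_frames = 200, dt = 0.1, water_relax_time = 2,
                    equilibrated_orientation_mean = -0.2, seed = 31)
  traj <- generate_trajectory(p)
  fit <- fit_solvent_relaxation(solvent_orientation(traj),
                                value = "orientation_per_water")
  expect_true(fit$converged)
  expect_lt(abs(fit$relax_time - 2) / 2, 0.15)
  expect_lt(abs(fit$asymptote - (-0.2)), 0.05)
})
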