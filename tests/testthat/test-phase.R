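test_that("area per lipid is lateral area over lipids per leaflet, in A^2", {
  traj <- toy_trajectory(n_frames = 3, n_per_leaflet = 64, lx = 6.4, ly = 5.23)
  apl <- area_per_lipid(traj)
  expect_equal(apl$apl, rep(52.3, 3), tolerance = 1e-12)
  expect_equal(attr(apl, "mean_apl"), 52.3, tolerance = 1e-12)
  # counting the probe as a lipid lowers the value
  expect_lt(attr(area_per_lipid(traj, count_probe = TRUE), "mean_apl"), 52.3)

  uneq <- traj
  uneq$lipids <- uneq$lipids[-1, ]
  expect_error(area_per_lipid(uneq), "unequal")
  expect_silent(area_per_lipid(uneq, allow_unequal = TRUE))
})

test_that("generator output returns the target APL exactly", {
  traj <- generate_trajectory(synth_params(n_lipids_per_leaflet = 16, apl_target = 57,
                                           n_waters = 10, n_frames = 2, n_carbons = 2))
  expect_equal(attr(area_per_lipid(traj), "mean_apl"), 57, tolerance = 1e-10)
})

test_that("order parameters hit the exact values for canonical geometries", {
  # all C-H perpendicular to z
  u_perp <- cbind(cos(seq(0, 2 * pi, length.out = 50)),
                  sin(seq(0, 2 * pi, length.out = 50)), 0)
  traj <- toy_trajectory(chains = chains_from_vectors(u_perp))
  expect_equal(deuterium_order_parameters(traj, "sn1")$scd, -0.5)

  # magic angle: cos^2 = 1/3
  cz <- 1 / sqrt(3); s <- sqrt(1 - cz^2)
  u_magic <- cbind(s * cos(seq_len(50)), s * sin(seq_len(50)), cz)
  u_magic <- u_magic / sqrt(rowSums(u_magic^2))
  traj2 <- toy_trajectory(chains = chains_from_vectors(u_magic))
  expect_equal(deuterium_order_parameters(traj2, "sn1")$scd, 0, tolerance = 1e-12)

  # isotropic vectors: 0 within Monte-Carlo error
  set.seed(6)
  traj3 <- toy_trajectory(chains = chains_from_vectors(random_unit_vectors(1e5)))
  expect_lt(abs(deuterium_order_parameters(traj3, "sn1")$scd), 0.005)
  expect_error(deuterium_order_parameters(traj3, "sn2"), "no 'sn2'")
})

test_that("S_CD stays within its theoretical bounds on generated data", {
  traj <- small_synth(seed = 44)
  for (tail in c("sn1", "sn2", "probe_tail")) {
    prof <- deuterium_order_parameters(traj, tail)
    expect_true(all(prof$scd >= -0.5 & prof$scd <= 1))
  }
})

test_that("a flat bilayer maps to uniform thickness, invariant under z-shifts", {
  traj <- toy_trajectory(n_per_leaflet = 64, lx = 6, ly = 6, half = 2)
  map <- thickness_map(traj, cell_size = 1.4)
  expect_true(all(abs(map$thickness - 4) < 1e-12))
  expect_false(any(map$interpolated))

  shifted <- traj
  shifted$lipids$z <- shifted$lipids$z + 1.3
  map2 <- thickness_map(shifted, cell_size = 1.4)
  expect_equal(map2$thickness, map$thickness)
  expect_error(thickness_map(traj, cell_size = 10), "larger than the box")
})

test_that("a generated ripple is recovered in peak-to-trough amplitude", {
  p <- synth_params(n_lipids_per_leaflet = 256, apl_target = 52.3,
                    ripple_amplitude = 0.4, ripple_wavelength = 2.5,
                    n_waters = 10, n_frames = 1, n_carbons = 2, seed = 12)
  traj <- generate_trajectory(p)
  map <- thickness_map(traj, cell_size = 0.35)
  th <- map$thickness[!map$interpolated]
  ptt <- max(th) - min(th)
  expect_lt(abs(ptt - 1.6) / 1.6, 0.10)   # both leaflets in phase: 2 x 2 x 0.4
})

test_that("ripple metrics find the injected wavelength and obey the rms identity", {
  # hand-built sinusoidal map: lambda = 2.5 nm on a 10 x 10 nm box
  nx <- ny <- 20; box <- c(10, 10)
  g <- tidyr::expand_grid(iy = 0:(ny - 1), ix = 0:(nx - 1))
  map <- tibble::tibble(x = (g$ix + 0.5) * box[1] / nx,
                        y = (g$iy + 0.5) * box[2] / ny,
                        thickness = 4 + 0.4 * sin(2 * pi * (g$ix + 0.5) / nx * 4),
                        interpolated = FALSE)
  attr(map, "cell_size") <- box / c(nx, ny)
  attr(map, "nx") <- nx; attr(map, "ny") <- ny; attr(map, "box") <- box
  class(map) <- c("thickness_map", class(map))
  rm <- ripple_metrics(map)
  expect_false(rm$flagged)
  # one spectral bin at this box size is 10/4 - 10/5 = 0.5 nm
  expect_lt(abs(rm$dominant_wavelength - 2.5), 0.51)

  flat <- map; flat$thickness <- 4
  expect_true(ripple_metrics(flat)$flagged)

  half_half <- map
  half_half$thickness <- rep(c(3.8, 4.2), length.out = nrow(map))
  expect_equal(ripple_metrics(half_half)$rms, 0.2, tolerance = 1e-12)
})

test_that("the map mean matches the global leaflet separation within 2%", {
  traj <- small_synth(seed = 51)
  map <- thickness_map(traj, cell_size = 0.5)
  lip <- traj$lipids[traj$lipids$frame == max(traj$lipids$frame), ]
  glob <- mean(lip$z[lip$leaflet == "upper"]) - mean(lip$z[lip$leaflet == "lower"])
  expect_lt(abs(mean(map$thickness) - glob) / glob, 0.02)
})

test_that("phase calls follow the documented rule table", {
  expect_equal(classify_phase(57.0, 0.05, 0.05)$label, "Lalpha")
  expect_equal(classify_phase(51.0, 0.35, 0.05)$label, "Lc")
  expect_equal(classify_phase(52.0, 0.30, 0.30)$label, "Pbeta")
  expect_equal(classify_phase(52.0, 0.30, 0.05)$label, "Lbeta")
  # thresholds are echoed in the call
  call <- classify_phase(57, 0.05, 0.05, thresholds = list(apl_alpha = 56))
  expect_equal(call$thresholds[[1]]$apl_alpha, 56)
})
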