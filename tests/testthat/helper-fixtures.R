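# Hand-built fixtures with exactly known geometry, used across the suite.

# water record from an oxygen position and the unit direction of the
# O -> H-midpoint bisector (TIP3P-like geometry, O-H 0.0957 nm, HOH 104.5 deg)
make_water <- function(id, o, bisector, inplane = NULL) {
  b <- bisector / sqrt(sum(bisector^2))
  ref <- if (abs(b[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- ref - sum(ref * b) * b
  t1 <- t1 / sqrt(sum(t1^2))
  if (!is.null(inplane)) t1 <- inplane / sqrt(sum(inplane^2))
  half <- 104.5 / 2 * pi / 180
  h1 <- o + 0.0957 * (cos(half) * b + sin(half) * t1)
  h2 <- o + 0.0957 * (cos(half) * b - sin(half) * t1)
  tibble::tibble(water_id = id,
                 ox = o[1], oy = o[2], oz = o[3],
                 h1x = h1[1], h1y = h1[2], h1z = h1[3],
                 h2x = h2[1], h2y = h2[2], h2z = h2[3])
}

# minimal deterministic bilayer: n_per_leaflet phosphorus atoms on a lattice
# at +/- half around the box centre, probe head on the axis, explicit waters
toy_trajectory <- function(n_frames = 1, n_per_leaflet = 4, half = 2,
                           lx = 4, ly = 4, lz = 10,
                           head_off = 1.5, co_off = -0.1, an_off = 0.2,
                           tdm = c(0, 0, 1), axis = c(0, 0, 1),
                           waters = NULL, dt = 0.1, excitation_time = 0,
                           leaflet_z = NULL, chains = NULL) {
  center <- lz / 2
  frames <- seq_len(n_frames)
  nx <- ceiling(sqrt(n_per_leaflet))
  gx <- ((seq_len(n_per_leaflet) - 1) %% nx + 0.5) * lx / nx
  gy <- ((seq_len(n_per_leaflet) - 1) %/% nx + 0.5) * ly / nx
  lipids <- purrr::map_dfr(frames, function(f) {
    zu <- if (is.null(leaflet_z)) rep(center + half, n_per_leaflet) else center + leaflet_z(gx, +1)
    zl <- if (is.null(leaflet_z)) rep(center - half, n_per_leaflet) else center + leaflet_z(gx, -1)
    tibble::tibble(frame = f,
                   lipid_id = seq_len(2 * n_per_leaflet),
                   leaflet = rep(c("upper", "lower"), each = n_per_leaflet),
                   x = rep(gx, 2), y = rep(gy, 2), z = c(zu, zl))
  })
  tdm <- tdm / sqrt(sum(tdm^2))
  axis <- axis / sqrt(sum(axis^2))
  probe <- tibble::tibble(frame = frames,
                          head_x = lx / 2, head_y = ly / 2, head_z = center + head_off,
                          tdm_x = tdm[1], tdm_y = tdm[2], tdm_z = tdm[3],
                          axis_x = axis[1], axis_y = axis[2], axis_z = axis[3],
                          co_x = lx / 2, co_y = ly / 2, co_z = center + head_off + co_off,
                          an_x = lx / 2, an_y = ly / 2, an_z = center + head_off + an_off)
  wtab <- if (is.null(waters)) {
    tibble::tibble(frame = integer(), water_id = integer(),
                   ox = double(), oy = double(), oz = double(),
                   h1x = double(), h1y = double(), h1z = double(),
                   h2x = double(), h2y = double(), h2z = double())
  } else {
    purrr::map_dfr(frames, function(f) dplyr::mutate(waters, frame = f, .before = 1))
  }
  membrane_trajectory(
    meta = list(temperature = 298, conformer = "I", dt = dt,
                excitation_time = excitation_time),
    box = tibble::tibble(frame = frames, time = (frames - 1) * dt,
                         lx = lx, ly = ly, lz = lz),
    lipids = lipids, probe = probe, waters = wtab, chains = chains)
}

# chains tibble from a matrix of unit vectors, all assigned to one carbon
chains_from_vectors <- function(u, tail = "sn1", carbon = 5, frame = 1L) {
  tibble::tibble(frame = frame, lipid_id = seq_len(nrow(u)), tail = tail,
                 carbon = carbon, h = 1L,
                 x = 0, y = 0, z = 0, ux = u[, 1], uy = u[, 2], uz = u[, 3])
}

# small fast synthetic system for integration-style tests
small_synth <- function(seed = 42, ...) {
  generate_trajectory(synth_params(n_lipids_per_leaflet = 16, n_waters = 150,
                                   n_frames = 20, n_carbons = 4, seed = seed, ...))
}

random_unit_vectors <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(phi), s * sin(phi), z)
}
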