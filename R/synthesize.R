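#' Parameters for the synthetic bilayer/probe/water generator
#'
#' The defaults describe the reference system the package emulates: a DPPC
#' bilayer of 64 lipids per leaflet solvated by 3314 waters with an embedded
#' Laurdan probe, at the gel-phase packing measured by X-ray diffraction
#' (52.3 A^2 per lipid at 298 K). The probe's transition dipole performs
#' wobbling-in-cone rotational diffusion; after the excitation time the
#' orientation of each water relaxes exponentially toward an equilibrated
#' mean, emulating post-excitation solvent reorganisation.
#'
#' @param n_lipids_per_leaflet lipids per leaflet
#' @param apl_target area per lipid, A^2; lateral box area is exactly
#'   `n_lipids_per_leaflet * apl_target`
#' @param scd_plateau_target expected deuterium order parameter S_CD of the
#'   plateau carbons (2-10), in `[-0.5, 0]`; -0.5 is perfectly ordered
#'   (C-H perpendicular to the normal), 0 isotropic
#' @param half_thickness nm, leaflet phosphorus plane distance from the
#'   membrane centre
#' @param ripple_amplitude,ripple_wavelength nm, sinusoidal modulation along
#'   x applied symmetrically to the two leaflet planes, so the local
#'   thickness varies by 4 x `ripple_amplitude` peak to trough
#' @param n_waters water count, uniformly placed in the solvent slab
#' @param conformer `"I"` or `"II"`
#' @param probe_depth nm of the probe head above the membrane centre
#' @param tdm_cone_semiangle degrees, wobbling-in-cone half-angle of the
#'   transition dipole (0 freezes the dipole)
#' @param tdm_wobble_rate ns^-1, wobbling diffusion coefficient (rad^2/ns)
#' @param water_relax_time ns, post-excitation orientation relaxation time
#' @param equilibrated_orientation_mean per-water asymptotic value of the
#'   signed orientation statistic (negative = oxygen toward the probe head)
#' @param orientation_noise half-width of the uniform scatter of each
#'   water's orientation cosine about its mean (a partially ordered shell;
#'   `abs(equilibrated_orientation_mean) + orientation_noise` must not
#'   exceed 1)
#' @param emission_mean,emission_sigma nm, Gaussian emission-wavelength
#'   distribution of the QM/MM-style snapshot records
#' @param oscillator_band length-2 band for uniform oscillator strengths
#' @param n_frames,dt frames and ns per frame
#' @param excitation_time ns at which the probe switches to S1
#' @param seed master seed; per-component streams (lipids, chains, probe,
#'   waters, emission) are split from it
#' @param n_carbons chain carbons per tail
#' @return a `synth_params` list
#' @export
synth_params <- function(n_lipids_per_leaflet = 64,
                         apl_target = 52.3,
                         scd_plateau_target = -0.25,
                         half_thickness = 2.0,
                         ripple_amplitude = 0.15,
                         ripple_wavelength = 3.0,
                         n_waters = 3314,
                         conformer = "I",
                         probe_depth = 1.8,
                         tdm_cone_semiangle = 25,
                         tdm_wobble_rate = 1.0,
                         water_relax_time = 1.5,
                         equilibrated_orientation_mean = -0.15,
                         orientation_noise = 0.5,
                         emission_mean = 380,
                         emission_sigma = 10,
                         oscillator_band = c(0.3, 0.5),
                         n_frames = 105,
                         dt = 0.2,
                         excitation_time = 0,
                         seed = 1L,
                         n_carbons = 16) {
  p <- as.list(environment())
  stopifnot(p$n_lipids_per_leaflet > 0, p$n_waters > 0, p$n_frames > 0,
            p$dt > 0, p$n_carbons > 0, p$emission_sigma >= 0,
            p$excitation_time >= 0)
  if (p$apl_target < 40) stop("apl_target below 40 A^2 would overlap lipids", call. = FALSE)
  if (p$tdm_cone_semiangle < 0 || p$tdm_cone_semiangle > 90) {
    stop("tdm_cone_semiangle must lie in [0, 90] degrees", call. = FALSE)
  }
  if (p$scd_plateau_target < -0.5 || p$scd_plateau_target > 0) {
    stop("scd_plateau_target must lie in [-0.5, 0]", call. = FALSE)
  }
  if (abs(p$equilibrated_orientation_mean) + p$orientation_noise > 1) {
    stop("abs(equilibrated_orientation_mean) + orientation_noise must be <= 1",
         call. = FALSE)
  }
  structure(p, class = "synth_params")
}

# per-carbon S_CD targets: plateau (carbons 2-10) at the target, carbon 1
# slightly less ordered, tapering toward the terminal methyl
scd_target_profile <- function(params) {
  s <- params$scd_plateau_target
  k <- seq_len(params$n_carbons)
  tgt <- rep(s, params$n_carbons)
  tgt[1] <- 0.8 * s
  post <- k > 10
  if (any(post)) tgt[post] <- s * (1 - 0.75 * (k[post] - 10) / max(params$n_carbons - 10, 1))
  tgt
}

#' Discrete-step rotational diffusion of a unit dipole, optionally confined
#' to a cone
#'
#' Tangential Gaussian steps on the unit sphere (variance `2 * rate * dt`
#' per step, sub-stepped so individual steps stay small) with reflective
#' confinement at the cone boundary. The stationary distribution is uniform
#' on the spherical cap, so the long-time anisotropy plateau obeys the
#' wobbling-in-cone closed form `r_inf/r_0 = (cos(tc) (1 + cos(tc)) / 2)^2`.
#'
#' @param n_steps number of frames to emit
#' @param dt ns per frame
#' @param rate wobbling diffusion coefficient, rad^2/ns
#' @param cone_semiangle degrees; `NULL` for unconstrained isotropic
#'   diffusion; 0 freezes the dipole on the axis
#' @param axis cone axis (unit length not required; normalised internally)
#' @param seed optional seed (uses the current RNG stream when `NULL`)
#' @return an `n_steps x 3` matrix of unit vectors
#' @export
simulate_dipole_trajectory <- function(n_steps, dt, rate, cone_semiangle = NULL,
                                       axis = c(0, 0, 1), seed = NULL) {
  run <- function() {
    axis <- axis / sqrt(sum(axis^2))
    out <- matrix(0, n_steps, 3)
    if (!is.null(cone_semiangle) && cone_semiangle == 0) {
      out[] <- rep(axis, each = n_steps)
      return(out)
    }
    theta_c <- if (is.null(cone_semiangle)) Inf else deg2rad(cone_semiangle)
    # sub-step so each tangential step stays in the diffusion limit
    step_var <- 2 * rate * dt
    nsub <- max(1L, ceiling(step_var / 0.01))
    s <- sqrt(step_var / nsub)
    u <- axis
    for (i in seq_len(n_steps)) {
      for (k in seq_len(nsub)) {
        # orthonormal tangent frame at u
        ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
        e1 <- ref - sum(ref * u) * u
        e1 <- e1 / sqrt(sum(e1^2))
        e2 <- c(u[2] * e1[3] - u[3] * e1[2],
                u[3] * e1[1] - u[1] * e1[3],
                u[1] * e1[2] - u[2] * e1[1])
        d <- stats::rnorm(2, 0, s)
        u <- u + d[1] * e1 + d[2] * e2
        u <- u / sqrt(sum(u^2))
        if (is.finite(theta_c)) {
          ca <- sum(u * axis)
          theta <- acos(pmin(pmax(ca, -1), 1))
          if (theta > theta_c) {
            # reflect across the cone boundary in the (axis, u) plane
            w <- u - ca * axis
            w <- w / sqrt(sum(w^2))
            theta_new <- max(2 * theta_c - theta, 0)
            u <- cos(theta_new) * axis + sin(theta_new) * w
          }
        }
      }
      out[i, ] <- u
    }
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a synthetic bilayer + probe + water trajectory
#'
#' Builds a trajectory whose downstream observables have known ground truth:
#' the lateral box area is exactly `n_lipids_per_leaflet * apl_target`;
#' leaflet phosphorus planes sit at `+/- half_thickness` modulated by a
#' sinusoidal ripple; chain C-H vectors are drawn from a mixture whose
#' expected S_CD equals the per-carbon target profile; the probe transition
#' dipole wobbles in a cone about the membrane normal; waters fill the
#' solvent slab and their orientation statistic relaxes exponentially after
#' the excitation time. Fully reproducible from `params$seed`.
#'
#' @param params a [synth_params()] list
#' @return a [membrane_trajectory()] with the generating parameters attached
#'   as attribute `"synth_params"`
#' @export
generate_trajectory <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  seeds <- split_seed(params$seed, c("lipids", "chains", "probe", "waters", "emission"))

  n_leaf <- params$n_lipids_per_leaflet
  apl_nm2 <- params$apl_target / 100
  nx <- max(1L, round(sqrt(n_leaf)))
  while (n_leaf %% nx != 0L) nx <- nx - 1L
  ny <- n_leaf %/% nx
  a <- sqrt(apl_nm2)
  lx <- nx * a
  ly <- ny * a
  center <- params$half_thickness + params$ripple_amplitude + 2.0
  lz <- 2 * center
  nf <- params$n_frames
  frames <- seq_len(nf)
  times <- (frames - 1L) * params$dt

  box <- tibble::tibble(frame = frames, time = times, lx = lx, ly = ly, lz = lz)

  # under periodic boundaries the ripple must be commensurate with the box:
  # snap to the nearest integer number of periods and record the effective
  # wavelength as ground truth
  ripple_lambda <- lx / max(1, round(lx / params$ripple_wavelength))
  params$ripple_wavelength_effective <- ripple_lambda

  # --- lipids: jittered lattice, rippled leaflet planes -------------------
  lipids <- with_seed(seeds$lipids, {
    lat <- expand.grid(ix = seq_len(nx) - 0.5, iy = seq_len(ny) - 0.5)
    one_leaf <- function(leaf, sgn, id0) {
      purrr::map_dfr(frames, function(f) {
        x <- (lat$ix * a + stats::rnorm(n_leaf, 0, 0.03)) %% lx
        y <- (lat$iy * a + stats::rnorm(n_leaf, 0, 0.03)) %% ly
        z <- center + sgn * (params$half_thickness +
                               params$ripple_amplitude * sin(2 * pi * x / ripple_lambda)) +
          stats::rnorm(n_leaf, 0, 0.02)
        tibble::tibble(frame = f, lipid_id = id0 + seq_len(n_leaf),
                       leaflet = leaf, x = x, y = y, z = z)
      })
    }
    dplyr::bind_rows(one_leaf("upper", +1, 0L), one_leaf("lower", -1, n_leaf))
  })

  # --- chain C-H vectors: mixture with exact expected S_CD ----------------
  chains <- with_seed(seeds$chains, {
    tgt <- scd_target_profile(params)
    lip0 <- lipids[lipids$frame == 1L, ]
    skel <- tidyr::expand_grid(frame = frames,
                               lipid_id = lip0$lipid_id,
                               tail = c("sn1", "sn2"),
                               carbon = seq_len(params$n_carbons),
                               h = 1:2)
    key <- paste(skel$frame, skel$lipid_id)
    pos <- lipids[match(key, paste(lipids$frame, lipids$lipid_id)), ]
    sgn <- ifelse(pos$leaflet == "upper", -1, +1)   # chains point to the centre
    skel$x <- pos$x + ifelse(skel$tail == "sn1", -0.05, 0.05)
    skel$y <- pos$y
    skel$z <- pos$z + sgn * (0.25 + 0.1 * skel$carbon)
    u <- draw_ch_vectors(tgt[skel$carbon])
    skel$ux <- u[, 1]; skel$uy <- u[, 2]; skel$uz <- u[, 3]
    skel
  })

  # --- probe: head position, wobbling dipole, tail ------------------------
  probe <- with_seed(seeds$probe, {
    hx <- lx / 2 + stats::rnorm(nf, 0, 0.02)
    hy <- ly / 2 + stats::rnorm(nf, 0, 0.02)
    hz <- center + params$probe_depth + stats::rnorm(nf, 0, 0.02)
    tdm <- simulate_dipole_trajectory(nf, params$dt, params$tdm_wobble_rate,
                                      params$tdm_cone_semiangle)
    ax <- simulate_dipole_trajectory(nf, params$dt, params$tdm_wobble_rate,
                                     params$tdm_cone_semiangle)
    tibble::tibble(frame = frames, head_x = hx, head_y = hy, head_z = hz,
                   tdm_x = tdm[, 1], tdm_y = tdm[, 2], tdm_z = tdm[, 3],
                   axis_x = ax[, 1], axis_y = ax[, 2], axis_z = ax[, 3],
                   co_x = hx, co_y = hy, co_z = hz - 0.10,
                   an_x = hx, an_y = hy, an_z = hz + 0.20)
  })

  # probe tail C-H vectors share the chain statistics
  probe_tail <- with_seed(seeds$chains + 1L, {
    tgt <- scd_target_profile(params)
    skel <- tidyr::expand_grid(frame = frames, lipid_id = 0L, tail = "probe_tail",
                               carbon = seq_len(params$n_carbons), h = 1:2)
    pp <- probe[match(skel$frame, probe$frame), ]
    skel$x <- pp$head_x
    skel$y <- pp$head_y
    skel$z <- pp$head_z - (0.25 + 0.1 * skel$carbon)
    u <- draw_ch_vectors(tgt[skel$carbon])
    skel$ux <- u[, 1]; skel$uy <- u[, 2]; skel$uz <- u[, 3]
    skel
  })

  # --- waters: static slab positions, relaxing orientations ---------------
  waters <- with_seed(seeds$waters, {
    nw <- params$n_waters
    # waters reach just past the phosphate planes, as in a hydrated bilayer
    slab_lo <- params$half_thickness + 0.1
    half_slab <- lz / 2 - slab_lo
    z0 <- center + sample(c(-1, 1), nw, replace = TRUE) *
      stats::runif(nw, slab_lo, slab_lo + half_slab)
    x0 <- stats::runif(nw, 0, lx)
    y0 <- stats::runif(nw, 0, ly)
    m_inf <- params$equilibrated_orientation_mean
    purrr::map_dfr(frames, function(f) {
      t_rel <- times[f] - params$excitation_time
      m_t <- if (t_rel < 0) 0 else m_inf * (1 - exp(-t_rel / params$water_relax_time))
      ox <- x0 + stats::rnorm(nw, 0, 0.02)
      oy <- y0 + stats::rnorm(nw, 0, 0.02)
      oz <- z0 + stats::rnorm(nw, 0, 0.02)
      hx <- probe$head_x[f]; hy <- probe$head_y[f]; hz <- probe$head_z[f]
      v1 <- normalize_rows(cbind(ox - hx, oy - hy, oz - hz))
      # measured statistic is -cos(theta); draw cos(theta) with mean -m_t
      # and uniform scatter of the configured half-width
      ct <- -m_t + stats::runif(nw, -params$orientation_noise,
                                params$orientation_noise)
      hh <- water_hydrogens(ox, oy, oz, v1, ct)
      tibble::tibble(frame = f, water_id = seq_len(nw),
                     ox = ox, oy = oy, oz = oz,
                     h1x = hh$h1[, 1], h1y = hh$h1[, 2], h1z = hh$h1[, 3],
                     h2x = hh$h2[, 1], h2y = hh$h2[, 2], h2z = hh$h2[, 3])
    })
  })

  traj <- membrane_trajectory(
    meta = list(temperature = 298, conformer = params$conformer,
                dt = params$dt, excitation_time = params$excitation_time),
    box = box, lipids = lipids, probe = probe, waters = waters,
    chains = dplyr::bind_rows(chains, probe_tail))
  attr(traj, "synth_params") <- params
  traj
}

# C-H unit vectors whose expected P2(cos angle to z) equals `target` per row:
# with probability 1 + 2*target the vector is isotropic (P2 mean 0), otherwise
# exactly perpendicular to z (P2 = -0.5)
draw_ch_vectors <- function(target) {
  n <- length(target)
  p_iso <- 1 + 2 * target
  iso <- stats::runif(n) < p_iso
  phi <- stats::runif(n, 0, 2 * pi)
  cz <- stats::runif(n, -1, 1)
  sz <- sqrt(pmax(1 - cz^2, 0))
  u <- cbind(sz * cos(phi), sz * sin(phi), cz)
  u[!iso, 3] <- 0
  u[!iso, 1] <- cos(phi[!iso])
  u[!iso, 2] <- sin(phi[!iso])
  u
}

# place the two hydrogens of a TIP3P-like water (O-H 0.0957 nm, HOH 104.5
# deg) so the O -> H-midpoint bisector makes angle acos(ct) with v1
water_hydrogens <- function(ox, oy, oz, v1, ct) {
  n <- length(ox)
  st <- sqrt(pmax(1 - ct^2, 0))
  # tangent e perpendicular to v1, random azimuth
  phi <- stats::runif(n, 0, 2 * pi)
  ref <- cbind(ifelse(abs(v1[, 3]) < 0.9, 0, 1), 0, ifelse(abs(v1[, 3]) < 0.9, 1, 0))
  e1 <- ref - rowSums(ref * v1) * v1
  e1 <- normalize_rows(e1)
  e2 <- cbind(v1[, 2] * e1[, 3] - v1[, 3] * e1[, 2],
              v1[, 3] * e1[, 1] - v1[, 1] * e1[, 3],
              v1[, 1] * e1[, 2] - v1[, 2] * e1[, 1])
  eperp <- cos(phi) * e1 + sin(phi) * e2
  b <- ct * v1 + st * eperp                    # bisector direction from O
  # hydrogen half-angle and random in-plane normal
  half <- deg2rad(104.5 / 2)
  psi <- stats::runif(n, 0, 2 * pi)
  t1 <- ref - rowSums(ref * b) * b
  t1 <- normalize_rows(t1)
  t2 <- cbind(b[, 2] * t1[, 3] - b[, 3] * t1[, 2],
              b[, 3] * t1[, 1] - b[, 1] * t1[, 3],
              b[, 1] * t1[, 2] - b[, 2] * t1[, 1])
  tperp <- cos(psi) * t1 + sin(psi) * t2
  oh <- 0.0957
  o <- cbind(ox, oy, oz)
  h1 <- o + oh * (cos(half) * b + sin(half) * tperp)
  h2 <- o + oh * (cos(half) * b - sin(half) * tperp)
  list(h1 = h1, h2 = h2)
}

#' Generate a synthetic per-snapshot emission table
#'
#' Emission wavelengths are Normal(`emission_mean`, `emission_sigma`)
#' truncated to > 200 nm; oscillator strengths are uniform in
#' `params$oscillator_band`. Reproducible from `params$seed` (emission
#' stream).
#'
#' @param params a [synth_params()]
#' @param n_records number of snapshot records (50 per conformer in the
#'   reference protocol)
#' @return emission tibble as from [read_emission_table()]
#' @export
generate_emission_table <- function(params, n_records = 50) {
  stopifnot(inherits(params, "synth_params"))
  if (n_records <= 0) stop("n_records must be > 0", call. = FALSE)
  seeds <- split_seed(params$seed, c("lipids", "chains", "probe", "waters", "emission"))
  with_seed(seeds$emission, {
    lam <- stats::rnorm(n_records, params$emission_mean, params$emission_sigma)
    while (any(lam <= 200)) {
      lam[lam <= 200] <- stats::rnorm(sum(lam <= 200), params$emission_mean,
                                      params$emission_sigma)
    }
    f <- stats::runif(n_records, params$oscillator_band[1], params$oscillator_band[2])
    tibble::tibble(snapshot_id = seq_len(n_records),
                   conformer = params$conformer,
                   wavelength_nm = lam,
                   energy_ev = nm_to_ev(lam),
                   oscillator_strength = f)
  })
}
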