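#' Radial distribution function of water oxygens around the probe head
#'
#' Minimum-image distances from the per-frame probe head centre of mass to
#' every water oxygen, binned in shells of width `dr`. `g(r)` is the shell
#' count normalised by the ideal-gas expectation `4 pi r^2 dr rho` at the
#' mean water number density; `coordination` is the exact cumulative count
#' N(r) averaged over frames.
#'
#' @param traj a [membrane_trajectory()]
#' @param r_max nm, at most half the smallest box edge
#' @param dr nm shell width
#' @param density water number density (nm^-3) used for normalisation;
#'   default `NULL` uses the whole-box mean `n_waters / V`. For a bilayer
#'   system pass the solvent-slab density instead.
#' @return `rdf_result` tibble: `r` (shell centre), `g`, `coordination`
#' @export
water_rdf <- function(traj, r_max = 1.2, dr = 0.02, density = NULL) {
  if (dr <= 0) stop("dr must be > 0", call. = FALSE)
  if (!nrow(traj$waters)) stop("trajectory has no waters", call. = FALSE)
  min_edge <- min(traj$box$lx, traj$box$ly, traj$box$lz)
  if (r_max > min_edge / 2 + 1e-9) {
    stop("r_max exceeds half the smallest box edge", call. = FALSE)
  }
  edges <- seq(0, r_max, by = dr)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nfr <- n_frames(traj)

  counts <- rep(0, length(edges) - 1L)
  for (f in traj$box$frame) {
    w <- traj$waters[traj$waters$frame == f, ]
    p <- traj$probe[traj$probe$frame == f, ]
    b <- traj$box[traj$box$frame == f, ]
    d <- min_image_dist(p$head_x, p$head_y, p$head_z, w$ox, w$oy, w$oz,
                        c(b$lx, b$ly, b$lz))
    counts <- counts + graphics::hist(d[d <= r_max], breaks = edges, plot = FALSE)$counts
  }
  counts <- counts / nfr

  if (is.null(density)) {
    v <- mean(traj$box$lx * traj$box$ly * traj$box$lz)
    density <- (nrow(traj$waters) / nfr) / v
  }
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  widths <- diff(edges)
  ideal <- 4 * pi * mids^2 * widths * density
  out <- tibble::tibble(r = mids, g = counts / ideal, coordination = cumsum(counts))
  class(out) <- c("rdf_result", class(out))
  out
}

#' Percentage of a reference water population inside a solvation shell
#'
#' @param rdf an [water_rdf()] result
#' @param shell_r nm shell boundary (e.g. the second minimum of g(r))
#' @param reference_total total water count the percentage refers to
#' @return percent of `reference_total` found within `shell_r`
#' @export
shell_occupancy <- function(rdf, shell_r, reference_total) {
  if (reference_total == 0) stop("reference_total must be non-zero", call. = FALSE)
  if (shell_r < min(rdf$r) - diff(rdf$r)[1] / 2 || shell_r > max(rdf$r) + diff(rdf$r)[1] / 2) {
    stop("shell_r outside the RDF range", call. = FALSE)
  }
  n <- rdf$coordination[which.min(abs(rdf$r - shell_r))]
  if (shell_r < rdf$r[1]) n <- 0
  100 * n / reference_total
}

#' Count water-to-probe hydrogen bonds near the probe head
#'
#' Geometric criterion: a water donates a hydrogen bond to a probe acceptor
#' (carbonyl oxygen or amino nitrogen) when the donor-acceptor (Ow-A)
#' distance is at most `d_max` and the H-Ow-A angle is at most `angle_max`.
#' Only waters whose oxygen lies within `region_r` of the head centre of
#' mass are considered. Distances use the minimum-image convention.
#'
#' @param traj a [membrane_trajectory()]
#' @param frames frames to analyse (default all)
#' @param region_r nm search region around the head (default 0.5, the
#'   second-shell cutoff)
#' @param d_max nm donor-acceptor cutoff (default 0.35)
#' @param angle_max degrees H-donor-acceptor cutoff (default 30)
#' @return tibble `frame`, `n_hbonds`
#' @export
count_hbonds <- function(traj, frames = NULL, region_r = 0.5, d_max = 0.35,
                         angle_max = 30) {
  if (!nrow(traj$waters) || !nrow(traj$probe)) {
    stop("trajectory needs probe and waters", call. = FALSE)
  }
  frames <- frames %||% traj$box$frame
  purrr::map_dfr(frames, function(f) {
    w <- traj$waters[traj$waters$frame == f, ]
    p <- traj$probe[traj$probe$frame == f, ]
    b <- traj$box[traj$box$frame == f, ]
    box <- c(b$lx, b$ly, b$lz)
    near <- min_image_dist(p$head_x, p$head_y, p$head_z, w$ox, w$oy, w$oz, box) <= region_r
    w <- w[near, ]
    n <- 0L
    for (acc in list(c(p$co_x, p$co_y, p$co_z), c(p$an_x, p$an_y, p$an_z))) {
      if (!nrow(w)) break
      dxa <- min_image(acc[1] - w$ox, box[1])
      dya <- min_image(acc[2] - w$oy, box[2])
      dza <- min_image(acc[3] - w$oz, box[3])
      da <- sqrt(dxa^2 + dya^2 + dza^2)
      ok_d <- da <= d_max
      if (!any(ok_d)) next
      for (h in 1:2) {
        hx <- w[[paste0("h", h, "x")]] - w$ox
        hy <- w[[paste0("h", h, "y")]] - w$oy
        hz <- w[[paste0("h", h, "z")]] - w$oz
        cosang <- (hx * dxa + hy * dya + hz * dza) /
          (sqrt(hx^2 + hy^2 + hz^2) * pmax(da, 1e-12))
        ang <- rad2deg(acos(pmin(pmax(cosang, -1), 1)))
        n <- n + sum(ok_d & ang <= angle_max)
      }
    }
    tibble::tibble(frame = f, n_hbonds = n)
  })
}

#' Per-frame signed solvent-orientation statistic around the probe head
#'
#' For every water whose oxygen lies within `radius` of the head centre of
#' mass, cos(theta) is taken between v1 = head -> oxygen and v2 = oxygen ->
#' midpoint of the two hydrogens. The per-frame statistic is the signed sum
#' `sign * sum(cos theta)` with `sign = -1` by default, so a water whose
#' oxygen points toward the probe (hydrogens away) contributes negatively —
#' the convention under which an equilibrated shell around the excited
#' probe's enlarged dipole gives negative values.
#'
#' @param traj a [membrane_trajectory()]
#' @param radius nm (default 1, the head-group shell used for the reference
#'   tables)
#' @param sign +1 or -1 (default -1, see above)
#' @return tibble `frame`, `time`, `t_after_excitation`, `n_waters`,
#'   `orientation` (signed sum), `orientation_per_water`
#' @export
solvent_orientation <- function(traj, radius = 1, sign = -1) {
  if (!nrow(traj$waters) || !nrow(traj$probe)) {
    stop("trajectory needs probe and waters", call. = FALSE)
  }
  purrr::map_dfr(traj$box$frame, function(f) {
    w <- traj$waters[traj$waters$frame == f, ]
    p <- traj$probe[traj$probe$frame == f, ]
    b <- traj$box[traj$box$frame == f, ]
    box <- c(b$lx, b$ly, b$lz)
    dx <- min_image(w$ox - p$head_x, box[1])
    dy <- min_image(w$oy - p$head_y, box[2])
    dz <- min_image(w$oz - p$head_z, box[3])
    r <- sqrt(dx^2 + dy^2 + dz^2)
    inside <- r <= radius
    mx <- (w$h1x + w$h2x) / 2 - w$ox
    my <- (w$h1y + w$h2y) / 2 - w$oy
    mz <- (w$h1z + w$h2z) / 2 - w$oz
    ct <- (dx * mx + dy * my + dz * mz) /
      (pmax(r, 1e-12) * sqrt(mx^2 + my^2 + mz^2))
    val <- sign * sum(ct[inside])
    tibble::tibble(frame = f, time = b$time,
                   t_after_excitation = b$time - traj$meta$excitation_time,
                   n_waters = sum(inside), orientation = val,
                   orientation_per_water = if (sum(inside)) val / sum(inside) else NA_real_)
  })
}

#' Cumulative solvent orientation in time windows after excitation
#'
#' Averages the per-frame signed orientation statistic of
#' [solvent_orientation()] over time windows expressed relative to the
#' excitation time. Default windows follow the reference reporting scheme:
#' 0-1, 3-4, 6-7, 9-10, 12-13 and 20-21 ns.
#'
#' @inheritParams solvent_orientation
#' @param windows list of `c(start, end)` ns after excitation
#' @return tibble `window_start`, `window_end`, `n_frames`, `value`
#' @export
cumulative_solvent_orientation <- function(traj, radius = 1,
                                           windows = default_orientation_windows(),
                                           sign = -1) {
  if (any(vapply(windows, function(w) w[1] < 0, logical(1)))) {
    stop("windows must start at or after excitation", call. = FALSE)
  }
  per_frame <- solvent_orientation(traj, radius = radius, sign = sign)
  purrr::map_dfr(windows, function(w) {
    sel <- per_frame$t_after_excitation >= w[1] & per_frame$t_after_excitation <= w[2]
    tibble::tibble(window_start = w[1], window_end = w[2],
                   n_frames = sum(sel),
                   value = if (any(sel)) mean(per_frame$orientation[sel]) else NA_real_)
  })
}

#' @rdname cumulative_solvent_orientation
#' @export
default_orientation_windows <- function() {
  list(c(0, 1), c(3, 4), c(6, 7), c(9, 10), c(12, 13), c(20, 21))
}

#' Fit an exponential relaxation to a solvent-orientation series
#'
#' Least-squares fit of `C(t) = A exp(-t / tau) + C_inf` to the per-frame
#' orientation values after excitation. Non-convergence or a degenerate
#' (constant) series is flagged rather than raised.
#'
#' @param series per-frame tibble from [solvent_orientation()], or any data
#'   frame with columns `t_after_excitation` and a value column
#' @param value column name holding the relaxing statistic
#' @return one-row tibble `relax_time`, `relax_time_se`, `asymptote`,
#'   `asymptote_se`, `amplitude`, `converged`
#' @export
fit_solvent_relaxation <- function(series, value = "orientation") {
  t <- series$t_after_excitation
  y <- series[[value]]
  keep <- t >= 0 & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 4) stop("need at least 4 time points after excitation", call. = FALSE)

  flagged <- tibble::tibble(relax_time = NA_real_, relax_time_se = NA_real_,
                            asymptote = mean(y), asymptote_se = stats::sd(y) / sqrt(length(y)),
                            amplitude = 0, converged = FALSE)
  if (stats::sd(y) < 1e-12) return(flagged)

  c_inf0 <- mean(y[t >= stats::quantile(t, 0.7)])
  a0 <- y[which.min(t)] - c_inf0
  if (abs(a0) < 1e-12) a0 <- stats::sd(y)
  span <- max(diff(range(t)), 1e-3)
  fit <- NULL
  for (tau0 in span * c(1 / 10, 1 / 3, 1, 1 / 30)) {   # deterministic start ladder
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-t / tau) + C,
                        start = list(A = a0, tau = tau0, C = c_inf0),
                        lower = c(-1e6, 1e-6, -1e6), upper = c(1e6, 1e6, 1e6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(flagged)
  s <- summary(fit)$coefficients
  tibble::tibble(relax_time = s["tau", 1], relax_time_se = s["tau", 2],
                 asymptote = s["C", 1], asymptote_se = s["C", 2],
                 amplitude = s["A", 1], converged = TRUE)
}
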