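#' Tilt angle of a unit vector against the membrane normal
#'
#' Plain arccos of the dot product, in degrees over \[0, 180\]. The angle is
#' deliberately not folded across 90 degrees: a dipole at 100 degrees is
#' physically distinct from one at 80 degrees for an embedded probe.
#'
#' @param v unit vector (length 3) or n x 3 matrix of unit vectors
#' @param normal membrane normal, default the z-axis
#' @param fold fold angles into \[0, 90\] for comparison with symmetric
#'   conventions (default `FALSE`)
#' @return angle(s) in degrees
#' @export
tilt_angle <- function(v, normal = c(0, 0, 1), fold = FALSE) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  assert_unit(v[, 1], v[, 2], v[, 3], "v")
  assert_unit(normal[1], normal[2], normal[3], "normal")
  ct <- pmin(pmax(v %*% normal, -1), 1)
  ang <- rad2deg(acos(drop(ct)))
  if (fold) ang <- pmin(ang, 180 - ang)
  ang
}

#' Per-frame probe orientation angles
#'
#' @param traj a [membrane_trajectory()]
#' @param fold see [tilt_angle()]
#' @return tibble with columns `frame`, `time`, `tdm_angle`, `axis_angle`
#'   (degrees to the membrane normal)
#' @export
probe_angles <- function(traj, fold = FALSE) {
  p <- traj$probe
  if (!nrow(p)) stop("trajectory has no probe", call. = FALSE)
  tibble::tibble(
    frame = p$frame,
    time = traj$box$time[match(p$frame, traj$box$frame)],
    tdm_angle = tilt_angle(cbind(p$tdm_x, p$tdm_y, p$tdm_z), fold = fold),
    axis_angle = tilt_angle(cbind(p$axis_x, p$axis_y, p$axis_z), fold = fold))
}

#' Angular distribution of the probe dipole or long axis
#'
#' Histogram of per-frame tilt angles over \[0, 180\] degrees, with the
#' modal angle (centre of the maximal bin; ties resolved toward the smaller
#' angle) and the half-width at half-maximum obtained by linear
#' interpolation of the bin counts. A windowed mode-drift diagnostic mirrors
#' the convergence check used for the source simulations (mode fluctuation
#' across thirds of the trajectory).
#'
#' @param traj a [membrane_trajectory()]
#' @param selector `"tdm"` or `"long_axis"`
#' @param bin_width degrees (default 5)
#' @param fold see [tilt_angle()]
#' @return an `angular_distribution` object: tibble of `bin_mid`, `count`
#'   with attributes `mode_angle`, `hwhm`, `mode_drift` (degrees)
#' @export
angle_distribution <- function(traj, selector = c("tdm", "long_axis"),
                               bin_width = 5, fold = FALSE) {
  selector <- match.arg(selector)
  if (n_frames(traj) < 1) stop("trajectory has no frames", call. = FALSE)
  ang <- probe_angles(traj, fold = fold)
  a <- if (selector == "tdm") ang$tdm_angle else ang$axis_angle

  # bins centred on multiples of bin_width so canonical angles (0, 90, ...)
  # are bin centres, not edges
  edges <- seq(-bin_width / 2, 180 + bin_width / 2, by = bin_width)
  counts <- graphics::hist(a, breaks = edges, plot = FALSE)$counts
  mids <- (edges[-1] + edges[-length(edges)]) / 2

  imode <- which(counts == max(counts))[1]          # ties -> smaller angle
  mode_angle <- mids[imode]
  hwhm <- hwhm_from_histogram(mids, counts, imode)

  # windowed mode drift across thirds of the trajectory
  thirds <- split(a, cut(seq_along(a), 3, labels = FALSE))
  modes <- vapply(thirds, function(w) {
    cw <- graphics::hist(w, breaks = edges, plot = FALSE)$counts
    mids[which(cw == max(cw))[1]]
  }, double(1))
  drift <- max(modes) - min(modes)

  out <- tibble::tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                        bin_mid = mids, count = counts)
  attr(out, "mode_angle") <- mode_angle
  attr(out, "hwhm") <- hwhm
  attr(out, "mode_drift") <- drift
  attr(out, "selector") <- selector
  class(out) <- c("angular_distribution", class(out))
  out
}

# half width at half of the modal count by linear interpolation between bin
# centres; a one-bin (delta) distribution gives bin_width / 2
hwhm_from_histogram <- function(mids, counts, imode) {
  half <- counts[imode] / 2
  cross <- function(idx_seq) {
    prev <- imode
    for (j in idx_seq) {
      if (counts[j] <= half) {
        # interpolate between centres j and prev
        if (counts[prev] == counts[j]) return(mids[j])
        frac <- (counts[prev] - half) / (counts[prev] - counts[j])
        return(mids[prev] + frac * (mids[j] - mids[prev]))
      }
      prev <- j
    }
    mids[idx_seq[length(idx_seq)]]                  # never crosses: edge
  }
  left <- if (imode > 1) cross(seq(imode - 1, 1)) else mids[1] - (mids[2] - mids[1]) / 2
  right <- if (imode < length(mids)) cross(seq(imode + 1, length(mids))) else
    mids[length(mids)] + (mids[2] - mids[1]) / 2
  (right - left) / 2
}

#' @export
print.angular_distribution <- function(x, ...) {
  cat(sprintf("<angular_distribution> %s: mode %.1f deg, HWHM %.2f deg, mode drift %.1f deg\n",
              attr(x, "selector"), attr(x, "mode_angle"), attr(x, "hwhm"),
              attr(x, "mode_drift")))
  NextMethod()
}

#' Depth profile of probe moieties and phosphorus relative to the membrane
#' centre
#'
#' The per-frame membrane centre is the midpoint between the leaflet-mean
#' phosphorus z. Distances |z - centre| of the probe head centre of mass,
#' carbonyl oxygen, amino nitrogen and all phosphorus atoms are histogrammed
#' and averaged.
#'
#' @param traj a [membrane_trajectory()]
#' @param bin_width nm histogram resolution
#' @return a `depth_profile` object: tibble `species`, `z_mid`, `density`
#'   with attribute `means` (named per-species mean distances, nm;
#'   `phosphorus` is the mean leaflet distance, i.e. the membrane
#'   half-thickness)
#' @export
depth_profile <- function(traj, bin_width = 0.05) {
  if (n_frames(traj) < 1 || !nrow(traj$lipids)) {
    stop("trajectory needs frames with lipids", call. = FALSE)
  }
  centers <- frame_centers(traj)
  p <- traj$probe
  cen_p <- centers$center[match(p$frame, centers$frame)]
  cen_l <- centers$center[match(traj$lipids$frame, centers$frame)]

  d <- dplyr::bind_rows(
    tibble::tibble(species = "probe_head", dist = abs(p$head_z - cen_p)),
    tibble::tibble(species = "carbonyl_o", dist = abs(p$co_z - cen_p)),
    tibble::tibble(species = "amino_n", dist = abs(p$an_z - cen_p)),
    tibble::tibble(species = "phosphorus", dist = abs(traj$lipids$z - cen_l)))

  r_max <- max(d$dist) + bin_width
  edges <- seq(0, r_max + bin_width, by = bin_width)
  prof <- d |>
    dplyr::group_by(.data$species) |>
    dplyr::reframe({
      h <- graphics::hist(.data$dist, breaks = edges, plot = FALSE)
      tibble::tibble(z_mid = h$mids, density = h$density)
    })
  means <- d |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(mean_dist = mean(.data$dist), .groups = "drop")

  out <- tibble::as_tibble(prof)
  attr(out, "means") <- stats::setNames(means$mean_dist, means$species)
  class(out) <- c("depth_profile", class(out))
  out
}

#' @export
print.depth_profile <- function(x, ...) {
  m <- attr(x, "means")
  cat("<depth_profile> mean |z - centre| (nm):\n")
  for (s in names(m)) cat(sprintf("  %-11s %.3f\n", s, m[[s]]))
  invisible(x)
}
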