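#' Membrane trajectory container
#'
#' A `membrane_trajectory` bundles the time-ordered configurations of a lipid
#' bilayer, an embedded Laurdan probe and the surrounding water, in the tidy
#' tabular form every analysis function in this package consumes. All lengths
#' are in nanometres and the z-axis is the membrane normal.
#'
#' @param meta named list with elements `temperature` (K), `conformer`
#'   (`"I"`, `"II"` or `"mixed"`), `dt` (ns per frame) and `excitation_time`
#'   (ns at which the probe is switched to its S1 state).
#' @param box tibble with one row per frame: `frame`, `time` (ns), `lx`, `ly`,
#'   `lz` (nm box edges).
#' @param lipids tibble of phosphorus positions: `frame`, `lipid_id`,
#'   `leaflet` (`"upper"`/`"lower"`), `x`, `y`, `z`.
#' @param chains tibble of C-H bond vectors, one row per hydrogen: `frame`,
#'   `lipid_id` (0 for the probe tail), `tail` (`"sn1"`, `"sn2"` or
#'   `"probe_tail"`), `carbon` (1 = glycerol end), `h` (1 or 2), carbon
#'   position `x`, `y`, `z` and unit vector `ux`, `uy`, `uz`.
#' @param probe tibble with one row per frame: head-group centre of mass
#'   (`head_x` ...), transition dipole (`tdm_x` ..., unit), long molecular
#'   axis (`axis_x` ..., unit), carbonyl oxygen (`co_x` ...) and amino
#'   nitrogen (`an_x` ...) positions.
#' @param waters tibble with one row per water per frame: `frame`,
#'   `water_id`, oxygen `ox`, `oy`, `oz` and hydrogens `h1x` ... `h2z`.
#'
#' @return An object of class `membrane_trajectory`.
#' @export
membrane_trajectory <- function(meta, box, lipids, probe, waters,
                                chains = NULL) {
  traj <- structure(
    list(meta = meta,
         box = tibble::as_tibble(box),
         lipids = tibble::as_tibble(lipids),
         chains = if (is.null(chains)) empty_chains() else tibble::as_tibble(chains),
         probe = tibble::as_tibble(probe),
         waters = tibble::as_tibble(waters)),
    class = "membrane_trajectory")
  validate_trajectory(traj)
  traj
}

empty_chains <- function() {
  tibble::tibble(frame = integer(), lipid_id = integer(), tail = character(),
                 carbon = integer(), h = integer(),
                 x = double(), y = double(), z = double(),
                 ux = double(), uy = double(), uz = double())
}

#' @export
print.membrane_trajectory <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<membrane_trajectory> %d frames, dt = %g ns, T = %g K, conformer %s\n",
              n_frames(x), m$dt, m$temperature, m$conformer))
  cat(sprintf("  lipids: %d/frame  waters: %d/frame  C-H rows: %d\n",
              if (n_frames(x)) nrow(x$lipids) / n_frames(x) else 0L,
              if (n_frames(x)) nrow(x$waters) / n_frames(x) else 0L,
              nrow(x$chains)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `membrane_trajectory`
#' @return integer frame count
#' @export
n_frames <- function(traj) nrow(traj$box)

#' Validate a membrane trajectory
#'
#' Checks the structural invariants: positive `dt` and temperature, finite
#' coordinates, unit-norm dipole/axis/C-H vectors, physical water O-H bond
#' lengths and a consistent leaflet assignment (leaflet label agrees with the
#' sign of the phosphorus z relative to the membrane midplane).
#'
#' @param traj a `membrane_trajectory`
#' @return `traj`, invisibly; errors describe the first violated invariant.
#' @export
validate_trajectory <- function(traj) {
  m <- traj$meta
  if (is.null(m$dt) || m$dt <= 0) stop("meta$dt must be > 0", call. = FALSE)
  if (is.null(m$temperature) || m$temperature <= 0) stop("meta$temperature must be > 0", call. = FALSE)
  if (is.null(m$excitation_time) || m$excitation_time < 0) stop("meta$excitation_time must be >= 0", call. = FALSE)
  if (!m$conformer %in% c("I", "II", "mixed")) stop("conformer must be 'I', 'II' or 'mixed'", call. = FALSE)

  num_cols <- function(df) df[vapply(df, is.numeric, logical(1))]
  for (part in c("box", "lipids", "chains", "probe", "waters")) {
    vals <- unlist(num_cols(traj[[part]]), use.names = FALSE)
    if (length(vals) && any(!is.finite(vals))) {
      stop(sprintf("non-finite value in trajectory component '%s'", part), call. = FALSE)
    }
  }

  if (nrow(traj$probe)) {
    assert_unit(traj$probe$tdm_x, traj$probe$tdm_y, traj$probe$tdm_z, "probe tdm", tol = 1e-4)
    assert_unit(traj$probe$axis_x, traj$probe$axis_y, traj$probe$axis_z, "probe long axis", tol = 1e-4)
  }
  if (nrow(traj$chains)) {
    assert_unit(traj$chains$ux, traj$chains$uy, traj$chains$uz, "C-H vector", tol = 1e-4)
  }
  if (nrow(traj$waters)) {
    d1 <- vec_norm(traj$waters$h1x - traj$waters$ox,
                   traj$waters$h1y - traj$waters$oy,
                   traj$waters$h1z - traj$waters$oz)
    d2 <- vec_norm(traj$waters$h2x - traj$waters$ox,
                   traj$waters$h2y - traj$waters$oy,
                   traj$waters$h2z - traj$waters$oz)
    if (any(d1 <= 0.05 | d1 >= 0.15) || any(d2 <= 0.05 | d2 >= 0.15)) {
      stop("water O-H distances must lie in (0.05, 0.15) nm", call. = FALSE)
    }
  }
  if (nrow(traj$lipids)) {
    bad <- traj$lipids |>
      dplyr::group_by(.data$frame) |>
      dplyr::mutate(center = midplane_z(.data$z, .data$leaflet),
                    ok = (.data$leaflet == "upper") == (.data$z >= .data$center)) |>
      dplyr::ungroup()
    if (!all(bad$ok)) {
      stop("leaflet labels disagree with phosphorus z relative to the membrane midplane",
           call. = FALSE)
    }
  }
  invisible(traj)
}

# membrane midplane: midpoint between the per-leaflet mean phosphorus z
midplane_z <- function(z, leaflet) {
  up <- mean(z[leaflet == "upper"])
  lo <- mean(z[leaflet == "lower"])
  if (!is.finite(up) || !is.finite(lo)) stop("a frame has an empty leaflet", call. = FALSE)
  (up + lo) / 2
}

# per-frame membrane centre as a tibble(frame, center)
frame_centers <- function(traj) {
  traj$lipids |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(center = midplane_z(.data$z, .data$leaflet), .groups = "drop")
}

# assign leaflets from scratch: split about the mean phosphorus z, then refine
# once with the midpoint of the leaflet means
assign_leaflets <- function(z) {
  mid <- mean(z)
  leaf <- ifelse(z >= mid, "upper", "lower")
  mid2 <- (mean(z[leaf == "upper"]) + mean(z[leaf == "lower"])) / 2
  ifelse(z >= mid2, "upper", "lower")
}
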