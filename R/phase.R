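#' Area per lipid
#'
#' Per frame, the lateral box area divided by the number of lipids per
#' leaflet, reported in A^2 (internal lengths are nm, hence the factor 100).
#' The probe is not counted as a lipid unless `count_probe = TRUE`.
#'
#' @param traj a [membrane_trajectory()]
#' @param count_probe add the probe to the per-leaflet lipid count
#' @param allow_unequal proceed when the leaflet counts differ (uses their
#'   mean)
#' @return tibble `frame`, `time`, `apl` with attribute `mean_apl` (A^2)
#' @export
area_per_lipid <- function(traj, count_probe = FALSE, allow_unequal = FALSE) {
  counts <- traj$lipids |>
    dplyr::group_by(.data$frame, .data$leaflet) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "leaflet", values_from = "n")
  if (!all(c("upper", "lower") %in% names(counts))) {
    stop("a frame has an empty leaflet", call. = FALSE)
  }
  if (any(counts$upper != counts$lower) && !allow_unequal) {
    stop("unequal lipid counts per leaflet; pass allow_unequal = TRUE to override",
         call. = FALSE)
  }
  n_leaf <- (counts$upper + counts$lower) / 2 + as.integer(count_probe)
  series <- tibble::tibble(frame = counts$frame,
                           time = traj$box$time[match(counts$frame, traj$box$frame)],
                           apl = traj$box$lx[match(counts$frame, traj$box$frame)] *
                             traj$box$ly[match(counts$frame, traj$box$frame)] *
                             100 / n_leaf)
  attr(series, "mean_apl") <- mean(series$apl)
  series
}

#' Deuterium order parameters per chain carbon
#'
#' `S_CD(k) = < (3 cos^2 theta - 1) / 2 >` with theta the angle between each
#' C-H bond of carbon k and the membrane normal, averaged over hydrogens,
#' lipids and frames. -0.5 means C-H perpendicular to the normal (fully
#' ordered chain), 0 isotropic.
#'
#' @param traj a [membrane_trajectory()]
#' @param tail `"sn1"`, `"sn2"` or `"probe_tail"`
#' @return tibble `carbon`, `scd`, `n` (samples per carbon)
#' @export
deuterium_order_parameters <- function(traj, tail = c("sn1", "sn2", "probe_tail")) {
  tail <- match.arg(tail)
  ch <- traj$chains[traj$chains$tail == tail, ]
  if (!nrow(ch)) stop(sprintf("trajectory has no '%s' C-H vectors", tail), call. = FALSE)
  ch |>
    dplyr::group_by(carbon = .data$carbon) |>
    dplyr::summarise(scd = mean(p2(.data$uz)), n = dplyr::n(), .groups = "drop")
}

#' Mean |S_CD| over the plateau carbons
#'
#' Convenience summary used as a phase feature: the plateau region (carbons
#' 2-10 by default) carries the phase signature.
#'
#' @param profile result of [deuterium_order_parameters()]
#' @param carbons plateau carbon indices
#' @return mean absolute S_CD
#' @export
scd_plateau <- function(profile, carbons = 2:10) {
  mean(abs(profile$scd[profile$carbon %in% carbons]))
}

#' Two-dimensional membrane thickness map
#'
#' For one frame, the lateral box is divided into square cells of
#' `cell_size`; per cell the thickness is the mean upper-leaflet phosphorus
#' z minus the mean lower-leaflet phosphorus z of the atoms falling in the
#' cell. Cells empty in either leaflet are filled by nearest-neighbour
#' interpolation and flagged.
#'
#' @param traj a [membrane_trajectory()]
#' @param frame frame to map (default the last, the conventional
#'   representative snapshot)
#' @param cell_size nm
#' @return `thickness_map` tibble `x`, `y` (cell centres), `thickness` (nm),
#'   `interpolated`; attributes `cell_size`, `nx`, `ny`, `box`
#' @export
thickness_map <- function(traj, frame = max(traj$box$frame), cell_size = 0.3) {
  b <- traj$box[traj$box$frame == frame, ]
  if (!nrow(b)) stop("frame not present in trajectory", call. = FALSE)
  if (cell_size > b$lx || cell_size > b$ly) {
    stop("cell_size larger than the box", call. = FALSE)
  }
  lip <- traj$lipids[traj$lipids$frame == frame, ]
  if (!all(c("upper", "lower") %in% lip$leaflet)) {
    stop("both leaflets must be populated", call. = FALSE)
  }
  nx <- max(1L, floor(b$lx / cell_size))
  ny <- max(1L, floor(b$ly / cell_size))
  cw_x <- b$lx / nx
  cw_y <- b$ly / ny
  ix <- pmin(pmax(floor((lip$x %% b$lx) / cw_x), 0), nx - 1)
  iy <- pmin(pmax(floor((lip$y %% b$ly) / cw_y), 0), ny - 1)

  agg <- tibble::tibble(ix = ix, iy = iy, leaflet = lip$leaflet, z = lip$z) |>
    dplyr::group_by(.data$ix, .data$iy, .data$leaflet) |>
    dplyr::summarise(z = mean(.data$z), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "leaflet", values_from = "z")
  if (!"upper" %in% names(agg)) agg$upper <- NA_real_
  if (!"lower" %in% names(agg)) agg$lower <- NA_real_

  grid <- tidyr::expand_grid(ix = 0:(nx - 1), iy = 0:(ny - 1)) |>
    dplyr::left_join(agg, by = c("ix", "iy")) |>
    dplyr::mutate(thickness = .data$upper - .data$lower,
                  interpolated = !is.finite(.data$thickness))

  # nearest-neighbour fill under periodic lateral boundaries
  if (any(grid$interpolated) && !all(grid$interpolated)) {
    known <- grid[!grid$interpolated, ]
    miss <- which(grid$interpolated)
    for (i in miss) {
      dx <- abs(grid$ix[i] - known$ix); dx <- pmin(dx, nx - dx) * cw_x
      dy <- abs(grid$iy[i] - known$iy); dy <- pmin(dy, ny - dy) * cw_y
      grid$thickness[i] <- known$thickness[which.min(dx^2 + dy^2)]
    }
  }

  out <- tibble::tibble(x = (grid$ix + 0.5) * cw_x, y = (grid$iy + 0.5) * cw_y,
                        thickness = grid$thickness,
                        interpolated = grid$interpolated)
  attr(out, "cell_size") <- c(cw_x, cw_y)
  attr(out, "nx") <- nx
  attr(out, "ny") <- ny
  attr(out, "box") <- c(b$lx, b$ly)
  class(out) <- c("thickness_map", class(out))
  out
}

#' Ripple metrics of a thickness map
#'
#' Root-mean-square thickness variation about the map mean, and the
#' dominant lateral wavelength from the peak of the two-dimensional spatial
#' power spectrum (zero mode excluded). A flat or fully interpolated map is
#' flagged and returns no wavelength.
#'
#' @param map a [thickness_map()]
#' @param flat_tol rms (nm) below which the map is treated as flat
#' @return one-row tibble `rms`, `dominant_wavelength`, `flagged`
#' @export
ripple_metrics <- function(map, flat_tol = 1e-6) {
  nx <- attr(map, "nx"); ny <- attr(map, "ny")
  if (nx < 4 || ny < 4) stop("map must cover at least 4 x 4 cells", call. = FALSE)
  box <- attr(map, "box")
  if (all(map$interpolated)) {
    return(tibble::tibble(rms = NA_real_, dominant_wavelength = NA_real_, flagged = TRUE))
  }
  m <- matrix(map$thickness[order(map$y, map$x)], nrow = ny, ncol = nx, byrow = TRUE)
  rms <- sqrt(mean((m - mean(m))^2))
  if (rms < flat_tol) {
    return(tibble::tibble(rms = rms, dominant_wavelength = NA_real_, flagged = TRUE))
  }
  sp <- Mod(stats::fft(m - mean(m)))^2
  kx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / box[1]   # cycles per nm
  ky <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / box[2]
  kmag <- sqrt(outer(ky^2, kx^2, `+`))
  sp[1, 1] <- 0                                        # drop the zero mode
  peak <- which(sp == max(sp), arr.ind = TRUE)[1, ]
  tibble::tibble(rms = rms, dominant_wavelength = 1 / kmag[peak[1], peak[2]],
                 flagged = FALSE)
}

#' Heuristic bilayer phase call from fingerprint features
#'
#' Rule-based labelling of the DPPC phase from the area per lipid, the
#' plateau |S_CD| and the thickness-ripple RMS: APL at or above
#' `apl_alpha` with low order is liquid-disordered (La); APL at or below
#' `apl_c` with high order is the liquid crystal (Lc); otherwise the gel
#' (Lb'), upgraded to the ripple phase (Pb') when the ripple RMS passes its
#' threshold. Advisory, mirroring identification by inspection of the same
#' features.
#'
#' @param apl area per lipid, A^2
#' @param scd_plateau mean plateau |S_CD|
#' @param ripple_rms nm
#' @param thresholds named list: `apl_alpha` (default 55), `apl_c` (51.5),
#'   `order_high` (0.25), `order_low` (0.15), `ripple_rms` (0.2)
#' @return one-row tibble `label`, the features and the thresholds echoed
#' @export
classify_phase <- function(apl, scd_plateau, ripple_rms,
                           thresholds = list()) {
  th <- utils::modifyList(list(apl_alpha = 55, apl_c = 51.5,
                               order_high = 0.25, order_low = 0.15,
                               ripple_rms = 0.2), thresholds)
  stopifnot(is.finite(apl), is.finite(scd_plateau), is.finite(ripple_rms))
  label <- if (apl >= th$apl_alpha && scd_plateau <= th$order_low) {
    "Lalpha"
  } else if (apl <= th$apl_c && scd_plateau >= th$order_high) {
    "Lc"
  } else if (ripple_rms >= th$ripple_rms) {
    "Pbeta"
  } else {
    "Lbeta"
  }
  tibble::tibble(label = label, apl = apl, scd_plateau = scd_plateau,
                 ripple_rms = ripple_rms,
                 thresholds = list(th))
}
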