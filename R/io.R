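# Trajectory, emission-table and curve file formats.
#
# Coordinate files use a GRO-style fixed-column dialect: per frame a title
# line carrying the time, an atom count, one line per atom
# (resid, resname, atom name, atom number, x, y, z in nm) and a box line.
# Positions are written with 7 decimals so write -> read round-trips to
# better than 1e-6 nm. Orientations (probe tdm/long axis, C-H bonds) are
# serialised as anchor-atom positions and recovered as normalised
# differences on read.
#
# Atom-name conventions (documented; remapping is not needed for files the
# package writes itself):
#   DPPC  P            lipid phosphorus
#         CAkk / HAkkh sn-1 carbon kk and its hydrogens (h = 1, 2)
#         CBkk / HBkkh sn-2 carbon kk and hydrogens
#   LAUR  HEAD         probe head-group centre of mass
#         TDM, AX      anchors at head + 0.1 nm along tdm / long axis
#         OC, NAM      carbonyl oxygen, amino nitrogen
#         CTkk / HTkkh probe lauric tail
#   SOL   OW, HW1, HW2 water

CH_BOND_NM <- 0.109     # C-H anchor distance used for serialisation
ANCHOR_NM <- 0.1        # tdm / long-axis anchor distance

gro_atom_line <- function(resid, resname, atom, atomno, x, y, z) {
  sprintf("%5d%-5s%5s%5d%12.7f%12.7f%12.7f",
          resid %% 100000L, resname, atom, atomno %% 100000L, x, y, z)
}

#' Write a membrane trajectory to a GRO-dialect coordinate file
#'
#' One snapshot block per frame; a YAML sidecar holds the metadata
#' (temperature, conformer, frame spacing, excitation time).
#'
#' @param traj a [membrane_trajectory()]
#' @param path output coordinate file; the sidecar is written to
#'   `meta_path` (default `paste0(path, ".yml")`)
#' @param meta_path sidecar path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path, meta_path = paste0(path, ".yml")) {
  validate_trajectory(traj)
  frames <- traj$box$frame
  blocks <- purrr::map(frames, function(f) gro_frame_block(traj, f))
  writeLines(as.character(unlist(blocks)), path)
  yaml::write_yaml(list(temperature = traj$meta$temperature,
                        conformer = traj$meta$conformer,
                        dt = traj$meta$dt,
                        excitation_time = traj$meta$excitation_time),
                   meta_path)
  invisible(path)
}

gro_frame_block <- function(traj, f) {
  box <- traj$box[traj$box$frame == f, ]
  lip <- traj$lipids[traj$lipids$frame == f, ]
  cha <- traj$chains[traj$chains$frame == f, ]
  pro <- traj$probe[traj$probe$frame == f, ]
  wat <- traj$waters[traj$waters$frame == f, ]

  lines <- character(0)
  resid <- 0L
  atomno <- 0L
  add <- function(resname, atom, x, y, z) {
    atomno <<- atomno + length(x)
    lines[[length(lines) + 1L]] <<-
      paste(gro_atom_line(resid, resname, atom,
                          seq(atomno - length(x) + 1L, atomno), x, y, z),
            collapse = "\n")
  }

  for (i in seq_len(nrow(lip))) {
    resid <- resid + 1L
    add("DPPC", "P", lip$x[i], lip$y[i], lip$z[i])
    ci <- cha[cha$lipid_id == lip$lipid_id[i] & cha$tail %in% c("sn1", "sn2"), ]
    if (nrow(ci)) {
      tl <- ifelse(ci$tail == "sn1", "A", "B")
      cn <- sprintf("C%s%02d", tl, ci$carbon)
      hn <- sprintf("H%s%02d%d", tl, ci$carbon, ci$h)
      first_h <- !duplicated(paste(cn))
      add("DPPC", cn[first_h], ci$x[first_h], ci$y[first_h], ci$z[first_h])
      add("DPPC", hn, ci$x + CH_BOND_NM * ci$ux,
          ci$y + CH_BOND_NM * ci$uy, ci$z + CH_BOND_NM * ci$uz)
    }
  }

  if (nrow(pro)) {
    resid <- resid + 1L
    add("LAUR", "HEAD", pro$head_x, pro$head_y, pro$head_z)
    add("LAUR", "TDM", pro$head_x + ANCHOR_NM * pro$tdm_x,
        pro$head_y + ANCHOR_NM * pro$tdm_y, pro$head_z + ANCHOR_NM * pro$tdm_z)
    add("LAUR", "AX", pro$head_x + ANCHOR_NM * pro$axis_x,
        pro$head_y + ANCHOR_NM * pro$axis_y, pro$head_z + ANCHOR_NM * pro$axis_z)
    add("LAUR", "OC", pro$co_x, pro$co_y, pro$co_z)
    add("LAUR", "NAM", pro$an_x, pro$an_y, pro$an_z)
    ct <- cha[cha$tail == "probe_tail", ]
    if (nrow(ct)) {
      cn <- sprintf("CT%02d", ct$carbon)
      hn <- sprintf("HT%02d%d", ct$carbon, ct$h)
      first_h <- !duplicated(cn)
      add("LAUR", cn[first_h], ct$x[first_h], ct$y[first_h], ct$z[first_h])
      add("LAUR", hn, ct$x + CH_BOND_NM * ct$ux,
          ct$y + CH_BOND_NM * ct$uy, ct$z + CH_BOND_NM * ct$uz)
    }
  }

  if (nrow(wat)) {
    resids <- resid + seq_len(nrow(wat))
    resid <- resid + nrow(wat)
    n0 <- atomno
    atomno <- atomno + 3L * nrow(wat)
    ww <- rbind(
      data.frame(resid = resids, atom = "OW", x = wat$ox, y = wat$oy, z = wat$oz, ord = 1),
      data.frame(resid = resids, atom = "HW1", x = wat$h1x, y = wat$h1y, z = wat$h1z, ord = 2),
      data.frame(resid = resids, atom = "HW2", x = wat$h2x, y = wat$h2y, z = wat$h2z, ord = 3))
    ww <- ww[order(ww$resid, ww$ord), ]
    lines[[length(lines) + 1L]] <-
      paste(gro_atom_line(ww$resid, "SOL", ww$atom, n0 + seq_len(nrow(ww)),
                          ww$x, ww$y, ww$z), collapse = "\n")
  }

  c(sprintf("laurdanscope frame=%d t=%.7f", f, box$time),
    sprintf("%5d", atomno),
    lines,
    sprintf("%12.7f%12.7f%12.7f", box$lx, box$ly, box$lz))
}

#' Read a membrane trajectory from a GRO-dialect coordinate file
#'
#' Inverse of [write_trajectory()]. Coordinates are wrapped into the primary
#' box (per residue, so molecules stay intact); leaflets are assigned from
#' the phosphorus z relative to the membrane midplane; C-H and probe
#' orientation unit vectors are recovered from their anchor atoms.
#'
#' @param path coordinate file
#' @param meta_path YAML sidecar (default `paste0(path, ".yml")`)
#' @return a [membrane_trajectory()]
#' @export
read_trajectory <- function(path, meta_path = paste0(path, ".yml")) {
  if (!file.exists(meta_path)) stop("metadata sidecar not found: ", meta_path, call. = FALSE)
  meta <- yaml::read_yaml(meta_path)
  for (k in c("temperature", "conformer", "dt", "excitation_time")) {
    if (is.null(meta[[k]])) stop("sidecar is missing field '", k, "'", call. = FALSE)
  }
  lines <- readLines(path)

  i <- 1L
  frame <- 0L
  times <- double(0)
  acc <- list(box = list(), lipids = list(), chains = list(),
              probe = list(), waters = list())
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame <- frame + 1L
    tmatch <- regmatches(lines[i], regexpr("t= *[-0-9.eE+]+", lines[i]))
    tval <- if (length(tmatch)) as.numeric(sub("t= *", "", tmatch)) else NA_real_
    natoms <- as.integer(trimws(lines[i + 1L]))
    if (is.na(natoms)) stop(sprintf("frame %d: unreadable atom count", frame), call. = FALSE)
    atom_lines <- lines[(i + 2L):(i + 1L + natoms)]
    box_line <- lines[i + 2L + natoms]
    bx <- as.numeric(substring(box_line, c(1, 13, 25), c(12, 24, 36)))
    if (any(is.na(bx))) stop(sprintf("frame %d: unreadable box line", frame), call. = FALSE)
    parsed <- parse_gro_frame(atom_lines, frame, bx)
    times <- c(times, tval)
    acc$box[[frame]] <- tibble::tibble(frame = frame, time = tval,
                                       lx = bx[1], ly = bx[2], lz = bx[3])
    acc$lipids[[frame]] <- parsed$lipids
    acc$chains[[frame]] <- parsed$chains
    acc$probe[[frame]] <- parsed$probe
    acc$waters[[frame]] <- parsed$waters
    i <- i + 3L + natoms
  }

  if (frame > 2L) {
    dts <- diff(times)
    if (max(dts) - min(dts) > 1e-6) stop("non-uniform frame spacing in trajectory file", call. = FALSE)
  }

  membrane_trajectory(
    meta = list(temperature = meta$temperature, conformer = meta$conformer,
                dt = meta$dt, excitation_time = meta$excitation_time),
    box = dplyr::bind_rows(acc$box),
    lipids = dplyr::bind_rows(acc$lipids),
    chains = dplyr::bind_rows(acc$chains),
    probe = dplyr::bind_rows(acc$probe),
    waters = dplyr::bind_rows(acc$waters))
}

parse_gro_frame <- function(atom_lines, frame, box) {
  resid <- as.integer(substring(atom_lines, 1, 5))
  resname <- trimws(substring(atom_lines, 6, 10))
  atom <- trimws(substring(atom_lines, 11, 15))
  x <- as.numeric(substring(atom_lines, 21, 32))
  y <- as.numeric(substring(atom_lines, 33, 44))
  z <- as.numeric(substring(atom_lines, 45, 56))
  if (any(is.na(x) | is.na(y) | is.na(z))) {
    stop(sprintf("frame %d: unreadable coordinates", frame), call. = FALSE)
  }

  # wrap per residue into the primary box, keeping molecules intact
  key <- paste(resname, resid)
  ref <- !duplicated(key)
  shift_x <- (x[ref] %% box[1]) - x[ref]
  shift_y <- (y[ref] %% box[2]) - y[ref]
  shift_z <- (z[ref] %% box[3]) - z[ref]
  idx <- match(key, key[ref])
  x <- x + shift_x[idx]; y <- y + shift_y[idx]; z <- z + shift_z[idx]

  df <- data.frame(resid, resname, atom, x, y, z, stringsAsFactors = FALSE)

  # waters
  wat <- df[df$resname == "SOL", ]
  waters <- tibble::tibble(frame = integer(0))
  if (nrow(wat)) {
    wsplit <- split(wat, wat$resid)
    rows <- lapply(wsplit, function(w) {
      for (a in c("OW", "HW1", "HW2")) {
        if (sum(w$atom == a) != 1) {
          stop(sprintf("frame %d: water residue %d is missing atom %s",
                       frame, w$resid[1], a), call. = FALSE)
        }
      }
      o <- w[w$atom == "OW", ]; h1 <- w[w$atom == "HW1", ]; h2 <- w[w$atom == "HW2", ]
      data.frame(ox = o$x, oy = o$y, oz = o$z, h1x = h1$x, h1y = h1$y, h1z = h1$z,
                 h2x = h2$x, h2y = h2$y, h2z = h2$z)
    })
    waters <- tibble::as_tibble(do.call(rbind, rows))
    waters <- dplyr::mutate(waters, frame = frame, water_id = dplyr::row_number(),
                            .before = 1)
  }

  # lipids: phosphorus + chain C-H
  lip <- df[df$resname == "DPPC", ]
  lipids <- tibble::tibble(frame = integer(0))
  chains_l <- list()
  if (nrow(lip)) {
    p <- lip[lip$atom == "P", ]
    if (!nrow(p)) stop(sprintf("frame %d: no lipid phosphorus (atom P) found", frame), call. = FALSE)
    lipid_id <- match(p$resid, sort(unique(p$resid)))
    lipids <- tibble::tibble(frame = frame, lipid_id = lipid_id,
                             leaflet = assign_leaflets(p$z),
                             x = p$x, y = p$y, z = p$z)
    ch <- lip[grepl("^[CH][AB][0-9]{2}", lip$atom), ]
    if (nrow(ch)) chains_l[[1]] <- recover_ch_vectors(ch, frame, id_map = stats::setNames(lipid_id, p$resid))
  }

  # probe
  pro <- df[df$resname == "LAUR", ]
  probe <- tibble::tibble(frame = integer(0))
  if (nrow(pro)) {
    need <- c("HEAD", "TDM", "AX", "OC", "NAM")
    for (a in need) {
      if (sum(pro$atom == a) != 1) {
        stop(sprintf("frame %d: probe residue is missing atom %s", frame, a), call. = FALSE)
      }
    }
    g <- function(a) unlist(pro[pro$atom == a, c("x", "y", "z")], use.names = FALSE)
    head <- g("HEAD")
    tdm <- normalize_rows(matrix(g("TDM") - head, 1))
    ax <- normalize_rows(matrix(g("AX") - head, 1))
    oc <- g("OC"); an <- g("NAM")
    probe <- tibble::tibble(frame = frame,
                            head_x = head[1], head_y = head[2], head_z = head[3],
                            tdm_x = tdm[1], tdm_y = tdm[2], tdm_z = tdm[3],
                            axis_x = ax[1], axis_y = ax[2], axis_z = ax[3],
                            co_x = oc[1], co_y = oc[2], co_z = oc[3],
                            an_x = an[1], an_y = an[2], an_z = an[3])
    ct <- pro[grepl("^[CH]T[0-9]{2}", pro$atom), ]
    if (nrow(ct)) chains_l[[length(chains_l) + 1L]] <- recover_ch_vectors(ct, frame, probe_tail = TRUE)
  }

  list(lipids = lipids,
       chains = if (length(chains_l)) dplyr::bind_rows(chains_l) else empty_chains(),
       probe = probe, waters = waters)
}

recover_ch_vectors <- function(ch, frame, id_map = NULL, probe_tail = FALSE) {
  is_h <- substring(ch$atom, 1, 1) == "H"
  tail_code <- substring(ch$atom, 2, 2)
  carbon <- as.integer(substring(ch$atom, 3, 4))
  h_idx <- ifelse(is_h, as.integer(substring(ch$atom, 5, 5)), NA_integer_)
  tail <- if (probe_tail) rep("probe_tail", nrow(ch)) else
    ifelse(tail_code == "A", "sn1", "sn2")
  lid <- if (probe_tail) rep(0L, nrow(ch)) else unname(id_map[as.character(ch$resid)])

  ckey <- paste(lid, tail, carbon)
  cdf <- data.frame(ckey = ckey[!is_h], cx = ch$x[!is_h], cy = ch$y[!is_h], cz = ch$z[!is_h])
  hi <- which(is_h)
  m <- match(ckey[hi], cdf$ckey)
  if (any(is.na(m))) stop(sprintf("frame %d: hydrogen without its carbon in chain atoms", frame), call. = FALSE)
  u <- normalize_rows(cbind(ch$x[hi] - cdf$cx[m], ch$y[hi] - cdf$cy[m], ch$z[hi] - cdf$cz[m]))
  tibble::tibble(frame = frame, lipid_id = lid[hi], tail = tail[hi],
                 carbon = carbon[hi], h = h_idx[hi],
                 x = cdf$cx[m], y = cdf$cy[m], z = cdf$cz[m],
                 ux = u[, 1], uy = u[, 2], uz = u[, 3])
}

#' Read or write a per-snapshot emission table
#'
#' Tab-separated table with one row per QM/MM-style S1 emission record:
#' `snapshot_id`, `conformer`, `wavelength_nm` and/or `energy_ev`, and
#' `oscillator_strength`. Wavelength and energy are reconciled through
#' E\[eV\] = 1239.84193 / lambda\[nm\]; if both are present they must agree
#' to 0.1%.
#'
#' @param path TSV file
#' @return tibble with columns `snapshot_id`, `conformer`, `wavelength_nm`,
#'   `energy_ev`, `oscillator_strength`
#' @export
read_emission_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  names(df) <- tolower(names(df))
  if (!"snapshot_id" %in% names(df)) df$snapshot_id <- seq_len(nrow(df))
  if (!"conformer" %in% names(df)) df$conformer <- "I"
  has_l <- "wavelength_nm" %in% names(df)
  has_e <- "energy_ev" %in% names(df)
  if (!has_l && !has_e) stop("emission table needs a wavelength_nm or energy_ev column", call. = FALSE)
  if (!"oscillator_strength" %in% names(df)) stop("emission table needs an oscillator_strength column", call. = FALSE)
  if (has_l && has_e) {
    rel <- abs(df$energy_ev - nm_to_ev(df$wavelength_nm)) / df$energy_ev
    if (any(rel > 0.001)) {
      stop(sprintf("row %d: energy and wavelength disagree by more than 0.1%%",
                   which(rel > 0.001)[1]), call. = FALSE)
    }
  }
  if (!has_l) df$wavelength_nm <- ev_to_nm(df$energy_ev)
  if (!has_e) df$energy_ev <- nm_to_ev(df$wavelength_nm)
  out <- tibble::as_tibble(df[c("snapshot_id", "conformer", "wavelength_nm",
                                "energy_ev", "oscillator_strength")])
  validate_emission(out)
  out
}

validate_emission <- function(records) {
  if (any(records$oscillator_strength < 0)) stop("oscillator strengths must be >= 0", call. = FALSE)
  if (any(records$energy_ev <= 0)) stop("emission energies must be > 0", call. = FALSE)
  invisible(records)
}

#' @rdname read_emission_table
#' @param records emission tibble as returned by [read_emission_table()] or
#'   [generate_emission_table()]
#' @export
write_emission_table <- function(records, path) {
  validate_emission(records)
  utils::write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a decay/anisotropy curve as TSV
#'
#' Columns `t` and `y`; the curve kind and any Gaussian IRF parameters are
#' carried in `#key=value` header comments.
#'
#' @param path TSV file
#' @return a [new_curve()] tibble
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#([a-z_]+)=(.*)$", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  df <- utils::read.delim(text = lines[!grepl("^#", lines)])
  irf <- NULL
  if (!is.null(kv$irf_mean)) irf <- list(mean = as.numeric(kv$irf_mean),
                                         sigma = as.numeric(kv$irf_sigma))
  new_curve(df$t, df$y, kind = kv$kind %||% "intensity", irf = irf)
}

#' @rdname read_curve
#' @param curve a [new_curve()] tibble
#' @export
write_curve <- function(curve, path) {
  hdr <- sprintf("#kind=%s", curve_kind(curve))
  irf <- curve_irf(curve)
  if (!is.null(irf) && !is.null(irf$mean)) {
    hdr <- c(hdr, sprintf("#irf_mean=%.9g", irf$mean), sprintf("#irf_sigma=%.9g", irf$sigma))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(curve[c("t", "y")]), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
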