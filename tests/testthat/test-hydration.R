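test_that("g(r) approaches 1 for uniformly distributed waters", {
  set.seed(2)
  n <- 20000
  waters <- purrr::map_dfr(seq_len(n), function(i) {
    make_water(i, stats::runif(3, 0, 6), random_unit_vectors(1)[1, ])
  })
  traj <- toy_trajectory(lx = 6, ly = 6, lz = 6, half = 1, head_off = 1.5,
                         waters = waters)
  # head sits at (3, 3, 4.5); uniform density everywhere
  rdf <- water_rdf(traj, r_max = 1.5, dr = 0.05)
  outer_bins <- rdf$g[rdf$r > 0.5]
  expect_lt(abs(mean(outer_bins) - 1), 0.05)     # ideal-gas limit on average
  expect_true(all(abs(outer_bins - 1) < 0.4))    # no bin far off (shot noise)
})

test_that("coordination numbers equal a brute-force pair count at every bin", {
  set.seed(3)
  waters <- purrr::map_dfr(1:200, function(i) {
    make_water(i, stats::runif(3, 0, 6), random_unit_vectors(1)[1, ])
  })
  traj <- toy_trajectory(n_frames = 2, lx = 6, ly = 6, lz = 6, half = 1,
                         head_off = 0.8, waters = waters)
  rdf <- water_rdf(traj, r_max = 2, dr = 0.1)

  # independent O(frames x waters) count with minimum image
  brute <- sapply(rdf$r + 0.05, function(rc) {
    tot <- 0
    for (f in 1:2) {
      w <- traj$waters[traj$waters$frame == f, ]
      p <- traj$probe[traj$probe$frame == f, ]
      d <- sqrt(pmin(abs(w$ox - p$head_x), 6 - abs(w$ox - p$head_x))^2 +
                  pmin(abs(w$oy - p$head_y), 6 - abs(w$oy - p$head_y))^2 +
                  pmin(abs(w$oz - p$head_z), 6 - abs(w$oz - p$head_z))^2)
      tot <- tot + sum(d <= rc + 1e-12)
    }
    tot / 2
  })
  expect_equal(rdf$coordination, brute)
})

test_that("a single water inside the shell gives N = 1 and sensible occupancy", {
  w <- make_water(1L, c(2, 2, 6.5 + 0.30), c(0, 0, 1))  # 0.30 nm above the head
  traj <- toy_trajectory(lx = 4, ly = 4, lz = 10, head_off = 1.5, waters = w)
  rdf <- water_rdf(traj, r_max = 1, dr = 0.05)
  expect_equal(rdf$coordination[which.min(abs(rdf$r - 0.35))], 1)
  expect_equal(shell_occupancy(rdf, 0.35, 10), 10)
  expect_equal(shell_occupancy(rdf, 0.1, 10), 0)
  expect_error(shell_occupancy(rdf, 0.35, 0), "reference_total")
  expect_error(water_rdf(traj, r_max = 3), "half the smallest")
})

test_that("hydrogen-bond counts follow the geometric criterion and match enumeration", {
  center_z <- 5; head_off <- 1.5
  co_z <- center_z + head_off - 0.1                     # carbonyl oxygen z
  co <- c(2, 2, co_z)
  # water whose H1 lies exactly on the O -> acceptor axis (angle 0)
  water_oh_toward <- function(id, o, target) {
    a <- target - o; a <- a / sqrt(sum(a^2))
    ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    p <- ref - sum(ref * a) * a; p <- p / sqrt(sum(p^2))
    half <- 104.5 / 2 * pi / 180
    make_water(id, o, cos(half) * a + sin(half) * p,
               inplane = sin(half) * a - cos(half) * p)
  }
  qualifying <- function(id, dist, dir) {
    dir <- dir / sqrt(sum(dir^2))
    water_oh_toward(id, co + dist * dir, co)
  }
  # 3 qualify on distance+angle, 2 fail (distance; orientation); directions
  # keep every oxygen > 0.35 nm from the amino nitrogen
  w <- dplyr::bind_rows(
    qualifying(1L, 0.28, c(0, 0, -1)),
    qualifying(2L, 0.30, c(1, 0, 0)),
    qualifying(3L, 0.33, c(0, 1, 0)),
    qualifying(4L, 0.40, c(0, 0, -1)),                  # distance fails
    make_water(5L, co + c(-0.30, 0, 0), c(-1, 0, 0)))   # hydrogens point away
  traj <- toy_trajectory(head_off = head_off, waters = w)
  counts <- count_hbonds(traj, region_r = 0.6)
  expect_equal(counts$n_hbonds, 3)

  # brute-force enumeration over all water-hydrogen/acceptor pairs
  brute <- 0
  p <- traj$probe[1, ]
  for (i in seq_len(nrow(w))) {
    o <- c(w$ox[i], w$oy[i], w$oz[i])
    if (sqrt(sum((o - c(p$head_x, p$head_y, p$head_z))^2)) > 0.6) next
    for (acc in list(c(p$co_x, p$co_y, p$co_z), c(p$an_x, p$an_y, p$an_z))) {
      da <- sqrt(sum((acc - o)^2))
      if (da > 0.35) next
      for (h in list(c(w$h1x[i], w$h1y[i], w$h1z[i]), c(w$h2x[i], w$h2y[i], w$h2z[i]))) {
        v1 <- h - o; v2 <- acc - o
        ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
        if (ang <= 30) brute <- brute + 1
      }
    }
  }
  expect_equal(counts$n_hbonds, brute)

  # moving the first water out to 0.40 nm drops its bond
  w2 <- dplyr::bind_rows(qualifying(1L, 0.40, c(0, 0, -1)))
  expect_equal(count_hbonds(toy_trajectory(head_off = head_off, waters = w2),
                            region_r = 0.6)$n_hbonds, 0)
})

test_that("the orientation statistic is signed so oxygen-toward-probe is negative", {
  head <- c(2, 2, 6.5)
  # O above the head, bisector pointing further away: v2 parallel to v1
  w_away <- make_water(1L, head + c(0, 0, 0.5), c(0, 0, 1))
  traj <- toy_trajectory(head_off = 1.5, waters = w_away)
  expect_equal(solvent_orientation(traj)$orientation, -1, tolerance = 1e-9)

  # both hydrogens toward the head: v2 antiparallel to v1, +1 each
  w_toward <- dplyr::bind_rows(lapply(1:3, function(i) {
    make_water(i, head + c(0.2 * i, 0, 0.4), c(-0.2 * i, 0, -0.4))
  }))
  traj2 <- toy_trajectory(head_off = 1.5, waters = w_toward)
  expect_equal(solvent_orientation(traj2)$orientation, 3, tolerance = 1e-9)
  # per-frame magnitude is bounded by the in-radius water count
  expect_lte(abs(solvent_orientation(traj2)$orientation),
             solvent_orientation(traj2)$n_waters)
})

test_that("isotropically oriented waters average to zero orientation", {
  set.seed(4)
  nf <- 40; nw <- 100
  waters <- purrr::map_dfr(seq_len(nw), function(i) {
    o <- c(2, 2, 6.5) + 0.9 * random_unit_vectors(1)[1, ]
    make_water(i, o, random_unit_vectors(1)[1, ])
  })
  traj <- toy_trajectory(n_frames = nf, head_off = 1.5, waters = waters)
  # same orientations every frame, so test the single-frame sum: mean cos of
  # nw isotropic waters has sd sqrt(nw/3)
  val <- solvent_orientation(traj)$orientation[1]
  expect_lt(abs(val), 3 * sqrt(nw / 3))
})

test_that("the orientation statistic is invariant under a global rotation about z", {
  set.seed(5)
  waters <- purrr::map_dfr(1:30, function(i) {
    o <- c(2, 2, 6.5) + 0.8 * random_unit_vectors(1)[1, ]
    make_water(i, o, random_unit_vectors(1)[1, ])
  })
  traj <- toy_trajectory(head_off = 1.5, waters = waters)
  ang <- 0.7
  R <- function(x, y, cx = 2, cy = 2) {
    list(x = cx + cos(ang) * (x - cx) - sin(ang) * (y - cy),
         y = cy + sin(ang) * (x - cx) + cos(ang) * (y - cy))
  }
  rot <- traj
  for (pre in c("o", "h1", "h2")) {
    xy <- R(rot$waters[[paste0(pre, "x")]], rot$waters[[paste0(pre, "y")]])
    rot$waters[[paste0(pre, "x")]] <- xy$x
    rot$waters[[paste0(pre, "y")]] <- xy$y
  }
  expect_equal(solvent_orientation(rot)$orientation,
               solvent_orientation(traj)$orientation, tolerance = 1e-9)
})

test_that("windowed cumulative orientation averages frames inside each window", {
  w <- make_water(1L, c(2, 2, 7), c(0, 0, 1))
  traj <- toy_trajectory(n_frames = 30, dt = 0.1, head_off = 1.5, waters = w)
  win <- cumulative_solvent_orientation(traj, windows = list(c(0, 1), c(2, 2.9)))
  expect_equal(nrow(win), 2)
  expect_equal(win$n_frames[1], 11)                     # t = 0, 0.1, ..., 1.0
  expect_equal(win$value[1], -1, tolerance = 1e-9)
  expect_error(cumulative_solvent_orientation(traj, windows = list(c(-1, 0))),
               "excitation")
})

test_that("exponential relaxation is recovered exactly from noiseless series", {
  t <- seq(0, 12, 0.2)
  series <- tibble::tibble(t_after_excitation = t,
                           orientation = 3 * exp(-t / 1.5) - 4)
  fit <- fit_solvent_relaxation(series)
  expect_true(fit$converged)
  expect_equal(fit$relax_time, 1.5, tolerance = 1e-6)
  expect_equal(fit$asymptote, -4, tolerance = 1e-6)

  flat <- tibble::tibble(t_after_excitation = t, orientation = rep(2, length(t)))
  ffit <- fit_solvent_relaxation(flat)
  expect_false(ffit$converged)
  expect_error(fit_solvent_relaxation(series[1:3, ]), "4 time points")
})
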