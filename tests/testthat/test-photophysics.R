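rec <- function(lambda, f = 0.4, conf = "I") {
  tibble::tibble(snapshot_id = seq_along(lambda), conformer = conf,
                 wavelength_nm = lambda, energy_ev = 1239.84193 / lambda,
                 oscillator_strength = f)
}

test_that("spectral convolution reproduces the Gaussian definition and is linear", {
  grid <- seq(350, 470, by = 0.25)
  sp <- convolve_spectrum(rec(400), fwhm = 15, grid = grid)
  expect_equal(sp$wavelength[which.max(sp$intensity)], 400)
  at <- function(s, l) s$intensity[which.min(abs(s$wavelength - l))]
  expect_equal(at(sp, 400 + 7.5) / at(sp, 400), 0.5, tolerance = 1e-9)
  expect_equal(at(sp, 400 - 7.5) / at(sp, 400), 0.5, tolerance = 1e-9)

  sp2 <- convolve_spectrum(rec(c(400, 430), f = c(0.4, 0.4)), fwhm = 15, grid = grid)
  n_max <- sum(diff(sign(diff(sp2$intensity))) == -2)
  expect_equal(n_max, 2)

  # brute-force per-record summation oracle
  set.seed(7)
  lam <- runif(50, 360, 440); f <- runif(50, 0.2, 0.6)
  sp3 <- convolve_spectrum(rec(lam, f), fwhm = 12, grid = grid)
  sigma <- 12 / (2 * sqrt(2 * log(2)))
  oracle <- sapply(grid, function(g) {
    tot <- 0
    for (i in 1:50) tot <- tot + f[i] * exp(-(g - lam[i])^2 / (2 * sigma^2))
    tot
  })
  expect_equal(sp3$intensity, oracle, tolerance = 1e-12)

  # linearity: spectrum(A union B) = spectrum(A) + spectrum(B)
  a <- rec(lam[1:20], f[1:20]); b <- rec(lam[21:50], f[21:50])
  expect_equal(convolve_spectrum(dplyr::bind_rows(a, b), fwhm = 12, grid = grid)$intensity,
               convolve_spectrum(a, fwhm = 12, grid = grid)$intensity +
                 convolve_spectrum(b, fwhm = 12, grid = grid)$intensity,
               tolerance = 1e-12)
  expect_error(convolve_spectrum(rec(400)[0, ]), "no emission records")
})

test_that("peak and shoulder detection separates merged conformer components", {
  grid <- seq(320, 440, by = 0.25)
  single <- convolve_spectrum(rec(380), fwhm = 15, grid = grid)
  res <- find_peak_and_shoulders(single)
  expect_equal(res$peak_nm, 380)
  expect_equal(nrow(res$shoulders), 0)

  mix <- convolve_spectrum(rec(c(360, 375), f = c(1, 0.4)), fwhm = 15, grid = grid)
  res2 <- find_peak_and_shoulders(mix)
  expect_lt(abs(res2$peak_nm - 360), 1)
  expect_equal(nrow(res2$shoulders), 1)
  expect_gt(res2$shoulders$wavelength, 370)
  expect_lt(res2$shoulders$wavelength, 385)

  flat <- tibble::tibble(wavelength = grid, intensity = 1)
  expect_true(find_peak_and_shoulders(flat)$flagged)
})

test_that("generalized polarization hits its degenerate limits", {
  expect_equal(generalized_polarization(2, 2), 0)
  expect_equal(generalized_polarization(3, 0), 1)
  expect_equal(generalized_polarization(0, 3), -1)
  expect_error(generalized_polarization(0, 0), "> 0")
  # band extraction: pure blue band spectrum gives GP = +1
  grid <- seq(400, 530, 0.5)
  sp <- convolve_spectrum(rec(440), fwhm = 10, grid = grid)
  expect_gt(gp_from_spectrum(sp), 0.99)
})

test_that("radiative lifetimes follow the f nu^2 rate relation", {
  # f = 1 at 25000 cm^-1 (3.09960 eV): tau = 1.499/25000^2 s = 2.3984 ns
  e <- 25000 * 1.23984193e-4
  expect_equal(radiative_lifetime(e, f = 1), 2.3984, tolerance = 1e-4)
  expect_equal(radiative_lifetime(2 * e, f = 1),
               radiative_lifetime(e, f = 1) / 4, tolerance = 1e-12)
  expect_equal(radiative_lifetime(e, f = 0.5),
               2 * radiative_lifetime(e, f = 1), tolerance = 1e-12)
  expect_error(radiative_lifetime(e, f = 0), "infinite lifetime")

  tab <- radiative_lifetime(rec(400, f = 0.4))
  expect_equal(tab$lifetime_ns, 1e9 * 1.499 / (0.4 * 25000^2), tolerance = 1e-9)
})

test_that("decay-time histograms are unit-area and mean-consistent per conformer", {
  same <- rec(rep(400, 20))
  h <- decay_time_histogram(same)
  widths <- diff(h$bin_mid)[1]
  expect_equal(sum(h$density * widths), 1, tolerance = 1e-12)
  expect_equal(sum(h$density > 0), 1)

  set.seed(8)
  records <- dplyr::bind_rows(rec(runif(50, 360, 420), conf = "I"),
                              rec(runif(50, 380, 440), conf = "II"))
  h2 <- decay_time_histogram(records, bins = 12)
  for (cf in c("I", "II")) {
    hh <- h2[h2$conformer == cf, ]
    w <- diff(hh$bin_mid)[1]
    expect_equal(sum(hh$density * w), 1, tolerance = 1e-9)
    direct <- mean(radiative_lifetime(records[records$conformer == cf, ])$lifetime_ns)
    expect_lt(abs(sum(hh$bin_mid * hh$density * w) - direct), w / 2)
    expect_equal(unname(attr(h2, "means")[cf]), direct)
  }
})

test_that("anisotropy decay has exact r(0) and the free/frozen/decorrelated limits", {
  # frozen dipole
  u <- matrix(rep(c(0, 0, 1), each = 50), ncol = 3)
  res <- anisotropy_decay(u, max_lag = 2, dt = 0.1)
  expect_equal(res$curve$y, rep(0.4, length(res$curve$y)))

  # independently resampled isotropic dipoles decorrelate immediately
  set.seed(9)
  u2 <- random_unit_vectors(10001)
  res2 <- anisotropy_decay(u2, max_lag = 0.5, dt = 0.1)
  expect_equal(res2$r0, 0.4)
  expect_true(all(abs(res2$curve$y[-1]) < 0.02))

  # free isotropic diffusion: r(t) = 0.4 exp(-6 D t), averaged over
  # independent trajectories to tame origin-correlation noise
  D <- 0.1
  curves <- lapply(1:4, function(k) {
    u3 <- simulate_dipole_trajectory(30000, 0.01, D, cone_semiangle = NULL,
                                     seed = 10 + k)
    anisotropy_decay(u3, max_lag = 3, dt = 0.01)$curve
  })
  avg <- new_curve(curves[[1]]$t, rowMeans(sapply(curves, `[[`, "y")),
                   kind = "anisotropy")
  fit <- fit_anisotropy(avg, offset = FALSE)
  expect_true(fit$converged)
  expect_lt(abs(1 / fit$time_constant - 6 * D) / (6 * D), 0.05)

  expect_error(anisotropy_decay(u, max_lag = 10, dt = 0.1), "below the trajectory span")
})

test_that("TCSPC simulation matches exponential-mixture moments and conserves photons", {
  cv <- simulate_tcspc_decay(list(c(4, 100)), n_photons = 50000, seed = 11)
  expect_equal(sum(cv$y), 50000)
  m <- sum(cv$t * cv$y) / sum(cv$y)
  expect_lt(abs(m - 4), 3 * 4 / sqrt(50000) + 0.05)   # CLT + binning slack

  cv2 <- simulate_tcspc_decay(list(c(4, 100)), n_photons = 50000,
                              irf = list(mean = 2, sigma = 0.3), seed = 11)
  m2 <- sum(cv2$t * cv2$y) / sum(cv2$y)
  expect_lt(abs(m2 - 6), 3 * sqrt(16 + 0.09) / sqrt(50000) + 0.05)

  expect_error(simulate_tcspc_decay(list(c(4, 100)), 0), "n_photons")
  expect_error(simulate_tcspc_decay(list(c(4, 60)), 10), "sum to 100")
})

test_that("a noiseless mono-exponential is fitted essentially exactly", {
  t <- seq(0.025, 40, by = 0.05)
  y <- 1e6 * exp(-t / 5) * 0.05 / 5
  cv <- new_curve(t, y, kind = "intensity")
  fit <- fit_exponential_decay(cv, n_components = 1)
  expect_true(fit$converged)
  expect_equal(fit$lifetimes, 5, tolerance = 1e-6)
  expect_equal(fit$intensity_fractions, 100)
})

test_that("bi-exponential Poisson fits agree with a grid-search oracle", {
  cv <- simulate_tcspc_decay(list(c(7, 60), c(2, 40)), n_photons = 2e5, seed = 12)
  fit <- fit_exponential_decay(cv, n_components = 2)
  expect_true(fit$converged)
  expect_equal(sum(fit$intensity_fractions), 100, tolerance = 1e-9)

  # exhaustive coarse grid over (tau_slow, tau_fast, f_slow), same likelihood
  bw <- cv$t[2] - cv$t[1]
  loglik <- function(t1, t2, f1) {
    m <- sum(cv$y) * (f1 * exp(-cv$t / t1) / t1 + (1 - f1) * exp(-cv$t / t2) / t2) * bw
    m <- pmax(m, 1e-300)
    sum(cv$y * log(m) - m)
  }
  gr <- expand.grid(t1 = seq(5, 9, 0.25), t2 = seq(1, 3, 0.25), f1 = seq(0.3, 0.9, 0.05))
  gr$ll <- mapply(loglik, gr$t1, gr$t2, gr$f1)
  top <- gr[which.max(gr$ll), ]
  expect_lt(abs(fit$lifetimes[1] - top$t1), 0.25 + 1e-9)
  expect_lt(abs(fit$lifetimes[2] - top$t2), 0.25 + 1e-9)
  expect_lt(abs(fit$intensity_fractions[1] / 100 - top$f1), 0.05 + 1e-9)

  # fits are equivariant under count rescaling
  cv3 <- new_curve(cv$t, cv$y * 3, kind = "intensity")
  fit3 <- fit_exponential_decay(cv3, n_components = 2)
  expect_equal(fit3$lifetimes, fit$lifetimes, tolerance = 1e-3)
  expect_equal(fit3$intensity_fractions, fit$intensity_fractions, tolerance = 1e-2)
})

test_that("tidy and glance expose the fit in Table form", {
  cv <- simulate_tcspc_decay(list(c(7, 60), c(2, 40)), n_photons = 5e4, seed = 13)
  fit <- fit_exponential_decay(cv, n_components = 2)
  td <- tidy(fit)
  expect_named(td, c("component", "lifetime", "lifetime_se",
                     "intensity_fraction", "fraction_se", "amplitude"))
  expect_equal(nrow(td), 2)
  expect_gte(td$lifetime[1], td$lifetime[2])            # slow first
  expect_equal(sum(td$intensity_fraction), 100, tolerance = 1e-9)
  expect_equal(sum(td$amplitude), 1, tolerance = 1e-12)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$total_counts, sum(cv$y))
})

test_that("mixture anisotropy reduces to the common value and shows the turn-up", {
  tg <- seq(0, 30, 0.05)
  pops_eq <- tibble::tibble(fraction = c(30, 70), lifetime = c(7, 3), r0 = 0.3)
  expect_equal(two_population_anisotropy(pops_eq, tg)$y, rep(0.3, length(tg)))

  # r(0) is the amplitude-weighted mean
  pops <- tibble::tibble(fraction = c(43, 57), lifetime = c(7.46, 3.58),
                         r0 = c(0.35, 0.35), r_inf = c(NA, 0), theta = c(NA, 1.39))
  w0 <- pops$fraction / pops$lifetime
  expect_equal(two_population_anisotropy(pops, tg)$y[1],
               sum(w0 * pops$r0) / sum(w0))

  # slow constant + fast decaying population: non-monotonic with a rise
  r <- two_population_anisotropy(pops, tg)$y
  dr <- diff(r)
  expect_true(any(dr < -1e-9) && any(dr > 1e-9))
  first_rise <- which(dr > 1e-9)[1]
  expect_true(any(dr[seq_len(first_rise - 1)] < 0))     # falls, then turns up
  expect_error(two_population_anisotropy(dplyr::mutate(pops, fraction = c(50, 40)), tg),
               "sum to 100")
})

test_that("steady-state anisotropy integrates to the Perrin form", {
  tg <- seq(0, 150, 0.01)
  ic <- new_curve(tg, exp(-tg / 4), kind = "intensity")
  rconst <- new_curve(tg, rep(0.32, length(tg)), kind = "anisotropy")
  expect_equal(steady_state_anisotropy(rconst, ic), 0.32, tolerance = 1e-12)

  theta <- 2
  rdec <- new_curve(tg, 0.4 * exp(-tg / theta), kind = "anisotropy")
  expect_equal(steady_state_anisotropy(rdec, ic), 0.4 / (1 + 4 / theta),
               tolerance = 1e-4)

  rzero <- new_curve(tg, rep(0, length(tg)), kind = "anisotropy")
  expect_equal(steady_state_anisotropy(rzero, ic), 0)
  expect_error(steady_state_anisotropy(rconst, new_curve(tg, rep(0, length(tg)))),
               "integral is zero")
})
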