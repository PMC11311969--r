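#' Gaussian-broadened emission spectrum from snapshot records
#'
#' Each snapshot emission line is broadened with a Gaussian of the given
#' full width at half maximum and summed, weighted by its oscillator
#' strength (or uniformly). Per-conformer component spectra are retained
#' alongside their sum. The default 15 nm broadening renders conformer
#' components ~15 nm apart as a peak plus shoulder, the fingerprint the
#' summed spectra show.
#'
#' @param records emission tibble ([read_emission_table()] /
#'   [generate_emission_table()])
#' @param fwhm nm full width at half maximum (sigma = fwhm / 2.3548)
#' @param grid wavelength grid, nm
#' @param weights `"oscillator"` (default) or `"uniform"`
#' @return `emission_spectrum` tibble: `wavelength`, `intensity`, one
#'   column per conformer component
#' @export
convolve_spectrum <- function(records, fwhm = 15,
                              grid = seq(300, 550, by = 0.5),
                              weights = c("oscillator", "uniform")) {
  weights <- match.arg(weights)
  if (!nrow(records)) stop("no emission records", call. = FALSE)
  if (fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  validate_emission(records)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w <- if (weights == "oscillator") records$oscillator_strength else rep(1, nrow(records))

  comps <- sort(unique(records$conformer))
  out <- tibble::tibble(wavelength = grid, intensity = 0)
  for (cf in comps) {
    sel <- records$conformer == cf
    # outer sum of Gaussians: grid x records
    comp <- colSums(w[sel] * exp(-outer(records$wavelength_nm[sel], grid, `-`)^2 /
                                   (2 * sigma^2)))
    out[[paste0("conformer_", cf)]] <- comp
    out$intensity <- out$intensity + comp
  }
  attr(out, "fwhm") <- fwhm
  class(out) <- c("emission_spectrum", class(out))
  out
}

#' Locate the spectral peak and red/blue shoulders
#'
#' The peak is the global intensity maximum (ties resolved toward the
#' shorter wavelength). Shoulder candidates are secondary local maxima plus
#' local minima of the smoothed second derivative (the classic signature of
#' a partially merged component), excluding the minimum belonging to the
#' main peak. Each shoulder is reported with its relative prominence.
#'
#' @param spec an [convolve_spectrum()] result (or any tibble with
#'   `wavelength` and `intensity`)
#' @param smooth_sigma nm Gaussian smoothing applied before
#'   differentiation (default 2 grid steps)
#' @param min_prominence minimum intensity at the shoulder relative to the
#'   peak (default 0.05)
#' @return list with `peak_nm`, `shoulders` (tibble `wavelength`,
#'   `prominence`), `flagged` (TRUE for a flat spectrum)
#' @export
find_peak_and_shoulders <- function(spec, smooth_sigma = NULL,
                                    min_prominence = 0.05) {
  lam <- spec$wavelength
  y <- spec$intensity
  if (max(y) - min(y) < 1e-12 * max(abs(y), 1)) {
    return(list(peak_nm = NA_real_, shoulders = tibble::tibble(
      wavelength = double(), prominence = double()), flagged = TRUE))
  }
  dl <- lam[2] - lam[1]
  smooth_sigma <- smooth_sigma %||% (2 * dl)
  ks <- max(1L, ceiling(3 * smooth_sigma / dl))
  kern <- stats::dnorm(seq(-ks, ks) * dl, 0, smooth_sigma)
  kern <- kern / sum(kern)
  ys <- stats::filter(c(rep(y[1], ks), y, rep(y[length(y)], ks)), kern, sides = 2)
  ys <- as.numeric(ys)[(ks + 1):(ks + length(y))]

  ipeak <- which(y == max(y))[1]
  peak_nm <- lam[ipeak]

  # secondary local maxima of the raw curve
  d <- diff(sign(diff(y)))
  locmax <- which(d == -2) + 1L
  locmax <- setdiff(locmax, ipeak)

  # local minima of the smoothed second derivative (component centres)
  d2 <- c(NA, diff(ys, differences = 2), NA) / dl^2
  dd2 <- diff(sign(diff(d2[!is.na(d2)])))
  mins2 <- which(dd2 == 2) + 2L            # offset for the leading NA
  mins2 <- mins2[d2[mins2] < 0]
  if (length(mins2)) mins2 <- mins2[-which.min(abs(lam[mins2] - peak_nm))]

  cand <- sort(unique(c(locmax, mins2)))
  if (length(cand)) {
    # classic saddle prominence for secondary maxima; inflection shoulders
    # (not local maxima) are graded by their relative intensity
    prom <- vapply(cand, function(i) {
      rng <- if (i < ipeak) i:ipeak else ipeak:i
      saddle <- (y[i] - min(y[rng])) / y[ipeak]
      if (i %in% locmax) saddle else y[i] / y[ipeak]
    }, double(1))
    keep <- y[cand] >= min_prominence * y[ipeak]
    cand <- cand[keep]; prom <- prom[keep]
  } else prom <- double()
  list(peak_nm = peak_nm,
       shoulders = tibble::tibble(wavelength = lam[cand], prominence = prom),
       flagged = FALSE)
}

#' Integrated band intensity of a spectrum
#'
#' @param spec spectrum tibble (`wavelength`, `intensity`)
#' @param center,width nm band centre and full width
#' @return trapezoidal integral of the intensity over the band
#' @export
band_intensity <- function(spec, center, width) {
  sel <- spec$wavelength >= center - width / 2 & spec$wavelength <= center + width / 2
  if (sum(sel) < 2) stop("band contains fewer than 2 grid points", call. = FALSE)
  pracma::trapz(spec$wavelength[sel], spec$intensity[sel])
}

#' Generalized polarization
#'
#' `GP = (I_blue - I_red) / (I_blue + I_red)`. The experimental channels sit
#' at 440 nm (gel-like emission) and 490 nm (relaxed emission);
#' [band_intensity()] extracts the two intensities from a spectrum.
#'
#' @param i_blue,i_red band intensities (both >= 0, not both zero)
#' @return GP in \[-1, 1\]
#' @export
generalized_polarization <- function(i_blue, i_red) {
  if (any(i_blue + i_red <= 0)) stop("i_blue + i_red must be > 0", call. = FALSE)
  (i_blue - i_red) / (i_blue + i_red)
}

#' @rdname generalized_polarization
#' @param spec spectrum tibble
#' @param blue,red band centres, nm
#' @param width band width, nm
#' @export
gp_from_spectrum <- function(spec, blue = 440, red = 490, width = 20) {
  generalized_polarization(band_intensity(spec, blue, width),
                           band_intensity(spec, red, width))
}

#' Radiative lifetime from emission energy and oscillator strength
#'
#' Standard radiative-rate relation `k_r (s^-1) = f nu^2 / 1.499` with `nu`
#' the emission energy in cm^-1; the lifetime is `1 / k_r` in ns. How the
#' reference decay-time histograms were derived from the QM/MM output is
#' not documented; this estimator is this package's documented choice, not
#' an asserted reproduction.
#'
#' @param records emission tibble, or a numeric vector of energies in eV
#'   together with `f`
#' @param f oscillator strengths when `records` is a numeric vector
#' @return `records` with columns `nu_cm1`, `k_r_s1`, `lifetime_ns` added
#'   (or a numeric vector of lifetimes)
#' @export
radiative_lifetime <- function(records, f = NULL) {
  if (is.numeric(records)) {
    if (is.null(f)) stop("supply oscillator strengths f", call. = FALSE)
    if (any(f <= 0)) stop("oscillator strength must be > 0 (zero gives an infinite lifetime)", call. = FALSE)
    nu <- records / 1.23984193e-4          # eV -> cm^-1
    return(1e9 * 1.499 / (f * nu^2))
  }
  if (any(records$oscillator_strength <= 0)) {
    stop("oscillator strength must be > 0 (zero gives an infinite lifetime)", call. = FALSE)
  }
  records |>
    dplyr::mutate(nu_cm1 = .data$energy_ev / 1.23984193e-4,
                  k_r_s1 = .data$oscillator_strength * .data$nu_cm1^2 / 1.499,
                  lifetime_ns = 1e9 / .data$k_r_s1)
}

#' Normalized histogram of radiative decay times per conformer
#'
#' @param records emission tibble
#' @param bins histogram bin count, or a vector of break points (ns)
#' @return tibble `conformer`, `bin_mid`, `density` (unit area per
#'   conformer), with attribute `means` (mean lifetime per conformer, ns)
#' @export
decay_time_histogram <- function(records, bins = 15) {
  lt <- radiative_lifetime(records)
  rng <- range(lt$lifetime_ns)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)          # all-identical records
  breaks <- if (length(bins) > 1) bins else
    seq(rng[1], rng[2] * (1 + 1e-9), length.out = bins + 1)
  out <- lt |>
    dplyr::group_by(conformer = .data$conformer) |>
    dplyr::reframe({
      h <- graphics::hist(.data$lifetime_ns, breaks = breaks, plot = FALSE)
      tibble::tibble(bin_mid = h$mids, density = h$density)
    })
  means <- lt |>
    dplyr::group_by(.data$conformer) |>
    dplyr::summarise(mean_lifetime = mean(.data$lifetime_ns), .groups = "drop")
  out <- tibble::as_tibble(out)
  attr(out, "means") <- stats::setNames(means$mean_lifetime, means$conformer)
  out
}

#' Fluorescence anisotropy decay from the transition dipole autocorrelation
#'
#' `r(t) = (2/5) <P2(u(t0) . u(t0 + t))>` averaged over all valid time
#' origins, for collinear absorption and emission dipoles, so r(0) = 0.4
#' exactly. The plateau is the mean over the final 20% of lags; a
#' single-exponential-plus-offset fit supplies the decay time constant.
#'
#' @param x a [membrane_trajectory()] (uses the probe tdm) or an n x 3
#'   matrix of unit dipole vectors
#' @param max_lag ns (must be below the trajectory span)
#' @param dt ns per frame (taken from the trajectory when `x` is one)
#' @param origin_stride use every k-th frame as a time origin (default 1)
#' @return `anisotropy_result` list: `curve` (a [new_curve()] of kind
#'   anisotropy), `r0`, `plateau`, `time_constant`, `fit_converged`
#' @export
anisotropy_decay <- function(x, max_lag, dt = NULL, origin_stride = 1L) {
  if (inherits(x, "membrane_trajectory")) {
    dt <- dt %||% x$meta$dt
    u <- as.matrix(x$probe[, c("tdm_x", "tdm_y", "tdm_z")])
  } else {
    if (is.null(dt)) stop("supply dt with a raw dipole matrix", call. = FALSE)
    u <- as.matrix(x)
  }
  n <- nrow(u)
  if (n < 2) stop("need at least 2 frames", call. = FALSE)
  span <- (n - 1) * dt
  if (max_lag >= span) stop("max_lag must be below the trajectory span", call. = FALSE)
  kmax <- floor(max_lag / dt)
  lags <- 0:kmax
  r <- vapply(lags, function(k) {
    o <- seq(1L, n - k, by = origin_stride)
    0.4 * mean(p2(rowSums(u[o, , drop = FALSE] * u[o + k, , drop = FALSE])))
  }, double(1))
  curve <- new_curve(lags * dt, r, kind = "anisotropy")

  n_tail <- max(1L, ceiling(0.2 * length(r)))
  plateau <- mean(r[(length(r) - n_tail + 1L):length(r)])
  fit <- fit_anisotropy(curve, offset = TRUE)
  structure(list(curve = curve, r0 = r[1], plateau = plateau,
                 time_constant = fit$time_constant,
                 fit_converged = fit$converged),
            class = "anisotropy_result")
}

#' @export
print.anisotropy_result <- function(x, ...) {
  cat(sprintf("<anisotropy_result> r0 = %.4f, plateau = %.4f, time constant = %s ns\n",
              x$r0, x$plateau,
              if (is.na(x$time_constant)) "n/a" else sprintf("%.3f", x$time_constant)))
  invisible(x)
}

#' Least-squares exponential fit of an anisotropy trace
#'
#' Fits `r(t) = r0 exp(-t / theta) + r_inf` (or with `r_inf = 0` when
#' `offset = FALSE`) by Levenberg-Marquardt least squares.
#'
#' @param curve a [new_curve()] of kind anisotropy (or any tibble with `t`,
#'   `y`)
#' @param offset fit a plateau term (default TRUE)
#' @return one-row tibble `r0`, `time_constant`, `offset_value`, standard
#'   errors, `converged`
#' @export
fit_anisotropy <- function(curve, offset = TRUE) {
  t <- curve$t; y <- curve$y
  flagged <- tibble::tibble(r0 = NA_real_, r0_se = NA_real_,
                            time_constant = NA_real_, time_constant_se = NA_real_,
                            offset_value = mean(y), offset_se = NA_real_,
                            converged = FALSE)
  if (stats::sd(y) < 1e-12) return(flagged)
  c0 <- if (offset) min(y) else 0
  a0 <- max(y) - c0
  span <- max(diff(range(t)), 1e-3)
  fit <- NULL
  for (th0 in span * c(1 / 10, 1 / 3, 1, 1 / 30)) {    # deterministic start ladder
    fit <- tryCatch({
      if (offset) {
        minpack.lm::nlsLM(y ~ A * exp(-t / th) + C,
                          start = list(A = a0, th = th0, C = c0),
                          lower = c(-10, 1e-6, -10), upper = c(10, 1e6, 10),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(y ~ A * exp(-t / th),
                          start = list(A = a0, th = th0),
                          lower = c(-10, 1e-6), upper = c(10, 1e6),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(flagged)
  s <- summary(fit)$coefficients
  tibble::tibble(r0 = s["A", 1], r0_se = s["A", 2],
                 time_constant = s["th", 1], time_constant_se = s["th", 2],
                 offset_value = if (offset) s["C", 1] else 0,
                 offset_se = if (offset) s["C", 2] else NA_real_,
                 converged = TRUE)
}

#' Simulate a TCSPC photon-arrival histogram
#'
#' Photon arrival times are drawn from an exponential mixture whose
#' per-component photon probabilities equal the integrated-intensity
#' fractions; optional Gaussian instrument-response jitter is added before
#' histogramming.
#'
#' @param components data frame or list of `c(lifetime, fraction)` pairs:
#'   lifetimes in ns, intensity fractions in percent summing to 100
#' @param n_photons photon count (> 0)
#' @param irf optional `list(mean =, sigma =)` Gaussian IRF in ns
#' @param bin_width ns (default 0.05)
#' @param t_max histogram upper edge, ns; default covers all arrivals
#' @param seed RNG seed
#' @return a [new_curve()] of kind intensity (counts per bin), IRF attached
#' @export
simulate_tcspc_decay <- function(components, n_photons, irf = NULL,
                                 bin_width = 0.05, t_max = NULL, seed = 1L) {
  comp <- normalize_components(components)
  if (n_photons <= 0) stop("n_photons must be > 0", call. = FALSE)
  with_seed(seed, {
    idx <- sample.int(nrow(comp), n_photons, replace = TRUE, prob = comp$fraction)
    t <- stats::rexp(n_photons, rate = 1 / comp$lifetime[idx])
    if (!is.null(irf)) t <- t + stats::rnorm(n_photons, irf$mean %||% 0, irf$sigma)
    lo <- floor(min(t, 0) / bin_width) * bin_width
    hi <- t_max %||% (ceiling(max(t) / bin_width) * bin_width)
    t <- t[t <= hi]
    edges <- seq(lo, hi, by = bin_width)
    counts <- graphics::hist(t, breaks = edges, plot = FALSE)$counts
    new_curve((edges[-1] + edges[-length(edges)]) / 2, counts,
              kind = "intensity", irf = irf)
  })
}

normalize_components <- function(components) {
  comp <- if (is.data.frame(components)) {
    tibble::tibble(lifetime = components$lifetime, fraction = components$fraction)
  } else {
    tibble::tibble(lifetime = vapply(components, `[`, double(1), 1),
                   fraction = vapply(components, `[`, double(1), 2))
  }
  if (any(comp$lifetime <= 0)) stop("lifetimes must be > 0", call. = FALSE)
  if (abs(sum(comp$fraction) - 100) > 1e-6) {
    stop("intensity fractions must sum to 100", call. = FALSE)
  }
  comp$fraction <- comp$fraction / 100
  comp
}

# exponential decay density reconvolved with a Gaussian IRF, numerically
# stable via the scaled complementary error function
exp_gauss_density <- function(t, tau, mu = 0, sigma = 0) {
  if (sigma <= 0) {
    return(ifelse(t - mu >= 0, exp(-(t - mu) / tau) / tau, 0))
  }
  z <- sigma / (sqrt(2) * tau) - (t - mu) / (sqrt(2) * sigma)
  out <- numeric(length(t))
  far <- z < -4                          # erfc(z) ~ 2: plain exponential tail
  out[far] <- exp(sigma^2 / (2 * tau^2) - (t[far] - mu) / tau) / tau
  nz <- !far
  out[nz] <- pracma::erfcx(z[nz]) * exp(-(t[nz] - mu)^2 / (2 * sigma^2)) / (2 * tau)
  out
}

#' Fit a reconvolved multi-exponential decay by Poisson maximum likelihood
#'
#' Models the expected counts per bin as a scaled mixture of exponential
#' densities, analytically reconvolved with a Gaussian IRF when one is
#' attached to (or supplied with) the curve, and maximises the Poisson
#' likelihood over deterministic multi-starts. Intensity fractions follow
#' the integrated-intensity convention `f_i = alpha_i tau_i / sum(alpha_j
#' tau_j)`; amplitudes `alpha_i` are recovered from the fitted mixture.
#' Uncertainties come from the observed information matrix. A least-squares
#' mode exists for parity checks.
#'
#' @param curve a [new_curve()] intensity histogram
#' @param n_components 1 or 2
#' @param irf optional `list(mean =, sigma =)`; defaults to the curve's IRF
#' @param method `"poisson"` (default) or `"least_squares"`
#' @return an `exp_fit` object; see [tidy.exp_fit()] and [glance.exp_fit()]
#' @export
fit_exponential_decay <- function(curve, n_components = 2, irf = curve_irf(curve),
                                  method = c("poisson", "least_squares")) {
  method <- match.arg(method)
  stopifnot(n_components %in% 1:2)
  t <- curve$t
  counts <- curve$y
  if (sum(counts > 0) < 10) stop("curve needs at least 10 bins with counts", call. = FALSE)
  bw <- t[2] - t[1]
  mu <- if (is.null(irf)) 0 else irf$mean %||% 0
  sigma <- if (is.null(irf)) 0 else irf$sigma

  total <- sum(counts)
  # moment start for the mean lifetime (first moment minus the IRF mean)
  tau_m <- max(sum(t * counts) / total - mu, bw)

  model_counts <- function(par) {
    if (n_components == 1) {
      tau <- exp(par[1]); s <- exp(par[2])
      m <- s * exp_gauss_density(t, tau, mu, sigma) * bw
    } else {
      tau1 <- exp(par[1]); tau2 <- exp(par[2])
      f1 <- stats::plogis(par[3]); s <- exp(par[4])
      m <- s * (f1 * exp_gauss_density(t, tau1, mu, sigma) +
                  (1 - f1) * exp_gauss_density(t, tau2, mu, sigma)) * bw
    }
    pmax(m, 1e-300)
  }
  nll <- function(par) {
    m <- model_counts(par)
    if (method == "poisson") sum(m - counts * log(m)) else sum((counts - m)^2)
  }

  starts <- if (n_components == 1) {
    list(c(log(tau_m), log(total)),
         c(log(tau_m * 2), log(total)),
         c(log(tau_m / 2), log(total)))
  } else {
    list(c(log(tau_m * 2), log(tau_m / 2), 0, log(total)),
         c(log(tau_m * 3), log(tau_m / 3), stats::qlogis(0.3), log(total)),
         c(log(tau_m * 1.5), log(tau_m / 1.5), stats::qlogis(0.7), log(total)),
         c(log(tau_m * 4), log(tau_m), stats::qlogis(0.5), log(total)))
  }

  best <- NULL
  for (st in starts) {
    res <- tryCatch(stats::optim(st, nll, method = "BFGS",
                                 control = list(maxit = 500, reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE, n_components = n_components,
                          diagnostics = "all starts failed"), class = "exp_fit"))
  }

  hess <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
  cov <- if (!is.null(hess)) tryCatch(solve(hess), error = function(e) NULL) else NULL

  par <- best$par
  if (n_components == 1) {
    taus <- exp(par[1]); fracs <- 1
    tau_se <- if (!is.null(cov)) taus * sqrt(pmax(cov[1, 1], 0)) else NA_real_
    frac_se <- 0
  } else {
    taus <- exp(par[1:2])
    f1 <- stats::plogis(par[3])
    fracs <- c(f1, 1 - f1)
    tau_se <- if (!is.null(cov)) taus * sqrt(pmax(diag(cov)[1:2], 0)) else rep(NA_real_, 2)
    f_se <- if (!is.null(cov)) f1 * (1 - f1) * sqrt(pmax(cov[3, 3], 0)) else NA_real_
    frac_se <- c(f_se, f_se)
    ord <- order(taus, decreasing = TRUE)      # slow component first
    taus <- taus[ord]; fracs <- fracs[ord]
    tau_se <- tau_se[ord]; frac_se <- frac_se[ord]
  }
  alphas <- (fracs / taus) / sum(fracs / taus)
  m <- model_counts(par)
  dof <- length(t) - length(par)
  chisq <- sum((counts - m)^2 / pmax(m, 1)) / dof

  structure(list(
    lifetimes = taus, lifetime_se = tau_se,
    intensity_fractions = 100 * fracs, fraction_se = 100 * frac_se,
    amplitude_coefficients = alphas,
    n_components = n_components, method = method,
    irf = if (sigma > 0) list(mean = mu, sigma = sigma) else NULL,
    reduced_chisq = chisq, logLik = -best$value, total_counts = total,
    fitted = new_curve(t, m, kind = "intensity"),
    data = curve,
    converged = best$convergence == 0,
    diagnostics = sprintf("optim convergence code %d", best$convergence)),
    class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<exp_fit> NOT converged:", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat(sprintf("<exp_fit> %d-component %s fit, reduced chi-square %.3f\n",
              x$n_components, x$method, x$reduced_chisq))
  for (i in seq_len(x$n_components)) {
    cat(sprintf("  tau%d = %.3f +/- %.3f ns  (%.1f +/- %.1f %%)\n",
                i, x$lifetimes[i], x$lifetime_se[i],
                x$intensity_fractions[i], x$fraction_se[i]))
  }
  invisible(x)
}

#' Anisotropy of a mixture of emitting populations
#'
#' The observed anisotropy of co-emitting populations is the
#' intensity-weighted mean `r(t) = sum w_i(t) r_i(t) / sum w_i(t)` with
#' `w_i(t) = (f_i / tau_i) exp(-t / tau_i)` (amplitudes recovered from the
#' integrated-intensity fractions). When a long-lived population holds a
#' high constant anisotropy and a short-lived one decays, the weights shift
#' back toward the slow population at late times and r(t) turns up — the
#' signature seen at the ripple phase.
#'
#' @param pops data frame with columns `fraction` (%, summing to 100),
#'   `lifetime` (ns), `r0`, and optionally `r_inf` and `theta` (ns): each
#'   population's own anisotropy is `r_inf + (r0 - r_inf) exp(-t / theta)`,
#'   or constant `r0` when `theta` is absent/NA
#' @param t_grid ns
#' @return a [new_curve()] of kind anisotropy; attribute `flagged` is TRUE
#'   if the curve was truncated where all weights underflowed
#' @export
two_population_anisotropy <- function(pops, t_grid) {
  if (abs(sum(pops$fraction) - 100) > 1e-6) {
    stop("population fractions must sum to 100", call. = FALSE)
  }
  if (!"r_inf" %in% names(pops)) pops$r_inf <- 0
  if (!"theta" %in% names(pops)) pops$theta <- NA_real_
  w <- sapply(seq_len(nrow(pops)), function(i) {
    (pops$fraction[i] / 100 / pops$lifetime[i]) * exp(-t_grid / pops$lifetime[i])
  })
  r <- sapply(seq_len(nrow(pops)), function(i) {
    if (is.na(pops$theta[i])) rep(pops$r0[i], length(t_grid))
    else pops$r_inf[i] + (pops$r0[i] - pops$r_inf[i]) * exp(-t_grid / pops$theta[i])
  })
  wsum <- rowSums(w)
  ok <- wsum > 1e-300
  flagged <- !all(ok)
  rt <- rowSums(w * r)[ok] / wsum[ok]
  out <- new_curve(t_grid[ok], rt, kind = "anisotropy")
  attr(out, "flagged") <- flagged
  out
}

#' Steady-state anisotropy from time-resolved curves
#'
#' Intensity-weighted time average `integral(r(t) I(t) dt) / integral(I(t)
#' dt)` by trapezoidal quadrature; the intensity curve is interpolated onto
#' the anisotropy grid when the grids differ. In the mono-exponential limit
#' this reproduces the Perrin result `r0 / (1 + tau/theta)`.
#'
#' @param r anisotropy curve (`t`, `y`)
#' @param i intensity curve (`t`, `y`)
#' @return steady-state anisotropy (dimensionless)
#' @export
steady_state_anisotropy <- function(r, i) {
  yi <- if (identical(r$t, i$t)) i$y else stats::approx(i$t, i$y, xout = r$t, rule = 2)$y
  denom <- pracma::trapz(r$t, yi)
  if (denom <= 0) stop("intensity integral is zero", call. = FALSE)
  pracma::trapz(r$t, r$y * yi) / denom
}
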