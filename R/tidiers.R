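#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a multi-exponential decay fit
#'
#' One row per fitted component with the Table-style quantities: lifetime
#' (ns), integrated-intensity fraction (%), amplitude coefficient, and
#' standard errors from the observed information matrix.
#'
#' @param x an `exp_fit` from [fit_exponential_decay()]
#' @param ... unused
#' @return tibble `component`, `lifetime`, `lifetime_se`,
#'   `intensity_fraction`, `fraction_se`, `amplitude`
#' @export
tidy.exp_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    return(tibble::tibble(component = integer(), lifetime = double(),
                          lifetime_se = double(), intensity_fraction = double(),
                          fraction_se = double(), amplitude = double()))
  }
  tibble::tibble(component = seq_len(x$n_components),
                 lifetime = x$lifetimes,
                 lifetime_se = x$lifetime_se,
                 intensity_fraction = x$intensity_fractions,
                 fraction_se = x$fraction_se,
                 amplitude = x$amplitude_coefficients)
}

#' @rdname tidy.exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 method = x$method %||% NA_character_,
                 reduced_chisq = x$reduced_chisq %||% NA_real_,
                 logLik = x$logLik %||% NA_real_,
                 total_counts = x$total_counts %||% NA_real_,
                 converged = isTRUE(x$converged))
}

#' Tidy an anisotropy-decay result
#'
#' @param x an `anisotropy_result` from [anisotropy_decay()]
#' @param ... unused
#' @return one-row tibble `r0`, `plateau`, `time_constant`, `fit_converged`
#' @export
tidy.anisotropy_result <- function(x, ...) {
  tibble::tibble(r0 = x$r0, plateau = x$plateau,
                 time_constant = x$time_constant,
                 fit_converged = x$fit_converged)
}
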