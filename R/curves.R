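#' Time-binned curve (intensity decay or anisotropy)
#'
#' Light tibble subclass used for TCSPC decay histograms and anisotropy
#' traces. The time grid must be uniform and strictly increasing; intensity
#' curves must be non-negative.
#'
#' @param t time grid in ns (uniform, strictly increasing)
#' @param y counts (kind `"intensity"`) or anisotropy values (kind
#'   `"anisotropy"`)
#' @param kind `"intensity"` or `"anisotropy"`
#' @param irf optional instrument response: either a list with `mean` and
#'   `sigma` (Gaussian, ns) or a two-column data frame `(t, y)`
#' @return a tibble of class `decay_curve` with columns `t`, `y`
#' @export
new_curve <- function(t, y, kind = c("intensity", "anisotropy"), irf = NULL) {
  kind <- match.arg(kind)
  if (length(t) != length(y)) stop("t and y must have equal length", call. = FALSE)
  if (length(t) > 1 && any(diff(t) <= 0)) stop("t must be strictly increasing", call. = FALSE)
  if (kind == "intensity" && any(y < 0)) stop("intensity must be >= 0", call. = FALSE)
  out <- tibble::tibble(t = as.double(t), y = as.double(y))
  attr(out, "kind") <- kind
  attr(out, "irf") <- irf
  class(out) <- c("decay_curve", class(out))
  out
}

curve_kind <- function(curve) attr(curve, "kind") %||% "intensity"
curve_irf <- function(curve) attr(curve, "irf")

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("<decay_curve> kind = %s, %d bins, t in [%g, %g] ns%s\n",
              curve_kind(x), nrow(x), min(x$t), max(x$t),
              if (is.null(curve_irf(x))) "" else ", with IRF"))
  NextMethod()
}
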