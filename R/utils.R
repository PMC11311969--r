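# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

vec_norm <- function(x, y, z) sqrt(x^2 + y^2 + z^2)

# row-wise normalisation of a 3-column matrix; rows of zero norm are an error
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  if (any(n < 1e-12)) stop("cannot normalize a zero-length vector", call. = FALSE)
  m / n
}

assert_unit <- function(x, y, z, what = "vector", tol = 1e-3) {
  n <- vec_norm(x, y, z)
  if (any(abs(n - 1) > tol)) {
    stop(sprintf("%s must be a unit vector (|norm - 1| <= %g); got norm %.6g",
                 what, tol, n[which.max(abs(n - 1))]), call. = FALSE)
  }
  invisible(TRUE)
}

# minimum-image displacement components under an orthorhombic box
min_image <- function(d, box_len) d - box_len * round(d / box_len)

# minimum-image distance between (x1,y1,z1) and (x2,y2,z2); box = c(lx, ly, lz)
min_image_dist <- function(x1, y1, z1, x2, y2, z2, box) {
  dx <- min_image(x2 - x1, box[1])
  dy <- min_image(y2 - y1, box[2])
  dz <- min_image(z2 - z1, box[3])
  sqrt(dx^2 + dy^2 + dz^2)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# P2 Legendre polynomial
p2 <- function(x) (3 * x^2 - 1) / 2

# energy (eV) <-> wavelength (nm)
EV_NM <- 1239.84193
ev_to_nm <- function(e) EV_NM / e
nm_to_ev <- function(l) EV_NM / l

# derive reproducible per-component sub-seeds from one master seed, so that
# enabling one component does not shift another component's random draws
split_seed <- function(seed, components) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  subs <- sample.int(.Machine$integer.max - 1L, length(components))
  stats::setNames(as.list(subs), components)
}

# run expr with a local RNG state seeded at `seed`, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
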