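# Internal numeric helpers and unit constants.

# Unit conventions used throughout: lengths in angstrom, scattering lengths in
# fm, pair weights in mbarn (1 fm^2 = 10 mbarn), charges in elementary charge.
.FM2_TO_MBARN <- 10
.WATER_MOLAR_MASS <- 18.0153      # g/mol
.WATER_MOL_PER_KG <- 55.508       # mol water per kg water (1000 / 18.0153)

#' @noRd
.sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- abs(x) > .Machine$double.eps
  out[nz] <- sin(x[nz]) / x[nz]
  out
}

# Minimum-image displacement for an orthorhombic box: dx is an n x 3 matrix of
# raw differences, box a length-3 vector of edge lengths.
#' @noRd
.minImage <- function(dx, box) {
  for (k in 1:3) dx[, k] <- dx[, k] - box[k] * round(dx[, k] / box[k])
  dx
}

#' @noRd
.assertScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# Uniformly distributed random rotation matrix (Arvo's method via quaternion).
#' @noRd
.randomRotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# Unit vectors to the four vertices of a regular tetrahedron (cube-diagonal
# embedding); the faces are opposite the vertices (-v), the six edge midpoints
# are the normalized pairwise sums.
#' @noRd
.tetrahedronVertices <- function() {
  v <- matrix(c(1, 1, 1,
                1, -1, -1,
                -1, 1, -1,
                -1, -1, 1), nrow = 4, byrow = TRUE)
  v / sqrt(3)
}
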