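# Faber-Ziman forward/inverse transforms between g(r) and S(Q) - 1, and the
# termination windows applied before the inverse transform.

#' Construct a termination window
#'
#' `"lorch"` gives W(Q) = sinc(pi Q / Qmax), `"cosine"` the raised-cosine
#' taper 0.5 (1 + cos(pi Q / Qmax)); both equal 1 at Q = 0 and 0 at Qmax and
#' suppress the termination ripple of a finite-Q inverse transform.
#'
#' @param kind `"lorch"`, `"cosine"` or `"none"`.
#' @param qmax Termination wavevector (angstrom^-1).
#' @return A [WindowSpec-class].
#' @export
windowSpec <- function(kind = c("lorch", "cosine", "none"), qmax = 10) {
  kind <- match.arg(kind)
  new("WindowSpec", kind = kind,
      qmax = if (kind == "none") Inf else qmax)
}

#' Evaluate a window on a Q grid
#'
#' @param window A [WindowSpec-class].
#' @param Q Wavevector grid (angstrom^-1).
#' @return Window values; 0 beyond `qmax`.
#' @export
windowValues <- function(window, Q) {
  stopifnot(is(window, "WindowSpec"))
  switch(window@kind,
         none = rep(1, length(Q)),
         lorch = ifelse(Q < window@qmax, .sinc(pi * Q / window@qmax), 0),
         cosine = ifelse(Q < window@qmax,
                         0.5 * (1 + cos(pi * Q / window@qmax)), 0))
}

#' Default Q and r grids
#'
#' Uniform grids used throughout: Q from 0.05 to 25 A^-1 in steps of 0.05,
#' r from 0.01 to 12 A in steps of 0.01.
#'
#' @return Numeric grid.
#' @export
defaultQGrid <- function() seq(0.05, 25, by = 0.05)

#' @rdname defaultQGrid
#' @export
defaultRGrid <- function() seq(0.01, 12, by = 0.01)

#' Forward transform: g(r) to S(Q) - 1
#'
#' Faber-Ziman convention:
#' S(Q) - 1 = 4 pi rho0 Int r^2 (g(r) - 1) sinc(Qr) dr, evaluated by
#' trapezoid rule on the stored r-grid (Q = 0 handled by the sinc limit).
#' rho0 is the total atomic number density of the system. The g - 1 tail
#' must have decayed within the grid; a non-decayed tail truncates the
#' integral and raises a warning (or an error when `strict = TRUE`).
#'
#' @param rdf A [PartialRDF-class].
#' @param rho0 Total atomic number density (angstrom^-3).
#' @param Q Output wavevector grid (angstrom^-1).
#' @param tailTol Tolerance on mean |g - 1| over the last 10% of the grid.
#' @param strict Escalate the tail warning to an error.
#' @return A [StructureFactor-class].
#' @export
rdfToSq <- function(rdf, rho0, Q = defaultQGrid(), tailTol = 0.02,
                    strict = FALSE) {
  stopifnot(is(rdf, "PartialRDF"))
  .assertScalarNumber(rho0, "rho0", positive = TRUE)
  r <- rdf@r
  h <- rdf@g - 1
  tail <- mean(abs(h[r >= stats::quantile(r, 0.9)]))
  if (is.finite(tail) && tail > tailTol) {
    msg <- sprintf("g - 1 has not decayed at r_max (mean tail %.3g > %.3g); transform is truncated",
                   tail, tailTol)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  dr <- r[2] - r[1]
  # trapezoid weights, with the integrand anchored to 0 at r = 0 so the
  # [0, r_1] segment is not dropped
  w <- rep(dr, length(r))
  w[1] <- dr / 2 + r[1] / 2
  w[length(r)] <- dr / 2
  integrand <- r^2 * h * w
  qr <- outer(Q, r)
  values <- 4 * pi * rho0 * as.numeric(matrix(.sinc(qr), nrow = length(Q)) %*%
                                         integrand)
  new("StructureFactor", labels = rdf@labels, Q = Q, values = values,
      rho0 = rho0)
}

#' Inverse transform: S(Q) - 1 to g(r) - 1
#'
#' g(r) - 1 = 1 / (2 pi^2 rho0) Int Q^2 (S(Q) - 1) W(Q) sinc(Qr) dQ by
#' trapezoid rule, where W is a termination window. The Q-grid must satisfy
#' the sampling bound dQ * r_max < pi / 4, otherwise the transform aliases
#' and an error is raised.
#'
#' @param sf A [StructureFactor-class].
#' @param r Output r grid (angstrom).
#' @param window A [WindowSpec-class]; default no window.
#' @param rho0 Number density override (defaults to the one stored in `sf`).
#' @return data.frame with columns `r` and `g` (the recovered g(r)).
#' @export
sqToGr <- function(sf, r = defaultRGrid(), window = windowSpec("none"),
                   rho0 = NULL) {
  stopifnot(is(sf, "StructureFactor"), is(window, "WindowSpec"))
  if (is.null(rho0)) rho0 <- sf@rho0
  Q <- sf@Q
  dQ <- Q[2] - Q[1]
  if (dQ * max(r) >= pi / 4)
    stop(sprintf("Q-grid too coarse: dQ * r_max = %.3g >= pi/4 (aliasing)",
                 dQ * max(r)), call. = FALSE)
  # trapezoid weights with the integrand anchored to 0 at Q = 0
  wq <- rep(dQ, length(Q))
  wq[1] <- dQ / 2 + Q[1] / 2
  wq[length(Q)] <- dQ / 2
  integrand <- Q^2 * sf@values * windowValues(window, Q) * wq
  qr <- outer(r, Q)
  h <- as.numeric(matrix(.sinc(qr), nrow = length(r)) %*% integrand) /
    (2 * pi^2 * rho0)
  data.frame(r = r, g = 1 + h)
}
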