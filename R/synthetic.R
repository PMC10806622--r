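# Synthetic trajectory fixtures: every downstream stage is testable against
# configurations whose statistical structure is known by construction.

#' Construct a fixture specification
#'
#' Supported kinds and their parameters (all lengths in angstrom):
#' \describe{
#'   \item{`ideal_gas`}{`n` uniform points of class `"X"` in a cubic `box`.}
#'   \item{`gaussian_shell`}{`nCenters` centers of class `"CEN"`, each
#'     with exactly `nShell` neighbors of class `"SHL"` at distances
#'     N(`r0`, `sigma`), directions uniform; centers uniform in `box`.}
#'   \item{`anisotropic`}{`nSolutes` rigid tetrahedral solutes (`"N"` center,
#'     4 `"C_TMA"` at 1.49) under independent uniform random rotations, with
#'     one planted atom of class `"P"` per pattern site -- `pattern` is
#'     `"faces"` (4 sites at -v), `"edges"` (6) or `"corners"` (4 at +v) --
#'     at distance `radius` with isotropic Gaussian `jitter`; solute centers
#'     keep a minimum separation `minSep` so foreign planted atoms never
#'     enter another solute's readout radius; `background` additional
#'     uniform atoms of class `"W"` per frame provide a structureless
#'     species.}
#'   \item{`tmacl_box`}{`nTMA` rigid TMA ions (N, 4 C at 1.49, 12 H at
#'     C-H 1.09; classes `"N"`, `"C_TMA"`, `"H_non"`), `nCl` chloride
#'     (`"Cl"`) and `nWater` rigid 3-site waters (O-H 0.9572, 104.52 deg;
#'     classes `"O_W"`, `"H_W"`), molecule anchors placed by
#'     minimum-distance rejection (`minSep`), orientations uniform. The
#'     50/50/1388 default in a 37.0 box reproduces the 2 mol/kg composition
#'     at realistic liquid density.}
#' }
#'
#' @param kind Fixture kind.
#' @param ... Kind-specific parameters (see Details).
#' @param seed Integer RNG seed (mandatory for reproducibility; default 0).
#' @return A [FixtureSpec-class].
#' @examples
#' fixtureSpec("gaussian_shell", nCenters = 20, nShell = 12, r0 = 6, seed = 1)
#' @export
fixtureSpec <- function(kind, ..., seed = 0L) {
  defaults <- switch(kind,
    ideal_gas = list(n = 1000L, box = 30),
    gaussian_shell = list(nCenters = 40L, nShell = 12L, r0 = 6, sigma = 0.3,
                          box = 40),
    anisotropic = list(nSolutes = 25L, box = 50, pattern = "faces",
                       radius = 4.5, jitter = 0.3, minSep = 12,
                       background = 0L),
    tmacl_box = list(nTMA = 50L, nCl = 50L, nWater = 1388L, box = 37.0,
                     minSep = 2.5),
    stop(sprintf("unknown fixture kind '%s'", kind), call. = FALSE))
  params <- utils::modifyList(defaults, list(...))
  bad <- setdiff(names(params), names(defaults))
  if (length(bad))
    stop(sprintf("unknown parameter(s) for kind '%s': %s", kind,
                 paste(bad, collapse = ", ")), call. = FALSE)
  new("FixtureSpec", kind = kind, params = params, seed = as.numeric(seed))
}

#' @noRd
.wrapBox <- function(X, box) {
  for (k in 1:3) X[, k] <- X[, k] %% box[k]
  X
}

# Random sequential placement of n points with a minimum pairwise
# (minimum-image) separation; packing error after bounded retries.
#' @noRd
.packPoints <- function(n, box, minSep, maxTry = 2000L) {
  pts <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(maxTry)) {
      p <- stats::runif(3) * box
      if (i == 1L ||
          min(.mimDist(p, pts[seq_len(i - 1L), , drop = FALSE], box)) >= minSep) {
        pts[i, ] <- p
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("packing failed: could not place point %d of %d at minSep %.2f after %d tries",
                   i, n, minSep, maxTry), call. = FALSE)
  }
  pts
}

# Rigid TMA geometry in a local frame centered on N: 4 C along the
# tetrahedron vertices at 1.49, 3 H per methyl at 1.09 with tetrahedral
# N-C-H angles. Returns 17 x 3 matrix; rows N, C1..C4, H1..H12.
#' @noRd
.tmaGeometry <- function(dNC = 1.49, dCH = 1.09) {
  v <- .tetrahedronVertices()
  out <- matrix(0, 17, 3)
  sinT <- 2 * sqrt(2) / 3  # sin of the tetrahedral angle; cos = -1/3
  row <- 6L
  for (i in 1:4) {
    a <- v[i, ]
    out[1L + i, ] <- dNC * a
    e1 <- c(-a[2], a[1], 0)
    if (sqrt(sum(e1^2)) < 1e-8) e1 <- c(1, 0, 0)
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(a[2] * e1[3] - a[3] * e1[2],
            a[3] * e1[1] - a[1] * e1[3],
            a[1] * e1[2] - a[2] * e1[1])
    for (phi in c(0, 2, 4) * pi / 3) {
      dir <- a / 3 + sinT * (cos(phi) * e1 + sin(phi) * e2)
      out[row, ] <- dNC * a + dCH * dir
      row <- row + 1L
    }
  }
  out
}

# Rigid 3-site water in a local frame centered on O.
#' @noRd
.waterGeometry <- function(dOH = 0.9572, angle = 104.52 * pi / 180) {
  rbind(c(0, 0, 0),
        dOH * c(sin(angle / 2), 0, cos(angle / 2)),
        dOH * c(-sin(angle / 2), 0, cos(angle / 2)))
}

#' @noRd
.patternDirections <- function(pattern) {
  v <- .tetrahedronVertices()
  switch(pattern,
         faces = -v,
         corners = v,
         edges = {
           pairs <- utils::combn(4, 2)
           t(apply(pairs, 2, function(ij) {
             e <- v[ij[1], ] + v[ij[2], ]
             e / sqrt(sum(e * e))
           }))
         },
         stop(sprintf("unknown pattern '%s'", pattern), call. = FALSE))
}

#' Generate a synthetic trajectory
#'
#' Realizes a [FixtureSpec-class] as a [Trajectory-class] with `nFrames`
#' statistically independent frames. Identical spec and seed give
#' bit-identical output; the caller's RNG state is left untouched.
#'
#' @param spec A [FixtureSpec-class].
#' @param nFrames Number of frames.
#' @return A [Trajectory-class].
#' @examples
#' traj <- generateFixture(fixtureSpec("ideal_gas", n = 200, seed = 1), 2)
#' @export
generateFixture <- function(spec, nFrames = 1L) {
  stopifnot(is(spec, "FixtureSpec"))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(as.integer(spec@seed))
  p <- spec@params
  gen <- switch(spec@kind,
                ideal_gas = .genIdealGas,
                gaussian_shell = .genGaussianShell,
                anisotropic = .genAnisotropic,
                tmacl_box = .genTmaclBox)
  gen(p, nFrames)
}

#' @noRd
.genIdealGas <- function(p, nFrames) {
  frames <- lapply(seq_len(nFrames), function(f)
    matrix(stats::runif(3 * p$n) * p$box, ncol = 3))
  trajectory(frames, rep("X", p$n), seq_len(p$n), p$box)
}

#' @noRd
.genGaussianShell <- function(p, nFrames) {
  k <- p$nShell
  # class names kept <= 5 characters so they survive a GRO round trip
  labels <- c(rep("CEN", p$nCenters), rep("SHL", p$nCenters * k))
  # every shell atom is its own molecule (a solvent particle, not part of
  # the center), so center-shell pairs survive the intramolecular exclusion
  mol <- c(seq_len(p$nCenters), p$nCenters + seq_len(p$nCenters * k))
  frames <- lapply(seq_len(nFrames), function(f) {
    centers <- matrix(stats::runif(3 * p$nCenters) * p$box, ncol = 3)
    u <- matrix(stats::rnorm(3 * p$nCenters * k), ncol = 3)
    u <- u / sqrt(rowSums(u * u))
    d <- stats::rnorm(p$nCenters * k, p$r0, p$sigma)
    shell <- centers[rep(seq_len(p$nCenters), each = k), ] + u * d
    .wrapBox(rbind(centers, shell), rep(p$box, 3))
  })
  trajectory(frames, labels, mol, p$box)
}

#' @noRd
.genAnisotropic <- function(p, nFrames) {
  v <- .tetrahedronVertices()
  dirs <- .patternDirections(p$pattern)
  nSite <- nrow(dirs)
  perSolute <- 5L + nSite
  labels <- c(rep(c("N", rep("C_TMA", 4), rep("P", nSite)), p$nSolutes),
              rep("W", p$background))
  mol <- c(rep(seq_len(p$nSolutes), each = perSolute),
           if (p$background > 0) p$nSolutes + seq_len(p$background))
  frames <- lapply(seq_len(nFrames), function(f) {
    centers <- .packPoints(p$nSolutes, rep(p$box, 3), p$minSep)
    blocks <- lapply(seq_len(p$nSolutes), function(s) {
      G <- .randomRotation()
      carbons <- 1.49 * v %*% t(G)
      planted <- p$radius * dirs %*% t(G) +
        matrix(stats::rnorm(3 * nSite, sd = p$jitter), ncol = 3)
      sweep(rbind(0, carbons, planted), 2, centers[s, ], `+`)
    })
    X <- do.call(rbind, blocks)
    if (p$background > 0)
      X <- rbind(X, matrix(stats::runif(3 * p$background) * p$box, ncol = 3))
    .wrapBox(X, rep(p$box, 3))
  })
  trajectory(frames, labels, mol, p$box)
}

#' @noRd
.genTmaclBox <- function(p, nFrames) {
  tma <- .tmaGeometry()
  wat <- .waterGeometry()
  nMol <- p$nTMA + p$nCl + p$nWater
  labels <- c(rep(c("N", rep("C_TMA", 4), rep("H_non", 12)), p$nTMA),
              rep("Cl", p$nCl),
              rep(c("O_W", "H_W", "H_W"), p$nWater))
  mol <- c(rep(seq_len(p$nTMA), each = 17L),
           p$nTMA + seq_len(p$nCl),
           rep(p$nTMA + p$nCl + seq_len(p$nWater), each = 3L))
  frames <- lapply(seq_len(nFrames), function(f) {
    anchors <- .packPoints(nMol, rep(p$box, 3), p$minSep)
    tmaBlocks <- lapply(seq_len(p$nTMA), function(s)
      sweep(tma %*% t(.randomRotation()), 2, anchors[s, ], `+`))
    watBlocks <- lapply(seq_len(p$nWater), function(s)
      sweep(wat %*% t(.randomRotation()), 2,
            anchors[p$nTMA + p$nCl + s, ], `+`))
    X <- rbind(do.call(rbind, tmaBlocks),
               anchors[p$nTMA + seq_len(p$nCl), , drop = FALSE],
               do.call(rbind, watBlocks))
    .wrapBox(X, rep(p$box, 3))
  })
  trajectory(frames, labels, mol, p$box)
}

#' Closed-form radial distribution of the Gaussian-shell model
#'
#' For a center with exactly `k` neighbors at distances N(`r0`, `sigma`)
#' embedded in a fluid of partner density `rho`, the pair distribution is
#' g(r) = 1 + k phi(r; r0, sigma) / (4 pi r^2 rho), whose excess integrates
#' to exactly k neighbors.
#'
#' @param k Neighbors per center.
#' @param r0,sigma Shell location and width (angstrom).
#' @param rho Partner number density (angstrom^-3).
#' @param r Output grid (angstrom).
#' @return A [PartialRDF-class] labeled `("center", "shell")`.
#' @export
analyticRdf <- function(k, r0 = 6, sigma = 0.3, rho,
                        r = seq(0.02, 12, by = 0.02)) {
  .assertScalarNumber(rho, "rho", positive = TRUE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  g <- 1 + k * stats::dnorm(r, r0, sigma) / (4 * pi * r^2 * rho)
  new("PartialRDF", labels = c("center", "shell"), r = r, g = g, rho = rho,
      nFrames = 1)
}
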