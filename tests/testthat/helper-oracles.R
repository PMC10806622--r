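# Independent brute-force oracles and hand-built fixtures used across tests.
# These deliberately avoid the package's vectorized internals.

# Naive O(N^2) minimum-image RDF histogram over explicit loops, with the same
# exact-shell-volume normalization contract as the package estimator.
naiveRDF <- function(traj, classA, classB, rMax, nBins) {
  box <- boxLengths(traj)
  lab <- atomLabels(traj)
  mol <- moleculeIndex(traj)
  iA <- which(lab == classA)
  iB <- which(lab == classB)
  breaks <- seq(0, rMax, length.out = nBins + 1L)
  counts <- numeric(nBins)
  for (f in seq_len(nFrames(traj))) {
    X <- frameCoords(traj, f)
    for (a in iA) for (b in iB) {
      if (mol[a] == mol[b]) next
      dx <- X[a, ] - X[b, ]
      dx <- dx - box * round(dx / box)
      d <- sqrt(sum(dx^2))
      if (d < rMax) {
        bin <- findInterval(d, breaks, left.open = TRUE)
        counts[bin] <- counts[bin] + 1
      }
    }
  }
  shell <- 4 / 3 * pi * (breaks[-1]^3 - breaks[-(nBins + 1L)]^3)
  rho <- length(iB) / prod(box)
  counts / (shell * rho * length(iA) * nFrames(traj))
}

# Brute-force label-free superposition: minimum over all 4! correspondences
# of the bio3d least-squares fit RMSD (recomputed from the fitted
# coordinates, since bio3d::rmsd() rounds its return value).
bruteForceAlignRMSD <- function(moving, ref) {
  perms <- allPermutations(nrow(moving))
  best <- Inf
  for (i in seq_len(nrow(perms))) {
    fitted <- suppressWarnings(
      bio3d::fit.xyz(as.vector(t(ref)),
                     as.vector(t(moving[perms[i, ], , drop = FALSE]))))
    fm <- matrix(fitted, ncol = 3, byrow = TRUE)
    best <- min(best, sqrt(mean(rowSums((fm - ref)^2))))
  }
  best
}

# A single rigid tetrahedral solute (N center + 4 C) plus arbitrary extra
# atoms, as a one-frame trajectory in a large box.
soluteFrame <- function(extra = NULL, extraLabels = character(),
                        rotation = diag(3), center = c(25, 25, 25),
                        box = 50) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  X <- rbind(c(0, 0, 0), 1.49 * v)
  if (!is.null(extra)) X <- rbind(X, extra)
  X <- X %*% t(rotation)
  X <- sweep(X, 2, center, `+`)
  labels <- c("N", rep("C_TMA", 4), extraLabels)
  mol <- c(rep(1L, 5), rep(2L, length(extraLabels)))
  trajectory(X, labels, mol, box)
}

# Rigid water at a given O position with the dipole along `dipoleDir`
# (O -> H-midpoint direction); returns 3 x 3 coords (O, H1, H2).
waterAt <- function(O, dipoleDir) {
  d <- dipoleDir / sqrt(sum(dipoleDir^2))
  # any unit vector orthogonal to d
  p <- c(-d[2], d[1], 0)
  if (sqrt(sum(p^2)) < 1e-8) p <- c(1, 0, 0)
  p <- p / sqrt(sum(p^2))
  ang <- 104.52 * pi / 180
  h1 <- O + 0.9572 * (cos(ang / 2) * d + sin(ang / 2) * p)
  h2 <- O + 0.9572 * (cos(ang / 2) * d - sin(ang / 2) * p)
  rbind(O, h1, h2)
}

randomRotationMatrix <- function() {
  M <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(M))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
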