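# Label-free rigid superposition: Kabsch with a search over index
# permutations so that symmetry-equivalent alignment atoms (e.g. the four
# methyl carbons of a tetrahedral solute) need not be sorted.

#' All permutations of 1..n
#'
#' @param n Set size (kept small; 4 for tetrahedral alignment).
#' @return n! x n integer matrix, one permutation per row.
#' @export
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' @noRd
.permutationParity <- function(p) {
  # +1 for even, -1 for odd, by counting inversions
  inv <- 0L
  n <- length(p)
  for (i in seq_len(n - 1L))
    inv <- inv + sum(p[(i + 1L):n] < p[i])
  if (inv %% 2L == 0L) 1L else -1L
}

#' Permutation sets for alignment
#'
#' `"full"` searches all k! correspondences; `"proper"` restricts to the even
#' permutations, which for 4 atoms are exactly the 12 correspondences
#' realizable by proper rotations of a regular tetrahedron (its rotation
#' group acts on the vertices as the alternating group A4) -- a faster search
#' when the reference is tetrahedral.
#'
#' @param k Number of alignment atoms.
#' @param symmetry `"full"` or `"proper"`.
#' @return m x k integer matrix of permutations.
#' @export
symmetryPermutations <- function(k, symmetry = c("full", "proper")) {
  symmetry <- match.arg(symmetry)
  p <- allPermutations(k)
  if (symmetry == "proper")
    p <- p[apply(p, 1, .permutationParity) == 1L, , drop = FALSE]
  p
}

#' Construct an alignment reference
#'
#' @param coords k x 3 matrix of alignment-atom coordinates; centered at the
#'   solute center (it is re-centered on its centroid if not already).
#' @param symmetry Permutation set to search, see [symmetryPermutations()],
#'   or an explicit m x k permutation matrix.
#' @return An [AlignmentReference-class].
#' @export
alignmentReference <- function(coords, symmetry = "full") {
  coords <- sweep(coords, 2, colMeans(coords))
  perms <- if (is.matrix(symmetry)) symmetry
           else symmetryPermutations(nrow(coords), symmetry)
  new("AlignmentReference", coords = coords, permutations = perms)
}

# Proper-rotation Kabsch: rotation R (3x3, det +1) minimizing
# || X %*% t(R) - Y ||_F for centered X (moving) and Y (target).
#' @noRd
.kabsch <- function(X, Y) {
  H <- crossprod(X, Y)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  reflected <- d < 0
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Xr <- X %*% t(R)
  list(R = R, rmsd = sqrt(mean(rowSums((Xr - Y)^2))), reflected = reflected)
}

# Best proper rotation over a permutation set; moving atoms X (k x 3,
# centered) onto reference Y under row correspondence X[perm, ] -> Y.
#' @noRd
.permutationKabsch <- function(X, Y, perms) {
  best <- NULL
  for (i in seq_len(nrow(perms))) {
    fit <- .kabsch(X[perms[i, ], , drop = FALSE], Y)
    if (is.null(best) || fit$rmsd < best$rmsd) {
      best <- fit
      best$permutation <- perms[i, ]
    }
  }
  best
}

# Solute bookkeeping: molecules containing a centerClass atom; returns a list
# of (center index, alignment-atom indices) per solute.
#' @noRd
.soluteSites <- function(traj, centerClass, alignClass) {
  iC <- .atomIndices(traj, centerClass)
  lapply(iC, function(ic) {
    ia <- which(traj@molecule == traj@molecule[ic] &
                  traj@labels %in% alignClass)
    list(center = ic, align = ia)
  })
}

# Alignment atoms of one solute in one frame, minimum-imaged and centered on
# the solute center.
#' @noRd
.alignCoords <- function(traj, frame, site) {
  X <- traj@coords[[frame]]
  .minImage(sweep(X[site$align, , drop = FALSE], 2, X[site$center, ]),
            traj@box)
}

#' Pick a representative alignment reference
#'
#' Scans a deterministic, seeded subsample of (frame, solute) conformations
#' and returns the one whose alignment-atom geometry minimizes the mean
#' permutation-aligned RMSD to all other subsample members -- a
#' representative conformation robust to outliers.
#'
#' @param traj A [Trajectory-class].
#' @param centerClass Class of the solute center atoms.
#' @param alignClass Class(es) of the alignment atoms (e.g. the methyl
#'   carbons); for a bead-model solute pass first-shell species instead and
#'   see `k`.
#' @param symmetry Permutation set, see [symmetryPermutations()].
#' @param subsample Number of conformations scanned.
#' @param k Number of alignment atoms for neighbor-based alignment: when the
#'   solute molecule itself has no `alignClass` atoms, the k nearest
#'   `alignClass` atoms of the center are used instead (bead model).
#' @param seed RNG seed for the subsample.
#' @return An [AlignmentReference-class].
#' @export
pickReference <- function(traj, centerClass, alignClass, symmetry = "full",
                          subsample = 32L, k = 4L, seed = 0L) {
  stopifnot(is(traj, "Trajectory"))
  sites <- .soluteSites(traj, centerClass, alignClass)
  if (length(sites) == 0L) stop("no solute found", call. = FALSE)
  bead <- all(lengths(lapply(sites, `[[`, "align")) == 0L)
  getCoords <- function(frame, s) {
    if (!bead) return(.alignCoords(traj, frame, s))
    X <- traj@coords[[frame]]
    iN <- .atomIndices(traj, alignClass)
    d <- .mimDist(X[s$center, ], X[iN, , drop = FALSE], traj@box)
    .minImage(sweep(X[iN[order(d)[seq_len(k)]], , drop = FALSE], 2,
                    X[s$center, ]), traj@box)
  }
  grid <- expand.grid(frame = seq_len(nFrames(traj)),
                      solute = seq_along(sites))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  pick <- grid[sample.int(nrow(grid), min(subsample, nrow(grid))), ,
               drop = FALSE]
  confs <- lapply(seq_len(nrow(pick)), function(i) {
    x <- getCoords(pick$frame[i], sites[[pick$solute[i]]])
    sweep(x, 2, colMeans(x))
  })
  perms <- symmetryPermutations(nrow(confs[[1]]),
                                if (is.matrix(symmetry)) "full" else symmetry)
  m <- length(confs)
  rmsdSum <- numeric(m)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    d <- .permutationKabsch(confs[[i]], confs[[j]], perms)$rmsd
    rmsdSum[i] <- rmsdSum[i] + d
    rmsdSum[j] <- rmsdSum[j] + d
  }
  alignmentReference(confs[[which.min(rmsdSum)]], symmetry)
}

#' @noRd
.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

#' @noRd
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Align one solute neighborhood to the reference
#'
#' Finds, over the reference's permutation set, the least-RMSD proper
#' rotation (det = +1) superposing the solute's alignment atoms onto the
#' reference, and applies it to every atom within `cutoff` of the solute
#' center. If the unconstrained optimum is a reflection, the best proper
#' rotation is returned and flagged.
#'
#' @param traj A [Trajectory-class].
#' @param frame Frame index.
#' @param solute Solute index (order of center-class atoms).
#' @param ref An [AlignmentReference-class].
#' @param centerClass,alignClass Class labels as in [pickReference()].
#' @param cutoff Neighborhood radius around the solute center (angstrom).
#' @return List with `rotation` (3 x 3), `rmsd`, `permutation`, `reflected`,
#'   `atoms` (indices of neighborhood atoms) and `coords` (their aligned
#'   coordinates relative to the solute center).
#' @export
alignNeighborhood <- function(traj, frame, solute, ref, centerClass,
                              alignClass, cutoff = 10) {
  stopifnot(is(traj, "Trajectory"), is(ref, "AlignmentReference"))
  sites <- .soluteSites(traj, centerClass, alignClass)
  if (solute < 1L || solute > length(sites))
    stop("solute index out of range", call. = FALSE)
  site <- sites[[solute]]
  k <- nrow(ref@coords)
  X <- traj@coords[[frame]]
  if (length(site$align) == 0L) {
    iN <- .atomIndices(traj, alignClass)
    d <- .mimDist(X[site$center, ], X[iN, , drop = FALSE], traj@box)
    site$align <- iN[order(d)[seq_len(k)]]
  }
  if (length(site$align) != k)
    stop(sprintf("solute has %d alignment atoms, reference expects %d",
                 length(site$align), k), call. = FALSE)
  A <- .alignCoords(traj, frame, site)
  A <- sweep(A, 2, colMeans(A))
  fit <- .permutationKabsch(A, ref@coords, ref@permutations)
  disp <- .minImage(sweep(X, 2, X[site$center, ]), traj@box)
  d <- sqrt(rowSums(disp * disp))
  atoms <- which(d <= cutoff)
  list(rotation = fit$R, rmsd = fit$rmsd, permutation = fit$permutation,
       reflected = fit$reflected, atoms = atoms,
       coords = disp[atoms, , drop = FALSE] %*% t(fit$R))
}
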