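# Real-space trajectory statistics: partial RDFs under minimum image,
# coordination numbers, ion-pair census, water-orientation profiles.

# Minimum-image distances from one atom to a coordinate block.
#' @noRd
.mimDist <- function(x0, X, box) {
  dx <- .minImage(sweep(X, 2, x0), box)
  sqrt(rowSums(dx * dx))
}

#' Partial radial distribution function
#'
#' Histogram estimator of g(r) between two site classes over all frames,
#' using minimum-image distances in the orthorhombic box. Counts are
#' normalized by exact spherical-shell volumes, the partner-class number
#' density N_beta/V, the number of alpha sites and the frame count.
#' Intramolecular pairs (shared molecule index) and self pairs are excluded.
#'
#' @param traj A [Trajectory-class].
#' @param classA,classB Site class labels (alpha = reference sites, beta =
#'   partner sites whose density normalizes g).
#' @param rMax Histogram range (angstrom); must not exceed half the smallest
#'   box edge (minimum-image bound).
#' @param nBins Number of uniform bins (default gives dr = 0.02 A at
#'   rMax = 12).
#' @return A [PartialRDF-class] with bin-center grid.
#' @examples
#' spec <- fixtureSpec("ideal_gas", n = 500, box = 20, seed = 1)
#' rdf <- computePartialRDF(generateFixture(spec, nFrames = 5), "X", "X",
#'                          rMax = 8, nBins = 80)
#' @export
computePartialRDF <- function(traj, classA, classB, rMax = 12, nBins = 600) {
  stopifnot(is(traj, "Trajectory"))
  .assertScalarNumber(rMax, "rMax", positive = TRUE)
  box <- traj@box
  if (rMax > min(box) / 2 + 1e-9)
    stop("rMax exceeds half the smallest box edge (minimum-image bound)",
         call. = FALSE)
  iA <- .atomIndices(traj, classA)
  iB <- .atomIndices(traj, classB)
  breaks <- seq(0, rMax, length.out = nBins + 1L)
  dr <- breaks[2]
  counts <- numeric(nBins)
  molA <- traj@molecule[iA]
  molB <- traj@molecule[iB]
  for (f in seq_len(nFrames(traj))) {
    X <- traj@coords[[f]]
    A <- X[iA, , drop = FALSE]
    B <- X[iB, , drop = FALSE]
    for (a in seq_along(iA)) {
      keep <- molB != molA[a]
      if (!any(keep)) next
      d <- .mimDist(A[a, ], B[keep, , drop = FALSE], box)
      d <- d[d < rMax]
      if (length(d))
        counts <- counts + tabulate(findInterval(d, breaks, left.open = TRUE),
                                    nbins = nBins)
    }
  }
  vol <- prod(box)
  rho <- length(iB) / vol
  shell <- 4 / 3 * pi * (breaks[-1]^3 - breaks[-(nBins + 1L)]^3)
  norm <- shell * rho * length(iA) * nFrames(traj)
  new("PartialRDF", labels = c(classA[1], classB[1]),
      r = breaks[-(nBins + 1L)] + dr / 2, g = counts / norm,
      rho = rho, nFrames = nFrames(traj))
}

#' Coordination number from a partial RDF
#'
#' n(r_cut) = 4 pi rho_beta Int_0^rcut r^2 g(r) dr by trapezoid rule, with
#' the integrand taken as 0 at r = 0 and linear interpolation at the cut.
#'
#' @param rdf A [PartialRDF-class].
#' @param rCut Integration limit (angstrom), within the r-grid.
#' @return Mean number of beta neighbors within `rCut` of an alpha site.
#' @export
coordinationNumber <- function(rdf, rCut) {
  stopifnot(is(rdf, "PartialRDF"))
  r <- rdf@r
  if (rCut <= 0 || rCut > max(r) + 1e-12)
    stop("rCut must lie within the r-grid", call. = FALSE)
  keep <- r <= rCut
  rr <- c(0, r[keep])
  ff <- c(0, r[keep]^2 * rdf@g[keep])
  if (max(r[keep]) < rCut && any(!keep)) {
    gcut <- stats::approx(r, rdf@g, xout = rCut)$y
    rr <- c(rr, rCut)
    ff <- c(ff, rCut^2 * gcut)
  }
  4 * pi * rdf@rho * pracma::trapz(rr, ff)
}

#' Contact and solvent-shared ion-pair census
#'
#' Mean number of anions within `[0, contactCut)` (contact pairs) and
#' `[contactCut, sharedCut)` (solvent-shared pairs) of each cation center,
#' using minimum-image distances, averaged over frames.
#'
#' @param traj A [Trajectory-class].
#' @param cationClass Class of the cation center atoms.
#' @param anionClass Class of the anions.
#' @param contactCut,sharedCut Distance cuts (angstrom), `contactCut <
#'   sharedCut`; defaults bracket the first and second counterion shells.
#'   Both must respect the minimum-image bound.
#' @return Named numeric: `contact` and `solventShared` counts per cation.
#' @export
ionPairCensus <- function(traj, cationClass, anionClass,
                          contactCut = 5.5, sharedCut = 8) {
  stopifnot(is(traj, "Trajectory"))
  if (contactCut >= sharedCut) stop("contactCut must be < sharedCut", call. = FALSE)
  if (sharedCut > min(traj@box) / 2 + 1e-9)
    stop("sharedCut exceeds half the smallest box edge", call. = FALSE)
  iC <- .atomIndices(traj, cationClass)
  iA <- .atomIndices(traj, anionClass)
  contact <- shared <- 0
  for (f in seq_len(nFrames(traj))) {
    X <- traj@coords[[f]]
    for (a in seq_along(iC)) {
      d <- .mimDist(X[iC[a], ], X[iA, , drop = FALSE], traj@box)
      contact <- contact + sum(d < contactCut)
      shared <- shared + sum(d >= contactCut & d < sharedCut)
    }
  }
  n <- length(iC) * nFrames(traj)
  c(contact = contact / n, solventShared = shared / n)
}

#' Water orientation profile around a solute center
#'
#' For every water whose oxygen falls in a radial bin around a solute center
#' atom, averages (a) cos(theta) between the water dipole vector (from O
#' toward the midpoint of its two hydrogens) and the center-to-O vector, and
#' (b) cos(theta) between each OH bond and the center-to-O vector. Under
#' this convention a dipole pointing at the ion gives cos(theta) = -1.
#'
#' @param traj A [Trajectory-class].
#' @param centerClass Class of the solute center atoms.
#' @param oClass,hClass Classes of water oxygen and hydrogen atoms; each
#'   water molecule must contain one O and exactly two H (shared molecule
#'   index).
#' @param rBreaks Radial bin edges (angstrom).
#' @return data.frame with columns `r` (bin centers), `cosDipole`, `cosOH`,
#'   `n` (waters per bin); empty bins hold `NA`.
#' @export
orientationProfile <- function(traj, centerClass, oClass = "O_W",
                               hClass = "H_W", rBreaks = seq(0, 8, by = 0.5)) {
  stopifnot(is(traj, "Trajectory"))
  iC <- .atomIndices(traj, centerClass)
  iO <- .atomIndices(traj, oClass)
  iH <- .atomIndices(traj, hClass)
  hByMol <- split(iH, traj@molecule[iH])
  if (any(lengths(hByMol) != 2L))
    stop("each water molecule must have exactly 2 hydrogens", call. = FALSE)
  hMat <- do.call(rbind, hByMol[as.character(traj@molecule[iO])])
  if (is.null(hMat) || nrow(hMat) != length(iO))
    stop("each water oxygen needs a molecule with 2 hydrogens", call. = FALSE)
  nb <- length(rBreaks) - 1L
  sDip <- sOH <- nDip <- nOH <- numeric(nb)
  box <- traj@box
  for (f in seq_len(nFrames(traj))) {
    X <- traj@coords[[f]]
    O <- X[iO, , drop = FALSE]
    oh1 <- .minImage(X[hMat[, 1], , drop = FALSE] - O, box)
    oh2 <- .minImage(X[hMat[, 2], , drop = FALSE] - O, box)
    dip <- oh1 + oh2
    dip <- dip / sqrt(rowSums(dip * dip))
    u1 <- oh1 / sqrt(rowSums(oh1 * oh1))
    u2 <- oh2 / sqrt(rowSums(oh2 * oh2))
    for (a in seq_along(iC)) {
      co <- .minImage(sweep(O, 2, X[iC[a], ]), box)
      d <- sqrt(rowSums(co * co))
      u <- co / d
      bin <- findInterval(d, rBreaks, left.open = TRUE)
      ok <- bin >= 1L & bin <= nb
      if (!any(ok)) next
      b <- bin[ok]
      sDip <- sDip + as.numeric(tapply(rowSums(dip[ok, , drop = FALSE] *
                                                 u[ok, , drop = FALSE]),
                                       factor(b, levels = 1:nb), sum,
                                       default = 0))
      cOH <- c(rowSums(u1[ok, , drop = FALSE] * u[ok, , drop = FALSE]),
               rowSums(u2[ok, , drop = FALSE] * u[ok, , drop = FALSE]))
      sOH <- sOH + as.numeric(tapply(cOH, factor(c(b, b), levels = 1:nb), sum,
                                     default = 0))
      nDip <- nDip + tabulate(b, nbins = nb)
      nOH <- nOH + 2 * tabulate(b, nbins = nb)
    }
  }
  data.frame(r = rBreaks[-(nb + 1L)] + diff(rBreaks) / 2,
             cosDipole = ifelse(nDip > 0, sDip / nDip, NA_real_),
             cosOH = ifelse(nOH > 0, sOH / nOH, NA_real_),
             n = nDip)
}

#' Molality of a simulated system
#'
#' @param nSolute Number of solute formula units.
#' @param nWater Number of water molecules.
#' @param waterMolarMass Molar mass of water (g/mol).
#' @return Molality in mol solute per kg water.
#' @examples
#' molalityOfSystem(50, 1388)  # ~2.0
#' @export
molalityOfSystem <- function(nSolute, nWater, waterMolarMass = .WATER_MOLAR_MASS) {
  if (!is.finite(nWater) || nWater <= 0) stop("nWater must be > 0", call. = FALSE)
  if (!is.finite(nSolute) || nSolute < 0) stop("nSolute must be >= 0", call. = FALSE)
  nSolute / (nWater * waterMolarMass * 1e-3)
}

#' Write / read a partial RDF as TSV
#'
#' Two columns `r_A` and `g` with the partner density and pair recorded in
#' `#`-comment header lines.
#'
#' @param rdf A [PartialRDF-class].
#' @param path File path.
#' @return `writeRDFTSV` returns `path` invisibly; `readRDFTSV` a
#'   [PartialRDF-class].
#' @export
writeRDFTSV <- function(rdf, path) {
  stopifnot(is(rdf, "PartialRDF"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pair\t%s\t%s", rdf@labels[1], rdf@labels[2]),
               sprintf("# rho_beta_A-3\t%.12g", rdf@rho),
               sprintf("# n_frames\t%g", rdf@nFrames),
               "r_A\tg"), con)
  utils::write.table(data.frame(rdf@r, rdf@g), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeRDFTSV
#' @export
readRDFTSV <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getTag <- function(tag) {
    h <- grep(paste0("^# ", tag), hdr, value = TRUE)
    if (length(h) == 0L) stop(sprintf("missing '# %s' header", tag), call. = FALSE)
    strsplit(h[1], "\t")[[1]][-1]
  }
  pair <- getTag("pair")
  rho <- as.numeric(getTag("rho_beta_A-3"))
  nf <- as.numeric(getTag("n_frames"))
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t")
  new("PartialRDF", labels = pair, r = df[[1]], g = df[[2]], rho = rho,
      nFrames = nf)
}
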