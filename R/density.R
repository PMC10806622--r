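# Bulk-normalized voxel density maps in the aligned solute frame, tetrahedral
# site readout, and volumetric file export.

#' Construct a density grid directly
#'
#' @param values 3D array of relative densities.
#' @param voxel Voxel edge length (angstrom).
#' @param origin Center of voxel (1,1,1); default centers the grid on 0.
#' @param species Species label.
#' @param nNeighborhoods,bulkDensity Accumulation metadata.
#' @return A [DensityGrid-class].
#' @export
densityGrid <- function(values, voxel, origin = NULL, species = "X",
                        nNeighborhoods = NA_real_, bulkDensity = NA_real_) {
  if (is.null(origin))
    origin <- -(dim(values) - 1) * voxel / 2
  new("DensityGrid", values = values, voxel = voxel, origin = origin,
      species = species, nNeighborhoods = nNeighborhoods,
      bulkDensity = bulkDensity)
}

#' Accumulate a species density map around aligned solutes
#'
#' For every (frame, solute) pair, aligns the neighborhood with
#' [alignNeighborhood()] and bins the chosen species' aligned positions into
#' a cubic voxel grid centered on the solute. Voxel values are counts per
#' voxel volume per neighborhood, divided by the species' bulk number
#' density, so a structureless fluid reads 1.
#'
#' @param traj A [Trajectory-class].
#' @param species Class label of the mapped species.
#' @param ref An [AlignmentReference-class].
#' @param centerClass,alignClass Class labels as in [pickReference()].
#' @param gridEdge Cube edge length (angstrom); the grid spans +/- gridEdge/2.
#' @param voxel Voxel edge length (angstrom).
#' @param cutoff Neighborhood radius (angstrom); atoms beyond it never enter
#'   the grid, so voxels near `cutoff` are only partially filled.
#' @param bulkDensity Bulk number density of the species (angstrom^-3);
#'   default is the global-box value N_species / V. For small boxes a local
#'   shell estimate can be supplied instead (see [shellDensityEstimate()]).
#' @return A [DensityGrid-class].
#' @export
accumulateDensity <- function(traj, species, ref, centerClass, alignClass,
                              gridEdge = 20, voxel = 0.5, cutoff = 10,
                              bulkDensity = NULL) {
  stopifnot(is(traj, "Trajectory"), is(ref, "AlignmentReference"))
  .assertScalarNumber(voxel, "voxel", positive = TRUE)
  .assertScalarNumber(gridEdge, "gridEdge", positive = TRUE)
  nv <- max(1L, round(gridEdge / voxel))
  half <- nv * voxel / 2
  iS <- .atomIndices(traj, species)
  if (is.null(bulkDensity)) bulkDensity <- length(iS) / prod(traj@box)
  sites <- .soluteSites(traj, centerClass, alignClass)
  counts <- array(0, dim = c(nv, nv, nv))
  nNeigh <- 0L
  isSpecies <- traj@labels %in% species
  for (f in seq_len(nFrames(traj))) {
    for (s in seq_along(sites)) {
      al <- alignNeighborhood(traj, f, s, ref, centerClass, alignClass,
                              cutoff = cutoff)
      nNeigh <- nNeigh + 1L
      pos <- al$coords[isSpecies[al$atoms], , drop = FALSE]
      if (nrow(pos) == 0L) next
      ijk <- floor((pos + half) / voxel) + 1
      ok <- rowSums(ijk >= 1 & ijk <= nv) == 3L
      if (!any(ok)) next
      ijk <- ijk[ok, , drop = FALSE]
      lin <- (ijk[, 3] - 1) * nv * nv + (ijk[, 2] - 1) * nv + ijk[, 1]
      tab <- table(lin)
      counts[as.integer(names(tab))] <- counts[as.integer(names(tab))] +
        as.integer(tab)
    }
  }
  new("DensityGrid",
      values = counts / (voxel^3 * nNeigh * bulkDensity),
      voxel = voxel, origin = rep(-half + voxel / 2, 3), species = species[1],
      nNeighborhoods = nNeigh, bulkDensity = bulkDensity)
}

#' Local-shell bulk density estimate
#'
#' Estimates a species' bulk number density from the mean count in a radial
#' shell around solute centers -- the fallback for small boxes where the
#' global composition over-counts excluded volume.
#'
#' @param traj A [Trajectory-class].
#' @param species Species class.
#' @param centerClass Solute center class.
#' @param shell Radial shell `c(inner, outer)` (angstrom).
#' @return Estimated number density (angstrom^-3).
#' @export
shellDensityEstimate <- function(traj, species, centerClass,
                                 shell = c(8, 9.5)) {
  stopifnot(is(traj, "Trajectory"))
  iS <- .atomIndices(traj, species)
  iC <- .atomIndices(traj, centerClass)
  total <- 0
  for (f in seq_len(nFrames(traj))) {
    X <- traj@coords[[f]]
    for (a in seq_along(iC)) {
      d <- .mimDist(X[iC[a], ], X[iS, , drop = FALSE], traj@box)
      total <- total + sum(d >= shell[1] & d < shell[2])
    }
  }
  vol <- 4 / 3 * pi * (shell[2]^3 - shell[1]^3)
  total / (vol * length(iC) * nFrames(traj))
}

#' @noRd
.gridAxes <- function(grid) {
  d <- dim(grid@values)
  lapply(1:3, function(k) grid@origin[k] + (seq_len(d[k]) - 1) * grid@voxel)
}

#' Trilinear interpolation of a density grid
#'
#' @param grid A [DensityGrid-class].
#' @param points m x 3 matrix of positions in the aligned frame (angstrom).
#' @return Interpolated relative densities (0 outside the grid).
#' @export
interpolateDensity <- function(grid, points) {
  stopifnot(is(grid, "DensityGrid"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  ax <- .gridAxes(grid)
  d <- dim(grid@values)
  out <- numeric(nrow(points))
  for (m in seq_len(nrow(points))) {
    t <- (points[m, ] - grid@origin) / grid@voxel
    i0 <- floor(t)
    fr <- t - i0
    i0 <- i0 + 1
    if (any(i0 < 1) || any(i0 + 1 > d)) { out[m] <- 0; next }
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
      acc <- acc + w * grid@values[i0[1] + dx, i0[2] + dy, i0[3] + dz]
    }
    out[m] <- acc
  }
  out
}

#' Mean relative density in a radial bulk shell
#'
#' Averages voxel values whose centers fall in the declared bulk shell; for
#' a homogeneous fluid this should be 1 within counting noise. The default
#' shell stops at 9.5 A because, with the standard 10 A neighborhood cutoff,
#' voxels nearer the cutoff are only partially filled.
#'
#' @param grid A [DensityGrid-class].
#' @param shell Radial shell `c(inner, outer)` (angstrom).
#' @return Mean relative density.
#' @export
bulkShellMean <- function(grid, shell = c(8, 9.5)) {
  stopifnot(is(grid, "DensityGrid"))
  ax <- .gridAxes(grid)
  r <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`))
  sel <- r >= shell[1] & r < shell[2]
  if (!any(sel)) stop("no voxel centers in the shell", call. = FALSE)
  mean(grid@values[sel])
}

#' Tetrahedral site directions
#'
#' Unit directions of the 4 faces (opposite the vertices), 6 edge midpoints
#' and 4 corners (vertices) of the reference tetrahedron. For a default
#' reference these are derived from the reference's own vertex directions.
#'
#' @param ref An [AlignmentReference-class] with 4 alignment atoms.
#' @return List of matrices `faces` (4 x 3), `edges` (6 x 3), `corners`
#'   (4 x 3), rows unit vectors.
#' @export
tetrahedralSites <- function(ref) {
  stopifnot(is(ref, "AlignmentReference"))
  v <- ref@coords
  if (nrow(v) != 4L) stop("tetrahedral site readout needs 4 alignment atoms",
                          call. = FALSE)
  vhat <- v / sqrt(rowSums(v * v))
  pairs <- utils::combn(4, 2)
  edges <- t(apply(pairs, 2, function(ij) {
    e <- vhat[ij[1], ] + vhat[ij[2], ]
    e / sqrt(sum(e * e))
  }))
  list(faces = -vhat, edges = edges, corners = vhat)
}

#' Face/edge/corner site occupancy
#'
#' Reads the relative density at the tetrahedron's 4 face, 6 edge and 4
#' corner directions at a stated radius by trilinear interpolation.
#'
#' @param grid A [DensityGrid-class].
#' @param ref An [AlignmentReference-class] (4 atoms).
#' @param radius Readout radius (angstrom), within the grid.
#' @return A [SiteOccupancy-class].
#' @export
siteOccupancy <- function(grid, ref, radius) {
  stopifnot(is(grid, "DensityGrid"))
  ax <- .gridAxes(grid)
  if (radius <= 0 || radius > min(vapply(ax, function(a) max(abs(a)), 0)))
    stop("radius outside the grid", call. = FALSE)
  sites <- tetrahedralSites(ref)
  new("SiteOccupancy",
      faces = interpolateDensity(grid, sites$faces * radius),
      edges = interpolateDensity(grid, sites$edges * radius),
      corners = interpolateDensity(grid, sites$corners * radius),
      radius = radius)
}

#' Write a site-occupancy table as TSV
#'
#' @param occ A [SiteOccupancy-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeOccupancyTSV <- function(occ, path) {
  stopifnot(is(occ, "SiteOccupancy"))
  df <- data.frame(
    site = c(rep("face", 4), rep("edge", 6), rep("corner", 4)),
    index = c(1:4, 1:6, 1:4),
    radius_A = occ@radius,
    relative_density = c(occ@faces, occ@edges, occ@corners))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a density grid as OpenDX
#'
#' Plain-text OpenDX general array format (z-fastest data order), readable
#' by VMD/PyMOL; values are bulk-normalized relative densities. Intended iso
#' levels can be recorded in a JSON sidecar (`<path>.meta.json`).
#'
#' @param grid A [DensityGrid-class].
#' @param path Output path.
#' @param isoLevels Optional numeric vector of iso levels for the sidecar.
#' @return `path`, invisibly.
#' @export
exportDensityDX <- function(grid, path, isoLevels = NULL) {
  stopifnot(is(grid, "DensityGrid"))
  d <- dim(grid@values)
  vals <- as.numeric(aperm(grid@values, c(3, 2, 1)))  # z fastest
  con <- file(path, "w")
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", grid@origin[1], grid@origin[2],
            grid@origin[3]),
    sprintf("delta %.6f 0 0", grid@voxel),
    sprintf("delta 0 %.6f 0", grid@voxel),
    sprintf("delta 0 0 %.6f", grid@voxel),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vals))), con)
  full <- length(vals) %/% 3L
  if (full > 0L)
    writeLines(sprintf("%.8g %.8g %.8g",
                       vals[seq_len(full) * 3 - 2],
                       vals[seq_len(full) * 3 - 1],
                       vals[seq_len(full) * 3]), con)
  if (length(vals) %% 3L)
    writeLines(paste(sprintf("%.8g", vals[(full * 3 + 1):length(vals)]),
                     collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               sprintf('object "%s density" class field', grid@species),
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  close(con)
  if (!is.null(isoLevels))
    jsonlite::write_json(list(species = grid@species, iso_levels = isoLevels,
                              units = "multiples of bulk density"),
                         paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an OpenDX density grid written by [exportDensityDX()]
#'
#' @param path DX file path.
#' @return A [DensityGrid-class] (species/normalization metadata not stored
#'   in DX are set to placeholders).
#' @export
readDensityDX <- function(path) {
  lines <- readLines(path)
  cnt <- as.integer(strsplit(sub(".*counts ", "",
                                 grep("gridpositions", lines, value = TRUE)[1]),
                             "\\s+")[[1]])
  org <- as.numeric(strsplit(sub("^origin ", "",
                                 grep("^origin", lines, value = TRUE)[1]),
                             "\\s+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  vox <- max(as.numeric(strsplit(sub("^delta ", "", deltas[1]), "\\s+")[[1]]))
  i0 <- grep("data follows", lines)[1]
  iEnd <- grep("^attribute", lines)[1]
  vals <- as.numeric(unlist(strsplit(trimws(lines[(i0 + 1L):(iEnd - 1L)]),
                                     "\\s+")))
  arr <- aperm(array(vals, dim = rev(cnt)), c(3, 2, 1))
  new("DensityGrid", values = arr, voxel = vox, origin = org,
      species = "unknown", nNeighborhoods = NA_real_, bulkDensity = NA_real_)
}

#' Export a density grid as a Gaussian cube file
#'
#' Standard cube layout (lengths converted to bohr, z-fastest data order)
#' with the reference alignment atoms written as carbon positions for
#' visualization overlays.
#'
#' @param grid A [DensityGrid-class].
#' @param ref An [AlignmentReference-class] providing overlay atoms, or
#'   `NULL` for a single dummy atom at the origin.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
exportDensityCube <- function(grid, path, ref = NULL) {
  stopifnot(is(grid, "DensityGrid"))
  b <- 1 / 0.529177210903  # angstrom -> bohr
  d <- dim(grid@values)
  atoms <- if (is.null(ref)) matrix(0, 1, 3) else ref@coords
  z <- if (is.null(ref)) 1L else rep(6L, nrow(atoms))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("%s density (multiples of bulk)", grid@species),
               "generated by ndiskit"), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nrow(atoms),
                     grid@origin[1] * b, grid@origin[2] * b,
                     grid@origin[3] * b), con)
  for (k in 1:3) {
    v <- c(0, 0, 0); v[k] <- grid@voxel * b
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", d[k], v[1], v[2], v[3]), con)
  }
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", z, 0,
                     atoms[, 1] * b, atoms[, 2] * b, atoms[, 3] * b), con)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    row <- grid@values[i, j, ]
    for (s in seq(1, d[3], by = 6))
      writeLines(paste(sprintf("%13.5e", row[s:min(s + 5, d[3])]),
                       collapse = " "), con)
  }
  invisible(path)
}
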