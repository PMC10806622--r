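#' Construct a trajectory
#'
#' @param coords A single n x 3 matrix or a list of them (angstrom), one per
#'   frame.
#' @param labels Per-atom class labels.
#' @param molecule Per-atom molecule indices (integer); defaults to one
#'   molecule per atom.
#' @param box Orthorhombic box edge lengths (angstrom, length 3 or a scalar
#'   for a cubic box). Triclinic boxes are not supported.
#' @param frameSpacing Time between frames in ps (`NA` if unknown).
#' @return A [Trajectory-class].
#' @export
trajectory <- function(coords, labels, molecule = NULL, box,
                       frameSpacing = NA_real_) {
  if (is.matrix(coords)) coords <- list(coords)
  if (length(box) == 1L) box <- rep(box, 3)
  if (length(box) != 3L)
    stop("box must be a scalar or three edge lengths (orthorhombic only)",
         call. = FALSE)
  if (is.null(molecule)) molecule <- seq_along(labels)
  new("Trajectory", coords = coords, labels = as.character(labels),
      molecule = as.integer(molecule), box = as.numeric(box),
      frameSpacing = frameSpacing)
}

#' Relabel trajectory atoms through a topology mapping
#'
#' @param traj A [Trajectory-class].
#' @param mapping Named character vector (or path to a YAML file with a
#'   top-level `classes:` map) from raw atom names to class labels; atoms
#'   with no entry keep their name.
#' @return The relabeled [Trajectory-class].
#' @export
applyTopology <- function(traj, mapping) {
  stopifnot(is(traj, "Trajectory"))
  if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping)) {
    y <- yaml::read_yaml(mapping)
    if (is.null(y$classes)) stop("topology YAML needs a 'classes:' map", call. = FALSE)
    mapping <- unlist(y$classes)
  }
  hit <- traj@labels %in% names(mapping)
  traj@labels[hit] <- unname(mapping[traj@labels[hit]])
  traj
}

#' @noRd
.atomIndices <- function(traj, class) {
  idx <- which(traj@labels %in% class)
  if (length(idx) == 0L)
    stop(sprintf("no atoms with class '%s'", paste(class, collapse = ",")),
         call. = FALSE)
  idx
}

#' Read a (multi-frame) GRO file
#'
#' Coordinates and box are converted from nm to angstrom. Residue numbers
#' become molecule indices, trimmed atom names become labels (map them to
#' classes with [applyTopology()]). Boxes with off-diagonal (triclinic)
#' components are rejected.
#'
#' @param path GRO file path.
#' @return A [Trajectory-class].
#' @export
readGRO <- function(path) {
  lines <- readLines(path)
  frames <- list(); labels <- NULL; mol <- NULL; box <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- as.integer(trimws(lines[i + 1L]))
    atomLines <- lines[(i + 2L):(i + 1L + nat)]
    resid <- as.integer(substr(atomLines, 1, 5))
    name <- trimws(substr(atomLines, 11, 15))
    xyz <- cbind(as.numeric(substr(atomLines, 21, 28)),
                 as.numeric(substr(atomLines, 29, 36)),
                 as.numeric(substr(atomLines, 37, 44))) * 10
    boxv <- as.numeric(strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1]])
    if (length(boxv) > 3L && any(abs(boxv[-(1:3)]) > 1e-9))
      stop("triclinic GRO box not supported (orthorhombic only)", call. = FALSE)
    if (is.null(labels)) { labels <- name; mol <- resid; box <- boxv[1:3] * 10 }
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 3L + nat
  }
  trajectory(frames, labels, mol, box)
}

#' Write a trajectory as GRO
#'
#' @param traj A [Trajectory-class].
#' @param path Output path.
#' @param resname Residue name stamped on every atom line.
#' @return `path`, invisibly.
#' @export
writeGRO <- function(traj, path, resname = "MOL") {
  stopifnot(is(traj, "Trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nAtoms(traj)
  for (f in seq_len(nFrames(traj))) {
    xyz <- traj@coords[[f]] / 10
    writeLines(sprintf("frame %d", f), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       traj@molecule %% 100000L, resname,
                       substr(traj@labels, 1, 5), seq_len(n) %% 100000L,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj@box[1] / 10,
                       traj@box[2] / 10, traj@box[3] / 10), con)
  }
  invisible(path)
}

#' Read a (multi-frame) XYZ file
#'
#' Expects the comment line of each frame to carry the orthorhombic box as
#' three numbers (e.g. `box = 30.0 30.0 30.0`), in angstrom.
#'
#' @param path XYZ file path.
#' @param molecule Optional per-atom molecule indices (XYZ has no residue
#'   field); defaults to one molecule per atom.
#' @return A [Trajectory-class].
#' @export
readXYZ <- function(path, molecule = NULL) {
  lines <- readLines(path)
  frames <- list(); labels <- NULL; box <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- as.integer(trimws(lines[i]))
    nums <- regmatches(lines[i + 1L],
                       gregexpr("[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?",
                                lines[i + 1L]))[[1]]
    if (length(nums) < 3L)
      stop("XYZ comment line must carry three box lengths", call. = FALSE)
    b <- as.numeric(utils::tail(nums, 3))
    parts <- strsplit(trimws(lines[(i + 2L):(i + 1L + nat)]), "\\s+")
    name <- vapply(parts, `[[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(labels)) { labels <- name; box <- b }
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + nat
  }
  trajectory(frames, labels, molecule, box)
}

#' Write a trajectory as XYZ
#'
#' @param traj A [Trajectory-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeXYZ <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(traj))) {
    xyz <- traj@coords[[f]]
    writeLines(sprintf("%d", nAtoms(traj)), con)
    writeLines(sprintf("box = %.6f %.6f %.6f", traj@box[1], traj@box[2],
                       traj@box[3]), con)
    writeLines(sprintf("%-6s %12.6f %12.6f %12.6f", traj@labels,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a PDB file as a trajectory
#'
#' Atom records are parsed with [bio3d::read.pdb()] (multi-MODEL files give
#' multiple frames); the orthorhombic box is taken from the CRYST1 record,
#' which must have 90-degree angles.
#'
#' @param path PDB file path.
#' @return A [Trajectory-class].
#' @export
readPDBTraj <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  cry <- grep("^CRYST1", readLines(path), value = TRUE)
  if (length(cry) == 0L) stop("PDB lacks a CRYST1 record", call. = FALSE)
  f <- as.numeric(strsplit(trimws(substr(cry[1], 7, 54)), "\\s+")[[1]])
  if (any(abs(f[4:6] - 90) > 1e-6))
    stop("triclinic PDB box not supported (orthorhombic only)", call. = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)),
                   function(i) matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  trajectory(frames, trimws(pdb$atom$elety), as.integer(pdb$atom$resno), f[1:3])
}
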