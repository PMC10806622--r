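# Accessors and show() methods. Slot access from user code is discouraged;
# these are the supported surface.

#' @rdname accessors
#' @export
setMethod("nFrames", "Trajectory", function(x) length(x@coords))

#' @rdname accessors
#' @export
setMethod("nFrames", "PartialRDF", function(x) x@nFrames)

#' @rdname accessors
#' @export
setMethod("nAtoms", "Trajectory", function(x) length(x@labels))

#' @rdname accessors
#' @export
setMethod("boxLengths", "Trajectory", function(x) x@box)

#' @rdname accessors
#' @export
setMethod("atomLabels", "Trajectory", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("moleculeIndex", "Trajectory", function(x) x@molecule)

#' Coordinates of one frame
#'
#' @param traj A [Trajectory-class].
#' @param i Frame index.
#' @return n x 3 matrix of coordinates (angstrom).
#' @export
frameCoords <- function(traj, i) {
  stopifnot(is(traj, "Trajectory"))
  if (i < 1L || i > nFrames(traj)) stop("frame index out of range", call. = FALSE)
  traj@coords[[i]]
}

#' @rdname accessors
#' @export
setMethod("rGrid", "PartialRDF", function(x) x@r)

#' @rdname accessors
#' @export
setMethod("gValues", "PartialRDF", function(x) x@g)

#' @rdname accessors
#' @export
setMethod("partnerDensity", "PartialRDF", function(x) x@rho)

#' @rdname accessors
#' @export
setMethod("pairLabels", "PartialRDF", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("qGrid", "StructureFactor", function(x) x@Q)

#' @rdname accessors
#' @export
setMethod("signalValues", "StructureFactor", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("pairLabels", "StructureFactor", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("qGrid", "DifferenceSignal", function(x) {
  if (x@space != "Q") stop("signal is in r-space; use rGrid()", call. = FALSE)
  x@grid
})

#' @rdname accessors
#' @export
setMethod("rGrid", "DifferenceSignal", function(x) {
  if (x@space != "r") stop("signal is in Q-space; use qGrid()", call. = FALSE)
  x@grid
})

#' @rdname accessors
#' @export
setMethod("signalValues", "DifferenceSignal", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("signalTerms", "DifferenceSignal", function(x) x@terms)

#' @rdname accessors
#' @export
setMethod("gridValues", "DensityGrid", function(x) x@values)

#' Scattering lengths as a named vector
#'
#' @param table A [ScatteringTable-class].
#' @return Named numeric vector (fm).
#' @export
scatteringLengths <- function(table) {
  stopifnot(is(table, "ScatteringTable"))
  table@entries
}

setMethod("show", "ScatteringTable", function(object) {
  cat("ScatteringTable:", length(object@entries), "species\n")
  print(round(object@entries, 4))
})

setMethod("show", "SolutionComposition", function(object) {
  cat(sprintf("SolutionComposition: molality %.4g mol/kg, %d solute site class(es)\n",
              object@molality, nrow(object@sites)))
  if (nrow(object@sites) > 0L) print(object@sites, row.names = FALSE)
  cat(sprintf("implicit water: %.3f mol/kg (classes O_W, H_W)\n",
              object@waterMolPerKg))
})

setMethod("show", "LabelingScheme", function(object) {
  cat("LabelingScheme:",
      paste(sprintf("%s=%s", names(object@assignments), object@assignments),
            collapse = ", "), "\n")
})

setMethod("show", "ChargeModel", function(object) {
  cat(sprintf("ChargeModel '%s' (net charge %+.4g e)\n", object@name,
              sum(object@types$charge * object@types$multiplicity)))
  print(object@types, row.names = FALSE)
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frame(s), %d atoms, box %.2f x %.2f x %.2f A\n",
              nFrames(object), nAtoms(object),
              object@box[1], object@box[2], object@box[3]))
  tab <- table(object@labels)
  cat("classes:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
})

setMethod("show", "PartialRDF", function(object) {
  cat(sprintf("PartialRDF g_%s,%s(r): %d bins on [%.3g, %.3g] A, rho_beta = %.4g A^-3, %g frame(s)\n",
              object@labels[1], object@labels[2], length(object@r),
              min(object@r), max(object@r), object@rho, object@nFrames))
})

setMethod("show", "StructureFactor", function(object) {
  cat(sprintf("StructureFactor S_%s,%s(Q) - 1: %d points on [%.3g, %.3g] A^-1\n",
              object@labels[1], object@labels[2], length(object@Q),
              min(object@Q), max(object@Q)))
})

setMethod("show", "DifferenceSignal", function(object) {
  cat(sprintf("DifferenceSignal (%s order, %s-space): %d term(s), %d points\n",
              object@order, object@space, nrow(object@terms),
              length(object@grid)))
  print(object@terms, row.names = FALSE)
})

setMethod("show", "WindowSpec", function(object) {
  if (object@kind == "none") cat("WindowSpec: none\n")
  else cat(sprintf("WindowSpec: %s, Qmax = %.3g A^-1\n", object@kind, object@qmax))
})

setMethod("show", "AlignmentReference", function(object) {
  cat(sprintf("AlignmentReference: %d atoms, %d permutation(s) searched\n",
              nrow(object@coords), nrow(object@permutations)))
})

setMethod("show", "DensityGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("DensityGrid '%s': %d x %d x %d voxels of %.3g A, %g neighborhood(s), bulk rho %.4g A^-3\n",
              object@species, d[1], d[2], d[3], object@voxel,
              object@nNeighborhoods, object@bulkDensity))
  cat(sprintf("relative density range [%.3g, %.3g]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "SiteOccupancy", function(object) {
  cat(sprintf("SiteOccupancy at r = %.3g A (relative to bulk):\n", object@radius))
  cat(sprintf("  faces   mean %.3g\n", mean(object@faces)))
  cat(sprintf("  edges   mean %.3g\n", mean(object@edges)))
  cat(sprintf("  corners mean %.3g\n", mean(object@corners)))
})

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf("FixtureSpec '%s' (seed %d)\n", object@kind, as.integer(object@seed)))
})
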