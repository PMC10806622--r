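#' Coherent neutron scattering length table
#'
#' Maps species labels (elements or isotopes, e.g. `"H"`, `"D"`, `"C"`,
#' `"N"`, `"O"`, `"Cl"`) to coherent scattering lengths in fm. Values may be
#' negative (notably for protium).
#'
#' @slot entries Named numeric vector of scattering lengths (fm).
#' @seealso [scatteringTable()], [defaultScatteringTable()]
#' @export
setClass("ScatteringTable", representation(entries = "numeric"))

setValidity("ScatteringTable", function(object) {
  e <- object@entries
  if (length(e) == 0L) return("table must contain at least one entry")
  if (is.null(names(e)) || any(!nzchar(names(e)))) return("all entries must be named")
  if (anyDuplicated(names(e))) return("duplicate species labels")
  if (any(!is.finite(e))) return("scattering lengths must be finite")
  TRUE
})

#' Solution composition with isotope-substitution site classes
#'
#' Describes the stoichiometry of a solution on a molality basis: `sites`
#' lists the solute atomic site classes (one row per class) with element,
#' count per formula unit and whether the class is open to H/D substitution.
#' Water is implicit: `waterMolPerKg` moles of 3-site water per kg define the
#' `O_W` and `H_W` classes, with `H_W` substitutable. A pure-water composition
#' has zero molality and an empty site table.
#'
#' @slot sites data.frame with columns `class`, `element`, `count`,
#'   `substitutable` describing the solute's atomic site classes.
#' @slot molality Mol solute per kg water (>= 0).
#' @slot waterMolPerKg Moles of water per kg of water (default 55.508).
#' @seealso [solutionComposition()], [tmaclComposition()], [atomicFractions()]
#' @export
setClass("SolutionComposition",
         representation(sites = "data.frame", molality = "numeric",
                        waterMolPerKg = "numeric"))

setValidity("SolutionComposition", function(object) {
  s <- object@sites
  need <- c("class", "element", "count", "substitutable")
  if (!all(need %in% names(s)))
    return(paste("sites must have columns", paste(need, collapse = ", ")))
  if (nrow(s) > 0L) {
    if (anyDuplicated(s$class)) return("duplicate site class labels")
    if (any(!is.finite(s$count)) || any(s$count <= 0))
      return("site counts must be positive")
    if (any(s$class %in% c("O_W", "H_W")))
      return("'O_W' and 'H_W' are reserved for the implicit water classes")
  }
  if (length(object@molality) != 1L || !is.finite(object@molality) ||
      object@molality < 0)
    return("molality must be a single number >= 0")
  if (object@molality == 0 && nrow(s) > 0L)
    return("molality 0 requires an empty solute site table")
  if (length(object@waterMolPerKg) != 1L || object@waterMolPerKg <= 0)
    return("waterMolPerKg must be a single positive number")
  TRUE
})

#' Isotope labeling scheme for one sample
#'
#' Assigns a scattering-table label (typically `"H"` or `"D"`) to each
#' substitutable site class of a composition, e.g. `H_non = "D", H_W = "H"`
#' for a d12 solute in light water.
#'
#' @slot assignments Named character vector: substitutable class -> label.
#' @seealso [labelingScheme()]
#' @export
setClass("LabelingScheme", representation(assignments = "character"))

setValidity("LabelingScheme", function(object) {
  a <- object@assignments
  if (length(a) == 0L) return("at least one class must be assigned")
  if (is.null(names(a)) || any(!nzchar(names(a)))) return("assignments must be named by class")
  if (anyDuplicated(names(a))) return("duplicate class in labeling")
  TRUE
})

#' Point-charge model of a molecule
#'
#' Partial charges (in e) per atom type together with the atom-type
#' stoichiometry of one molecule, as used to compare force-field variants.
#'
#' @slot name Model name.
#' @slot types data.frame with columns `type`, `charge`, `multiplicity`.
#' @seealso [chargeModel()], [tmaChargeModels()], [netCharge()]
#' @export
setClass("ChargeModel",
         representation(name = "character", types = "data.frame"))

setValidity("ChargeModel", function(object) {
  t <- object@types
  need <- c("type", "charge", "multiplicity")
  if (!all(need %in% names(t)))
    return(paste("types must have columns", paste(need, collapse = ", ")))
  if (nrow(t) == 0L) return("at least one atom type required")
  if (any(!is.finite(t$charge))) return("charges must be finite")
  m <- t$multiplicity
  if (any(!is.finite(m)) || any(m <= 0) || any(m != round(m)))
    return("multiplicities must be positive integers")
  TRUE
})

#' Periodic trajectory of labeled coordinates
#'
#' An ordered set of frames sharing one topology: per-atom species/class
#' labels, molecule indices, and one orthorhombic box. Coordinates are in
#' angstrom.
#'
#' @slot coords List of n x 3 coordinate matrices (angstrom), one per frame.
#' @slot labels Character vector of per-atom class labels.
#' @slot molecule Integer vector of per-atom molecule indices.
#' @slot box Numeric length-3 orthorhombic box edge lengths (angstrom).
#' @slot frameSpacing Time between frames (ps; `NA` if unknown).
#' @seealso [trajectory()], [computePartialRDF()]
#' @export
setClass("Trajectory",
         representation(coords = "list", labels = "character",
                        molecule = "integer", box = "numeric",
                        frameSpacing = "numeric"))

setValidity("Trajectory", function(object) {
  if (length(object@coords) == 0L) return("at least one frame required")
  n <- length(object@labels)
  for (i in seq_along(object@coords)) {
    x <- object@coords[[i]]
    if (!is.matrix(x) || ncol(x) != 3L) return("each frame must be an n x 3 matrix")
    if (nrow(x) != n) return("atom count must be constant across frames")
    if (any(!is.finite(x))) return("coordinates must be finite")
  }
  if (length(object@molecule) != n) return("molecule index length must match atom count")
  if (length(object@box) != 3L || any(!is.finite(object@box)) || any(object@box <= 0))
    return("box must be three positive edge lengths (orthorhombic only)")
  TRUE
})

#' Partial radial distribution function
#'
#' g(r) between two site classes on a uniform r-grid, with the partner-class
#' number density used for normalization.
#'
#' @slot labels Character(2): the (alpha, beta) class labels.
#' @slot r Bin-center grid (angstrom, uniform, strictly increasing).
#' @slot g g(r) values (dimensionless, >= 0).
#' @slot rho Number density of the beta class (angstrom^-3).
#' @slot nFrames Number of frames averaged.
#' @seealso [computePartialRDF()], [coordinationNumber()], [rdfToSq()]
#' @export
setClass("PartialRDF",
         representation(labels = "character", r = "numeric", g = "numeric",
                        rho = "numeric", nFrames = "numeric"))

setValidity("PartialRDF", function(object) {
  if (length(object@labels) != 2L) return("labels must have length 2")
  r <- object@r
  if (length(r) < 2L || any(diff(r) <= 0)) return("r must be strictly increasing")
  if (max(abs(diff(diff(r)))) > 1e-8 * mean(diff(r))) return("r grid must be uniform")
  if (length(object@g) != length(r)) return("g and r lengths differ")
  if (any(!is.finite(object@g)) || any(object@g < -1e-12)) return("g must be finite and >= 0")
  if (object@rho <= 0) return("rho must be positive")
  TRUE
})

#' Faber-Ziman partial structure factor
#'
#' Stores S(Q) - 1 for one class pair on a uniform Q-grid together with the
#' total atomic number density used in the transform convention.
#'
#' @slot labels Character(2) class pair.
#' @slot Q Uniform Q grid (angstrom^-1).
#' @slot values S(Q) - 1 (dimensionless).
#' @slot rho0 Total atomic number density (angstrom^-3).
#' @seealso [rdfToSq()], [sqToGr()], [assembleDifference()]
#' @export
setClass("StructureFactor",
         representation(labels = "character", Q = "numeric",
                        values = "numeric", rho0 = "numeric"))

setValidity("StructureFactor", function(object) {
  if (length(object@labels) != 2L) return("labels must have length 2")
  Q <- object@Q
  if (length(Q) < 2L || any(diff(Q) <= 0)) return("Q must be strictly increasing")
  if (length(object@values) != length(Q)) return("values and Q lengths differ")
  if (any(!is.finite(object@values))) return("values must be finite")
  if (object@rho0 <= 0) return("rho0 must be positive")
  TRUE
})

#' Weighted isotopic difference signal
#'
#' A weighted combination of partial structure factors (or its real-space
#' counterpart), in mbarn: first-order (one isotope swap on the solute) or
#' second-order (difference of two first orders, isolating one pair).
#'
#' @slot order `"first"` or `"second"`.
#' @slot terms data.frame with columns `classA`, `classB`, `weight` (mbarn).
#' @slot grid Abscissa: Q (angstrom^-1) or r (angstrom).
#' @slot values Signal values (mbarn).
#' @slot space `"Q"` or `"r"`.
#' @seealso [assembleDifference()], [simulatedDdg()]
#' @export
setClass("DifferenceSignal",
         representation(order = "character", terms = "data.frame",
                        grid = "numeric", values = "numeric",
                        space = "character"))

setValidity("DifferenceSignal", function(object) {
  if (!object@order %in% c("first", "second")) return("order must be 'first' or 'second'")
  if (!object@space %in% c("Q", "r")) return("space must be 'Q' or 'r'")
  need <- c("classA", "classB", "weight")
  if (!all(need %in% names(object@terms)))
    return(paste("terms must have columns", paste(need, collapse = ", ")))
  if (length(object@grid) != length(object@values)) return("grid and values lengths differ")
  if (object@order == "second" && nrow(object@terms) != 1L)
    return("a second-order signal has exactly one weighted pair")
  TRUE
})

#' Termination window specification
#'
#' Window applied to S(Q) - 1 before the inverse transform, equal to 1 at
#' Q = 0 and 0 at `qmax`.
#'
#' @slot kind `"lorch"`, `"cosine"` or `"none"`.
#' @slot qmax Termination wavevector (angstrom^-1; ignored for `"none"`).
#' @seealso [windowSpec()], [sqToGr()]
#' @export
setClass("WindowSpec", representation(kind = "character", qmax = "numeric"))

setValidity("WindowSpec", function(object) {
  if (!object@kind %in% c("lorch", "cosine", "none"))
    return("kind must be 'lorch', 'cosine' or 'none'")
  if (object@kind != "none" &&
      (length(object@qmax) != 1L || !is.finite(object@qmax) || object@qmax <= 0))
    return("qmax must be a single positive number")
  TRUE
})

#' Reference geometry for label-free neighborhood alignment
#'
#' Centered reference coordinates of the alignment atoms (e.g. the four
#' methyl carbons) plus the set of index permutations searched during
#' superposition, so that equivalent atoms need not be pre-sorted.
#'
#' @slot coords k x 3 matrix of reference coordinates, centered at the solute
#'   center (angstrom).
#' @slot permutations m x k integer matrix; each row is one candidate
#'   correspondence.
#' @seealso [alignmentReference()], [pickReference()], [alignNeighborhood()]
#' @export
setClass("AlignmentReference",
         representation(coords = "matrix", permutations = "matrix"))

setValidity("AlignmentReference", function(object) {
  x <- object@coords
  if (!is.numeric(x) || ncol(x) != 3L || nrow(x) < 3L)
    return("coords must be a k x 3 matrix with k >= 3")
  if (max(abs(colMeans(x))) > 1e-6)
    return("reference must be centered at the solute center")
  p <- object@permutations
  if (ncol(p) != nrow(x)) return("permutation width must match atom count")
  for (i in seq_len(nrow(p)))
    if (!setequal(p[i, ], seq_len(ncol(p)))) return("rows must be permutations of 1..k")
  TRUE
})

#' Voxel density map around an aligned solute
#'
#' Cubic voxel grid of a species' density in the solute-fixed frame, in
#' multiples of that species' bulk number density.
#'
#' @slot values nx x ny x nz array of relative densities (>= 0).
#' @slot voxel Voxel edge length (angstrom).
#' @slot origin Coordinates of the center of voxel (1,1,1) (angstrom).
#' @slot species Species class mapped.
#' @slot nNeighborhoods Number of aligned neighborhoods accumulated.
#' @slot bulkDensity Bulk number density used for normalization (angstrom^-3).
#' @seealso [accumulateDensity()], [siteOccupancy()], [exportDensityDX()]
#' @export
setClass("DensityGrid",
         representation(values = "array", voxel = "numeric", origin = "numeric",
                        species = "character", nNeighborhoods = "numeric",
                        bulkDensity = "numeric"))

setValidity("DensityGrid", function(object) {
  if (length(dim(object@values)) != 3L) return("values must be a 3D array")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    return("densities must be finite and >= 0")
  if (object@voxel <= 0) return("voxel size must be positive")
  if (length(object@origin) != 3L) return("origin must have length 3")
  TRUE
})

#' Tetrahedral site occupancies
#'
#' Mean relative density read out at the 4 face, 6 edge and 4 corner
#' directions of the reference tetrahedron at a stated radius.
#'
#' @slot faces,edges,corners Numeric vectors (length 4, 6, 4) of relative
#'   densities.
#' @slot radius Readout radius (angstrom).
#' @seealso [siteOccupancy()]
#' @export
setClass("SiteOccupancy",
         representation(faces = "numeric", edges = "numeric",
                        corners = "numeric", radius = "numeric"))

setValidity("SiteOccupancy", function(object) {
  if (length(object@faces) != 4L || length(object@edges) != 6L ||
      length(object@corners) != 4L)
    return("need 4 face, 6 edge and 4 corner values")
  if (any(c(object@faces, object@edges, object@corners) < 0))
    return("occupancies must be >= 0")
  TRUE
})

#' Synthetic fixture specification
#'
#' Declarative description of a synthetic trajectory: homogeneous gas,
#' Gaussian hydration shell, planted anisotropic (face/edge/corner) pattern,
#' or a 2 m TMACl-like labeled box. All randomness is controlled by `seed`.
#'
#' @slot kind One of `"ideal_gas"`, `"gaussian_shell"`, `"anisotropic"`,
#'   `"tmacl_box"`.
#' @slot params Named list of kind-specific parameters.
#' @slot seed Integer RNG seed.
#' @seealso [fixtureSpec()], [generateFixture()]
#' @export
setClass("FixtureSpec",
         representation(kind = "character", params = "list", seed = "numeric"))

setValidity("FixtureSpec", function(object) {
  kinds <- c("ideal_gas", "gaussian_shell", "anisotropic", "tmacl_box")
  if (!object@kind %in% kinds)
    return(paste("kind must be one of", paste(kinds, collapse = ", ")))
  if (length(object@seed) != 1L || !is.finite(object@seed) ||
      object@seed != round(object@seed))
    return("seed must be a single integer")
  TRUE
})
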