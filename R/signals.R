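# Assembly of weighted NDIS difference signals and their consistency checks.

#' Construct a structure factor directly
#'
#' @param labels Character(2) class pair.
#' @param Q Uniform Q grid (angstrom^-1).
#' @param values S(Q) - 1.
#' @param rho0 Total atomic number density (angstrom^-3).
#' @return A [StructureFactor-class].
#' @export
structureFactor <- function(labels, Q, values, rho0) {
  new("StructureFactor", labels = labels, Q = Q, values = values, rho0 = rho0)
}

#' @noRd
.pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Assemble a weighted difference signal
#'
#' Sums weight * (S_pair(Q) - 1) over the weighted pairs of a difference
#' prefactor table, in mbarn. Every pair with a nonzero weight must have a
#' matching partial on a common Q-grid; a second-order signal must reduce to
#' exactly one term.
#'
#' @param partials List of [StructureFactor-class] objects.
#' @param weights data.frame with columns `classA`, `classB`, `weight`
#'   (mbarn), e.g. from [firstOrderPrefactors()].
#' @param order `"first"` or `"second"`.
#' @return A [DifferenceSignal-class] in Q-space.
#' @export
assembleDifference <- function(partials, weights, order = c("first", "second")) {
  order <- match.arg(order)
  weights <- weights[abs(weights$weight) > 0, , drop = FALSE]
  if (order == "second" && nrow(weights) != 1L)
    stop("a second-order difference must reduce to exactly one weighted pair",
         call. = FALSE)
  have <- vapply(partials, function(p) .pairKey(p@labels[1], p@labels[2]), "")
  want <- .pairKey(weights$classA, weights$classB)
  missing <- setdiff(want, have)
  if (length(missing))
    stop(sprintf("no partial structure factor for pair(s): %s",
                 paste(gsub("\\|", "-", missing), collapse = ", ")),
         call. = FALSE)
  Q <- partials[[1]]@Q
  for (p in partials[match(want, have)])
    if (length(p@Q) != length(Q) || max(abs(p@Q - Q)) > 1e-9)
      stop("partials must share a common Q-grid", call. = FALSE)
  values <- numeric(length(Q))
  for (k in seq_len(nrow(weights)))
    values <- values + weights$weight[k] *
      partials[[match(want[k], have)]]@values
  new("DifferenceSignal", order = order,
      terms = weights[, c("classA", "classB", "weight")],
      grid = Q, values = values, space = "Q")
}

#' Placzek background cancellation check
#'
#' The inelasticity (Placzek) background of an H-rich sample is a smooth
#' function of Q set by the 1H content; two first-order differences taken at
#' the same solvent 1H content carry the same background, which must vanish
#' in their difference. Given synthetic smooth backgrounds added to the two
#' first-order signals, the residual background of the second order is
#' `bgA - bgB`, reported as max |residual|. With no backgrounds supplied,
#' the smooth baseline of the second-order signal is estimated by a
#' smoothing spline and its maximum magnitude reported (this is an estimate
#' of the signal's own smooth component, not zero).
#'
#' @param diffA,diffB First-order [DifferenceSignal-class] objects on a
#'   common Q-grid.
#' @param backgroundA,backgroundB Numeric vectors on the common Q-grid, or
#'   functions of Q, or `NULL`.
#' @return List with `metric` (mbarn), `residual` (vector on the Q grid) and
#'   `secondOrder` (the contaminated second-order values).
#' @export
placzekCancellationCheck <- function(diffA, diffB, backgroundA = NULL,
                                     backgroundB = backgroundA) {
  stopifnot(is(diffA, "DifferenceSignal"), is(diffB, "DifferenceSignal"))
  if (diffA@space != "Q" || diffB@space != "Q")
    stop("first-order signals must be in Q-space", call. = FALSE)
  Q <- diffA@grid
  if (length(diffB@grid) != length(Q) || max(abs(diffB@grid - Q)) > 1e-9)
    stop("signals must share a common Q-grid", call. = FALSE)
  evalBg <- function(bg) {
    if (is.null(bg)) return(numeric(length(Q)))
    if (is.function(bg)) bg <- bg(Q)
    if (length(bg) != length(Q)) stop("background length mismatch", call. = FALSE)
    bg
  }
  bgA <- evalBg(backgroundA)
  bgB <- evalBg(backgroundB)
  second <- (diffA@values + bgA) - (diffB@values + bgB)
  if (is.null(backgroundA) && is.null(backgroundB)) {
    baseline <- stats::smooth.spline(Q, second, df = 4)$y
    list(metric = max(abs(baseline)), residual = baseline,
         secondOrder = second)
  } else {
    residual <- bgA - bgB
    list(metric = max(abs(residual)), residual = residual,
         secondOrder = second)
  }
}

#' Simulated real-space double-difference signal
#'
#' Converts a simulated solute-H/water-H partial RDF into the real-space
#' double-difference prefactor * (g(r) - 1) in mbarn, directly comparable to
#' the Fourier-transformed experimental signal. Optionally the curve is
#' passed through the forward transform and windowed inverse transform to
#' mimic the experiment's finite-Q termination.
#'
#' @param rdf A [PartialRDF-class] of the solute-H / water-H pair.
#' @param comp A [SolutionComposition-class].
#' @param table A [ScatteringTable-class].
#' @param window Optional [WindowSpec-class]; when supplied, the curve is
#'   round-tripped through Q-space with this termination window.
#' @param rho0 Total atomic number density for the round trip (defaults to
#'   the RDF's partner density, adequate for the round trip since the
#'   density cancels between the two transforms).
#' @param Q Q-grid used for the round trip.
#' @return A [DifferenceSignal-class] in r-space (mbarn).
#' @export
simulatedDdg <- function(rdf, comp, table = defaultScatteringTable(),
                         window = NULL, rho0 = NULL, Q = defaultQGrid()) {
  stopifnot(is(rdf, "PartialRDF"))
  pref <- secondOrderPrefactor(comp, table)
  if (is.null(window)) {
    r <- rdf@r
    h <- rdf@g - 1
  } else {
    if (is.null(rho0)) rho0 <- rdf@rho
    sf <- rdfToSq(rdf, rho0 = rho0, Q = Q)
    gr <- sqToGr(sf, r = rdf@r, window = window, rho0 = rho0)
    r <- gr$r
    h <- gr$g - 1
  }
  new("DifferenceSignal", order = "second",
      terms = data.frame(classA = rdf@labels[1], classB = rdf@labels[2],
                         weight = pref),
      grid = r, values = pref * h, space = "r")
}

#' Write / read a (Q, value) or (r, value) signal as TSV
#'
#' @param x A [DifferenceSignal-class] or [StructureFactor-class].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeSignalTSV <- function(x, path) {
  if (is(x, "DifferenceSignal")) {
    hdr <- sprintf("%s\tvalue_mbarn",
                   if (x@space == "Q") "Q_A-1" else "r_A")
    df <- data.frame(x@grid, x@values)
  } else if (is(x, "StructureFactor")) {
    hdr <- "Q_A-1\tS_minus_1"
    df <- data.frame(x@Q, x@values)
  } else stop("unsupported object", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
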