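#' Construct a scattering-length table
#'
#' @param entries Named numeric vector of coherent scattering lengths (fm),
#'   named by species label (element or isotope).
#' @return A [ScatteringTable-class].
#' @examples
#' scatteringTable(c(H = -3.739, D = 6.671, O = 5.803))
#' @export
scatteringTable <- function(entries) {
  new("ScatteringTable", entries = entries)
}

#' Default coherent scattering lengths
#'
#' Standard tabulated (Sears) bound coherent scattering lengths for the
#' species appearing in aqueous TMACl systems: b(H) = -3.739, b(D) = 6.671,
#' b(C) = 6.646, b(N) = 9.36, b(O) = 5.803, b(Cl) = 9.577 fm. Override any
#' entry by supplying your own table (e.g. via [readScatteringTable()]).
#'
#' @return A [ScatteringTable-class].
#' @export
defaultScatteringTable <- function() {
  scatteringTable(c(H = -3.739, D = 6.671, C = 6.646, N = 9.36,
                    O = 5.803, Cl = 9.577))
}

#' Read / write a scattering-length table as TSV
#'
#' Two-column tab-separated format with header `label<TAB>b_fm`.
#'
#' @param path File path.
#' @param table A [ScatteringTable-class] (for writing).
#' @return `readScatteringTable` returns a [ScatteringTable-class];
#'   `writeScatteringTable` returns `path` invisibly.
#' @export
readScatteringTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("label", "b_fm") %in% names(df)))
    stop("expected columns 'label' and 'b_fm'", call. = FALSE)
  scatteringTable(stats::setNames(df$b_fm, df$label))
}

#' @rdname readScatteringTable
#' @export
writeScatteringTable <- function(table, path) {
  stopifnot(is(table, "ScatteringTable"))
  df <- data.frame(label = names(table@entries), b_fm = unname(table@entries))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
.lookupB <- function(table, label) {
  b <- table@entries[label]
  if (any(is.na(b)))
    stop(sprintf("species '%s' missing from scattering table",
                 paste(label[is.na(b)], collapse = "', '")), call. = FALSE)
  unname(b)
}

#' Construct a solution composition
#'
#' @param sites data.frame with columns `class`, `element`, `count` (atoms
#'   per formula unit) and `substitutable` (logical: open to H/D labeling).
#'   Pass a zero-row frame (or `NULL`) for pure water.
#' @param molality Mol solute per kg water; 0 only for pure water.
#' @param waterMolPerKg Moles of water per kg of water; the 55.508 default
#'   corresponds to M(H2O) = 18.0153 g/mol.
#' @return A [SolutionComposition-class].
#' @seealso [tmaclComposition()] for the ready-made aqueous TMACl system.
#' @export
solutionComposition <- function(sites = NULL, molality = 0,
                                waterMolPerKg = .WATER_MOL_PER_KG) {
  if (is.null(sites))
    sites <- data.frame(class = character(), element = character(),
                        count = numeric(), substitutable = logical())
  if (is.numeric(molality) && length(molality) == 1L && !is.na(molality) &&
      molality < 0)
    stop("molality must be >= 0", call. = FALSE)
  new("SolutionComposition", sites = sites, molality = molality,
      waterMolPerKg = waterMolPerKg)
}

#' Aqueous TMACl composition
#'
#' The tetramethylammonium chloride solution used throughout: per formula
#' unit one central nitrogen, four methyl carbons, twelve non-exchangeable
#' hydrogens (class `H_non`, substitutable) and one chloride counterion, in
#' water at the given molality.
#'
#' @param molality Mol TMACl per kg water (default 2, the experimental
#'   concentration).
#' @return A [SolutionComposition-class].
#' @examples
#' comp <- tmaclComposition(2)
#' atomicFractions(comp)
#' @export
tmaclComposition <- function(molality = 2) {
  solutionComposition(
    sites = data.frame(
      class = c("N", "C_TMA", "H_non", "Cl"),
      element = c("N", "C", "H", "Cl"),
      count = c(1, 4, 12, 1),
      substitutable = c(FALSE, FALSE, TRUE, FALSE)),
    molality = molality)
}

# Full per-class site table on a per-kg-water basis, with the implicit water
# classes appended.
#' @noRd
.compositionSites <- function(comp) {
  s <- comp@sites
  solute <- data.frame(class = as.character(s$class),
                       element = as.character(s$element),
                       substitutable = as.logical(s$substitutable),
                       molPerKg = s$count * comp@molality,
                       stringsAsFactors = FALSE)
  water <- data.frame(class = c("O_W", "H_W"), element = c("O", "H"),
                      substitutable = c(FALSE, TRUE),
                      molPerKg = c(1, 2) * comp@waterMolPerKg,
                      stringsAsFactors = FALSE)
  rbind(solute, water)
}

#' Atomic fractions of all site classes
#'
#' Fractions of each atomic site class (solute classes plus the implicit
#' water classes `O_W` and `H_W`) over all atoms in the solution, computed on
#' a per-kg-water basis. These are the concentrations entering the
#' Faber-Ziman pair weights.
#'
#' @param comp A [SolutionComposition-class].
#' @return Named numeric vector of fractions summing to 1.
#' @examples
#' atomicFractions(tmaclComposition(2))[["H_non"]]  # ~0.1185
#' @export
atomicFractions <- function(comp) {
  stopifnot(is(comp, "SolutionComposition"))
  sites <- .compositionSites(comp)
  stats::setNames(sites$molPerKg / sum(sites$molPerKg), sites$class)
}

# Per-class scattering lengths under one labeling: substitutable classes take
# the isotope label assigned by the scheme, others their element.
#' @noRd
.classScatteringLengths <- function(comp, table, labeling) {
  sites <- .compositionSites(comp)
  lab <- sites$element
  sub <- sites$substitutable
  if (any(sub)) {
    if (is.null(labeling))
      stop("composition has substitutable classes; a labeling is required",
           call. = FALSE)
    a <- labeling@assignments
    missing <- setdiff(sites$class[sub], names(a))
    if (length(missing))
      stop(sprintf("labeling does not assign class(es): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    extra <- setdiff(names(a), sites$class[sub])
    if (length(extra))
      stop(sprintf("labeling assigns undeclared class(es): %s",
                   paste(extra, collapse = ", ")), call. = FALSE)
    lab[sub] <- a[sites$class[sub]]
  }
  stats::setNames(.lookupB(table, lab), sites$class)
}

#' Construct an isotope labeling scheme
#'
#' @param ... Named assignments, e.g. `H_non = "D", H_W = "H"`, or a single
#'   named character vector.
#' @return A [LabelingScheme-class].
#' @export
labelingScheme <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]])))
    a <- args[[1]]
  else a <- unlist(args)
  new("LabelingScheme", assignments = a)
}

#' Faber-Ziman pair weight (mbarn)
#'
#' With one labeling, the weight of the (alpha, beta) partial in the total
#' pattern: (2 - delta_ab) c_a c_b b_a b_b, converted from fm^2 to mbarn.
#' With two labelings, the double-contrast weight
#' (2 - delta_ab) c_a c_b (b_a^A - b_a^B) (b_b^A - b_b^B) that a pair carries
#' in a difference experiment in which both classes change isotope between
#' the two samples; classes not substituted contribute zero contrast.
#'
#' @param comp A [SolutionComposition-class].
#' @param pair Character(2): the two class labels.
#' @param table A [ScatteringTable-class].
#' @param labelingA,labelingB [LabelingScheme-class] objects; `labelingB`
#'   may be `NULL` for the single-sample weight.
#' @return Weight in mbarn; exactly symmetric in the pair.
#' @examples
#' comp <- tmaclComposition(2)
#' allD <- labelingScheme(H_non = "D", H_W = "D")
#' allH <- labelingScheme(H_non = "H", H_W = "H")
#' pairWeight(comp, c("H_non", "H_W"), defaultScatteringTable(), allD, allH)
#' @export
pairWeight <- function(comp, pair, table, labelingA, labelingB = NULL) {
  stopifnot(is(comp, "SolutionComposition"), is(table, "ScatteringTable"))
  if (length(pair) != 2L) stop("pair must name two classes", call. = FALSE)
  c_all <- atomicFractions(comp)
  missing <- setdiff(pair, names(c_all))
  if (length(missing))
    stop(sprintf("unknown site class(es): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  bA <- .classScatteringLengths(comp, table, labelingA)
  pref <- if (pair[1] == pair[2]) 1 else 2
  if (is.null(labelingB)) {
    w <- pref * c_all[[pair[1]]] * c_all[[pair[2]]] * bA[[pair[1]]] * bA[[pair[2]]]
  } else {
    bB <- .classScatteringLengths(comp, table, labelingB)
    w <- pref * c_all[[pair[1]]] * c_all[[pair[2]]] *
      (bA[[pair[1]]] - bB[[pair[1]]]) * (bA[[pair[2]]] - bB[[pair[2]]])
  }
  w * .FM2_TO_MBARN
}

# All unordered pair weights for one labeled sample, in mbarn.
#' @noRd
.fullPairWeights <- function(comp, table, labeling) {
  c_all <- atomicFractions(comp)
  b <- .classScatteringLengths(comp, table, labeling)
  cls <- names(c_all)
  idx <- which(upper.tri(matrix(0, length(cls), length(cls)), diag = TRUE),
               arr.ind = TRUE)
  data.frame(
    classA = cls[idx[, 1]],
    classB = cls[idx[, 2]],
    weight = ifelse(idx[, 1] == idx[, 2], 1, 2) *
      c_all[idx[, 1]] * c_all[idx[, 2]] * b[idx[, 1]] * b[idx[, 2]] *
      .FM2_TO_MBARN,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' First-order difference prefactors
#'
#' Pair weights of the first-order NDIS difference between two samples whose
#' labelings differ in exactly one substitutable class (the solute's
#' non-exchangeable hydrogens in the TMACl experiment). Cross terms to the
#' substituted class X carry 2 c_sub c_X b_X (b_A - b_B); the self term
#' carries c_sub^2 (b_A^2 - b_B^2); all pairs not involving the substituted
#' class cancel to exactly zero and are dropped unless `keepZero = TRUE`.
#'
#' @inheritParams pairWeight
#' @param keepZero Keep the exactly-cancelled pairs (weight 0) in the output.
#' @return data.frame with columns `classA`, `classB`, `weight` (mbarn).
#' @examples
#' comp <- tmaclComposition(2)
#' d12 <- labelingScheme(H_non = "D", H_W = "D")
#' h12 <- labelingScheme(H_non = "H", H_W = "D")
#' firstOrderPrefactors(comp, defaultScatteringTable(), d12, h12)
#' @export
firstOrderPrefactors <- function(comp, table, labelingA, labelingB,
                                 keepZero = FALSE) {
  stopifnot(is(labelingA, "LabelingScheme"), is(labelingB, "LabelingScheme"))
  aA <- labelingA@assignments
  aB <- labelingB@assignments
  if (!setequal(names(aA), names(aB)))
    stop("labelings must assign the same classes", call. = FALSE)
  changed <- names(aA)[aA[names(aA)] != aB[names(aA)]]
  if (length(changed) > 1L)
    stop(sprintf("labelings must differ in exactly one class (differ in %d)",
                 length(changed)), call. = FALSE)
  wA <- .fullPairWeights(comp, table, labelingA)
  wB <- .fullPairWeights(comp, table, labelingB)
  out <- wA
  out$weight <- wA$weight - wB$weight
  if (!keepZero)
    out <- if (length(changed))
      out[out$classA == changed | out$classB == changed, , drop = FALSE]
    else out[FALSE, , drop = FALSE]  # identical labelings: everything cancels
  rownames(out) <- NULL
  out
}

#' Second-order difference prefactor (mbarn)
#'
#' The single weight surviving in the difference of the two first-order
#' differences: 2 c_Hnon c_HW (b_D - b_H)^2, converted to mbarn. For the 2 m
#' TMACl solution with the default scattering lengths this is 140.8 mbarn.
#'
#' @param comp A [SolutionComposition-class] declaring both a substitutable
#'   solute-hydrogen class and the water-hydrogen class.
#' @param table A [ScatteringTable-class] containing `"H"` and `"D"`.
#' @param hNon,hW Class labels of the solute and water hydrogen classes.
#' @return Prefactor in mbarn.
#' @examples
#' secondOrderPrefactor(tmaclComposition(2), defaultScatteringTable())
#' @export
secondOrderPrefactor <- function(comp, table = defaultScatteringTable(),
                                 hNon = "H_non", hW = "H_W") {
  stopifnot(is(comp, "SolutionComposition"), is(table, "ScatteringTable"))
  c_all <- atomicFractions(comp)
  sites <- .compositionSites(comp)
  for (cl in c(hNon, hW)) {
    if (!cl %in% names(c_all))
      stop(sprintf("composition does not declare class '%s'", cl), call. = FALSE)
    if (!sites$substitutable[sites$class == cl])
      stop(sprintf("class '%s' is not substitutable", cl), call. = FALSE)
  }
  db <- diff(.lookupB(table, c("H", "D")))
  2 * c_all[[hNon]] * c_all[[hW]] * db^2 * .FM2_TO_MBARN
}

#' Write a pair-weight table as TSV
#'
#' @param weights data.frame with columns `classA`, `classB`, `weight`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeWeightsTSV <- function(weights, path) {
  names(weights)[names(weights) == "weight"] <- "weight_mbarn"
  utils::write.table(weights, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
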