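# Pipeline driver: YAML config -> staged execution -> manifest with content
# hashes, so a full weights -> rdf -> signal -> densmap run is reproducible
# from one file.

#' Read / write a solution composition as YAML
#'
#' Layout: top-level `molality`, optional `water_mol_per_kg`, and `sites:` a
#' list of maps with keys `class`, `element`, `count`, `substitutable`.
#'
#' @param path YAML file path.
#' @param comp A [SolutionComposition-class] (for writing).
#' @return `readCompositionYAML` returns a [SolutionComposition-class].
#' @export
readCompositionYAML <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$molality)) stop("composition YAML needs 'molality'", call. = FALSE)
  sites <- if (length(y$sites)) do.call(rbind, lapply(y$sites, function(s)
    data.frame(class = s$class, element = s$element, count = s$count,
               substitutable = isTRUE(s$substitutable)))) else NULL
  solutionComposition(sites, molality = y$molality,
                      waterMolPerKg = if (is.null(y$water_mol_per_kg))
                        .WATER_MOL_PER_KG else y$water_mol_per_kg)
}

#' @rdname readCompositionYAML
#' @export
writeCompositionYAML <- function(comp, path) {
  stopifnot(is(comp, "SolutionComposition"))
  s <- comp@sites
  yaml::write_yaml(list(
    molality = comp@molality,
    water_mol_per_kg = comp@waterMolPerKg,
    sites = lapply(seq_len(nrow(s)), function(i)
      list(class = s$class[i], element = s$element[i], count = s$count[i],
           substitutable = s$substitutable[i]))), path)
  invisible(path)
}

#' Read labeling schemes from YAML
#'
#' Layout: `samples:` map of sample name -> map of class -> isotope label.
#'
#' @param path YAML file path.
#' @return Named list of [LabelingScheme-class] objects.
#' @export
readLabelingYAML <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$samples)) stop("labeling YAML needs 'samples'", call. = FALSE)
  lapply(y$samples, function(s) labelingScheme(unlist(s)))
}

# Minimal structural validation with field paths (no JSON-schema engine is
# required for this fixed layout).
#' @noRd
.checkConfig <- function(cfg) {
  fail <- function(path, why)
    stop(sprintf("config error at '%s': %s", path, why), call. = FALSE)
  if (!is.list(cfg)) fail("(root)", "must be a map")
  if (is.null(cfg$stages)) fail("stages", "missing")
  stages <- unlist(cfg$stages)
  known <- c("synth", "weights", "rdf", "signal", "densmap")
  for (s in stages) {
    if (!s %in% known)
      fail(paste0("stages/", s), paste("unknown stage; expected one of",
                                       paste(known, collapse = ", ")))
    if (is.null(cfg[[s]])) fail(s, "stage listed but has no parameter block")
  }
  needs <- list(
    synth = c("kind", "frames", "out"),
    weights = c("composition", "out"),
    rdf = c("traj", "pairs", "out"),
    signal = c("rdf", "composition", "out"),
    densmap = c("traj", "solute_center", "align_class", "species", "out"))
  for (s in stages)
    for (k in needs[[s]])
      if (is.null(cfg[[s]][[k]])) fail(paste0(s, "/", k), "missing")
  stoch <- intersect(stages, c("synth", "densmap"))
  if (length(stoch) && is.null(cfg$seed))
    fail("seed", paste("required by stochastic stage(s):",
                       paste(stoch, collapse = ", ")))
  invisible(stages)
}

#' @noRd
.resolveComposition <- function(x) {
  if (is.character(x) && x == "tmacl2m") return(tmaclComposition(2))
  if (is.character(x)) {
    if (!file.exists(x)) stop(sprintf("composition file '%s' not found", x),
                              call. = FALSE)
    return(readCompositionYAML(x))
  }
  stop("composition must be a YAML path or 'tmacl2m'", call. = FALSE)
}

#' Run the staged analysis pipeline
#'
#' Executes the stages named in the config in their dependency order
#' (synth, weights, rdf, signal, densmap), each parameterized by its own
#' block, and returns a manifest listing every output file with its MD5
#' hash and the parameters that produced it. Reruns of the same config and
#' seed give identical hashes. An empty stage list yields an empty manifest.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param manifestPath Optional path to also write the manifest as JSON.
#' @return The manifest (list), invisibly when `manifestPath` is given.
#' @examples
#' cfg <- list(stages = list("weights"),
#'             weights = list(composition = "tmacl2m",
#'                            out = tempfile(fileext = ".tsv")))
#' runPipeline(cfg)
#' @export
runPipeline <- function(config, manifestPath = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stages <- .checkConfig(cfg)
  order <- c("synth", "weights", "rdf", "signal", "densmap")
  stages <- order[order %in% stages]
  manifest <- list(stages = stages, outputs = list())
  record <- function(stage, path, params) {
    manifest$outputs[[length(manifest$outputs) + 1L]] <<- list(
      stage = stage, path = path,
      md5 = unname(tools::md5sum(path)), params = params)
  }
  runStage <- function(stage, body) {
    tryCatch(body(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  for (stage in stages) {
    p <- cfg[[stage]]
    message(sprintf("[ndiskit] running stage '%s'", stage))
    if (stage == "synth") runStage(stage, function() {
      spec <- do.call(fixtureSpec, c(list(kind = p$kind, seed = cfg$seed),
                                     p$params))
      traj <- generateFixture(spec, nFrames = p$frames)
      writeGRO(traj, p$out)
      record(stage, p$out, p)
    })
    if (stage == "weights") runStage(stage, function() {
      comp <- .resolveComposition(p$composition)
      if (!is.null(p$samples)) {
        labs <- readLabelingYAML(p$samples)
        if (length(labs) < 2L) stop("need at least two labeled samples")
        w <- firstOrderPrefactors(comp, defaultScatteringTable(),
                                  labs[[1]], labs[[2]])
        w$order <- "first"
      } else w <- NULL
      w2 <- data.frame(classA = "H_non", classB = "H_W",
                       weight = secondOrderPrefactor(comp),
                       order = "second")
      writeWeightsTSV(rbind(w, w2), p$out)
      record(stage, p$out, p)
    })
    if (stage == "rdf") runStage(stage, function() {
      traj <- readGRO(p$traj)
      if (!is.null(p$topology)) traj <- applyTopology(traj, p$topology)
      for (pair in strsplit(unlist(p$pairs), ":")) {
        rdf <- computePartialRDF(traj, pair[1], pair[2],
                                 rMax = if (is.null(p$rmax)) 12 else p$rmax,
                                 nBins = if (is.null(p$bins)) 600 else p$bins)
        out <- sprintf(p$out, paste(pair, collapse = "_"))
        writeRDFTSV(rdf, out)
        record(stage, out, c(p, list(pair = paste(pair, collapse = ":"))))
      }
    })
    if (stage == "signal") runStage(stage, function() {
      rdf <- readRDFTSV(p$rdf)
      comp <- .resolveComposition(p$composition)
      win <- if (is.null(p$window)) NULL else {
        parts <- strsplit(p$window, ":")[[1]]
        windowSpec(parts[1], as.numeric(parts[2]))
      }
      sig <- simulatedDdg(rdf, comp, window = win)
      writeSignalTSV(sig, p$out)
      record(stage, p$out, p)
    })
    if (stage == "densmap") runStage(stage, function() {
      traj <- readGRO(p$traj)
      if (!is.null(p$topology)) traj <- applyTopology(traj, p$topology)
      ref <- pickReference(traj, p$solute_center, p$align_class,
                           seed = cfg$seed)
      for (sp in unlist(p$species)) {
        grid <- accumulateDensity(
          traj, sp, ref, p$solute_center, p$align_class,
          voxel = if (is.null(p$voxel)) 0.5 else p$voxel,
          cutoff = if (is.null(p$cutoff)) 10 else p$cutoff)
        out <- sprintf(p$out, sp)
        exportDensityDX(grid, out, isoLevels = p$iso_levels)
        record(stage, out, c(p, list(species = sp)))
      }
    })
  }
  if (!is.null(manifestPath)) {
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA)
    return(invisible(manifest))
  }
  manifest
}
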