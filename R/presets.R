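# Shipped (patho)physiological presets and configuration validation.
#
# The preset constants below are the package's calibration of the unknown
# supplement-level parameters (HO baseline is literature; active stress,
# preload, anatomy and scar settings were calibrated once so that the
# simulated EF/EDV/mass/strain indices land on the published targets).

presetTable <- function() {
  list(
    NOR = list(
      anatomy = list(cavityLength = 90, baseRadius = 23.4,
                     wallThicknessBase = 6.6, wallThicknessApex = 5.2,
                     sphericity = 0.5),
      TaMax = 192, pathologyScale = 1,
      circulation = list(),
      scar = FALSE),
    DCM = list(
      anatomy = list(cavityLength = 102, baseRadius = 29.2,
                     wallThicknessBase = 7.0, wallThicknessApex = 5.7,
                     sphericity = 0.75),
      TaMax = 215, pathologyScale = 5,
      circulation = list(),
      scar = FALSE),
    HCM = list(
      anatomy = list(cavityLength = 89, baseRadius = 24.8,
                     wallThicknessBase = 11.5, wallThicknessApex = 8.0,
                     sphericity = 0.55),
      TaMax = 175, pathologyScale = 5,
      circulation = list(),
      scar = FALSE),
    INFARCT = list(
      anatomy = list(cavityLength = 92, baseRadius = 24.2,
                     wallThicknessBase = 6.4, wallThicknessApex = 5.2,
                     sphericity = 0.55),
      TaMax = 330, pathologyScale = 1,
      circulation = list(),
      scar = list(semiCirc = 20)))
}

#' Construct a preset configuration
#'
#' Returns the shipped configuration of one of the four (patho)physiologic
#' presets — NOR (healthy), DCM (dilated), HCM (hypertrophic), INFARCT
#' (healthy-sized LV with an elliptical free-wall scar) — with optional
#' overrides.
#'
#' @param name one of "NOR", "DCM", "HCM", "INFARCT".
#' @param overrides named list of overrides; recognized keys: anatomy
#'   (list of \code{\link{anatomyParams}} arguments), TaMax,
#'   pathologyScale, circulation (list of \code{\link{circulationModel}}
#'   arguments), scar (list of \code{\link{scarDefect}} arguments),
#'   sequence (list of \code{\link{sequenceParams}} arguments), seeds
#'   (list: shape, texture, noise), solver (list: nCirc, nLong, nTrans,
#'   nFrames, dt, basisSize, kPeri, gridNU, gridNV).
#' @return a \linkS4class{PresetConfig}.
#' @export
presetConfig <- function(name = c("NOR", "DCM", "HCM", "INFARCT"),
                         overrides = list()) {
  name <- match.arg(name)
  base <- presetTable()[[name]]
  known <- c("anatomy", "TaMax", "pathologyScale", "circulation", "scar",
             "sequence", "seeds", "solver")
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  an <- utils::modifyList(base$anatomy, overrides$anatomy %||% list())
  anat <- do.call(anatomyParams, an)
  circ <- do.call(circulationModel,
                  utils::modifyList(base$circulation,
                                    overrides$circulation %||% list()))
  act <- activationModel(TaMax = overrides$TaMax %||% base$TaMax)
  mat <- materialParams()
  if ((overrides$pathologyScale %||% base$pathologyScale) > 1)
    mat@pathologyScale <- overrides$pathologyScale %||% base$pathologyScale
  scar <- list(NULL)
  if (!isFALSE(base$scar) || is.list(overrides$scar)) {
    scarArgs <- if (is.list(base$scar)) base$scar else list()
    scarArgs <- utils::modifyList(scarArgs, overrides$scar %||% list())
    scar <- list(do.call(scarDefect, scarArgs))
  }
  sq <- do.call(sequenceParams, overrides$sequence %||% list())
  seeds <- utils::modifyList(list(shape = 1, texture = 11, noise = 21),
                             overrides$seeds %||% list())
  solver <- utils::modifyList(
    list(nCirc = 16L, nLong = 8L, nTrans = 3L, nFrames = 50L, dt = 5,
         basisSize = 10L, kPeri = 400, gridNU = 64L, gridNV = 64L,
         nSlices = 1L, hiResFactor = 4L, fiberEndo = 60, fiberEpi = -45),
    overrides$solver %||% list())
  validObject(anat); validObject(mat); validObject(sq)
  new("PresetConfig", name = name, anatomy = anat, material = mat,
      activation = act, circulation = circ, scar = scar, sequence = sq,
      seeds = seeds, solver = solver)
}

#' Validate a raw configuration list
#'
#' Schema-checks a plain list (e.g. parsed from YAML): fills defaults from
#' the named preset, normalizes types and reports every violation at once.
#'
#' @param raw named list with at least \code{name}; remaining entries as
#'   the \code{overrides} of \code{\link{presetConfig}}.
#' @return a validated \linkS4class{PresetConfig}.
#' @export
validateConfig <- function(raw) {
  errs <- character()
  if (is.null(raw$name) || !raw$name %in% c("NOR", "DCM", "HCM", "INFARCT"))
    errs <- c(errs, "name must be one of NOR, DCM, HCM, INFARCT")
  sq <- raw$sequence %||% list()
  if (!is.null(sq$TE) && !is.null(sq$TR) && sq$TE > sq$TR)
    errs <- c(errs, "TE must not exceed TR")
  if (!is.null(sq$SNR) && sq$SNR <= 0)
    errs <- c(errs, "SNR must be positive")
  if (!is.null(raw$pathologyScale) &&
      (raw$pathologyScale < 1 || raw$pathologyScale > 10))
    errs <- c(errs, "pathologyScale must lie in [1, 10]")
  if (length(errs)) stop("invalid configuration:\n  - ",
                         paste(errs, collapse = "\n  - "))
  overrides <- raw[setdiff(names(raw), "name")]
  presetConfig(raw$name, overrides)
}

#' Serialize a preset configuration to a list (YAML-ready)
#' @param config a \linkS4class{PresetConfig}.
#' @return nested plain list.
#' @export
configToList <- function(config) {
  s4ToList <- function(x) {
    out <- lapply(slotNames(x), function(sn) slot(x, sn))
    names(out) <- slotNames(x)
    out
  }
  list(name = config@name, anatomy = s4ToList(config@anatomy),
       material = s4ToList(config@material),
       activation = s4ToList(config@activation),
       circulation = s4ToList(config@circulation),
       scar = if (is.null(config@scar[[1]])) NULL else
         s4ToList(config@scar[[1]]),
       sequence = s4ToList(config@sequence),
       seeds = config@seeds, solver = config@solver)
}

setMethod("show", "PresetConfig", function(object) {
  cat(sprintf(
    "PresetConfig '%s': TaMax %.0f kPa, pathologyScale %.0f, scar: %s\n",
    object@name, object@activation@TaMax,
    object@material@pathologyScale,
    if (is.null(object@scar[[1]])) "none" else "elliptical free wall"))
})

#' Shipped latent-space preset clusters
#'
#' Fits the generative shape model on a mixed synthetic population
#' (healthy, dilated, hypertrophic thirds), clusters the training latents
#' with k-means and labels the centers by decoded anatomy. This is the
#' latent-space counterpart of the anatomy presets; cached per session.
#'
#' @param n population size.
#' @param d latent dimension.
#' @param seed population/clustering seed.
#' @return list with elements \code{model} (\linkS4class{ShapeModel}),
#'   \code{clusters} (\linkS4class{PresetClusters}) and \code{latents}.
#' @export
presetShapeClusters <- function(n = 120, d = 16, seed = 7) {
  key <- sprintf("clusters_%d_%d_%d", n, d, seed)
  if (!is.null(.presetCache[[key]])) return(.presetCache[[key]])
  pop <- lapply(sampleAnatomyParams(n, "MIX", seed = seed),
                generateAnatomy, nU = 32L, nV = 32L)
  model <- fitShapeModel(pop, d = d, seed = seed)
  lat <- t(vapply(pop, function(s) encodeShape(model, s), numeric(model@d)))
  cl <- clusterLatent(lat, 3L, seed = seed, model = model)
  out <- list(model = model, clusters = cl, latents = lat)
  .presetCache[[key]] <- out
  out
}

.presetCache <- new.env(parent = emptyenv())
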