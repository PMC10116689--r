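#' @import methods
NULL

#' Paired endocardial/epicardial surface grids of a left ventricle
#'
#' Structured point grids describing the inner (endocardial) and outer
#' (epicardial) surface of an LV wall. Both grids share the same layout:
#' a 3 x Nu x Nv array of coordinates in mm, where the first grid index is
#' the circumferential direction u (periodic) and the second the
#' apex-to-base direction v (v = 1 is the apex row, v = Nv the base row).
#' The convention mirrors the 6-channel coordinate-image representation
#' used by generative LV shape models (two surfaces x three coordinates).
#'
#' @slot endo 3 x Nu x Nv array, endocardial points (mm).
#' @slot epi 3 x Nu x Nv array, epicardial points (mm).
#' @slot basePlane list with elements \code{point} and \code{normal}
#'   (unit vector) describing the basal truncation plane.
#' @slot apex numeric(3), apex position (mm).
#' @export
setClass("LVSurfaceGrid",
  representation(endo = "array", epi = "array",
                 basePlane = "list", apex = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@endo)) != 3L || dim(object@endo)[1] != 3L)
      msg <- c(msg, "endo must be a 3 x Nu x Nv array")
    if (!identical(dim(object@endo), dim(object@epi)))
      msg <- c(msg, "endo and epi grids must have identical dimensions")
    if (length(msg) == 0L) {
      thick <- sqrt(colSums((object@epi - object@endo)^2, dims = 1))
      if (any(thick <= 0.5 - 1e-9))
        msg <- c(msg, sprintf(
          "wall thickness must exceed 0.5 mm everywhere (min %.3f mm)",
          min(thick)))
    }
    if (length(msg)) msg else TRUE
  })

#' Anatomical parameters of the procedural LV generator
#'
#' Scalar descriptors of a truncated thick-walled prolate-ellipsoid left
#' ventricle. All lengths in mm, angles in degrees.
#'
#' @slot cavityLength apex-to-base cavity length (mm).
#' @slot baseRadius endocardial radius at the base plane (mm).
#' @slot wallThicknessBase,wallThicknessApex wall thickness at base/apex (mm).
#' @slot sphericity 0 (elongated) to 1 (spherical) cavity shape factor.
#' @slot baseTilt tilt of the basal plane (deg) about the y axis.
#' @slot globalScale isotropic scale factor (dimensionless).
#' @slot rngSeed integer seed recorded for provenance.
#' @export
setClass("AnatomyParams",
  representation(cavityLength = "numeric", baseRadius = "numeric",
                 wallThicknessBase = "numeric", wallThicknessApex = "numeric",
                 sphericity = "numeric", baseTilt = "numeric",
                 globalScale = "numeric", rngSeed = "numeric"),
  prototype(cavityLength = 90, baseRadius = 23.5, wallThicknessBase = 9,
            wallThicknessApex = 7, sphericity = 0.5, baseTilt = 0,
            globalScale = 1, rngSeed = 0),
  validity = function(object) {
    msg <- character()
    for (s in c("cavityLength", "baseRadius", "wallThicknessBase",
                "wallThicknessApex", "globalScale"))
      if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be positive"))
    if (object@sphericity < 0 || object@sphericity > 1)
      msg <- c(msg, "sphericity must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Low-rank generative LV shape model
#'
#' Principal-component embedding of flattened surface-grid coordinates with
#' a whitened latent space: training latents have per-coordinate mean ~0 and
#' variance ~1, decoding the zero vector returns the population mean shape.
#'
#' @slot mean numeric, flattened mean shape (endo then epi coordinates).
#' @slot rotation p x d matrix of principal directions.
#' @slot sdev length-d singular standard deviations used for whitening.
#' @slot d latent dimension.
#' @slot gridDim integer(2), (Nu, Nv) of the training grids.
#' @slot meta list of training metadata (population size, seed).
#' @export
setClass("ShapeModel",
  representation(mean = "numeric", rotation = "matrix", sdev = "numeric",
                 d = "integer", gridDim = "integer", meta = "list"))

#' Latent-space cluster centers labelled with anatomical presets
#' @slot centers k x d matrix of latent centers.
#' @slot labels character(k), one of NOR, DCM, HCM.
#' @export
setClass("PresetClusters",
  representation(centers = "matrix", labels = "character"),
  validity = function(object) {
    if (nrow(object@centers) != length(object@labels))
      "one label per center required" else TRUE
  })

#' Layered hexahedral mesh of the LV wall
#'
#' Nodes are organised as transmural layers of a structured circumferential
#' x longitudinal grid interpolated between the endo- and epicardial
#' surfaces. Every node carries the transmural coordinate t (0 = endo,
#' 1 = epi), the normalized longitudinal coordinate (0 = apex, 1 = base),
#' the azimuth, and an orthonormal local frame (radial, circumferential,
#' longitudinal).
#'
#' @slot nodes N x 3 matrix of reference node positions (mm).
#' @slot elems E x 8 integer matrix of hexahedral connectivity.
#' @slot nodeT,nodeV,nodePhi per-node transmural/longitudinal/azimuthal
#'   coordinates.
#' @slot frameR,frameC,frameL N x 3 matrices: radial (outward),
#'   circumferential, longitudinal (apex to base) unit vectors.
#' @slot dims integer(3): (n transmural layers + 1, n circumferential,
#'   n longitudinal + 1).
#' @slot gradN E x 8 x 3 array of trilinear shape-function gradients at
#'   element centroids (reference configuration).
#' @slot elemVol element volumes (mm^3, 2x2x2 Gauss).
#' @slot elemT,elemV,elemPhi element-centroid coordinates.
#' @export
setClass("VolumetricMesh",
  representation(nodes = "matrix", elems = "matrix",
                 nodeT = "numeric", nodeV = "numeric", nodePhi = "numeric",
                 frameR = "matrix", frameC = "matrix", frameL = "matrix",
                 dims = "integer", gradN = "array", elemVol = "numeric",
                 elemT = "numeric", elemV = "numeric", elemPhi = "numeric"),
  validity = function(object) {
    if (any(object@elemVol <= 0)) "all element volumes must be positive"
    else TRUE
  })

#' Transmurally varying myofiber field
#' @slot fibers N x 3 unit fiber vectors.
#' @slot sheets N x 3 unit sheet vectors (radial by construction).
#' @slot helixEndo,helixEpi helix angles (deg) at endo/epi.
#' @export
setClass("FiberField",
  representation(fibers = "matrix", sheets = "matrix",
                 helixEndo = "numeric", helixEpi = "numeric"))

#' Holzapfel-Ogden material parameters
#'
#' Four-term invariant-based strain energy (isotropic I1, fiber I4f, sheet
#' I4s, shear I8fs terms, each of a*(exp(b*x) - 1) type) plus a volumetric
#' penalty kappa*(J-1)^2/2. Stress-like coefficients in kPa, exponents
#' dimensionless.
#'
#' @slot a,b,af,bf,as,bs,afs,bfs HO coefficients.
#' @slot kappa incompressibility penalty (kPa).
#' @slot pathologyScale multiplier applied to the a* coefficients for
#'   stiffened (cardiomyopathic) tissue; 1 for healthy.
#' @slot rho tissue density (g/ml).
#' @export
setClass("MaterialParams",
  representation(a = "numeric", b = "numeric", af = "numeric", bf = "numeric",
                 as = "numeric", bs = "numeric", afs = "numeric",
                 bfs = "numeric", kappa = "numeric",
                 pathologyScale = "numeric", rho = "numeric"),
  prototype(a = 0.496, b = 7.209, af = 15.193, bf = 20.417,
            as = 3.283, bs = 11.176, afs = 0.662, bfs = 9.466,
            kappa = 2000, pathologyScale = 1, rho = 1.05),
  validity = function(object) {
    msg <- character()
    for (s in c("a", "af", "as", "afs", "kappa", "rho"))
      if (any(slot(object, s) <= 0)) msg <- c(msg, paste(s, "must be > 0"))
    if (object@pathologyScale < 1 || object@pathologyScale > 10)
      msg <- c(msg, "pathologyScale must lie in [1, 10]")
    if (length(msg)) msg else TRUE
  })

#' Electrical activation and active-stress transient
#'
#' Activation times come from front propagation at conduction velocity
#' \code{v}; the active fiber stress follows a smooth two-sigmoid twitch
#' normalized so its peak equals \code{TaMax}.
#'
#' @slot v conduction velocity (mm/ms); an effective velocity that folds in
#'   the fast endocardial (Purkinje) conduction not modelled explicitly.
#' @slot stimulusNode index (into mesh nodes) of the pacing site(s);
#'   0 selects the default apical endocardial ring.
#' @slot TaMax peak active stress (kPa).
#' @slot riseTime,plateauTime,relaxTime twitch shape parameters (ms).
#' @slot cycleLength cardiac cycle length (ms).
#' @export
setClass("ActivationModel",
  representation(v = "numeric", stimulusNode = "integer", TaMax = "numeric",
                 riseTime = "numeric", plateauTime = "numeric",
                 relaxTime = "numeric", cycleLength = "numeric"),
  prototype(v = 1.2, stimulusNode = 0L, TaMax = 120, riseTime = 90,
            plateauTime = 320, relaxTime = 45, cycleLength = 1000))

#' Lumped-parameter systemic circulation (three-element windkessel)
#'
#' Aortic valve (resistance RAv plus characteristic impedance Zc) feeding a
#' compliance C drained by the peripheral resistance Rp; mitral valve
#' resistance RMv fed from a constant venous/preload pressure. Pressures in
#' mmHg, volumes in ml, time in ms; resistances mmHg*ms/ml, compliance
#' ml/mmHg. Both valves behave as diodes.
#'
#' @slot Zc,Rp,C windkessel constants.
#' @slot RAv,RMv valve resistances.
#' @slot pAo aortic pressure state (mmHg).
#' @slot pVen venous filling pressure (mmHg).
#' @slot edp target end-diastolic LV pressure used for the filling ramp.
#' @export
setClass("CirculationModel",
  representation(Zc = "numeric", Rp = "numeric", C = "numeric",
                 RAv = "numeric", RMv = "numeric", pAo = "numeric",
                 pVen = "numeric", edp = "numeric"),
  prototype(Zc = 50, Rp = 1100, C = 1.6, RAv = 10, RMv = 8,
            pAo = 78, pVen = 10, edp = 10),
  validity = function(object) {
    if (object@Zc <= 0 || object@Rp <= 0 || object@C <= 0 ||
        object@RAv <= 0 || object@RMv <= 0)
      "windkessel/valve constants must be positive" else TRUE
  })

#' Elliptical free-wall scar description
#'
#' Core properties blend smoothly (C1 smoothstep) into healthy tissue over
#' \code{transitionWidth}; remote tissue is exactly healthy.
#'
#' @slot centerPhi azimuth of the scar center (rad, free wall).
#' @slot centerV longitudinal position of the center (0 apex .. 1 base).
#' @slot semiCirc,semiLong elliptical semi-axes (mm).
#' @slot transitionWidth width of the core-to-remote transition (mm).
#' @slot thicknessFactor wall-thinning multiplier (< 1) at the core.
#' @slot stiffnessFactor passive-stiffness multiplier (> 1) at the core.
#' @slot taFactor active-stress multiplier (~0) at the core.
#' @slot conductionFactor conduction-velocity multiplier (< 1) at the core.
#' @export
setClass("ScarDefect",
  representation(centerPhi = "numeric", centerV = "numeric",
                 semiCirc = "numeric", semiLong = "numeric",
                 transitionWidth = "numeric", thicknessFactor = "numeric",
                 stiffnessFactor = "numeric", taFactor = "numeric",
                 conductionFactor = "numeric"),
  prototype(centerPhi = pi, centerV = 0.55, semiCirc = 25, semiLong = 25,
            transitionWidth = 8, thicknessFactor = 0.7, stiffnessFactor = 5,
            taFactor = 0.02, conductionFactor = 0.5))

#' Result of one simulated cardiac cycle
#'
#' @slot mesh the reference \linkS4class{VolumetricMesh}.
#' @slot positions N x 3 x F array of node positions per output frame (mm).
#' @slot time frame times (ms); frame 1 is end-diastole (strain reference).
#' @slot plv,pao LV and aortic pressure traces (mmHg).
#' @slot volume cavity volume trace (ml).
#' @slot qAo,qMit valve flow traces (ml/ms).
#' @slot EDV,ESV,EF,mass global indices (ml, ml, percent, g).
#' @slot Fel 9 x E x F array: element deformation gradients w.r.t. the
#'   stress-free reference, column-major 3x3 per element.
#' @slot FelED 9 x E matrix: deformation gradient at end-diastole.
#' @slot positionsED N x 3 matrix: end-diastolic node positions (the
#'   strain and displacement reference; equals frame 1).
#' @slot scarWeight per-element scar blend weight (0 remote .. 1 core).
#' @export
setClass("SimulationResult",
  representation(mesh = "VolumetricMesh", positions = "array",
                 time = "numeric", plv = "numeric", pao = "numeric",
                 volume = "numeric", qAo = "numeric", qMit = "numeric",
                 EDV = "numeric", ESV = "numeric", EF = "numeric",
                 mass = "numeric", Fel = "array", FelED = "matrix",
                 positionsED = "matrix", scarWeight = "numeric"))

#' Directional strain field over the cardiac cycle
#'
#' Engineering strains (stretch minus one) of the end-diastolic local
#' radial/circumferential/longitudinal directions, per mesh element and
#' output frame. Strains are zero at the reference (end-diastolic) frame.
#'
#' @slot er,ec,el E x F matrices of directional strains.
#' @slot region factor of length E: "scar" or "remote".
#' @slot time frame times (ms).
#' @export
setClass("StrainField",
  representation(er = "matrix", ec = "matrix", el = "matrix",
                 region = "factor", time = "numeric"))

#' Integer multi-class label volume
#'
#' @slot data integer array (nx x ny x nz), one hard label per voxel.
#' @slot spacing voxel spacing (mm) per axis.
#' @slot origin world position of voxel (1,1,1) (mm).
#' @slot classes named integer vector mapping class names to label values.
#' @slot frame cardiac frame index the volume belongs to.
#' @export
setClass("LabelVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 classes = "integer", frame = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
    if (!all(unique(as.vector(object@data)) %in% object@classes))
      msg <- c(msg, "labels present in data must appear in the class dictionary")
    if (length(msg)) msg else TRUE
  })

#' Per-voxel PD/T1/T2 tissue property maps
#' @slot PD,T1,T2 arrays co-registered with a \linkS4class{LabelVolume}
#'   (PD relative 0-1, T1/T2 in ms).
#' @slot spacing,origin grid geometry (mm).
#' @slot frame cardiac frame index.
#' @export
setClass("TissueMaps",
  representation(PD = "array", T1 = "array", T2 = "array",
                 spacing = "numeric", origin = "numeric", frame = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@PD), dim(object@T1)) ||
        !identical(dim(object@PD), dim(object@T2)))
      msg <- c(msg, "PD/T1/T2 must share dimensions")
    if (any(object@T2 > object@T1 + 1e-9))
      msg <- c(msg, "T2 must not exceed T1 anywhere")
    if (length(msg)) msg else TRUE
  })

#' Smooth per-slice 2D warp field
#' @slot dx,dy displacement components (mm) on the voxel grid
#'   (nx x ny x nz arrays; backward convention, see \code{applyWarp}).
#' @slot controls list per slice: matrices of control points
#'   (target position, displacement).
#' @slot spacing,origin grid geometry (mm).
#' @export
setClass("WarpField",
  representation(dx = "array", dy = "array", controls = "list",
                 spacing = "numeric", origin = "numeric"))

#' Procedural torso background model (anthropomorphic-phantom stand-in)
#' @slot params named list of primitive geometry (body/lung/heart ellipses,
#'   positions in mm) drawn once from \code{seed}.
#' @slot seed integer seed.
#' @export
setClass("TorsoModel", representation(params = "list", seed = "numeric"))

#' bSSFP sequence and acquisition parameters
#' @slot TR,TE repetition/echo time (ms).
#' @slot flip flip angle (deg).
#' @slot SNR target signal-to-noise ratio (Inf for noiseless).
#' @slot nCoils number of receive coils.
#' @slot matrixSize integer(2) target image matrix.
#' @slot resolution target in-plane resolution (mm).
#' @slot sliceThickness slice thickness (mm).
#' @slot nFrames number of cine frames.
#' @slot seed noise seed.
#' @export
setClass("SequenceParams",
  representation(TR = "numeric", TE = "numeric", flip = "numeric",
                 SNR = "numeric", nCoils = "integer", matrixSize = "integer",
                 resolution = "numeric", sliceThickness = "numeric",
                 nFrames = "integer", seed = "numeric"),
  prototype(TR = 3.0, TE = 1.5, flip = 60, SNR = 30, nCoils = 8L,
            matrixSize = c(128L, 128L), resolution = 2.0, sliceThickness = 8,
            nFrames = 25L, seed = 1),
  validity = function(object) {
    msg <- character()
    if (object@TE > object@TR) msg <- c(msg, "TE must not exceed TR")
    if (object@flip <= 0 || object@flip >= 180)
      msg <- c(msg, "flip angle must lie in (0, 180) deg")
    if (object@SNR <= 0) msg <- c(msg, "SNR must be positive (Inf allowed)")
    if (length(msg)) msg else TRUE
  })

#' Set of complex receive-coil sensitivity maps
#' @slot maps list of complex matrices (one per coil) on the image grid.
#' @slot centers nCoils x 2 coil center positions (mm).
#' @slot sigma Gaussian falloff width (mm).
#' @slot phaseCoef tangential phase-ramp coefficient (rad/mm).
#' @slot grid list with x and y world coordinate vectors (mm).
#' @export
setClass("CoilSet",
  representation(maps = "list", centers = "matrix", sigma = "numeric",
                 phaseCoef = "numeric", grid = "list"))

#' Cartesian k-space data for one slice-frame
#' @slot data complex array nx x ny x nCoils on the target matrix.
#' @slot mask sampling mask (full Cartesian by default).
#' @export
setClass("KSpaceData", representation(data = "array", mask = "matrix"))

#' Reconstructed cine magnitude image stack
#' @slot frames nx x ny x nFrames magnitude array.
#' @slot reference noiseless counterpart of \code{frames}.
#' @slot spacing,origin grid geometry (mm).
#' @slot meta acquisition metadata list.
#' @export
setClass("CineImage",
  representation(frames = "array", reference = "array", spacing = "numeric",
                 origin = "numeric", meta = "list"),
  validity = function(object) {
    if (any(object@frames < 0)) "magnitude frames must be nonnegative"
    else TRUE
  })

#' Ground-truth bundle paired with a synthetic cine acquisition
#' @slot masks list per frame of \linkS4class{LabelVolume} LV masks on the
#'   image grid (myocardium + blood pool).
#' @slot displacement list per frame of nx x ny x nz x 3 arrays (mm),
#'   displacement from the end-diastolic reference; zero at the reference.
#' @slot strain \linkS4class{StrainField}.
#' @slot strainSummary data.frame of region strain curves.
#' @slot EDV,ESV,EF,mass global indices.
#' @slot scarMasks list per frame of scar-region masks (NULL if no scar).
#' @export
setClass("GroundTruthBundle",
  representation(masks = "list", displacement = "list",
                 strain = "StrainField", strainSummary = "data.frame",
                 EDV = "numeric", ESV = "numeric", EF = "numeric",
                 mass = "numeric", scarMasks = "list"))

#' Full preset configuration of the simulator
#' @slot name NOR, DCM, HCM or INFARCT.
#' @slot anatomy \linkS4class{AnatomyParams}.
#' @slot material \linkS4class{MaterialParams}.
#' @slot activation \linkS4class{ActivationModel}.
#' @slot circulation \linkS4class{CirculationModel}.
#' @slot scar \linkS4class{ScarDefect} or NULL (list wrapper).
#' @slot sequence \linkS4class{SequenceParams}.
#' @slot seeds named list of seeds (shape, texture, noise).
#' @slot solver named list of solver controls (mesh resolution, dt, frames).
#' @export
setClass("PresetConfig",
  representation(name = "character", anatomy = "AnatomyParams",
                 material = "MaterialParams", activation = "ActivationModel",
                 circulation = "CirculationModel", scar = "list",
                 sequence = "SequenceParams", seeds = "list",
                 solver = "list"))
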