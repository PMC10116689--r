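#' Enclosed cavity volume (ml)
#'
#' Divergence-theorem volume of the closed endocardial surface (apex cap and
#' base cap included). Methods exist for \linkS4class{LVSurfaceGrid},
#' \linkS4class{VolumetricMesh} and deformed mesh states.
#'
#' @param x object with an endocardial surface.
#' @param ... passed to methods.
#' @return volume in ml.
#' @export
setGeneric("cavityVolume", function(x, ...) standardGeneric("cavityVolume"))

#' Wall (myocardial) volume in ml
#' @param x mesh-like object.
#' @param ... passed to methods.
#' @export
setGeneric("wallVolume", function(x, ...) standardGeneric("wallVolume"))

#' Left-ventricular mass (g)
#'
#' Wall volume times tissue density.
#' @param x mesh-like object.
#' @param rho tissue density in g/ml (default 1.05).
#' @param ... passed to methods.
#' @export
setGeneric("lvMass", function(x, rho = 1.05, ...) standardGeneric("lvMass"))

#' @rdname LVSurfaceGrid-class
#' @param object an object.
#' @export
setGeneric("gridDim", function(object) standardGeneric("gridDim"))

#' Ejection fraction accessor (percent)
#' @param object simulation result or ground-truth bundle.
#' @export
setGeneric("ejectionFraction",
           function(object) standardGeneric("ejectionFraction"))
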