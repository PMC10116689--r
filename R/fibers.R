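#' Assign a transmurally rotating myofiber field
#'
#' Linear transmural helix-angle law: the fiber lies in the plane spanned
#' by the circumferential and longitudinal frame vectors, rotated by the
#' helix angle which varies linearly in the transmural coordinate from
#' \code{endoDeg} at the endocardium to \code{epiDeg} at the epicardium.
#' The sheet direction is the (radial) frame vector, orthogonal to the
#' fiber by construction.
#'
#' @param mesh a \linkS4class{VolumetricMesh} with local frames.
#' @param endoDeg,epiDeg helix angles (deg), defaults +60/-60.
#' @return a \linkS4class{FiberField}.
#' @export
assignFibers <- function(mesh, endoDeg = 60, epiDeg = -60) {
  alpha <- deg2rad(endoDeg + (epiDeg - endoDeg) * mesh@nodeT)
  fibers <- cos(alpha) * mesh@frameC + sin(alpha) * mesh@frameL
  new("FiberField", fibers = fibers, sheets = mesh@frameR,
      helixEndo = endoDeg, helixEpi = epiDeg)
}

#' Helix angle of a fiber field at transmural depth t
#' @param field a \linkS4class{FiberField}.
#' @param t transmural coordinate(s) in [0, 1].
#' @return helix angle(s) in degrees.
#' @export
helixAngle <- function(field, t) {
  field@helixEndo + (field@helixEpi - field@helixEndo) * t
}
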