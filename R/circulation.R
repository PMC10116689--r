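#' Construct a lumped-parameter circulation model
#'
#' Three-element windkessel afterload (characteristic impedance, peripheral
#' resistance, compliance) behind a diode aortic valve, plus a diode mitral
#' valve fed from a constant venous pressure. Units: mmHg, ml, ms.
#'
#' @param Zc characteristic impedance (mmHg ms/ml).
#' @param Rp peripheral resistance (mmHg ms/ml).
#' @param C arterial compliance (ml/mmHg).
#' @param RAv,RMv aortic/mitral valve resistances (mmHg ms/ml).
#' @param pAo initial aortic pressure (mmHg).
#' @param pVen venous filling pressure (mmHg).
#' @param edp end-diastolic LV pressure targeted by the filling ramp.
#' @return a \linkS4class{CirculationModel}.
#' @export
circulationModel <- function(Zc = 50, Rp = 1100, C = 1.6, RAv = 10,
                             RMv = 8, pAo = 78, pVen = 10, edp = 10) {
  obj <- new("CirculationModel", Zc = Zc, Rp = Rp, RAv = RAv, RMv = RMv,
             pAo = pAo, pVen = pVen, edp = edp)
  obj@C <- C        # assigned after new(): "C" partially matches new()'s
  validObject(obj)  # Class argument and cannot be passed by name
  obj
}

# Smooth (C1) diode ramp: exactly zero for non-positive pressure
# differences (no leak, no regurgitation), quadratic blend of width eps,
# linear with a small eps/2 opening offset beyond.
smoothPos <- function(x, eps = 0.25) {
  out <- x - eps / 2
  mid <- x > 0 & x < eps
  out[mid] <- x[mid]^2 / (2 * eps)
  out[x <= 0] <- 0
  out
}

# Valve flows (ml/ms) at LV pressure pLv given the current aortic state.
valveFlows <- function(circ, pLv, eps = 0.25) {
  list(qAo = smoothPos(pLv - circ@pAo, eps) / (circ@RAv + circ@Zc),
       qMit = smoothPos(circ@pVen - pLv, eps) / circ@RMv)
}

#' Advance the windkessel circulation by one time step
#'
#' Valve flows behave as diodes (aortic flow only when LV pressure exceeds
#' aortic pressure, mitral flow only when venous pressure exceeds LV
#' pressure, up to a small smoothing width). The compliance update is
#' semi-implicit and unconditionally stable; with both valves closed the
#' aortic pressure decays exponentially with time constant Rp * C.
#'
#' @param circ a \linkS4class{CirculationModel}.
#' @param pLv LV cavity pressure (mmHg).
#' @param dt time step (ms), at most 1 ms advised for accuracy.
#' @param eps valve smoothing half-width (mmHg); 0 gives hard diodes.
#' @return list with the updated model (\code{circ}) and the flows
#'   \code{qAo}, \code{qMit} (ml/ms) used for the update.
#' @export
circulationStep <- function(circ, pLv, dt, eps = 0.25) {
  stopifnot(dt > 0)
  validObject(circ)
  fl <- if (eps > 0) valveFlows(circ, pLv, eps) else
    list(qAo = max(pLv - circ@pAo, 0) / (circ@RAv + circ@Zc),
         qMit = max(circ@pVen - pLv, 0) / circ@RMv)
  pAoNew <- (circ@pAo + dt * fl$qAo / circ@C) / (1 + dt / (circ@Rp * circ@C))
  circ@pAo <- pAoNew
  list(circ = circ, qAo = fl$qAo, qMit = fl$qMit)
}
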