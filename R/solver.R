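# Reduced-order Galerkin mechanics of one cardiac cycle.
#
# Displacements are restricted to a small library of smooth deformation
# modes (endocardial squeeze and thickening profiles, longitudinal
# shortening, torsion, transmural shears, low-order circumferential
# harmonics, plus scar-localized modes). Energies and virtual work are
# integrated over the hexahedral mesh by one-point quadrature. At fixed
# cavity pressure the equilibrium is the minimum of a potential, found by
# damped Newton with an energy line search; the LV pressure itself is the
# root of the monotone volume-flow constraint (cavity volume change equals
# net valve flow), solved per time step with the windkessel sub-stepped at
# fine resolution.

# Build the analytic mode library as nodal displacement fields.
buildReducedBasis <- function(mesh, basisSize = 12L, scar = NULL) {
  t <- mesh@nodeT; zeta <- mesh@nodeV; phi <- mesh@nodePhi
  rr <- mesh@frameR; cc <- mesh@frameC
  zhat <- matrix(rep(c(0, 0, 1), each = nrow(mesh@nodes)), ncol = 3)
  R <- sqrt(mesh@nodes[, 1]^2 + mesh@nodes[, 2]^2)
  w <- sqrt(zeta)
  sq <- -(1 - t) * w
  # inverse-radius radial profile: the (near) volume-preserving radial
  # field u_r ~ 1/R, steep at the endocardium as in incompressible
  # thick-wall contraction (capped near the apex pole)
  Rref <- mean(R)
  inv <- Rref / pmax(R, 0.35 * Rref)
  # axisymmetric core library; circumferential harmonics are only added
  # together with a scar: under symmetric activation they form symmetric
  # double wells (elliptical buckling) with no physical preference, while
  # a scar fixes both their need and their orientation
  modes <- list(
    endoSqueeze = sq * rr,
    invSqueeze  = -w * inv * rr,
    invSqueeze2 = -w * inv^2 * rr,
    uniSqueeze  = -w * rr,
    longShort   = -zeta * zhat,
    torsion     = (R / Rref) * (zeta - 0.5) * cc,
    shearC      = (t - 0.5) * w * cc,
    shearL      = (t - 0.5) * w * zhat,
    thickGrad   = -(1 - t)^2 * w * rr,
    longShortEn = -(1 - t) * zeta * zhat)
  modes <- modes[seq_len(min(basisSize, length(modes)))]
  if (!is.null(scar)) {
    b <- scarBlend(mesh, scar, "node")
    modes$endoSqCos <- sq * cos(phi) * rr
    modes$endoSqSin <- sq * sin(phi) * rr
    modes$endoSqCos2 <- sq * cos(2 * phi) * rr
    modes$endoSqSin2 <- sq * sin(2 * phi) * rr
    modes$scarSqueeze <- -(1 - t) * b * rr
    modes$scarBulge <- b * rr
    modes$scarShear <- (t - 0.5) * b * cc
  }
  modes
}

# Assemble precomputed operators for the reduced model.
assembleReduced <- function(mesh, fibers, modes) {
  E <- nrow(mesh@elems); nm <- length(modes)
  elemAvg <- function(nodal) {
    out <- matrix(0, E, ncol(nodal))
    for (a in 1:8) out <- out + nodal[mesh@elems[, a], , drop = FALSE]
    out / 8
  }
  fib <- normalizeRows(elemAvg(fibers@fibers))
  sht <- normalizeRows(elemAvg(fibers@sheets))

  # Garr[i, (col-1)*E + e] with col = (k-1)*3 + d: mode gradient tensors
  Garr <- matrix(0, nm, 9L * E)
  for (i in seq_len(nm)) {
    phiI <- modes[[i]]
    for (k in 1:3) for (d in 1:3) {
      col <- (k - 1L) * 3L + d
      acc <- numeric(E)
      for (a in 1:8)
        acc <- acc + phiI[mesh@elems[, a], d] * mesh@gradN[, a, k]
      Garr[i, (col - 1L) * E + seq_len(E)] <- acc
    }
  }
  PhiMat <- do.call(cbind, lapply(modes, as.vector))  # (3N) x nm

  # endo surface triangulation (with apex/base cap centroids) for cavity
  # volume and its modal gradient
  idx <- layerIndex(mesh, "endo")
  nCirc <- nrow(idx); nLongP <- ncol(idx)
  nEn <- length(idx)
  apexId <- nEn + 1L; baseId <- nEn + 2L
  lid <- matrix(seq_len(nEn), nCirc, nLongP)
  tri <- NULL
  for (j in seq_len(nLongP - 1L)) {
    i1 <- seq_len(nCirc); i2 <- i1 %% nCirc + 1L
    tri <- rbind(tri,
      cbind(lid[i1, j], lid[i2, j], lid[i2, j + 1L]),
      cbind(lid[i1, j], lid[i2, j + 1L], lid[i1, j + 1L]))
  }
  i1 <- seq_len(nCirc); i2 <- i1 %% nCirc + 1L
  tri <- rbind(tri, cbind(apexId, lid[i2, 1], lid[i1, 1]),
                    cbind(baseId, lid[i1, nLongP], lid[i2, nLongP]))

  endoNodes <- as.vector(idx)
  augment <- function(P) {
    rbind(P, colMeans(P[lid[, 1], , drop = FALSE]),
          colMeans(P[lid[, nLongP], , drop = FALSE]))
  }
  nT <- nrow(tri)
  # Mtri[i, ]: mode displacements at triangle slots a,b,c (each 3 comps)
  Mtri <- matrix(0, length(modes), 9L * nT)
  for (i in seq_along(modes)) {
    am <- augment(modes[[i]][endoNodes, , drop = FALSE])
    Mtri[i, ] <- c(am[tri[, 1], ], am[tri[, 2], ], am[tri[, 3], ])
  }

  signedVol <- function(positions) {
    P <- augment(positions[endoNodes, , drop = FALSE])
    triVolume(P[tri[, 1], , drop = FALSE], P[tri[, 2], , drop = FALSE],
              P[tri[, 3], , drop = FALSE])
  }
  orient <- sign(signedVol(mesh@nodes))

  volume <- function(positions) orient * signedVol(positions)
  volGrad <- function(positions) {
    P <- augment(positions[endoNodes, , drop = FALSE])
    a <- P[tri[, 1], , drop = FALSE]; b <- P[tri[, 2], , drop = FALSE]
    cc <- P[tri[, 3], , drop = FALSE]
    cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                               u[, 3] * v[, 1] - u[, 1] * v[, 3],
                               u[, 1] * v[, 2] - u[, 2] * v[, 1])
    Cvec <- c(cr(b, cc), cr(cc, a), cr(a, b))
    orient * as.vector(Mtri %*% Cvec) / 6
  }

  # epicardial radial-displacement penalty operator
  epiIdx <- as.vector(layerIndex(mesh, "epi"))
  Bperi <- vapply(modes, function(phiI)
    rowSums(phiI[epiIdx, , drop = FALSE] * mesh@frameR[epiIdx, , drop = FALSE]),
    numeric(length(epiIdx)))

  list(E = E, nm = nm, fib = fib, sht = sht, Garr = Garr, PhiMat = PhiMat,
       wRep = rep(mesh@elemVol, 9L), w = mesh@elemVol,
       volume = volume, volGrad = volGrad, Bperi = Bperi,
       N = nrow(mesh@nodes))
}

# Deformation gradients (E x 9) at modal amplitudes q.
reducedF <- function(asm, q) {
  Fv <- matrix(as.vector(q %*% asm$Garr), asm$E, 9)
  Fv[, 1] <- Fv[, 1] + 1; Fv[, 5] <- Fv[, 5] + 1; Fv[, 9] <- Fv[, 9] + 1
  Fv
}

reducedPositions <- function(mesh, asm, q) {
  mesh@nodes + matrix(asm$PhiMat %*% q, asm$N, 3)
}

MMHG2KPA <- 0.1333224

# Gradient of the total potential w.r.t. q (kPa mm^3 per unit amplitude)
# and the potential itself. Ta: per-element active stress (kPa).
reducedResidual <- function(asm, mesh, mp, q, Ta, stiffScale, pKpa,
                            kPeri = 0, periAnchor = NULL, qVisc = NULL,
                            eta = 0, vTarget = NULL, mu = 0.1) {
  Fv <- reducedF(asm, q)
  ho <- hoStressBatch(Fv, asm$fib, asm$sht, mp, scale = stiffScale)
  P <- ho$P
  lam <- sqrt(ho$I4f)
  if (any(Ta != 0)) {
    cA <- Ta / lam
    for (d in 1:3) for (k in 1:3)
      P[, (k - 1L) * 3L + d] <- P[, (k - 1L) * 3L + d] +
        cA * ho$Ff[, d] * asm$fib[, k]
  }
  grad <- as.vector(asm$Garr %*% (as.vector(P) * asm$wRep))
  energy <- sum(asm$w * (ho$W + Ta * (lam - 1)))
  pos <- reducedPositions(mesh, asm, q)
  V <- asm$volume(pos)
  dV <- asm$volGrad(pos)
  pEff <- pKpa
  if (is.null(vTarget)) {
    grad <- grad - pKpa * dV
    energy <- energy - pKpa * V
  } else {
    # volume control: stiff penalty toward the target cavity volume;
    # the conjugate pressure is recovered as mu * (vTarget - V)
    grad <- grad + mu * (V - vTarget) * dV
    energy <- energy + 0.5 * mu * (V - vTarget)^2
    pEff <- mu * (vTarget - V)
  }
  if (kPeri > 0) {
    dPeri <- as.vector(asm$Bperi %*% q) - periAnchor
    grad <- grad + kPeri * as.vector(crossprod(asm$Bperi, dPeri))
    energy <- energy + 0.5 * kPeri * sum(dPeri^2)
  }
  if (eta > 0 && !is.null(qVisc)) {
    # step-wise viscous regularization: smooths quasi-static snap-through
    grad <- grad + eta * (q - qVisc)
    energy <- energy + 0.5 * eta * sum((q - qVisc)^2)
  }
  list(grad = grad, energy = energy, V = V, dV = dV, Fv = Fv, pEff = pEff)
}

# Damped Newton minimization of the potential at fixed pressure and
# activation. hEnv caches the modal Hessian across calls (quasi-static
# warm starts make it an excellent preconditioner).
solveEquilibrium <- function(asm, mesh, mp, q0, Ta, stiffScale, pKpa,
                             kPeri = 0, periAnchor = NULL, tol = 0.5,
                             maxIter = 60, hEnv = NULL, qVisc = NULL,
                             eta = 0, vTarget = NULL, mu = 0.1) {
  q <- q0
  res <- reducedResidual(asm, mesh, mp, q, Ta, stiffScale, pKpa, kPeri,
                         periAnchor, qVisc, eta, vTarget, mu)
  h <- 1e-5
  refresh <- function(qAt, resAt) {
    H <- matrix(0, asm$nm, asm$nm)
    for (i in seq_len(asm$nm)) {
      qp <- qAt; qp[i] <- qp[i] + h
      rp <- reducedResidual(asm, mesh, mp, qp, Ta, stiffScale, pKpa,
                            kPeri, periAnchor, qVisc, eta, vTarget, mu)
      H[, i] <- (rp$grad - resAt$grad) / h
    }
    (H + t(H)) / 2
  }
  H <- if (!is.null(hEnv) && !is.null(hEnv$H)) hEnv$H else NULL
  sinceRefresh <- 100L
  lam <- 1e-6
  for (iter in seq_len(maxIter)) {
    if (max(abs(res$grad)) < tol) {
      if (!is.null(hEnv)) hEnv$H <- H
      return(list(q = q, res = res, iter = iter, converged = TRUE))
    }
    if (is.null(H)) { H <- refresh(q, res); sinceRefresh <- 0L }
    dScale <- max(abs(diag(H)), 1)
    improved <- FALSE
    for (trial in 1:20) {
      dq <- tryCatch(-solve(H + diag(lam * dScale, asm$nm), res$grad),
                     error = function(e) NULL)
      if (!is.null(dq)) {
        if (sum(dq * res$grad) > 0) dq <- -dq   # enforce descent direction
        rn <- tryCatch(reducedResidual(asm, mesh, mp, q + dq, Ta,
                                       stiffScale, pKpa, kPeri, periAnchor,
                                       qVisc, eta, vTarget, mu),
                       error = function(e) NULL)
        if (!is.null(rn) && is.finite(rn$energy) &&
            all(is.finite(rn$grad)) &&
            (rn$energy < res$energy + 1e-10 * abs(res$energy) ||
             max(abs(rn$grad)) < 0.5 * max(abs(res$grad)))) {
          q <- q + dq; res <- rn; improved <- TRUE
          lam <- max(lam / 4, 1e-8)
          break
        }
      }
      lam <- lam * 8
      if (lam > 1e6 && sinceRefresh > 0L) {
        H <- refresh(q, res); sinceRefresh <- 0L; lam <- 1e-3
      }
    }
    if (!improved) break
    if (sinceRefresh > 8L) { H <- refresh(q, res); sinceRefresh <- 0L }
    else sinceRefresh <- sinceRefresh + 1L
  }
  if (!is.null(hEnv)) hEnv$H <- H
  if (max(abs(res$grad)) < 20 * tol)
    return(list(q = q, res = res, iter = maxIter, converged = TRUE))
  stop(sprintf(
    "Newton iteration did not converge (residual %.3g, tol %.3g)",
    max(abs(res$grad)), tol))
}

#' Simulate one cardiac cycle of LV contraction
#'
#' Reduced-order quasi-static mechanics: passive Holzapfel-Ogden stress,
#' active fiber stress following the local activation time, a pericardial
#' penalty on epicardial radial displacement (anchored at the end-diastolic
#' configuration; longitudinal and circumferential motion free), and
#' endocardial pressure coupled to a windkessel circulation with diode
#' valves. Diastolic filling is simulated first by ramping the preload
#' pressure to the end-diastolic pressure; the resulting end-diastolic
#' state defines the strain reference and EDV. During the cycle the LV
#' pressure is solved at every mechanics step so that the cavity volume
#' change matches the net valve flow (monotone scalar root), with the
#' windkessel integrated at \code{dtCirc} resolution underneath.
#'
#' @param mesh a \linkS4class{VolumetricMesh} (reference, stress-free).
#' @param fibers a \linkS4class{FiberField} on the mesh.
#' @param material a \linkS4class{MaterialParams}.
#' @param activation an \linkS4class{ActivationModel}.
#' @param circ a \linkS4class{CirculationModel}.
#' @param scar optional \linkS4class{ScarDefect}.
#' @param basisSize number of standard deformation modes (default 12;
#'   scar-localized modes are appended automatically).
#' @param nFrames output frames over one cycle (default 50).
#' @param dt mechanics time step (ms, default 5).
#' @param dtCirc circulation sub-step (ms, default 1).
#' @param kPeri pericardial penalty stiffness (kPa/mm per epicardial node).
#' @param tol Newton tolerance on the modal virtual-work residual
#'   (kPa mm^3).
#' @param fillSteps pressure increments of the passive filling ramp.
#' @return a \linkS4class{SimulationResult}.
#' @export
solveCycle <- function(mesh, fibers, material, activation, circ,
                       scar = NULL, basisSize = 10L, nFrames = 50L,
                       dt = 5, dtCirc = 1, kPeri = 400, tol = 0.5,
                       fillSteps = 12L, eta = 30) {
  modes <- buildReducedBasis(mesh, basisSize, scar)
  asm <- assembleReduced(mesh, fibers, modes)
  nm <- asm$nm

  stiffScale <- rep(1, asm$E)
  taScale <- rep(1, asm$E)
  scarW <- rep(0, asm$E)
  if (!is.null(scar)) {
    scarW <- scarBlend(mesh, scar, "elem")
    stiffScale <- 1 + (scar@stiffnessFactor - 1) * scarW
    taScale <- 1 - (1 - scar@taFactor) * scarW
  }
  tAct <- computeActivationMap(mesh, activation@v, activation@stimulusNode,
                               scar)
  tActE <- rowMeans(matrix(tAct[mesh@elems], asm$E))
  peak <- twitchPeak(activation)

  # --- passive filling ramp (no pericardium, no active stress) ---
  q <- numeric(nm)
  zerosTa <- numeric(asm$E)
  hEnv <- new.env()
  sol <- NULL
  for (pr in seq_len(fillSteps) / fillSteps * circ@edp) {
    sol <- solveEquilibrium(asm, mesh, material, q, zerosTa, stiffScale,
                            pr * MMHG2KPA, tol = tol, hEnv = hEnv)
    q <- sol$q
  }
  qED <- q
  resED <- sol$res
  EDV <- resED$V / 1000
  FelED <- t(resED$Fv)
  periAnchor <- as.vector(asm$Bperi %*% qED)

  # --- cycle with valve/windkessel coupling ---
  nSteps <- round(activation@cycleLength / dt)
  frameEvery <- nSteps / nFrames
  if (frameEvery != round(frameEvery))
    stop("cycleLength/dt must be a multiple of nFrames")
  nSub <- round(dt / dtCirc)
  times <- numeric(nFrames); vols <- numeric(nFrames)
  plv <- numeric(nFrames); pao <- numeric(nFrames)
  qAoTr <- numeric(nSteps * nSub); qMitTr <- numeric(nSteps * nSub)
  volTr <- numeric(nSteps)
  positions <- array(0, c(asm$N, 3, nFrames))
  Fel <- array(0, c(9, asm$E, nFrames))
  hEnv$H <- NULL

  pCur <- circ@edp
  Vprev <- resED$V
  # frame 1 is the end-diastolic reference state
  posED <- reducedPositions(mesh, asm, qED)
  times[1] <- 0; vols[1] <- EDV; plv[1] <- circ@edp; pao[1] <- circ@pAo
  positions[, , 1] <- posED
  Fel[, , 1] <- FelED
  frame <- 1L

  # last successfully solved state, for adaptive continuation in the
  # volume-control solve (target volume is the continuation parameter)
  qStep <- q
  last <- list(q = q, Ta = zerosTa, V = resED$V)
  verbose <- isTRUE(getOption("CardioPhantom.verbose"))
  nEq <- 0L
  mu <- 0.25
  solveAt <- function(Ta1, Vt, depth = 0, etaLoc = eta) {
    nEq <<- nEq + 1L
    sol <- tryCatch(
      solveEquilibrium(asm, mesh, material, last$q, Ta1, stiffScale, 0,
                       kPeri, periAnchor, tol = tol, hEnv = hEnv,
                       qVisc = qStep, eta = etaLoc, vTarget = Vt, mu = mu),
      error = function(e) NULL)
    if (is.null(sol)) {
      if (depth >= 8) {
        # last resort: restart from the committed state with much
        # stronger step-wise damping
        if (etaLoc < 100 * eta) {
          last$q <<- qStep
          return(solveAt(Ta1, Vt, 0, etaLoc * 25))
        }
        stop("equilibrium continuation failed: non-convergent Newton ",
             "iteration despite path subdivision")
      }
      TaM <- (last$Ta + Ta1) / 2; VM <- (last$V + Vt) / 2
      solveAt(TaM, VM, depth + 1, etaLoc)
      return(solveAt(Ta1, Vt, depth + 1, etaLoc))
    }
    last <<- list(q = sol$q, Ta = Ta1, V = Vt)
    sol
  }

  for (s in seq_len(nSteps)) {
    tNow <- s * dt
    TaE <- activation@TaMax * taScale *
      twitchShape(tNow - tActE, activation) / peak

    # self-consistency between flows and mechanics: windkessel flows at
    # trial pressure p set the volume target, the volume-control solve
    # returns the conjugate pressure pNew(p); solve h(p) = pNew - p = 0
    # by safeguarded secant/bisection (h is decreasing in p)
    # solve with target correction: the stiff-penalty bias p/mu would
    # otherwise leak volume systematically, so the target is adjusted
    # until the achieved cavity volume matches the flow target
    solveTarget <- function(TaE, Vt) {
      adj <- 0
      sol <- solveAt(TaE, Vt)
      for (cc in 1:4) {
        err <- Vt - sol$res$V
        if (abs(err) < 1) break          # mm^3
        adj <- adj + err
        sol <- solveAt(TaE, Vt + adj)
      }
      sol
    }
    evalH <- function(p) {
      circT <- circ
      qa <- numeric(nSub); qm <- numeric(nSub)
      for (k in seq_len(nSub)) {
        st <- circulationStep(circT, p, dtCirc)
        circT <- st$circ; qa[k] <- st$qAo; qm[k] <- st$qMit
      }
      Vt <- Vprev + dt * (mean(qm) - mean(qa)) * 1000
      solT <- solveTarget(TaE, Vt)
      pNew <- solT$res$pEff / MMHG2KPA
      list(h = pNew - p, sol = solT, circ = circT, qa = qa, qm = qm,
           p = pNew)
    }
    lo <- pCur - 8; hi <- pCur + 8
    ehi <- evalH(hi); em <- ehi
    if (abs(ehi$h) > 0.005) {
      elo <- evalH(lo); em <- elo
      it <- 0
      while (elo$h < 0 && it < 40) { lo <- lo - 15; elo <- evalH(lo); it <- it + 1 }
      while (ehi$h > 0 && it < 80) { hi <- hi + 15; ehi <- evalH(hi); it <- it + 1 }
      if (elo$h < 0 || ehi$h > 0)
        stop(sprintf("could not bracket LV pressure at t = %g ms", tNow))
      for (it in 1:60) {
        pMid <- if (abs(elo$h - ehi$h) > 1e-12)
          lo + elo$h * (hi - lo) / (elo$h - ehi$h) else (lo + hi) / 2
        if (pMid <= lo || pMid >= hi) pMid <- (lo + hi) / 2
        em <- evalH(pMid)
        if (abs(em$h) < 0.005 || (hi - lo) < 0.002) break
        if (em$h > 0) { lo <- pMid; elo <- em } else { hi <- pMid; ehi <- em }
      }
    }
    pCur <- em$p
    q <- em$sol$q
    qStep <- q
    circ <- em$circ
    Vprev <- em$sol$res$V
    ix <- (s - 1L) * nSub + seq_len(nSub)
    qAoTr[ix] <- em$qa; qMitTr[ix] <- em$qm
    volTr[s] <- Vprev / 1000
    if (verbose && s %% 10 == 0)
      message(sprintf("  t=%4.0f ms p=%6.1f V=%6.1f nEq=%d", tNow, pCur,
                      Vprev / 1000, nEq))
    if (s %% frameEvery == 0 && frame < nFrames) {
      frame <- frame + 1L
      times[frame] <- tNow
      vols[frame] <- Vprev / 1000
      plv[frame] <- pCur
      pao[frame] <- circ@pAo
      positions[, , frame] <- reducedPositions(mesh, asm, q)
      Fel[, , frame] <- t(em$sol$res$Fv)
    }
  }

  ESV <- min(c(EDV, volTr))
  EF <- 100 * (EDV - ESV) / EDV
  out <- new("SimulationResult", mesh = mesh, positions = positions,
             time = times, plv = plv, pao = pao, volume = vols,
             qAo = qAoTr[seq(nSub * frameEvery, length(qAoTr),
                             by = nSub * frameEvery)],
             qMit = qMitTr[seq(nSub * frameEvery, length(qMitTr),
                               by = nSub * frameEvery)],
             EDV = EDV, ESV = ESV, EF = EF,
             mass = lvMass(mesh, material@rho), Fel = Fel, FelED = FelED,
             positionsED = posED, scarWeight = scarW)
  attr(out, "trace") <- list(qAo = qAoTr, qMit = qMitTr, vol = volTr,
                             dt = dt, dtCirc = dtCirc)
  attr(out, "qED") <- qED
  out
}

#' @describeIn ejectionFraction EF of a simulated cycle.
#' @export
setMethod("ejectionFraction", "SimulationResult", function(object) object@EF)

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf(
    "SimulationResult: %d frames, EDV %.1f ml, ESV %.1f ml, EF %.1f%%, mass %.1f g\n",
    length(object@time), object@EDV, object@ESV, object@EF, object@mass))
})
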