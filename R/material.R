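# Holzapfel-Ogden passive law and active-stress transient.

#' Construct material parameters
#'
#' Holzapfel-Ogden coefficients with the published shear-data fit as the
#' healthy baseline, a volumetric penalty enforcing near-incompressibility,
#' and a pathology multiplier applied to the stress-like a* coefficients.
#'
#' @param a,b,af,bf,as,bs,afs,bfs HO coefficients (a* in kPa).
#' @param kappa volumetric penalty (kPa).
#' @param pathologyScale multiplier on the a* coefficients in [1, 10].
#' @param rho tissue density (g/ml).
#' @return a \linkS4class{MaterialParams}.
#' @export
materialParams <- function(a = 0.496, b = 7.209, af = 15.193, bf = 20.417,
                           as = 3.283, bs = 11.176, afs = 0.662,
                           bfs = 9.466, kappa = 2000, pathologyScale = 1,
                           rho = 1.05) {
  new("MaterialParams", a = a, b = b, af = af, bf = bf, as = as, bs = bs,
      afs = afs, bfs = bfs, kappa = kappa, pathologyScale = pathologyScale,
      rho = rho)
}

# Batch evaluation of the HO energy and first Piola-Kirchhoff stress.
# Fv: E x 9 deformation gradients (column-major 3x3 per row); fib/sht:
# E x 3 unit fiber/sheet vectors; scale: per-element stiffness multiplier
# on the a* coefficients (pathologyScale folded in by the caller).
# Returns list(W = energy density kPa, P = E x 9 stress).
hoStressBatch <- function(Fv, fib, sht, mp, scale = 1) {
  E <- nrow(Fv)
  Fc <- function(d, k) Fv[, (k - 1L) * 3L + d]
  J <- Fc(1,1) * (Fc(2,2) * Fc(3,3) - Fc(2,3) * Fc(3,2)) -
       Fc(1,2) * (Fc(2,1) * Fc(3,3) - Fc(2,3) * Fc(3,1)) +
       Fc(1,3) * (Fc(2,1) * Fc(3,2) - Fc(2,2) * Fc(3,1))
  if (any(J <= 0)) stop("element inversion: det F <= 0")
  I1 <- rowSums(Fv^2)
  Ff <- sapply(1:3, function(d)
    Fc(d,1) * fib[, 1] + Fc(d,2) * fib[, 2] + Fc(d,3) * fib[, 3])
  Fs <- sapply(1:3, function(d)
    Fc(d,1) * sht[, 1] + Fc(d,2) * sht[, 2] + Fc(d,3) * sht[, 3])
  if (E == 1L) { Ff <- matrix(Ff, 1); Fs <- matrix(Fs, 1) }
  I4f <- rowSums(Ff^2); I4s <- rowSums(Fs^2); I8 <- rowSums(Ff * Fs)

  aS <- mp@a * mp@pathologyScale * scale
  afS <- mp@af * mp@pathologyScale * scale
  asS <- mp@as * mp@pathologyScale * scale
  afsS <- mp@afs * mp@pathologyScale * scale

  e1 <- exp(mp@b * (I1 - 3))
  q4f <- pmax(I4f - 1, 0); e4f <- exp(mp@bf * q4f^2)
  q4s <- pmax(I4s - 1, 0); e4s <- exp(mp@bs * q4s^2)
  e8 <- exp(mp@bfs * I8^2)

  # the -a log(J) term cancels the hydrostatic stress of the I1 term at
  # the identity (standard in nearly-incompressible formulations), so the
  # reference configuration is exactly stress free
  W <- aS / (2 * mp@b) * (e1 - 1) - aS * log(J) +
       afS / (2 * mp@bf) * (e4f - 1) +
       asS / (2 * mp@bs) * (e4s - 1) +
       afsS / (2 * mp@bfs) * (e8 - 1) +
       mp@kappa / 2 * (J - 1)^2

  # inverse transpose of F (adjugate / J), stored column-major
  FinvT <- matrix(0, E, 9)
  FinvT[, 1] <- (Fc(2,2) * Fc(3,3) - Fc(2,3) * Fc(3,2)) / J
  FinvT[, 2] <- (Fc(1,3) * Fc(3,2) - Fc(1,2) * Fc(3,3)) / J
  FinvT[, 3] <- (Fc(1,2) * Fc(2,3) - Fc(1,3) * Fc(2,2)) / J
  FinvT[, 4] <- (Fc(2,3) * Fc(3,1) - Fc(2,1) * Fc(3,3)) / J
  FinvT[, 5] <- (Fc(1,1) * Fc(3,3) - Fc(1,3) * Fc(3,1)) / J
  FinvT[, 6] <- (Fc(1,3) * Fc(2,1) - Fc(1,1) * Fc(2,3)) / J
  FinvT[, 7] <- (Fc(2,1) * Fc(3,2) - Fc(2,2) * Fc(3,1)) / J
  FinvT[, 8] <- (Fc(1,2) * Fc(3,1) - Fc(1,1) * Fc(3,2)) / J
  FinvT[, 9] <- (Fc(1,1) * Fc(2,2) - Fc(1,2) * Fc(2,1)) / J

  c1 <- aS * e1
  c4f <- 2 * afS * q4f * e4f
  c4s <- 2 * asS * q4s * e4s
  c8 <- afsS * I8 * e8
  cv <- mp@kappa * (J - 1) * J - aS

  P <- matrix(0, E, 9)
  for (k in 1:3) for (d in 1:3) {
    col <- (k - 1L) * 3L + d
    P[, col] <- c1 * Fv[, col] +
      c4f * Ff[, d] * fib[, k] + c4s * Fs[, d] * sht[, k] +
      c8 * (Ff[, d] * sht[, k] + Fs[, d] * fib[, k]) +
      cv * FinvT[, col]
  }
  list(W = W, P = P, J = J, I4f = I4f, Ff = Ff)
}

#' Passive Holzapfel-Ogden energy and stress
#'
#' Strain-energy density and first Piola-Kirchhoff stress of the four-term
#' invariant HO law (isotropic I1, fiber I4f, sheet I4s and shear I8fs
#' exponential terms) with volumetric penalty kappa*(J-1)^2/2 and the
#' -a log(J) compensation that makes the reference configuration exactly
#' stress free. Both energy and stress vanish at the identity.
#'
#' @param F 3 x 3 deformation gradient with positive determinant.
#' @param params a \linkS4class{MaterialParams}.
#' @param f,s unit fiber and sheet vectors.
#' @return list with \code{energy} (kPa) and \code{stress} (3 x 3, kPa).
#' @export
passiveStress <- function(F, params, f, s) {
  stopifnot(all(dim(F) == c(3, 3)))
  if (det(F) <= 0) stop("element inversion: det F <= 0")
  out <- hoStressBatch(matrix(as.vector(F), 1), matrix(f, 1), matrix(s, 1),
                       params)
  list(energy = out$W[1], stress = matrix(out$P[1, ], 3, 3))
}

#' Construct an activation model
#'
#' @param v conduction velocity (mm/ms).
#' @param stimulusNode pacing-site node index.
#' @param TaMax peak active fiber stress (kPa).
#' @param riseTime,plateauTime,relaxTime twitch timing (ms).
#' @param cycleLength cycle length (ms).
#' @return an \linkS4class{ActivationModel}.
#' @export
activationModel <- function(v = 1.2, stimulusNode = 0L, TaMax = 120,
                            riseTime = 90, plateauTime = 320,
                            relaxTime = 45, cycleLength = 1000) {
  new("ActivationModel", v = v, stimulusNode = as.integer(stimulusNode),
      TaMax = TaMax, riseTime = riseTime, plateauTime = plateauTime,
      relaxTime = relaxTime, cycleLength = cycleLength)
}

# Unnormalized twitch shape; zero for tau <= 0, continuous at onset.
twitchShape <- function(tau, model) {
  kr <- model@riseTime / 4
  g10 <- 1 / (1 + exp(model@riseTime / kr))
  g1 <- 1 / (1 + exp(-(tau - model@riseTime) / kr))
  g2 <- 1 / (1 + exp((tau - model@riseTime - model@plateauTime) /
                       model@relaxTime))
  out <- pmax(g1 - g10, 0) / (1 - g10) * g2
  out[tau <= 0] <- 0
  out
}

twitchPeak <- function(model) {
  tau <- seq(0, model@cycleLength, by = 0.25)
  max(twitchShape(tau, model))
}

#' Active fiber stress transient
#'
#' Smooth two-sigmoid twitch (rise and decay) normalized so that its peak
#' equals \code{TaMax}. Zero before local activation and back below 1
#' percent of the peak by cycle end.
#'
#' @param t time (ms), vectorized.
#' @param tAct local activation time (ms).
#' @param model an \linkS4class{ActivationModel}.
#' @return active stress (kPa).
#' @export
activeStress <- function(t, tAct, model) {
  model@TaMax * twitchShape(t - tAct, model) / twitchPeak(model)
}
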