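# bSSFP image formation: closed-form signal, coil sensitivities,
# Cartesian k-space encoding with low-pass cropping (partial voluming),
# complex noise at target SNR, root-sum-of-squares reconstruction.

#' Construct bSSFP sequence parameters
#'
#' Defaults follow a typical 1.5 T cine protocol: TR 3.0 ms, TE 1.5 ms,
#' flip 60 degrees, SNR 30, 8 coils, 128 x 128 matrix at 2 mm in-plane.
#'
#' @param TR,TE repetition/echo time (ms), TE <= TR.
#' @param flip flip angle (deg).
#' @param SNR target signal-to-noise ratio (Inf = noiseless).
#' @param nCoils number of receive coils.
#' @param matrixSize integer(2) target matrix.
#' @param resolution target in-plane resolution (mm).
#' @param sliceThickness slice thickness (mm).
#' @param nFrames cine frames.
#' @param seed noise seed.
#' @return a \linkS4class{SequenceParams}.
#' @export
sequenceParams <- function(TR = 3.0, TE = 1.5, flip = 60, SNR = 30,
                           nCoils = 8L, matrixSize = c(128L, 128L),
                           resolution = 2.0, sliceThickness = 8,
                           nFrames = 25L, seed = 1) {
  new("SequenceParams", TR = TR, TE = TE, flip = flip, SNR = SNR,
      nCoils = as.integer(nCoils), matrixSize = as.integer(matrixSize),
      resolution = resolution, sliceThickness = sliceThickness,
      nFrames = as.integer(nFrames), seed = seed)
}

#' Closed-form on-resonance bSSFP steady-state signal
#'
#' S = PD sin(a) (1 - E1) / (1 - (E1 - E2) cos(a) - E1 E2) * exp(-TE/T2)
#' with E1 = exp(-TR/T1), E2 = exp(-TR/T2). Linear in PD; vectorized over
#' voxel inputs.
#'
#' @param PD proton density (a.u.).
#' @param T1,T2 relaxation times (ms), positive.
#' @param seq a \linkS4class{SequenceParams}.
#' @return signal (a.u.).
#' @export
bssfpSignal <- function(PD, T1, T2, seq) {
  stopifnot(all(T1 > 0), all(T2 > 0))
  a <- deg2rad(seq@flip)
  E1 <- exp(-seq@TR / T1); E2 <- exp(-seq@TR / T2)
  PD * sin(a) * (1 - E1) / (1 - (E1 - E2) * cos(a) - E1 * E2) *
    exp(-seq@TE / T2)
}

# Analytic coil sensitivity at world points (n x 2), complex.
coilSensitivityAt <- function(coils, i, pts) {
  ctr <- coils@centers[i, ]
  d2 <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2
  mag <- exp(-d2 / (2 * coils@sigma^2))
  tang <- c(-ctr[2], ctr[1]) / sqrt(sum(ctr^2))
  phase <- coils@phaseCoef * (pts[, 1] * tang[1] + pts[, 2] * tang[2])
  mag * exp(1i * phase)
}

#' Create a set of surface-coil sensitivity maps
#'
#' Coils are placed evenly around a circle enclosing the torso outline;
#' each sensitivity is a Gaussian falloff with distance from the coil
#' center with a smooth tangential phase ramp, so an n-fold rotation maps
#' coil i onto coil i+1 exactly.
#'
#' @param nCoils number of coils (>= 1).
#' @param grid a \code{\link{gridSpec}} (in-plane part used).
#' @param torsoRadius radius of the coil circle (mm).
#' @param torsoCenter center of the coil circle (mm).
#' @param sigma Gaussian falloff width (mm; default 0.8 * torsoRadius).
#' @param phaseCoef tangential phase-ramp coefficient (rad/mm).
#' @return a \linkS4class{CoilSet}.
#' @export
makeCoils <- function(nCoils, grid, torsoRadius = 180,
                      torsoCenter = c(55, -15), sigma = NULL,
                      phaseCoef = 0.01) {
  stopifnot(nCoils >= 1)
  if (is.null(sigma)) sigma <- 0.8 * torsoRadius
  ang <- 2 * pi * (seq_len(nCoils) - 1) / nCoils
  centers <- cbind(torsoCenter[1] + torsoRadius * cos(ang),
                   torsoCenter[2] + torsoRadius * sin(ang))
  xs <- gridAxis(grid, 1); ys <- gridAxis(grid, 2)
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  cs <- new("CoilSet", maps = list(), centers = centers, sigma = sigma,
            phaseCoef = phaseCoef, grid = list(x = xs, y = ys,
                                               center = torsoCenter))
  cs@maps <- lapply(seq_len(nCoils), function(i)
    matrix(coilSensitivityAt(cs, i, pts), length(xs)))
  cs
}

#' Encode a high-resolution signal image into target k-space
#'
#' Per coil: multiply by the sensitivity, 2D DFT, and symmetric central
#' crop to the target matrix. The crop is the low-pass operation that
#' produces partial-voluming at tissue boundaries. Scaling is chosen so
#' that a band-limited image is reproduced exactly by
#' \code{\link{reconstructImage}} (DFT normalized by the source grid size;
#' DC at index floor(n/2)+1 after shifting).
#'
#' @param signal high-resolution real signal image (matrix).
#' @param coils a \linkS4class{CoilSet} on the high-resolution grid.
#' @param seq a \linkS4class{SequenceParams} (target matrix).
#' @return a \linkS4class{KSpaceData}.
#' @export
encodeKspace <- function(signal, coils, seq) {
  nh <- dim(signal); nt <- seq@matrixSize
  if (any(nh %% nt != 0))
    stop("high-resolution grid must be an integer multiple of the target matrix")
  nC <- length(coils@maps)
  out <- array(0i, c(nt[1], nt[2], nC))
  i1 <- floor(nh[1] / 2) + 1L; i2 <- floor(nh[2] / 2) + 1L
  sel1 <- (i1 - floor(nt[1] / 2)):(i1 + ceiling(nt[1] / 2) - 1L)
  sel2 <- (i2 - floor(nt[2] / 2)):(i2 + ceiling(nt[2] / 2) - 1L)
  for (cIdx in seq_len(nC)) {
    K <- fftshift2(ft2(signal * coils@maps[[cIdx]]))
    out[, , cIdx] <- K[sel1, sel2]
  }
  new("KSpaceData", data = out, mask = matrix(1, nt[1], nt[2]))
}

#' Add complex Gaussian noise at a target SNR
#'
#' The noise standard deviation is calibrated so that (mean magnitude of
#' the reference region in the noiseless reconstruction) / (image-domain
#' noise standard deviation) equals the target SNR. Deterministic given
#' the seed; SNR = Inf returns the input unchanged.
#'
#' @param k a \linkS4class{KSpaceData}.
#' @param seq a \linkS4class{SequenceParams} (SNR and seed).
#' @param refSignal mean magnitude of the reference region (e.g. LV blood
#'   pool) in the noiseless reconstruction.
#' @return a \linkS4class{KSpaceData} with noise added.
#' @export
addNoise <- function(k, seq, refSignal) {
  if (!is.finite(seq@SNR)) return(k)
  if (missing(refSignal) || !is.finite(refSignal) || refSignal <= 0)
    stop("a positive reference-region signal is required to calibrate noise")
  nt <- dim(k@data)[1:2]
  sigmaIm <- refSignal / seq@SNR
  sigmaK <- sigmaIm / sqrt(prod(nt))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seq@seed)
  n <- length(k@data)
  noise <- (stats::rnorm(n) + 1i * stats::rnorm(n)) * sigmaK
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  new("KSpaceData", data = k@data + array(noise, dim(k@data)),
      mask = k@mask)
}

#' Reconstruct a magnitude image from Cartesian k-space
#'
#' Inverse DFT per coil and root-sum-of-squares combination.
#'
#' @param k a \linkS4class{KSpaceData} (full Cartesian).
#' @return nonnegative magnitude matrix on the target grid.
#' @export
reconstructImage <- function(k) {
  nt <- dim(k@data)[1:2]
  acc <- matrix(0, nt[1], nt[2])
  for (cIdx in seq_len(dim(k@data)[3])) {
    img <- ift2(ifftshift2(k@data[, , cIdx]))
    acc <- acc + Mod(img)^2
  }
  sqrt(acc)
}

#' Simulate a cine bSSFP acquisition for one slice
#'
#' Per frame: closed-form bSSFP signal from the PD/T1/T2 maps, coil
#' encoding with central k-space cropping, complex noise at the target
#' SNR (calibrated on the LV blood pool of the noiseless reconstruction),
#' and root-sum-of-squares reconstruction. Returns both noisy frames and
#' the noiseless reference.
#'
#' @param maps list of \linkS4class{TissueMaps} (one per frame,
#'   high-resolution grid), or a single object reused for all frames.
#' @param labels list of \linkS4class{LabelVolume} matching \code{maps}
#'   (for the blood-pool reference region).
#' @param coils a \linkS4class{CoilSet} on the high-resolution grid.
#' @param seq a \linkS4class{SequenceParams}.
#' @param slice slice index within the volumes (default 1).
#' @return a \linkS4class{CineImage}.
#' @export
simulateCine <- function(maps, labels, coils, seq, slice = 1L) {
  if (is(maps, "TissueMaps")) maps <- list(maps)
  if (is(labels, "LabelVolume")) labels <- list(labels)
  if (length(maps) != seq@nFrames)
    stop(sprintf("expected %d frames of tissue maps, got %d",
                 seq@nFrames, length(maps)))
  nt <- seq@matrixSize
  frames <- array(0, c(nt[1], nt[2], seq@nFrames))
  refFrames <- frames
  spacingHi <- maps[[1]]@spacing
  for (f in seq_len(seq@nFrames)) {
    lab <- labels[[min(f, length(labels))]]
    sig <- bssfpSignal(maps[[f]]@PD[, , slice], maps[[f]]@T1[, , slice],
                       maps[[f]]@T2[, , slice], seq)
    k <- encodeKspace(sig, coils, seq)
    noiseless <- reconstructImage(k)
    blood <- lab@data[, , slice] == lab@classes[["lvBlood"]]
    ratio <- dim(sig) / nt
    bloodLow <- blood[seq(1, dim(sig)[1], by = ratio[1]),
                      seq(1, dim(sig)[2], by = ratio[2])]
    refSig <- mean(noiseless[bloodLow])
    sq <- seq; sq@seed <- seq@seed + f - 1
    kN <- addNoise(k, sq, refSignal = refSig)
    frames[, , f] <- reconstructImage(kN)
    refFrames[, , f] <- noiseless
  }
  new("CineImage", frames = frames, reference = refFrames,
      spacing = c(spacingHi[1:2] * (dim(maps[[1]]@PD)[1:2] / nt),
                  spacingHi[3]),
      origin = maps[[1]]@origin,
      meta = list(TR = seq@TR, TE = seq@TE, flip = seq@flip,
                  SNR = seq@SNR, nCoils = seq@nCoils, seed = seq@seed,
                  slice = slice))
}

setMethod("show", "CineImage", function(object) {
  cat(sprintf(
    "CineImage: %d x %d, %d frames (TR %.1f / TE %.1f ms, flip %.0f deg, SNR %s)\n",
    dim(object@frames)[1], dim(object@frames)[2], dim(object@frames)[3],
    object@meta$TR, object@meta$TE, object@meta$flip,
    format(object@meta$SNR)))
})
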