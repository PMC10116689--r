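# PD/T1/T2 tissue property assignment, procedural texture, warping with
# the motion, and the closed-form bSSFP property fit.

#' Default tissue property table (1.5 T regime)
#'
#' Literature-regime PD (relative), T1 and T2 (ms) per phantom class.
#' Values are configuration, not constants: pass an edited copy to
#' \code{\link{assignProperties}} to override. The table is also shipped
#' as YAML in \code{inst/extdata/tissue_properties.yaml}.
#'
#' @return data.frame with columns class, label, PD, T1, T2.
#' @export
defaultTissueTable <- function() {
  cls <- phantomClasses()
  tb <- rbind(
    background = c(0.02, 100, 10),
    body       = c(0.75, 900, 50),
    lungL      = c(0.20, 800, 40),
    lungR      = c(0.20, 800, 40),
    lvMyo      = c(0.80, 870, 50),
    lvBlood    = c(0.95, 1200, 250),
    rvMyo      = c(0.80, 870, 50),
    rvBlood    = c(0.95, 1200, 250),
    la         = c(0.95, 1200, 250),
    ra         = c(0.95, 1200, 250),
    aorta      = c(0.95, 1200, 250),
    liverFat   = c(0.85, 380, 55))
  data.frame(class = unname(cls[rownames(tb)]), label = rownames(tb),
             PD = tb[, 1], T1 = tb[, 2], T2 = tb[, 3],
             row.names = NULL)
}

#' Read a tissue property table from YAML
#' @param path YAML file with one entry per class label.
#' @return data.frame as \code{\link{defaultTissueTable}}.
#' @export
readTissueTable <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(rbind, lapply(names(y$classes), function(nm) {
    e <- y$classes[[nm]]
    data.frame(class = e$class, label = nm, PD = e$PD, T1 = e$T1, T2 = e$T2)
  }))
}

checkTissueTable <- function(table) {
  stopifnot(all(c("class", "PD", "T1", "T2") %in% names(table)))
  if (any(table$T2 > table$T1))
    stop("tissue table violates T2 <= T1")
  if (any(table$PD <= 0 | table$PD > 1) || any(table$T1 <= 0) ||
      any(table$T2 <= 0))
    stop("tissue table values out of range")
  table
}

#' Assign piecewise-constant tissue properties to a label volume
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param table property table (default \code{\link{defaultTissueTable}}).
#' @return a \linkS4class{TissueMaps}.
#' @export
assignProperties <- function(labels, table = defaultTissueTable()) {
  checkTissueTable(table)
  present <- sort(unique(as.vector(labels@data)))
  missing <- setdiff(present, table$class)
  if (length(missing))
    stop("no tissue properties for class id(s): ",
         paste(missing, collapse = ", "))
  lut <- function(col) {
    v <- numeric(max(table$class) + 1L)
    v[table$class + 1L] <- table[[col]]
    array(v[labels@data + 1L], dim(labels@data))
  }
  new("TissueMaps", PD = lut("PD"), T1 = lut("T1"), T2 = lut("T2"),
      spacing = labels@spacing, origin = labels@origin,
      frame = labels@frame)
}

#' Construct a texture model
#'
#' Per-class mean-one log-normal multiplicative Gaussian random fields:
#' white noise smoothed to the stated correlation length, exponentiated
#' and normalized. The LV myocardium and the background are excluded by
#' default (the LV stays uniform so its ground-truth masks remain exact).
#'
#' @param sd relative standard deviation (fraction of the class mean).
#' @param corrLength correlation length (mm).
#' @param seed RNG seed.
#' @param exclude class names never textured.
#' @return list texture model.
#' @export
textureModel <- function(sd = 0.08, corrLength = 6, seed = 1,
                         exclude = c("lvMyo", "background")) {
  stopifnot(sd >= 0, corrLength > 0)
  list(sd = sd, corrLength = corrLength, seed = seed, exclude = exclude)
}

# Smooth unit-variance Gaussian random field per slice (FFT convolution).
gaussianField2 <- function(nx, ny, sigmaPx) {
  z <- matrix(stats::rnorm(nx * ny), nx, ny)
  if (sigmaPx <= 0) return(z)
  kx <- c(0:(floor(nx / 2)), -((ceiling(nx / 2) - 1):1)) / nx
  ky <- c(0:(floor(ny / 2)), -((ceiling(ny / 2) - 1):1)) / ny
  H <- exp(-2 * pi^2 * sigmaPx^2 * outer(kx^2, ky^2, "+"))
  f <- Re(stats::fft(stats::fft(z) * H, inverse = TRUE)) / (nx * ny)
  f / stats::sd(as.vector(f))
}

#' Apply multiplicative texture to tissue maps
#'
#' Deterministic given the seed; class means are preserved exactly
#' (renormalized per class), excluded classes are untouched, and the
#' voxel-wise constraint T2 <= T1 is re-imposed after texturing.
#'
#' @param maps a \linkS4class{TissueMaps}.
#' @param labels the matching \linkS4class{LabelVolume}.
#' @param texture a \code{\link{textureModel}}.
#' @return a \linkS4class{TissueMaps}.
#' @export
applyTexture <- function(maps, labels, texture = textureModel()) {
  if (texture$sd == 0) return(maps)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(texture$seed)
  dims <- dim(labels@data)
  sigmaPx <- texture$corrLength / mean(labels@spacing[1:2])
  sLog <- sqrt(log(1 + texture$sd^2))
  field <- array(1, dims)
  for (k in seq_len(dims[3])) {
    z <- gaussianField2(dims[1], dims[2], sigmaPx)
    field[, , k] <- exp(sLog * z - sLog^2 / 2)
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  exclIds <- labels@classes[texture$exclude]
  excl <- array(labels@data %in% exclIds, dims)
  field[excl] <- 1
  # preserve per-class means exactly
  for (id in setdiff(unique(as.vector(labels@data)), exclIds)) {
    sel <- labels@data == id
    field[sel] <- field[sel] / mean(field[sel])
  }
  out <- new("TissueMaps", PD = pmin(maps@PD * field, 1),
             T1 = maps@T1 * field,
             T2 = pmin(maps@T2 * field, maps@T1 * field),
             spacing = maps@spacing, origin = maps@origin,
             frame = maps@frame)
  out
}

#' Warp tissue maps with the tissue motion
#'
#' Backward warping of the reference-frame property maps so that texture
#' features advect with the tissue over the cycle (a bright speckle stays
#' on its tissue patch). Thin wrapper around \code{\link{applyWarp}} that
#' re-imposes T2 <= T1 after interpolation.
#'
#' @param maps reference \linkS4class{TissueMaps}.
#' @param warp a \linkS4class{WarpField} (backward, reference <- frame).
#' @return warped \linkS4class{TissueMaps}.
#' @export
warpProperties <- function(maps, warp) {
  out <- applyWarp(maps, warp)
  out@T2 <- pmin(out@T2, out@T1)
  out
}

#' Fit PD/T1/T2 from multi-acquisition bSSFP magnitudes
#'
#' Per-pixel bounded least squares against the closed-form bSSFP signal,
#' requiring at least three acquisitions with distinct repetition times
#' (a single bSSFP image cannot identify three parameters, and at a fixed
#' short TR the signal depends on T2/T1 only, so flip-angle variation
#' alone leaves a T1 ridge; TR variation makes the inverse problem well
#' posed).
#' Pixels with all-zero signal are returned at the lower bounds and
#' flagged degenerate.
#'
#' @param signals matrix (nPixels x nAcq) of bSSFP magnitudes.
#' @param seqs list of \linkS4class{SequenceParams}, one per acquisition.
#' @param lower,upper parameter bounds c(PD, T1, T2).
#' @param nStarts number of multi-start initializations.
#' @return data.frame with PD, T1, T2, residual (RMS), degenerate flag.
#' @export
fitTissueProperties <- function(signals, seqs,
                                lower = c(1e-3, 100, 10),
                                upper = c(1, 3000, 2000),
                                nStarts = 4) {
  signals <- as.matrix(signals)
  if (length(seqs) != ncol(signals))
    stop("one SequenceParams per signal column required")
  if (ncol(signals) < 3)
    stop("underdetermined: at least 3 acquisitions are needed to fit ",
         "PD, T1 and T2")
  fwd <- function(par) {
    vapply(seqs, function(sq)
      bssfpSignal(par[1], par[2], par[3], sq), numeric(1))
  }
  starts <- rbind(c(0.8, 900, 80), c(0.5, 400, 40), c(0.95, 1500, 250),
                  c(0.3, 1200, 60))[seq_len(nStarts), , drop = FALSE]
  n <- nrow(signals)
  out <- data.frame(PD = numeric(n), T1 = numeric(n), T2 = numeric(n),
                    residual = numeric(n), degenerate = logical(n))
  for (i in seq_len(n)) {
    y <- signals[i, ]
    if (all(y == 0)) {
      out[i, 1:3] <- lower; out$residual[i] <- 0; out$degenerate[i] <- TRUE
      next
    }
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      fit <- tryCatch(stats::optim(
        starts[s, ], function(p) {
          p2 <- p; p2[3] <- min(p2[3], p2[2])   # T2 <= T1
          sum((fwd(p2) - y)^2)
        },
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(parscale = c(0.5, 500, 100), maxit = 500,
                       factr = 1e4)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
    # polish from the best start at tight tolerance
    pol <- tryCatch(stats::optim(
      best$par, function(p) {
        p2 <- p; p2[3] <- min(p2[3], p2[2])
        sum((fwd(p2) - y)^2)
      },
      method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(parscale = c(0.5, 500, 100), maxit = 1000,
                     factr = 10)),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value <= best$value) best <- pol
    p <- best$par; p[3] <- min(p[3], p[2])
    out$PD[i] <- p[1]; out$T1[i] <- p[2]; out$T2[i] <- p[3]
    out$residual[i] <- sqrt(best$value / length(y))
  }
  out
}

setMethod("show", "TissueMaps", function(object) {
  cat(sprintf(
    "TissueMaps: %s voxels, PD [%.2f, %.2f], T1 [%.0f, %.0f] ms, T2 [%.0f, %.0f] ms\n",
    paste(dim(object@PD), collapse = " x "),
    min(object@PD), max(object@PD), min(object@T1), max(object@T1),
    min(object@T2), max(object@T2)))
})
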