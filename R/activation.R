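# Front-propagation activation mapping (graph-geodesic eikonal
# approximation on mesh edges).

# Undirected edge list (node pairs) of the structured hex mesh: transmural,
# circumferential and longitudinal nearest-neighbour connections.
meshEdges <- function(mesh) {
  nLayers <- mesh@dims[1]; nCirc <- mesh@dims[2]; nLongP <- mesh@dims[3]
  nStations <- nCirc * nLongP
  sid <- function(i, j) (j - 1L) * nCirc + i
  nid <- function(i, j, k) (k - 1L) * nStations + sid(i, j)
  i <- rep(seq_len(nCirc), times = nLongP)
  j <- rep(seq_len(nLongP), each = nCirc)
  edges <- NULL
  for (k in seq_len(nLayers)) {
    a <- nid(i, j, k)
    edges <- rbind(edges,
      cbind(a, nid(i %% nCirc + 1L, j, k)),
      cbind(a[j < nLongP], nid(i[j < nLongP], j[j < nLongP] + 1L, k)))
    if (k < nLayers) edges <- rbind(edges, cbind(a, nid(i, j, k + 1L)))
  }
  edges
}

#' Compute per-node activation times by front propagation
#'
#' Eikonal-style activation: the stimulus node activates at time zero and
#' the front propagates along mesh edges at the local conduction velocity
#' (graph-geodesic shortest-path approximation). A scar slows conduction
#' through its \code{conductionFactor}, blended smoothly from core to
#' remote tissue.
#'
#' @param mesh a \linkS4class{VolumetricMesh}.
#' @param v conduction velocity (mm/ms), > 0.
#' @param stimulus node index (or indices) of the pacing site(s); NULL or
#'   0 selects the apical endocardial ring (the fast His-Purkinje spread
#'   is folded into this choice and the effective velocity).
#' @param scar optional \linkS4class{ScarDefect}.
#' @return numeric vector of activation times (ms), zero at the stimulus.
#' @export
computeActivationMap <- function(mesh, v = 0.6, stimulus = NULL,
                                 scar = NULL) {
  stopifnot(v > 0)
  if (is.null(stimulus) || identical(as.integer(stimulus), 0L)) {
    endoIdx <- which(mesh@nodeT == 0)
    stimulus <- endoIdx[mesh@nodeV[endoIdx] == min(mesh@nodeV[endoIdx])]
  }
  edges <- meshEdges(mesh)
  len <- sqrt(rowSums((mesh@nodes[edges[, 1], , drop = FALSE] -
                       mesh@nodes[edges[, 2], , drop = FALSE])^2))
  fac <- rep(1, nrow(mesh@nodes))
  if (!is.null(scar)) {
    b <- scarBlend(mesh, scar, what = "node")
    fac <- 1 - (1 - scar@conductionFactor) * b
  }
  vEdge <- v * (fac[edges[, 1]] + fac[edges[, 2]]) / 2
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  d <- igraph::distances(g, v = stimulus, weights = len / vEdge)
  tAct <- apply(d, 2, min)
  if (any(!is.finite(tAct))) stop("mesh graph is disconnected")
  unname(tAct)
}
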