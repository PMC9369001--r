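## Sparse inverse-covariance (graphical lasso) estimation over a candidate
## gene set, penalty tuning to a target selection size, and merging of
## per-cohort selections.
##
## The solver itself lives in src/glasso.cpp (block coordinate descent with
## an off-diagonal L1 penalty).  estimatePrecision() first splits the problem
## into the connected components of the graph {|S_ij| > lambda}: the
## graphical-lasso solution is exactly block diagonal over those components
## (Witten et al. 2011; Mazumder & Hastie 2012), so solving per block is both
## exact and fast, and the same fact yields the selection size at any lambda
## without refitting during bisection.

#' Graphical lasso solver
#'
#' L1-penalized Gaussian log-likelihood maximization for the precision
#' matrix, with the penalty on off-diagonal entries only (so the working
#' covariance keeps the input diagonal, and `lambda = 0` returns the direct
#' inverse).
#'
#' @param S Symmetric covariance/correlation matrix.
#' @param lambda Non-negative penalty.
#' @param tol Outer convergence tolerance (relative mean change of the
#'   working covariance off-diagonal).
#' @param maxIter Maximum outer sweeps.
#' @return List with `theta`, `w`, `iterations`, `converged`.
#' @export
graphicalLasso <- function(S, lambda, tol = 1e-4, maxIter = 200L) {
  .assert(is.matrix(S) && nrow(S) == ncol(S), "S must be square")
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric", call. = FALSE)
  .assert(lambda >= 0, "lambda must be >= 0")
  res <- .glassoCpp(S, lambda, tol, as.integer(maxIter))
  if (!res$converged)
    stop(sprintf("graphical lasso did not converge at lambda = %g", lambda),
         call. = FALSE)
  res
}

## connected components of the screening graph {|S_ij| > lambda}
.screenComponents <- function(S, lambda) {
  A <- abs(S) > lambda
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::components(g)$membership
}

#' Estimate a sparse precision graph over a gene set
#'
#' @param corr Symmetric correlation matrix of standardized genes (unit
#'   diagonal), gene symbols as dimnames.
#' @param lambda Non-negative L1 penalty.
#' @param epsEdge Numerical zero threshold defining the edge set.
#' @param tol,maxIter Solver controls, see [graphicalLasso()].
#' @return A [PrecisionGraph-class].
#' @export
estimatePrecision <- function(corr, lambda, epsEdge = 1e-6, tol = 1e-4,
                              maxIter = 200L) {
  .assert(is.matrix(corr) && nrow(corr) == ncol(corr), "corr must be square")
  if (max(abs(corr - t(corr))) > 1e-8)
    stop("correlation matrix must be symmetric", call. = FALSE)
  genes <- rownames(corr)
  if (is.null(genes)) genes <- sprintf("V%d", seq_len(nrow(corr)))
  p <- nrow(corr)
  theta <- matrix(0, p, p, dimnames = list(genes, genes))

  memb <- .screenComponents(corr, lambda)
  for (comp in unique(memb)) {
    idx <- which(memb == comp)
    if (length(idx) == 1L) {
      theta[idx, idx] <- 1 / corr[idx, idx]
    } else {
      sub <- graphicalLasso(corr[idx, idx, drop = FALSE], lambda,
                            tol = tol, maxIter = maxIter)
      theta[idx, idx] <- sub$theta
    }
  }
  theta <- (theta + t(theta)) / 2
  ut <- which(upper.tri(theta) & abs(theta) > epsEdge, arr.ind = TRUE)
  edges <- matrix(as.integer(ut), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  new("PrecisionGraph", genes = genes, lambda = lambda, theta = theta,
      edges = edges, epsEdge = epsEdge)
}

#' Genes retained in the sparse network
#'
#' A gene is selected when it is incident to at least one edge of the
#' precision graph; the anchor gene itself is excluded from the returned set.
#'
#' @param graph A [PrecisionGraph-class].
#' @param anchor Anchor symbol to exclude (or `NULL`).
#' @return Sorted character vector of selected genes.
#' @export
selectGenes <- function(graph, anchor = NULL) {
  deg <- nodeDegree(graph)
  sel <- names(deg)[deg >= 1L]
  sort(setdiff(sel, anchor))
}

## Selection size at a penalty without refitting: by the block-diagonal
## screening theorem, a gene has >= 1 edge iff some |corr| to another gene
## exceeds lambda.
.selectionSize <- function(maxAbsOff, lambda, anchorIdx = NULL) {
  sel <- maxAbsOff > lambda
  if (!is.null(anchorIdx)) sel[anchorIdx] <- FALSE
  sum(sel)
}

#' Tune the graphical-lasso penalty to select a target number of genes
#'
#' Monotone bisection on lambda over `lambdaRange` seeking a selection of
#' exactly `target` non-anchor genes.  Because the selection size is a step
#' function of lambda, the bisection converges to the smallest lambda whose
#' selection is at least the target; if that selection overshoots, the excess
#' genes with the smallest maximum off-diagonal precision magnitude are
#' dropped (ties by symbol), guaranteeing exactly `target` genes.
#'
#' @param corr Correlation matrix over the candidate genes (anchor included
#'   when `anchor` is given), with gene dimnames.
#' @param target Number of genes to select.
#' @param anchor Anchor symbol contained in `corr` (excluded from the
#'   selection count) or `NULL`.
#' @param lambdaRange Bisection interval, default `c(1e-3, 1)`.
#' @param maxIter Maximum bisection iterations (default 40).
#' @param cohort Label stored in the returned set.
#' @param epsEdge,tol Passed to [estimatePrecision()].
#' @return List with `lambda`, `set` (a [SelectedGeneSet-class]) and `graph`
#'   (the [PrecisionGraph-class] at the tuned lambda).
#' @export
tuneLambdaToTarget <- function(corr, target, anchor = NULL,
                               lambdaRange = c(1e-3, 1), maxIter = 40L,
                               cohort = "cohort", epsEdge = 1e-6, tol = 1e-4) {
  genes <- rownames(corr)
  .assert(!is.null(genes), "corr must carry gene dimnames")
  anchorIdx <- if (!is.null(anchor)) match(anchor, genes) else NULL
  nCand <- length(genes) - length(anchorIdx)
  if (target > nCand)
    stop(sprintf("target (%d) exceeds candidate genes (%d)", target, nCand),
         call. = FALSE)

  offAbs <- abs(corr)
  diag(offAbs) <- 0
  maxAbsOff <- apply(offAbs, 1L, max)

  lo <- lambdaRange[[1L]]; hi <- lambdaRange[[2L]]
  nLo <- .selectionSize(maxAbsOff, lo, anchorIdx)
  if (nLo < target)
    stop(sprintf("target %d not reachable: only %d genes selected at lambda = %g",
                 target, nLo, lo), call. = FALSE)
  for (k in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    if (.selectionSize(maxAbsOff, mid, anchorIdx) >= target) lo <- mid else hi <- mid
  }
  lambda <- lo

  graph <- estimatePrecision(corr, lambda, epsEdge = epsEdge, tol = tol)
  sel <- selectGenes(graph, anchor)
  ## numerical-edge repair: back off slightly if the realized selection falls
  ## short of the screening count at the bisection boundary
  tries <- 0L
  while (length(sel) < target && tries < 8L) {
    lambda <- lambda * 0.995
    graph <- estimatePrecision(corr, lambda, epsEdge = epsEdge, tol = tol)
    sel <- selectGenes(graph, anchor)
    tries <- tries + 1L
  }
  if (length(sel) < target)
    stop(sprintf("could not reach target %d (best %d at lambda = %g)",
                 target, length(sel), lambda), call. = FALSE)
  if (length(sel) > target) {
    th <- abs(graph@theta)
    diag(th) <- 0
    strength <- apply(th[sel, , drop = FALSE], 1L, max)
    keep <- sel[order(-strength, sel)][seq_len(target)]
    apLog("lambda tuning on ", cohort, ": dropped ", length(sel) - target,
          " weakest-edge genes to reach target ", target)
    sel <- sort(keep)
  }
  set <- new("SelectedGeneSet", cohort = cohort, genes = sel, lambda = lambda,
             criterion = "edge-incident, weakest-edge top-up")
  list(lambda = lambda, set = set, graph = graph)
}

#' Merge two per-cohort gene selections
#'
#' @param setA,setB [SelectedGeneSet-class] objects.
#' @return Character vector of the union, sorted by symbol, with attribute
#'   `overlap` (number of shared symbols).
#' @export
mergeSelectedSets <- function(setA, setB) {
  ov <- intersect(setA@genes, setB@genes)
  merged <- sort(union(setA@genes, setB@genes))
  apLog("merged ", length(setA@genes), " + ", length(setB@genes),
        " genes -> ", length(merged), " unique (overlap ", length(ov), ")")
  attr(merged, "overlap") <- length(ov)
  merged
}

#' Edge counts along a penalty path
#'
#' Convenience helper: fits [estimatePrecision()] at each penalty and returns
#' the realized edge counts, whose non-increase in lambda is a basic sanity
#' property of the solver.
#'
#' @param corr Correlation matrix.
#' @param lambdas Increasing penalty values.
#' @return Integer vector of edge counts.
#' @export
precisionPathEdgeCounts <- function(corr, lambdas) {
  vapply(lambdas, function(l) numEdges(estimatePrecision(corr, l)), 1L)
}
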