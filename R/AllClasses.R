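#' @import SummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## CohortExpression
## ---------------------------------------------------------------------------

#' CohortExpression: one cancer type's genes x samples expression matrix
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] carrying one
#' cohort's expression values plus transform bookkeeping.  The transform state
#' machine (`raw` -> `standardized` via [logStandardize()]) is enforced so a
#' cohort cannot be standardized twice by accident.
#'
#' @slot cancerType Short cohort label, e.g. `"CESC"`.
#' @slot transformState One of `"raw"`, `"log"`, `"standardized"`.
#' @export
setClass("CohortExpression",
  contains = "SummarizedExperiment",
  slots = c(cancerType = "character", transformState = "character"))

setValidity("CohortExpression", function(object) {
  msgs <- character()
  if (length(object@cancerType) != 1L || !nzchar(object@cancerType))
    msgs <- c(msgs, "cancerType must be a single non-empty label")
  if (!object@transformState %in% c("raw", "log", "standardized"))
    msgs <- c(msgs, "transformState must be raw, log or standardized")
  g <- rownames(object); s <- colnames(object)
  if (is.null(g) || anyDuplicated(g)) msgs <- c(msgs, "duplicate or missing gene ids")
  if (is.null(s) || anyDuplicated(s)) msgs <- c(msgs, "duplicate or missing sample ids")
  v <- SummarizedExperiment::assay(object)
  if (object@transformState == "raw" && any(v < 0))
    msgs <- c(msgs, "raw expression values must be non-negative")
  if (object@transformState == "standardized" && ncol(v) > 1L && nrow(v) > 0L) {
    m <- rowMeans(v)
    sdv <- apply(v, 1L, stats::sd)
    if (max(abs(m)) > 1e-8) msgs <- c(msgs, "standardized rows must have mean 0 (1e-8)")
    if (max(abs(sdv - 1)) > 1e-6) msgs <- c(msgs, "standardized rows must have sd 1 (1e-6)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CohortExpression object
#'
#' @param values Numeric genes x samples matrix with gene symbols as rownames
#'   and sample ids as colnames.
#' @param cancerType Cohort label.
#' @param transformState Transform state of `values` (default `"raw"`).
#' @return A [CohortExpression-class] object.
#' @export
#' @examples
#' m <- matrix(1:6, 3, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' CohortExpression(m, "TOY")
CohortExpression <- function(values, cancerType, transformState = "raw") {
  .assert(is.matrix(values) && is.numeric(values), "values must be a numeric matrix")
  .assert(nrow(values) > 0L && ncol(values) > 0L, "empty expression matrix")
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(expr = values))
  new("CohortExpression", se, cancerType = cancerType,
      transformState = transformState)
}

#' @describeIn CohortExpression-class Cohort label accessor.
#' @param object,x A `CohortExpression`.
#' @export
setGeneric("cancerType", function(object) standardGeneric("cancerType"))

#' @export
setMethod("cancerType", "CohortExpression", function(object) object@cancerType)

#' @describeIn CohortExpression-class Transform-state accessor.
#' @export
setGeneric("transformState", function(object) standardGeneric("transformState"))

#' @export
setMethod("transformState", "CohortExpression", function(object) object@transformState)

#' Expression matrix, gene ids and sample ids of a cohort
#' @param x A [CohortExpression-class].
#' @return `exprValues`: the numeric matrix; `geneIDs`/`sampleIDs`: character.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "expr")

#' @rdname exprValues
#' @export
geneIDs <- function(x) rownames(x)

#' @rdname exprValues
#' @export
sampleIDs <- function(x) colnames(x)

setMethod("show", "CohortExpression", function(object) {
  cat("CohortExpression '", object@cancerType, "': ", nrow(object), " genes x ",
      ncol(object), " samples [", object@transformState, "]\n", sep = "")
})

## ---------------------------------------------------------------------------
## PrecisionGraph
## ---------------------------------------------------------------------------

#' PrecisionGraph: sparse inverse-covariance estimate over a gene set
#'
#' Result of [estimatePrecision()]: the graphical-lasso precision matrix at a
#' given penalty, with its edge set (off-diagonal entries above the numerical
#' zero threshold `epsEdge`).
#'
#' @slot genes Gene symbols (matrix order).
#' @slot lambda Non-negative L1 penalty.
#' @slot theta Symmetric precision matrix estimate.
#' @slot edges Two-column integer matrix of edge endpoints (i < j).
#' @slot epsEdge Numerical zero threshold for edges.
#' @export
setClass("PrecisionGraph",
  slots = c(genes = "character", lambda = "numeric", theta = "matrix",
            edges = "matrix", epsEdge = "numeric"))

setValidity("PrecisionGraph", function(object) {
  msgs <- character()
  p <- length(object@genes)
  th <- object@theta
  if (!all(dim(th) == p)) msgs <- c(msgs, "theta dimension mismatch")
  else {
    if (max(abs(th - t(th))) > 1e-8) msgs <- c(msgs, "theta must be symmetric (1e-8)")
    if (any(diag(th) <= 0)) msgs <- c(msgs, "theta diagonal must be positive")
  }
  if (object@lambda < 0) msgs <- c(msgs, "lambda must be >= 0")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PrecisionGraph", function(object) {
  cat("PrecisionGraph: ", length(object@genes), " genes, lambda = ",
      signif(object@lambda, 4), ", ", nrow(object@edges), " edges\n", sep = "")
})

#' Number of edges / per-gene degree of a PrecisionGraph
#' @param graph A [PrecisionGraph-class].
#' @return `numEdges`: integer; `nodeDegree`: named integer vector.
#' @export
numEdges <- function(graph) nrow(graph@edges)

#' @rdname numEdges
#' @export
nodeDegree <- function(graph) {
  d <- integer(length(graph@genes))
  names(d) <- graph@genes
  if (nrow(graph@edges)) {
    t1 <- tabulate(graph@edges[, 1L], nbins = length(d))
    t2 <- tabulate(graph@edges[, 2L], nbins = length(d))
    d <- d + t1 + t2
  }
  d
}

## ---------------------------------------------------------------------------
## SelectedGeneSet
## ---------------------------------------------------------------------------

#' SelectedGeneSet: genes retained by penalty tuning on one cohort
#'
#' @slot cohort Source cohort label.
#' @slot genes Selected gene symbols (sorted).
#' @slot lambda Penalty at which the selection was made.
#' @slot criterion Short tag describing the selection rule.
#' @export
setClass("SelectedGeneSet",
  slots = c(cohort = "character", genes = "character", lambda = "numeric",
            criterion = "character"))

setMethod("show", "SelectedGeneSet", function(object) {
  cat("SelectedGeneSet [", object@cohort, "]: ", length(object@genes),
      " genes at lambda = ", signif(object@lambda, 4), " (",
      object@criterion, ")\n", sep = "")
})

#' Genes of a SelectedGeneSet
#' @param set A [SelectedGeneSet-class].
#' @export
selectedGenes <- function(set) set@genes

## ---------------------------------------------------------------------------
## AnchorForest
## ---------------------------------------------------------------------------

#' AnchorForest: fitted two-cohort random-forest classifier
#'
#' Wraps a [randomForest::randomForest] fit over the merged feature gene set,
#' together with the group semantics (group1 = reference-A-like, i.e. high
#' anchor expression associated with worse survival; group2 =
#' reference-B-like) and normalized Gini importances.
#'
#' @slot fit The underlying randomForest object.
#' @slot features Feature gene symbols, in training column order.
#' @slot classes Named character of length 2 mapping `group1`/`group2` to the
#'   reference cohort labels.
#' @slot seed Integer seed used for the fit.
#' @slot importance Named per-feature importance shares (sum 1).
#' @slot params List of forest hyperparameters.
#' @export
setClass("AnchorForest",
  slots = c(fit = "ANY", features = "character", classes = "character",
            seed = "integer", importance = "numeric", params = "list"))

setValidity("AnchorForest", function(object) {
  msgs <- character()
  if (length(object@classes) != 2L ||
      !identical(sort(names(object@classes)), c("group1", "group2")))
    msgs <- c(msgs, "classes must be named group1/group2")
  imp <- object@importance
  if (length(imp)) {
    if (any(imp < 0)) msgs <- c(msgs, "importances must be >= 0")
    if (abs(sum(imp) - 1) > 1e-8) msgs <- c(msgs, "importances must sum to 1 (1e-8)")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AnchorForest", function(object) {
  cat("AnchorForest: ", length(object@features), " features, ",
      object@params$nTrees, " trees; group1 = '", object@classes[["group1"]],
      "'-like, group2 = '", object@classes[["group2"]], "'-like\n", sep = "")
})

## ---------------------------------------------------------------------------
## GeneNetwork
## ---------------------------------------------------------------------------

#' GeneNetwork: refined core gene association network for one cohort
#'
#' @slot cohort Cohort label.
#' @slot genes Gene symbols (network node order).
#' @slot adjacency Symmetric logical adjacency matrix.
#' @slot weights Symmetric numeric matrix of |partial correlation| proxies
#'   (off-diagonal precision magnitudes).
#' @slot clusters List of integer vectors: connected components, decreasing
#'   size.
#' @slot ordering Integer permutation of nodes (reverse Cuthill-McKee).
#' @slot topFlag Logical per gene: member of the classifier's top-k
#'   importance list.
#' @slot lambda Penalty used for the refinement.
#' @export
setClass("GeneNetwork",
  slots = c(cohort = "character", genes = "character", adjacency = "matrix",
            weights = "matrix", clusters = "list", ordering = "integer",
            topFlag = "logical", lambda = "numeric"))

setValidity("GeneNetwork", function(object) {
  msgs <- character()
  p <- length(object@genes)
  if (!all(dim(object@adjacency) == p)) msgs <- c(msgs, "adjacency dimension mismatch")
  else if (!isTRUE(all(object@adjacency == t(object@adjacency))))
    msgs <- c(msgs, "adjacency must be symmetric")
  if (length(object@ordering) != p || !setequal(object@ordering, seq_len(p)))
    msgs <- c(msgs, "ordering must be a permutation of the gene list")
  memb <- sort(unlist(object@clusters))
  if (!identical(as.integer(memb), seq_len(p)))
    msgs <- c(msgs, "clusters must partition the gene set")
  if (length(object@topFlag) != p) msgs <- c(msgs, "topFlag length mismatch")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GeneNetwork", function(object) {
  sizes <- vapply(object@clusters, length, 1L)
  cat("GeneNetwork [", object@cohort, "]: ", length(object@genes), " genes, ",
      sum(object@adjacency[upper.tri(object@adjacency)]), " edges, ",
      length(sizes), " clusters (sizes ", paste(sizes, collapse = ", "),
      ")\n", sep = "")
})
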