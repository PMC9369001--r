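## Correlation ranking of all genes against the anchor gene within one
## cohort, and top-k positive/negative candidate pooling.

#' Rank genes by correlation with the anchor gene
#'
#' Computes the per-gene Pearson (on the standardized log values) or Spearman
#' (on within-gene ranks) correlation with the anchor gene and returns the
#' ranking sorted by coefficient, anchor excluded.  Genes whose correlation
#' is undefined (zero variance) are excluded and logged.
#'
#' @param cohort A standardized [CohortExpression-class].
#' @param anchor Anchor gene symbol.
#' @param method `"pearson"` or `"spearman"`.
#' @return Data.frame with columns `gene`, `r`, sorted by `r` descending
#'   (ties by symbol); attributes `cohort`, `method`, `anchor`.
#' @export
rankGenes <- function(cohort, anchor, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  .assert(is(cohort, "CohortExpression"), "cohort must be a CohortExpression")
  .assert(transformState(cohort) == "standardized",
          "rankGenes expects a standardized cohort")
  v <- exprValues(cohort)
  if (!anchor %in% rownames(v))
    stop(sprintf("anchor gene '%s' not present in cohort '%s'",
                 anchor, cancerType(cohort)), call. = FALSE)
  if (ncol(v) < 3L) stop("need at least 3 samples to rank genes", call. = FALSE)
  a <- v[anchor, ]
  rest <- v[setdiff(rownames(v), anchor), , drop = FALSE]
  r <- as.numeric(suppressWarnings(
    cor(t(rest), a, method = method)))
  names(r) <- rownames(rest)
  bad <- !is.finite(r)
  if (any(bad)) {
    apLog("excluding ", sum(bad), " genes with undefined correlation in ",
          cancerType(cohort))
    r <- r[!bad]
  }
  ord <- order(-r, names(r))
  out <- data.frame(gene = names(r)[ord], r = unname(r[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "cohort") <- cancerType(cohort)
  attr(out, "method") <- method
  attr(out, "anchor") <- anchor
  out
}

#' Build the positive/negative candidate gene pool from a ranking
#'
#' Takes the top `nPos` genes by correlation descending (restricted to
#' positive coefficients) and the top `nNeg` by correlation ascending
#' (restricted to negative ones); ties at the boundary are broken by
#' lexicographic gene symbol.
#'
#' @param ranking A [rankGenes()] result.
#' @param nPos,nNeg Candidate counts per sign.
#' @return Data.frame with columns `gene`, `sign` (`"positive"`/`"negative"`),
#'   `r`; positive block first.
#' @export
buildCandidatePool <- function(ranking, nPos = 500L, nNeg = 500L) {
  .assert(nPos >= 0 && nNeg >= 0, "candidate counts must be non-negative")
  pos <- ranking[ranking$r > 0, , drop = FALSE]
  neg <- ranking[ranking$r < 0, , drop = FALSE]
  if (nrow(pos) < nPos || nrow(neg) < nNeg)
    stop(sprintf(paste0("insufficient candidates: need %d positive (have %d) ",
                        "and %d negative (have %d)"),
                 nPos, nrow(pos), nNeg, nrow(neg)), call. = FALSE)
  pos <- pos[order(-pos$r, pos$gene), , drop = FALSE][seq_len(nPos), , drop = FALSE]
  neg <- neg[order(neg$r, neg$gene), , drop = FALSE][seq_len(nNeg), , drop = FALSE]
  out <- rbind(
    if (nPos) data.frame(gene = pos$gene, sign = "positive", r = pos$r,
                         stringsAsFactors = FALSE),
    if (nNeg) data.frame(gene = neg$gene, sign = "negative", r = neg$r,
                         stringsAsFactors = FALSE))
  if (is.null(out)) out <- data.frame(gene = character(), sign = character(),
                                      r = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cohort") <- attr(ranking, "cohort")
  out
}

#' Correlation range summary of a candidate pool
#'
#' Reproduces the standard reporting layout for anchor-correlation pools: the
#' maximum and minimum coefficient of the positive block and the minimum and
#' maximum of the negative block.
#'
#' @param ranking A [rankGenes()] result.
#' @param nPos,nNeg Block sizes.
#' @return Named numeric: `posMax`, `posMin`, `negMin`, `negMax`.
#' @export
correlationRangeSummary <- function(ranking, nPos = 500L, nNeg = 500L) {
  pool <- buildCandidatePool(ranking, nPos, nNeg)
  pos <- pool$r[pool$sign == "positive"]
  neg <- pool$r[pool$sign == "negative"]
  c(posMax = if (length(pos)) max(pos) else NA_real_,
    posMin = if (length(pos)) min(pos) else NA_real_,
    negMin = if (length(neg)) min(neg) else NA_real_,
    negMax = if (length(neg)) max(neg) else NA_real_)
}
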