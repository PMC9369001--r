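## Balanced two-cohort random-forest classifier over the merged feature set,
## held-out validation, and transfer classification of all other cohorts.
##
## Features are log2(x+1) values standardized per gene with parameters
## fitted on the pooled reference cohorts and applied frozen to every other
## cohort.  A per-cohort z-score would remove any cohort-constant expression
## signature (two pure-context cohorts become distributionally identical), so
## the classifier uses a train-time scaler instead; see the methods vignette.

#' Fit the per-gene feature scaler on the reference cohorts
#'
#' @param refA,refB Raw [CohortExpression-class] reference cohorts.
#' @param genes Feature gene symbols; every gene must be present in both
#'   cohorts (no imputation).
#' @return List with `genes`, per-gene `mean` and `sd` of pooled log2(x+1)
#'   values.
#' @export
featureScaler <- function(refA, refB, genes) {
  for (co in list(refA, refB)) {
    miss <- setdiff(genes, geneIDs(co))
    if (length(miss))
      stop(sprintf("cohort '%s' lacks %d feature gene(s): %s",
                   cancerType(co), length(miss),
                   paste(head(miss, 5L), collapse = ", ")), call. = FALSE)
  }
  pooled <- cbind(log2(exprValues(refA)[genes, , drop = FALSE] + 1),
                  log2(exprValues(refB)[genes, , drop = FALSE] + 1))
  m <- rowMeans(pooled)
  s <- apply(pooled, 1L, stats::sd)
  s[s == 0] <- 1
  list(genes = genes, mean = m, sd = s)
}

#' Build a samples x features matrix for classification
#'
#' @param cohort A raw [CohortExpression-class].
#' @param scaler A [featureScaler()] result.
#' @return Numeric samples x features matrix (feature order = scaler order).
#' @export
buildFeatureMatrix <- function(cohort, scaler) {
  miss <- setdiff(scaler$genes, geneIDs(cohort))
  if (length(miss))
    stop(sprintf("cohort '%s' lacks %d feature gene(s): %s",
                 cancerType(cohort), length(miss),
                 paste(head(miss, 5L), collapse = ", ")), call. = FALSE)
  lv <- log2(exprValues(cohort)[scaler$genes, , drop = FALSE] + 1)
  z <- (lv - scaler$mean) / scaler$sd
  t(z)
}

#' Under-sample the majority class to the minority size
#'
#' @param samplesA,samplesB Sample id vectors of the two classes.
#' @param seed Integer seed (uniform sampling without replacement).
#' @return List with elements `A` and `B`, each of length
#'   `min(|A|, |B|)`.
#' @export
undersampleBalance <- function(samplesA, samplesB, seed) {
  set.seed(seed)
  k <- min(length(samplesA), length(samplesB))
  a <- if (length(samplesA) > k) sort(sample(samplesA, k)) else samplesA
  b <- if (length(samplesB) > k) sort(sample(samplesB, k)) else samplesB
  list(A = a, B = b)
}

#' Stratified train/test split
#'
#' Per class, `round(trainFraction * n)` samples go to training; the split is
#' disjoint and exhaustive.
#'
#' @param ids Sample ids.
#' @param labels Class label per id.
#' @param trainFraction Fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` id vectors.
#' @export
splitTrainTest <- function(ids, labels, trainFraction, seed) {
  .assert(trainFraction > 0 && trainFraction < 1,
          "trainFraction must be in (0,1)")
  .assert(length(ids) == length(labels), "ids/labels length mismatch")
  set.seed(seed)
  train <- character()
  for (cl in unique(labels)) {
    cls <- ids[labels == cl]
    nTrain <- round(trainFraction * length(cls))
    train <- c(train, sample(cls, nTrain))
  }
  list(train = ids[ids %in% train], test = ids[!ids %in% train])
}

#' Train the two-cohort random-forest classifier
#'
#' @param x Samples x features numeric matrix (training rows).
#' @param labels Reference cohort label per row; exactly two classes.  The
#'   first element of `groupOrder` is the "group 1" (anchor-high-is-worse)
#'   reference.
#' @param groupOrder Length-2 character: which label is group1 / group2.
#' @param nTrees Number of trees (default 500).
#' @param mtry Features tried per split (default `floor(sqrt(p))`).
#' @param seed Integer seed.
#' @return An [AnchorForest-class].
#' @export
trainForest <- function(x, labels, groupOrder = sort(unique(labels)),
                        nTrees = 500L, mtry = NULL, seed = 1L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class", call. = FALSE)
  .assert(setequal(unique(labels), groupOrder), "groupOrder must match labels")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  y <- factor(labels, levels = groupOrder)
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = nTrees, mtry = mtry,
                                    importance = FALSE)
  imp <- fit$importance[, "MeanDecreaseGini"]
  imp <- if (sum(imp) > 0) imp / sum(imp) else
    setNames(rep(1 / length(imp), length(imp)), names(imp))
  new("AnchorForest", fit = fit, features = colnames(x),
      classes = c(group1 = groupOrder[[1L]], group2 = groupOrder[[2L]]),
      seed = as.integer(seed), importance = imp,
      params = list(nTrees = as.integer(nTrees), mtry = as.integer(mtry)))
}

#' Held-out accuracy of the classifier
#'
#' @param model An [AnchorForest-class].
#' @param x Samples x features matrix.
#' @param labels True reference cohort label per row.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluateHoldout <- function(model, x, labels) {
  pred <- as.character(predict(model@fit, newdata = x))
  mean(pred == as.character(labels))
}

#' Transfer-classify patients of non-reference cohorts
#'
#' Each patient receives the forest's group-1 vote fraction; the predicted
#' group is group1 when the fraction is at least 0.5 (exact ties go to
#' group1 and are logged).
#'
#' @param model An [AnchorForest-class].
#' @param x Samples x features matrix.
#' @param cancerTypes Cohort label per row.
#' @return Data.frame with `sample_id`, `cancer_type`, `group`,
#'   `vote_group1`.
#' @export
transferClassify <- function(model, x, cancerTypes) {
  if (nrow(x) == 0L)
    return(data.frame(sample_id = character(), cancer_type = character(),
                      group = character(), vote_group1 = numeric(),
                      stringsAsFactors = FALSE))
  votes <- predict(model@fit, newdata = x, type = "vote")
  v1 <- votes[, model@classes[["group1"]]]
  ties <- sum(v1 == 0.5)
  if (ties) apLog(ties, " patients at exact 0.5 vote fraction -> group1")
  data.frame(sample_id = rownames(x),
             cancer_type = as.character(cancerTypes),
             group = ifelse(v1 >= 0.5, "group1", "group2"),
             vote_group1 = as.numeric(v1),
             stringsAsFactors = FALSE)
}

#' Per-cancer-type group counts of an assignment table
#' @param assignments A [transferClassify()] result.
#' @return Data.frame `cancer_type`, `group1`, `group2`.
#' @export
groupCounts <- function(assignments) {
  tab <- table(assignments$cancer_type, factor(assignments$group,
                                               c("group1", "group2")))
  data.frame(cancer_type = rownames(tab),
             group1 = as.integer(tab[, "group1"]),
             group2 = as.integer(tab[, "group2"]),
             stringsAsFactors = FALSE)
}

#' Top-k features by importance, with cumulative share
#'
#' @param model An [AnchorForest-class].
#' @param k Number of genes to keep.
#' @return Data.frame `gene`, `importance`, `cumulative`, sorted by
#'   importance descending (ties by symbol); attribute `cumulativeShare`
#'   gives the share at `k`.
#' @export
featureImportanceTopK <- function(model, k) {
  imp <- model@importance
  ord <- order(-imp, names(imp))
  k <- min(k, length(imp))
  top <- imp[ord][seq_len(k)]
  out <- data.frame(gene = names(top), importance = unname(top),
                    cumulative = cumsum(unname(top)),
                    stringsAsFactors = FALSE)
  attr(out, "cumulativeShare") <- sum(top)
  out
}
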