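test_that("under-sampling balances to the minority size reproducibly", {
  a <- sprintf("a%03d", 1:291)
  b <- sprintf("b%03d", 1:176)
  bal <- undersampleBalance(a, b, seed = 1)
  expect_length(bal$A, 176L)
  expect_length(bal$B, 176L)
  expect_length(c(bal$A, bal$B), 352L)
  expect_identical(bal, undersampleBalance(a, b, seed = 1))
  bal2 <- undersampleBalance(a, b, seed = 2)
  expect_false(identical(bal, bal2))
  expect_length(bal2$A, 176L)
  # equal classes: identity
  expect_identical(undersampleBalance(a[1:5], b[1:5], 1),
                   list(A = a[1:5], B = b[1:5]))
})

test_that("the stratified split is exact, disjoint and exhaustive", {
  ids <- c(sprintf("a%03d", 1:100), sprintf("b%03d", 1:100))
  labels <- rep(c("A", "B"), each = 100)
  sp <- splitTrainTest(ids, labels, 0.7, seed = 3)
  expect_length(sp$train, 140L)
  expect_length(sp$test, 60L)
  expect_equal(sum(startsWith(sp$train, "a")), 70L)
  expect_equal(sum(startsWith(sp$test, "b")), 30L)
  # tiny case
  sp2 <- splitTrainTest(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"),
                        0.5, seed = 4)
  expect_length(sp2$train, 2L)
  # partition property on random instances
  for (k in 1:10) {
    set.seed(k)
    n <- sample(10:60, 1)
    ids <- sprintf("s%03d", 1:n)
    labels <- sample(c("A", "B"), n, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(labels)) < 2) next
    sp <- splitTrainTest(ids, labels, runif(1, 0.2, 0.8), seed = k)
    expect_setequal(c(sp$train, sp$test), ids)
    expect_length(intersect(sp$train, sp$test), 0L)
  }
})

mkSepData <- function(n = 50, p = 50, shift = 3, seed = 5) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * p), n), matrix(rnorm(n * p, shift), n))
  rownames(x) <- sprintf("s%03d", seq_len(2 * n))
  colnames(x) <- sprintf("G%03d", seq_len(p))
  list(x = x, y = rep(c("A", "B"), each = n))
}

test_that("a 3-SD-separated problem is learned perfectly and deterministically", {
  d <- mkSepData()
  m <- trainForest(d$x, d$y, groupOrder = c("A", "B"), nTrees = 100, seed = 6)
  expect_equal(evaluateHoldout(m, d$x, d$y), 1.0)
  expect_equal(sum(m@importance), 1, tolerance = 1e-8)
  expect_true(all(m@importance >= 0))
  m2 <- trainForest(d$x, d$y, groupOrder = c("A", "B"), nTrees = 100, seed = 6)
  a1 <- transferClassify(m, d$x, rep("T", nrow(d$x)))
  a2 <- transferClassify(m2, d$x, rep("T", nrow(d$x)))
  expect_identical(a1, a2)
  expect_error(trainForest(d$x, rep("A", nrow(d$x))), "single class")
})

test_that("label permutation destroys the signal (no leakage)", {
  accs <- numeric(20)
  for (k in 1:20) {
    d <- mkSepData(n = 25, p = 30, shift = 3, seed = 100 + k)
    set.seed(200 + k)
    yPerm <- sample(d$y)
    tr <- c(1:18, 26:43)
    m <- trainForest(d$x[tr, ], yPerm[tr], groupOrder = c("A", "B"),
                     nTrees = 100, seed = k)
    accs[k] <- evaluateHoldout(m, d$x[-tr, ], yPerm[-tr])
  }
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("perfect and fully wrong holdouts hit the accuracy endpoints", {
  d <- mkSepData(n = 20, p = 20, shift = 4, seed = 7)
  m <- trainForest(d$x, d$y, groupOrder = c("A", "B"), nTrees = 50, seed = 8)
  expect_equal(evaluateHoldout(m, d$x, d$y), 1.0)
  expect_equal(evaluateHoldout(m, d$x, rev(d$y)), 0.0)
})

test_that("transfer classification handles empty cohorts and tabulates groups", {
  d <- mkSepData(n = 20, p = 20, shift = 4, seed = 9)
  m <- trainForest(d$x, d$y, groupOrder = c("A", "B"), nTrees = 50, seed = 10)
  empty <- transferClassify(m, d$x[0, , drop = FALSE], character(0))
  expect_equal(nrow(empty), 0L)
  asn <- transferClassify(m, d$x, rep(c("C1", "C2"), each = 20))
  expect_true(all(asn$vote_group1 >= 0 & asn$vote_group1 <= 1))
  expect_identical(asn$group, ifelse(asn$vote_group1 >= 0.5,
                                     "group1", "group2"))
  gc <- groupCounts(asn)
  expect_equal(gc$group1 + gc$group2, c(20L, 20L))
})

test_that("importance ranking accumulates to 1 and finds the informative gene", {
  d <- mkSepData(n = 30, p = 40, shift = 0, seed = 11)
  hits <- 0L
  for (k in 1:20) {
    set.seed(300 + k)
    x <- d$x + rnorm(length(d$x), 0, 1e-8)
    x[, "G007"] <- rnorm(nrow(x)) + ifelse(d$y == "A", 0, 3)
    m <- trainForest(x, d$y, groupOrder = c("A", "B"), nTrees = 100, seed = k)
    if (featureImportanceTopK(m, 1)$gene == "G007") hits <- hits + 1L
  }
  expect_gte(hits, 19L)
  top <- featureImportanceTopK(m, ncol(d$x))
  expect_equal(attr(top, "cumulativeShare"), 1, tolerance = 1e-8)
  expect_true(!is.unsorted(rev(top$importance)))
})

test_that("transfer recovers planted contexts on synthetic mixtures", {
  # full selection + training chain on a reference pair, then per-patient
  # group recovery on one mixed and two pure transfer cohorts
  synth <- syntheticConfig(nGenes = 400, nPosMod = 30, nNegMod = 30,
                           nSignature = 40, samplesPerCohort = 200, seed = 61)
  sc <- syntheticScenario(synth, nTransfer = 3)
  cfg <- runConfig(nPos = 120, nNeg = 120, targetSelect = 120,
                   networkTopK = 40, networkCore = 20, nTrees = 300,
                   seed = 61)
  out <- withr::local_tempdir()
  res <- runPipeline(sc$cohorts, sc$clinical, cfg, outdir = out,
                     writeFigures = FALSE)
  expect_equal(res$accuracy, 1.0, tolerance = 0.051)
  asn <- res$assignments
  truth <- unlist(lapply(names(sc$truth), function(lb)
    setNames(sc$truth[[lb]]$context,
             sprintf("%s-S%04d", lb, seq_along(sc$truth[[lb]]$context)))))
  acc <- mean((asn$group == "group1") == (truth[asn$sample_id] == "A"))
  expect_gte(acc, 0.9)
  # pure context-A transfer cohort: >= 90% assigned group1
  transferLabels <- setdiff(names(sc$truth), c("REFA", "REFB"))
  pureA <- transferLabels[vapply(sc$truth[transferLabels], function(tr)
    all(tr$context == "A"), TRUE)][1]
  shareA <- mean(asn$group[asn$cancer_type == pureA] == "group1")
  expect_gte(shareA, 0.9)
  # 50/50 mixture cohort: group-1 share within 50% +/- 10%
  mixed <- transferLabels[vapply(sc$truth[transferLabels], function(tr)
    length(unique(tr$context)) == 2, TRUE)][1]
  shareMix <- mean(asn$group[asn$cancer_type == mixed] == "group1")
  expect_gt(shareMix, 0.4)
  expect_lt(shareMix, 0.6)
  # assignment is invariant to cohort input order
  x3 <- buildFeatureMatrix(sc$cohorts[[3]], featureScaler(
    sc$cohorts$REFA, sc$cohorts$REFB, res$merged))
  a1 <- transferClassify(res$model, x3, rep("X", nrow(x3)))
  expect_identical(a1$group, asn$group[asn$cancer_type == names(sc$cohorts)[3]])
})
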