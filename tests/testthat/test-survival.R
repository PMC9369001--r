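test_that("time normalization maps each type's maximum to exactly 1000", {
  clin <- data.frame(sample_id = sprintf("s%d", 1:5),
                     cancer_type = c("X", "X", "X", "Y", "Y"),
                     time_days = c(100, 200, 400, 30, 60),
                     event = c(1L, 0L, 1L, 1L, 1L))
  ns <- normalizeTimes(clin)
  expect_equal(sort(ns$time_norm[ns$cancer_type == "X"]), c(250, 500, 1000))
  expect_equal(sort(ns$time_norm[ns$cancer_type == "Y"]), c(500, 1000))
  expect_identical(ns$event, clin$event[match(ns$sample_id, clin$sample_id)])
  # single patient: own maximum
  one <- normalizeTimes(data.frame(sample_id = "s9", cancer_type = "Z",
                                   time_days = 17.3, event = 0L))
  expect_equal(one$time_norm, 1000)
  # all-zero type is an error
  expect_error(normalizeTimes(data.frame(sample_id = c("a", "b"),
                                         cancer_type = "W",
                                         time_days = c(0, 0),
                                         event = c(1L, 0L))), "positive")
  # idempotent on its own output (max is already 1000)
  ns2 <- normalizeTimes(data.frame(sample_id = ns$sample_id,
                                   cancer_type = ns$cancer_type,
                                   time_days = ns$time_norm,
                                   event = ns$event))
  expect_equal(sort(ns2$time_norm), sort(ns$time_norm))
})

test_that("the anchor median split follows the at-or-below-to-low rule", {
  lab <- stratifyByAnchor(c(s1 = 1, s2 = 2, s3 = 3, s4 = 4))
  expect_identical(unname(lab), c("low", "low", "high", "high"))
  lab2 <- stratifyByAnchor(c(a = 1, b = 2, c = 3))
  expect_identical(unname(lab2["b"]), "low")        # unique middle -> low
  expect_warning(lab3 <- stratifyByAnchor(c(a = 2, b = 2, c = 2)), "constant")
  expect_true(all(lab3 == "low"))
})

test_that("K-M estimates match the stated single-step cases", {
  # one event at the earliest time among 4 patients, rest censored later
  km <- kmEstimate(c(1, 5, 6, 7), c(1, 0, 0, 0))
  expect_equal(nrow(km), 1L)
  expect_equal(km$surv, 0.75)
  expect_equal(km$n_risk, 4)
  # no events: S identically 1
  km0 <- kmEstimate(c(2, 3), c(0, 0))
  expect_equal(nrow(km0), 0L)
  expect_equal(kmSurvAt(km0, 99), 1)
})

test_that("K-M and log-rank agree with brute-force oracles on random data", {
  maxChiErr <- 0
  for (k in 1:100) {
    set.seed(1000 + k)
    n <- sample(6:40, 1)
    times <- round(rexp(n, 0.1), 1) + 0.1
    events <- rbinom(n, 1, 0.7)
    km <- kmEstimate(times, events)
    oracle <- productLimitOracle(times, events)
    expect_equal(km$time, oracle$time)
    expect_equal(km$surv, oracle$surv, tolerance = 1e-12)
    expect_equal(km$n_risk, oracle$n_risk)
    # survival invariants
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_true(all(km$surv >= 0 & km$surv <= 1))

    m <- sample(5:30, 1)
    tA <- round(rexp(m, 0.1), 1) + 0.1; eA <- rbinom(m, 1, 0.8)
    tB <- round(rexp(m, 0.15), 1) + 0.1; eB <- rbinom(m, 1, 0.8)
    if (sum(eA) + sum(eB) == 0) next
    lr <- logrankTest(tA, eA, tB, eB)
    ora <- logrankOracle(tA, eA, tB, eB)
    maxChiErr <- max(maxChiErr, abs(lr$chisq - ora$chisq))
    expect_equal(lr$p, ora$p, tolerance = 1e-8)
    expect_equal(sum(lr$observed), sum(lr$expected), tolerance = 1e-8)
  }
  expect_lt(maxChiErr, 1e-10)
})

test_that("log-rank symmetry and degenerate contracts hold", {
  t1 <- c(1, 2, 3, 4, 6); e1 <- c(1, 0, 1, 1, 0)
  same <- logrankTest(t1, e1, t1, e1)
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  t2 <- c(2, 3, 5, 8); e2 <- c(1, 1, 0, 1)
  ab <- logrankTest(t1, e1, t2, e2)
  ba <- logrankTest(t2, e2, t1, e1)
  expect_equal(ab$chisq, ba$chisq, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_error(logrankTest(numeric(0), numeric(0), t1, e1), "non-empty")
  expect_warning(z <- logrankTest(c(1, 2), c(0, 0), c(3, 4), c(0, 0)),
                 "no events")
  expect_equal(z$p, 1)
})

mkSurvPool <- function(seedBase, nA = 4, nNoise = 2, betaA = 0.3,
                       nPerA = 40L, nPerNoise = 1500L) {
  ## nA small informative context-A cohorts drowned by nNoise large null
  ## cohorts: the pooled anchor effect only emerges once the null cohorts
  ## are removed
  one <- function(n, beta, idx, label) {
    cfg <- syntheticConfig(nGenes = 12, nPosMod = 2, nNegMod = 2,
                           nSignature = 2, samplesPerCohort = n,
                           beta = abs(beta), censoring = 0.2,
                           seed = seedBase + idx)
    co <- generateCohort(cfg, idx, context = "A", label = label, beta = beta)
    std <- logStandardize(co$expression)
    ns <- normalizeTimes(co$clinical)
    ns$anchor <- exprValues(std)["POLI", ns$sample_id]
    ns
  }
  surv <- NULL
  for (i in seq_len(nA))
    surv <- rbind(surv, one(nPerA, betaA, i, sprintf("EFF%d", i)))
  for (i in seq_len(nNoise))
    surv <- rbind(surv, one(nPerNoise, 0, i + 10L, sprintf("NULL%d", i)))
  surv
}

test_that("backward selection handles the trivial boundary cases", {
  surv <- mkSurvPool(7000, nA = 1, nNoise = 0, betaA = 1.5)
  bs <- backwardSelect(surv, alpha = 0.05)
  expect_identical(bs$finalTypes, "EFF1")
  expect_equal(nrow(bs$trace), 1L)
  expect_lt(bs$finalP, 0.05)
  # alpha = 1: stops immediately with the full set
  surv2 <- mkSurvPool(7100, nA = 2, nNoise = 1, betaA = 0, nPerNoise = 100L)
  bs2 <- backwardSelect(surv2, alpha = 1)
  expect_equal(nrow(bs2$trace), 1L)
  expect_length(bs2$finalTypes, 3L)
})

test_that("backward selection strips null cohorts and recovers the direction", {
  removedBoth <- 0L
  dirOk <- 0L; nSig <- 0L
  for (k in 1:20) {
    surv <- mkSurvPool(8000 + 100 * k)
    bs <- backwardSelect(surv, alpha = 0.001)
    gone <- setdiff(unique(surv$cancer_type), bs$finalTypes)
    if (all(c("NULL1", "NULL2") %in% gone)) removedBoth <- removedBoth + 1L
    if (bs$significant) {
      nSig <- nSig + 1L
      if (bs$direction == "high_worse") dirOk <- dirOk + 1L
    }
    # recorded p at each removal step is the minimum over candidates
    tr <- bs$trace
    expect_true(all(tr$p >= 0 & tr$p <= 1))
  }
  expect_gte(removedBoth, 16L)           # >= 80% of 20 replicates
  if (nSig > 0) expect_gte(dirOk / nSig, 0.9)
})

test_that("null-everywhere backward selection yields valid (inflated) traces", {
  sig <- 0L
  for (k in 1:15) {
    surv <- mkSurvPool(9000 + 37 * k, nA = 3, nNoise = 1, betaA = 0,
                       nPerNoise = 150L)
    bs <- backwardSelect(surv, alpha = 0.05)
    expect_true(all(diff(bs$trace$step) == 1))
    expect_true(is.finite(bs$finalP))
    if (bs$significant) sig <- sig + 1L
  }
  # greedy minimization inflates significance relative to alpha; the rate is
  # reported, not controlled
  expect_true(sig >= 0)
})
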