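test_that("generation is reproducible from the seed and seed-sensitive", {
  cfg <- syntheticConfig(nGenes = 60, nPosMod = 8, nNegMod = 8,
                         nSignature = 8, samplesPerCohort = 30, seed = 11)
  a1 <- generateCohort(cfg, 1, context = "mixed")
  a2 <- generateCohort(cfg, 1, context = "mixed")
  expect_identical(exprValues(a1$expression), exprValues(a2$expression))
  expect_identical(a1$clinical, a2$clinical)
  cfg2 <- syntheticConfig(nGenes = 60, nPosMod = 8, nNegMod = 8,
                          nSignature = 8, samplesPerCohort = 30, seed = 12)
  b <- generateCohort(cfg2, 1, context = "mixed")
  expect_false(identical(exprValues(a1$expression), exprValues(b$expression)))
})

test_that("planted module correlations match the factor-model closed form", {
  # corr(gene, anchor) = sqrt(rhoMod) * sqrt(rhoAnchor) under the one-factor
  # model; the log2(x+1) mapping attenuates this only marginally.
  cfg <- syntheticConfig(nGenes = 300, nPosMod = 40, nNegMod = 40,
                         nSignature = 20, samplesPerCohort = 400, seed = 5)
  co <- generateCohort(cfg, 1, context = "A")
  std <- logStandardize(co$expression)
  rk <- rankGenes(std, "POLI")
  roles <- co$truth$roles
  pos <- roles$gene[roles$role == "posModule"]
  neg <- roles$gene[roles$role == "negModule"]
  expected <- sqrt(cfg$rhoMod) * sqrt(cfg$rhoAnchor)
  expect_equal(mean(rk$r[match(pos, rk$gene)]), expected, tolerance = 0.05)
  expect_equal(mean(rk$r[match(neg, rk$gene)]), -expected, tolerance = 0.05)
})

test_that("with vanishing module correlation, noise genes sit at the null scale", {
  cfg <- syntheticConfig(nGenes = 220, nPosMod = 5, nNegMod = 5,
                         nSignature = 0, rhoMod = 1e-4, rhoSig = 1e-4,
                         samplesPerCohort = 100, seed = 6)
  co <- generateCohort(cfg, 1, context = "A")
  std <- logStandardize(co$expression)
  rk <- rankGenes(std, "POLI")
  noise <- co$truth$roles$gene[co$truth$roles$role == "noise"]
  expect_lt(mean(abs(rk$r[match(noise, rk$gene)])),
            2 / sqrt(cfg$samplesPerCohort))
})

test_that("the reference pair realizes the planted context separation", {
  cfg <- syntheticConfig(nGenes = 200, nPosMod = 20, nNegMod = 20,
                         nSignature = 30, samplesPerCohort = 150, seed = 21)
  pair <- generateReferencePair(cfg)
  roles <- pair$A$truth$roles
  sig <- roles$gene[roles$role == "signature"]
  # on the exact log2 scale the per-gene mean contexts differ by +/- delta
  # field SDs; family-wise bound of 4 SE per gene across the 30 genes, and
  # the average separation within 3 SE of its mean
  lA <- log2(exprValues(pair$A$expression)[sig, ])
  lB <- log2(exprValues(pair$B$expression)[sig, ])
  d <- (rowMeans(lA) - rowMeans(lB)) / cfg$sdLog
  se <- sqrt(2 / ncol(lA))
  expect_true(all(abs(abs(d) - cfg$delta) < 4 * se))
  expect_lt(abs(mean(abs(d)) - cfg$delta), 3 * se / sqrt(length(d) / 4))
  # the pipeline's log2(x+1) transform attenuates the shift only mildly
  pA <- log2(exprValues(pair$A$expression)[sig, ] + 1)
  pB <- log2(exprValues(pair$B$expression)[sig, ] + 1)
  dp <- abs(rowMeans(pA) - rowMeans(pB)) / cfg$sdLog
  expect_gt(mean(dp), 0.8 * cfg$delta)
  expect_lt(mean(dp), 1.02 * cfg$delta)
  expect_identical(unique(pair$A$truth$context), "A")
  expect_identical(unique(pair$B$truth$context), "B")
  # administrative censoring hits the configured event rate
  expect_equal(mean(pair$A$clinical$event), 1 - cfg$censoring,
               tolerance = 2 / cfg$samplesPerCohort)
  expect_true(all(pair$A$clinical$time_days >= 0))
})

test_that("gene roles partition the gene set with a single anchor", {
  cfg <- syntheticConfig(nGenes = 50, nPosMod = 7, nNegMod = 6,
                         nSignature = 4, samplesPerCohort = 10, seed = 2)
  co <- generateCohort(cfg, 1)
  roles <- co$truth$roles
  expect_equal(nrow(roles), cfg$nGenes)
  expect_equal(sum(roles$role == "anchor"), 1L)
  expect_false(anyDuplicated(roles$gene) > 0)
  expect_setequal(unique(roles$role),
                  c("anchor", "posModule", "negModule", "signature", "noise"))
  expect_error(syntheticConfig(nGenes = 10, nPosMod = 6, nNegMod = 6),
               "exceed")
})

test_that("the planted anchor effect is detectable and sign-correct", {
  # power: beta = 1, n = 300, 20% censoring -> log-rank p < 0.05 in >= 90%
  # of replicates; context A puts the anchor-high arm on the lower curve
  cfg0 <- syntheticConfig(nGenes = 12, nPosMod = 2, nNegMod = 2,
                          nSignature = 2, samplesPerCohort = 300,
                          beta = 1, censoring = 0.2)
  hits <- 0L
  dirOkA <- TRUE; dirOkB <- TRUE
  for (k in 1:50) {
    cfg <- syntheticConfig(nGenes = 12, nPosMod = 2, nNegMod = 2,
                           nSignature = 2, samplesPerCohort = 300,
                           beta = 1, censoring = 0.2, seed = 100 + k)
    ctx <- if (k %% 2 == 0) "A" else "B"
    co <- generateCohort(cfg, 1, context = ctx)
    z <- setNames(log2(exprValues(co$expression)["POLI", ] + 1),
                  co$clinical$sample_id)
    lab <- stratifyByAnchor(z)
    hi <- lab == "high"
    lr <- logrankTest(co$clinical$time_days[hi], co$clinical$event[hi],
                      co$clinical$time_days[!hi], co$clinical$event[!hi])
    if (lr$p < 0.05) hits <- hits + 1L
    tMed <- median(co$clinical$time_days)
    sHigh <- kmSurvAt(kmEstimate(co$clinical$time_days[hi],
                                 co$clinical$event[hi]), tMed)
    sLow <- kmSurvAt(kmEstimate(co$clinical$time_days[!hi],
                                co$clinical$event[!hi]), tMed)
    if (ctx == "A" && sHigh >= sLow) dirOkA <- FALSE
    if (ctx == "B" && sHigh <= sLow) dirOkB <- FALSE
  }
  expect_gte(hits, 45L)          # >= 90% of 50 replicates
  expect_true(dirOkA)
  expect_true(dirOkB)
})
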