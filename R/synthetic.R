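## Synthetic multi-cohort generator.
##
## Expression follows a one-factor Gaussian field per cohort: the anchor gene
## loads on a latent factor f with loading sqrt(rhoAnchor); planted
## positive/negative module genes load with +/- sqrt(rhoMod); context
## signature genes load with +/- sqrt(rhoSig) and additionally receive a
## context-dependent mean shift of +/- delta/2 (so the two pure contexts
## differ by delta SD per signature gene); remaining genes are independent
## noise.  The field is mapped to a non-negative FPKM-like scale by
## exponentiation, so log2(x + 1) standardization approximately recovers it.
## Survival is exponential with hazard h0 * exp(s * beta * z_anchor), where
## s = +1 in context A (high anchor -> shorter survival, "group 1"-like) and
## s = -1 in context B; censoring is administrative at the empirical time
## quantile matching the configured censoring rate.

#' Configuration of the synthetic cohort generator
#'
#' @param nGenes Total genes (anchor included).
#' @param nPosMod,nNegMod Sizes of the positively / negatively
#'   anchor-correlated modules.
#' @param nSignature Number of context-signature genes (half shifted up in
#'   context A, half up in context B).
#' @param rhoMod Within-module correlation target in (0, 1).
#' @param rhoSig Anchor-factor loading (squared) of signature genes; ties the
#'   context signature into the anchor-correlated pool, mirroring the working
#'   hypothesis that the transcriptome context of the anchor carries its
#'   prognostic sign.
#' @param rhoAnchor Anchor reliability: squared loading of the anchor gene on
#'   the latent factor.
#' @param delta Context mean shift, in SD units of the log-scale field.
#' @param samplesPerCohort Samples per generated cohort.
#' @param mixFraction Probability of context A per sample in mixed cohorts.
#' @param beta Hazard coefficient (> 0); the per-sample sign follows context.
#' @param h0 Baseline exponential hazard per day.
#' @param censoring Target censoring rate in `[0, 1)`.
#' @param sdLog Log2-scale SD used when exponentiating the field.
#' @param seed Master seed for the generator.
#' @return A validated `SyntheticConfig` list.
#' @export
syntheticConfig <- function(nGenes = 1200L, nPosMod = 60L, nNegMod = 60L,
                            nSignature = 60L, rhoMod = 0.7, rhoSig = 0.3,
                            rhoAnchor = 0.9, delta = 2, samplesPerCohort = 100L,
                            mixFraction = 0.5, beta = 1, h0 = 0.001,
                            censoring = 0.2, sdLog = 2, seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes), nPosMod = as.integer(nPosMod),
              nNegMod = as.integer(nNegMod), nSignature = as.integer(nSignature),
              rhoMod = rhoMod, rhoSig = rhoSig, rhoAnchor = rhoAnchor,
              delta = delta, samplesPerCohort = as.integer(samplesPerCohort),
              mixFraction = mixFraction, beta = beta, h0 = h0,
              censoring = censoring, sdLog = sdLog, seed = as.integer(seed))
  .assert(cfg$nGenes >= 1L + cfg$nPosMod + cfg$nNegMod + cfg$nSignature,
          "module sizes exceed nGenes")
  .assert(cfg$rhoMod > 0 && cfg$rhoMod < 1, "rhoMod must be in (0,1)")
  .assert(cfg$censoring >= 0 && cfg$censoring < 1, "censoring must be in [0,1)")
  .assert(cfg$samplesPerCohort >= 2L, "need >= 2 samples per cohort")
  class(cfg) <- "SyntheticConfig"
  cfg
}

## gene roles are a fixed partition determined by the config sizes
.syntheticRoles <- function(cfg) {
  roles <- rep("noise", cfg$nGenes)
  roles[1L] <- "anchor"
  i <- 2L
  if (cfg$nPosMod) roles[i:(i + cfg$nPosMod - 1L)] <- "posModule"
  i <- i + cfg$nPosMod
  if (cfg$nNegMod) roles[i:(i + cfg$nNegMod - 1L)] <- "negModule"
  i <- i + cfg$nNegMod
  if (cfg$nSignature) roles[i:(i + cfg$nSignature - 1L)] <- "signature"
  genes <- sprintf("G%06d", seq_len(cfg$nGenes))
  genes[1L] <- "POLI"                       # anchor aliased for readability
  ## signature genes carry an anchor-factor loading sign (loadDir) and a
  ## context-shift direction (sigDir); the two are balanced against each
  ## other (cycle ++, +-, -+, --) so the context discriminant is orthogonal
  ## to the latent expression factor
  sigDir <- loadDir <- integer(cfg$nGenes)
  sigIdx <- which(roles == "signature")
  if (length(sigIdx)) {
    loadDir[sigIdx] <- rep_len(c(1L, 1L, -1L, -1L), length(sigIdx))
    sigDir[sigIdx] <- rep_len(c(1L, -1L), length(sigIdx))
  }
  data.frame(gene = genes, role = roles, sigDir = sigDir, loadDir = loadDir,
             stringsAsFactors = FALSE)
}

#' Generate one synthetic cohort
#'
#' @param config A [syntheticConfig()] list.
#' @param cohortIndex Integer index; combined with the master seed it makes
#'   each cohort reproducible in isolation.
#' @param context `"mixed"` (per-sample contexts drawn with `mixFraction`),
#'   `"A"` or `"B"` (pure cohorts).
#' @param label Cohort label (default `SYN<k>`).
#' @param beta Optional hazard coefficient override (e.g. 0 for a
#'   survival-null cohort).
#' @return A list with elements `expression` (raw [CohortExpression-class]),
#'   `clinical` (data.frame) and `truth` (per-sample context/sign, per-gene
#'   roles, realized per-sample hazard coefficient).
#' @export
generateCohort <- function(config, cohortIndex, context = c("mixed", "A", "B"),
                           label = sprintf("SYN%d", cohortIndex),
                           beta = config$beta) {
  context <- match.arg(context)
  roles <- .syntheticRoles(config)
  n <- config$samplesPerCohort
  G <- config$nGenes
  ## per-gene baseline abundance is a property of the gene, shared across
  ## cohorts (drawn from its own seed stream), so cohorts differ only through
  ## the planted structure and sampling noise
  set.seed(stageSeed(config$seed, "baseMeans"))
  baseMean <- runif(G, 2, 10)
  seed <- stageSeed(config$seed, paste0("cohort:", cohortIndex, ":", label))
  set.seed(seed)

  s <- switch(context,
    A = rep(1L, n),
    B = rep(-1L, n),
    mixed = ifelse(runif(n) < config$mixFraction, 1L, -1L))

  f <- rnorm(n)
  eps <- matrix(rnorm(G * n), nrow = G)
  load <- numeric(G)
  load[roles$role == "anchor"] <- sqrt(config$rhoAnchor)
  load[roles$role == "posModule"] <- sqrt(config$rhoMod)
  load[roles$role == "negModule"] <- -sqrt(config$rhoMod)
  load[roles$role == "signature"] <- roles$loadDir[roles$role == "signature"] *
    sqrt(config$rhoSig)
  z <- outer(load, f) + sqrt(1 - load^2) * eps
  sigIdx <- which(roles$role == "signature")
  if (length(sigIdx)) {
    shift <- outer(roles$sigDir[sigIdx] * config$delta / 2, as.numeric(s))
    z[sigIdx, ] <- z[sigIdx, ] + shift
  }

  x <- 2^(config$sdLog * z + baseMean)
  ids <- sprintf("%s-S%04d", label, seq_len(n))
  dimnames(x) <- list(roles$gene, ids)

  zAnchor <- z[1L, ]
  rate <- config$h0 * exp(s * beta * zAnchor)
  tt <- rexp(n, rate)
  if (config$censoring > 0) {
    cc <- as.numeric(quantile(tt, 1 - config$censoring))
    event <- as.integer(tt <= cc)
    tt <- pmin(tt, cc)
  } else {
    event <- rep(1L, n)
  }

  clinical <- data.frame(sample_id = ids, cancer_type = label,
                         time_days = tt, event = event,
                         stringsAsFactors = FALSE)
  truth <- list(context = ifelse(s > 0, "A", "B"), sign = s,
                roles = roles[, c("gene", "role")],
                betaPerSample = s * beta, seed = seed)
  list(expression = CohortExpression(x, cancerType = label),
       clinical = validateClinical(clinical), truth = truth)
}

#' Generate a pure-context reference cohort pair
#'
#' Cohort A is all context `s = +1` (high anchor expression hastens events,
#' the "group 1" pattern); cohort B is all `s = -1`.  The pair stands in for
#' the two real reference cancer types with opposite anchor prognosis.
#'
#' @param config A [syntheticConfig()] list.
#' @param labels Labels for the two cohorts.
#' @return Named list with elements `A` and `B`, each as [generateCohort()].
#' @export
generateReferencePair <- function(config, labels = c("REFA", "REFB")) {
  list(A = generateCohort(config, 1L, context = "A", label = labels[[1L]]),
       B = generateCohort(config, 2L, context = "B", label = labels[[2L]]))
}

#' Write a generated cohort's ground truth as TSV
#' @param cohort A [generateCohort()] result.
#' @param path Output path.
#' @export
writeTruth <- function(cohort, path) {
  df <- data.frame(sample_id = cohort$clinical$sample_id,
                   context = cohort$truth$context,
                   beta = cohort$truth$betaPerSample)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
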