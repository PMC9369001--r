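## End-to-end orchestration: load/standardize -> rank -> pool -> tune ->
## merge -> balance/split/train/evaluate -> transfer-classify -> normalize
## times -> backward-select per group -> importance -> core networks ->
## figures, with a deterministic run manifest.

#' Pipeline run configuration
#'
#' @param anchor Anchor gene symbol.
#' @param nPos,nNeg Candidate counts per correlation sign (defaults 500/500).
#' @param targetSelect Genes selected per reference cohort (default 200).
#' @param trainFraction Training fraction of the balanced reference samples.
#' @param networkTopK Importance genes fed into network refinement (100).
#' @param networkCore Core network size (50).
#' @param nTrees Random-forest trees (500).
#' @param corMethod `"pearson"` or `"spearman"`.
#' @param alpha Log-rank significance threshold (0.05).
#' @param seed Master seed; per-stage seeds derive via [stageSeed()].
#' @return Validated config list.
#' @export
runConfig <- function(anchor = "POLI", nPos = 500L, nNeg = 500L,
                      targetSelect = 200L, trainFraction = 0.7,
                      networkTopK = 100L, networkCore = 50L, nTrees = 500L,
                      corMethod = c("pearson", "spearman"), alpha = 0.05,
                      seed = 1L) {
  corMethod <- match.arg(corMethod)
  cfg <- list(anchor = anchor, nPos = as.integer(nPos), nNeg = as.integer(nNeg),
              targetSelect = as.integer(targetSelect),
              trainFraction = trainFraction,
              networkTopK = as.integer(networkTopK),
              networkCore = as.integer(networkCore),
              nTrees = as.integer(nTrees), corMethod = corMethod,
              alpha = alpha, seed = as.integer(seed))
  .assert(cfg$trainFraction > 0 && cfg$trainFraction < 1,
          "trainFraction must be in (0,1)")
  .assert(cfg$networkCore <= cfg$networkTopK,
          "networkCore must not exceed networkTopK")
  .assert(all(c(cfg$nPos, cfg$nNeg, cfg$targetSelect, cfg$nTrees) >= 0),
          "counts must be non-negative")
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full pipeline
#'
#' @param cohorts Named list of raw [CohortExpression-class] objects; must
#'   contain both `reference` labels.  Non-reference cohorts are
#'   transfer-classified.
#' @param clinical Clinical data.frame covering (a subset of) the samples.
#'   Expression samples without clinical rows stay in the
#'   correlation/classification stages and are excluded (logged) from the
#'   survival stages.
#' @param config A [runConfig()] list.
#' @param reference Length-2 character: group-1-like and group-2-like
#'   reference cohort labels.
#' @param outdir Output directory for all stage TSVs, figures and the
#'   manifest.
#' @param writeFigures Write chord/heatmap figures (default TRUE).
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
runPipeline <- function(cohorts, clinical, config = runConfig(),
                        reference = c("REFA", "REFB"), outdir,
                        writeFigures = TRUE) {
  .assert(all(reference %in% names(cohorts)),
          "reference cohorts missing from input")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  .logEnv$logFile <- file.path(outdir, "run.log")
  on.exit(.logEnv$logFile <- NULL, add = TRUE)
  warnings <- character()
  timings <- list()
  outputs <- character()
  stamp <- function(stage, t0) timings[[stage]] <<-
    round(as.numeric(Sys.time()) - t0, 3)
  emit <- function(df, name) {
    f <- file.path(outdir, name)
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, f)
    f
  }
  runStage <- function(stage, expr) {
    t0 <- as.numeric(Sys.time())
    apLog("stage ", stage, " ...")
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE)),
      warning = function(w) {
        warnings <<- c(warnings, sprintf("[%s] %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    stamp(stage, t0)
    res
  }

  refA <- reference[[1L]]; refB <- reference[[2L]]

  std <- runStage("standardize", lapply(cohorts, logStandardize))

  pools <- runStage("rank", {
    out <- list()
    for (ref in reference) {
      rk <- rankGenes(std[[ref]], config$anchor, config$corMethod)
      emit(rk, sprintf("ranking_%s.tsv", ref))
      pool <- buildCandidatePool(rk, config$nPos, config$nNeg)
      emit(pool, sprintf("pool_%s.tsv", ref))
      out[[ref]] <- pool
    }
    out
  })

  sets <- runStage("select", {
    out <- list()
    for (ref in reference) {
      v <- exprValues(std[[ref]])
      genes <- intersect(c(pools[[ref]]$gene, config$anchor), rownames(v))
      cc <- cor(t(v[genes, , drop = FALSE]))
      tuned <- tuneLambdaToTarget(cc, config$targetSelect,
                                  anchor = config$anchor, cohort = ref)
      emit(data.frame(gene = tuned$set@genes, lambda = tuned$lambda),
           sprintf("selected_%s.tsv", ref))
      out[[ref]] <- tuned$set
    }
    out
  })

  merged <- runStage("merge", {
    m <- mergeSelectedSets(sets[[refA]], sets[[refB]])
    emit(data.frame(gene = m), "features_merged.tsv")
    m
  })

  model <- NULL; accuracy <- NA_real_
  scaler <- runStage("scale", featureScaler(cohorts[[refA]], cohorts[[refB]],
                                            merged))
  trainRes <- runStage("train", {
    bal <- undersampleBalance(sampleIDs(cohorts[[refA]]),
                              sampleIDs(cohorts[[refB]]),
                              stageSeed(config$seed, "balance"))
    ids <- c(bal$A, bal$B)
    labels <- rep(c(refA, refB), c(length(bal$A), length(bal$B)))
    names(labels) <- ids
    sp <- splitTrainTest(ids, labels, config$trainFraction,
                         stageSeed(config$seed, "split"))
    x <- rbind(buildFeatureMatrix(cohorts[[refA]], scaler),
               buildFeatureMatrix(cohorts[[refB]], scaler))
    model <- trainForest(x[sp$train, , drop = FALSE], labels[sp$train],
                         groupOrder = reference, nTrees = config$nTrees,
                         seed = stageSeed(config$seed, "train"))
    accuracy <- evaluateHoldout(model, x[sp$test, , drop = FALSE],
                                labels[sp$test])
    apLog("held-out accuracy: ", accuracy)
    emit(data.frame(key = c("reference_A", "reference_B", "n_train", "n_test",
                            "n_trees", "mtry", "seed", "holdout_accuracy"),
                    value = c(refA, refB, length(sp$train), length(sp$test),
                              model@params$nTrees, model@params$mtry,
                              model@seed, accuracy)),
         "model_card.tsv")
    list(split = sp, balanced = bal)
  })

  others <- setdiff(names(cohorts), reference)
  assignments <- runStage("classify", {
    if (!length(others)) {
      data.frame(sample_id = character(), cancer_type = character(),
                 group = character(), vote_group1 = numeric())
    } else {
      asn <- do.call(rbind, lapply(others, function(lb) {
        transferClassify(model, buildFeatureMatrix(cohorts[[lb]], scaler),
                         rep(lb, ncol(cohorts[[lb]])))
      }))
      emit(asn, "assignments.tsv")
      emit(groupCounts(asn), "group_counts.tsv")
      asn
    }
  })

  survivalRes <- runStage("survive", {
    out <- list()
    if (nrow(assignments)) {
      nmiss <- sum(!assignments$sample_id %in% clinical$sample_id)
      if (nmiss) apLog(nmiss, " classified samples lack clinical rows; ",
                       "excluded from survival stages")
      norm <- normalizeTimes(clinical[clinical$cancer_type %in% others, ,
                                      drop = FALSE])
      anchorZ <- unlist(lapply(others, function(lb) {
        v <- exprValues(std[[lb]])
        setNames(v[config$anchor, ], colnames(v))
      }))
      surv <- merge(merge(assignments, norm, by = c("sample_id", "cancer_type")),
                    data.frame(sample_id = names(anchorZ), anchor = anchorZ),
                    by = "sample_id")
      for (grp in c("group1", "group2")) {
        d <- surv[surv$group == grp, , drop = FALSE]
        if (!nrow(d)) {
          warnings <- c(warnings, sprintf("no patients in %s", grp))
          next
        }
        bs <- backwardSelect(d, alpha = config$alpha, group = grp)
        emit(bs$trace, sprintf("backward_trace_%s.tsv", grp))
        fin <- d[d$cancer_type %in% bs$finalTypes, , drop = FALSE]
        lab <- stratifyByAnchor(setNames(fin$anchor, fin$sample_id))
        for (arm in c("high", "low")) {
          km <- kmEstimate(fin$time_norm[lab == arm], fin$event[lab == arm])
          emit(km, sprintf("km_%s_%s.tsv", grp, arm))
        }
        emit(data.frame(group = grp,
                        final_types = paste(bs$finalTypes, collapse = ","),
                        p = bs$finalP, direction = bs$direction,
                        significant = bs$significant),
             sprintf("logrank_%s.tsv", grp))
        out[[grp]] <- bs
      }
    }
    out
  })

  networks <- runStage("network", {
    top <- featureImportanceTopK(model, config$networkTopK)
    emit(top, "importance_topk.tsv")
    writeGeneList(top$gene, file.path(outdir, "importance_ranked_genes.txt"))
    outputs <- c(outputs, file.path(outdir, "importance_ranked_genes.txt"))
    rfcTop <- head(top$gene, config$networkCore)
    nets <- list()
    for (ref in reference) {
      nw <- refineCoreGenes(top$gene, std[[ref]], target = config$networkCore,
                            rfcTop = rfcTop)
      writeNetwork(nw, outdir)
      outputs <- c(outputs,
                   file.path(outdir, sprintf("%s_%s.tsv", ref,
                                             c("edges", "clusters", "ordering"))))
      if (writeFigures) {
        v <- exprValues(std[[ref]])[nw@genes, , drop = FALSE]
        exportFigures(nw, cor(t(v)), dir = outdir)
      }
      nets[[ref]] <- nw
    }
    nets
  })

  manifest <- list(
    config = unclass(config),
    reference = reference,
    seeds = sapply(c("balance", "split", "train"),
                   function(s) stageSeed(config$seed, s)),
    holdout_accuracy = accuracy,
    overlap = attr(merged, "overlap"),
    outputs = as.list(setNames(as.character(tools::md5sum(unique(outputs))),
                               basename(unique(outputs)))),
    timings = timings,
    warnings = warnings)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  apLog("pipeline complete; outputs in ", outdir)
  invisible(list(manifest = manifest, model = model, sets = sets,
                 merged = merged, assignments = assignments,
                 survival = survivalRes, networks = networks,
                 accuracy = accuracy))
}

#' Generate the default synthetic multi-cohort scenario
#'
#' Two pure-context reference cohorts plus `nTransfer` cohorts (mix of pure
#' and 50/50 mixed contexts), with one joint clinical table.
#'
#' @param synth A [syntheticConfig()] list.
#' @param nTransfer Number of non-reference cohorts (default 3).
#' @return List with `cohorts` (named list of raw expression), `clinical`,
#'   `truth` (per cohort).
#' @export
syntheticScenario <- function(synth = syntheticConfig(), nTransfer = 3L) {
  pair <- generateReferencePair(synth)
  cohorts <- list(REFA = pair$A$expression, REFB = pair$B$expression)
  clin <- rbind(pair$A$clinical, pair$B$clinical)
  truth <- list(REFA = pair$A$truth, REFB = pair$B$truth)
  ctx <- rep(c("A", "B", "mixed"), length.out = nTransfer)
  for (k in seq_len(nTransfer)) {
    co <- generateCohort(synth, k + 2L, context = ctx[[k]])
    lb <- cancerType(co$expression)
    cohorts[[lb]] <- co$expression
    clin <- rbind(clin, co$clinical)
    truth[[lb]] <- co$truth
  }
  list(cohorts = cohorts, clinical = clin, truth = truth)
}
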