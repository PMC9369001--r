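## Readers/writers for expression and clinical tables, plus the transform
## bookkeeping.  Expression files are tab-separated text: first column gene
## symbols, header row sample ids, body numeric.  Clinical files carry
## sample_id, cancer_type, time_days, event.

#' Read a genes x samples expression table
#'
#' Duplicated gene symbols are resolved by keeping the row with the highest
#' mean expression (logged).  Any non-numeric body cell is a parse error
#' naming the offending row and column.
#'
#' @param path Path to a tab-separated expression file.
#' @param cancerType Cohort label to attach.
#' @return A raw-state [CohortExpression-class].
#' @export
readExpression <- function(path, cancerType) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  .assert(ncol(df) >= 2L && nrow(df) >= 1L,
          sprintf("empty expression matrix in '%s'", path))
  genes <- df[[1L]]
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = dimnames(body)))
  bad <- which(is.na(num) | body == "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric expression cell at gene '%s', sample '%s' in '%s'",
                 genes[bad[1L, 1L]], colnames(body)[bad[1L, 2L]], path),
         call. = FALSE)
  }
  rownames(num) <- genes
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    apLog("dropping duplicate gene rows (keeping highest mean): ",
          paste(dup, collapse = ", "))
    warning(sprintf("duplicate gene symbols resolved by highest mean: %s",
                    paste(dup, collapse = ", ")), call. = FALSE)
    keep <- order(-rowMeans(num))
    num <- num[keep[!duplicated(genes[keep])], , drop = FALSE]
    num <- num[order(match(rownames(num), unique(genes))), , drop = FALSE]
  }
  CohortExpression(num, cancerType = cancerType, transformState = "raw")
}

#' Log-transform and per-gene standardize a cohort
#'
#' Applies `log2(x + 1)` then a per-gene z-score within the cohort (sample
#' standard deviation).  Genes with zero variance after the log transform are
#' dropped and logged.  The transform is applied per cancer type, before any
#' cross-cohort pooling.
#'
#' @param cohort A raw-state [CohortExpression-class] with non-negative values.
#' @return A standardized [CohortExpression-class].
#' @export
logStandardize <- function(cohort) {
  .assert(is(cohort, "CohortExpression"), "cohort must be a CohortExpression")
  if (transformState(cohort) != "raw")
    stop(sprintf("logStandardize expects a raw cohort, got '%s'",
                 transformState(cohort)), call. = FALSE)
  v <- exprValues(cohort)
  if (any(v < 0)) stop("negative expression values", call. = FALSE)
  lv <- log2(v + 1)
  sds <- apply(lv, 1L, stats::sd)
  drop <- which(sds == 0 | !is.finite(sds))
  if (length(drop)) {
    apLog("dropping ", length(drop), " zero-variance genes in ",
          cancerType(cohort), ": ",
          paste(head(rownames(lv)[drop], 5L), collapse = ", "),
          if (length(drop) > 5L) ", ..." else "")
    lv <- lv[-drop, , drop = FALSE]
    sds <- sds[-drop]
  }
  z <- (lv - rowMeans(lv)) / sds
  CohortExpression(z, cancerType = cancerType(cohort),
                   transformState = "standardized")
}

#' Read a clinical table
#'
#' Requires columns `sample_id`, `cancer_type`, `time_days`, `event`;
#' validates non-negative follow-up times, binary events and unique sample
#' ids.
#'
#' @param path Path to a tab-separated clinical file.
#' @return A validated data.frame.
#' @export
readClinical <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "cancer_type", "time_days", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("clinical table missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  validateClinical(df[need])
}

#' Validate a clinical data.frame against its invariants
#' @param df Data.frame with sample_id, cancer_type, time_days, event.
#' @return The data.frame, invisibly unchanged, or an error.
#' @export
validateClinical <- function(df) {
  .assert(!anyDuplicated(df$sample_id), "duplicate sample_id in clinical table")
  if (any(df$time_days < 0)) stop("negative time_days in clinical table", call. = FALSE)
  .assert(all(df$event %in% c(0, 1)), "event must be 0 (censored) or 1 (death)")
  df
}

#' Write a clinical table (TSV round-trip partner of readClinical)
#' @param df Clinical data.frame.
#' @param path Output path.
#' @export
writeClinical <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort expression matrix as TSV
#' @param cohort A [CohortExpression-class].
#' @param path Output path.
#' @export
writeExpression <- function(cohort, path) {
  v <- exprValues(cohort)
  df <- data.frame(gene = rownames(v), v, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a ranked gene list, one symbol per line
#'
#' The single-column ranked format is directly usable by GO enrichment tools
#' that take one ranked list.
#'
#' @param genes Character vector in importance order.
#' @param path Output path.
#' @export
writeGeneList <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Write per-patient group assignments as TSV
#' @param assignments Data.frame from [transferClassify()].
#' @param path Output path.
#' @export
writeAssignments <- function(assignments, path) {
  write.table(assignments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
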