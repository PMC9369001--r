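## Survival-time normalization, anchor-expression stratification, K-M
## estimation, log-rank testing and greedy backward selection of cancer
## types.  K-M curves and the log-rank statistic are computed through the
## survival package (product-limit estimator; hypergeometric variance at
## each distinct event time).

#' Normalize follow-up times within each cancer type
#'
#' Each cancer type's times are divided by that type's maximum follow-up and
#' multiplied by 1000, so cohorts with different follow-up horizons become
#' poolable; event indicators are unchanged.
#'
#' @param clinical Clinical data.frame (`sample_id`, `cancer_type`,
#'   `time_days`, `event`).
#' @return Data.frame with `sample_id`, `cancer_type`, `time_norm`, `event`.
#' @export
normalizeTimes <- function(clinical) {
  validateClinical(clinical)
  out <- lapply(split(clinical, clinical$cancer_type), function(d) {
    mx <- max(d$time_days)
    if (mx <= 0)
      stop(sprintf("cancer type '%s' has no positive follow-up time",
                   d$cancer_type[[1L]]), call. = FALSE)
    data.frame(sample_id = d$sample_id, cancer_type = d$cancer_type,
               time_norm = 1000 * d$time_days / mx, event = d$event,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Median split of anchor expression into high/low arms
#'
#' Samples at or below the median are labeled `"low"`; a fully constant
#' anchor yields all-low with a warning (no test possible downstream).
#'
#' @param anchorValues Named numeric vector of anchor expression (names =
#'   sample ids) over the analyzed sample set.
#' @return Named character vector `"high"`/`"low"`.
#' @export
stratifyByAnchor <- function(anchorValues) {
  med <- stats::median(anchorValues)
  lab <- ifelse(anchorValues > med, "high", "low")
  if (all(lab == "low"))
    warning("anchor expression constant: all samples labeled 'low'",
            call. = FALSE)
  nAt <- sum(anchorValues == med)
  if (nAt) apLog(nAt, " samples exactly at the anchor median -> 'low'")
  names(lab) <- names(anchorValues)
  lab
}

#' Kaplan-Meier product-limit curve
#'
#' @param times Follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return Data.frame over distinct event times: `time`, `n_risk`,
#'   `n_event`, `surv` (stepwise survival estimate).  With no events the
#'   curve is identically 1 (zero rows).
#' @export
kmEstimate <- function(times, events) {
  .assert(length(times) == length(events) && length(times) > 0,
          "times/events must be equal-length and non-empty")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
             n_event = fit$n.event[keep], surv = fit$surv[keep])
}

#' Survival probability of a K-M curve at a time point
#' @param curve A [kmEstimate()] result.
#' @param t Time point.
#' @return S(t).
#' @export
kmSurvAt <- function(curve, t) {
  if (!nrow(curve)) return(1)
  idx <- which(curve$time <= t)
  if (!length(idx)) 1 else curve$surv[max(idx)]
}

#' Two-sample log-rank test
#'
#' Standard log-rank: at each distinct event time the observed arm-A events
#' are compared with the hypergeometric expectation and variance;
#' `chisq = (O - E)^2 / V` is referred to the upper tail of chi-square(1).
#'
#' @param timesA,eventsA Arm A follow-up and event indicators.
#' @param timesB,eventsB Arm B follow-up and event indicators.
#' @return List with `chisq`, `df`, `p`, `observed` (length 2), `expected`
#'   (length 2).
#' @export
logrankTest <- function(timesA, eventsA, timesB, eventsB) {
  if (!length(timesA) || !length(timesB))
    stop("log-rank test needs two non-empty arms", call. = FALSE)
  if (sum(eventsA) + sum(eventsB) == 0) {
    warning("no events in either arm; log-rank p set to 1", call. = FALSE)
    return(list(chisq = 0, df = 1L, p = 1,
                observed = c(0, 0), expected = c(0, 0)))
  }
  time <- c(timesA, timesB)
  event <- c(eventsA, eventsB)
  arm <- factor(rep(c("A", "B"), c(length(timesA), length(timesB))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm)
  p <- as.numeric(pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
  list(chisq = as.numeric(sd$chisq), df = 1L, p = p,
       observed = as.numeric(sd$obs), expected = as.numeric(sd$exp))
}

## pooled anchor-stratified log-rank over a set of cancer types
.pooledLogrank <- function(surv, types) {
  d <- surv[surv$cancer_type %in% types, , drop = FALSE]
  lab <- stratifyByAnchor(setNames(d$anchor, d$sample_id))
  if (length(unique(lab)) < 2L)
    return(list(p = 1, chisq = 0, direction = NA_character_))
  hi <- lab == "high"
  lr <- logrankTest(d$time_norm[hi], d$event[hi],
                    d$time_norm[!hi], d$event[!hi])
  tMed <- stats::median(d$time_norm)
  sHigh <- kmSurvAt(kmEstimate(d$time_norm[hi], d$event[hi]), tMed)
  sLow <- kmSurvAt(kmEstimate(d$time_norm[!hi], d$event[!hi]), tMed)
  dir <- if (sHigh < sLow) "high_worse" else if (sHigh > sLow) "high_better"
         else "tied"
  list(p = lr$p, chisq = lr$chisq, direction = dir)
}

#' Greedy backward selection of cancer types against a log-rank objective
#'
#' Starting from all cancer types present in `surv`, the pooled
#' anchor-stratified log-rank p-value is computed (stratification by anchor
#' median within the pooled set, on per-type normalized times).  While the
#' pooled p is not below `alpha` and more than one type remains, the single
#' cancer type whose removal minimizes the pooled p is removed.  Every step
#' is recorded, together with the direction of the effect (which arm's K-M
#' curve lies lower at the pooled median follow-up).
#'
#' @param surv Data.frame with columns `sample_id`, `cancer_type`,
#'   `time_norm`, `event`, `anchor` (per-cohort standardized anchor
#'   expression).
#' @param alpha Significance threshold (default 0.05).
#' @param group Label stored in the trace.
#' @return List with `trace` (data.frame: step, removed, n_types, p,
#'   direction), `finalTypes`, `finalP`, `direction`, `significant`.
#' @export
backwardSelect <- function(surv, alpha = 0.05, group = "group") {
  types <- sort(unique(surv$cancer_type))
  if (!length(types)) stop("no cancer types to select over", call. = FALSE)
  cur <- .pooledLogrank(surv, types)
  trace <- data.frame(step = 0L, removed = NA_character_,
                      n_types = length(types), p = cur$p,
                      direction = cur$direction, stringsAsFactors = FALSE)
  step <- 0L
  while (cur$p >= alpha && length(types) > 1L) {
    step <- step + 1L
    cand <- vapply(types, function(tp)
      .pooledLogrank(surv, setdiff(types, tp))$p, 1.0)
    drop <- names(cand)[order(cand, names(cand))][[1L]]
    types <- setdiff(types, drop)
    cur <- .pooledLogrank(surv, types)
    trace <- rbind(trace, data.frame(step = step, removed = drop,
                                     n_types = length(types), p = cur$p,
                                     direction = cur$direction,
                                     stringsAsFactors = FALSE))
  }
  attr(trace, "group") <- group
  list(trace = trace, finalTypes = types, finalP = cur$p,
       direction = cur$direction, significant = cur$p < alpha)
}
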