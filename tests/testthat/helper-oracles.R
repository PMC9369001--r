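## Independent brute-force oracles used to check the package implementations.
## These are deliberately written from the textbook definitions, not by
## calling the code paths they verify.

## Pearson correlation from the definition
pearsonOracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

## Product-limit estimator by direct evaluation at distinct event times
productLimitOracle <- function(times, events) {
  et <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = numeric(), n_risk = numeric(),
                    n_event = numeric(), surv = numeric())
  for (t in et) {
    nRisk <- sum(times >= t)
    nEvent <- sum(times == t & events == 1)
    s <- s * (1 - nEvent / nRisk)
    out <- rbind(out, data.frame(time = t, n_risk = nRisk,
                                 n_event = nEvent, surv = s))
  }
  out
}

## Two-sample log-rank statistic by summing hypergeometric moments at each
## distinct event time
logrankOracle <- function(timesA, eventsA, timesB, eventsB) {
  times <- c(timesA, timesB)
  events <- c(eventsA, eventsB)
  inA <- rep(c(TRUE, FALSE), c(length(timesA), length(timesB)))
  et <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in et) {
    atRisk <- times >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & inA)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & inA)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

## Connected components by flood fill
floodFillOracle <- function(adj) {
  p <- nrow(adj)
  comp <- rep(NA_integer_, p)
  k <- 0L
  for (i in seq_len(p)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- k
      stack <- c(stack, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

## random sparse symmetric adjacency
randomAdjacency <- function(p, prob) {
  a <- matrix(runif(p * p) < prob, p, p)
  a[lower.tri(a, diag = TRUE)] <- FALSE
  a | t(a)
}

## tiny raw cohort from a numeric matrix
toyCohort <- function(values, label = "TOY", state = "raw") {
  CohortExpression(values, cancerType = label, transformState = state)
}
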