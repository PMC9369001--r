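## Core gene association networks: graphical-lasso refinement of the
## classifier's top features, connected-component clusters, reverse
## Cuthill-McKee band ordering, and chord/heatmap figure export.

#' Refine top-ranked genes into a core association network
#'
#' Computes the correlation matrix of the top-ranked genes within one
#' standardized cohort, tunes the graphical-lasso penalty to a target core
#' size with the same edge-incidence + weakest-edge top-up rule used for the
#' candidate selection, and builds the resulting network (adjacency, partial
#' correlation magnitudes, clusters, RCM ordering).
#'
#' @param topGenes Ranked gene symbols (e.g. the classifier's top 100).
#' @param cohort Standardized [CohortExpression-class].
#' @param target Core network size (default 50).
#' @param rfcTop Character vector flagged as the classifier's top importance
#'   genes (drives label hiding in the heatmap export); default: the first
#'   `target` entries of `topGenes`.
#' @param lambdaRange,maxIter Passed to [tuneLambdaToTarget()].
#' @return A [GeneNetwork-class] over exactly `target` genes.
#' @export
refineCoreGenes <- function(topGenes, cohort, target = 50L,
                            rfcTop = head(topGenes, target),
                            lambdaRange = c(1e-3, 1), maxIter = 40L) {
  .assert(transformState(cohort) == "standardized",
          "refineCoreGenes expects a standardized cohort")
  present <- intersect(topGenes, geneIDs(cohort))
  .assert(length(present) >= target, "fewer candidate genes than target")
  v <- exprValues(cohort)[present, , drop = FALSE]
  cc <- cor(t(v))
  if (target == length(present)) {
    ## identity refinement: keep all genes, network at the minimal penalty
    graph <- estimatePrecision(cc, lambdaRange[[1L]])
    sel <- present
    lambda <- lambdaRange[[1L]]
  } else {
    tuned <- tuneLambdaToTarget(cc, target, anchor = NULL,
                                lambdaRange = lambdaRange, maxIter = maxIter,
                                cohort = cancerType(cohort))
    graph <- tuned$graph
    sel <- tuned$set@genes
    lambda <- tuned$lambda
  }
  idx <- match(sel, graph@genes)
  th <- graph@theta[idx, idx, drop = FALSE]
  w <- abs(th); diag(w) <- 0
  adj <- w > graph@epsEdge
  dimnames(adj) <- dimnames(w) <- list(sel, sel)
  clusters <- extractClusters(adj)
  ord <- rcmOrder(adj)
  new("GeneNetwork", cohort = cancerType(cohort), genes = sel,
      adjacency = adj, weights = w, clusters = clusters,
      ordering = ord, topFlag = sel %in% rfcTop, lambda = lambda)
}

#' Connected-component clusters of an adjacency matrix or network
#'
#' @param x A [GeneNetwork-class] or a symmetric logical adjacency matrix.
#' @return List of integer node-index vectors, by decreasing component size
#'   (singletons are their own clusters).
#' @export
extractClusters <- function(x) {
  adj <- if (is(x, "GeneNetwork")) x@adjacency else x
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  comps <- split(seq_along(memb), memb)
  comps <- lapply(comps, as.integer)
  comps[order(-vapply(comps, length, 1L),
              vapply(comps, min, 1L))]
}

#' Reverse Cuthill-McKee node ordering
#'
#' Breadth-first ordering from a pseudo-peripheral minimum-degree start node
#' (George-Liu), visiting neighbors by increasing degree, with the final
#' order reversed; components are processed one after another so each is
#' contiguous in the result.  An edgeless graph keeps its input order.
#'
#' @param x A [GeneNetwork-class] or a symmetric logical adjacency matrix.
#' @return Integer permutation of the nodes.
#' @export
rcmOrder <- function(x) {
  adj <- if (is(x, "GeneNetwork")) x@adjacency else x
  p <- nrow(adj)
  deg <- rowSums(adj)
  if (all(deg == 0)) return(seq_len(p))
  nbrs <- lapply(seq_len(p), function(i) {
    nb <- which(adj[i, ])
    nb[order(deg[nb], nb)]
  })

  bfsLevels <- function(start, nodes) {
    lev <- rep(NA_integer_, p)
    lev[start] <- 0L
    frontier <- start
    l <- 0L
    while (length(frontier)) {
      l <- l + 1L
      nxt <- unique(unlist(nbrs[frontier]))
      nxt <- nxt[is.na(lev[nxt])]
      lev[nxt] <- l
      frontier <- nxt
    }
    lev
  }

  visited <- rep(FALSE, p)
  order <- integer(0)
  repeat {
    rest <- which(!visited)
    if (!length(rest)) break
    ## pseudo-peripheral start within this component
    r <- rest[which.min(deg[rest] + rest / (p + 1))]
    repeat {
      lev <- bfsLevels(r, rest)
      ecc <- max(lev, na.rm = TRUE)
      last <- which(lev == ecc)
      x2 <- last[order(deg[last], last)][[1L]]
      lev2 <- bfsLevels(x2, rest)
      if (max(lev2, na.rm = TRUE) > ecc) r <- x2 else break
    }
    ## Cuthill-McKee BFS from r
    comp <- integer(0)
    queue <- r
    seen <- visited
    seen[r] <- TRUE
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      comp <- c(comp, v)
      nb <- nbrs[[v]]
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    visited[comp] <- TRUE
    order <- c(order, comp)
  }
  rev(order)
}

#' Bandwidth of an adjacency pattern under a node ordering
#'
#' @param adj Symmetric logical adjacency matrix.
#' @param ordering Integer permutation (default: input order).
#' @return Maximum |position(i) - position(j)| over edges (0 if edgeless).
#' @export
matrixBandwidth <- function(adj, ordering = seq_len(nrow(adj))) {
  pos <- integer(nrow(adj))
  pos[ordering] <- seq_along(ordering)
  e <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (!nrow(e)) return(0L)
  as.integer(max(abs(pos[e[, 1L]] - pos[e[, 2L]])))
}

#' Export chord-style and heatmap figures of a gene network
#'
#' Writes a circos-style chord plot (nodes on a circle in RCM order, edges as
#' curved chords with width proportional to |partial correlation|) and a
#' heatmap of correlation magnitudes in RCM order.  On the heatmap gene
#' axis, labels are drawn only for genes flagged as classifier top-importance
#' genes.
#'
#' @param network A [GeneNetwork-class].
#' @param corrMatrix Correlation matrix over the network genes (for the
#'   heatmap); defaults to the network's weight matrix.
#' @param dir Output directory.
#' @param format `"png"` or `"svg"`.
#' @return Invisible character vector of the two file paths.
#' @export
exportFigures <- function(network, corrMatrix = NULL, dir = ".",
                          format = c("png", "svg")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- length(network@genes)
  ord <- network@ordering
  genes <- network@genes[ord]
  theta <- 2 * pi * (seq_len(p) - 0.5) / p
  xy <- cbind(cos(theta), sin(theta))

  open <- function(f) {
    if (format == "png") grDevices::png(f, width = 900, height = 900)
    else grDevices::svg(f, width = 9, height = 9)
  }
  chordFile <- file.path(dir, sprintf("%s_chord.%s", network@cohort, format))
  open(chordFile)
  graphics::par(mar = c(1, 1, 2, 1))
  graphics::plot(NA, xlim = c(-1.35, 1.35), ylim = c(-1.35, 1.35),
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("%s core gene network (RCM order)",
                                network@cohort))
  pos <- integer(p); pos[ord] <- seq_len(p)
  e <- which(network@adjacency & upper.tri(network@adjacency), arr.ind = TRUE)
  if (nrow(e)) {
    wmax <- max(network@weights[e])
    for (k in seq_len(nrow(e))) {
      i <- pos[e[k, 1L]]; j <- pos[e[k, 2L]]
      w <- network@weights[e[k, 1L], e[k, 2L]]
      cx <- (xy[i, 1] + xy[j, 1]) / 4
      cy <- (xy[i, 2] + xy[j, 2]) / 4
      graphics::xspline(c(xy[i, 1], cx, xy[j, 1]),
                        c(xy[i, 2], cy, xy[j, 2]), shape = 1,
                        border = grDevices::adjustcolor("steelblue", 0.6),
                        lwd = 0.5 + 3 * w / wmax)
    }
  }
  graphics::points(xy, pch = 19, cex = 0.7,
                   col = ifelse(network@topFlag[ord], "firebrick", "grey40"))
  graphics::text(1.15 * xy, labels = genes, cex = 0.55,
                 srt = 0, xpd = NA)
  grDevices::dev.off()

  if (is.null(corrMatrix)) corrMatrix <- network@weights
  cm <- abs(corrMatrix[ord, ord])
  heatFile <- file.path(dir, sprintf("%s_heatmap.%s", network@cohort, format))
  open(heatFile)
  graphics::par(mar = c(6, 6, 2, 1))
  graphics::image(seq_len(p), seq_len(p), t(cm[p:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = sprintf("%s |correlation|, RCM order", network@cohort))
  show <- network@topFlag[ord]
  graphics::axis(1, at = which(show), labels = genes[show], las = 2,
                 cex.axis = 0.5, tick = FALSE)
  graphics::axis(2, at = p + 1 - which(show), labels = genes[show], las = 2,
                 cex.axis = 0.5, tick = FALSE)
  grDevices::dev.off()

  invisible(c(chord = chordFile, heatmap = heatFile))
}

#' Write a network's edge list, clusters and ordering as TSVs
#' @param network A [GeneNetwork-class].
#' @param dir Output directory.
#' @return Invisible character vector of file paths.
#' @export
writeNetwork <- function(network, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  e <- which(network@adjacency & upper.tri(network@adjacency), arr.ind = TRUE)
  edges <- data.frame(gene_i = network@genes[e[, 1L]],
                      gene_j = network@genes[e[, 2L]],
                      weight = network@weights[e])
  f1 <- file.path(dir, sprintf("%s_edges.tsv", network@cohort))
  write.table(edges[order(edges$gene_i, edges$gene_j), ], f1, sep = "\t",
              quote = FALSE, row.names = FALSE)
  cl <- data.frame(
    gene = network@genes[unlist(network@clusters)],
    cluster = rep(seq_along(network@clusters),
                  vapply(network@clusters, length, 1L)))
  f2 <- file.path(dir, sprintf("%s_clusters.tsv", network@cohort))
  write.table(cl, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  f3 <- file.path(dir, sprintf("%s_ordering.tsv", network@cohort))
  write.table(data.frame(position = seq_along(network@ordering),
                         gene = network@genes[network@ordering]),
              f3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(edges = f1, clusters = f2, ordering = f3))
}
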