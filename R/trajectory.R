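#' @include AllClasses.R
NULL

#' PCA embedding and union-kNN graph
#'
#' Individuals are embedded by principal components (all components are
#' kept, so pairwise distances equal those of the centred input) and
#' connected to their nearest neighbours; the graph is the symmetric
#' union of the directed kNN relations, unweighted. Following the
#' convention of single-cell neighbourhood graphs, `nNeighbors` counts
#' the individual itself, so the minimum useful value 2 links each
#' individual to exactly one other.
#'
#' @param X features x individuals matrix (centred expression on the
#'   relevant gene-set union).
#' @param nNeighbors neighbourhood size including self (default 2, the
#'   minimum that still yields a non-redundant graph).
#' @return symmetric logical adjacency matrix over individuals.
#' @export
embedAndKnn <- function(X, nNeighbors = 2) {
  X <- as.matrix(X)
  n <- ncol(X)
  k <- nNeighbors - 1
  if (k < 1) stop("nNeighbors must be at least 2")
  if (n < nNeighbors) stop("need at least nNeighbors individuals")
  if (all(apply(X, 1, stats::sd) == 0))
    stop("degenerate input: all features constant")
  emb <- stats::prcomp(t(X), center = TRUE, scale. = FALSE)$x
  D <- as.matrix(stats::dist(emb))
  adj <- matrix(FALSE, n, n, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(n)) {
    nb <- order(D[i, -i])[seq_len(k)]
    nb <- seq_len(n)[-i][nb]
    adj[i, nb] <- TRUE
  }
  adj | t(adj)
}

#' Partition connectivity confidences
#'
#' For partitions i, j with `e_ij` observed inter-partition edges and
#' `E` total inter-partition edges, the expected count under uniform
#' placement of the E edges over unordered partition pairs is
#' `E n_i n_j / sum_{k<l} n_k n_l`; the connection confidence is
#' `min(1, e_ij / expected)`, 0 when no edge crosses the pair. This is
#' the partition-based graph-abstraction statistic in its simplest form;
#' any external implementation producing a symmetric confidence matrix
#' can be substituted through the [PartitionGraph-class] interface.
#'
#' @param adj symmetric logical adjacency matrix (from [embedAndKnn()]).
#' @param labels named character of partition (substage) labels per
#'   individual; every level must be non-empty.
#' @param nodes optional node order (defaults to sorted unique labels).
#' @return a [PartitionGraph-class].
#' @export
partitionConnectivity <- function(adj, labels, nodes = NULL) {
  labels <- labels[rownames(adj)]
  if (anyNA(labels)) stop("every individual needs a partition label")
  if (is.null(nodes)) nodes <- sort(unique(labels))
  if (!all(labels %in% nodes)) stop("labels outside the node set")
  sizes <- vapply(nodes, function(nd) sum(labels == nd), numeric(1))
  if (any(sizes == 0)) stop("empty partition(s): ",
                            paste(nodes[sizes == 0], collapse = ", "))
  k <- length(nodes)
  eObs <- matrix(0, k, k, dimnames = list(nodes, nodes))
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    a <- labels[idx[r, 1]]; b <- labels[idx[r, 2]]
    if (a != b) {
      eObs[a, b] <- eObs[a, b] + 1
      eObs[b, a] <- eObs[b, a] + 1
    }
  }
  E <- sum(eObs[upper.tri(eObs)])
  pairWeight <- outer(sizes, sizes)
  totalW <- sum(pairWeight[upper.tri(pairWeight)])
  conf <- matrix(0, k, k, dimnames = list(nodes, nodes))
  if (E > 0) {
    expected <- E * pairWeight / totalW
    conf <- ifelse(eObs > 0, pmin(1, eObs / expected), 0)
  }
  diag(conf) <- 0
  PartitionGraph(nodes, conf)
}

#' Prune a partition graph at twice the NCI-AD ceiling
#'
#' `md_na` is the maximum confidence over all NCI-substage x AD-substage
#' pairs; only edges with confidence strictly greater than `2 * md_na`
#' survive. Direct NCI-AD edges therefore never survive when
#' `md_na > 0`. In the limit `md_na = 0` all positive edges are kept.
#'
#' @param pg a [PartitionGraph-class].
#' @param stageMap named character mapping each node to its clinical
#'   stage (NCI/MCI/AD).
#' @param multiplier pruning multiplier (default 2).
#' @return pruned [PartitionGraph-class]; the threshold is attached as
#'   attribute `mdNA`.
#' @export
pruneGraph <- function(pg, stageMap, multiplier = 2) {
  if (!all(pg@nodes %in% names(stageMap)))
    stop("stage map must cover all nodes")
  st <- stageMap[pg@nodes]
  w <- pg@weights
  nci <- pg@nodes[st == "NCI"]; ad <- pg@nodes[st == "AD"]
  mdNA <- if (length(nci) && length(ad)) max(w[nci, ad, drop = FALSE]) else 0
  keep <- if (mdNA > 0) w > multiplier * mdNA else w > 0
  w[!keep] <- 0
  out <- PartitionGraph(pg@nodes, w)
  attr(out, "mdNA") <- mdNA
  out
}

#' Intersect two partition graphs
#'
#' Edges present in both graphs survive with the smaller of the two
#' confidences.
#'
#' @param a,b [PartitionGraph-class] objects over the same node set.
#' @return a [PartitionGraph-class].
#' @export
intersectGraphs <- function(a, b) {
  if (!setequal(a@nodes, b@nodes)) stop("node sets differ")
  wb <- b@weights[a@nodes, a@nodes]
  w <- pmin(a@weights, wb)
  w[a@weights == 0 | wb == 0] <- 0
  PartitionGraph(a@nodes, w)
}

#' Orient edges along the clinical stage order
#'
#' Cross-stage edges point from the lower-ranked to the higher-ranked
#' stage (NCI < MCI < AD); same-stage edges stay undirected.
#'
#' @param pg a [PartitionGraph-class].
#' @param stageMap named character node -> stage.
#' @return data.frame (from, to, weight, directed).
#' @export
orientGraph <- function(pg, stageMap) {
  if (!all(pg@nodes %in% names(stageMap)))
    stop("stage map must cover all nodes")
  rank <- c(NCI = 1, MCI = 2, AD = 3)
  e <- graphEdges(pg)
  if (!nrow(e)) return(cbind(e, directed = logical(0)))
  rFrom <- rank[stageMap[e$from]]; rTo <- rank[stageMap[e$to]]
  swap <- rFrom > rTo
  tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
  e$directed <- rFrom != rTo
  e
}

#' Substage adjacency network from a gene-set union
#'
#' Convenience wrapper: centred expression on the union of two gene sets,
#' PCA + union-kNN, partition connectivity over the substage labels.
#'
#' @param cohort an [ExpressionCohort-class].
#' @param setA,setB [GeneSetRecord-class] objects (e.g. M-NA and N-A1).
#' @param labels named substage labels per individual.
#' @param nNeighbors kNN parameter (default 2).
#' @return a [PartitionGraph-class].
#' @export
substageNetwork <- function(cohort, setA, setB, labels, nNeighbors = 2) {
  genes <- union(geneIds(setA), geneIds(setB))
  X <- centerLogExpression(tpm(cohort))[genes, , drop = FALSE]
  adj <- embedAndKnn(X, nNeighbors = nNeighbors)
  partitionConnectivity(adj, labels)
}
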