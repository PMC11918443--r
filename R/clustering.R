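#' @include AllClasses.R stats.R fisher.R
NULL

#' Correlation distance between individuals
#'
#' `d(i, j) = 1 - Pearson(column_i, column_j)` over the feature rows.
#' A constant column cannot carry correlation information; its
#' correlations are set to 0 (distance 1) with a warning.
#'
#' @param X features x individuals matrix (>= 2 features).
#' @return symmetric distance matrix with zero diagonal, values in [0, 2].
#' @export
correlationDistance <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 features per individual")
  sds <- apply(X, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(X))
  if (any(sds == 0)) {
    warning("constant column(s); correlations set to 0 (distance 1)")
    cc[sds == 0, ] <- 0
    cc[, sds == 0] <- 0
  }
  d <- 1 - cc
  diag(d) <- 0
  d
}

#' Group-average (UPGMA) hierarchical clustering
#'
#' Average-linkage agglomeration over a precomputed distance matrix.
#'
#' @param d symmetric distance matrix or `dist` object.
#' @return an [stats::hclust] tree.
#' @export
averageLinkage <- function(d) {
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  if (anyNA(d) || any(!is.finite(d))) stop("distances must be finite")
  if (attr(d, "Size") < 2) stop("need at least 2 leaves to cluster")
  stats::hclust(d, method = "average")
}

#' First-branch split of a dendrogram
#'
#' The two subtrees of the root. The side containing the
#' lexicographically smallest leaf id is reported first.
#'
#' @param hc an [stats::hclust] tree.
#' @return list of two character vectors of leaf ids.
#' @export
firstBranchSplit <- function(hc) {
  ct <- stats::cutree(hc, k = 2)
  a <- names(ct)[ct == 1]; b <- names(ct)[ct == 2]
  if (min(b) < min(a)) list(b, a) else list(a, b)
}

#' Cut a dendrogram into k clusters
#'
#' Cuts the k - 1 highest merges.
#'
#' @param hc an [stats::hclust] tree.
#' @param k number of clusters, 1 <= k <= n.
#' @return named integer vector of cluster indices per leaf.
#' @export
cutK <- function(hc, k) {
  n <- length(hc$labels)
  if (k < 1 || k > n) stop("k must lie in [1, n]")
  stats::cutree(hc, k = k)
}

#' Enrichment criterion for a first-branch cluster
#'
#' A cluster counts as the group-g-enriched cluster when it (i) contains
#' strictly more than 2/3 of the individuals of group g and (ii) a
#' two-sided 2 x 2 Fisher exact test of cluster membership against group
#' membership gives p < 0.05.
#'
#' @param members ids inside the cluster.
#' @param labels named character of group labels for all individuals.
#' @param group the group tested for enrichment.
#' @return list with `passes`, `p`, `inCluster` (count of g members inside).
#' @export
enrichedClusterTest <- function(members, labels, group) {
  nG <- sum(labels == group)
  if (nG == 0) stop("group '", group, "' is empty")
  if (anyNA(labels[members])) stop("labels unknown for some members")
  inG <- sum(labels[members] == group)
  outCl <- setdiff(names(labels), members)
  tab <- rbind(c(inG, length(members) - inG),
               c(nG - inG, sum(labels[outCl] != group)))
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
       else fisherExact2x2(tab)
  list(passes = (inG > 2 / 3 * nG) && (p < 0.05), p = p, inCluster = inG)
}

# ---------------------------------------------------------------------------
# k-means with elbow selection
# ---------------------------------------------------------------------------

# maximal-second-difference elbow over an SSE curve; ties -> smallest k;
# a flat/convex curve (no positive curvature anywhere) means no elbow at
# all, i.e. the smallest k
.elbowK <- function(ks, sse) {
  if (length(ks) == 1) return(ks)
  if (length(ks) == 2) return(ks[which.min(sse)])
  d2 <- sse[seq_len(length(ks) - 2)] - 2 * sse[seq(2, length(ks) - 1)] +
    sse[seq(3, length(ks))]
  if (max(d2) <= 0) return(ks[1])
  ks[which.max(d2) + 1]
}

# k-means++ seeding (deterministic under the current RNG state)
.kmeansppCenters <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[idx[1], ])^2)
  if (k > 1) for (i in 2:k) {
    idx[i] <- if (sum(d2) == 0) sample.int(n, 1)
      else sample.int(n, 1, prob = d2)
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[i], ])^2))
  }
  X[idx, , drop = FALSE]
}

.kmeansBest <- function(X, k, nInit) {
  best <- NULL
  for (i in seq_len(nInit)) {
    C <- .kmeansppCenters(X, k)
    C <- C + stats::rnorm(length(C), sd = 1e-9)  # break duplicate centers
    fit <- suppressWarnings(stats::kmeans(X, centers = C, iter.max = 100))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' k-means clustering with elbow selection of k
#'
#' For each k in `kRange` runs best-of-`nInit` k-means with k-means++
#' seeding; the selected `k*` maximises the second difference
#' `SSE(k-1) - 2 SSE(k) + SSE(k+1)` over interior k. For k at or above the
#' number of distinct points the SSE is 0 by definition.
#'
#' @param data matrix (observations in rows) or numeric vector.
#' @param kRange candidate k values (default 1:6, truncated to n).
#' @param seed RNG seed for reproducible restarts.
#' @param nInit restarts per k (default 50).
#' @return list with `k` (selected), `cluster` (named assignment at k*),
#'   `sse` (named SSE curve over `kRange`).
#' @export
kmeansWithElbow <- function(data, kRange = 1:6, seed = 1, nInit = 50) {
  X <- as.matrix(data)
  n <- nrow(X)
  if (n < max(kRange)) stop("fewer observations than max(kRange)")
  distinct <- nrow(unique(X))
  sse <- numeric(length(kRange))
  fits <- vector("list", length(kRange))
  set.seed(seed)
  for (i in seq_along(kRange)) {
    k <- kRange[i]
    if (k == 1) {
      sse[i] <- sum(sweep(X, 2, colMeans(X))^2)
      fits[[i]] <- rep(1L, n)
    } else if (k >= distinct) {
      grp <- match(apply(X, 1, paste, collapse = "\r"),
                   unique(apply(X, 1, paste, collapse = "\r")))
      sse[i] <- 0
      fits[[i]] <- as.integer(grp)
    } else {
      fit <- .kmeansBest(X, k, nInit)
      sse[i] <- fit$tot.withinss
      fits[[i]] <- fit$cluster
    }
  }
  kStar <- .elbowK(kRange, sse)
  cl <- fits[[match(kStar, kRange)]]
  names(cl) <- rownames(X)
  names(sse) <- kRange
  list(k = kStar, cluster = cl, sse = sse)
}

#' Export a dendrogram as a Newick string
#'
#' Merge heights become branch lengths.
#'
#' @param hc an [stats::hclust] tree.
#' @return single Newick-format character string.
#' @export
dendrogramNewick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
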