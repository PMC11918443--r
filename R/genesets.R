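#' @include AllClasses.R stats.R clustering.R
NULL

#' Directional gene selection at a threshold pair
#'
#' Selects genes whose mean is higher in the second compared group with
#' p <= pUp, together with genes whose mean is lower with p <= pDown.
#' Thresholds are inclusive.
#'
#' @param results a pairwise [testResultTable()].
#' @param pUp,pDown p-value thresholds for up-/down-regulated genes
#'   (relative to the second group).
#' @return data.frame (gene, direction, p) of selected genes, ordered by p.
#' @export
directionalSelect <- function(results, pUp, pDown) {
  sel <- (results$direction == "up" & results$p <= pUp) |
    (results$direction == "down" & results$p <= pDown)
  out <- results[sel, c("gene", "direction", "p")]
  out[order(out$p, out$gene), ]
}

# cluster the cohort individuals belonging to `groups` on gene set `genes`
# and evaluate the first-branch split + per-group enrichment
.clusterCell <- function(X, labels, genes) {
  if (length(genes) < 2)
    return(list(split = NULL, enrich = NULL))
  d <- suppressWarnings(correlationDistance(X[genes, , drop = FALSE]))
  hc <- averageLinkage(d)
  split <- firstBranchSplit(hc)
  groups <- unique(labels)
  enrich <- lapply(groups, function(g) {
    for (side in 1:2) {
      r <- enrichedClusterTest(split[[side]], labels, g)
      if (r$passes)
        return(list(passes = TRUE, p = r$p, side = side,
                    members = split[[side]]))
    }
    list(passes = FALSE, p = NA_real_, side = NA_integer_,
         members = character())
  })
  names(enrich) <- groups
  list(split = split, enrich = enrich)
}

# shared grid scanner: for each cell select genes, cluster, record split +
# enrichment. `grid` is a data.frame with pUp/pDown (pairwise) or p
# (omnibus).
.scanGrid <- function(cohort, groups, backend, grid, results = NULL) {
  st <- stageLabels(cohort)
  keep <- names(st)[st %in% groups]
  labels <- st[keep]
  if (is.null(results)) results <- testResultTable(cohort, groups, backend)
  X <- centerLogExpression(tpm(cohort)[, keep, drop = FALSE])
  omnibus <- length(groups) == 3
  ncell <- nrow(grid)
  sets <- splits <- enrich <- vector("list", ncell)
  cells <- grid
  cells$nUp <- cells$nDown <- cells$nGenes <- 0L
  cells$separating <- FALSE
  for (i in seq_len(ncell)) {
    if (omnibus) {
      sel <- results[results$p <= grid$p[i], c("gene", "direction", "p")]
    } else {
      sel <- directionalSelect(results, grid$pUp[i], grid$pDown[i])
    }
    sets[[i]] <- sel$gene
    cells$nGenes[i] <- nrow(sel)
    cells$nUp[i] <- sum(sel$direction == "up")
    cells$nDown[i] <- sum(sel$direction == "down")
    cl <- .clusterCell(X, labels, sel$gene)
    splits[[i]] <- cl$split
    enrich[[i]] <- cl$enrich
    if (!omnibus && !is.null(cl$split)) {
      g1 <- names(labels)[labels == groups[1]]
      g2 <- names(labels)[labels == groups[2]]
      cells$separating[i] <-
        (setequal(cl$split[[1]], g1) && setequal(cl$split[[2]], g2)) ||
        (setequal(cl$split[[1]], g2) && setequal(cl$split[[2]], g1))
    }
  }
  methods::new("PhaseDiagram", groups = groups, backend = backend,
               cells = cells, sets = sets, splits = splits, enrich = enrich)
}

#' Complete-separation phase diagram over a threshold grid
#'
#' For every cell of the `(pUp, pDown)` grid: build the directional gene
#' set, centre-log the two groups' individuals on those genes, cluster
#' with correlation distance and group-average linkage, and flag the cell
#' as separating when the first dendrogram branch splits the individuals
#' exactly into the two clinical groups. Only the two compared groups'
#' individuals enter the clustering. An empty gene set never separates.
#'
#' @param cohort an [ExpressionCohort-class].
#' @param groups two stage names, e.g. `c("NCI", "AD")`.
#' @param pUp,pDown threshold vectors spanning the grid (all pairs are
#'   scanned).
#' @param backend `"tpm"` or `"counts"` (see [testResultTable()]).
#' @param results optional precomputed [testResultTable()] to reuse.
#' @return a [PhaseDiagram-class].
#' @export
separationScan <- function(cohort, groups, pUp = seq(0.01, 0.05, 0.01),
                           pDown = pUp, backend = "tpm", results = NULL) {
  if (length(groups) != 2) stop("separationScan compares exactly 2 groups")
  grid <- expand.grid(pUp = pUp, pDown = pDown, KEEP.OUT.ATTRS = FALSE)
  .scanGrid(cohort, groups, backend, grid, results)
}

#' Omnibus scan over scalar thresholds
#'
#' Grid version of the three-group (NCI/MCI/AD) clustering: at each scalar
#' threshold P, genes with omnibus-test p <= P are used to cluster ALL
#' individuals; the first-branch split and per-group enrichment are
#' recorded (feeding [stableMembers()]).
#'
#' @param cohort an [ExpressionCohort-class].
#' @param p scalar thresholds (default 0.01..0.05).
#' @param backend `"tpm"` (ANOVA) or `"counts"`.
#' @return a [PhaseDiagram-class].
#' @export
omnibusScan <- function(cohort, p = seq(0.01, 0.05, 0.01), backend = "tpm") {
  grid <- data.frame(p = p)
  .scanGrid(cohort, .STAGES, backend, grid)
}

#' Largest completely separating gene set in a phase diagram
#'
#' Among separating cells the one with the maximal gene count; ties go to
#' the smallest `(pUp, pDown)` lexicographically. If no cell separates, a
#' zero-gene record with rule `"none found"` is returned.
#'
#' @param diagram a [PhaseDiagram-class] from [separationScan()].
#' @param name name for the resulting [GeneSetRecord-class].
#' @param by rank cells by total gene count (`"genes"`, default) or by
#'   down-regulated gene count (`"down"`).
#' @return a [GeneSetRecord-class].
#' @export
largestSeparatingSet <- function(diagram, name = "N-A", by = "genes") {
  by <- match.arg(by, c("genes", "down"))
  cells <- diagram@cells
  idx <- which(cells$separating)
  if (!length(idx))
    return(GeneSetRecord(name, character(), backend = diagram@backend,
                         rule = "none found"))
  score <- if (by == "genes") cells$nGenes[idx] else cells$nDown[idx]
  ord <- order(-score, cells$pUp[idx], cells$pDown[idx])
  best <- idx[ord[1]]
  genes <- diagram@sets[[best]]
  # re-derive directions from the winning cell's thresholds
  GeneSetRecord(name, genes,
                backend = diagram@backend,
                thresholds = c(pUp = cells$pUp[best],
                               pDown = cells$pDown[best]),
                rule = sprintf("largest separating cell (%s) of %s grid",
                               by, paste(diagram@groups, collapse = "-")))
}

#' Stable cluster members across a grid of diagrams
#'
#' Across every cell (of every supplied diagram) where the group-g-enriched
#' first-branch cluster exists, the always-in members are the individuals
#' of g inside that cluster in EVERY such cell; the remaining g individuals
#' are the deviators.
#'
#' @param diagrams list of [PhaseDiagram-class] objects (e.g. the omnibus
#'   scans of both backends).
#' @param group the group, e.g. `"MCI"`.
#' @param labels named character of group labels (taken from the first
#'   diagram's enrich records if omitted is not possible; supply the cohort
#'   stages).
#' @return list with `stable` and `deviators` (character id vectors) and
#'   `nCells` (number of contributing cells).
#' @export
stableMembers <- function(diagrams, group, labels) {
  members <- names(labels)[labels == group]
  stable <- members
  nCells <- 0L
  for (dg in diagrams) for (e in dg@enrich) {
    if (is.null(e) || is.null(e[[group]]) || !isTRUE(e[[group]]$passes)) next
    nCells <- nCells + 1L
    stable <- intersect(stable, e[[group]]$members)
  }
  if (nCells == 0L)
    stop("no grid cell produced an enriched cluster for group '", group, "'")
  list(stable = stable, deviators = setdiff(members, stable),
       nCells = nCells)
}

#' Grow a gene set by a p-ranked prefix under complete separation
#'
#' Returns `base UNION prefix(m*)` of the candidate genes (sorted by
#' ascending p), where m* is the largest prefix length whose union still
#' completely separates the two groups at the first dendrogram branch;
#' m is scanned from all candidates down to 0. The separation of the
#' returned set is re-verified.
#'
#' @param base a [GeneSetRecord-class] (or character vector of gene ids).
#' @param candidates data.frame (gene, p) or character vector already in
#'   ascending-p order.
#' @param cohort an [ExpressionCohort-class].
#' @param groups the two compared stages.
#' @param name name of the resulting record.
#' @return a [GeneSetRecord-class]; zero genes with rule "none found" if
#'   even m = 0 fails.
#' @export
unionWithSeparation <- function(base, candidates, cohort, groups,
                                name = "union") {
  baseGenes <- if (methods::is(base, "GeneSetRecord")) geneIds(base) else base
  cand <- if (is.data.frame(candidates)) {
    candidates$gene[order(candidates$p)]
  } else as.character(candidates)
  cand <- setdiff(cand, baseGenes)
  st <- stageLabels(cohort)
  keep <- names(st)[st %in% groups]
  labels <- st[keep]
  X <- centerLogExpression(tpm(cohort)[, keep, drop = FALSE])
  g1 <- keep[labels == groups[1]]; g2 <- keep[labels == groups[2]]
  separates <- function(genes) {
    cl <- .clusterCell(X, labels, genes)
    if (is.null(cl$split)) return(FALSE)
    (setequal(cl$split[[1]], g1) && setequal(cl$split[[2]], g2)) ||
      (setequal(cl$split[[1]], g2) && setequal(cl$split[[2]], g1))
  }
  for (m in rev(0:length(cand))) {
    genes <- union(baseGenes, cand[seq_len(m)])
    if (separates(genes)) {
      stopifnot(separates(genes))  # postcondition re-verification
      return(GeneSetRecord(name, genes,
                           rule = sprintf("base (%d) + %d of %d candidates",
                                          length(baseGenes), m,
                                          length(cand))))
    }
  }
  GeneSetRecord(name, character(), rule = "none found")
}

#' Discover AD subgroups and the CA/CB gene clusters
#'
#' (1) The AD-only dendrogram on the NCI-vs-AD gene set is cut into three
#' subgroups. (2) One-way ANOVA across the subgroups over the set's
#' up-in-AD genes, BH FDR < `fdr`. (3) k-means (with elbow selection) of
#' the significant genes' standardised AD expression profiles. (4) Each
#' gene cluster is typed from its size-ordered per-subgroup centroid
#' `m(1) <= m(2) <= m(3)`: deviant-low (CA-like) when
#' `m(2) - m(1) > 0.5 (m(3) - m(1))`; deviant-high (CB-like) when
#' `m(3) - m(2) > 0.5 (m(3) - m(1))`. (5) Subgroups are labelled from the
#' CA/CB cluster means: HH = high in CA and CB, LL = low in both,
#' HL = high in CA, low in CB.
#'
#' @param cohort an [ExpressionCohort-class].
#' @param naSet a [GeneSetRecord-class] separating NCI from AD, with
#'   direction labels.
#' @param fdr FDR level for the subgroup ANOVA (default 0.1).
#' @param kRange candidate k for the gene k-means.
#' @param seed RNG seed for k-means restarts.
#' @return list with `subgroups` (named labels HH/LL/HL per AD individual),
#'   `caGenes`, `cbGenes`, `k`, `nSignificant`, `assignments` (raw subgroup
#'   index). When fewer than 2 genes are significant the list carries
#'   `insufficient = TRUE` and empty gene clusters.
#' @export
adSubgroupDiscovery <- function(cohort, naSet, fdr = 0.1, kRange = 1:6,
                                seed = 1) {
  st <- stageLabels(cohort)
  adIds <- names(st)[st == "AD"]
  if (length(adIds) < 6) stop("need at least 6 AD individuals")
  genes <- geneIds(naSet)
  X <- centerLogExpression(tpm(cohort)[, adIds, drop = FALSE])
  hc <- averageLinkage(correlationDistance(X[genes, , drop = FALSE]))
  sub <- cutK(hc, 3)
  upGenes <- genes[geneDirections(naSet)[genes] == "up"]
  vals <- tpm(cohort)[upGenes, adIds, drop = FALSE]
  r <- .rowAnova(vals, factor(sub[adIds]))
  q <- bhFdr(r$p, alpha = fdr)
  sig <- upGenes[q$reject]
  subLevels0 <- sort(unique(sub))
  ord0 <- order(-table(factor(sub, levels = subLevels0)), subLevels0)
  lab0 <- setNames(c("HH", "LL", "HL"), subLevels0[ord0])
  none <- list(subgroups = setNames(lab0[as.character(sub[adIds])], adIds),
               caGenes = character(), cbGenes = character(), k = NA_integer_,
               nSignificant = length(sig), assignments = sub,
               insufficient = TRUE)
  if (length(sig) < 2) return(none)
  # standardised AD profiles of significant genes
  Z <- X[sig, , drop = FALSE]
  Z <- (Z - rowMeans(Z)) / pmax(apply(Z, 1, stats::sd), 1e-12)
  km <- kmeansWithElbow(Z, kRange = kRange[kRange <= nrow(Z)], seed = seed)
  caGenes <- cbGenes <- character()
  subLevels <- sort(unique(sub))
  centroidBySub <- function(genes) {
    vapply(subLevels, function(s)
      mean(Z[genes, adIds[sub[adIds] == s], drop = FALSE]), numeric(1))
  }
  for (cl in unique(km$cluster)) {
    g <- sig[km$cluster == cl]
    m <- sort(centroidBySub(g))
    rng <- m[3] - m[1]
    if (rng <= 0) next
    if (m[2] - m[1] > 0.5 * rng) caGenes <- c(caGenes, g)
    else if (m[3] - m[2] > 0.5 * rng) cbGenes <- c(cbGenes, g)
  }
  if (!length(caGenes) || !length(cbGenes)) {
    # no CA/CB pair: keep the size-ordered fallback labels; the
    # `insufficient` flag marks the result as weak
    none$caGenes <- caGenes; none$cbGenes <- cbGenes; none$k <- km$k
    return(none)
  }
  # assign HH/LL/HL by best permutation match of the normalised
  # (CA mean, CB mean) profile against the canonical patterns
  ca <- centroidBySub(caGenes); cb <- centroidBySub(cbGenes)
  norm01 <- function(v) if (diff(range(v)) == 0) rep(0.5, length(v))
    else (v - min(v)) / diff(range(v))
  prof <- cbind(norm01(ca), norm01(cb))
  canon <- rbind(HH = c(1, 1), LL = c(0, 0), HL = c(1, 0))
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  cost <- vapply(perms, function(p) sum((prof - canon[p, ])^2), numeric(1))
  lab <- setNames(rownames(canon)[perms[[which.min(cost)]]], subLevels)
  subgroups <- setNames(lab[as.character(sub[adIds])], adIds)
  list(subgroups = subgroups, caGenes = caGenes, cbGenes = cbGenes,
       k = km$k, nSignificant = length(sig), assignments = sub,
       insufficient = FALSE)
}
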