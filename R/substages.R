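#' @include AllClasses.R genesets.R
NULL

#' Per-individual deviation counts across a pairwise threshold grid
#'
#' For a stage pair (A, B), scans the `(pUp, pDown)` grid with both test
#' backends. A grid cell is valid only when both the A-enriched and the
#' B-enriched first-branch clusters pass [enrichedClusterTest()]. In every
#' valid cell, an A individual sitting inside the B-enriched cluster
#' deviates toward B (and vice versa); the counts accumulate over cells
#' and backends.
#'
#' @param cohort an [ExpressionCohort-class].
#' @param pair two stage names, e.g. `c("NCI", "MCI")`.
#' @param pUp,pDown grid thresholds (default 0.01..0.05 each).
#' @param backends test backends scanned (default both).
#' @return list with `towardSecond` (named counts for pair[1] individuals
#'   deviating into the pair[2] cluster), `towardFirst` (the reverse),
#'   `nValidCells`, and the underlying diagrams.
#' @export
deviationCounts <- function(cohort, pair, pUp = seq(0.01, 0.05, 0.01),
                            pDown = pUp, backends = c("tpm", "counts")) {
  st <- stageLabels(cohort)
  idsA <- names(st)[st == pair[1]]
  idsB <- names(st)[st == pair[2]]
  towardB <- setNames(integer(length(idsA)), idsA)
  towardA <- setNames(integer(length(idsB)), idsB)
  nValid <- 0L
  diagrams <- list()
  for (bk in backends) {
    dg <- separationScan(cohort, pair, pUp = pUp, pDown = pDown,
                         backend = bk)
    diagrams[[bk]] <- dg
    for (e in dg@enrich) {
      if (is.null(e)) next
      eA <- e[[pair[1]]]; eB <- e[[pair[2]]]
      if (!isTRUE(eA$passes) || !isTRUE(eB$passes)) next
      nValid <- nValid + 1L
      devA <- intersect(idsA, eB$members)
      devB <- intersect(idsB, eA$members)
      towardB[devA] <- towardB[devA] + 1L
      towardA[devB] <- towardA[devB] + 1L
    }
  }
  if (nValid == 0L)
    stop("no valid grid cell: enriched clusters never formed for both ",
         pair[1], " and ", pair[2])
  list(towardSecond = towardB, towardFirst = towardA,
       nValidCells = nValid, diagrams = diagrams)
}

# label k-means clusters of 1-D deviation counts: near-zero centroid ->
# baseline label, others -> deviating label
.labelByCentroid1d <- function(counts, km, baseline, deviating,
                               nearZero = 0.5) {
  lab <- setNames(rep(baseline, length(counts)), names(counts))
  for (cl in unique(km$cluster)) {
    cen <- mean(counts[km$cluster == cl])
    if (cen >= nearZero) lab[names(km$cluster)[km$cluster == cl]] <- deviating
  }
  lab
}

#' Classify MCI individuals into detailed substages
#'
#' Individuals flagged as deviators by [stableMembers()] become
#' `MCI_NCI_AD`. The remaining (MCI_Major) individuals are embedded as 2-D
#' points `(count toward NCI, count toward AD)` and split by
#' [kmeansWithElbow()]; clusters are labelled by centroid position: near
#' the origin = `MCI_Typical`, dominant NCI axis = `MCI_NCI`, dominant AD
#' axis = `MCI_AD`.
#'
#' @param countsNci,countsAd named deviation counts for all MCI
#'   individuals (from [deviationCounts()]).
#' @param deviators ids of the MCI_NCI_AD individuals.
#' @param kRange candidate k (default 1:4).
#' @param seed k-means seed.
#' @return named character of detailed substages for all MCI individuals.
#' @export
classifyMci <- function(countsNci, countsAd, deviators, kRange = 1:4,
                        seed = 1) {
  ids <- names(countsNci)
  major <- setdiff(ids, deviators)
  lab <- setNames(rep("MCI_NCI_AD", length(ids)), ids)
  if (!length(major)) return(lab)
  P <- cbind(nci = countsNci[major], ad = countsAd[major])
  rownames(P) <- major
  km <- kmeansWithElbow(P, kRange = kRange[kRange <= length(major)],
                        seed = seed)
  if (km$k == 1) {
    warning("elbow selected k = 1; all MCI_Major labelled MCI_Typical")
    lab[major] <- "MCI_Typical"
    return(lab)
  }
  for (cl in unique(km$cluster)) {
    mem <- major[km$cluster == cl]
    cen <- colMeans(P[mem, , drop = FALSE])
    lab[mem] <- if (sqrt(sum(cen^2)) < 0.5) "MCI_Typical"
      else if (cen["ad"] > cen["nci"]) "MCI_AD" else "MCI_NCI"
  }
  lab
}

#' Classify NCI individuals into detailed substages
#'
#' 1-D k-means with elbow selection over the counts of deviation toward
#' the MCI cluster; clusters away from zero become `NCI_MCI`.
#'
#' @param countsMci named deviation counts for NCI individuals.
#' @param kRange candidate k (default 1:3).
#' @param seed k-means seed.
#' @return named character (`NCI_Typical` / `NCI_MCI`).
#' @export
classifyNci <- function(countsMci, kRange = 1:3, seed = 1) {
  km <- kmeansWithElbow(matrix(countsMci, ncol = 1,
                               dimnames = list(names(countsMci), NULL)),
                        kRange = kRange[kRange <= length(countsMci)],
                        seed = seed)
  if (km$k == 1) {
    if (any(countsMci > 0))
      warning("elbow selected k = 1; all NCI labelled NCI_Typical")
    return(setNames(rep("NCI_Typical", length(countsMci)),
                    names(countsMci)))
  }
  .labelByCentroid1d(countsMci, km, "NCI_Typical", "NCI_MCI")
}

#' Classify AD individuals into detailed substages
#'
#' 1-D k-means with elbow selection over the counts of deviation toward
#' the MCI cluster. Individuals in near-zero clusters keep their typical
#' substage (`AD_HH` / `AD_LL` / `AD_HL`); the others move to the
#' corresponding `*_MCI` substage.
#'
#' @param countsMci named deviation counts for AD individuals.
#' @param subgroupLabels named HH/LL/HL labels from
#'   [adSubgroupDiscovery()].
#' @param kRange candidate k (default 1:4).
#' @param seed k-means seed.
#' @return named character of detailed AD substages.
#' @export
classifyAd <- function(countsMci, subgroupLabels, kRange = 1:4, seed = 1) {
  ids <- names(countsMci)
  if (!all(ids %in% names(subgroupLabels)))
    stop("subgroup labels missing for some AD individuals")
  km <- kmeansWithElbow(matrix(countsMci, ncol = 1,
                               dimnames = list(ids, NULL)),
                        kRange = kRange[kRange <= length(ids)], seed = seed)
  typical <- setNames(paste0("AD_", subgroupLabels[ids]), ids)
  if (km$k == 1) {
    if (any(countsMci > 0))
      warning("elbow selected k = 1; all AD kept at typical substages")
    return(typical)
  }
  near <- .labelByCentroid1d(countsMci, km, "typ", "mci")
  ifelse(near == "typ", typical, paste0(typical, "_MCI")) |>
    setNames(ids)
}

#' APOE carrier classification
#'
#' Any e2 allele (without e4) makes an APOE2 carrier; any e4 (without e2)
#' an APOE4 carrier; e3/e3 an APOE3 carrier. The e2 + e4 combination is
#' outside the scheme and raises an error.
#'
#' @param allele1,allele2 character alleles among "e2", "e3", "e4"
#'   (vectorised).
#' @return character vector of carrier classes.
#' @export
apoeCarrier <- function(allele1, allele2) {
  ok <- c("e2", "e3", "e4")
  if (!all(allele1 %in% ok) || !all(allele2 %in% ok))
    stop("alleles must be e2, e3 or e4")
  has2 <- allele1 == "e2" | allele2 == "e2"
  has4 <- allele1 == "e4" | allele2 == "e4"
  if (any(has2 & has4))
    stop("e2 + e4 genotype is unclassifiable in this scheme")
  ifelse(has2, "APOE2", ifelse(has4, "APOE4", "APOE3"))
}

#' Assemble a full SubstageAssignment
#'
#' Combines the per-stage classifications into one
#' [SubstageAssignment-class], with coarse substages `MCI_Major` /
#' `MCI_NCI_AD` for MCI, `AD_HH` / `AD_LL` / `AD_HL` for AD, and the stage
#' itself for NCI.
#'
#' @param stageLabels named character of stages per individual.
#' @param nciLabels,mciLabels,adLabels named detailed labels from the
#'   classify functions.
#' @return a [SubstageAssignment-class].
#' @export
assembleSubstages <- function(stageLabels, nciLabels, mciLabels, adLabels) {
  detailed <- c(nciLabels, mciLabels, adLabels)
  ids <- names(stageLabels)
  if (!setequal(ids, names(detailed)))
    stop("labels must cover exactly the cohort individuals")
  detailed <- detailed[ids]
  coarse <- ifelse(stageLabels == "NCI", "NCI",
            ifelse(stageLabels == "MCI",
                   ifelse(detailed == "MCI_NCI_AD", "MCI_NCI_AD",
                          "MCI_Major"),
                   sub("_MCI$", "", detailed)))
  SubstageAssignment(ids, stageLabels[ids], coarse, detailed)
}
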