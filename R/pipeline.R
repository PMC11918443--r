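#' @include AllClasses.R simulate.R genesets.R substages.R trajectory.R io.R
NULL

# deterministic per-stage seed fan-out from one master seed
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + as.integer(h %% 100000L)) %% 2147483587L
}

#' Run the full substaging analysis
#'
#' Orchestrates the complete pipeline on one cohort: low-expression
#' filtering; the omnibus threshold-grid scan with stable-member
#' extraction (MCI_Major vs MCI_NCI_AD) and the M-NA set; the NCI-vs-AD
#' separation scans giving the N-A gene sets and their separating unions
#' (N-A1, N-A2); AD subgroup discovery with the CA/CB gene clusters;
#' pairwise deviation counting and the detailed 12-substage
#' classification; epigenome Jaccard typing, promoter-density
#' correlations and substage association tables; and the pruned,
#' intersected, stage-oriented adjacency networks.
#'
#' @param cohort an [ExpressionCohort-class]; if `NULL`, one is generated
#'   from `spec`.
#' @param spec a [cohortSpec()] used when `cohort` is NULL (synthetic
#'   mode; also produces epigenome tracks and genotypes).
#' @param peaks optional named list of GRanges peak sets per individual.
#' @param genotypes optional genotype data.frame (individual, allele1,
#'   allele2).
#' @param annotation optional gene annotation data.frame (synthetic mode
#'   takes it from the generator truth).
#' @param chromLengths named chromosome lengths for density computations.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param omnibusP scalar thresholds of the omnibus scan.
#' @param mnaP threshold of the cell defining the M-NA set (TPM/ANOVA
#'   backend; default 0.04).
#' @param naPUp,naPDown NCI-vs-AD grid for the counts backend.
#' @param naTPUp,naTPDown NCI-vs-AD grid for the TPM backend (the wider
#'   default follows the study's extended t-test search).
#' @param devP pairwise deviation grid thresholds.
#' @param outdir optional directory; when given, gene sets, assignments,
#'   Jaccard matrix and networks are written there as TSV/JSON.
#' @return list of class `txSubstagePipeline` with components `cohort`,
#'   `truth`, `filteredGenes`, `omnibus`, `mna`, `stableMci`, `naSets`,
#'   `adSubgroups`, `deviations`, `assignment`, `epigenome`,
#'   `associations`, `networks`, `manifest`.
#' @export
runPipeline <- function(cohort = NULL, spec = NULL, peaks = NULL,
                        genotypes = NULL, annotation = NULL,
                        chromLengths = NULL, seed = 1L,
                        omnibusP = seq(0.01, 0.05, 0.01), mnaP = 0.04,
                        naPUp = seq(0.01, 0.05, 0.01), naPDown = naPUp,
                        naTPUp = seq(0.01, 0.1, 0.01), naTPDown = naTPUp,
                        devP = seq(0.01, 0.05, 0.01), outdir = NULL) {
  truth <- NULL
  if (is.null(cohort)) {
    if (is.null(spec)) stop("supply a cohort or a spec")
    spec@seed <- .stageSeed(seed, "simulate")
    sim <- generateCohort(spec)
    cohort <- sim$cohort
    truth <- sim$truth
    if (is.null(peaks))
      peaks <- generateEpigenome(spec, truth,
                                 seed = .stageSeed(seed, "epigenome"))
    if (is.null(genotypes))
      genotypes <- generateGenotypes(truth,
                                     seed = .stageSeed(seed, "genotypes"))
    if (is.null(annotation)) annotation <- truth@annotation
    if (is.null(chromLengths)) chromLengths <- spec@chromLengths
  }
  st <- stageLabels(cohort)

  ## 1. filter
  kept <- lowExpressionFilter(tpm(cohort), st)
  cohort <- cohort[kept, ]

  ## 2. omnibus scan, stable members, M-NA set
  omni <- list(tpm = omnibusScan(cohort, p = omnibusP, backend = "tpm"),
               counts = omnibusScan(cohort, p = omnibusP,
                                    backend = "counts"))
  stableMci <- stableMembers(omni, "MCI", st)
  mnaCell <- which(abs(omni$tpm@cells$p - mnaP) < 1e-12)[1]
  if (is.na(mnaCell)) stop("mnaP must be one of the omnibus thresholds")
  resNMA <- testResultTable(cohort, .STAGES, backend = "tpm")
  mnaGenes <- omni$tpm@sets[[mnaCell]]
  mUp <- resNMA[mnaGenes, paste0("mean_", "MCI")] >
    pmax(resNMA[mnaGenes, "mean_NCI"], resNMA[mnaGenes, "mean_AD"])
  mna <- GeneSetRecord("M-NA", mnaGenes,
                       direction = ifelse(mUp, "up", "down"),
                       backend = "tpm", thresholds = c(p = mnaP),
                       rule = "omnibus ANOVA grid cell")

  ## 3. NCI-vs-AD gene sets
  resNAt <- testResultTable(cohort, c("NCI", "AD"), backend = "tpm")
  resNAd <- testResultTable(cohort, c("NCI", "AD"), backend = "counts")
  scanD <- separationScan(cohort, c("NCI", "AD"), pUp = naPUp,
                          pDown = naPDown, backend = "counts",
                          results = resNAd)
  scanT <- separationScan(cohort, c("NCI", "AD"), pUp = naTPUp,
                          pDown = naTPDown, backend = "tpm",
                          results = resNAt)
  naD1 <- largestSeparatingSet(scanD, "N-A_D1")
  naD2 <- largestSeparatingSet(scanD, "N-A_D2", by = "down")
  naT <- largestSeparatingSet(scanT, "N-A_t")
  candD1 <- resNAd[geneIds(naD1), c("gene", "p")]
  candD2 <- resNAd[geneIds(naD2), c("gene", "p")]
  na1 <- unionWithSeparation(naT, candD1, cohort, c("NCI", "AD"), "N-A1")
  na2 <- unionWithSeparation(naT, candD2, cohort, c("NCI", "AD"), "N-A2")
  fillDir <- function(set) {
    d <- ifelse(resNAt[geneIds(set), "direction"] == "up", "up", "down")
    methods::initialize(set, direction = unname(d))
  }
  na1 <- fillDir(na1); na2 <- fillDir(na2)
  naSets <- list(naD1 = naD1, naD2 = naD2, naT = naT, na1 = na1, na2 = na2)

  ## 4. AD subgroups (from N-A1; N-A2 kept for the robustness comparison)
  adSub <- adSubgroupDiscovery(cohort, na1,
                               seed = .stageSeed(seed, "adsubgroups"))
  adSub2 <- adSubgroupDiscovery(cohort, na2,
                                seed = .stageSeed(seed, "adsubgroups2"))

  ## 5. deviation counting and detailed classification
  devNM <- deviationCounts(cohort, c("NCI", "MCI"), pUp = devP)
  devMA <- deviationCounts(cohort, c("MCI", "AD"), pUp = devP)
  nciLab <- classifyNci(devNM$towardSecond,
                        seed = .stageSeed(seed, "classifynci"))
  mciLab <- classifyMci(devNM$towardFirst, devMA$towardSecond,
                        stableMci$deviators,
                        seed = .stageSeed(seed, "classifymci"))
  adLab <- classifyAd(devMA$towardFirst, adSub$subgroups,
                      seed = .stageSeed(seed, "classifyad"))
  assignment <- assembleSubstages(st, nciLab, mciLab, adLab)

  ## 6. epigenome
  epi <- NULL
  if (!is.null(peaks)) {
    jmat <- jaccardMatrix(peaks)
    typing <- epigenomeTyping(jmat)
    dens <- if (!is.null(chromLengths))
      vapply(peaks, chromosomeDensity, numeric(length(chromLengths)),
             chromLengths = chromLengths) else NULL
    promCor <- NULL
    if (!is.null(annotation) && !adSub$insufficient) {
      proms <- promoterRegions(annotation, chromLengths = chromLengths)
      adIds <- names(st)[st == "AD"]
      genes <- intersect(c(adSub$caGenes, adSub$cbGenes), names(proms))
      if (length(genes) >= 1) {
        pd <- vapply(peaks, function(p)
          promoterDensity(p, proms[genes]), numeric(length(genes)))
        rownames(pd) <- genes
        use <- intersect(adIds, colnames(pd))
        promCor <- list(
          ca = expressionPromoterCorrelation(
            tpm(cohort), pd, use, intersect(adSub$caGenes, genes)),
          cb = expressionPromoterCorrelation(
            tpm(cohort), pd, use, intersect(adSub$cbGenes, genes)))
      }
    }
    epi <- list(jaccard = jmat, typing = typing,
                chromDensity = dens, promoterCorrelation = promCor)
  }

  ## 7. association tables (epigenome typing / APOE vs substage)
  assoc <- list()
  det <- substages(assignment)
  if (!is.null(epi)) {
    ids <- intersect(names(epi$typing$typing), names(det))
    tab <- table(epi$typing$typing[ids],
                 .substageStage(det[ids]))
    assoc$epigenomeByStage <- list(table = tab, p = fisherExactRxC(tab))
  }
  if (!is.null(genotypes)) {
    carrier <- apoeCarrier(genotypes$allele1, genotypes$allele2)
    names(carrier) <- genotypes$individual
    ids <- intersect(names(carrier), names(det))
    tabStage <- table(carrier[ids], .substageStage(det[ids]))
    assoc$apoeByStage <- list(table = tabStage,
                              p = fisherExactRxC(tabStage))
    mciIds <- ids[.substageStage(det[ids]) == "MCI"]
    coarse <- substages(assignment, "coarse")
    if (length(unique(coarse[mciIds])) > 1) {
      tabMci <- table(carrier[mciIds], coarse[mciIds])
      assoc$apoeByMciSubstage <- list(table = tabMci,
                                      p = fisherExactRxC(tabMci))
    }
    adIds <- ids[.substageStage(det[ids]) == "AD"]
    if (length(unique(coarse[adIds])) > 1) {
      tabAd <- table(carrier[adIds], coarse[adIds])
      assoc$apoeByAdSubgroup <- list(table = tabAd,
                                     p = fisherExactRxC(tabAd))
    }
  }

  ## 8. adjacency networks
  stageMap <- stats::setNames(.substageStage(unique(det)), unique(det))
  netA <- substageNetwork(cohort, mna, na1, det)
  netB <- substageNetwork(cohort, mna, na2, det)
  prunedA <- pruneGraph(netA, stageMap)
  prunedB <- pruneGraph(netB, stageMap)
  common <- intersectGraphs(prunedA, prunedB)
  networks <- list(raw = list(na1 = netA, na2 = netB),
                   pruned = list(na1 = prunedA, na2 = prunedB),
                   common = common,
                   oriented = orientGraph(common, stageMap))

  manifest <- list(package = "txSubstage",
                   version = as.character(utils::packageVersion("txSubstage")),
                   seed = as.integer(seed),
                   synthetic = !is.null(truth),
                   nGenesKept = length(kept),
                   thresholds = list(omnibusP = omnibusP, mnaP = mnaP,
                                     naPUp = naPUp, naTPUp = naTPUp,
                                     devP = devP))

  out <- list(cohort = cohort, truth = truth, filteredGenes = kept,
              omnibus = omni, mna = mna, stableMci = stableMci,
              naSets = naSets, adSubgroups = adSub, adSubgroups2 = adSub2,
              deviations = list(nm = devNM[c("towardSecond", "towardFirst",
                                             "nValidCells")],
                                ma = devMA[c("towardSecond", "towardFirst",
                                             "nValidCells")]),
              assignment = assignment, epigenome = epi,
              associations = assoc, networks = networks,
              manifest = manifest)
  class(out) <- "txSubstagePipeline"
  if (!is.null(outdir)) .writePipeline(out, outdir)
  out
}

.writePipeline <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeSubstageAssignment(res$assignment,
                          file.path(outdir, "substages.tsv"))
  writeGeneSetRecord(res$mna, file.path(outdir, "geneset_MNA.tsv"))
  for (nm in names(res$naSets))
    writeGeneSetRecord(res$naSets[[nm]],
                       file.path(outdir, paste0("geneset_", nm, ".tsv")))
  if (!is.null(res$epigenome))
    utils::write.table(res$epigenome$jaccard,
                       file.path(outdir, "jaccard.tsv"), sep = "\t",
                       quote = FALSE)
  writeGraphEdges(res$networks$oriented,
                  file.path(outdir, "network_common.tsv"))
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.txSubstagePipeline <- function(x, ...) {
  cat("txSubstage pipeline result\n")
  cat("  genes kept:", length(x$filteredGenes), "\n")
  cat("  M-NA set:", length(geneIds(x$mna)), "genes;",
      "N-A1:", length(geneIds(x$naSets$na1)), "genes;",
      "N-A2:", length(geneIds(x$naSets$na2)), "genes\n")
  cat("  detailed substages:\n")
  print(table(substages(x$assignment)))
  invisible(x)
}
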