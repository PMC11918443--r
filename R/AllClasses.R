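#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
NULL

# ---------------------------------------------------------------------------
# ExpressionCohort
# ---------------------------------------------------------------------------

#' ExpressionCohort: counts + TPM with clinical stage labels
#'
#' The central input container of the package: a
#' \linkS4class{SummarizedExperiment} carrying two assays, \code{"counts"}
#' (non-negative integers) and \code{"tpm"} (non-negative reals), over the
#' same genes and samples, plus a per-sample clinical stage label
#' (\code{"NCI"}, \code{"MCI"} or \code{"AD"}) in \code{colData(x)$stage}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @seealso [ExpressionCohort()] for the constructor, [tpm()],
#'   [stageLabels()] for accessors.
#' @exportClass ExpressionCohort
setClass("ExpressionCohort", contains = "SummarizedExperiment")

.validExpressionCohort <- function(object) {
  msg <- NULL
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("counts", "tpm") %in% an))
    msg <- c(msg, "assays must contain 'counts' and 'tpm'")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    tp <- SummarizedExperiment::assay(object, "tpm")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(abs(cts - round(cts)) > 1e-8))
      msg <- c(msg, "counts must be integers")
    if (any(tp < 0)) msg <- c(msg, "tpm must be non-negative")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  st <- SummarizedExperiment::colData(object)$stage
  if (is.null(st)) msg <- c(msg, "colData must contain a 'stage' column")
  else if (!all(as.character(st) %in% c("NCI", "MCI", "AD")))
    msg <- c(msg, "stage labels must be NCI, MCI or AD")
  if (is.null(msg)) TRUE else msg
}
setValidity("ExpressionCohort", .validExpressionCohort)

#' Construct an ExpressionCohort
#'
#' @param counts genes x samples matrix of non-negative integer read counts.
#' @param tpm genes x samples matrix of TPM values with the same dimnames.
#'   If `NULL`, TPM is derived from counts by per-sample total scaling to
#'   `1e6` (all genes are treated as unit length).
#' @param stage character or factor of per-sample clinical stages
#'   (`"NCI"`, `"MCI"`, `"AD"`), in column order or named by sample id.
#' @return An [ExpressionCohort-class] object.
#' @examples
#' cts <- matrix(rpois(12, 50), 3, 4,
#'               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ec <- ExpressionCohort(cts, stage = c("NCI", "NCI", "MCI", "AD"))
#' colSums(tpm(ec))  # each 1e6
#' @export
ExpressionCohort <- function(counts, tpm = NULL, stage) {
  counts <- as.matrix(counts)
  if (is.null(tpm)) {
    tot <- colSums(counts)
    if (any(tot == 0)) stop("cannot derive TPM: a sample has zero total count")
    tpm <- sweep(counts, 2, tot, "/") * 1e6
  }
  tpm <- as.matrix(tpm)
  if (!identical(dim(counts), dim(tpm)))
    stop("counts and tpm must share dimensions")
  if (!is.null(names(stage))) stage <- stage[colnames(counts)]
  stage <- factor(as.character(stage), levels = c("NCI", "MCI", "AD"))
  if (anyNA(stage)) stop("every sample needs a stage in NCI/MCI/AD")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, tpm = tpm),
    colData = S4Vectors::DataFrame(stage = stage, row.names = colnames(counts)))
  methods::new("ExpressionCohort", se)
}

# ---------------------------------------------------------------------------
# CohortSpec / CohortTruth
# ---------------------------------------------------------------------------

#' CohortSpec: parameters of the synthetic cohort generator
#'
#' Describes a synthetic dementia cohort: how many individuals per clinical
#' stage, how each stage is split into detailed substages, which planted
#' gene modules exist and how strong their effects are, and the noise model
#' for the negative-binomial count draw. See [cohortSpec()] for the
#' constructor with study defaults.
#'
#' @slot nPerStage named integer, individuals per stage (NCI/MCI/AD).
#' @slot substageFractions named numeric, fraction of each detailed substage
#'   within its stage; per-stage fractions sum to 1.
#' @slot nGenes total number of genes (excluding spike-ins).
#' @slot moduleSizes named integer: genes per planted module
#'   (mna_up, mna_down, na_up, na_down, ca_like, cb_like; the remainder is
#'   the null module).
#' @slot effectLog2 named numeric, log2 fold-change magnitude per module.
#' @slot noiseSdLog2 per-gene, per-sample log2 biological noise sd.
#' @slot libsizeSigma log-normal spread of library sizes.
#' @slot dispersion negative-binomial dispersion (1/size).
#' @slot bridgeWeights named numeric, mixture weight of the non-own flanking
#'   archetype for each bridge substage family.
#' @slot nSpikeIns number of constant spike-in genes (ERCC- ids).
#' @slot chromLengths named numeric, synthetic genome model.
#' @slot seed integer RNG seed.
#' @exportClass CohortSpec
setClass("CohortSpec", representation(
  nPerStage = "integer", substageFractions = "numeric", nGenes = "integer",
  moduleSizes = "integer", effectLog2 = "numeric", noiseSdLog2 = "numeric",
  libsizeSigma = "numeric", dispersion = "numeric", bridgeWeights = "numeric",
  nSpikeIns = "integer", chromLengths = "numeric", seed = "integer"))

.STAGES <- c("NCI", "MCI", "AD")
.SUBSTAGES <- c("NCI_Typical", "NCI_MCI",
                "MCI_Typical", "MCI_NCI", "MCI_AD", "MCI_NCI_AD",
                "AD_HH", "AD_HL", "AD_LL",
                "AD_HH_MCI", "AD_HL_MCI", "AD_LL_MCI")
.MODULES <- c("mna_up", "mna_down", "na_up", "na_down", "ca_like", "cb_like")

.substageStage <- function(s) sub("_.*$", "", s)

.validCohortSpec <- function(object) {
  msg <- NULL
  if (!identical(sort(names(object@nPerStage)), sort(.STAGES)) ||
      any(object@nPerStage <= 0L))
    msg <- c(msg, "nPerStage: need positive counts for NCI, MCI and AD")
  if (!all(names(object@substageFractions) %in% .SUBSTAGES))
    msg <- c(msg, paste("substageFractions: unknown substage name(s):",
                        paste(setdiff(names(object@substageFractions),
                                      .SUBSTAGES), collapse = ", ")))
  for (st in .STAGES) {
    f <- object@substageFractions[
      .substageStage(names(object@substageFractions)) == st]
    if (abs(sum(f) - 1) > 1e-9)
      msg <- c(msg, sprintf(
        "substageFractions: fractions within stage %s sum to %g, not 1",
        st, sum(f)))
  }
  if (!all(names(object@moduleSizes) %in% .MODULES))
    msg <- c(msg, "moduleSizes: unknown module name(s)")
  if (sum(object@moduleSizes) > object@nGenes)
    msg <- c(msg, "moduleSizes: module sizes sum to more than nGenes")
  if (object@nGenes <= 0L) msg <- c(msg, "nGenes must be positive")
  if (any(object@effectLog2 < 0)) msg <- c(msg, "effectLog2 must be >= 0")
  if (object@noiseSdLog2 < 0) msg <- c(msg, "noiseSdLog2 must be >= 0")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (any(object@bridgeWeights < 0 | object@bridgeWeights > 1))
    msg <- c(msg, "bridgeWeights must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
}
setValidity("CohortSpec", .validCohortSpec)

#' CohortTruth: planted structure of a synthetic cohort
#'
#' @slot substage named character, detailed substage per individual.
#' @slot module named character, planted module per gene.
#' @slot meanLog2 genes x individuals matrix of planted log2 effect means.
#' @slot annotation data.frame (gene_id, chrom, strand, tss) on the
#'   synthetic genome.
#' @slot spec the generating [CohortSpec-class].
#' @exportClass CohortTruth
setClass("CohortTruth", representation(
  substage = "character", module = "character", meanLog2 = "matrix",
  annotation = "data.frame", spec = "CohortSpec"))

# ---------------------------------------------------------------------------
# GeneSetRecord
# ---------------------------------------------------------------------------

#' GeneSetRecord: a named gene set with directions and provenance
#'
#' @slot name set name (e.g. "M-NA", "N-A1").
#' @slot genes member gene ids.
#' @slot direction named character ("up"/"down" in the later-stage group;
#'   "any" for omnibus sets), aligned with `genes`.
#' @slot backend test backend that produced the set.
#' @slot thresholds numeric threshold(s) used.
#' @slot rule free-text construction rule.
#' @exportClass GeneSetRecord
setClass("GeneSetRecord", representation(
  name = "character", genes = "character", direction = "character",
  backend = "character", thresholds = "numeric", rule = "character"))

setValidity("GeneSetRecord", function(object) {
  if (length(object@direction) && length(object@direction) !=
      length(object@genes))
    "direction must align with genes" else TRUE
})

GeneSetRecord <- function(name, genes, direction = character(), backend = NA_character_,
                          thresholds = numeric(), rule = "") {
  methods::new("GeneSetRecord", name = name, genes = as.character(genes),
               direction = direction, backend = backend,
               thresholds = thresholds, rule = rule)
}

# ---------------------------------------------------------------------------
# SubstageAssignment
# ---------------------------------------------------------------------------

#' SubstageAssignment: per-individual labels at three granularities
#'
#' @slot individual sample ids.
#' @slot stage clinical stage per individual.
#' @slot coarse coarse substage (e.g. MCI_Major, AD_HH).
#' @slot detailed detailed substage (one of the 12 labels).
#' @exportClass SubstageAssignment
setClass("SubstageAssignment", representation(
  individual = "character", stage = "character", coarse = "character",
  detailed = "character"))

setValidity("SubstageAssignment", function(object) {
  n <- length(object@individual)
  msg <- NULL
  if (length(object@stage) != n || length(object@coarse) != n ||
      length(object@detailed) != n)
    msg <- c(msg, "all slots must have one entry per individual")
  if (anyDuplicated(object@individual))
    msg <- c(msg, "individual ids must be unique")
  if (!all(object@detailed %in% .SUBSTAGES))
    msg <- c(msg, "unknown detailed substage label")
  if (length(object@stage) == n &&
      !all(.substageStage(object@detailed) == object@stage))
    msg <- c(msg, "detailed substage inconsistent with stage")
  if (is.null(msg)) TRUE else msg
})

SubstageAssignment <- function(individual, stage, coarse, detailed) {
  methods::new("SubstageAssignment", individual = as.character(individual),
               stage = as.character(stage), coarse = as.character(coarse),
               detailed = as.character(detailed))
}

# ---------------------------------------------------------------------------
# PhaseDiagram
# ---------------------------------------------------------------------------

#' PhaseDiagram: per-cell results of a threshold-grid clustering scan
#'
#' One record per grid cell: the thresholds, the selected gene set size,
#' whether the first dendrogram branch completely separates the two compared
#' groups, the two first-branch sides, and per-group enrichment test
#' results.
#'
#' @slot groups the compared groups (length 2, or 3 for omnibus scans).
#' @slot backend test backend.
#' @slot cells data.frame with one row per cell (pUp, pDown, nUp, nDown,
#'   nGenes, separating).
#' @slot sets list of per-cell gene id vectors.
#' @slot splits list of per-cell `list(sideA=, sideB=)` membership vectors.
#' @slot enrich list of per-cell named lists: for each group, the
#'   [enrichedClusterTest()] outcome and the enriched side's members.
#' @exportClass PhaseDiagram
setClass("PhaseDiagram", representation(
  groups = "character", backend = "character", cells = "data.frame",
  sets = "list", splits = "list", enrich = "list"))

# ---------------------------------------------------------------------------
# PartitionGraph
# ---------------------------------------------------------------------------

#' PartitionGraph: substage nodes with connection-confidence weights
#'
#' @slot nodes node (substage) labels.
#' @slot weights symmetric matrix of connection confidences in [0, 1] with
#'   zero diagonal.
#' @exportClass PartitionGraph
setClass("PartitionGraph", representation(
  nodes = "character", weights = "matrix"))

setValidity("PartitionGraph", function(object) {
  w <- object@weights
  msg <- NULL
  if (!identical(dim(w), c(length(object@nodes), length(object@nodes))))
    msg <- c(msg, "weights must be square over the nodes")
  else {
    if (max(abs(w - t(w))) > 1e-12) msg <- c(msg, "weights must be symmetric")
    if (any(diag(w) != 0)) msg <- c(msg, "no self-edges allowed")
    if (any(w < 0 | w > 1)) msg <- c(msg, "weights must lie in [0, 1]")
  }
  if (is.null(msg)) TRUE else msg
})

PartitionGraph <- function(nodes, weights) {
  dimnames(weights) <- list(nodes, nodes)
  methods::new("PartitionGraph", nodes = nodes, weights = weights)
}
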