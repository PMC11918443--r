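#' @include AllClasses.R epigenome.R
NULL

# largest-remainder allocation of n among fractions (sums exactly to n)
.allocateCounts <- function(n, fractions) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Construct a CohortSpec
#'
#' Defaults emulate the study cohort: 25 NCI / 29 MCI / 28 AD female
#' individuals with detailed-substage counts 22+3, 17+4+3+5 and
#' 7+5+7+3+3+3, six planted gene modules among 2000 genes, log2
#' effect size 2, per-gene log2 noise sd 0.3, negative-binomial
#' dispersion 0.2, and a 3 x 1 Mbp synthetic genome.
#'
#' @param nPerStage named counts of individuals per stage.
#' @param substageFractions named fractions of detailed substages within
#'   their stage (per-stage sums must be 1).
#' @param nGenes number of genes.
#' @param moduleSizes named gene counts for the planted modules
#'   (mna_up/mna_down shift in MCI_Major; na_up/na_down shift in AD;
#'   ca_like is low in only the AD_LL subgroup; cb_like is high in only
#'   the AD_HH subgroup; the remainder of the genes is null).
#' @param effectLog2 named log2 fold-change magnitudes per module (a
#'   single unnamed value recycles to all modules).
#' @param noiseSdLog2 per-gene per-sample log2 noise sd.
#' @param libsizeSigma log-normal library size spread.
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param bridgeWeights mixture weight of the non-own flanking archetype
#'   for each bridge substage family (see the methods vignette for why the
#'   defaults are asymmetric).
#' @param nSpikeIns number of constant ERCC- spike-in genes.
#' @param chromLengths named synthetic chromosome lengths.
#' @param seed integer RNG seed.
#' @return a validated [CohortSpec-class].
#' @export
cohortSpec <- function(
    nPerStage = c(NCI = 25L, MCI = 29L, AD = 28L),
    substageFractions = c(
      NCI_Typical = 22 / 25, NCI_MCI = 3 / 25,
      MCI_Typical = 17 / 29, MCI_NCI = 4 / 29, MCI_AD = 3 / 29,
      MCI_NCI_AD = 5 / 29,
      AD_HH = 7 / 28, AD_HL = 5 / 28, AD_LL = 7 / 28,
      AD_HH_MCI = 3 / 28, AD_HL_MCI = 3 / 28, AD_LL_MCI = 3 / 28),
    nGenes = 2000L,
    moduleSizes = c(mna_up = 150L, mna_down = 150L, na_up = 90L,
                    na_down = 60L, ca_like = 150L, cb_like = 150L),
    effectLog2 = 2, noiseSdLog2 = 0.3, libsizeSigma = 0.2,
    dispersion = 0.2,
    bridgeWeights = .defaultBridgeWeights,
    nSpikeIns = 10L,
    chromLengths = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6),
    seed = 1L) {
  if (length(effectLog2) == 1 && is.null(names(effectLog2)))
    effectLog2 <- stats::setNames(rep(effectLog2, length(moduleSizes)),
                                  names(moduleSizes))
  methods::new("CohortSpec",
               nPerStage = stats::setNames(as.integer(nPerStage),
                                           names(nPerStage)),
               substageFractions = substageFractions,
               nGenes = as.integer(nGenes),
               moduleSizes = stats::setNames(as.integer(moduleSizes),
                                             names(moduleSizes)),
               effectLog2 = effectLog2, noiseSdLog2 = noiseSdLog2,
               libsizeSigma = libsizeSigma, dispersion = dispersion,
               bridgeWeights = bridgeWeights,
               nSpikeIns = as.integer(nSpikeIns),
               chromLengths = chromLengths, seed = as.integer(seed))
}

# per-substage log2 archetype matrix (genes x 12 substages)
#
# The MCI axis (mna modules) and the AD axis (na + subgroup modules) are
# mixed per axis, not by one global weight: the AD-near-MCI bridges keep
# their subgroup (ca/cb) and na patterns close to the parent archetype
# (weight `AD_MCI` toward zero) while carrying a strong MCI-module
# signature (`AD_MCI_mna`); typical AD individuals carry the compensating
# negative MCI-module offset (`AD_typ_mna`) so that the cohort-level
# NCI-vs-AD contrast on mna genes stays null. MCI_NCI additionally gets a
# small negative na offset (`MCI_NCI_na`), i.e. it is AD-distal.
# The methods vignette derives why these asymmetries are required for the
# planted substages to be identifiable by the clustering pipeline.
.substageArchetypes <- function(module, effect, bridgeWeights) {
  e <- function(m) ifelse(module == m, effect[m], 0)
  arch <- matrix(0, length(module), length(.SUBSTAGES),
                 dimnames = list(names(module), .SUBSTAGES))
  w <- .defaultBridgeWeights
  w[names(bridgeWeights)] <- bridgeWeights
  nci <- rep(0, length(module))
  mci <- e("mna_up") - e("mna_down")
  na <- e("na_up") - e("na_down")
  sub <- list(AD_HH = e("ca_like") + e("cb_like"),
              AD_HL = e("ca_like"),
              AD_LL = rep(0, length(module)))
  adTyp <- lapply(sub, function(s) na + s - w["AD_typ_mna"] * mci)
  adBase <- na + (sub$AD_HH + sub$AD_HL + sub$AD_LL) / 3
  arch[, "NCI_Typical"] <- nci
  arch[, "NCI_MCI"] <- (1 - w["NCI_MCI"]) * nci + w["NCI_MCI"] * mci
  arch[, "MCI_Typical"] <- mci
  arch[, "MCI_NCI"] <- (1 - w["MCI_NCI"]) * mci + w["MCI_NCI"] * nci -
    w["MCI_NCI_na"] * na
  arch[, "MCI_AD"] <- w["MCI_AD_mna"] * mci + w["MCI_AD"] * adBase
  arch[, "MCI_NCI_AD"] <- (1 - w["MCI_NCI_AD"]) * nci +
    w["MCI_NCI_AD"] * adBase
  for (s in c("AD_HH", "AD_HL", "AD_LL")) {
    arch[, s] <- adTyp[[s]]
    arch[, paste0(s, "_MCI")] <-
      (1 - w["AD_MCI"]) * (na + sub[[s]]) + w["AD_MCI_mna"] * mci
  }
  arch
}

.defaultBridgeWeights <- c(NCI_MCI = 0.5, MCI_NCI = 0.635, MCI_AD = 1,
                           MCI_AD_mna = 0.45, MCI_NCI_AD = 0.5,
                           AD_MCI = 0.3, AD_MCI_mna = 0.8,
                           AD_typ_mna = 0.38, MCI_NCI_na = 0)

#' Generate a synthetic cohort with planted substage structure
#'
#' Draws read counts from a negative-binomial model with log-normal
#' library sizes: per-gene baseline abundances, per-substage planted log2
#' offsets (bridge substages receive convex mixtures of their flanking
#' archetypes), and per-gene/per-sample log2 noise. TPM is derived from
#' the counts by per-sample total scaling to 1e6. The same seed yields
#' byte-identical output.
#'
#' @param spec a [cohortSpec()].
#' @return list with `cohort` (an [ExpressionCohort-class]) and `truth`
#'   (a [CohortTruth-class]).
#' @export
generateCohort <- function(spec) {
  methods::validObject(spec)
  set.seed(spec@seed)
  # individuals, ids N1.., M1.., A1.. by clinical stage
  substage <- character(0)
  ids <- character(0)
  for (st in .STAGES) {
    fr <- spec@substageFractions[
      .substageStage(names(spec@substageFractions)) == st]
    cnt <- .allocateCounts(spec@nPerStage[[st]], fr)
    substage <- c(substage, rep(names(cnt), cnt))
    ids <- c(ids, paste0(substr(st, 1, 1), seq_len(spec@nPerStage[[st]])))
  }
  names(substage) <- ids
  n <- length(ids)
  # gene modules
  geneIds <- sprintf("g%04d", seq_len(spec@nGenes))
  module <- rep("null", spec@nGenes)
  free <- sample.int(spec@nGenes)
  off <- 0
  for (m in names(spec@moduleSizes)) {
    module[free[off + seq_len(spec@moduleSizes[[m]])]] <- m
    off <- off + spec@moduleSizes[[m]]
  }
  names(module) <- geneIds
  effect <- spec@effectLog2[.MODULES]
  names(effect) <- .MODULES
  effect[is.na(effect)] <- 0
  arch <- .substageArchetypes(module, effect, spec@bridgeWeights)
  meanLog2 <- arch[, substage, drop = FALSE]
  colnames(meanLog2) <- ids
  # spike-ins: constant abundance, no planted effect
  if (spec@nSpikeIns > 0) {
    spikeIds <- sprintf("ERCC-%05d", seq_len(spec@nSpikeIns))
    geneIds <- c(geneIds, spikeIds)
    module <- c(module, stats::setNames(rep("spikein", spec@nSpikeIns),
                                        spikeIds))
    meanLog2 <- rbind(meanLog2,
                      matrix(0, spec@nSpikeIns, n,
                             dimnames = list(spikeIds, ids)))
  }
  nAll <- length(geneIds)
  baseline <- 2^stats::rnorm(nAll, mean = 0, sd = 2)
  if (spec@nSpikeIns > 0)
    baseline[(spec@nGenes + 1):nAll] <- stats::median(baseline)
  noise <- matrix(stats::rnorm(nAll * n, sd = spec@noiseSdLog2), nAll, n)
  wgt <- baseline * 2^(meanLog2 + noise)
  frac <- sweep(wgt, 2, colSums(wgt), "/")
  libSize <- round(2e6 * exp(stats::rnorm(n, sd = spec@libsizeSigma)))
  mu <- sweep(frac, 2, libSize, "*")
  counts <- if (spec@dispersion > 0) {
    matrix(stats::rnbinom(nAll * n, mu = mu, size = 1 / spec@dispersion),
           nAll, n)
  } else matrix(stats::rpois(nAll * n, mu), nAll, n)
  dimnames(counts) <- list(geneIds, ids)
  # annotation on the synthetic genome (spike-ins have no locus)
  chroms <- names(spec@chromLengths)
  chromOf <- chroms[(seq_len(spec@nGenes) - 1) %% length(chroms) + 1]
  perChrom <- ceiling(spec@nGenes / length(chroms))
  slot <- (seq_len(spec@nGenes) - 1) %/% length(chroms)
  gap <- floor((min(spec@chromLengths) - 4000) / perChrom)
  tss <- 2000 + slot * gap
  annot <- data.frame(gene_id = sprintf("g%04d", seq_len(spec@nGenes)),
                      chrom = chromOf,
                      strand = sample(c("+", "-"), spec@nGenes,
                                      replace = TRUE),
                      tss = tss, stringsAsFactors = FALSE)
  stage <- .substageStage(substage)
  names(stage) <- ids
  cohort <- ExpressionCohort(counts, stage = stage)
  truth <- methods::new("CohortTruth", substage = substage,
                        module = module, meanLog2 = meanLog2,
                        annotation = annot, spec = spec)
  list(cohort = cohort, truth = truth)
}

# sample peak intervals on the synthetic genome; optionally rejecting
# overlap with `avoid`
.samplePeaks <- function(nPeaks, chromLengths, widthRange, avoid = NULL) {
  chroms <- names(chromLengths)
  res <- GenomicRanges::GRanges()
  tries <- 0
  while (length(res) < nPeaks && tries < 50) {
    need <- nPeaks - length(res)
    chr <- sample(chroms, need, replace = TRUE,
                  prob = chromLengths / sum(chromLengths))
    w <- round(stats::runif(need, widthRange[1], widthRange[2]))
    s <- floor(stats::runif(need, 1, chromLengths[chr] - w))
    gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(s, width = w))
    if (!is.null(avoid)) {
      hit <- IRanges::overlapsAny(gr, avoid)
      gr <- gr[!hit]
    }
    res <- c(res, gr)
    tries <- tries + 1
  }
  utils::head(res, nPeaks)
}

#' Generate synthetic epigenome peak tracks
#'
#' Typical individuals jitter a shared peak template (per-peak drop and
#' shift noise); untypical individuals jitter a template placed away from
#' the typical one. With `nTemplates = 2` the typical group itself is
#' split over two related templates (emulating the Typical1/Typical2
#' substructure). For cb_like genes the 1 kbp promoter additionally
#' carries a peak covering a fraction of the promoter that increases
#' logistically with the individual's planted expression offset, so
#' expression-promoter-density correlation is positive by construction.
#'
#' @param spec the generating [CohortSpec-class] (chromosome model).
#' @param truth the matching [CohortTruth-class].
#' @param typicalFraction fraction of individuals on the typical template
#'   (default 0.72).
#' @param nTemplates 1 or 2 typical templates.
#' @param nPeaks template peak count (default 400).
#' @param widthRange peak width range in bp.
#' @param jitterSd sd of the per-peak position shift (bp); 0 disables.
#' @param dropProb per-peak drop probability; 0 disables.
#' @param templateDivergence fraction of template-1 peaks relocated in
#'   the second typical template.
#' @param couplingSlope logistic slope tying promoter peaks of cb_like
#'   genes to planted expression.
#' @param seed RNG seed (default spec seed + 1).
#' @return named list of merged GRanges (one per individual) with
#'   attributes `typing` (planted Typical1/Typical2/Untypical labels) and
#'   `templates`.
#' @export
generateEpigenome <- function(spec, truth, typicalFraction = 0.72,
                              nTemplates = 2, nPeaks = 400,
                              widthRange = c(200, 1000), jitterSd = 150,
                              dropProb = 0.15, couplingSlope = 2,
                              templateDivergence = 0.3,
                              seed = spec@seed + 1L) {
  if (typicalFraction <= 0 || typicalFraction >= 1)
    stop("typicalFraction must lie strictly between 0 and 1")
  if (!nTemplates %in% 1:2) stop("nTemplates must be 1 or 2")
  if (!length(spec@chromLengths)) stop("chromosome model missing")
  set.seed(as.integer(seed))
  chrLen <- spec@chromLengths
  t1 <- .samplePeaks(nPeaks, chrLen, widthRange)
  t2 <- t1
  if (nTemplates == 2) {
    swap <- sample(c(TRUE, FALSE), length(t1), replace = TRUE,
                   prob = c(templateDivergence, 1 - templateDivergence))
    t2 <- c(t1[!swap], .samplePeaks(sum(swap), chrLen, widthRange))
  }
  tU <- .samplePeaks(nPeaks, chrLen, widthRange,
                     avoid = GenomicRanges::reduce(c(t1, t2)))
  ids <- colnames(truth@meanLog2)
  nUn <- max(1, round((1 - typicalFraction) * length(ids)))
  untypical <- sample(ids, nUn)
  template <- stats::setNames(rep(1L, length(ids)), ids)
  template[untypical] <- 0L
  typIds <- setdiff(ids, untypical)
  if (nTemplates == 2)
    template[typIds] <- sample(1:2, length(typIds), replace = TRUE)
  # promoter windows of the coupled module
  cbGenes <- names(truth@module)[truth@module == "cb_like"]
  proms <- promoterRegions(
    truth@annotation[truth@annotation$gene_id %in% cbGenes, , drop = FALSE],
    chromLengths = chrLen)
  m <- truth@meanLog2[cbGenes, , drop = FALSE]
  mc <- m - rowMeans(m)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    tpl <- switch(template[[id]] + 1L, tU, t1, t2)
    keep <- stats::runif(length(tpl)) >= dropProb
    peaks <- tpl[keep]
    if (jitterSd > 0 && length(peaks)) {
      shift <- round(stats::rnorm(length(peaks), sd = jitterSd))
      lim <- chrLen[as.character(GenomicRanges::seqnames(peaks))]
      shift <- pmax(pmin(shift, lim - GenomicRanges::end(peaks)),
                    1 - GenomicRanges::start(peaks))
      peaks <- GenomicRanges::shift(peaks, shift)
    }
    if (length(cbGenes)) {
      frac <- stats::plogis(couplingSlope * mc[names(proms), id])
      wbp <- round(frac * GenomicRanges::width(proms))
      keep <- wbp >= 1
      pr <- GenomicRanges::resize(proms[keep], width = wbp[keep],
                                  fix = "start")
      peaks <- c(peaks, GenomicRanges::granges(pr))
    }
    out[[id]] <- GenomicRanges::reduce(peaks, ignore.strand = TRUE)
  }
  typing <- ifelse(template == 0L, "Untypical",
                   ifelse(template == 1L, "Typical1", "Typical2"))
  if (nTemplates == 1) typing[typing == "Typical1"] <- "Typical"
  attr(out, "typing") <- stats::setNames(typing, ids)
  attr(out, "templates") <- list(typical1 = t1, typical2 = t2,
                                 untypical = tU)
  out
}

#' Generate APOE genotypes
#'
#' Each individual receives exactly one carrier class (APOE2/APOE3/APOE4)
#' drawn from `carrierProbs`; APOE2 and APOE4 carriers are heterozygous
#' (e2/e3, e3/e4) except for a `homoProb` chance of homozygosity. The
#' e2 + e4 combination is never emitted.
#'
#' @param truth a [CohortTruth-class] (provides the individual ids).
#' @param carrierProbs named probabilities (must sum to 1) for APOE2,
#'   APOE3, APOE4; defaults follow the study frequencies 12/54/16 of 82.
#' @param homoProb probability of a homozygous e2/e2 or e4/e4 genotype.
#' @param seed RNG seed (default spec seed + 2).
#' @return data.frame (individual, allele1, allele2, carrier).
#' @export
generateGenotypes <- function(truth,
                              carrierProbs = c(APOE2 = 12 / 82,
                                               APOE3 = 54 / 82,
                                               APOE4 = 16 / 82),
                              homoProb = 0.1,
                              seed = truth@spec@seed + 2L) {
  if (abs(sum(carrierProbs) - 1) > 1e-9)
    stop("carrier probabilities must sum to 1")
  set.seed(as.integer(seed))
  ids <- names(truth@substage)
  carrier <- sample(names(carrierProbs), length(ids), replace = TRUE,
                    prob = carrierProbs)
  homo <- stats::runif(length(ids)) < homoProb
  a1 <- ifelse(carrier == "APOE2", "e2",
               ifelse(carrier == "APOE4", ifelse(homo, "e4", "e3"), "e3"))
  a2 <- ifelse(carrier == "APOE2", ifelse(homo, "e2", "e3"),
               ifelse(carrier == "APOE4", "e4", "e3"))
  data.frame(individual = ids, allele1 = a1, allele2 = a2,
             carrier = carrier, stringsAsFactors = FALSE)
}

#' Simulate a linear-progression chain cohort
#'
#' Substage clusters arranged along a line in expression space (each node
#' one step from the next) with isotropic noise, on two disjoint gene
#' blocks carrying the same chain; used to validate the adjacency-network
#' construction (the kNN graph should link only adjacent substages).
#'
#' @param nPerSubstage individuals per chain node.
#' @param nGenesPerSet genes per block.
#' @param step mean shift between adjacent nodes (per gene).
#' @param noiseSd per-gene noise sd.
#' @param nodes chain node labels in order.
#' @param seed RNG seed.
#' @return list with `X` (genes x individuals, centred scale), `labels`,
#'   `stageMap`, `setA`, `setB`, `chain` (adjacency matrix of the planted
#'   chain).
#' @export
simulateChainCohort <- function(nPerSubstage = 12, nGenesPerSet = 40,
                                step = 0.5, noiseSd = 1,
                                nodes = c("NCI_Typical", "NCI_MCI",
                                          "MCI_NCI", "MCI_Typical",
                                          "MCI_AD", "AD_LL_MCI", "AD_LL"),
                                seed = 1) {
  set.seed(seed)
  k <- length(nodes)
  labels <- rep(nodes, each = nPerSubstage)
  ids <- sprintf("i%03d", seq_along(labels))
  names(labels) <- ids
  g <- 2 * nGenesPerSet
  mu <- outer(rep(step, g), as.numeric(factor(labels, levels = nodes)) - 1)
  X <- mu + matrix(stats::rnorm(g * length(ids), sd = noiseSd), g)
  genes <- sprintf("cg%03d", seq_len(g))
  dimnames(X) <- list(genes, ids)
  stageMap <- stats::setNames(.substageStage(nodes), nodes)
  chain <- matrix(0, k, k, dimnames = list(nodes, nodes))
  for (i in seq_len(k - 1)) chain[i, i + 1] <- chain[i + 1, i] <- 1
  list(X = X, labels = labels, stageMap = stageMap,
       setA = genes[seq_len(nGenesPerSet)],
       setB = genes[(nGenesPerSet + 1):g], chain = chain)
}
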