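test_that("cohort generation is byte-identical under a fixed seed", {
  sp <- cohortSpec(seed = 9, nGenes = 300L,
                   moduleSizes = c(mna_up = 30L, mna_down = 30L,
                                   na_up = 20L, na_down = 10L,
                                   ca_like = 20L, cb_like = 20L))
  a <- generateCohort(sp)
  b <- generateCohort(sp)
  expect_identical(SummarizedExperiment::assay(a$cohort, "counts"),
                   SummarizedExperiment::assay(b$cohort, "counts"))
  expect_identical(a$truth@meanLog2, b$truth@meanLog2)
  pa <- generateEpigenome(sp, a$truth)
  pb <- generateEpigenome(sp, b$truth)
  expect_identical(lapply(pa, as.data.frame), lapply(pb, as.data.frame))
  expect_identical(generateGenotypes(a$truth), generateGenotypes(b$truth))
})

test_that("spec invariants are enforced with named diagnostics", {
  expect_error(cohortSpec(substageFractions = c(NCI_Typical = 0.5,
                                                NCI_MCI = 0.4)),
               "substageFractions")
  expect_error(cohortSpec(nGenes = 100L), "moduleSizes")
  expect_error(cohortSpec(nPerStage = c(NCI = 0L, MCI = 29L, AD = 28L)),
               "nPerStage")
})

test_that("generated cohorts carry the study structure", {
  sim <- sharedSim()
  ec <- sim$cohort
  expect_equal(as.vector(table(stageLabels(ec))[c("NCI", "MCI", "AD")]),
               c(25L, 29L, 28L))
  tab <- table(sim$truth@substage)
  expect_equal(as.vector(tab[c("MCI_Typical", "MCI_NCI", "MCI_AD",
                              "MCI_NCI_AD")]), c(17L, 4L, 3L, 5L))
  expect_true(all(abs(colSums(tpm(ec)) - 1e6) < 1e3))
  expect_true(all(startsWith(
    names(sim$truth@module)[sim$truth@module == "spikein"], "ERCC-")))
  # every individual exactly one substage; every gene one module
  expect_equal(sort(names(sim$truth@substage)), sort(colnames(ec)))
  expect_equal(sort(names(sim$truth@module)), sort(rownames(ec)))
})

test_that("genotype generator respects carrier classes and exclusions", {
  sim <- sharedSim()
  g3 <- generateGenotypes(sim$truth, carrierProbs = c(APOE2 = 0, APOE3 = 1,
                                                      APOE4 = 0))
  expect_true(all(g3$carrier == "APOE3"))
  expect_true(all(g3$allele1 == "e3" & g3$allele2 == "e3"))
  g <- generateGenotypes(sim$truth, carrierProbs = c(APOE2 = 0.2,
                                                     APOE3 = 0.6,
                                                     APOE4 = 0.2), seed = 99)
  # never e2 together with e4
  expect_false(any((g$allele1 == "e2" & g$allele2 == "e4") |
                   (g$allele1 == "e4" & g$allele2 == "e2")))
  # class frequencies within binomial 99% CI at n = 82
  n <- nrow(g)
  for (cls in c("APOE2", "APOE4")) {
    k <- sum(g$carrier == cls)
    ci <- qbinom(c(0.005, 0.995), n, 0.2)
    expect_gte(k, ci[1]); expect_lte(k, ci[2])
  }
  expect_equal(apoeCarrier(g$allele1, g$allele2), g$carrier)
  expect_error(generateGenotypes(sim$truth,
                                 carrierProbs = c(APOE2 = 0.5, APOE3 = 0.2,
                                                  APOE4 = 0.2)), "sum to 1")
})

test_that("epigenome generator plants typical/untypical structure", {
  sim <- sharedSim()
  sp <- sim$truth@spec
  # no jitter, no drops, single template: typical individuals identical
  clean <- generateEpigenome(sp, sim$truth, nTemplates = 1, jitterSd = 0,
                             dropProb = 0, couplingSlope = 0, seed = 5)
  typ <- names(attr(clean, "typing"))[attr(clean, "typing") != "Untypical"]
  expect_equal(intervalJaccard(clean[[typ[1]]], clean[[typ[2]]]), 1)
  # typical-vs-untypical similarity below within-typical similarity
  peaks <- generateEpigenome(sp, sim$truth, seed = 6)
  ty <- attr(peaks, "typing")
  tIds <- names(ty)[ty != "Untypical"][1:4]
  uIds <- names(ty)[ty == "Untypical"][1:2]
  within <- intervalJaccard(peaks[[tIds[1]]], peaks[[tIds[2]]])
  across <- intervalJaccard(peaks[[tIds[1]]], peaks[[uIds[1]]])
  expect_gt(within, across)
  expect_error(generateEpigenome(sp, sim$truth, typicalFraction = 1.2),
               "typicalFraction")
})

test_that("planted promoter coupling yields positive expression correlation", {
  sim <- sharedSim()
  sp <- sim$truth@spec
  peaks <- generateEpigenome(sp, sim$truth, seed = 7)
  cb <- names(sim$truth@module)[sim$truth@module == "cb_like"]
  ann <- sim$truth@annotation
  proms <- promoterRegions(ann[ann$gene_id %in% cb, ],
                           chromLengths = sp@chromLengths)
  dens <- vapply(peaks, function(p) promoterDensity(p, proms),
                 numeric(length(proms)))
  r <- expressionPromoterCorrelation(tpm(sim$cohort), dens,
                                     colnames(dens), rownames(dens))
  expect_gt(median(r), 0.5)
})

test_that("chain cohorts expose their planted adjacency", {
  ch <- simulateChainCohort(seed = 3)
  expect_equal(length(ch$labels), 12 * 7)
  expect_equal(sum(ch$chain) / 2, 6)
  expect_true(all(ch$stageMap[c("NCI_Typical", "MCI_AD", "AD_LL")] ==
                  c("NCI", "MCI", "AD")))
  expect_identical(simulateChainCohort(seed = 3)$X, ch$X)
})
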