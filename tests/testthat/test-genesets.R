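test_that("directional selection matches a hand oracle and is monotone", {
  res <- data.frame(gene = paste0("g", 1:6),
                    p = c(0.001, 0.04, 0.2, 0.01, 0.06, 0.5),
                    direction = c("up", "up", "up", "down", "down", "down"),
                    stringsAsFactors = FALSE)
  sel <- directionalSelect(res, pUp = 0.05, pDown = 0.01)
  expect_setequal(sel$gene, c("g1", "g2", "g4"))
  expect_equal(nrow(directionalSelect(res, 0, 0)), 0)
  expect_equal(nrow(directionalSelect(res, 1, 1)), 6)
  # monotone in both thresholds (set inclusion)
  s1 <- directionalSelect(res, 0.01, 0.01)$gene
  s2 <- directionalSelect(res, 0.05, 0.06)$gene
  expect_true(all(s1 %in% s2))
})

test_that("separation scan finds planted NCI-AD separation, none when permuted", {
  sim <- sharedSim()
  sc <- cached("scanNA42",
               separationScan(sim$cohort, c("NCI", "AD"), backend = "tpm"))
  expect_gt(sum(sc@cells$separating), 0)
  # permuted labels: no separating cell
  ec <- sim$cohort
  set.seed(77)
  perm <- setNames(sample(stageLabels(ec)), colnames(ec))
  ecPerm <- ExpressionCohort(SummarizedExperiment::assay(ec, "counts"),
                             tpm(ec), stage = perm)
  scP <- separationScan(ecPerm, c("NCI", "AD"), backend = "tpm",
                        pUp = c(0.01, 0.05))
  expect_equal(sum(scP@cells$separating), 0)
})

test_that("largest separating set picks maximal cells with lexicographic ties", {
  mkDiagram <- function(cells, sets) {
    methods::new("PhaseDiagram", groups = c("NCI", "AD"), backend = "tpm",
                 cells = cells, sets = sets, splits = list(),
                 enrich = list())
  }
  cells <- data.frame(pUp = c(0.01, 0.02, 0.02), pDown = c(0.01, 0.01, 0.02),
                      nUp = c(5, 8, 9), nDown = c(5, 4, 3),
                      nGenes = c(10, 12, 12),
                      separating = c(TRUE, TRUE, TRUE))
  sets <- list(paste0("a", 1:10), paste0("b", 1:12), paste0("c", 1:12))
  best <- largestSeparatingSet(mkDiagram(cells, sets))
  expect_equal(geneIds(best), sets[[2]])  # 12 > 10; tie broken by pUp
  bestDown <- largestSeparatingSet(mkDiagram(cells, sets), by = "down")
  expect_equal(geneIds(bestDown), sets[[1]])
  cells$separating <- FALSE
  none <- largestSeparatingSet(mkDiagram(cells, sets))
  expect_equal(length(geneIds(none)), 0)
  expect_match(none@rule, "none found")
})

test_that("stable members intersect enriched clusters across cells", {
  labels <- setNames(rep(c("MCI", "x"), c(5, 5)), paste0("i", 1:10))
  mk <- function(members) {
    methods::new("PhaseDiagram", groups = c("NCI", "MCI", "AD"),
                 backend = "tpm", cells = data.frame(p = 0.01),
                 sets = list(character()), splits = list(NULL),
                 enrich = list(list(MCI = list(passes = TRUE, p = 0.001,
                                               side = 1,
                                               members = members))))
  }
  allIn <- stableMembers(list(mk(paste0("i", 1:5)), mk(paste0("i", 1:5))),
                         "MCI", labels)
  expect_equal(length(allIn$deviators), 0)
  oneOut <- stableMembers(list(mk(paste0("i", 1:5)), mk(paste0("i", 2:5))),
                          "MCI", labels)
  expect_equal(oneOut$deviators, "i1")
  noCell <- methods::new("PhaseDiagram", groups = c("NCI", "MCI", "AD"),
                         backend = "tpm", cells = data.frame(p = 0.01),
                         sets = list(character()), splits = list(NULL),
                         enrich = list(list(MCI = list(passes = FALSE))))
  expect_error(stableMembers(list(noCell), "MCI", labels), "no grid cell")
})

test_that("omnibus stable members isolate the planted MCI_NCI_AD bridges", {
  sim <- sharedSim()
  omni <- cached("omni42", omnibusScan(sim$cohort, backend = "tpm"))
  sm <- stableMembers(list(omni), "MCI", stageLabels(sim$cohort))
  planted <- names(sim$truth@substage)[sim$truth@substage == "MCI_NCI_AD"]
  expect_true(all(planted %in% sm$deviators))
  expect_lte(length(setdiff(sm$deviators, planted)), 1)
})

test_that("union growth keeps complete separation and re-verifies it", {
  sim <- sharedSim()
  sc <- cached("scanNA42",
               separationScan(sim$cohort, c("NCI", "AD"), backend = "tpm"))
  base <- largestSeparatingSet(sc, "base")
  res <- testResultTable(sim$cohort, c("NCI", "AD"), backend = "counts")
  # candidates from the planted na modules: full union should separate
  cand <- res[res$gene %in% names(sim$truth@module)[
    sim$truth@module %in% c("na_up", "na_down")], c("gene", "p")]
  grown <- unionWithSeparation(base, cand, sim$cohort, c("NCI", "AD"),
                               name = "grown")
  expect_true(all(geneIds(base) %in% geneIds(grown)))
  expect_true(all(cand$gene %in% geneIds(grown)))
})

test_that("AD subgroup discovery recovers planted CA/CB clusters and labels", {
  sim <- sharedSim()
  sc <- cached("scanNA42",
               separationScan(sim$cohort, c("NCI", "AD"), backend = "tpm"))
  base <- largestSeparatingSet(sc, "N-A_t")
  resD <- testResultTable(sim$cohort, c("NCI", "AD"), backend = "counts")
  scD <- cached("scanNAD42",
                separationScan(sim$cohort, c("NCI", "AD"),
                               backend = "counts", results = resD))
  candD <- resD[geneIds(largestSeparatingSet(scD, "N-A_D1")),
                c("gene", "p")]
  naSet <- unionWithSeparation(base, candD, sim$cohort, c("NCI", "AD"),
                               name = "N-A1")
  res <- testResultTable(sim$cohort, c("NCI", "AD"), backend = "tpm")
  naSet@direction <- unname(ifelse(
    res[geneIds(naSet), "direction"] == "up", "up", "down"))
  ad <- adSubgroupDiscovery(sim$cohort, naSet, seed = 1)
  expect_false(ad$insufficient)
  mods <- sim$truth@module
  expect_gt(mean(mods[ad$caGenes] == "ca_like"), 0.9)
  expect_gt(mean(mods[ad$cbGenes] == "cb_like"), 0.7)
  parent <- sub("^(AD_..).*$", "\\1", sim$truth@substage)
  adIds <- names(ad$subgroups)
  expect_gt(mean(paste0("AD_", ad$subgroups[adIds]) == parent[adIds]), 0.9)
})

test_that("an effectless cohort yields no usable AD subgroup signal", {
  simNull <- cached("simNull", generateCohort(
    cohortSpec(effectLog2 = 0, seed = 15)))
  st <- stageLabels(simNull$cohort)
  fake <- GeneSetRecord("fake", rownames(simNull$cohort)[1:200],
                        direction = rep(c("up", "down"), 100))
  ad <- adSubgroupDiscovery(simNull$cohort, fake, seed = 1)
  expect_true(ad$insufficient || ad$nSignificant < 10)
})
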