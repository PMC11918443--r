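library(GenomicRanges)

gr <- function(chr, s0, e0)  # 0-based half-open helper
  GRanges(chr, IRanges::IRanges(s0 + 1, e0))

test_that("peak extraction applies the strict fold-change threshold", {
  tr <- GRanges(rep("chr1", 3), IRanges::IRanges(c(1, 11, 21), c(10, 20, 30)),
                score = c(6, 4, 7))
  pk <- peaksFromTrack(tr, 5)
  expect_equal(start(pk), c(1, 21))
  expect_equal(end(pk), c(10, 30))
  border <- GRanges("chr1", IRanges::IRanges(1, 10), score = 5)
  expect_equal(length(peaksFromTrack(border, 5)), 0)
  low <- GRanges("chr1", IRanges::IRanges(1, 10), score = 2)
  expect_equal(length(peaksFromTrack(low, 5)), 0)
})

test_that("interval Jaccard follows the bedtools definition", {
  a <- gr("chr1", 0, 10)
  expect_equal(intervalJaccard(a, a), 1)
  expect_equal(intervalJaccard(a, gr("chr1", 5, 20)), 5 / 20)
  expect_equal(intervalJaccard(a, gr("chr2", 0, 10)), 0)
  expect_equal(intervalJaccard(GRanges(), GRanges()), 0)
})

test_that("the Jaccard matrix matches bitmap and per-pair oracles", {
  set.seed(31)
  sets <- lapply(1:6, function(i) {
    s <- sort(sample(900, 8))
    reduce(GRanges("chr1", IRanges::IRanges(s, s + sample(5:60, 8, TRUE))))
  })
  names(sets) <- paste0("p", 1:6)
  J <- jaccardMatrix(sets)
  expect_equal(J, t(J))
  expect_equal(unname(diag(J)), rep(1, 6))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(J[i, j], bitmapJaccard(sets[[i]], sets[[j]]),
                 tolerance = 1e-12)
    expect_equal(J[i, j], intervalJaccard(sets[[i]], sets[[j]]),
                 tolerance = 1e-12)
  }
})

test_that("epigenome typing recovers planted template groups", {
  # 8 typical + 3 untypical: block-structured Jaccard matrix
  n <- 11
  ids <- sprintf("s%02d", 1:n)
  J <- matrix(0.05, n, n, dimnames = list(ids, ids))
  J[1:8, 1:8] <- 0.6
  J[9:11, 9:11] <- 0.55
  diag(J) <- 1
  ty <- epigenomeTyping(J)
  expect_equal(unname(ty$typing[1:8]), rep("Typical", 8))
  expect_equal(unname(ty$typing[9:11]), rep("Untypical", 3))
  # order invariance up to the documented tie rules
  ord <- sample(ids)
  ty2 <- epigenomeTyping(J[ord, ord])
  expect_equal(ty2$typing[ids], ty$typing)
  # identical individuals degenerate to all-Typical
  flat <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  expect_warning(tf <- epigenomeTyping(flat), "identical")
  expect_true(all(tf$typing == "Typical"))
})

test_that("three-cluster similarity structure selects k = 3 with subtypes", {
  n <- 12
  ids <- sprintf("s%02d", 1:n)
  J <- matrix(0.05, n, n, dimnames = list(ids, ids))
  J[1:4, 1:4] <- 0.8; J[5:8, 5:8] <- 0.8; J[9:12, 9:12] <- 0.8
  J[1:4, 5:8] <- J[5:8, 1:4] <- 0.15  # two related typical templates
  diag(J) <- 1
  ty <- epigenomeTyping(J)
  expect_equal(ty$k, 3)
  expect_setequal(unique(unname(ty$typing[1:8])), c("Typical1", "Typical2"))
  expect_equal(unname(ty$typing[9:12]), rep("Untypical", 4))
})

test_that("chromosome density is covered length over chromosome length", {
  lens <- c(chr1 = 1000, chr2 = 500)
  expect_equal(chromosomeDensity(gr("chr1", 0, 1000), lens),
               c(chr1 = 1, chr2 = 0))
  expect_equal(unname(chromosomeDensity(gr("chr2", 0, 250), lens)["chr2"]),
               0.5)
  expect_equal(unname(chromosomeDensity(GRanges(), lens)), c(0, 0))
  expect_error(chromosomeDensity(gr("chrX", 0, 10), lens), "chrX")
})

test_that("promoters are 1 kbp upstream with strand and clipping rules", {
  ann <- data.frame(gene_id = c("plus", "minus", "edge"),
                    chrom = "chr1", strand = c("+", "-", "+"),
                    tss = c(5000, 5000, 400))
  pr <- promoterRegions(ann)
  # + strand: 0-based [4000, 5000) -> 1-based [4001, 5000]
  expect_equal(start(pr["plus"]), 4001)
  expect_equal(end(pr["plus"]), 5000)
  # - strand: 0-based [5000, 6000)
  expect_equal(start(pr["minus"]), 5001)
  expect_equal(end(pr["minus"]), 6000)
  # clipped at zero: [0, 400), width 400
  expect_equal(width(pr["edge"]), 400)
  expect_equal(start(pr["edge"]), 1)
})

test_that("promoter density uses the fixed 1 kb denominator", {
  ann <- data.frame(gene_id = c("full", "half", "none"),
                    chrom = "chr1", strand = "+",
                    tss = c(2000, 5000, 9000))
  pr <- promoterRegions(ann)
  peaks <- reduce(c(gr("chr1", 1000, 2000), gr("chr1", 4000, 4500)))
  d <- promoterDensity(peaks, pr)
  expect_equal(unname(d), c(1, 0.5, 0))
  # overlap totals never exceed total peak length
  expect_lte(sum(d) * 1000, sum(width(peaks)))
})

test_that("expression-promoter correlations respect planted sign and zeros", {
  set.seed(32)
  ids <- paste0("i", 1:20)
  expr <- rbind(pos = runif(20, 1, 10), neg = runif(20, 1, 10),
                none = runif(20, 1, 10))
  colnames(expr) <- ids
  dens <- rbind(pos = expr["pos", ] / 10 + rnorm(20, 0, 0.05),
                neg = 1 - expr["neg", ] / 10 + rnorm(20, 0, 0.05),
                none = rep(0, 20))
  colnames(dens) <- ids
  r <- expressionPromoterCorrelation(expr, dens, ids, rownames(expr))
  expect_gt(r["pos"], 0.5)
  expect_lt(r["neg"], -0.5)
  expect_equal(unname(r["none"]), 0)
  expect_error(expressionPromoterCorrelation(expr, dens, ids[1:2], "pos"),
               "at least 3")
})
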