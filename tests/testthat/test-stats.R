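test_that("centering transform zeroes per-gene means of log2(TPM+1)", {
  tpmMat <- rbind(g1 = c(3, 3, 3), g2 = c(0, 3, 0))
  X <- centerLogExpression(tpmMat)
  expect_equal(unname(X["g1", ]), c(0, 0, 0))
  # log2(1)=0, log2(4)=2, mean 1 over the two distinct values
  expect_equal(unname(centerLogExpression(rbind(c(0, 3)))[1, ]), c(-1, 1))
  set.seed(1)
  M <- matrix(rexp(60), 6)
  expect_equal(unname(rowMeans(centerLogExpression(M))), rep(0, 6))
  expect_error(centerLogExpression(matrix(-1)), "non-negative")
})

test_that("Welch t matches stats::t.test and degenerates sanely", {
  a <- c(1, 2, 3)
  expect_equal(welchT(a, a)[c("t", "p")], list(t = 0, p = 1))
  r <- welchT(a, a + 10)
  expect_lt(r$p, 0.01)
  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(5 + i %% 4); y <- rnorm(7, 0.5)
    ref <- t.test(x, y)
    got <- welchT(x, y)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
  }
  # zero variance in both groups
  expect_equal(welchT(c(1, 1), c(1, 1))$p, 1)
  expect_equal(welchT(c(1, 1), c(2, 2))$p, 0)
  expect_error(welchT(1, c(1, 2)), "at least 2")
})

test_that("Welch p agrees with a permutation oracle", {
  set.seed(3)
  x <- rnorm(10); y <- rnorm(10, 0.8)
  obs <- abs(welchT(x, y)$t)
  pooled <- c(x, y)
  perm <- replicate(4000, {
    idx <- sample(20, 10)
    abs(welchT(pooled[idx], pooled[-idx])$t)
  })
  pPerm <- mean(perm >= obs)
  expect_lt(abs(welchT(x, y)$p - pPerm), 0.02)
})

test_that("one-way ANOVA matches sums-of-squares oracle and F = t^2", {
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  r <- anovaOneway(g)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  set.seed(4)
  gs <- list(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  r <- anovaOneway(gs)
  # brute-force SS oracle
  x <- unlist(gs); grand <- mean(x)
  ssb <- sum(vapply(gs, function(v) length(v) * (mean(v) - grand)^2, 1))
  ssw <- sum(vapply(gs, function(v) sum((v - mean(v))^2), 1))
  Fref <- (ssb / 2) / (ssw / 21)
  expect_equal(r$F, Fref, tolerance = 1e-10)
  expect_equal(r$p, pf(Fref, 2, 21, lower.tail = FALSE), tolerance = 1e-10)
  # two groups: equals pooled-variance t-test
  a <- rnorm(6); b <- rnorm(6, 1)
  r2 <- anovaOneway(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-10)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("BH step-up matches hand computation and is monotone in alpha", {
  r <- bhFdr(c(0.01, 0.04, 0.03, 0.005), alpha = 0.1)
  expect_equal(r$q, c(0.02, 0.04, 0.04, 0.02))
  expect_true(all(r$reject))
  r1 <- bhFdr(0.04, alpha = 0.1)
  expect_equal(r1$q, 0.04)
  expect_true(r1$reject)
  expect_false(any(bhFdr(rep(1, 5))$reject))
  set.seed(5)
  p <- runif(200)^2
  prev <- rep(FALSE, 200)
  for (a in c(0.01, 0.05, 0.1, 0.2)) {
    cur <- bhFdr(p, alpha = a)$reject
    expect_true(all(cur[prev]))  # rejections grow with alpha
    prev <- cur
  }
})

test_that("ratio-method size factors: scale equivariance and hand oracle", {
  cts <- matrix(c(10, 20, 30, 40,
                  20, 40, 60, 80,
                  10, 10, 10, 10), 4, 3,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  sf <- sizeFactors(cts, q = 0.5)
  ref <- exp(rowMeans(log(cts)))
  expect_equal(unname(sf$factors),
               unname(apply(cts / ref, 2, median)))
  # identical samples
  same <- cbind(a = c(5, 8), b = c(5, 8), c = c(5, 8))
  sfs <- sizeFactors(same)
  expect_equal(sfs$dispersionRatio, 0)
  # duplicating a sample at double depth doubles its factor
  dup <- cbind(cts, s4 = 2 * cts[, 1])
  sfd <- sizeFactors(dup)
  expect_equal(unname(sfd$factors["s4"]), 2 * unname(sfd$factors["s1"]))
  # gene permutation invariance
  expect_equal(sizeFactors(cts[c(3, 1, 4, 2), ])$factors, sf$factors)
  # quartile variants stay positive
  expect_true(all(sizeFactors(cts, q = 0.25)$factors > 0))
  expect_true(all(sizeFactors(cts, q = 0.75)$factors > 0))
  expect_error(sizeFactors(matrix(c(0, 1, 1, 0), 2)), "all-positive")
})

test_that("low-expression filter drops only genes low in all three stages", {
  tpmMat <- rbind(low = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
                  mid = c(0.05, 0.05, 0.2, 0.2, 0.05, 0.05),
                  "ERCC-00002" = c(50, 50, 50, 50, 50, 50),
                  hi = c(5, 5, 5, 5, 5, 5))
  colnames(tpmMat) <- paste0("s", 1:6)
  stage <- setNames(rep(c("NCI", "MCI", "AD"), each = 2), colnames(tpmMat))
  kept <- lowExpressionFilter(tpmMat, stage)
  expect_setequal(kept, c("mid", "hi"))
})

test_that("pearson handles exact and degenerate cases", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(pearson(x, rep(3, 10)), 0)
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("test result tables carry directions relative to the later group", {
  ec <- tinyCohort()
  res <- testResultTable(ec, c("NCI", "AD"), backend = "tpm")
  tp <- tpm(ec)
  st <- stageLabels(ec)
  up <- rowMeans(tp[, st == "AD"]) > rowMeans(tp[, st == "NCI"])
  expect_equal(res$direction == "up", unname(up))
  res3 <- testResultTable(ec, c("NCI", "MCI", "AD"), backend = "counts")
  expect_true(all(res3$p >= 0 & res3$p <= 1))
  expect_true(all(res3$direction == "any"))
})
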