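#' @include AllClasses.R
NULL

#' Centering transform for clustering
#'
#' Computes `X = log2(tpm + 1) - C`, with per-gene `C` chosen so that the
#' mean of X over the included individuals is zero for every gene. This is
#' the expression representation used by every cluster analysis in the
#' package.
#'
#' @param tpm genes x samples matrix of non-negative TPM values.
#' @return matrix of the same shape with zero row means.
#' @export
centerLogExpression <- function(tpm) {
  if (any(tpm < 0)) stop("tpm must be non-negative")
  x <- log2(tpm + 1)
  x - rowMeans(x)
}

#' Welch's two-sample t-test
#'
#' Two-tailed Welch t with Satterthwaite degrees of freedom. When both
#' groups have zero variance the p-value is 1 for equal means and 0
#' (degenerate limit) for unequal means.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t`, `p`, `df`, `meanA`, `meanB`.
#' @export
welchT <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per group")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("values must be finite")
  r <- .rowWelch(matrix(a, 1), matrix(b, 1))
  list(t = r$stat[1], p = r$p[1], df = r$df[1],
       meanA = mean(a), meanB = mean(b))
}

# vectorised Welch t over rows of two matrices (same genes, two sample sets)
.rowWelch <- function(A, B) {
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  se2 <- vA / nA + vB / nB
  t <- (mA - mB) / sqrt(se2)
  df <- se2^2 / (vA^2 / (nA^2 * (nA - 1)) + vB^2 / (nB^2 * (nB - 1)))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & (mA == mB)
    t[eq] <- 0; p[eq] <- 1; df[eq] <- nA + nB - 2
    ne <- degen & (mA != mB)
    t[ne] <- sign(mA - mB)[ne] * Inf; p[ne] <- 0; df[ne] <- nA + nB - 2
  }
  list(stat = t, p = p, df = df, meanA = mA, meanB = mB)
}

#' One-way analysis of variance
#'
#' Classical one-way fixed-effects ANOVA. With all groups identical the
#' statistic is defined as F = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, each length >= 2).
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
anovaOneway <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 values")
  x <- matrix(unlist(groups), 1)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  r <- .rowAnova(x, g)
  list(F = r$stat[1], p = r$p[1], df1 = r$df1, df2 = r$df2)
}

# vectorised one-way ANOVA over rows; g: factor over columns
.rowAnova <- function(X, g) {
  g <- droplevels(as.factor(g))
  k <- nlevels(g); n <- ncol(X)
  grand <- rowMeans(X)
  ssb <- 0
  gm <- vector("list", k)
  for (i in seq_len(k)) {
    idx <- which(g == levels(g)[i])
    gm[[i]] <- rowMeans(X[, idx, drop = FALSE])
    ssb <- ssb + length(idx) * (gm[[i]] - grand)^2
  }
  sst <- rowSums((X - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1; df2 <- n - k
  F <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  zerow <- ssw == 0
  if (any(zerow)) {
    eq <- zerow & (ssb <= 1e-300)
    F[eq] <- 0; p[eq] <- 1
    ne <- zerow & (ssb > 1e-300)
    F[ne] <- Inf; p[ne] <- 0
  }
  names(gm) <- levels(g)
  list(stat = F, p = p, df1 = df1, df2 = df2, groupMeans = gm)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted q-values (via [stats::p.adjust()]) and rejection flags
#' at the given FDR level. The package-wide significance convention is
#' FDR < 0.1.
#'
#' @param p vector of p-values in [0, 1].
#' @param alpha FDR level (default 0.1).
#' @return list with `q` (adjusted values) and `reject` (logical).
#' @export
bhFdr <- function(p, alpha = 0.1) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = !is.na(q) & q <= alpha)
}

#' Size factors by the ratio method
#'
#' Per-sample size factors defined as a quantile over genes of the ratio of
#' each sample's count to a reference built from per-gene geometric means
#' over samples (genes containing any zero are excluded from the reference).
#' `q = 0.5` gives the median-of-ratios (MOR) factor; `q = 0.25` and
#' `q = 0.75` the first/third-quartile variants (1OR, 3OR). The dispersion
#' ratio sd(factors)/mean(factors) summarises between-sample depth spread.
#'
#' @param counts genes x samples non-negative count matrix.
#' @param q quantile of the ratio distribution (0.25, 0.5 or 0.75 in
#'   typical use; any value in (0,1) is accepted).
#' @return list with `factors` (named, per sample), `q`,
#'   `dispersionRatio`.
#' @export
sizeFactors <- function(counts, q = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene with all-positive counts; cannot build reference")
  ref <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  ratios <- counts[pos, , drop = FALSE] / ref
  f <- apply(ratios, 2, stats::quantile, probs = q, names = FALSE)
  names(f) <- colnames(counts)
  list(factors = f, q = q, dispersionRatio = stats::sd(f) / mean(f))
}

#' Low-expression and spike-in filter
#'
#' Drops a gene only when its mean TPM is below `threshold` in the NCI
#' group AND the MCI group AND the AD group, and drops any gene whose id
#' matches one of the spike-in prefixes.
#'
#' @param tpm genes x samples TPM matrix.
#' @param stage named character of per-sample stages.
#' @param threshold TPM threshold (default 0.1).
#' @param spikePrefixes character vector of id prefixes to drop
#'   unconditionally (default `"ERCC-"`).
#' @return character vector of kept gene ids.
#' @export
lowExpressionFilter <- function(tpm, stage, threshold = 0.1,
                                spikePrefixes = "ERCC-") {
  stage <- stage[colnames(tpm)]
  if (anyNA(stage)) stop("every sample needs a stage label")
  low <- rep(TRUE, nrow(tpm))
  for (st in intersect(.STAGES, unique(stage))) {
    m <- rowMeans(tpm[, stage == st, drop = FALSE])
    low <- low & (m < threshold)
  }
  spike <- rep(FALSE, nrow(tpm))
  for (pre in spikePrefixes)
    spike <- spike | startsWith(rownames(tpm), pre)
  rownames(tpm)[!(low | spike)]
}

#' Pearson correlation with a constant-vector convention
#'
#' Plain Pearson correlation, except that a constant vector (e.g. a gene
#' whose promoter never carries an epigenome mark) yields r = 0 rather
#' than NA, so such genes populate the zero bin of correlation histograms.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation coefficient in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

# ---------------------------------------------------------------------------
# Test result tables (the backend layer of the threshold-grid searches)
# ---------------------------------------------------------------------------

# expression values a backend tests on: raw TPM for the "tpm" backend,
# log2(1 + MOR-normalised counts) for the "counts" backend
.backendValues <- function(cohort, backend) {
  backend <- match.arg(backend, c("tpm", "counts"))
  if (backend == "tpm") return(tpm(cohort))
  cts <- SummarizedExperiment::assay(cohort, "counts")
  f <- sizeFactors(cts, q = 0.5)$factors
  log2(1 + sweep(cts, 2, f, "/"))
}

#' Per-gene differential test table
#'
#' Runs the per-gene test behind a threshold-grid search: Welch's t for a
#' pair of stages, one-way ANOVA for a triple. The `"tpm"` backend tests
#' raw TPM values; the `"counts"` backend tests log2(1 + x) of
#' median-of-ratios-normalised counts. Any function producing a per-gene
#' p-value table of the same shape can be plugged in where a
#' `TestResultTable` is consumed (e.g. a negative-binomial likelihood-ratio
#' test for real-data runs).
#'
#' @param cohort an [ExpressionCohort-class].
#' @param groups 2 (pairwise) or 3 (omnibus) stage names; for a pair the
#'   direction labels refer to the SECOND group ("up" = higher mean there).
#' @param backend `"tpm"` or `"counts"`.
#' @param genes optional subset of gene ids to test.
#' @return data.frame with columns gene, stat, p, direction and per-group
#'   means.
#' @export
testResultTable <- function(cohort, groups, backend = "tpm", genes = NULL) {
  st <- stageLabels(cohort)
  if (!all(groups %in% st)) stop("group(s) absent from the cohort")
  vals <- .backendValues(cohort, backend)
  if (!is.null(genes)) vals <- vals[genes, , drop = FALSE]
  if (length(groups) == 2) {
    A <- vals[, st == groups[1], drop = FALSE]
    B <- vals[, st == groups[2], drop = FALSE]
    r <- .rowWelch(A, B)
    out <- data.frame(gene = rownames(vals), stat = r$stat, p = r$p,
                      meanA = r$meanA, meanB = r$meanB,
                      direction = ifelse(r$meanB > r$meanA, "up",
                                         ifelse(r$meanB < r$meanA, "down",
                                                "none")),
                      stringsAsFactors = FALSE)
  } else if (length(groups) == 3) {
    keep <- st %in% groups
    r <- .rowAnova(vals[, keep, drop = FALSE],
                   factor(st[keep], levels = groups))
    out <- data.frame(gene = rownames(vals), stat = r$stat, p = r$p,
                      direction = "any", stringsAsFactors = FALSE)
    for (g in groups) out[[paste0("mean_", g)]] <- r$groupMeans[[g]]
  } else stop("groups must name 2 or 3 stages")
  rownames(out) <- out$gene
  attr(out, "groups") <- groups
  attr(out, "backend") <- backend
  out
}
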