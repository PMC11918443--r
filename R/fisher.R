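#' @include AllClasses.R
NULL

# log multivariate-hypergeometric probability constant for fixed margins:
# log P(table) = sum(lfactorial(rowsums)) + sum(lfactorial(colsums))
#              - lfactorial(n) - sum(lfactorial(cells))

.checkContingency <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("contingency table entries must be non-negative")
  if (any(abs(tab - round(tab)) > 1e-8))
    stop("contingency table entries must be integers")
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least a 2 x 2 table")
  storage.mode(tab) <- "double"
  round(tab)
}

# upper bound on the number of tables with the given margins
.tableCountBound <- function(rs, cS) {
  prod(vapply(rs, function(r) choose(r + length(cS) - 1, length(cS) - 1),
              numeric(1)))
}

#' Exact Fisher test for r x c contingency tables
#'
#' Exact two-sided p-value by full enumeration of all tables with the
#' observed margins: p is the total multivariate-hypergeometric probability
#' of tables whose probability does not exceed that of the observed table
#' (with relative tolerance 1e-7, the convention needed to reproduce
#' p-values printed by standard statistical environments).
#'
#' @param tab non-negative integer matrix, at least 2 x 2.
#' @param details if TRUE also return the total enumerated probability
#'   (which must be 1 up to rounding) and the number of tables.
#' @return the p-value, or (with `details`) a list with `p`, `totalProb`,
#'   `nTables`.
#' @examples
#' fisherExactRxC(rbind(c(6, 4, 3), c(0, 0, 4)))  # 0.04328
#' @export
fisherExactRxC <- function(tab, details = FALSE) {
  tab <- .checkContingency(tab)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (n < 1) stop("table total must be at least 1")
  if (any(rs == 0) || any(cs == 0)) {
    warning("degenerate margin (all-zero row or column); p = 1")
    if (details) return(list(p = 1, totalProb = 1, nTables = 1L))
    return(1)
  }
  if (.tableCountBound(rs, cs) > 1e8)
    stop("margin space too large for exact enumeration (> 1e8 tables); ",
         "consider a Monte-Carlo approximation")
  K <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n)
  logPObs <- K - sum(lfactorial(tab))
  cut <- logPObs + log1p(1e-7)
  r <- length(rs); cc <- length(cs)
  pSum <- 0; totSum <- 0; nTab <- 0L
  colRem <- cs
  # enumerate rows 1..r-1 as bounded compositions; last row is forced
  enumRow <- function(i, logAcc) {
    if (i == r) {
      lp <- K - (logAcc + sum(lfactorial(colRem)))
      pr <- exp(lp)
      totSum <<- totSum + pr
      nTab <<- nTab + 1L
      if (lp <= cut) pSum <<- pSum + pr
      return(invisible())
    }
    enumCell(i, 1L, rs[i], logAcc)
  }
  enumCell <- function(i, j, rowRem, logAcc) {
    if (j == cc) {
      if (rowRem > colRem[j]) return(invisible())
      colRem[j] <<- colRem[j] - rowRem
      enumRow(i + 1L, logAcc + lfactorial(rowRem))
      colRem[j] <<- colRem[j] + rowRem
      return(invisible())
    }
    hi <- min(rowRem, colRem[j])
    lo <- max(0, rowRem - sum(colRem[(j + 1L):cc]))
    if (lo > hi) return(invisible())
    for (v in lo:hi) {
      colRem[j] <<- colRem[j] - v
      enumCell(i, j + 1L, rowRem - v, logAcc + lfactorial(v))
      colRem[j] <<- colRem[j] + v
    }
  }
  enumRow(1L, 0)
  p <- min(pSum, 1)
  if (details) list(p = p, totalProb = totSum, nTables = nTab) else p
}

#' Exact Fisher test for 2 x 2 tables
#'
#' Closed-form two-sided p via the hypergeometric tail-sum with the same
#' probability-mass ordering rule as [fisherExactRxC()]; serves as an
#' independent oracle for the general enumerator on their shared domain.
#'
#' @param tab 2 x 2 non-negative integer matrix.
#' @return the two-sided p-value.
#' @examples
#' fisherExact2x2(rbind(c(19, 5), c(3, 2)))  # 0.5688
#' @export
fisherExact2x2 <- function(tab) {
  tab <- .checkContingency(tab)
  if (nrow(tab) != 2 || ncol(tab) != 2) stop("table must be 2 x 2")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    warning("degenerate margin (all-zero row or column); p = 1")
    return(1)
  }
  m <- cs[1]; nn <- cs[2]; k <- rs[1]
  lo <- max(0, k - nn); hi <- min(k, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, nn, k)
  pObs <- stats::dhyper(tab[1, 1], m, nn, k)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}
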