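# shared fixtures, computed lazily and cached for the whole test run
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# default synthetic cohort (the study conditions)
sharedSim <- function() cached("sim", generateCohort(cohortSpec(seed = 42)))

# a small hand-made cohort for cheap I/O-ish tests
tinyCohort <- function() {
  set.seed(7)
  counts <- matrix(rpois(60, 60), 10, 6,
                   dimnames = list(sprintf("g%02d", 1:10),
                                   sprintf("s%d", 1:6)))
  ExpressionCohort(counts, stage = rep(c("NCI", "MCI", "AD"), each = 2))
}

# brute-force per-basepair Jaccard on a small genome
bitmapJaccard <- function(a, b, len = 1000) {
  cov <- function(gr) {
    v <- rep(FALSE, len)
    for (i in seq_along(gr)) {
      s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
      v[s:min(e, len)] <- TRUE
    }
    v
  }
  va <- cov(a); vb <- cov(b)
  u <- sum(va | vb)
  if (u == 0) 0 else sum(va & vb) / u
}

# quadratic-time reference UPGMA returning cophenetic distances
referenceUpgmaCophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n + (n - 1))
  dd <- matrix(Inf, n + n - 1, n + n - 1)
  dd[seq_len(n), seq_len(n)] <- d
  diag(dd) <- Inf
  coph <- matrix(0, n, n)
  sizes <- c(rep(1, n), rep(0, n - 1))
  members <- c(lapply(seq_len(n), identity), vector("list", n - 1))
  cur <- n
  repeat {
    idx <- which(active[seq_len(cur)])
    if (length(idx) < 2) break
    sub <- dd[idx, idx, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- idx[best[1]]; j <- idx[best[2]]
    h <- dd[i, j]
    cur <- cur + 1
    members[[cur]] <- c(members[[i]], members[[j]])
    sizes[cur] <- sizes[i] + sizes[j]
    for (a in members[[i]]) for (b in members[[j]]) {
      coph[a, b] <- coph[b, a] <- h
    }
    for (k in which(active[seq_len(cur - 1)])) {
      if (k == i || k == j) next
      dd[cur, k] <- dd[k, cur] <-
        (sizes[i] * dd[i, k] + sizes[j] * dd[j, k]) / (sizes[i] + sizes[j])
    }
    active[c(i, j)] <- FALSE
    active[cur] <- TRUE
  }
  coph
}
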