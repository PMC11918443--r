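#' @include AllClasses.R clustering.R
#' @import GenomicRanges
#' @importFrom IRanges IRanges
NULL

# internal: total covered length of a (merged) GRanges
.coveredLength <- function(gr) sum(as.numeric(GenomicRanges::width(gr)))

#' Extract peak regions from a fold-change track
#'
#' Regions where the fold-change-over-control signal is strictly greater
#' than `fcThreshold` (default 5) define the peak set; adjacent qualifying
#' segments are merged.
#'
#' @param track a GRanges with a numeric `score` column (a step function:
#'   segments must not overlap), e.g. from [readBedGraph()].
#' @param fcThreshold threshold on the fold change (strict inequality).
#' @return merged GRanges of peak regions.
#' @export
peaksFromTrack <- function(track, fcThreshold = 5) {
  sc <- GenomicRanges::mcols(track)$score
  if (is.null(sc)) stop("track needs a numeric 'score' column")
  GenomicRanges::reduce(track[sc > fcThreshold])
}

#' Jaccard coefficient of two genomic interval sets
#'
#' `J = |a INTERSECT b| / (|a| + |b| - |a INTERSECT b|)` over covered base
#' pairs; 0 when the union is empty.
#'
#' @param a,b GRanges (merged internally).
#' @return Jaccard coefficient in [0, 1].
#' @export
intervalJaccard <- function(a, b) {
  a <- GenomicRanges::reduce(a); b <- GenomicRanges::reduce(b)
  # disjoint seqlevels are a legitimate input (Jaccard 0), not a warning
  inter <- .coveredLength(suppressWarnings(
    GenomicRanges::intersect(a, b, ignore.strand = TRUE)))
  uni <- .coveredLength(a) + .coveredLength(b) - inter
  if (uni == 0) return(0)
  inter / uni
}

#' Pairwise Jaccard matrix over individuals
#'
#' Equivalent to [intervalJaccard()] on every pair, but computed by a
#' linear event sweep on flattened coordinates so that large cohorts stay
#' fast.
#'
#' @param sets named list of GRanges, one per individual.
#' @return symmetric matrix with unit diagonal.
#' @export
jaccardMatrix <- function(sets) {
  sets <- lapply(sets, GenomicRanges::reduce)
  n <- length(sets)
  chroms <- unique(unlist(lapply(sets, function(g)
    as.character(GenomicRanges::seqnames(g)))))
  # flatten (chrom, start, end] to one axis; merged sets cannot straddle
  # the 1e12 offsets
  flat <- lapply(sets, function(g) {
    off <- (match(as.character(GenomicRanges::seqnames(g)), chroms) - 1) * 1e12
    list(s = off + GenomicRanges::start(g) - 1, e = off + GenomicRanges::end(g))
  })
  len <- vapply(flat, function(f) sum(f$e - f$s), numeric(1))
  J <- diag(1, n)
  dimnames(J) <- list(names(sets), names(sets))
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- flat[[i]]; b <- flat[[j]]
    p <- c(a$s, a$e, b$s, b$e)
    dA <- c(rep(1, length(a$s)), rep(-1, length(a$e)),
            numeric(2 * length(b$s)))
    dB <- c(numeric(2 * length(a$s)),
            rep(1, length(b$s)), rep(-1, length(b$e)))
    o <- order(p)
    p <- p[o]
    both <- cumsum(dA[o]) > 0 & cumsum(dB[o]) > 0
    inter <- sum(diff(p)[both[-length(both)]])
    uni <- len[i] + len[j] - inter
    J[i, j] <- J[j, i] <- if (uni == 0) 0 else inter / uni
  }
  J
}

#' Type individuals by their epigenome similarity vectors
#'
#' Each individual is represented by its row of the Jaccard matrix (the
#' self-entry 1.0 is retained by default). Rows are clustered with
#' Euclidean distance and group-average linkage. The larger side of the
#' first split is `Typical`, the smaller `Untypical` (tie: the side with
#' the lexicographically smallest id is Typical, with a warning). The
#' number of clusters `k*` is selected by the elbow method over the SSE of
#' hierarchical cuts; when `k* >= 3` the Typical side is split at its top
#' merge into `Typical1` / `Typical2` (Typical1 holds the smallest id).
#'
#' @param jmat symmetric Jaccard matrix with dimnames.
#' @param kMax maximum k scanned by the elbow (default 6).
#' @param dropSelf drop the self-similarity entries from the vectors.
#' @return list with `typing` (named character), `k` (selected number of
#'   clusters), `sse` (curve), `tree` (the hclust object).
#' @export
epigenomeTyping <- function(jmat, kMax = 6, dropSelf = FALSE) {
  n <- nrow(jmat)
  if (n < 3) stop("need at least 3 individuals")
  ids <- rownames(jmat)
  V <- jmat
  if (dropSelf) {
    V <- t(vapply(seq_len(n), function(i) jmat[i, -i], numeric(n - 1)))
    rownames(V) <- ids
  }
  D <- as.matrix(stats::dist(V))
  if (max(D) == 0) {
    warning("all individuals identical; typing degenerates to all-Typical")
    return(list(typing = setNames(rep("Typical", n), ids), k = 1L,
                sse = c(`1` = 0), tree = NULL))
  }
  hc <- averageLinkage(D)
  ks <- seq_len(min(kMax, n))
  sse <- vapply(ks, function(k) {
    ct <- stats::cutree(hc, k)
    sum(vapply(unique(ct), function(cl) {
      M <- V[ct == cl, , drop = FALSE]
      sum(sweep(M, 2, colMeans(M))^2)
    }, numeric(1)))
  }, numeric(1))
  kStar <- .elbowK(ks, sse)
  split <- firstBranchSplit(hc)
  sizes <- lengths(split)
  if (sizes[1] == sizes[2]) {
    warning("first split is a tie; side with smallest id taken as Typical")
    typSide <- 1L
  } else typSide <- which.max(sizes)
  typing <- setNames(rep("Untypical", n), ids)
  typing[split[[typSide]]] <- "Typical"
  if (kStar >= 3) {
    typIds <- split[[typSide]]
    for (k in 3:n) {
      ct <- stats::cutree(hc, k)
      inTyp <- unique(ct[typIds])
      if (length(inTyp) >= 2) {
        sub1 <- typIds[ct[typIds] == ct[min(typIds)]]
        typing[typIds] <- "Typical2"
        typing[sub1] <- "Typical1"
        break
      }
    }
  }
  names(sse) <- ks
  list(typing = typing, k = kStar, sse = sse, tree = hc)
}

#' Per-chromosome peak density
#'
#' Total covered peak length on each chromosome divided by the chromosome
#' length.
#'
#' @param set GRanges of (merged) peaks.
#' @param chromLengths named numeric of chromosome lengths (bp).
#' @return named numeric densities in [0, 1] (one per chromosome in
#'   `chromLengths`).
#' @export
chromosomeDensity <- function(set, chromLengths) {
  set <- GenomicRanges::reduce(set)
  chroms <- as.character(GenomicRanges::seqnames(set))
  unknown <- setdiff(unique(chroms), names(chromLengths))
  if (length(unknown))
    stop("peaks on chromosome(s) missing from lengths: ",
         paste(unknown, collapse = ", "))
  out <- setNames(numeric(length(chromLengths)), names(chromLengths))
  w <- tapply(as.numeric(GenomicRanges::width(set)), chroms, sum)
  out[names(w)] <- w / chromLengths[names(w)]
  out
}

#' Promoter regions: 1 kbp upstream of each TSS
#'
#' On the + strand the promoter is the half-open interval
#' `[tss - upstream, tss)` (0-based); on the - strand `[tss, tss +
#' upstream)`. Promoters are clipped at position 0 and at the chromosome
#' end.
#'
#' @param annot data.frame with columns gene_id, chrom, strand ("+"/"-"),
#'   tss (0-based).
#' @param upstream promoter length in bp (default 1000).
#' @param chromLengths optional named lengths for right-clipping.
#' @return named GRanges, one (possibly clipped) promoter per gene.
#' @export
promoterRegions <- function(annot, upstream = 1000, chromLengths = NULL) {
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(annot)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  if (any(annot$tss < 0)) stop("tss must be >= 0")
  if (!all(annot$strand %in% c("+", "-"))) stop("strand must be + or -")
  # 0-based half-open -> 1-based closed GRanges
  start0 <- ifelse(annot$strand == "+", annot$tss - upstream, annot$tss)
  end0 <- start0 + upstream
  start0 <- pmax(start0, 0)
  if (!is.null(chromLengths))
    end0 <- pmin(end0, chromLengths[annot$chrom])
  keep <- end0 > start0
  gr <- GenomicRanges::GRanges(
    annot$chrom[keep],
    IRanges::IRanges(start = start0[keep] + 1, end = end0[keep]),
    strand = annot$strand[keep])
  names(gr) <- annot$gene_id[keep]
  gr
}

#' Epigenome mark density on promoters
#'
#' For each gene: covered length of the overlap between the peak set and
#' the gene's promoter, divided by the nominal promoter length
#' (`denominator`, default 1000 bp even for clipped promoters).
#'
#' @param peaks GRanges of peaks (merged internally).
#' @param promoters named GRanges from [promoterRegions()].
#' @param denominator fixed denominator in bp.
#' @return named numeric densities in [0, 1].
#' @export
promoterDensity <- function(peaks, promoters, denominator = 1000) {
  peaks <- GenomicRanges::reduce(peaks)
  ov <- GenomicRanges::findOverlaps(promoters, peaks, ignore.strand = TRUE)
  out <- setNames(numeric(length(promoters)), names(promoters))
  if (length(ov)) {
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      promoters[S4Vectors::queryHits(ov)], peaks[S4Vectors::subjectHits(ov)],
      ignore.strand = TRUE))
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    out[as.integer(names(agg))] <- agg
  }
  pmin(out / denominator, 1)
}

#' Correlation between expression and promoter mark density
#'
#' Per-gene Pearson correlation (with the constant-vector = 0 convention
#' of [pearson()]) between TPM and promoter mark density across the given
#' individuals.
#'
#' @param tpm genes x samples TPM matrix.
#' @param densities genes x samples matrix of promoter densities.
#' @param individuals sample ids used (>= 3).
#' @param genes gene ids evaluated.
#' @return named numeric of per-gene correlations.
#' @export
expressionPromoterCorrelation <- function(tpm, densities, individuals,
                                          genes) {
  if (length(individuals) < 3) stop("need at least 3 individuals")
  vapply(genes, function(g)
    pearson(tpm[g, individuals], densities[g, individuals]), numeric(1))
}
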