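#' @include AllClasses.R
#' @importFrom utils read.table write.table head
NULL

#' Read a TSV expression table
#'
#' Genes in rows (first column = gene id), samples in columns, header row
#' of sample ids. Strictly validated: duplicate gene ids, non-numeric
#' cells, and (for `kind = "counts"`) non-integer values are errors.
#'
#' @param path file path.
#' @param kind `"tpm"` or `"counts"`.
#' @return numeric matrix with gene ids as rownames.
#' @export
readExpressionTable <- function(path, kind = c("tpm", "counts")) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("malformed numeric cell at gene '%s', sample '%s'",
                 ids[bad[1]], colnames(body)[bad[2]]))
  }
  if (kind == "counts" && any(abs(num - round(num)) > 1e-8)) {
    bad <- which(abs(num - round(num)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 ids[bad[1]], colnames(body)[bad[2]]))
  }
  if (any(num < 0)) stop("negative expression value")
  dimnames(num) <- list(ids, colnames(body))
  num
}

#' Write an expression matrix as TSV
#'
#' @param mat genes x samples matrix.
#' @param path output path.
#' @param idColumn header for the gene id column.
#' @export
writeExpressionTable <- function(mat, path, idColumn = "gene_id") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# BED convention: 0-based half-open on disk; GRanges (1-based closed) in
# memory. Conversion happens only here.

#' Read a BED3+ file as a merged interval set
#'
#' Intervals are validated (integer coordinates, start < end), converted
#' from the 0-based half-open convention, then sorted and merged per
#' chromosome, so `readBed(writeBed(x))` equals `reduce(x)`.
#'
#' @param path BED file path (whitespace-separated, >= 3 columns; empty
#'   file allowed).
#' @return merged GRanges.
#' @export
readBed <- function(path) {
  if (file.size(path) == 0)
    return(GenomicRanges::GRanges())
  df <- utils::read.table(path, header = FALSE, colClasses = "character",
                          quote = "")
  if (ncol(df) < 3) stop("BED needs at least 3 columns")
  suppressWarnings({
    s <- as.numeric(df[[2]]); e <- as.numeric(df[[3]])
  })
  if (anyNA(s) || anyNA(e) || any(s != round(s)) || any(e != round(e)))
    stop("non-integer BED coordinate")
  if (any(s < 0)) stop("negative BED coordinate")
  if (any(s >= e)) stop("BED interval with start >= end")
  GenomicRanges::reduce(GenomicRanges::GRanges(
    df[[1]], IRanges::IRanges(start = s + 1, end = e)))
}

#' Write an interval set as BED3
#'
#' @param set GRanges (merged on output).
#' @param path output path.
#' @export
writeBed <- function(set, path) {
  set <- GenomicRanges::sort(GenomicRanges::reduce(set))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(set)),
                   start = GenomicRanges::start(set) - 1,
                   end = GenomicRanges::end(set))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a bedGraph track
#'
#' 4-column chrom/start/end/value (0-based half-open). Overlapping
#' segments and non-numeric values are errors.
#'
#' @param path bedGraph file path.
#' @return GRanges with a numeric `score` column (a step function).
#' @export
readBedGraph <- function(path) {
  if (file.size(path) == 0)
    return(GenomicRanges::GRanges(score = numeric()))
  df <- utils::read.table(path, header = FALSE, colClasses = "character",
                          quote = "")
  if (ncol(df) < 4) stop("bedGraph needs 4 columns")
  suppressWarnings({
    s <- as.numeric(df[[2]]); e <- as.numeric(df[[3]])
    v <- as.numeric(df[[4]])
  })
  if (anyNA(s) || anyNA(e) || any(s != round(s)) || any(e != round(e)))
    stop("non-integer bedGraph coordinate")
  if (anyNA(v)) stop("non-numeric bedGraph value")
  if (any(s >= e)) stop("bedGraph segment with start >= end")
  gr <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(start = s + 1, end = e),
                               score = v)
  cov <- sum(as.numeric(GenomicRanges::width(gr)))
  merged <- sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(gr))))
  if (cov != merged) stop("overlapping bedGraph segments")
  GenomicRanges::sort(gr)
}

#' Read a 4-column gene annotation table
#'
#' TSV with header gene_id, chrom, strand, tss (0-based TSS coordinate).
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
readGeneAnnotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(df)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotation")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (any(df$tss < 0)) stop("tss must be >= 0")
  df
}

#' Export a substage assignment as TSV
#'
#' @param assign a [SubstageAssignment-class].
#' @param path output path.
#' @export
writeSubstageAssignment <- function(assign, path) {
  utils::write.table(
    data.frame(individual = assign@individual, stage = assign@stage,
               coarse = assign@coarse, detailed = assign@detailed),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Export a gene-set record as TSV
#'
#' @param set a [GeneSetRecord-class].
#' @param path output path.
#' @export
writeGeneSetRecord <- function(set, path) {
  dir <- geneDirections(set)
  utils::write.table(
    data.frame(gene = geneIds(set),
               direction = if (length(dir)) unname(dir) else NA,
               set = set@name, backend = set@backend,
               thresholds = paste(signif(set@thresholds, 4),
                                  collapse = "/")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Export a partition graph as an edge-list TSV
#'
#' @param edges data.frame from [orientGraph()] or [graphEdges()].
#' @param path output path.
#' @export
writeGraphEdges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
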