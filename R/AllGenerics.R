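#' @include AllClasses.R
NULL

#' Access the TPM assay
#' @param x an [ExpressionCohort-class].
#' @return genes x samples TPM matrix.
#' @export
setGeneric("tpm", function(x) standardGeneric("tpm"))

#' @rdname tpm
#' @export
setMethod("tpm", "ExpressionCohort", function(x)
  SummarizedExperiment::assay(x, "tpm"))

#' Access per-sample clinical stage labels
#' @param x an [ExpressionCohort-class].
#' @return named character vector of stages (NCI/MCI/AD) per sample.
#' @export
setGeneric("stageLabels", function(x) standardGeneric("stageLabels"))

#' @rdname stageLabels
#' @export
setMethod("stageLabels", "ExpressionCohort", function(x) {
  st <- as.character(SummarizedExperiment::colData(x)$stage)
  names(st) <- colnames(x)
  st
})

#' Member genes of a gene-set record
#' @param x a [GeneSetRecord-class].
#' @return character vector of gene ids.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneSetRecord", function(x) x@genes)

#' Per-gene direction labels of a gene-set record
#' @param x a [GeneSetRecord-class].
#' @return named character vector ("up"/"down"/"any") over member genes.
#' @export
setGeneric("geneDirections", function(x) standardGeneric("geneDirections"))

#' @rdname geneDirections
#' @export
setMethod("geneDirections", "GeneSetRecord", function(x) {
  d <- x@direction
  if (length(d)) names(d) <- x@genes
  d
})

#' Detailed substage labels of an assignment
#' @param x a [SubstageAssignment-class].
#' @param level one of "detailed", "coarse", "stage".
#' @return named character vector per individual.
#' @export
setGeneric("substages", function(x, level = "detailed")
  standardGeneric("substages"))

#' @rdname substages
#' @export
setMethod("substages", "SubstageAssignment", function(x, level = "detailed") {
  level <- match.arg(level, c("detailed", "coarse", "stage"))
  v <- slot(x, level)
  names(v) <- x@individual
  v
})

#' Connection-confidence weight matrix of a partition graph
#' @param x a [PartitionGraph-class].
#' @return symmetric numeric matrix over the nodes.
#' @export
setGeneric("confidence", function(x) standardGeneric("confidence"))

#' @rdname confidence
#' @export
setMethod("confidence", "PartitionGraph", function(x) x@weights)

#' Edge list of a partition graph
#' @param x a [PartitionGraph-class].
#' @return data.frame (from, to, weight) of edges with positive confidence.
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname graphEdges
#' @export
setMethod("graphEdges", "PartitionGraph", function(x) {
  w <- x@weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  data.frame(from = x@nodes[idx[, 1]], to = x@nodes[idx[, 2]],
             weight = w[idx], stringsAsFactors = FALSE)
})

# -- show methods -----------------------------------------------------------

setMethod("show", "ExpressionCohort", function(object) {
  st <- table(SummarizedExperiment::colData(object)$stage)
  cat("ExpressionCohort:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  stages:", paste(names(st), st, sep = "=", collapse = " "), "\n")
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", sum(object@nPerStage), "individuals (",
      paste(names(object@nPerStage), object@nPerStage, sep = "=",
            collapse = " "), "),", object@nGenes, "genes\n")
  cat("  modules:", paste(names(object@moduleSizes), object@moduleSizes,
                          sep = "=", collapse = " "), "\n")
  cat("  noise sd (log2):", object@noiseSdLog2,
      " dispersion:", object@dispersion, " seed:", object@seed, "\n")
})

setMethod("show", "GeneSetRecord", function(object) {
  cat("GeneSetRecord '", object@name, "': ", length(object@genes),
      " genes", sep = "")
  if (length(object@direction))
    cat(" (", sum(object@direction == "up"), " up, ",
        sum(object@direction == "down"), " down)", sep = "")
  cat("\n  backend:", object@backend,
      " thresholds:", paste(signif(object@thresholds, 3), collapse = "/"),
      "\n")
  if (nzchar(object@rule)) cat("  rule:", object@rule, "\n")
})

setMethod("show", "SubstageAssignment", function(object) {
  cat("SubstageAssignment over", length(object@individual), "individuals\n")
  print(table(object@detailed))
})

setMethod("show", "PhaseDiagram", function(object) {
  cat("PhaseDiagram (", paste(object@groups, collapse = " vs "),
      ", backend ", object@backend, "): ", nrow(object@cells), " cells",
      sep = "")
  if ("separating" %in% names(object@cells))
    cat(", ", sum(object@cells$separating), " separating", sep = "")
  cat("\n")
})

setMethod("show", "PartitionGraph", function(object) {
  e <- graphEdges(object)
  cat("PartitionGraph:", length(object@nodes), "nodes,", nrow(e), "edges\n")
  if (nrow(e)) print(utils::head(e[order(-e$weight), ], 10))
})
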