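#' @import methods
#' @importFrom Matrix Matrix sparseMatrix rowSums colSums t
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand reduce
#'   findOverlaps countOverlaps resize mid
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom Biostrings DNAStringSet reverseComplement subseq width
#' @importFrom stats rnbinom rpois rnorm runif rlnorm cor pnorm pchisq phyper
#'   p.adjust sd quantile glm binomial setNames median complete.cases
#' @importFrom utils read.table write.table head combn packageVersion
NULL

#' Sparse feature-by-cell count matrix with modality tag
#'
#' Thin S4 wrapper around a `dgCMatrix` carrying unique feature identifiers
#' (rownames), unique cell barcodes (colnames) and a modality label
#' (`"rna"` or `"atac"`).
#'
#' @slot counts sparse non-negative integer matrix, features x cells.
#' @slot modality `"rna"` or `"atac"`.
#' @export
setClass("CountMatrix",
  representation(counts = "Matrix", modality = "character"))

setValidity("CountMatrix", function(object) {
  m <- object@counts
  msg <- character()
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    msg <- c(msg, "counts must carry feature ids (rownames) and barcodes (colnames)")
  else {
    if (anyDuplicated(rownames(m))) msg <- c(msg, "feature ids must be unique")
    if (anyDuplicated(colnames(m))) msg <- c(msg, "barcodes must be unique")
  }
  if (length(m@x) && min(m@x) < 0) msg <- c(msg, "negative counts are not allowed")
  if (!object@modality %in% c("rna", "atac"))
    msg <- c(msg, "modality must be 'rna' or 'atac'")
  if (length(msg)) msg else TRUE
})

#' Construct a CountMatrix
#'
#' @param counts matrix or sparse Matrix of non-negative counts with dimnames.
#' @param modality `"rna"` or `"atac"`.
#' @return A [CountMatrix-class] object.
#' @export
CountMatrix <- function(counts, modality = c("rna", "atac")) {
  modality <- match.arg(modality)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  new("CountMatrix", counts = counts, modality = modality)
}

#' @describeIn CountMatrix-class underlying sparse matrix
#' @param x a CountMatrix.
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname CountMatrix-class
#' @export
setMethod("counts", "CountMatrix", function(x) x@counts)

#' @describeIn CountMatrix-class ordered feature identifiers
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname CountMatrix-class
#' @export
setMethod("featureIds", "CountMatrix", function(x) rownames(x@counts))

#' @describeIn CountMatrix-class ordered cell barcodes
#' @export
setGeneric("barcodes", function(x) standardGeneric("barcodes"))
#' @rdname CountMatrix-class
#' @export
setMethod("barcodes", "CountMatrix", function(x) colnames(x@counts))

#' @describeIn CountMatrix-class modality label
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname CountMatrix-class
#' @export
setMethod("modality", "CountMatrix", function(x) x@modality)

setMethod("show", "CountMatrix", function(object) {
  cat("CountMatrix [", object@modality, "]: ",
      nrow(object@counts), " features x ", ncol(object@counts), " cells, ",
      length(object@counts@x), " non-zero entries\n", sep = "")
})

setMethod("dim", "CountMatrix", function(x) dim(x@counts))

#' Joint single-nucleus multiome dataset
#'
#' Container for a matched RNA + ATAC single-nucleus experiment: the two count
#' matrices over an identical ordered barcode list, per-cell metadata, the peak
#' set, gene models, genome sequence, optional histone ChIP interval tracks and
#' (for synthetic data) ground-truth tables.
#'
#' @slot rna [CountMatrix-class], modality `"rna"`.
#' @slot atac [CountMatrix-class], modality `"atac"`; rows follow `peaks`.
#' @slot cells `DataFrame` of per-cell metadata keyed by `barcode`.
#' @slot peaks `GRanges` of ATAC peaks; `names()` are the ATAC feature ids.
#' @slot geneModels `data.frame` with gene_id, chrom, strand, tss, span_start,
#'   span_end (0-based half-open span; tss 0-based).
#' @slot exons `data.frame` with gene_id, exon_rank, start, end (0-based
#'   half-open).
#' @slot genome `DNAStringSet`, one entry per chromosome.
#' @slot chipTracks named `list` of `GRanges`, keyed `"<mark>.<cell_state>"`.
#' @slot truth named `list` of ground-truth `data.frame`s (synthetic data only).
#' @export
setClass("MultiomeDataset",
  representation(rna = "CountMatrix", atac = "CountMatrix",
                 cells = "DataFrame", peaks = "GRanges",
                 geneModels = "data.frame", exons = "data.frame",
                 genome = "DNAStringSet", chipTracks = "list",
                 truth = "list"))

setValidity("MultiomeDataset", function(object) {
  msg <- character()
  if (!identical(barcodes(object@rna), barcodes(object@atac)))
    msg <- c(msg, "rna and atac must share an identical ordered barcode list")
  if (nrow(object@cells) != length(barcodes(object@rna)))
    msg <- c(msg, "cells table must have one row per barcode")
  if (nrow(object@cells) &&
      !identical(as.character(object@cells$barcode), barcodes(object@rna)))
    msg <- c(msg, "cells$barcode must match the matrix barcode order")
  if (length(object@peaks) != nrow(counts(object@atac)))
    msg <- c(msg, "peaks must parallel the atac feature rows")
  if (length(msg)) msg else TRUE
})

#' @describeIn MultiomeDataset-class RNA count matrix
#' @param x a MultiomeDataset.
#' @export
setGeneric("rnaCounts", function(x) standardGeneric("rnaCounts"))
#' @rdname MultiomeDataset-class
#' @export
setMethod("rnaCounts", "MultiomeDataset", function(x) x@rna)

#' @describeIn MultiomeDataset-class ATAC count matrix
#' @export
setGeneric("atacCounts", function(x) standardGeneric("atacCounts"))
#' @rdname MultiomeDataset-class
#' @export
setMethod("atacCounts", "MultiomeDataset", function(x) x@atac)

#' @describeIn MultiomeDataset-class per-cell metadata
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))
#' @rdname MultiomeDataset-class
#' @export
setMethod("cellData", "MultiomeDataset", function(x) x@cells)

#' @describeIn MultiomeDataset-class peak ranges
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))
#' @rdname MultiomeDataset-class
#' @export
setMethod("peakRanges", "MultiomeDataset", function(x) x@peaks)

#' @describeIn MultiomeDataset-class gene model table
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))
#' @rdname MultiomeDataset-class
#' @export
setMethod("geneModels", "MultiomeDataset", function(x) x@geneModels)

#' @describeIn MultiomeDataset-class genome sequence
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname MultiomeDataset-class
#' @export
setMethod("genomeSeq", "MultiomeDataset", function(x) x@genome)

#' @describeIn MultiomeDataset-class histone ChIP tracks
#' @export
setGeneric("chipTracks", function(x) standardGeneric("chipTracks"))
#' @rdname MultiomeDataset-class
#' @export
setMethod("chipTracks", "MultiomeDataset", function(x) x@chipTracks)

#' @describeIn MultiomeDataset-class ground-truth tables
#' @export
setGeneric("truthTables", function(x) standardGeneric("truthTables"))
#' @rdname MultiomeDataset-class
#' @export
setMethod("truthTables", "MultiomeDataset", function(x) x@truth)

setMethod("show", "MultiomeDataset", function(object) {
  cat("MultiomeDataset:", ncol(counts(object@rna)), "cells\n")
  cat("  rna : ", nrow(counts(object@rna)), " genes\n", sep = "")
  cat("  atac: ", nrow(counts(object@atac)), " peaks\n", sep = "")
  if (nrow(object@cells)) {
    tab <- table(object@cells$declared_sex, object@cells$stage)
    cat("  cells by sex x stage:\n")
    print(tab)
  }
  if (length(object@truth))
    cat("  truth tables:", paste(names(object@truth), collapse = ", "), "\n")
})
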