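#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList start end width seqnames strand
#'   findOverlaps countOverlaps promoters resize
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<- DataFrame
#' @importFrom Matrix Matrix sparseMatrix colSums rowSums t readMM writeMM
#' @importFrom data.table fread fwrite data.table as.data.table setorder :=
#' @importFrom stats sd wilcox.test prcomp setNames
#' @importFrom utils head tail
NULL

#' Cell-by-feature accessibility matrix
#'
#' Container for a scATAC-seq peak-count or bin-count matrix: a sparse
#' feature-by-cell count matrix together with the genomic interval of every
#' feature and the cell barcodes. Features may be irregular peaks or
#' fixed-width genomic bins; all downstream overlap arithmetic treats them
#' identically. Counts are binarized (count > 0 means the feature is open in
#' that cell) wherever the method requires a peak set per cell.
#'
#' @slot counts sparse feature-by-cell non-negative count matrix
#'   (\code{dgCMatrix}).
#' @slot features \code{GRanges} of feature intervals, one per matrix row.
#' @slot barcodes character vector of cell barcodes, one per matrix column.
#'
#' @seealso [readCellMatrix()], [coveredBp()], [knnSmooth()]
#' @export
setClass("CellPeakMatrix",
  representation(
    counts = "dgCMatrix",
    features = "GRanges",
    barcodes = "character"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@features) != nrow(object@counts))
      msg <- c(msg, sprintf("features (%d) must match matrix rows (%d)",
                            length(object@features), nrow(object@counts)))
    if (length(object@barcodes) != ncol(object@counts))
      msg <- c(msg, sprintf("barcodes (%d) must match matrix columns (%d)",
                            length(object@barcodes), ncol(object@counts)))
    if (anyDuplicated(object@barcodes))
      msg <- c(msg, "barcodes must be unique")
    if (length(object@counts@x) && any(object@counts@x < 0))
      msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
  }
)

#' Searchable reference of TR interval datasets
#'
#' Holds a curated collection of TR ChIP-seq peak sets and/or motif-derived
#' pseudo-peak sets, each attached to a factor (TR) identifier and free-form
#' metadata. The per-dataset peak counts (the \eqn{D} vector used for
#' normalization) are stored explicitly and always equal the number of
#' intervals kept for that dataset.
#'
#' @slot peaks named list of \code{GRanges}, one per dataset; names are
#'   dataset identifiers.
#' @slot meta \code{data.frame} with one row per dataset and columns
#'   \code{dataset_id}, \code{factor}, \code{cell_type}, \code{species},
#'   \code{n_peaks}.
#'
#' @seealso [buildIndex()], [readIndex()], [writeIndex()]
#' @export
setClass("ReferenceIndex",
  representation(peaks = "list", meta = "data.frame"),
  validity = function(object) {
    msg <- character()
    m <- object@meta
    need <- c("dataset_id", "factor", "cell_type", "species", "n_peaks")
    miss <- setdiff(need, colnames(m))
    if (length(miss))
      msg <- c(msg, paste("metadata missing columns:", paste(miss, collapse = ", ")))
    if (!length(msg)) {
      if (anyDuplicated(m$dataset_id))
        msg <- c(msg, "duplicate dataset_id in metadata")
      if (!identical(names(object@peaks), as.character(m$dataset_id)))
        msg <- c(msg, "peak list names must equal metadata dataset_id, in order")
      stored <- vapply(object@peaks, length, integer(1))
      if (length(stored) && any(stored != m$n_peaks))
        msg <- c(msg, "n_peaks must equal the number of stored intervals")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Per-cell TR activity scores
#'
#' Result of the enrichment pipeline: a TR-by-cell activity matrix after the
#' full normalization chain (overlap counting, size normalization, dataset
#' centering, per-TR deduplication, per-TR sigmoid scaling, per-cell
#' z-scoring), the intermediate enrichment scores, and the best-matched
#' reference dataset for every (cell, TR) pair under the \code{max} strategy.
#'
#' @slot activity TR-by-cell numeric matrix of final activity scores
#'   (each cell column has mean 0 and, when non-constant, unit sd).
#' @slot enrichment TR-by-cell matrix of deduplicated enrichment scores
#'   before sigmoid/z-score scaling.
#' @slot best_match \code{data.frame} with columns \code{cell}, \code{factor},
#'   \code{dataset_id}; empty when the \code{average} strategy was used.
#' @slot strategy the deduplication strategy used, \code{"max"} or
#'   \code{"average"}.
#'
#' @seealso [trActivity()]
#' @export
setClass("TRActivity",
  representation(
    activity = "matrix",
    enrichment = "matrix",
    best_match = "data.frame",
    strategy = "character"
  )
)

#' Gene models for regulatory-potential scoring
#'
#' One model per gene symbol: the transcription start site (strand-aware),
#' the promoter window (TSS +/- 1 kb), the union of exon intervals and the
#' total exon length in kb. Built from a refGene-style table or a GTF by
#' [readGeneAnnotation()].
#'
#' @slot tss \code{GRanges} of width-1 TSS positions, named by gene symbol.
#' @slot promoters \code{GRanges} of promoter windows (TSS +/- 1000 bp,
#'   clipped at the chromosome start), named by gene symbol.
#' @slot exons \code{GRangesList} of reduced exon intervals per gene.
#' @slot exon_kb numeric total exon length per gene, in kb.
#'
#' @export
setClass("GeneModels",
  representation(
    tss = "GRanges",
    promoters = "GRanges",
    exons = "CompressedGRangesList",
    exon_kb = "numeric"
  ),
  validity = function(object) {
    n <- length(object@tss)
    if (length(object@promoters) != n || length(object@exons) != n ||
        length(object@exon_kb) != n)
      return("tss, promoters, exons and exon_kb must have equal length")
    TRUE
  }
)

setMethod("show", "CellPeakMatrix", function(object) {
  cat(sprintf("CellPeakMatrix: %d features x %d cells (%.2f%% nonzero)\n",
              nrow(object@counts), ncol(object@counts),
              100 * length(object@counts@x) / prod(dim(object@counts))))
})

setMethod("show", "ReferenceIndex", function(object) {
  cat(sprintf("ReferenceIndex: %d datasets, %d factors, %s intervals\n",
              nrow(object@meta), length(unique(object@meta$factor)),
              format(sum(object@meta$n_peaks), big.mark = ",")))
})

setMethod("show", "TRActivity", function(object) {
  cat(sprintf("TRActivity: %d TRs x %d cells (strategy: %s)\n",
              nrow(object@activity), ncol(object@activity), object@strategy))
})

setMethod("show", "GeneModels", function(object) {
  cat(sprintf("GeneModels: %d genes\n", length(object@tss)))
})

#' @describeIn CellPeakMatrix-class number of features and cells
#' @param x a \code{CellPeakMatrix}
#' @export
setMethod("dim", "CellPeakMatrix", function(x) dim(x@counts))

#' Accessors for package containers
#'
#' Small generic accessors: `counts()` returns the sparse count matrix,
#' `features()` the feature intervals, `barcodes()` the cell barcodes,
#' `activityScores()` the final TR-by-cell activity matrix, `bestMatch()`
#' the per-(cell, TR) best-matched dataset table, `datasetPeaks()` one
#' dataset's intervals, `indexMeta()` the reference metadata table and
#' `peakCounts()` the per-dataset interval counts (the `D` vector).
#'
#' @param x a package container object
#' @param dataset_id a dataset identifier present in the index
#' @return the component named by the accessor
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setMethod("counts", "CellPeakMatrix", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname accessors
#' @export
setMethod("features", "CellPeakMatrix", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("barcodes", function(x) standardGeneric("barcodes"))
#' @rdname accessors
#' @export
setMethod("barcodes", "CellPeakMatrix", function(x) x@barcodes)

#' @rdname accessors
#' @export
setGeneric("activityScores", function(x) standardGeneric("activityScores"))
#' @rdname accessors
#' @export
setMethod("activityScores", "TRActivity", function(x) x@activity)

#' @rdname accessors
#' @export
setGeneric("bestMatch", function(x) standardGeneric("bestMatch"))
#' @rdname accessors
#' @export
setMethod("bestMatch", "TRActivity", function(x) x@best_match)

#' @rdname accessors
#' @export
setGeneric("indexMeta", function(x) standardGeneric("indexMeta"))
#' @rdname accessors
#' @export
setMethod("indexMeta", "ReferenceIndex", function(x) x@meta)

#' @rdname accessors
#' @export
setGeneric("peakCounts", function(x) standardGeneric("peakCounts"))
#' @rdname accessors
#' @export
setMethod("peakCounts", "ReferenceIndex", function(x)
  setNames(x@meta$n_peaks, x@meta$dataset_id))

#' @rdname accessors
#' @export
setGeneric("datasetPeaks", function(x, dataset_id) standardGeneric("datasetPeaks"))
#' @rdname accessors
#' @export
setMethod("datasetPeaks", "ReferenceIndex", function(x, dataset_id) {
  if (!dataset_id %in% names(x@peaks))
    stop("unknown dataset_id: ", dataset_id)
  x@peaks[[dataset_id]]
})

#' Construct a CellPeakMatrix
#'
#' @param counts feature-by-cell count matrix (coerced to sparse).
#' @param features \code{GRanges} of feature intervals (one per row).
#' @param barcodes character vector of cell barcodes (one per column).
#' @return a validated [CellPeakMatrix-class] object
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 201), c(100, 300)))
#' m <- Matrix::Matrix(c(1, 0, 0, 2), 2, 2, sparse = TRUE)
#' CellPeakMatrix(m, gr, c("cellA", "cellB"))
#' @export
CellPeakMatrix <- function(counts, features, barcodes) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  validatePeaks(features, what = "feature")
  new("CellPeakMatrix", counts = counts, features = features,
      barcodes = as.character(barcodes))
}

#' Per-cell accessible base pairs
#'
#' Total genomic span open in each cell: the sum of feature widths over
#' features with a nonzero count in that cell. This is the quantity that,
#' divided by 1e8 (per 100 million bp), forms the per-cell size factor `Q`
#' used by [normalizeOverlaps()].
#'
#' @param cells a [CellPeakMatrix-class]
#' @return numeric vector of covered bp, named by barcode
#' @export
coveredBp <- function(cells) {
  stopifnot(methods::is(cells, "CellPeakMatrix"))
  b <- binarizeCounts(cells@counts)
  setNames(as.numeric(GenomicRanges::width(cells@features) %*% b),
           cells@barcodes)
}

binarizeCounts <- function(m) {
  m@x <- rep(1, length(m@x))
  m
}
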