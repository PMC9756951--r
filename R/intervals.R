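# Interval overlap engine. All public coordinates follow the BED convention
# (0-based, half-open) at the file boundary; in memory intervals live in
# GRanges (1-based, closed), so BED [s, e) maps to GRanges [s + 1, e] and
# abutting BED intervals do not overlap. Strand is ignored throughout:
# ChIP-seq peaks and ATAC features are unstranded.

#' Validate a peak set
#'
#' Checks that a \code{GRanges} is a usable peak set: every interval has
#' width >= 1 bp and a positive start. Malformed records are reported by
#' position so the offending input line can be located.
#'
#' @param gr a \code{GRanges}
#' @param what label used in error messages (e.g. "peak", "feature")
#' @return invisibly, \code{gr}
#' @export
validatePeaks <- function(gr, what = "interval") {
  if (!methods::is(gr, "GRanges"))
    stop(what, " set must be a GRanges object")
  bad <- which(GenomicRanges::width(gr) < 1L)
  if (length(bad))
    stop(sprintf("malformed %s (end <= start) at record %d: %s:%d-%d",
                 what, bad[1],
                 as.character(GenomicRanges::seqnames(gr)[bad[1]]),
                 GenomicRanges::start(gr)[bad[1]] - 1L,
                 GenomicRanges::end(gr)[bad[1]]))
  bad <- which(GenomicRanges::start(gr) < 1L)
  if (length(bad))
    stop(sprintf("malformed %s (negative start) at record %d", what, bad[1]))
  invisible(gr)
}

#' Count overlapping interval pairs
#'
#' Number of (query interval, subject interval) pairs sharing at least one
#' base pair — bedtools/GIGGLE row semantics: a query interval overlapped by
#' three subject intervals contributes three, and duplicate intervals each
#' count as their own pair. Symmetric in its arguments.
#'
#' @param query,subject \code{GRanges} peak sets (unstranded comparison).
#' @return a single non-negative integer
#' @examples
#' a <- bedToGRanges(data.frame(chrom = "chr1", start = c(0, 200), end = c(100, 300)))
#' b <- bedToGRanges(data.frame(chrom = "chr1", start = 90, end = 210))
#' countPeakOverlaps(a, b)  # 2
#' @export
countPeakOverlaps <- function(query, subject) {
  validatePeaks(query, "query")
  validatePeaks(subject, "subject")
  # seqlevel mismatch between the sets is a legitimate zero, not a warning
  suppressWarnings(
    length(GenomicRanges::findOverlaps(query, subject, minoverlap = 1L,
                                       ignore.strand = TRUE)))
}

#' Intervals of one set overlapped by another
#'
#' Returns the intervals of \code{a} that overlap at least one interval of
#' \code{b} (bedtools \code{intersect -u} semantics: the original interval of
#' \code{a} is reported once, however many \code{b} intervals hit it).
#'
#' @param a,b \code{GRanges} peak sets
#' @return a \code{GRanges}, always a subset of \code{a}
#' @export
intersectPeaks <- function(a, b) {
  validatePeaks(a, "a")
  validatePeaks(b, "b")
  suppressWarnings(
    IRanges::subsetByOverlaps(a, b, minoverlap = 1L, ignore.strand = TRUE))
}

#' Dataset-by-cell overlap matrix
#'
#' For every reference dataset j and cell i, counts the overlapping
#' (cell feature, dataset interval) pairs, where a cell's peak set is the
#' features with nonzero count in that cell. This is the raw matrix `M` that
#' the normalization chain consumes.
#'
#' Cells with no open feature produce a column of zeros and a warning rather
#' than an error, so sparse low-depth cells survive to the QC stage.
#'
#' @param cells a [CellPeakMatrix-class]
#' @param index a [ReferenceIndex-class]
#' @return integer matrix, datasets x cells, with dimnames
#'   (dataset_id, barcode)
#' @export
overlapMatrix <- function(cells, index) {
  stopifnot(methods::is(cells, "CellPeakMatrix"),
            methods::is(index, "ReferenceIndex"))
  if (!nrow(index@meta)) stop("reference index is empty")
  validatePeaks(cells@features, "feature")
  b <- binarizeCounts(cells@counts)
  empty <- Matrix::colSums(b) == 0
  if (any(empty))
    warning(sprintf("%d cell(s) with no open features; overlap counts set to 0 (e.g. %s)",
                    sum(empty), cells@barcodes[which(empty)[1]]))
  # per-feature pair counts against each dataset, then weight by cell presence
  M <- vapply(index@peaks, function(ref) {
    per_feature <- GenomicRanges::countOverlaps(cells@features, ref,
                                                minoverlap = 1L,
                                                ignore.strand = TRUE)
    as.numeric(per_feature %*% b)
  }, numeric(ncol(b)))
  # vapply drops to a vector when there is a single cell
  M <- if (is.null(dim(M))) matrix(M, ncol = 1L) else t(M)
  dimnames(M) <- list(index@meta$dataset_id, cells@barcodes)
  storage.mode(M) <- "integer"
  M
}
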