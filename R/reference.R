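# Curation of raw ChIP-seq peak sets and motif scan hits into the searchable
# TR reference. The QC thresholds are the standard ChIP-seq quality gates
# (sequence quality, mapping rate, library complexity, peak enrichment,
# FRiP, DHS concordance); all are strict inequalities.

.qc_metrics <- c("median_quality", "unique_map_frac", "pbc",
                 "fold10_peaks", "frip", "dhs_top5000_frac")

.qc_thresholds <- c(median_quality = 25, unique_map_frac = 0.5, pbc = 0.8,
                    fold10_peaks = 100, frip = 0.01, dhs_top5000_frac = 0.7)

#' Filter ChIP-seq datasets on quality metrics
#'
#' Retains datasets passing all six quality gates, each a strict inequality:
#' median raw sequence quality above 25, uniquely-mapped read fraction above
#' 0.5, PCR bottleneck coefficient (PBC) above 0.8, more than 100
#' 10-fold-enriched peaks, fraction of reads in peaks (FRiP) above 0.01, and
#' more than 70% of the top 5000 peaks overlapping union DHS. Input order is
#' preserved.
#'
#' @param qc data.frame with columns \code{dataset_id}, \code{median_quality},
#'   \code{unique_map_frac}, \code{pbc}, \code{fold10_peaks}, \code{frip},
#'   \code{dhs_top5000_frac}; a missing column or \code{NA} value is an
#'   error naming the field.
#' @return character vector of retained dataset ids, in input order
#' @export
applyQCFilters <- function(qc) {
  miss <- setdiff(c("dataset_id", .qc_metrics), colnames(qc))
  if (length(miss))
    stop("QC table missing metric(s): ", paste(miss, collapse = ", "))
  for (m in .qc_metrics) {
    if (anyNA(qc[[m]]))
      stop(sprintf("missing value for metric '%s' (dataset %s)", m,
                   qc$dataset_id[which(is.na(qc[[m]]))[1]]))
  }
  frac <- c("unique_map_frac", "pbc", "frip", "dhs_top5000_frac")
  for (m in frac)
    if (any(qc[[m]] < 0 | qc[[m]] > 1))
      stop("metric '", m, "' must lie in [0, 1]")
  keep <- rep(TRUE, nrow(qc))
  for (m in .qc_metrics)
    keep <- keep & (qc[[m]] > .qc_thresholds[[m]])
  as.character(qc$dataset_id[keep])
}

#' Keep high-confidence peaks by fold enrichment
#'
#' Retains peaks with fold enrichment at or above \code{min_fold}
#' (default 5), preserving order. A peak exactly at the threshold is kept:
#' an n-fold peak satisfies its own definition.
#'
#' @param peaks \code{GRanges} with a \code{fold} metadata column
#' @param min_fold minimum fold enrichment (default 5)
#' @return filtered \code{GRanges}
#' @export
filterPeaksByFold <- function(peaks, min_fold = 5) {
  validatePeaks(peaks, "peak")
  if (!"fold" %in% colnames(S4Vectors::mcols(peaks)))
    stop("peak set has no 'fold' attribute")
  peaks[S4Vectors::mcols(peaks)$fold >= min_fold]
}

#' Drop reference datasets with too few peaks
#'
#' Removes datasets whose peak count (after fold filtering) is below
#' \code{min_peaks} (default 1000).
#'
#' @param peaksets named list of \code{GRanges}
#' @param min_peaks minimum retained peak count (default 1000)
#' @return the retained subset of \code{peaksets}, order preserved
#' @export
dropSmallDatasets <- function(peaksets, min_peaks = 1000) {
  stopifnot(is.list(peaksets))
  n <- vapply(peaksets, length, integer(1))
  peaksets[n >= min_peaks]
}

#' Build motif pseudo-peaks from genome-wide motif scan hits
#'
#' Standardizes raw motif scan intervals into ChIP-peak-like pseudo-peaks:
#' (1) keep hits overlapping the union of candidate cis-regulatory elements
#' (ccRE) and DNase hypersensitive sites (DHS); (2) drop hits overlapping the
#' blacklist; (3) extend every surviving hit symmetrically about its midpoint
#' to exactly \code{width} bp (default 340 bp, the typical ChIP-seq peak
#' width), giving the extra base to the left when the extension is odd and
#' clipping at position 0; extended hits that now touch the blacklist are
#' dropped; (4) if more than \code{max_sites} hits remain (default 25000),
#' keep those with the smallest scan p-values.
#'
#' @param sites \code{GRanges} of motif scan hits for one motif, with a
#'   \code{pvalue} metadata column (required only when the cap applies).
#' @param ccre,dhs,blacklist \code{GRanges} region lists; \code{blacklist}
#'   may be empty.
#' @param width standardized pseudo-peak width in bp (default 340)
#' @param max_sites per-motif site cap (default 25000)
#' @return \code{GRanges} of pseudo-peaks
#' @export
buildMotifPseudoPeaks <- function(sites, ccre, dhs, blacklist,
                                  width = 340L, max_sites = 25000L) {
  validatePeaks(sites, "motif site")
  open_regions <- c(GenomicRanges::granges(ccre), GenomicRanges::granges(dhs))
  keep <- IRanges::overlapsAny(sites, open_regions, ignore.strand = TRUE)
  out <- sites[keep]
  if (length(blacklist))
    out <- out[!IRanges::overlapsAny(out, blacklist, ignore.strand = TRUE)]
  if (length(out)) {
    # recenter on the midpoint at exactly `width` bp; when the extension is
    # odd the extra base goes left; clipping at the chromosome start may
    # leave a shorter interval but never moves the right edge
    w <- GenomicRanges::width(out)
    left <- ceiling((width - w) / 2)
    new_end <- GenomicRanges::start(out) - left + width - 1L
    new_start <- pmax(GenomicRanges::start(out) - left, 1L)
    pv <- S4Vectors::mcols(out)$pvalue
    out <- GenomicRanges::GRanges(GenomicRanges::seqnames(out),
                                  IRanges::IRanges(new_start, new_end))
    if (!is.null(pv)) S4Vectors::mcols(out)$pvalue <- pv
    if (length(blacklist))
      out <- out[!IRanges::overlapsAny(out, blacklist, ignore.strand = TRUE)]
  }
  if (length(out) > max_sites) {
    p <- S4Vectors::mcols(out)$pvalue
    if (is.null(p) || anyNA(p))
      stop("site cap requires a p-value for every site")
    out <- out[order(p)[seq_len(max_sites)]]
    out <- GenomicRanges::sort(out, ignore.strand = TRUE)
  }
  out
}

#' Build a reference index from curated peak sets
#'
#' Combines ChIP-seq peak sets and motif pseudo-peak sets into one searchable
#' [ReferenceIndex-class]. Every dataset needs a metadata row mapping it to a
#' factor (TR); ChIP and motif datasets for the same factor coexist and are
#' merged only at the deduplication step of the activity pipeline. The
#' per-dataset interval counts (the \code{D} vector) are recorded at build
#' time.
#'
#' @param peaksets named list of \code{GRanges}; names are dataset ids.
#' @param metadata data.frame with columns \code{dataset_id}, \code{factor}
#'   and optionally \code{cell_type}, \code{species}; one row per dataset.
#' @return a [ReferenceIndex-class]
#' @export
buildIndex <- function(peaksets, metadata) {
  stopifnot(is.list(peaksets), !is.null(names(peaksets)))
  if (anyDuplicated(names(peaksets)))
    stop("duplicate dataset_id: ",
         names(peaksets)[anyDuplicated(names(peaksets))])
  if (!all(c("dataset_id", "factor") %in% colnames(metadata)))
    stop("metadata needs dataset_id and factor columns")
  miss <- setdiff(names(peaksets), metadata$dataset_id)
  if (length(miss))
    stop("no metadata for dataset(s): ", paste(miss, collapse = ", "))
  meta <- as.data.frame(metadata)[match(names(peaksets), metadata$dataset_id), ]
  if (is.null(meta$cell_type)) meta$cell_type <- NA_character_
  if (is.null(meta$species)) meta$species <- NA_character_
  for (i in seq_along(peaksets)) {
    validatePeaks(peaksets[[i]], paste0("dataset ", names(peaksets)[i]))
    peaksets[[i]] <- GenomicRanges::sort(GenomicRanges::granges(peaksets[[i]]),
                                         ignore.strand = TRUE)
  }
  meta$n_peaks <- vapply(peaksets, length, integer(1))
  rownames(meta) <- NULL
  new("ReferenceIndex", peaks = peaksets,
      meta = meta[, c("dataset_id", "factor", "cell_type", "species", "n_peaks")])
}

#' Persist a reference index to a directory
#'
#' Writes one sorted \code{<dataset_id>.bed.gz} per dataset plus
#' \code{metadata.tsv} (dataset_id, factor, cell_type, species, n_peaks) and
#' \code{factor_map.tsv} (dataset_id, factor). Round-trips through
#' [readIndex()].
#'
#' @param index a [ReferenceIndex-class]
#' @param dir output directory (created if absent)
#' @return invisibly, \code{dir}
#' @export
writeIndex <- function(index, dir) {
  stopifnot(methods::is(index, "ReferenceIndex"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(index@peaks))
    writeBed(index@peaks[[id]], file.path(dir, paste0(id, ".bed.gz")))
  data.table::fwrite(index@meta, file.path(dir, "metadata.tsv"), sep = "\t")
  data.table::fwrite(index@meta[, c("dataset_id", "factor")],
                     file.path(dir, "factor_map.tsv"), sep = "\t")
  invisible(dir)
}

#' Load a reference index from a directory
#'
#' @param dir directory written by [writeIndex()]
#' @return a [ReferenceIndex-class]
#' @export
readIndex <- function(dir) {
  mf <- file.path(dir, "metadata.tsv")
  if (!file.exists(mf)) stop("no metadata.tsv in ", dir)
  meta <- as.data.frame(data.table::fread(mf, sep = "\t"))
  peaks <- lapply(meta$dataset_id, function(id) {
    f <- findFirst(dir, paste0(id, c(".bed.gz", ".bed")))
    if (is.null(f)) stop("missing BED for dataset ", id)
    readBed(f)
  })
  names(peaks) <- meta$dataset_id
  new("ReferenceIndex", peaks = peaks, meta = meta)
}
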