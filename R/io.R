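# Readers and writers for the plain-text formats the pipeline consumes:
# BED3(+) peak files (gzip transparent), Matrix Market cell matrices with
# feature/barcode sidecars, and dense TSV matrices. BED coordinates on disk
# are 0-based half-open and are shifted to 1-based closed GRanges on read.

#' Convert BED-convention coordinates to GRanges
#'
#' @param df data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open); any further columns become metadata columns.
#' @return unstranded \code{GRanges}
#' @export
bedToGRanges <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% colnames(df)))
  if (nrow(df) == 0)
    return(GenomicRanges::GRanges())
  if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
    stop("non-numeric coordinates in BED input")
  if (any(df$start < 0))
    stop("negative start coordinate at record ", which(df$start < 0)[1])
  if (any(df$end <= df$start))
    stop(sprintf("malformed interval (end <= start) at record %d: %s:%d-%d",
                 which(df$end <= df$start)[1],
                 df$chrom[which(df$end <= df$start)[1]],
                 df$start[which(df$end <= df$start)[1]],
                 df$end[which(df$end <= df$start)[1]]))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = as.integer(df$start) + 1L,
                              end = as.integer(df$end)))
  extra <- setdiff(colnames(df), c("chrom", "start", "end"))
  if (length(extra))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(df[, extra, drop = FALSE])
  gr
}

#' Convert GRanges back to BED-convention coordinates
#'
#' @param gr a \code{GRanges}
#' @return data.frame with \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open) plus any metadata columns
#' @export
grangesToBed <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  m <- S4Vectors::mcols(gr)
  if (ncol(m))
    df <- cbind(df, as.data.frame(m))
  df
}

#' Read a BED3+ peak file
#'
#' Reads a (possibly gzip-compressed) BED file with three coordinate columns
#' plus optional named extra columns (e.g. fold enrichment, p-value).
#' Comment (`#`) and `track`/`browser` lines are skipped. Coordinate errors
#' report the 1-based data line number.
#'
#' @param path file path; \code{.gz} handled transparently.
#' @param extra_cols optional character vector naming columns 4, 5, ... in
#'   order (e.g. \code{c("fold", "pvalue")}); unnamed trailing columns are
#'   kept as \code{V4}, \code{V5}, ...
#' @return \code{GRanges} with any extra columns as metadata
#' @export
readBed <- function(path, extra_cols = NULL) {
  if (!file.exists(path)) stop("no such BED file: ", path)
  dt <- freadMaybeGz(path, header = FALSE, sep = "\t",
                     blank.lines.skip = TRUE, colClasses = list(character = 1))
  if (nrow(dt) == 0)
    return(GenomicRanges::GRanges())
  drop <- grepl("^#|^track\\b|^browser\\b", dt[[1]])
  dt <- dt[!drop]
  if (nrow(dt) == 0)
    return(GenomicRanges::GRanges())
  if (ncol(dt) < 3) stop("BED file needs at least 3 columns: ", path)
  s <- suppressWarnings(as.numeric(dt[[2]]))
  e <- suppressWarnings(as.numeric(dt[[3]]))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad))
    stop(sprintf("non-numeric coordinates at line %d of %s", bad[1], path))
  df <- data.frame(chrom = dt[[1]], start = s, end = e, stringsAsFactors = FALSE)
  if (ncol(dt) > 3) {
    xn <- paste0("V", seq(4L, ncol(dt)))
    if (!is.null(extra_cols))
      xn[seq_along(extra_cols)] <- extra_cols
    for (k in seq(4L, ncol(dt)))
      df[[xn[k - 3L]]] <- dt[[k]]
  }
  bedToGRanges(df)
}

#' Write a peak set as sorted BED
#'
#' Writes 0-based half-open coordinates, sorted by (chrom, start, end);
#' metadata columns follow the coordinates. A \code{.gz} suffix triggers
#' gzip compression.
#'
#' @param gr \code{GRanges} to write
#' @param path output path
#' @return invisibly, \code{path}
#' @export
writeBed <- function(gr, path) {
  df <- grangesToBed(gr)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Parse feature identifier strings into intervals
#'
#' Accepts the common single-string dialects for genomic features:
#' \code{"chr1:100-200"} and \code{"chr1_100_200"} (coordinates read as
#' 0-based half-open, matching the peak files they index). Chromosome names
#' containing underscores are handled by splitting from the right.
#'
#' @param x character vector of feature strings
#' @return \code{GRanges}
#' @export
parseFeatureStrings <- function(x) {
  m <- regmatches(x, regexec("^(.+)[:_]([0-9]+)[-_]([0-9]+)$", x))
  bad <- which(vapply(m, length, integer(1)) != 4L)
  if (length(bad))
    stop("unparseable feature string: ", x[bad[1]])
  bedToGRanges(data.frame(
    chrom = vapply(m, `[`, character(1), 2L),
    start = as.numeric(vapply(m, `[`, character(1), 3L)),
    end = as.numeric(vapply(m, `[`, character(1), 4L)),
    stringsAsFactors = FALSE))
}

# fread with gzip handled through base R connections, so no optional
# decompression package is needed
freadMaybeGz <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    lines <- readLines(con)
    if (!length(lines)) return(data.table::data.table())
    data.table::fread(text = lines, ...)
  } else data.table::fread(path, ...)
}

findFirst <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Read a cell-by-feature matrix
#'
#' Reads either a 10x-style directory — \code{matrix.mtx(.gz)} plus a
#' features file (\code{peaks.bed}, \code{peaks.tsv} or \code{features.tsv};
#' three coordinate columns or one column of \code{chr:start-end} strings)
#' plus \code{barcodes.tsv} — or a dense TSV whose first column holds feature
#' strings and whose header holds barcodes. Dimensions of the three sidecar
#' files must agree; mismatches are reported with the offending counts.
#'
#' @param path directory or dense TSV file
#' @return a [CellPeakMatrix-class]
#' @export
readCellMatrix <- function(path) {
  if (dir.exists(path)) {
    mtx <- findFirst(path, c("matrix.mtx", "matrix.mtx.gz"))
    if (is.null(mtx)) stop("no matrix.mtx(.gz) in ", path)
    feat <- findFirst(path, c("peaks.bed", "peaks.bed.gz", "peaks.tsv",
                              "features.tsv", "features.tsv.gz"))
    if (is.null(feat)) stop("no peaks/features file in ", path)
    bc <- findFirst(path, c("barcodes.tsv", "barcodes.tsv.gz"))
    if (is.null(bc)) stop("no barcodes.tsv in ", path)
    m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    fdt <- freadMaybeGz(feat, header = FALSE, sep = "\t")
    gr <- if (ncol(fdt) >= 3 && is.numeric(fdt[[2]]) && is.numeric(fdt[[3]]))
      bedToGRanges(data.frame(chrom = as.character(fdt[[1]]),
                              start = fdt[[2]], end = fdt[[3]]))
    else
      parseFeatureStrings(as.character(fdt[[1]]))
    barcodes <- freadMaybeGz(bc, header = FALSE, sep = "\t")[[1]]
    if (length(gr) != nrow(m))
      stop(sprintf("feature file has %d records but matrix has %d rows",
                   length(gr), nrow(m)))
    if (length(barcodes) != ncol(m))
      stop(sprintf("barcodes file has %d records but matrix has %d columns",
                   length(barcodes), ncol(m)))
    CellPeakMatrix(m, gr, barcodes)
  } else if (file.exists(path)) {
    dt <- data.table::fread(path, header = TRUE, sep = "\t")
    gr <- parseFeatureStrings(as.character(dt[[1]]))
    m <- Matrix::Matrix(as.matrix(dt[, -1]), sparse = TRUE)
    CellPeakMatrix(m, gr, colnames(dt)[-1])
  } else stop("no such input: ", path)
}

#' Write a cell-by-feature matrix
#'
#' Writes \code{matrix.mtx}, \code{peaks.bed} and \code{barcodes.tsv} into a
#' directory, round-trippable through [readCellMatrix()].
#'
#' @param cells a [CellPeakMatrix-class]
#' @param dir output directory (created if absent)
#' @return invisibly, \code{dir}
#' @export
writeCellMatrix <- function(cells, dir) {
  stopifnot(methods::is(cells, "CellPeakMatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(cells@counts, file.path(dir, "matrix.mtx"))
  df <- grangesToBed(cells@features)[, c("chrom", "start", "end")]
  data.table::fwrite(df, file.path(dir, "peaks.bed"), sep = "\t",
                     col.names = FALSE)
  writeLines(cells@barcodes, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
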