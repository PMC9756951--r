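# Seeded generators for self-contained testing: a toy genome with planted
# cell-type-specific TR binding, a matching reference index and cell matrix,
# gene models, and QC tables with controlled pass/fail structure. The
# generators emulate the one statistical assumption the method rests on —
# cell-type-specific TR binding is reflected in that cell type's open
# chromatin — and nothing else about real scATAC-seq data.

# run code under a temporary RNG state so generators never disturb the
# caller's stream and regeneration is exactly reproducible
withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a planted-structure toy world
#'
#' Builds a small two-chromosome genome (2 x 10 Mb) carrying one planted TR
#' per cell type. Each TR gets a reference dataset of
#' \code{peaks_per_dataset} disjoint binding sites; the cell matrix opens
#' each cell's own-TR sites with probability \code{signal_rate} and every
#' other feature (other TRs' sites plus background-only features) with
#' probability \code{noise_rate}. Gene models with TSS and exons are placed
#' across the genome for regulatory-potential tests. Regeneration with the
#' same parameters and seed is identical; with \code{dir} set, all standard
#' input files plus the ground truth are written to disk.
#'
#' @param n_cell_types number of planted cell types / TRs (default 3)
#' @param cells_per_type cells per type (default 50)
#' @param peaks_per_dataset binding sites per reference dataset (default 1000)
#' @param noise_rate probability a cell opens a feature outside its own TR's
#'   sites (default 0.1; must be in \[0, 1) and below \code{signal_rate})
#' @param signal_rate probability a cell opens one of its own TR's sites
#'   (default 0.6)
#' @param n_background background features belonging to no TR (default
#'   \code{peaks_per_dataset})
#' @param n_genes gene models to place (default 200)
#' @param peak_width width of every planted site, bp (default 500)
#' @param seed integer seed (required)
#' @param dir optional directory; when given, writes \code{matrix/} (MTX +
#'   peaks + barcodes), \code{index/} (reference), \code{genes.tsv}
#'   (refGene-style) and \code{truth/} (labels TSV + parameters JSON)
#' @return list with \code{cells} ([CellPeakMatrix-class]), \code{index}
#'   ([ReferenceIndex-class]), \code{genes} ([GeneModels-class]),
#'   \code{labels} (barcode -> cell type), \code{tr_of_type} (cell type ->
#'   TR), \code{params}
#' @export
makeToyWorld <- function(n_cell_types = 3L, cells_per_type = 50L,
                         peaks_per_dataset = 1000L, noise_rate = 0.1,
                         signal_rate = 0.6, n_background = peaks_per_dataset,
                         n_genes = 200L, peak_width = 500L, seed, dir = NULL) {
  if (missing(seed)) stop("a seed is required")
  if (noise_rate < 0 || noise_rate >= 1) stop("noise_rate must lie in [0, 1)")
  if (noise_rate >= signal_rate)
    stop("background rate (", noise_rate, ") must be below signal rate (",
         signal_rate, ")")
  chrom_size <- 1e7L
  chroms <- c("chr1", "chr2")
  total_feat <- n_cell_types * peaks_per_dataset + n_background
  per_chrom <- ceiling(total_feat / 2)
  spacing <- chrom_size %/% (per_chrom + 1L)
  if (spacing < 2L * peak_width)
    stop("infeasible geometry: ", total_feat, " peaks of ", peak_width,
         " bp do not fit in 2 x ", chrom_size, " bp")
  withSeed(seed, {
    slot <- seq_len(total_feat)
    chrom <- chroms[(slot - 1L) %% 2L + 1L]
    start <- ((slot - 1L) %/% 2L) * spacing + 1000L  # BED start
    feat <- bedToGRanges(data.frame(chrom = chrom, start = start,
                                    end = start + peak_width))
    owner <- sample(rep(c(paste0("TR", seq_len(n_cell_types)), "background"),
                        times = c(rep(peaks_per_dataset, n_cell_types),
                                  n_background)))
    trs <- paste0("TR", seq_len(n_cell_types))
    peaksets <- lapply(trs, function(tr) GenomicRanges::sort(feat[owner == tr]))
    names(peaksets) <- paste0("DS_", trs)
    metadata <- data.frame(dataset_id = names(peaksets), factor = trs,
                           cell_type = paste0("type", seq_len(n_cell_types)),
                           species = "toy", stringsAsFactors = FALSE)
    index <- buildIndex(peaksets, metadata)
    types <- paste0("type", seq_len(n_cell_types))
    tr_of_type <- setNames(trs, types)
    labels <- rep(types, each = cells_per_type)
    barcodes <- sprintf("cell_%s_%03d", labels, seq_len(cells_per_type))
    n_cells <- length(barcodes)
    prob <- matrix(noise_rate, total_feat, n_cells)
    for (t in seq_along(types))
      prob[owner == trs[t], labels == types[t]] <- signal_rate
    open <- matrix(stats::rbinom(length(prob), 1L, prob), total_feat, n_cells)
    cells <- CellPeakMatrix(Matrix::Matrix(open, sparse = TRUE), feat, barcodes)
    genes <- toyGenes(n_genes, chroms, chrom_size)
    names(labels) <- barcodes
    params <- list(n_cell_types = n_cell_types, cells_per_type = cells_per_type,
                   peaks_per_dataset = peaks_per_dataset,
                   noise_rate = noise_rate, signal_rate = signal_rate,
                   n_background = n_background, n_genes = n_genes,
                   peak_width = peak_width, seed = seed)
    world <- list(cells = cells, index = index,
                  genes = genes$models, genes_table = genes$table,
                  labels = labels, tr_of_type = tr_of_type, params = params)
    if (!is.null(dir)) writeToyWorld(world, dir)
    world
  })
}

# gene models scattered over the toy genome: 3-exon genes spanning 3 kb
toyGenes <- function(n_genes, chroms, chrom_size) {
  chrom <- sample(chroms, n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  tx_start <- sample.int(chrom_size - 20000L, n_genes) + 8000L  # BED coords
  tx_end <- tx_start + 3000L
  rel_s <- c(0L, 1000L, 2800L); rel_e <- c(200L, 1200L, 3000L)
  tbl <- data.frame(
    name = sprintf("G%03d", seq_len(n_genes)),
    chrom = chrom, strand = strand, txStart = tx_start, txEnd = tx_end,
    exonStarts = vapply(tx_start, function(s)
      paste0(paste(s + rel_s, collapse = ","), ","), character(1)),
    exonEnds = vapply(tx_start, function(s)
      paste0(paste(s + rel_e, collapse = ","), ","), character(1)),
    stringsAsFactors = FALSE)
  exon_list <- lapply(seq_len(n_genes), function(i)
    GenomicRanges::GRanges(chrom[i],
      IRanges::IRanges(tx_start[i] + rel_s + 1L, tx_start[i] + rel_e)))
  exons <- GenomicRanges::GRangesList(exon_list)
  names(exons) <- tbl$name
  models <- geneModelsFromParts(tbl$name, chrom, strand,
                                tx_start + 1L, tx_end, exons)
  list(models = models, table = tbl)
}

writeToyWorld <- function(world, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  writeCellMatrix(world$cells, file.path(dir, "matrix"))
  writeIndex(world$index, file.path(dir, "index"))
  data.table::fwrite(world$genes_table, file.path(dir, "genes.tsv"), sep = "\t")
  data.table::fwrite(data.frame(cell = names(world$labels),
                                cell_type = unname(world$labels),
                                tr = unname(world$tr_of_type[world$labels])),
                     file.path(dir, "truth", "labels.tsv"), sep = "\t")
  jsonlite::write_json(world$params, file.path(dir, "truth", "world.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

.qc_pass_values <- c(median_quality = 30, unique_map_frac = 0.8, pbc = 0.9,
                     fold10_peaks = 500, frip = 0.2, dhs_top5000_frac = 0.9)
.qc_fail_values <- c(median_quality = 20, unique_map_frac = 0.4, pbc = 0.7,
                     fold10_peaks = 50, frip = 0.005, dhs_top5000_frac = 0.5)

#' Generate a QC table with controlled failures
#'
#' Builds a dataset QC table where every metric sits strictly on the
#' requested side of its filtering threshold: for each entry of \code{fail},
#' either \code{"none"} (passes all gates) or the name of exactly one metric
#' to fail.
#'
#' @param fail character vector, one entry per synthetic dataset: "none" or
#'   one of \code{median_quality}, \code{unique_map_frac}, \code{pbc},
#'   \code{fold10_peaks}, \code{frip}, \code{dhs_top5000_frac}
#' @return data.frame consumable by [applyQCFilters()] with dataset ids
#'   \code{qc1}, \code{qc2}, ...
#' @export
makeQCTable <- function(fail) {
  bad <- setdiff(fail, c("none", names(.qc_pass_values)))
  if (length(bad))
    stop("unknown QC criterion: ", paste(unique(bad), collapse = ", "))
  m <- t(vapply(fail, function(f) {
    v <- .qc_pass_values
    if (f != "none") v[f] <- .qc_fail_values[f]
    v
  }, numeric(length(.qc_pass_values))))
  rownames(m) <- NULL
  qc <- as.data.frame(m)
  cbind(data.frame(dataset_id = sprintf("qc%d", seq_along(fail)),
                   stringsAsFactors = FALSE), qc)
}

#' Simulate RP matrices with planted differential targets
#'
#' Two groups of cells with lognormal per-gene regulatory potential; the
#' first \code{n_shift} genes are multiplied by \code{fold} in group A.
#' Used to exercise [differentialTargets()] against known truth.
#'
#' @param n_genes total genes (default 200)
#' @param n_shift planted shifted genes (default 20)
#' @param cells_per_group cells per group (default 50)
#' @param fold multiplicative shift in group A (default 2)
#' @param seed integer seed (required)
#' @return list with matrices \code{A}, \code{B} and character vector
#'   \code{shifted} of planted gene names
#' @export
simulateDifferentialRP <- function(n_genes = 200L, n_shift = 20L,
                                   cells_per_group = 50L, fold = 2,
                                   seed) {
  if (missing(seed)) stop("a seed is required")
  withSeed(seed, {
    genes <- sprintf("G%03d", seq_len(n_genes))
    base <- stats::rlnorm(n_genes, meanlog = 0.5, sdlog = 0.5)
    draw <- function(shift) {
      m <- base * shift *
        matrix(stats::rlnorm(n_genes * cells_per_group, 0, 0.3),
               n_genes, cells_per_group)
      rownames(m) <- genes
      m
    }
    shift_vec <- c(rep(fold, n_shift), rep(1, n_genes - n_shift))
    A <- draw(shift_vec)
    B <- draw(1)
    colnames(A) <- sprintf("A%03d", seq_len(cells_per_group))
    colnames(B) <- sprintf("B%03d", seq_len(cells_per_group))
    list(A = A, B = B, shifted = genes[seq_len(n_shift)])
  })
}
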