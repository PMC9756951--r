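# Target-gene inference: per-cell TR binding-site imputation from the
# best-matched reference dataset, the exponential distance-decay
# regulatory-potential (RP) model, differential targets between cell
# groups, and GRN edge construction.

#' Read gene models from a refGene-style table or GTF
#'
#' Builds one model per gene symbol: strand-aware TSS, promoter window
#' (TSS +/- 1000 bp, clipped at the chromosome start), the reduced union of
#' exon intervals and the total exon length in kb. For symbols with several
#' transcripts the transcript with the longest genomic span supplies the
#' TSS; exons are the union over all transcripts of the symbol.
#'
#' refGene-style input is a TSV with header columns \code{name},
#' \code{chrom}, \code{strand}, \code{txStart}, \code{txEnd},
#' \code{exonStarts}, \code{exonEnds} (comma-separated, 0-based half-open)
#' and optionally \code{name2} (the symbol; falls back to \code{name}).
#' GTF input is parsed via \pkg{rtracklayer} from \code{exon} records
#' carrying \code{gene_name} (or \code{gene_id}).
#'
#' @param path annotation file; format picked by extension (\code{.gtf}/
#'   \code{.gff} vs anything else) unless forced.
#' @param format \code{"auto"}, \code{"refgene"} or \code{"gtf"}
#' @return a [GeneModels-class]
#' @export
readGeneAnnotation <- function(path, format = c("auto", "refgene", "gtf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(gtf|gff[23]?)(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "refgene"
  if (format == "gtf") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("GTF input requires the rtracklayer package")
    gtf <- rtracklayer::import(path)
    ex <- gtf[gtf$type == "exon"]
    sym <- as.character(if (!is.null(ex$gene_name)) ex$gene_name else ex$gene_id)
    df <- data.frame(sym = sym,
                     chrom = as.character(GenomicRanges::seqnames(ex)),
                     strand = as.character(GenomicRanges::strand(ex)),
                     start = GenomicRanges::start(ex),
                     end = GenomicRanges::end(ex),
                     stringsAsFactors = FALSE)
    genes <- unique(df$sym)
    first <- match(genes, df$sym)
    exon_list <- lapply(genes, function(g) {
      d <- df[df$sym == g, ]
      GenomicRanges::reduce(GenomicRanges::GRanges(
        d$chrom[1], IRanges::IRanges(d$start, d$end)))
    })
    exons <- GenomicRanges::GRangesList(exon_list)
    names(exons) <- genes
    tx_start <- tapply(df$start, df$sym, min)[genes]
    tx_end <- tapply(df$end, df$sym, max)[genes]
    geneModelsFromParts(genes, df$chrom[first], df$strand[first],
                        as.integer(tx_start), as.integer(tx_end), exons)
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE)
    need <- c("name", "chrom", "strand", "txStart", "txEnd",
              "exonStarts", "exonEnds")
    miss <- setdiff(need, colnames(dt))
    if (length(miss))
      stop("annotation missing column(s): ", paste(miss, collapse = ", "))
    sym <- if ("name2" %in% colnames(dt)) dt$name2 else dt$name
    # one model per symbol: longest-span transcript anchors the TSS
    span <- dt$txEnd - dt$txStart
    pick <- tapply(seq_len(nrow(dt)), sym, function(ix) ix[which.max(span[ix])])
    genes <- names(pick)
    pick <- as.integer(pick)
    parse_pos <- function(x) lapply(strsplit(as.character(x), ","), as.integer)
    estarts <- parse_pos(dt$exonStarts)
    eends <- parse_pos(dt$exonEnds)
    exon_list <- lapply(genes, function(g) {
      ix <- which(sym == g)
      s <- unlist(estarts[ix]); e <- unlist(eends[ix])
      keep <- !is.na(s) & !is.na(e) & e > s
      GenomicRanges::reduce(GenomicRanges::GRanges(
        dt$chrom[ix[1]], IRanges::IRanges(s[keep] + 1L, e[keep])))
    })
    exons <- GenomicRanges::GRangesList(exon_list)
    names(exons) <- genes
    geneModelsFromParts(genes, dt$chrom[pick], dt$strand[pick],
                        dt$txStart[pick] + 1L, dt$txEnd[pick], exons)
  }
}

# assemble a GeneModels from per-gene chrom/strand/1-based tx span + exons
geneModelsFromParts <- function(genes, chrom, strand, tx_start, tx_end, exons) {
  strand <- ifelse(strand %in% c("+", "-"), strand, "+")
  tss_pos <- ifelse(strand == "+", tx_start, tx_end)
  tss <- GenomicRanges::GRanges(chrom, IRanges::IRanges(tss_pos, tss_pos),
                                strand = strand)
  names(tss) <- genes
  prom <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(pmax(tss_pos - 1000L, 1L), tss_pos + 1000L))
  names(prom) <- genes
  kb <- vapply(seq_along(exons),
               function(i) sum(GenomicRanges::width(exons[[i]])) / 1000,
               numeric(1))
  names(kb) <- genes
  new("GeneModels", tss = tss, promoters = prom, exons = exons, exon_kb = kb)
}

#' Impute a TR's binding sites in one cell
#'
#' The binding sites of a TR in a cell are taken to be the peaks of the
#' cell's best-matched reference dataset that fall in the cell's open
#' chromatin: reference peaks overlapping at least one of the cell's peaks.
#' In \code{extended} mode, reference datasets that are the best match for
#' at least one cell of the TR are pooled first (useful when individual
#' datasets are shallow or mix cell types), then intersected with the
#' cell's peaks.
#'
#' @param cell_peaks \code{GRanges} of the cell's open features
#' @param best_dataset \code{GRanges} of the cell's best-matched dataset
#' @param extended pool peaks across best-match datasets of this TR
#' @param all_best named list of \code{GRanges}: every dataset that is a
#'   best match for some cell of this TR (required when \code{extended})
#' @return \code{GRanges} of imputed binding sites (subset of the reference
#'   peaks)
#' @export
imputeTRPeaks <- function(cell_peaks, best_dataset, extended = FALSE,
                          all_best = NULL) {
  if (extended) {
    if (is.null(all_best) || !length(all_best))
      stop("extended mode requires the pooled best-match datasets")
    pool <- do.call(c, unname(lapply(all_best, GenomicRanges::granges)))
    pool <- GenomicRanges::sort(unique(pool), ignore.strand = TRUE)
    intersectPeaks(pool, cell_peaks)
  } else {
    if (is.null(best_dataset))
      stop("no best-match dataset assigned for this cell/TR")
    intersectPeaks(best_dataset, cell_peaks)
  }
}

#' Classify a TR as promoter- or enhancer-type
#'
#' The fraction of a TR's binding sites overlapping promoter windows
#' (TSS +/- 1 kb) determines its regulatory range: above 20% the TR is
#' promoter-type with half-decay distance 1 kb, otherwise enhancer-type with
#' 10 kb. The boundary is strict: exactly 20% is enhancer-type.
#'
#' @param tr_peaks \code{GRanges} of TR binding sites (non-empty)
#' @param genes a [GeneModels-class]
#' @return list with \code{type} ("promoter"/"enhancer"), \code{d0} (bp) and
#'   \code{promoter_fraction}
#' @export
classifyTRType <- function(tr_peaks, genes) {
  stopifnot(methods::is(genes, "GeneModels"))
  if (!length(tr_peaks)) stop("cannot classify a TR with no peaks")
  frac <- mean(IRanges::overlapsAny(tr_peaks, genes@promoters,
                                    ignore.strand = TRUE))
  if (frac > 0.20) list(type = "promoter", d0 = 1000, promoter_fraction = frac)
  else list(type = "enhancer", d0 = 10000, promoter_fraction = frac)
}

#' Regulatory-potential scores for one peak set
#'
#' Scores every gene by the distance-decayed contribution of nearby binding
#' sites: S_g = sum_i 2^(-d_i / d0), where d_i is the distance between the
#' i-th peak's center and the gene's TSS and d0 the half-decay distance.
#' Only peaks whose center lies within \code{cutoff_mult * d0} (default 15,
#' where a single peak's contribution has fallen below 0.0005) of the TSS
#' are counted.
#'
#' The \code{enhanced} model refines two cases: a peak overlapping an exon
#' of the scored gene contributes 1 / (total exon length of that gene in kb)
#' instead of the decay term, and a peak overlapping the promoter or an exon
#' of any *other* gene contributes 0 (it is accounted to that gene, not to
#' bystanders). When neither rule fires the enhanced model equals the simple
#' one.
#'
#' @param tr_peaks \code{GRanges} of (imputed) TR binding sites
#' @param genes a [GeneModels-class]
#' @param d0 half-decay distance in bp, or \code{"auto"} to pick 1 kb /
#'   10 kb from the promoter-peak fraction via [classifyTRType()]
#' @param model \code{"simple"} (default) or \code{"enhanced"}
#' @param cutoff_mult search-window radius in units of d0 (default 15);
#'   \code{Inf} disables truncation
#' @return named numeric vector of RP scores, one per gene (0 when no peak
#'   is in range)
#' @export
rpScore <- function(tr_peaks, genes, d0 = "auto",
                    model = c("simple", "enhanced"), cutoff_mult = 15) {
  model <- match.arg(model)
  stopifnot(methods::is(genes, "GeneModels"), cutoff_mult > 0)
  if (identical(d0, "auto"))
    d0 <- classifyTRType(tr_peaks, genes)$d0
  d0 <- as.numeric(d0)
  if (!is.finite(d0) || d0 <= 0) stop("d0 must be a positive number")
  gene_names <- names(genes@tss)
  scores <- setNames(numeric(length(gene_names)), gene_names)
  if (!length(tr_peaks)) return(scores)
  centers <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(tr_peaks),
    IRanges::IRanges(peakCenters(tr_peaks), width = 1L))
  radius <- if (is.finite(cutoff_mult)) cutoff_mult * d0 else NULL
  tss_pos <- GenomicRanges::start(genes@tss)
  if (is.null(radius)) {
    win <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(genes@tss),
      IRanges::IRanges(1L, .Machine$integer.max %/% 2L))
  } else {
    win <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(genes@tss),
      IRanges::IRanges(pmax(tss_pos - radius, 1), tss_pos + radius))
  }
  hits <- GenomicRanges::findOverlaps(centers, win, ignore.strand = TRUE)
  if (!length(hits)) return(scores)
  pk <- S4Vectors::queryHits(hits)
  gn <- S4Vectors::subjectHits(hits)
  d <- abs(GenomicRanges::start(centers)[pk] - tss_pos[gn])
  contrib <- 2^(-d / d0)
  if (model == "enhanced") {
    exon_flat <- unlist(genes@exons, use.names = FALSE)
    exon_gene <- rep(seq_along(genes@exons),
                     lengths(genes@exons))
    eh <- GenomicRanges::findOverlaps(tr_peaks, exon_flat, ignore.strand = TRUE)
    exon_pairs <- unique(cbind(S4Vectors::queryHits(eh),
                               exon_gene[S4Vectors::subjectHits(eh)]))
    ph <- GenomicRanges::findOverlaps(tr_peaks, genes@promoters,
                                      ignore.strand = TRUE)
    prom_pairs <- unique(cbind(S4Vectors::queryHits(ph),
                               S4Vectors::subjectHits(ph)))
    touch_pairs <- unique(rbind(exon_pairs, prom_pairs))
    # per peak: which genes' exons it sits in, and how many genes it touches
    in_own_exon <- paste(pk, gn) %in% paste(exon_pairs[, 1], exon_pairs[, 2])
    touch_count <- tabulate(touch_pairs[, 1], nbins = length(tr_peaks))
    touches_pair <- paste(pk, gn) %in% paste(touch_pairs[, 1], touch_pairs[, 2])
    touches_other <- (touch_count[pk] - as.integer(touches_pair)) > 0
    kb <- genes@exon_kb[gn]
    if (any(in_own_exon & kb == 0))
      stop("gene with zero exon length cannot take an exon-normalized score: ",
           gene_names[gn[which(in_own_exon & kb == 0)[1]]])
    contrib[in_own_exon] <- 1 / kb[in_own_exon]
    contrib[!in_own_exon & touches_other] <- 0
  }
  agg <- tapply(contrib, gn, sum)
  scores[as.integer(names(agg))] <- as.numeric(agg)
  setNames(scores, gene_names)
}

peakCenters <- function(gr) {
  (GenomicRanges::start(gr) + GenomicRanges::end(gr)) %/% 2L
}

#' Gene-by-cell RP matrix for one TR
#'
#' For every cell, imputes the TR's binding sites from the cell's
#' best-matched dataset ([imputeTRPeaks()]) and scores all genes with
#' [rpScore()]. Cells sharing both the best-matched dataset and (up to
#' binarization) the same open features are computed once. The half-decay
#' distance under \code{d0 = "auto"} is classified once per best-matched
#' dataset from its full peak set.
#'
#' @param cells a [CellPeakMatrix-class]
#' @param index a [ReferenceIndex-class]
#' @param tr factor name present in the index
#' @param best_match best-match table from [trActivity()] (columns cell,
#'   factor, dataset_id)
#' @param genes a [GeneModels-class]
#' @param d0,model,cutoff_mult passed to [rpScore()]
#' @param extended pool best-match datasets as in [imputeTRPeaks()]
#' @return gene-by-cell numeric matrix of RP scores
#' @export
rpMatrix <- function(cells, index, tr, best_match, genes, d0 = "auto",
                     model = c("simple", "enhanced"), cutoff_mult = 15,
                     extended = FALSE) {
  model <- match.arg(model)
  stopifnot(methods::is(cells, "CellPeakMatrix"),
            methods::is(index, "ReferenceIndex"))
  bm <- best_match[best_match$factor == tr, , drop = FALSE]
  if (!nrow(bm)) stop("no best-match assignments for TR '", tr, "'")
  miss <- setdiff(cells@barcodes, bm$cell)
  if (length(miss))
    stop("cell(s) without best-match assignment: ",
         paste(head(miss, 3), collapse = ", "))
  ds_of_cell <- setNames(bm$dataset_id, bm$cell)[cells@barcodes]
  all_best <- index@peaks[unique(bm$dataset_id)]
  b <- binarizeCounts(cells@counts)
  out <- matrix(0, length(genes@tss), ncol(b),
                dimnames = list(names(genes@tss), cells@barcodes))
  d0_of_ds <- vapply(unique(ds_of_cell), function(id) {
    if (identical(d0, "auto")) classifyTRType(index@peaks[[id]], genes)$d0
    else as.numeric(d0)
  }, numeric(1))
  for (i in seq_len(ncol(b))) {
    open <- cells@features[b[, i] > 0]
    imputed <- imputeTRPeaks(open, index@peaks[[ds_of_cell[i]]],
                             extended = extended, all_best = all_best)
    out[, i] <- rpScore(imputed, genes, d0 = d0_of_ds[[ds_of_cell[i]]],
                        model = model, cutoff_mult = cutoff_mult)
  }
  out
}

#' Rank target genes by regulatory potential
#'
#' Aggregates a gene-by-cell RP matrix over cells (mean by default) and
#' returns the top-scoring genes in decreasing order; ties break
#' alphabetically by symbol, and genes with zero aggregate score are never
#' reported.
#'
#' @param rp gene-by-cell RP matrix (or a named per-gene vector)
#' @param top_n number of targets to report
#' @param aggregate \code{"mean"} (default) or \code{"max"} over cells
#' @return named numeric vector of aggregate RP, decreasing, length
#'   <= \code{top_n}
#' @export
rankTargets <- function(rp, top_n, aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  stopifnot(top_n >= 1)
  score <- if (is.matrix(rp)) {
    if (aggregate == "mean") rowMeans(rp) else apply(rp, 1, max)
  } else rp
  score <- score[score > 0]
  score <- score[order(-score, names(score))]
  head(score, top_n)
}

#' Differential TR targets between two cell groups
#'
#' Compares gene-level regulatory potential between two groups of cells.
#' RP is normalized with the natural logarithm (log(1 + RP)) and scaled
#' within each cell (z-score over genes); per gene, a two-sided Wilcoxon
#' rank-sum test compares the scaled values between groups and the log fold
#' change is the difference of group means on the ln scale. A gene is
#' significant when |logFC| >= \code{logfc} (default 0.25) and
#' p <= \code{pcut} (default 0.01); both boundaries inclusive. Genes with
#' zero RP in every cell of both groups are dropped before testing.
#'
#' @param rpA,rpB gene-by-cell RP matrices with identical gene rows; each
#'   group needs at least 3 cells.
#' @param logfc minimum absolute ln-scale fold change (default 0.25)
#' @param pcut maximum p-value (default 0.01)
#' @return data.frame (gene, logFC, p, significant) ordered by p
#' @export
differentialTargets <- function(rpA, rpB, logfc = 0.25, pcut = 0.01) {
  stopifnot(is.matrix(rpA), is.matrix(rpB),
            identical(rownames(rpA), rownames(rpB)))
  if (ncol(rpA) < 3 || ncol(rpB) < 3)
    stop("each group needs at least 3 cells")
  keep <- rowSums(rpA) + rowSums(rpB) > 0
  rpA <- rpA[keep, , drop = FALSE]
  rpB <- rpB[keep, , drop = FALSE]
  lnA <- log1p(rpA); lnB <- log1p(rpB)
  scale_cells <- function(m) apply(m, 2, function(x) {
    s <- sdPop(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  sA <- scale_cells(lnA); sB <- scale_cells(lnB)
  p <- vapply(seq_len(nrow(sA)), function(g) {
    suppressWarnings(stats::wilcox.test(sA[g, ], sB[g, ], exact = FALSE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  lfc <- rowMeans(lnA) - rowMeans(lnB)
  res <- data.frame(gene = rownames(rpA), logFC = lfc, p = p,
                    significant = abs(lfc) >= logfc & p <= pcut,
                    row.names = NULL, stringsAsFactors = FALSE)
  res[order(res$p, res$gene), ]
}

#' Build a gene-regulatory network from RP matrices
#'
#' For every (TR, cell type) pair, keeps the \code{top_cells} cells with the
#' highest total RP in that cell type (all of them when fewer are
#' available), aggregates RP per gene over those cells (\code{max} by
#' default, \code{mean} optional), ranks targets and emits weighted
#' TR-to-gene edges. Edges from different TRs share gene nodes, exposing
#' co-regulation.
#'
#' @param rp_list named list of gene-by-cell RP matrices, one per TR
#' @param cell_labels named character vector: barcode -> cell type; every
#'   column of every matrix must be labeled.
#' @param top_cells per-(TR, cell type) cell budget (default 500)
#' @param top_n targets per (TR, cell type) (default 1000)
#' @param aggregate \code{"max"} (default) or \code{"mean"}
#' @return data.frame of edges (tr, gene, weight, context), no duplicate
#'   (tr, gene, context) rows
#' @export
buildGRN <- function(rp_list, cell_labels, top_cells = 500L, top_n = 1000L,
                     aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.list(rp_list), !is.null(names(rp_list)))
  edges <- list()
  for (tr in names(rp_list)) {
    rp <- rp_list[[tr]]
    unlabeled <- setdiff(colnames(rp), names(cell_labels))
    if (length(unlabeled))
      stop("unlabeled cell(s): ", paste(head(unlabeled, 3), collapse = ", "))
    labs <- cell_labels[colnames(rp)]
    for (ct in unique(labs)) {
      cols <- which(labs == ct)
      tot <- colSums(rp[, cols, drop = FALSE])
      keep <- cols[order(-tot, seq_along(cols))][seq_len(min(top_cells, length(cols)))]
      targets <- rankTargets(rp[, keep, drop = FALSE], top_n,
                             aggregate = if (aggregate == "max") "max" else "mean")
      if (length(targets))
        edges[[length(edges) + 1L]] <- data.frame(
          tr = tr, gene = names(targets), weight = as.numeric(targets),
          context = ct, stringsAsFactors = FALSE)
    }
  }
  if (!length(edges))
    return(data.frame(tr = character(), gene = character(),
                      weight = numeric(), context = character()))
  do.call(rbind, edges)
}
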