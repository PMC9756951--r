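# The TR activity scoring chain. Raw overlap counts M (dataset x cell) are
# normalized by reference size and per-cell accessible bp, centered per
# dataset, deduplicated to one score per TR, compressed through a logistic
# sigmoid per TR, and z-scored per cell. All standard deviations use the
# population (1/n) denominator.

sdPop <- function(x) sqrt(mean((x - mean(x))^2))

#' Normalize an overlap matrix for reference and cell size
#'
#' Divides each raw overlap count by the product of the dataset's peak count
#' D_j and the cell's accessible base pairs per 100 million bp Q_i:
#' M'\[j, i\] = M\[j, i\] / (D_j * Q_i). This removes the bias toward large
#' reference datasets and deeply covered cells.
#'
#' @param M dataset-by-cell overlap count matrix from [overlapMatrix()]
#' @param D per-dataset peak counts (length nrow(M))
#' @param Q per-cell accessible bp divided by 1e8 (length ncol(M))
#' @return dataset-by-cell numeric matrix M'
#' @export
normalizeOverlaps <- function(M, D, Q) {
  stopifnot(is.matrix(M), length(D) == nrow(M), length(Q) == ncol(M))
  if (any(D <= 0))
    stop("dataset with zero peaks cannot be normalized: ",
         paste(head(rownames(M)[D <= 0], 3), collapse = ", "))
  if (any(Q <= 0))
    stop("cell with zero covered bp cannot be normalized: ",
         paste(head(colnames(M)[Q <= 0], 3), collapse = ", "))
  M / outer(as.numeric(D), as.numeric(Q))
}

#' Center normalized scores per reference dataset
#'
#' Subtracts from every dataset's scores its mean over cells, so datasets of
#' different baseline enrichment become comparable:
#' M''\[j, \] = M'\[j, \] - mean(M'\[j, \]).
#'
#' @param Mprime dataset-by-cell matrix from [normalizeOverlaps()]
#' @return centered matrix with per-dataset mean 0
#' @export
centerByDataset <- function(Mprime) {
  stopifnot(is.matrix(Mprime), ncol(Mprime) >= 1)
  Mprime - rowMeans(Mprime)
}

#' Collapse duplicate datasets to one score per TR
#'
#' Many TRs are represented by several ChIP-seq datasets (different tissues
#' or cell lines) and possibly a motif pseudo-peak set. Under the default
#' \code{max} strategy each cell independently keeps, for every TR, the
#' largest centered score among that TR's datasets; the winning dataset is
#' recorded as the cell's best match for the TR (ties break to the
#' lexicographically smallest dataset id, for determinism). The
#' \code{average} strategy takes the mean over the TR's datasets instead and
#' defines no best match.
#'
#' @param Mpp dataset-by-cell centered matrix from [centerByDataset()]
#' @param factor_map character vector mapping dataset id to factor: values
#'   are factors, names are dataset ids (all rows of \code{Mpp} must appear).
#' @param strategy \code{"max"} (default) or \code{"average"}
#' @return list with \code{Y} (TR-by-cell matrix, TRs in first-appearance
#'   order) and \code{best_match} (data.frame cell/factor/dataset_id; empty
#'   for \code{average})
#' @export
deduplicateFactors <- function(Mpp, factor_map, strategy = c("max", "average")) {
  strategy <- match.arg(strategy)
  stopifnot(is.matrix(Mpp))
  ids <- rownames(Mpp)
  if (is.null(ids)) stop("Mpp must have dataset ids as rownames")
  miss <- setdiff(ids, names(factor_map))
  if (length(miss))
    stop("dataset(s) not mapped to a factor: ", paste(miss, collapse = ", "))
  fac <- as.character(factor_map[ids])
  factors <- unique(fac)
  Y <- matrix(0, length(factors), ncol(Mpp),
              dimnames = list(factors, colnames(Mpp)))
  bm <- vector("list", length(factors))
  for (fi in seq_along(factors)) {
    rows <- which(fac == factors[fi])
    # deterministic tie-break: scan datasets in id order, first max wins
    rows <- rows[order(ids[rows])]
    sub <- Mpp[rows, , drop = FALSE]
    if (strategy == "max") {
      win <- apply(sub, 2, which.max)
      Y[fi, ] <- sub[cbind(win, seq_len(ncol(sub)))]
      bm[[fi]] <- data.frame(cell = colnames(Mpp), factor = factors[fi],
                             dataset_id = ids[rows][win],
                             stringsAsFactors = FALSE)
    } else {
      Y[fi, ] <- colMeans(sub)
    }
  }
  best_match <- if (strategy == "max") do.call(rbind, bm)
                else data.frame(cell = character(), factor = character(),
                                dataset_id = character())
  rownames(best_match) <- NULL
  list(Y = Y, best_match = best_match)
}

#' Sigmoid-compress enrichment scores per TR
#'
#' Stabilizes each TR's scores and compresses outliers: within a TR the
#' scores are z-scored across cells (population sd) and passed through the
#' logistic sigmoid 1 / (1 + exp(-z)), mapping every score into (0, 1) with
#' cells at the TR mean landing on 0.5. A TR constant across all cells has
#' undefined z; its z is set to 0 (all cells 0.5) with a warning.
#'
#' @param Y TR-by-cell matrix from [deduplicateFactors()]
#' @return matrix of the same shape with entries in (0, 1)
#' @export
sigmoidScale <- function(Y) {
  stopifnot(is.matrix(Y), ncol(Y) >= 2)
  out <- Y
  flat <- character()
  for (k in seq_len(nrow(Y))) {
    s <- sdPop(Y[k, ])
    if (s == 0) {
      flat <- c(flat, if (is.null(rownames(Y))) as.character(k) else rownames(Y)[k])
      z <- rep(0, ncol(Y))
    } else z <- (Y[k, ] - mean(Y[k, ])) / s
    out[k, ] <- 1 / (1 + exp(-z))
  }
  if (length(flat))
    warning(length(flat), " TR(s) constant across cells; sigmoid set to 0.5 (",
            paste(head(flat, 3), collapse = ", "), ")")
  out
}

#' z-score activity within each cell
#'
#' Final scaling step: each cell's scores over TRs are centered and divided
#' by their population sd, giving every cell the same dynamic range (mean 0,
#' sd 1) so cells are comparable for clustering. A degenerate cell with
#' identical scores for all TRs gets zeros and a warning.
#'
#' @param Y TR-by-cell matrix from [sigmoidScale()]
#' @return matrix with per-cell (column) mean 0 and sd 1
#' @export
cellZscore <- function(Y) {
  stopifnot(is.matrix(Y), nrow(Y) >= 2)
  out <- Y
  flat <- character()
  for (i in seq_len(ncol(Y))) {
    s <- sdPop(Y[, i])
    if (s == 0) {
      flat <- c(flat, if (is.null(colnames(Y))) as.character(i) else colnames(Y)[i])
      out[, i] <- 0
    } else out[, i] <- (Y[, i] - mean(Y[, i])) / s
  }
  if (length(flat))
    warning(length(flat), " cell(s) with constant TR scores; set to 0 (",
            paste(head(flat, 3), collapse = ", "), ")")
  out
}

#' Smooth sparse cell profiles with nearest neighbors
#'
#' scATAC-seq profiles are near-binary and sparse; before overlap scoring
#' each cell's profile is combined with its k nearest neighbors. Cells are
#' embedded by TF-IDF weighting of the binarized matrix followed by a
#' truncated SVD (LSI); neighbors are found by cosine similarity in the
#' embedding. With \code{aggregate = "union"} (default) a feature is open in
#' the smoothed cell if open in the cell or any neighbor; \code{"sum"} sums
#' raw counts instead. \code{k = 0} returns the input unchanged. The
#' procedure is deterministic; \code{seed} is accepted for interface
#' stability with stochastic smoothers.
#'
#' @param cells a [CellPeakMatrix-class]
#' @param k neighbor count (default 20; must be < number of cells)
#' @param dims LSI dimensionality (default 50, clamped to the matrix rank)
#' @param aggregate \code{"union"} or \code{"sum"}
#' @param seed unused placeholder, kept so callers can thread one seed
#'   through the whole pipeline
#' @return a smoothed [CellPeakMatrix-class]
#' @export
knnSmooth <- function(cells, k = 20L, dims = 50L,
                      aggregate = c("union", "sum"), seed = NULL) {
  aggregate <- match.arg(aggregate)
  stopifnot(methods::is(cells, "CellPeakMatrix"))
  n <- ncol(cells@counts)
  if (k < 0) stop("k must be non-negative")
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells (", n, ")")
  if (k == 0) return(cells)
  b <- binarizeCounts(cells@counts)
  emb <- lsiEmbedding(b, dims)
  # cosine similarity on row-normalized embedding
  nrm <- sqrt(rowSums(emb^2))
  nrm[nrm == 0] <- 1
  emb <- emb / nrm
  sim <- emb %*% t(emb)
  smoothed <- cells@counts
  for (i in seq_len(n)) {
    ord <- order(-sim[i, ], seq_len(n))
    nn <- setdiff(ord, i)[seq_len(k)]
    grp <- c(i, nn)
    v <- Matrix::rowSums(cells@counts[, grp, drop = FALSE])
    if (aggregate == "union") v <- as.numeric(v > 0)
    smoothed[, i] <- v
  }
  CellPeakMatrix(smoothed, cells@features, cells@barcodes)
}

# TF-IDF + truncated SVD (LSI) embedding of a binarized feature-by-cell
# matrix; returns cells x dims. Dense SVD — intended for the matrix sizes
# this package targets (up to a few thousand cells).
lsiEmbedding <- function(b, dims) {
  depth <- Matrix::colSums(b)
  depth[depth == 0] <- 1
  tf <- b %*% Matrix::Diagonal(x = 1 / depth)
  idf <- ncol(b) / pmax(Matrix::rowSums(b), 1)
  x <- log1p(as.matrix(tf * 1e4) * idf)
  dims <- max(1L, min(dims, nrow(x) - 1L, ncol(x) - 1L))
  sv <- svd(t(x), nu = dims, nv = 0)
  sv$u %*% diag(sv$d[seq_len(dims)], dims, dims)
}

#' Score per-cell TR activity against a reference index
#'
#' End-to-end activity pipeline: optional kNN smoothing of cell profiles,
#' overlap counting against every reference dataset, normalization by
#' reference peak count and per-cell accessible bp, per-dataset centering,
#' deduplication to one score per TR (recording each cell's best-matched
#' dataset), per-TR sigmoid compression and per-cell z-scoring.
#'
#' @param cells a [CellPeakMatrix-class]
#' @param index a [ReferenceIndex-class]
#' @param knn_k neighbors for smoothing (default 20; 0 disables)
#' @param strategy deduplication strategy, \code{"max"} or \code{"average"}
#' @param seed integer seed threaded through the pipeline
#' @param dims LSI dimensionality for the smoothing embedding
#' @return a [TRActivity-class]
#' @examples
#' tw <- makeToyWorld(n_cell_types = 2, cells_per_type = 10,
#'                    peaks_per_dataset = 200, seed = 7)
#' act <- trActivity(tw$cells, tw$index, knn_k = 3, seed = 7)
#' activityScores(act)[, 1:3]
#' @export
trActivity <- function(cells, index, knn_k = 20L,
                       strategy = c("max", "average"), seed = 1L, dims = 50L) {
  strategy <- match.arg(strategy)
  stopifnot(methods::is(cells, "CellPeakMatrix"),
            methods::is(index, "ReferenceIndex"))
  if (knn_k > 0)
    cells <- knnSmooth(cells, k = knn_k, dims = dims, seed = seed)
  M <- overlapMatrix(cells, index)
  D <- peakCounts(index)
  Q <- coveredBp(cells) / 1e8
  Mpp <- centerByDataset(normalizeOverlaps(M, D, Q))
  fmap <- setNames(as.character(index@meta$factor), index@meta$dataset_id)
  dd <- deduplicateFactors(Mpp, fmap, strategy = strategy)
  act <- cellZscore(sigmoidScale(dd$Y))
  new("TRActivity", activity = act, enrichment = dd$Y,
      best_match = dd$best_match, strategy = strategy)
}
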