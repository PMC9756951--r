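test_that("QC gates are strict inequalities applied jointly", {
  qc <- makeQCTable(c("none", "median_quality", "unique_map_frac", "pbc",
                      "fold10_peaks", "frip", "dhs_top5000_frac"))
  expect_identical(applyQCFilters(qc), "qc1")
  # a dataset sitting exactly at a threshold is removed (strict >)
  qc2 <- makeQCTable("none")
  qc2$frip <- 0.01
  expect_identical(applyQCFilters(qc2), character(0))
  # all metrics comfortably above thresholds -> retained
  qc3 <- data.frame(dataset_id = "x", median_quality = 30,
                    unique_map_frac = 0.8, pbc = 0.9, fold10_peaks = 500,
                    frip = 0.2, dhs_top5000_frac = 0.9)
  expect_identical(applyQCFilters(qc3), "x")
  # hand-checked mixed table: per-row re-evaluation of every gate
  set.seed(404)
  opts <- c("none", "median_quality", "frip", "pbc")
  fails <- sample(opts, 10, replace = TRUE)
  tab <- makeQCTable(fails)
  expect_identical(applyQCFilters(tab), tab$dataset_id[fails == "none"])
})

test_that("QC filtering demands every metric", {
  qc <- makeQCTable("none")
  qc$pbc <- NULL
  expect_error(applyQCFilters(qc), "pbc")
  qc2 <- makeQCTable("none")
  qc2$frip <- NA
  expect_error(applyQCFilters(qc2), "frip")
})

test_that("fold filtering keeps >= min_fold and is idempotent", {
  pk <- bed_gr("chr1", c(0, 100, 200, 300), c(50, 150, 250, 350),
               fold = c(2, 4.9, 5, 8))
  kept <- filterPeaksByFold(pk)
  expect_equal(S4Vectors::mcols(kept)$fold, c(5, 8))
  expect_equal(filterPeaksByFold(pk, 0), pk)
  expect_equal(filterPeaksByFold(kept), kept)  # idempotent
  expect_error(filterPeaksByFold(bed_gr("chr1", 0, 10)), "fold")
  set.seed(9)
  folds <- stats::runif(100, 0, 10)
  pk2 <- bed_gr("chr1", seq(0, by = 100, length.out = 100),
                seq(50, by = 100, length.out = 100), fold = folds)
  expect_equal(S4Vectors::mcols(filterPeaksByFold(pk2, 5))$fold,
               folds[folds >= 5])
})

test_that("small datasets are dropped below 1000 peaks", {
  mk <- function(n) bed_gr("chr1", seq_len(n) * 10, seq_len(n) * 10 + 5)
  sets <- list(a = mk(500), b = mk(999), c = mk(1000), d = mk(2500))
  expect_identical(names(dropSmallDatasets(sets)), c("c", "d"))
  expect_length(dropSmallDatasets(list()), 0)
  set.seed(5)
  ns <- sample(1:3000, 50)
  sets2 <- lapply(ns, mk)
  names(sets2) <- paste0("s", seq_along(ns))
  expect_identical(names(dropSmallDatasets(sets2)),
                   paste0("s", which(ns >= 1000)))
  # idempotent
  expect_identical(dropSmallDatasets(dropSmallDatasets(sets)),
                   dropSmallDatasets(sets))
})

test_that("motif pseudo-peaks are standardized to 340 bp within open regions", {
  ccre <- bed_gr("chr1", 1000, 2000)
  dhs <- bed_gr("chr1", 5000, 6000)
  blk <- bed_gr("chr1", 9000, 9500)
  # 12 bp site inside ccRE -> width exactly 340
  s <- bed_gr("chr1", 1500, 1512, pvalue = 1e-5)
  out <- buildMotifPseudoPeaks(s, ccre, dhs, blk)
  expect_equal(GenomicRanges::width(out), 340)
  # symmetric about the midpoint, odd extension biased left
  mid_in <- (1500 + 1512) / 2
  bed <- grangesToBed(out)
  expect_lte(abs((bed$start + bed$end) / 2 - mid_in), 1)
  # DHS membership is sufficient (union rule)
  s2 <- bed_gr("chr1", 5100, 5112, pvalue = 1e-5)
  expect_length(buildMotifPseudoPeaks(s2, ccre, dhs, blk), 1)
  # neither list -> dropped; blacklisted -> dropped
  s3 <- bed_gr("chr1", 3000, 3012, pvalue = 1e-5)
  expect_length(buildMotifPseudoPeaks(s3, ccre, dhs, blk), 0)
  s4 <- bed_gr("chr1", c(1500, 9100), c(1512, 9112), pvalue = c(1e-5, 1e-9))
  expect_length(buildMotifPseudoPeaks(s4, ccre, bed_gr("chr1", 9000, 9500), blk), 1)
  # clipping at the chromosome start shortens, never shifts the right edge
  near0 <- bed_gr("chr1", 10, 22, pvalue = 1e-4)
  out0 <- buildMotifPseudoPeaks(near0, bed_gr("chr1", 0, 100), dhs,
                                GenomicRanges::GRanges())
  expect_lt(GenomicRanges::width(out0), 340)
  expect_identical(grangesToBed(out0)$start, 0L)
})

test_that("the per-motif cap keeps the smallest p-values", {
  n <- 400
  starts <- seq(0, by = 1000, length.out = n)
  sites <- bed_gr("chr1", starts, starts + 12, pvalue = stats::runif(n))
  ccre <- bed_gr("chr1", 0, max(starts) + 1000)
  out <- buildMotifPseudoPeaks(sites, ccre, GenomicRanges::GRanges(),
                               GenomicRanges::GRanges(), max_sites = 100)
  expect_length(out, 100)
  expect_setequal(S4Vectors::mcols(out)$pvalue,
                  sort(S4Vectors::mcols(sites)$pvalue)[1:100])
  # cap never exceeded, missing p-values only matter when the cap binds
  nop <- bed_gr("chr1", starts[1:50], starts[1:50] + 12)
  expect_length(buildMotifPseudoPeaks(nop, ccre, GenomicRanges::GRanges(),
                                      GenomicRanges::GRanges()), 50)
  expect_error(buildMotifPseudoPeaks(nop, ccre, GenomicRanges::GRanges(),
                                     GenomicRanges::GRanges(), max_sites = 10),
               "p-value")
})

test_that("index build records counts and survives a disk round trip", {
  mk <- function(n, off = 0) bed_gr("chr1", seq_len(n) * 50 + off,
                                    seq_len(n) * 50 + 20 + off)
  sets <- list(chip1 = mk(30), chip2 = mk(40, 7), chip3 = mk(50, 13),
               motif1 = mk(25, 3), motif2 = mk(35, 11))
  meta <- data.frame(dataset_id = names(sets),
                     factor = c("FOXA1", "GATA3", "FOXA1", "TCF7", "SPI1"),
                     cell_type = "t", species = "toy")
  idx <- buildIndex(sets, meta)
  expect_identical(nrow(indexMeta(idx)), 5L)
  expect_identical(length(unique(indexMeta(idx)$factor)), 4L)
  expect_identical(unname(peakCounts(idx)), c(30L, 40L, 50L, 25L, 35L))
  # motif-only factor is searchable like any dataset
  expect_length(datasetPeaks(idx, "motif1"), 25)
  dir <- withr::local_tempdir()
  writeIndex(idx, dir)
  idx2 <- readIndex(dir)
  expect_identical(peakCounts(idx2), peakCounts(idx))
  expect_identical(indexMeta(idx2)$factor, indexMeta(idx)$factor)
  for (id in names(sets))
    expect_identical(grangesToBed(datasetPeaks(idx2, id)),
                     grangesToBed(datasetPeaks(idx, id)))
  dup <- sets
  names(dup)[2] <- "chip1"
  expect_error(buildIndex(dup, meta), "duplicate")
})
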