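test_that("gene annotation readers agree on TSS, promoters and exons", {
  g <- make_genes(c(A = 100000, B = 500000), strand = c("+", "-"))
  expect_identical(names(g@tss), c("A", "B"))
  # plus strand: TSS at txStart; minus strand: TSS at txEnd
  expect_identical(GenomicRanges::start(g@tss), c(100001L, 503000L))
  expect_identical(GenomicRanges::width(g@promoters), c(2001L, 2001L))
  expect_equal(unname(g@exon_kb), c(2, 2))
})

test_that("GTF input yields the same gene models as the refGene table", {
  skip_if_not_installed("rtracklayer")
  gtf <- withr::local_tempfile(fileext = ".gtf")
  # two exons of gene A on +, GTF coordinates are 1-based closed
  writeLines(c(
    paste("chr1", "src", "exon", "100001", "100200", ".", "+", ".",
          'gene_name "A";', sep = "\t"),
    paste("chr1", "src", "exon", "101001", "102000", ".", "+", ".",
          'gene_name "A";', sep = "\t")), gtf)
  g <- readGeneAnnotation(gtf)
  expect_identical(names(g@tss), "A")
  expect_identical(GenomicRanges::start(g@tss), 100001L)
  expect_equal(unname(g@exon_kb), 1.2)
  expect_identical(GenomicRanges::width(g@promoters), 2001L)
})

test_that("TR type classification uses the strict 20% promoter boundary", {
  g <- make_genes(c(A = 100000))
  n_in <- function(k, total) {
    cen <- c(rep(100500, k), seq(2e6, by = 1e5, length.out = total - k))
    do.call(c, lapply(cen, peak_at))
  }
  cls <- classifyTRType(n_in(3, 10), g)  # 30% in promoter
  expect_identical(cls$type, "promoter")
  expect_equal(cls$d0, 1000)
  cls2 <- classifyTRType(n_in(1, 10), g)  # 10%
  expect_identical(cls2$type, "enhancer")
  expect_equal(cls2$d0, 10000)
  cls3 <- classifyTRType(n_in(2, 10), g)  # exactly 20% -> enhancer
  expect_identical(cls3$type, "enhancer")
  expect_error(classifyTRType(GenomicRanges::GRanges(), g), "no peaks")
})

test_that("RP closed forms: 1 at the TSS, halving per d0, 15*d0 window", {
  g <- make_genes(c(A = 100000))
  tss <- 100001  # 1-based position of the + strand TSS
  d0 <- 1000
  expect_equal(rpScore(peak_at(tss), g, d0)[["A"]], 1)
  expect_equal(rpScore(peak_at(tss + d0), g, d0)[["A"]], 0.5)
  expect_equal(rpScore(peak_at(tss + 15 * d0), g, d0)[["A"]], 2^-15)
  expect_lt(2^-15, 0.0005)
  expect_equal(rpScore(peak_at(tss + 16 * d0), g, d0)[["A"]], 0)
  # peaks at d0 and 2*d0 sum term by term
  both <- c(peak_at(tss + d0), peak_at(tss + 2 * d0))
  expect_equal(rpScore(both, g, d0)[["A"]], 0.75)
  # distance is strand-independent and symmetric around the TSS
  expect_equal(rpScore(peak_at(tss - d0), g, d0)[["A"]], 0.5)
})

test_that("RP is additive over peak-set partitions and decay is monotone", {
  g <- make_genes(c(A = 100000, B = 500000))
  set.seed(61)
  centers <- sample(seq(90000, 510000, by = 100), 60)
  pk <- do.call(c, lapply(centers, peak_at))
  whole <- rpScore(pk, g, 10000)
  split1 <- rpScore(pk[1:25], g, 10000)
  split2 <- rpScore(pk[26:60], g, 10000)
  expect_equal(whole, split1 + split2, tolerance = 1e-12)
  d <- seq(0, 15000, by = 1000)
  s <- vapply(d, function(x) rpScore(peak_at(100001 + x), g, 1000)[["A"]],
              numeric(1))
  expect_true(all(diff(s) < 0))
  expect_equal(s[2:16] / s[1:15], rep(0.5, 15), tolerance = 1e-12)
})

test_that("truncation at 15*d0 loses less than 0.0005 per omitted peak", {
  g <- make_genes(c(A = 1000000))
  set.seed(62)
  centers <- sample(seq(0, 2e6, by = 50), 500)
  pk <- do.call(c, lapply(centers, peak_at))
  d0 <- 10000
  full <- rpScore(pk, g, d0, cutoff_mult = Inf)[["A"]]
  trunc <- rpScore(pk, g, d0, cutoff_mult = 15)[["A"]]
  omitted <- sum(abs(centers - 1000000) > 15 * d0)
  expect_gte(full, trunc)
  expect_lt(full - trunc, 0.0005 * omitted)
})

test_that("enhanced RP applies exon and nearby-gene rules", {
  # gene A with a 2 kb exon block, gene B far away with its own promoter
  g <- make_genes(c(A = 100000, B = 130000))
  d0 <- 10000
  # peak inside A's exon: contribution 1 / (2 kb) = 0.5, not the decay term
  in_exon <- peak_at(100500)
  expect_equal(rpScore(in_exon, g, d0, model = "enhanced")[["A"]], 0.5)
  # the same peak contributes 0 to B (it lies in another gene's exon)
  expect_equal(rpScore(in_exon, g, d0, model = "enhanced")[["B"]], 0)
  # peak in B's promoter (upstream, outside B's exon) zeroes A's score but
  # decays normally for B itself
  in_b_prom <- peak_at(129500)
  expect_equal(rpScore(in_b_prom, g, d0, model = "enhanced")[["A"]], 0)
  expect_equal(rpScore(in_b_prom, g, d0, model = "enhanced")[["B"]],
               rpScore(in_b_prom, g, d0, model = "simple")[["B"]])
  # with no exon or neighbor overlap anywhere, enhanced equals simple
  lone <- peak_at(110000)
  expect_equal(rpScore(lone, g, d0, model = "enhanced"),
               rpScore(lone, g, d0, model = "simple"))
})

test_that("binding-site imputation is reference peaks in open chromatin", {
  tw <- toy_world_small()
  ds <- datasetPeaks(tw$index, "DS_TR1")
  # cell peaks superset of dataset peaks -> all dataset peaks imputed
  expect_length(imputeTRPeaks(features(tw$cells), ds), length(ds))
  # disjoint -> empty
  far <- bed_gr("chr9", 0, 100)
  expect_length(imputeTRPeaks(far, ds), 0)
  # random cells match a brute-force filter, and output is a subset of ds
  set.seed(91)
  for (rep in 1:5) {
    open <- random_peaks(150, max_pos = 9e6)
    got <- imputeTRPeaks(open, ds)
    expect_equal(grangesToBed(got), grangesToBed(brute_intersect(ds, open)))
    expect_true(gr_subset(got, ds))
  }
  # extended mode pools best-match datasets before intersecting
  pool <- list(a = ds[1:100], b = ds[50:200])
  ext <- imputeTRPeaks(features(tw$cells), NULL, extended = TRUE,
                       all_best = pool)
  expect_length(ext, 200)
  expect_error(imputeTRPeaks(far, NULL), "best-match")
})

test_that("target ranking orders by aggregate RP with stable ties", {
  rp <- matrix(c(2, 1, 0), 3, 1, dimnames = list(c("A", "B", "C"), "c1"))
  expect_identical(names(rankTargets(rp, 2)), c("A", "B"))
  # zero-score genes never reported even under a large top_n
  expect_identical(names(rankTargets(rp, 1000)), c("A", "B"))
  tie <- matrix(c(1, 1, 0.5), 3, 1, dimnames = list(c("Z", "M", "Q"), "c1"))
  expect_identical(names(rankTargets(tie, 3)), c("M", "Z", "Q"))
  set.seed(71)
  sc <- matrix(runif(300), 100, 3,
               dimnames = list(sprintf("g%03d", 1:100), NULL))
  got <- rankTargets(sc, 10)
  oracle <- sort(rowMeans(sc), decreasing = TRUE)[1:10]
  expect_equal(got, oracle)
})

test_that("differential targets flag planted shifts at 0.25/0.01 thresholds", {
  # identical groups produce no significant genes
  sim0 <- simulateDifferentialRP(n_shift = 0, seed = 11)
  dt0 <- differentialTargets(sim0$A, sim0$A)
  expect_false(any(dt0$significant))
  sim <- simulateDifferentialRP(seed = 12)
  dt <- differentialTargets(sim$A, sim$B)
  hits <- dt$gene[dt$significant]
  expect_gte(sum(hits %in% sim$shifted), 18)
  expect_lte(sum(!hits %in% sim$shifted), 8)  # ~nominal false positives
  expect_error(differentialTargets(sim$A[, 1:2], sim$B), "at least 3")
  # inclusive boundaries: logFC exactly at 0.25 with small p is significant
  set.seed(13)
  nA <- matrix(rlnorm(50 * 6, 0, 0.05), 50, 6,
               dimnames = list(sprintf("g%02d", 1:50), NULL))
  nB <- nA[, 1:6]
  g1A <- expm1(log1p(nA[1, ]) + 0.25)  # engineered ln1p shift of exactly 0.25
  nA[1, ] <- g1A
  dtb <- differentialTargets(nA, nB)
  row1 <- dtb[dtb$gene == "g01", ]
  expect_equal(row1$logFC, 0.25, tolerance = 1e-10)
  if (row1$p <= 0.01) expect_true(row1$significant)
})

test_that("GRN construction keeps top cells per type and shares gene nodes", {
  set.seed(81)
  genes <- sprintf("g%02d", 1:30)
  mk <- function(seed) {
    m <- matrix(rlnorm(30 * 8), 30, 8,
                dimnames = list(genes, sprintf("c%02d", 1:8)))
    m
  }
  rp_list <- list(TRa = mk(1), TRb = mk(2))
  # both TRs share a dominant target
  rp_list$TRa["g05", ] <- 50
  rp_list$TRb["g05", ] <- 60
  labels <- setNames(rep(c("t1", "t2"), each = 4), sprintf("c%02d", 1:8))
  grn <- buildGRN(rp_list, labels, top_cells = 500, top_n = 1)
  expect_identical(nrow(grn), 4L)  # 2 TRs x 2 contexts
  expect_true(all(grn$gene == "g05"))  # shared node
  # top_cells larger than available cells: clamp, no error
  grn2 <- buildGRN(rp_list["TRa"], labels, top_cells = 500, top_n = 5)
  expect_identical(nrow(grn2), 10L)
  expect_error(buildGRN(rp_list, labels[1:4]), "unlabeled")
  # manual oracle on a tiny instance with top_cells binding
  rp <- matrix(c(10, 0, 1, 1, 0, 10), 3, 2,
               dimnames = list(c("x", "y", "z"), c("c1", "c2")))
  lab <- c(c1 = "ct", c2 = "ct")
  g1 <- buildGRN(list(TR = rp), lab, top_cells = 1, top_n = 3)
  # c1 and c2 tie on total RP (11 each); the tie breaks to the first cell,
  # whose nonzero genes are x (10) and z (1)
  expect_identical(g1$gene, c("x", "z"))
  expect_equal(g1$weight, c(10, 1))
})
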