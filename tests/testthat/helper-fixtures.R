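# shared fixtures and independent oracles

# GRanges from BED-convention coordinates (0-based half-open)
bed_gr <- function(chrom, start, end, ...) {
  bedToGRanges(data.frame(chrom = chrom, start = start, end = end, ...,
                          stringsAsFactors = FALSE))
}

# O(n*m) brute-force pair counting straight from the overlap definition:
# same chromosome and at least one shared base. Independent of the
# interval-index implementation under test.
brute_count_overlaps <- function(a, b) {
  ca <- as.character(GenomicRanges::seqnames(a))
  cb <- as.character(GenomicRanges::seqnames(b))
  sa <- GenomicRanges::start(a); ea <- GenomicRanges::end(a)
  sb <- GenomicRanges::start(b); eb <- GenomicRanges::end(b)
  total <- 0L
  for (i in seq_along(a))
    total <- total + sum(cb == ca[i] & sb <= ea[i] & eb >= sa[i])
  total
}

# brute-force `intersect -u`: intervals of a hit by >= 1 interval of b
brute_intersect <- function(a, b) {
  ca <- as.character(GenomicRanges::seqnames(a))
  cb <- as.character(GenomicRanges::seqnames(b))
  sa <- GenomicRanges::start(a); ea <- GenomicRanges::end(a)
  sb <- GenomicRanges::start(b); eb <- GenomicRanges::end(b)
  hit <- vapply(seq_along(a), function(i)
    any(cb == ca[i] & sb <= ea[i] & eb >= sa[i]), logical(1))
  a[hit]
}

# random interval set in BED coordinates on a small 2-chromosome genome
random_peaks <- function(n, max_pos = 1e6, max_width = 1000) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  bed_gr(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
         start = start,
         end = start + sample.int(max_width, n, replace = TRUE))
}

# small shared toy world; memoised so several test files can reuse it
toy_world_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makeToyWorld(n_cell_types = 3, cells_per_type = 20,
                             peaks_per_dataset = 300, seed = 101)
    cache
  }
})

# population-sd helper mirroring the package's z-score convention
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# a minimal GeneModels written as a refGene-style table and read back:
# genes on chr1 with known TSS (BED txStart) and one 2 kb exon by default
make_genes <- function(tss = c(A = 100000, B = 500000), strand = "+",
                       exon_offsets = list(c(0, 2000))) {
  n <- length(tss)
  tbl <- data.frame(
    name = names(tss), chrom = "chr1",
    strand = rep(strand, length.out = n),
    txStart = unname(tss), txEnd = unname(tss) + 3000,
    exonStarts = vapply(unname(tss), function(s)
      paste0(paste(s + vapply(exon_offsets, `[`, numeric(1), 1),
                   collapse = ","), ","), character(1)),
    exonEnds = vapply(unname(tss), function(s)
      paste0(paste(s + vapply(exon_offsets, `[`, numeric(1), 2),
                   collapse = ","), ","), character(1)))
  f <- tempfile(fileext = ".tsv")
  data.table::fwrite(tbl, f, sep = "\t")
  on.exit(unlink(f))
  readGeneAnnotation(f)
}

# width-11 peak whose center sits exactly at 1-based position `center`
peak_at <- function(center) {
  bed_gr("chr1", center - 6, center + 5)
}

# GRanges subset test without relying on the S4 %in% method being attached
gr_subset <- function(a, b) {
  all(IRanges::overlapsAny(a, b, type = "equal", ignore.strand = TRUE))
}
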