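test_that("merging collapses overlaps and is idempotent", {
  gr <- GRanges("chr1", IRanges(c(1, 51), c(100, 150)))
  m <- merge_intervals(gr)
  expect_equal(length(m), 1L)
  expect_equal(start(m), 1L)
  expect_equal(end(m), 150L)
  one <- GRanges("chr1", IRanges(1, 100))
  expect_equal(ranges(merge_intervals(one)), ranges(one))
  expect_equal(ranges(merge_intervals(m)), ranges(m))
})

test_that("merging preserves per-base coverage on random sets", {
  set.seed(11)
  genome <- toy_genome(5e4, 3e4)
  for (rep in 1:5) {
    gr <- random_regions(genome, 100, min_len = 10, max_len = 3000)
    m <- merge_intervals(gr)
    for (chrom in seqlevels(genome)) {
      expect_identical(
        base_membership(m, chrom, seqlengths(genome)[[chrom]]),
        base_membership(gr, chrom, seqlengths(genome)[[chrom]]))
    }
    # minimality: merged intervals are strictly separated
    st <- split(m, seqnames(m))
    for (s in st) {
      if (length(s) > 1) expect_true(all(start(s)[-1] > end(s)[-length(s)] + 1))
    }
  }
})

test_that("merge rejects intervals outside chromosome bounds", {
  genome <- toy_genome(1000)
  gr <- suppressWarnings(GRanges("chr1", IRanges(900, 1100),
                                 seqinfo = genome))
  expect_error(merge_intervals(gr), "bounds")
})

test_that("overlap_kb matches hand-computed and brute-force values", {
  genome <- toy_genome()
  q <- GRanges("chr1", IRanges(1, 500), seqinfo = genome)
  f <- GRanges("chr1", IRanges(601, 700), seqinfo = genome)
  expect_equal(overlap_kb(q, f), 0)
  kb1 <- GRanges("chr1", IRanges(1, 1000), seqinfo = genome)
  expect_equal(overlap_kb(kb1, kb1), 1)
  q2 <- GRanges("chr1", IRanges(c(1, 801), c(500, 2000)), seqinfo = genome)
  f2 <- GRanges("chr1", IRanges(401, 900), seqinfo = genome)
  expect_equal(overlap_kb(q2, f2), 0.2)
  # symmetry and self-overlap identities
  set.seed(21)
  a <- random_regions(genome, 40)
  b <- random_regions(genome, 25)
  expect_equal(overlap_kb(a, b), overlap_kb(b, a))
  expect_equal(overlap_kb(a, a),
               sum(width(merge_intervals(a))) / 1000)
  expect_equal(overlap_kb(a, b), brute_overlap_kb(a, b, genome))
})

test_that("overlap_kb refuses mismatched genome layouts", {
  a <- GRanges("chr1", IRanges(1, 10), seqinfo = Seqinfo("chr1", 1e4))
  b <- GRanges("chr1", IRanges(1, 10), seqinfo = Seqinfo("chr1", 2e4))
  expect_error(overlap_kb(a, b), "different genome")
})

test_that("replicate intersection is class-aware and matches a pairwise oracle", {
  a <- GRanges("chr1", IRanges(1, 100), cnc_class = "gain")
  b_same <- GRanges("chr1", IRanges(51, 150), cnc_class = "gain")
  b_diff <- GRanges("chr1", IRanges(1, 100), cnc_class = "loss")
  expect_equal(length(intersect_replicates(a, b_same)), 1L)
  expect_equal(length(intersect_replicates(a, b_diff)), 0L)
  expect_error(intersect_replicates(a, GRanges("chr1", IRanges(1, 10))),
               "cnc_class")

  set.seed(31)
  genome <- toy_genome()
  for (rep in 1:3) {
    x <- random_regions(genome, 30)
    y <- random_regions(genome, 30)
    mcols(x)$cnc_class <- sample(c("gain", "loss"), 30, replace = TRUE)
    mcols(y)$cnc_class <- sample(c("gain", "loss"), 30, replace = TRUE)
    got <- intersect_replicates(x, y)
    keep <- vapply(seq_along(x), function(i) {
      any(as.character(seqnames(y)) == as.character(seqnames(x))[i] &
            start(y) <= end(x)[i] & end(y) >= start(x)[i] &
            mcols(y)$cnc_class == mcols(x)$cnc_class[i])
    }, logical(1))
    expect_equal(length(got), sum(keep))
    expect_lte(length(got), length(x))
  }
})

test_that("nearest TSS distance uses midpoints and flags geneless chromosomes", {
  # region [901,1100] has midpoint 1001; TSS at 1001 -> 0 kb
  g <- toy_genes("a", "chr1", "+", 1001, 3000)
  expect_equal(nearest_tss_distance(GRanges("chr1", IRanges(901, 1100)), g), 0)
  # region [4001,6000] midpoint 5001, single TSS at 1 -> 5 kb
  g2 <- toy_genes("b", "chr1", "+", 1, 4000)
  expect_equal(nearest_tss_distance(GRanges("chr1", IRanges(4001, 6000)), g2), 5)
  # no gene on the region's chromosome -> NA, not zero
  expect_true(is.na(nearest_tss_distance(GRanges("chr2", IRanges(1, 10)), g)))
})

test_that("nearest TSS distance equals an exhaustive scan on random layouts", {
  set.seed(41)
  genome <- toy_genome()
  regions <- random_regions(genome, 500)
  tsspos <- sort(sample(seqlengths(genome)[["chr1"]], 50))
  genes <- toy_genes(paste0("g", 1:50), "chr1", "+", tsspos, tsspos + 10)
  got <- nearest_tss_distance(regions, genes)
  chr <- as.character(seqnames(regions))
  mid <- start(regions) + width(regions) %/% 2L
  want <- ifelse(chr == "chr1",
                 vapply(mid, function(m) min(abs(m - tsspos)), numeric(1)) / 1000,
                 NA_real_)
  expect_equal(got, want)
})

test_that("genes per region counts TSSs in the extended window", {
  genes <- toy_genes(c("a", "b", "c"), "chr1", "+",
                     c(100, 200, 300), c(150, 260, 380))
  r <- GRanges("chr1", IRanges(50, 350))
  expect_equal(genes_per_region(r, genes, window_bp = 0), 3L)
  empty <- genes[0, ]
  expect_equal(genes_per_region(r, empty), 0L)
  expect_error(genes_per_region(r, genes, window_bp = -1), ">= 0")

  set.seed(51)
  genome <- toy_genome()
  regions <- random_regions(genome, 200)
  tsspos <- sample(seqlengths(genome)[["chr1"]], 80)
  rg <- toy_genes(paste0("g", 1:80), "chr1", "+", tsspos, tsspos + 5)
  for (w in c(0, 500, 5000)) {
    got <- genes_per_region(regions, rg, window_bp = w)
    want <- vapply(seq_along(regions), function(i) {
      if (as.character(seqnames(regions))[i] != "chr1") return(0L)
      sum(tsspos >= start(regions)[i] - w & tsspos <= end(regions)[i] + w)
    }, integer(1))
    expect_equal(got, want)
  }
})
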