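test_that("interval density matches per-bp summation", {
  tr <- toy_track(chr1 = rep(4, 1000))
  expect_equal(interval_density(tr, "chr1", 1, 1000), 4)
  expect_equal(interval_density(tr, "chr1", 37, 411), 4)
  tr2 <- toy_track(chr1 = c(rep(10, 500), rep(0, 500)))
  expect_equal(interval_density(tr2, "chr1", 1, 1000), 5)
  set.seed(29)
  v <- rpois(2000, 3)
  tr3 <- toy_track(chr1 = v)
  for (i in 1:10) {
    s <- sample(1500, 1); e <- s + sample(400, 1)
    expect_equal(interval_density(tr3, "chr1", s, e),
                 sum(v[s:e]) / (e - s + 1))
  }
  expect_error(interval_density(tr, "chr1", 10, 9), "length")
  expect_error(interval_density(tr, "chr1", 900, 1100), "extent")
})

test_that("traveling ratio identities hold", {
  genes <- toy_genes(c("a", "b"), "chr1", c("+", "-"),
                     c(1000, 9000), c(5000, 6000))
  uni <- toy_track(chr1 = rep(2, 10000))
  tr <- traveling_ratio(uni, genes)
  expect_false(any(tr$excluded))
  expect_equal(tr$tr, c(1, 1))

  # promoter density 10, body density 2 -> tr = 5 (pseudocount 0)
  v <- rep(0, 10000)
  v[970:1299] <- 10      # promoter window of "a": [tss-30, tss+299]
  v[1300:5000] <- 2      # body of "a"
  t2 <- traveling_ratio(toy_track(chr1 = v), genes[1, ])
  expect_equal(t2$promoter_density, 10)
  expect_equal(t2$body_density, 2)
  expect_equal(t2$tr, 5)
})

test_that("TR is invariant under coverage scaling and strand mirroring", {
  set.seed(31)
  L <- 20000
  v <- rpois(L, 2) + 0.5
  plus <- toy_genes("p", "chr1", "+", 3000, 9000)
  tr1 <- traveling_ratio(toy_track(chr1 = v), plus)
  tr5 <- traveling_ratio(toy_track(chr1 = 5 * v), plus)
  expect_equal(tr1$tr, tr5$tr)

  # mirror the chromosome: a "-"-strand gene at mirrored coordinates
  # sees the same transcription-oriented coverage
  minus <- toy_genes("m", "chr1", "-", L - 3000 + 1, L - 9000 + 1)
  trm <- traveling_ratio(toy_track(chr1 = rev(v)), minus)
  expect_equal(trm$tr, tr1$tr)
  expect_equal(trm$promoter_density, tr1$promoter_density)
  expect_equal(trm$body_density, tr1$body_density)
})

test_that("short genes and zero-density bodies are excluded with reasons", {
  genes <- toy_genes(c("short", "zero"), "chr1", "+",
                     c(1000, 5000), c(1200, 9000))
  v <- rep(0, 10000); v[4970:5299] <- 3
  tr <- traveling_ratio(toy_track(chr1 = v), genes)
  expect_true(all(tr$excluded))
  expect_equal(tr$reason,
               c("body_shorter_than_promoter_window", "zero_body_density"))
  # a pseudocount rescues the zero-body gene
  tr2 <- traveling_ratio(toy_track(chr1 = v), genes, pseudocount = 0.1)
  expect_false(tr2$excluded[2])
  expect_gt(tr2$tr[2], 1)
})

test_that("RoTR is 1 when chip equals input, and divides TRs otherwise", {
  set.seed(37)
  genes <- toy_genes(paste0("g", 1:5), "chr1", "+",
                     seq(1000, 41000, by = 10000),
                     seq(1000, 41000, by = 10000) + 6000)
  v <- rpois(50000, 4) + 1
  track <- toy_track(chr1 = v)
  tr <- traveling_ratio(track, genes)
  ro <- ratio_of_traveling_ratios(tr, tr)
  expect_equal(ro$rotr, rep(1, 5))
  tr_b <- tr; tr_b$tr <- tr_b$tr / 3
  ro2 <- ratio_of_traveling_ratios(tr, tr_b)
  expect_equal(ro2$rotr, rep(3, 5))
})

test_that("a simulated chip-only pausing factor shows up as median RoTR", {
  cfg <- sim_config(seed = 41, chrom_lengths = c(chrS1 = 3e6, chrS2 = 3e6),
                    n_genes = 220, frac_expressed = 1)
  gg <- simulate_genome_genes(cfg)
  chip <- simulate_coverage(gg$genes, gg$genome, "chip", pausing = 2,
                            config = cfg, seed = 1)
  inp <- simulate_coverage(gg$genes, gg$genome, "input", config = cfg,
                           seed = 2)
  ro <- ratio_of_traveling_ratios(traveling_ratio(chip, gg$genes),
                                  traveling_ratio(inp, gg$genes))
  expect_gt(nrow(ro), 200)
  expect_lt(abs(median(ro$rotr) - 2) / 2, 0.1)
})

test_that("active-gene calling recovers expressed genes and is monotone", {
  cfg <- sim_config(seed = 43, chrom_lengths = c(chrS1 = 2e6, chrS2 = 2e6),
                    n_genes = 150)
  gg <- simulate_genome_genes(cfg)
  chip <- simulate_coverage(gg$genes, gg$genome, "chip", pausing = 2,
                            config = cfg, seed = 3)
  inp <- simulate_coverage(gg$genes, gg$genome, "input", config = cfg,
                           seed = 4)
  active <- call_active_genes(chip, inp, gg$genes)
  expressed <- gg$genes$gene_id[gg$genes$expressed]
  expect_gte(mean(expressed %in% active), 0.99)
  expect_equal(sum(!(active %in% expressed)), 0L)
  sizes <- vapply(c(1, 2, 4, 8), function(th) {
    length(call_active_genes(chip, inp, gg$genes, enrichment_threshold = th))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # identical chip and input at threshold 2: nothing passes
  expect_equal(length(call_active_genes(inp, inp, gg$genes)), 0L)
})

test_that("metagene profiles are exact for constant and single-gene cases", {
  genes <- toy_genes(c("a", "b"), "chr1", "+", c(5000, 20000),
                     c(9000, 24000))
  const <- toy_track(chr1 = rep(3, 30000))
  prof <- metagene_profile(const, genes, n_body_bins = 10, flank_bp = 500,
                           n_flank_bins = 5)
  expect_equal(prof$n_genes, 2L)
  expect_equal(prof$profile$mean_signal, rep(3, 20))
  expect_equal(as.character(unique(prof$profile$region)),
               c("upstream", "body", "downstream"))

  v <- rep(1, 30000); v[5000:9000] <- 7
  single <- metagene_profile(toy_track(chr1 = v), genes[1, ],
                             n_body_bins = 4, flank_bp = 100, n_flank_bins = 2)
  expect_equal(single$profile$mean_signal[3:6], rep(7, 4))

  # two constant genes average to the mean of the constants
  v2 <- rep(0, 30000); v2[5000:9000] <- 2; v2[20000:24000] <- 4
  two <- metagene_profile(toy_track(chr1 = v2), genes, n_body_bins = 5,
                          flank_bp = 200, n_flank_bins = 2)
  expect_equal(two$profile$mean_signal[3:7], rep(3, 5))
  expect_error(metagene_profile(const, genes[0, ]), "empty")
})

test_that("cumulative curves report percent at-or-below each value", {
  cc <- cumulative_curve(c(1, 2, 3, 4))
  expect_equal(cc$percent[cc$value == 2], 50)
  expect_equal(cc$percent[length(cc$percent)], 100)
  expect_equal(cumulative_curve(7)$percent, 100)
  set.seed(47)
  cc2 <- cumulative_curve(rnorm(200))
  expect_true(all(diff(cc2$percent) > 0))
  expect_true(all(diff(cc2$value) > 0))
})
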