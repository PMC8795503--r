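probe_df <- function(pos, lr, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, log2_ratio = lr)
}

test_that("the run-threshold caller finds constructed segments and nothing else", {
  flat <- probe_df(seq(100, 10000, by = 100), 0)
  expect_equal(length(call_cnc(flat)), 0L)

  pos <- seq(100, 5000, by = 100)
  lr <- rep(0, length(pos))
  lr[11:30] <- 1.0
  calls <- call_cnc(probe_df(pos, lr), threshold_log2 = 0.5, min_probes = 5)
  expect_equal(length(calls), 1L)
  expect_equal(mcols(calls)$cnc_class, "gain")
  expect_equal(start(calls), pos[11])
  expect_equal(end(calls), pos[30])
  expect_equal(mcols(calls)$n_probes, 20L)
  expect_equal(mcols(calls)$mean_log2_ratio, 1.0)

  # losses, and runs shorter than min_probes are dropped
  lr2 <- rep(0, length(pos))
  lr2[5:9] <- -0.8   # 5 probes: kept
  lr2[20:23] <- -0.8 # 4 probes: dropped
  calls2 <- call_cnc(probe_df(pos, lr2), 0.5, 5)
  expect_equal(length(calls2), 1L)
  expect_equal(mcols(calls2)$cnc_class, "loss")
})

test_that("every call re-checks probe-by-probe and calls never overlap", {
  set.seed(13)
  for (rep in 1:5) {
    pos <- seq(200, 2e5, by = 200)
    lr <- rnorm(length(pos), 0, 0.3)
    seg <- sample(length(pos) - 30, 3)
    for (s in seg) lr[s:(s + 14)] <- lr[s:(s + 14)] + sample(c(2, -2), 1)
    probes <- probe_df(pos, lr)
    calls <- call_cnc(probes, 0.5, 5)
    if (length(calls) > 1) {
      expect_true(all(start(calls)[-1] > end(calls)[-length(calls)]))
    }
    for (i in seq_along(calls)) {
      inside <- probes$pos >= start(calls)[i] & probes$pos <= end(calls)[i]
      thr <- if (mcols(calls)$cnc_class[i] == "gain") {
        all(probes$log2_ratio[inside] >= 0.5)
      } else all(probes$log2_ratio[inside] <= -0.5)
      expect_true(thr)
      expect_gte(sum(inside), 5L)
      expect_equal(mcols(calls)$n_probes[i], sum(inside))
    }
  }
})

test_that("pure-noise tables essentially never produce calls", {
  hits <- 0L
  for (s in 1:30) {
    set.seed(s)
    probes <- probe_df(seq(100, 1e6, by = 100), rnorm(9999 + 1, 0, 0.1))
    hits <- hits + (length(call_cnc(probes, 0.5, 5)) > 0L)
  }
  expect_equal(hits, 0L)
})

test_that("unsorted probe positions are rejected", {
  expect_error(call_cnc(probe_df(c(100, 50, 200), c(0, 0, 0))),
               "strictly increasing")
})

test_that("planted-segment recovery has at most one-probe boundary error", {
  genome <- Seqinfo(c("chrS1", "chrS2"), c(2e6, 2e6))
  cfg <- sim_config(seed = 3, chrom_lengths = c(chrS1 = 2e6, chrS2 = 2e6),
                    n_cnc = 20, planted_frac = 0)
  sim <- simulate_cnc_features(genome, cfg, probe_noise_sd = 0)
  calls <- call_cnc(sim$probes, 0.5, 5, genome = genome)
  expect_equal(length(calls), length(sim$cnc))
  hits <- findOverlaps(sort(sim$cnc, ignore.strand = TRUE), calls)
  expect_equal(length(hits), length(calls))
  tr <- sort(sim$cnc, ignore.strand = TRUE)
  expect_true(all(abs(start(tr)[queryHits(hits)] -
                        start(calls)[subjectHits(hits)]) <=
                    cfg$probe_spacing_bp))
  expect_true(all(abs(end(tr)[queryHits(hits)] -
                        end(calls)[subjectHits(hits)]) <=
                    cfg$probe_spacing_bp))
})

test_that("CNC summaries match exact counts on toy layouts", {
  genes <- toy_genes(c("a", "b"), "chr1", "+", c(1000, 5000), c(2000, 6000))
  inside <- GRanges("chr1", IRanges(c(1200, 5100), width = 100),
                    cnc_class = c("gain", "loss"))
  s <- summarize_cnc(inside, genes)
  expect_equal(s$genic_fraction_pct, 100)
  expect_equal(s$n_gain, 1L)
  expect_equal(s$n_loss, 1L)
  expect_equal(s$genes_per_call, list("a", "b"))
  outside <- GRanges("chr1", IRanges(3000, 3100), cnc_class = "gain")
  expect_equal(summarize_cnc(outside, genes)$genic_fraction_pct, 0)
  expect_equal(summarize_cnc(outside, genes[0, ])$genic_fraction_pct, 0)
})

test_that("CNC genic fraction matches a pairwise oracle on random layouts", {
  set.seed(17)
  genome <- toy_genome()
  tsspos <- sort(sample(80000, 30))
  genes <- toy_genes(paste0("g", 1:30), "chr1", "+", tsspos, tsspos + 900)
  calls <- random_regions(genome, 40)
  mcols(calls)$cnc_class <- "gain"
  s <- summarize_cnc(calls, genes)
  want <- mean(vapply(seq_along(calls), function(i) {
    as.character(seqnames(calls))[i] == "chr1" &&
      any(genes$tss <= end(calls)[i] & genes$tes >= start(calls)[i])
  }, logical(1)))
  expect_equal(s$genic_fraction_pct, 100 * want)
})

test_that("the DE-gene overlap statistic is a gene count matching brute force", {
  genome <- toy_genome()
  set.seed(19)
  tsspos <- sort(sample(90000, 40))
  all_genes <- toy_genes(paste0("g", 1:40), "chr1", "+", tsspos, tsspos + 800)
  de <- all_genes[1:15, ]
  regions <- random_regions(genome, 20)
  r <- expression_overlap_test(regions, de, all_genes, genome,
                               n_perm = 30, seed = 4)
  want <- sum(vapply(seq_len(nrow(de)), function(i) {
    any(as.character(seqnames(regions)) == de$chrom[i] &
          start(regions) <= de$tes[i] & end(regions) >= de$tss[i])
  }, logical(1)))
  expect_equal(r$statistic, want)
  expect_equal(r$stat_name, "de_gene_count")
  # empty DE set: observed 0
  r0 <- expression_overlap_test(regions, de[0, ], all_genes, genome,
                                n_perm = 10, seed = 4)
  expect_equal(r0$statistic, 0)
  expect_error(expression_overlap_test(
    regions, toy_genes("zz", "chr1", "+", 1, 50), all_genes, genome,
    n_perm = 5, seed = 1), "subset")
})

test_that("regions planted on upregulated genes show expression enrichment", {
  genome <- Seqinfo("chr1", 5e6)
  set.seed(23)
  tsspos <- seq(10000, 4.9e6, by = 50000)
  all_genes <- toy_genes(sprintf("g%03d", seq_along(tsspos)), "chr1", "+",
                         tsspos, tsspos + 5000)
  up <- all_genes[sample(nrow(all_genes), 20), ]
  regions <- GRanges("chr1", IRanges(up$tss[1:15] + 100, width = 2000),
                     seqinfo = genome)
  r <- expression_overlap_test(regions, up, all_genes, genome,
                               n_perm = 300, seed = 8)
  expect_equal(r$direction, "enrichment")
  expect_lt(r$p_empirical, 0.05)
})
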