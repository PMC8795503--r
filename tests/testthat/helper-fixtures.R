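suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(GenomeInfoDb)
  library(Biostrings)
})

# Small two-chromosome layout used across tests.
toy_genome <- function(len1 = 1e5, len2 = 8e4) {
  Seqinfo(c("chr1", "chr2"), c(len1, len2))
}

# Coverage track from explicit per-base value vectors.
toy_track <- function(...) {
  vals <- list(...)
  IRanges::RleList(lapply(vals, Rle), compress = FALSE)
}

# Random region set on a genome layout.
random_regions <- function(genome, n, min_len = 50, max_len = 2000) {
  lens <- seqlengths(genome)
  chr <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
  L <- sample(min_len:max_len, n, replace = TRUE)
  starts <- floor(runif(n) * (lens[chr] - L + 1)) + 1
  GRanges(chr, IRanges(as.integer(starts), width = L), seqinfo = genome)
}

# Per-base membership vector of a region set on one chromosome.
base_membership <- function(gr, chrom, len) {
  v <- logical(len)
  g <- gr[as.character(seqnames(gr)) == chrom]
  for (i in seq_along(g)) v[start(g)[i]:end(g)[i]] <- TRUE
  v
}

# Brute-force kb overlap by per-base boolean AND.
brute_overlap_kb <- function(a, b, genome) {
  lens <- seqlengths(genome)
  bp <- 0
  for (chrom in names(lens)) {
    bp <- bp + sum(base_membership(a, chrom, lens[[chrom]]) &
                     base_membership(b, chrom, lens[[chrom]]))
  }
  bp / 1000
}

# Tiny gene table helper.
toy_genes <- function(gene_id, chrom, strand, tss, tes) {
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             tss = tss, tes = tes)
}

# Exact two-sided Wilcoxon p by direct enumeration over group
# assignments (independent of the package's implementation).
enum_wilcox_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(combn(n, n1), 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}
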