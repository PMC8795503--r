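# Copy-number-change (CNC) calling from aCGH probe log2 ratios. This is a
# deliberately transparent run-threshold caller — maximal runs of
# consecutive probes beyond a symmetric log2 threshold — not a
# reimplementation of any vendor segmentation algorithm: it is exact,
# seedless, and checkable probe-by-probe, which is what the downstream
# enrichment analyses need.

#' Call copy-number changes from a probe log2-ratio table
#'
#' A gain is a maximal run of at least `min_probes` consecutive probes
#' with `log2_ratio >= threshold_log2`; a loss, the same with
#' `<= -threshold_log2`. Each call spans the first to the last probe of
#' its run, so calls never overlap.
#'
#' @param probes probe data.frame (`chrom`, `pos`, `log2_ratio`;
#'   see [validate_probes()]).
#' @param threshold_log2 positive log2-ratio threshold (default 0.5).
#' @param min_probes minimum run length in probes (default 5).
#' @param genome optional `Seqinfo` attached to the calls.
#' @return a `GRanges` with metadata columns `cnc_class`
#'   (`"gain"`/`"loss"`), `mean_log2_ratio` and `n_probes`.
#' @export
call_cnc <- function(probes, threshold_log2 = 0.5, min_probes = 5,
                     genome = NULL) {
  if (threshold_log2 <= 0) stop("threshold_log2 must be > 0")
  if (min_probes < 1) stop("min_probes must be >= 1")
  probes <- validate_probes(probes)
  calls <- lapply(split(probes, probes$chrom), function(pt) {
    state <- ifelse(pt$log2_ratio >= threshold_log2, 1L,
                    ifelse(pt$log2_ratio <= -threshold_log2, -1L, 0L))
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0L & r$lengths >= min_probes
    if (!any(keep)) return(NULL)
    i0 <- starts[keep]; i1 <- ends[keep]
    data.frame(
      chrom = pt$chrom[1L],
      start = pt$pos[i0],
      end = pt$pos[i1],
      cnc_class = ifelse(r$values[keep] > 0L, "gain", "loss"),
      mean_log2_ratio = mapply(function(a, b) mean(pt$log2_ratio[a:b]), i0, i1),
      n_probes = i1 - i0 + 1L)
  })
  calls <- do.call(rbind, calls)
  if (is.null(calls) || nrow(calls) == 0L) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(cnc_class = character(0),
                                      mean_log2_ratio = numeric(0),
                                      n_probes = integer(0))
  } else {
    gr <- GRanges(calls$chrom, IRanges(calls$start, calls$end),
                  cnc_class = calls$cnc_class,
                  mean_log2_ratio = calls$mean_log2_ratio,
                  n_probes = calls$n_probes)
  }
  if (!is.null(genome)) gr <- .with_seqinfo(gr, genome)
  sort(gr, ignore.strand = TRUE)
}

#' Summarize CNC calls against a gene annotation
#'
#' Reports gain/loss counts and the fraction of calls that touch at least
#' one gene body (TSS-TES interval, >= 1 bp overlap) — the "located in
#' regions containing known genes" summary — plus the genes hit by each
#' call.
#'
#' @param calls `GRanges` of CNC calls (with `cnc_class`).
#' @param genes gene-model data.frame.
#' @return a list with `n_gain`, `n_loss`, `genic_fraction_pct` (0-100)
#'   and `genes_per_call` (a list of gene-id character vectors, one per
#'   call).
#' @export
summarize_cnc <- function(calls, genes) {
  bodies <- gene_body_granges(genes)
  hits <- findOverlaps(calls, bodies, ignore.strand = TRUE)
  per_call <- split(names(bodies)[subjectHits(hits)],
                    factor(queryHits(hits), levels = seq_along(calls)))
  genic <- lengths(per_call) > 0L
  list(n_gain = sum(mcols(calls)$cnc_class == "gain"),
       n_loss = sum(mcols(calls)$cnc_class == "loss"),
       genic_fraction_pct = if (length(calls)) 100 * mean(genic) else NA_real_,
       genes_per_call = unname(as.list(per_call)))
}

#' Permutation test of region overlap with a differentially expressed gene set
#'
#' The statistic is the number of `de_genes` whose gene body overlaps the
#' regions by at least 1 bp (a gene count, not kilobases — gene
#' membership is effectively point-like relative to CNC sizes). The null
#' re-places the regions with [randomize_regions()] and recounts.
#'
#' @param regions `GRanges` (e.g. gain or loss CNCs).
#' @param de_genes gene-model data.frame of the differentially expressed
#'   subset (must be a subset of `all_genes` by `gene_id`).
#' @param all_genes gene-model data.frame of the full annotation (used
#'   only to validate the subset relation).
#' @inheritParams permutation_overlap_test
#' @return a `permutation_result` with `stat_name = "de_gene_count"`.
#' @export
expression_overlap_test <- function(regions, de_genes, all_genes, genome,
                                    n_perm = 1000, seed = NULL, mask = NULL,
                                    one_sided = FALSE) {
  if (!all(de_genes$gene_id %in% all_genes$gene_id)) {
    stop("de_genes must be a subset of all_genes")
  }
  regions <- .with_seqinfo(regions, genome)
  de_gr <- gene_body_granges(de_genes, genome)
  observed <- sum(countOverlaps(de_gr, regions, ignore.strand = TRUE) > 0L)

  # per-chromosome gene IRanges for the null recount
  chr_de <- as.character(seqnames(de_gr))
  de_ir <- lapply(split(seq_along(de_gr), chr_de), function(i) {
    IRanges(start(de_gr)[i], end(de_gr)[i])
  })

  if (!is.null(seed)) set.seed(seed)
  space <- .perm_space(genome, mask)
  chr_q <- as.character(seqnames(regions))
  by_chr <- split(width(regions), chr_q)
  null_counts <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    cnt <- 0L
    for (c in names(by_chr)) {
      L <- by_chr[[c]]
      s <- .rand_starts(space[[c]], L, c)
      if (!is.null(de_ir[[c]])) {
        cnt <- cnt + sum(overlapsAny(de_ir[[c]], IRanges(s, width = L)))
      }
    }
    null_counts[p] <- cnt
  }
  .perm_result(observed, null_counts, "de_gene_count", n_perm, seed, one_sided)
}
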