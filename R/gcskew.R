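# GC content and GC skew of genic and promoter-proximal intervals, and
# the quantile stratifications used to relate skew and gene length to
# promoter pausing. Skew is always reported on the transcribed (sense)
# strand, so positive skew means a G-rich non-template strand — the
# orientation that favors R-loop formation behind an elongating
# polymerase.

#' GC skew of a sequence on its sense strand
#'
#' `skew = (G - C) / (G + C)` counted after reverse-complementing
#' minus-strand sequences, so the value always refers to the transcribed
#' strand. `N` bases are ignored; a sequence without any G or C gives
#' `NA` (undefined, flagged by the callers).
#'
#' @param sequence a character string or [Biostrings::DNAString] over
#'   `A`, `C`, `G`, `T`, `N`.
#' @param strand `"+"` (default) or `"-"`.
#' @return skew in `[-1, 1]`, or `NA` when G + C = 0.
#' @export
gc_skew <- function(sequence, strand = "+") {
  s <- if (methods::is(sequence, "DNAString")) sequence else DNAString(sequence)
  if (length(s) == 0L) stop("empty sequence")
  if (strand == "-") s <- reverseComplement(s)
  counts <- letterFrequency(s, c("G", "C"))
  gc <- sum(counts)
  if (gc == 0) return(NA_real_)
  unname((counts[["G"]] - counts[["C"]]) / gc)
}

#' Per-gene GC content and GC skew from a genome sequence
#'
#' Measures each gene either over its full genic interval (TSS to TES)
#' or over the promoter-proximal traveling-ratio window (-30 to +300 bp
#' of the TSS, strand-aware), always on the sense strand.
#'
#' @param genome_seq a [Biostrings::DNAStringSet] named by chromosome.
#' @param genes gene-model data.frame.
#' @param mode `"genic"` (default) or `"promoter_proximal"`.
#' @param upstream,downstream promoter window in bp (used in promoter
#'   mode; defaults 30 and 300).
#' @return data.frame `gene_id`, `gc_content` (fraction of non-N bases),
#'   `gcskew` (`NA` when undefined), `n_fraction`, `flagged` (`TRUE` when
#'   skew is undefined or more than half the bases are N).
#' @export
genic_gcskew <- function(genome_seq, genes, mode = c("genic",
                                                     "promoter_proximal"),
                         upstream = 30L, downstream = 300L) {
  mode <- match.arg(mode)
  genes <- validate_genes(genes)
  miss <- setdiff(genes$chrom, names(genome_seq))
  if (length(miss)) stop("sequence unavailable for chromosome(s): ",
                         paste(unique(miss), collapse = ", "))
  if (mode == "genic") {
    lo <- pmin(genes$tss, genes$tes)
    hi <- pmax(genes$tss, genes$tes)
  } else {
    w <- .gene_windows(genes, upstream, downstream)
    lo <- w$pw_start
    hi <- w$pw_end
  }
  lens <- setNames(Biostrings::width(genome_seq), names(genome_seq))
  if (any(lo < 1L) || any(hi > lens[genes$chrom])) {
    stop("gene interval outside genome sequence bounds")
  }
  out <- data.frame(gene_id = genes$gene_id, gc_content = NA_real_,
                    gcskew = NA_real_, n_fraction = NA_real_,
                    flagged = FALSE)
  for (i in seq_len(nrow(genes))) {
    s <- subseq(genome_seq[[genes$chrom[i]]], lo[i], hi[i])
    if (genes$strand[i] == "-") s <- reverseComplement(s)
    cnt <- letterFrequency(s, c("A", "C", "G", "T"))
    acgt <- sum(cnt)
    out$n_fraction[i] <- 1 - acgt / length(s)
    if (acgt > 0) out$gc_content[i] <- (cnt[["G"]] + cnt[["C"]]) / acgt
    gc <- cnt[["G"]] + cnt[["C"]]
    if (gc > 0) out$gcskew[i] <- (cnt[["G"]] - cnt[["C"]]) / gc
  }
  out$flagged <- is.na(out$gcskew) | out$n_fraction > 0.5
  out
}

#' Stratify genes into GC-skew-high and GC-skew-low groups
#'
#' Thresholds are the empirical 10% and 90% quantiles (type 7, the R
#' default) of the skew distribution over the FULL universe of genes;
#' `low` collects genes with skew at or below the lower quantile, `high`
#' those at or above the upper one. Each group is then intersected with
#' the active-gene set, mirroring how skew classes are restricted to
#' genes with measurable RNAPII signal.
#'
#' @param universe data.frame from [genic_gcskew()] (all genes, not just
#'   active ones); rows with undefined skew are ignored for the
#'   thresholds.
#' @param active_genes character vector of active `gene_id`s (defaults to
#'   the whole universe).
#' @param low_quantile,high_quantile quantile bounds (defaults 0.10 and
#'   0.90; must satisfy `0 < low < high < 1`).
#' @return a list with `high` and `low` gene-id vectors, the numeric
#'   `thresholds`, and `degenerate` (`TRUE` when the two thresholds
#'   coincide, in which case the groups are not meaningful).
#' @export
stratify_by_gcskew <- function(universe, active_genes = universe$gene_id,
                               low_quantile = 0.10, high_quantile = 0.90) {
  if (!(low_quantile > 0 && low_quantile < high_quantile &&
        high_quantile < 1)) {
    stop("need 0 < low_quantile < high_quantile < 1")
  }
  ok <- !is.na(universe$gcskew)
  if (!any(ok)) stop("no defined GC-skew values in the universe")
  qs <- quantile(universe$gcskew[ok], c(low_quantile, high_quantile),
                 names = FALSE)
  degenerate <- qs[1] == qs[2]
  low <- universe$gene_id[ok & universe$gcskew <= qs[1]]
  high <- universe$gene_id[ok & universe$gcskew >= qs[2]]
  list(high = intersect(high, active_genes),
       low = intersect(low, active_genes),
       thresholds = c(low = qs[1], high = qs[2]),
       degenerate = degenerate)
}

#' Stratify genes by length
#'
#' `mode = "threshold"` splits at a fixed length (default 100 kb): short
#' genes are strictly below the threshold, long genes strictly above;
#' genes exactly at the boundary are assigned to `short`. `mode =
#' "quantile"` forms shortest-20%, middle (40-60%), and longest-20%
#' groups from the empirical length distribution (type-7 quantiles,
#' boundaries inclusive).
#'
#' @param genes gene-model data.frame (uses `length_bp`).
#' @param mode `"threshold"` (default) or `"quantile"`.
#' @param threshold_bp length cutoff for threshold mode (default 1e5).
#' @return threshold mode: list with `short` and `long` gene-id vectors;
#'   quantile mode: list with `short`, `medium`, `long`.
#' @export
stratify_by_length <- function(genes, mode = c("threshold", "quantile"),
                               threshold_bp = 1e5) {
  mode <- match.arg(mode)
  genes <- validate_genes(genes)
  len <- genes$length_bp
  if (mode == "threshold") {
    list(short = genes$gene_id[len <= threshold_bp],
         long = genes$gene_id[len > threshold_bp])
  } else {
    qs <- quantile(len, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
    list(short = genes$gene_id[len <= qs[1]],
         medium = genes$gene_id[len >= qs[2] & len <= qs[3]],
         long = genes$gene_id[len >= qs[4]])
  }
}
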