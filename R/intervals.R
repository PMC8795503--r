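#' Merge a region set into minimal disjoint intervals
#'
#' Collapses overlapping or book-ended intervals so that per-base coverage
#' is preserved with the minimal number of intervals. Idempotent. Metadata
#' columns are dropped (merged intervals have no single class).
#'
#' @param gr a `GRanges`; if it carries seqlengths, intervals are
#'   bounds-checked.
#' @return a merged, sorted `GRanges`.
#' @export
merge_intervals <- function(gr) {
  .check_bounds(gr)
  reduce(gr, ignore.strand = TRUE)
}

.check_bounds <- function(gr) {
  lens <- seqlengths(gr)[as.character(seqnames(gr))]
  known <- !is.na(lens)
  if (any(start(gr) < 1L) || any(end(gr)[known] > lens[known])) {
    stop("interval outside chromosome bounds")
  }
  invisible(gr)
}

#' Total overlap between two region sets, in kilobases
#'
#' Both sets are merged internally, so multiply-covered bases count once;
#' the result is symmetric in its arguments.
#'
#' @param query,features `GRanges` on the same genome layout.
#' @return total shared coverage in kb (bp / 1000).
#' @export
overlap_kb <- function(query, features) {
  .check_same_genome(query, features)
  q <- reduce(query, ignore.strand = TRUE)
  f <- reduce(features, ignore.strand = TRUE)
  hits <- findOverlaps(q, f, ignore.strand = TRUE)
  if (length(hits) == 0L) return(0)
  ov <- pintersect(q[queryHits(hits)], f[subjectHits(hits)],
                   ignore.strand = TRUE)
  sum(as.numeric(width(ov))) / 1000
}

.check_same_genome <- function(a, b) {
  la <- seqlengths(a); lb <- seqlengths(b)
  shared <- intersect(names(la)[!is.na(la)], names(lb)[!is.na(lb)])
  if (length(shared) && !identical(la[shared], lb[shared])) {
    stop("region sets are on different genome layouts")
  }
  invisible(NULL)
}

#' Intervals of one replicate confirmed by another, class-aware
#'
#' Returns the intervals of `a` that overlap an interval of `b` carrying
#' the same copy-number class (gain with gain, loss with loss). This is
#' the "common to both experiments" rule used to intersect replicate aCGH
#' runs; the minimum overlap is 1 bp by default.
#'
#' @param a,b `GRanges` with a `cnc_class` metadata column
#'   (`"gain"`/`"loss"`).
#' @param min_overlap_frac minimum fraction of each `a` interval that must
#'   be covered by a single same-class `b` interval (default 0, i.e. any
#'   1-bp overlap qualifies).
#' @return the qualifying subset of `a`.
#' @export
intersect_replicates <- function(a, b, min_overlap_frac = 0) {
  for (gr in list(a, b)) {
    if (is.null(mcols(gr)$cnc_class) || anyNA(mcols(gr)$cnc_class)) {
      stop("both region sets need a complete 'cnc_class' column")
    }
  }
  hits <- findOverlaps(a, b, ignore.strand = TRUE)
  same <- mcols(a)$cnc_class[queryHits(hits)] ==
    mcols(b)$cnc_class[subjectHits(hits)]
  hits <- hits[same]
  if (min_overlap_frac > 0 && length(hits)) {
    ov <- width(pintersect(a[queryHits(hits)], b[subjectHits(hits)],
                           ignore.strand = TRUE))
    hits <- hits[ov / width(a)[queryHits(hits)] >= min_overlap_frac]
  }
  a[sort(unique(queryHits(hits)))]
}

#' Distance from each region to its nearest TSS, in kilobases
#'
#' By default the distance is measured from the region midpoint
#' (`start + floor(width/2)`) to the closest transcription start site on
#' the same chromosome; `mode = "edge"` measures from the nearest region
#' edge instead (0 for a TSS inside the region). Regions on chromosomes
#' without any gene get `NA` rather than 0.
#'
#' @param regions a `GRanges`.
#' @param genes gene-model data.frame (see [validate_genes()]).
#' @param mode `"midpoint"` (default) or `"edge"`.
#' @return numeric vector of distances in kb, one per region, `NA` where
#'   undefined.
#' @export
nearest_tss_distance <- function(regions, genes, mode = c("midpoint", "edge")) {
  mode <- match.arg(mode)
  chr <- as.character(seqnames(regions))
  out <- rep(NA_real_, length(regions))
  for (c in unique(chr)) {
    tss <- sort(genes$tss[genes$chrom == c])
    if (length(tss) == 0L) next
    i <- which(chr == c)
    if (mode == "midpoint") {
      lo <- hi <- start(regions)[i] + width(regions)[i] %/% 2L
    } else {
      lo <- start(regions)[i]; hi <- end(regions)[i]
    }
    # nearest sorted TSS via binary search on both flanks
    d_lo <- .nearest_point_dist(lo, tss)
    d_hi <- .nearest_point_dist(hi, tss)
    d <- pmin(d_lo, d_hi)
    if (mode == "edge") d[.any_inside(lo, hi, tss)] <- 0
    out[i] <- d / 1000
  }
  out
}

.nearest_point_dist <- function(x, sorted) {
  j <- findInterval(x, sorted)
  left <- ifelse(j >= 1L, abs(x - sorted[pmax(j, 1L)]), Inf)
  right <- ifelse(j < length(sorted), abs(sorted[pmin(j + 1L, length(sorted))] - x), Inf)
  pmin(left, right)
}

.any_inside <- function(lo, hi, sorted) {
  findInterval(hi, sorted) - findInterval(lo - 1L, sorted) > 0L
}

#' Number of gene TSSs associated with each region
#'
#' Counts genes whose TSS lies within the region extended by `window_bp`
#' on both sides. This is a deliberately simple window rule standing in
#' for regulatory-domain assignment tools such as GREAT; it is not
#' expected to reproduce their gene counts.
#'
#' @param regions a `GRanges`.
#' @param genes gene-model data.frame.
#' @param window_bp nonnegative extension in bp (default 0).
#' @return integer vector of gene counts, one per region.
#' @export
genes_per_region <- function(regions, genes, window_bp = 0) {
  if (window_bp < 0) stop("window_bp must be >= 0")
  if (nrow(genes) == 0L) return(integer(length(regions)))
  ext <- GRanges(seqnames(regions),
                 IRanges(pmax(start(regions) - window_bp, 1L),
                         end(regions) + window_bp))
  tss <- GRanges(genes$chrom, IRanges(genes$tss, width = 1L))
  countOverlaps(ext, tss, ignore.strand = TRUE)
}
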