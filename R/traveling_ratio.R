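# RNAPII traveling-ratio (pausing-index) statistics from coverage tracks.
# A CoverageTrack is an RleList of nonnegative per-base signal, one Rle
# per chromosome (read_bedgraph() builds one from a bedGraph file, so
# interval-resolution files are represented exactly). The traveling ratio
# compares RNAPII density in the promoter-proximal window [-30, +300) bp
# around the TSS, in transcription coordinates, with density over the
# remaining gene body — high TR means promoter-proximal pausing.

#' Mean signal per bp of a coverage track over an interval
#'
#' @param track an `RleList` coverage track.
#' @param chrom chromosome name.
#' @param start,end 1-based closed interval bounds (scalar or vectors of
#'   equal length).
#' @return numeric density (signal per bp), vectorized over intervals.
#' @export
interval_density <- function(track, chrom, start, end) {
  if (any(end < start)) stop("zero- or negative-length interval")
  v <- track[[chrom]]
  if (is.null(v)) stop("no coverage for chromosome ", chrom)
  if (any(start < 1L) || any(end > length(v))) {
    stop("interval outside the coverage extent of ", chrom)
  }
  as.numeric(viewSums(Views(v, start = start, end = end))) / (end - start + 1)
}

# Strand-aware promoter and body windows (1-based closed genomic coords).
# Offsets are in transcription coordinates: promoter covers offsets
# [-upstream, downstream) around the TSS, body covers [downstream, L).
.gene_windows <- function(genes, upstream = 30L, downstream = 300L) {
  plus <- genes$strand == "+"
  pw_start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream + 1L)
  pw_end   <- ifelse(plus, genes$tss + downstream - 1L, genes$tss + upstream)
  bd_start <- ifelse(plus, genes$tss + downstream, genes$tes)
  bd_end   <- ifelse(plus, genes$tes, genes$tss - downstream)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             pw_start = as.integer(pw_start), pw_end = as.integer(pw_end),
             bd_start = as.integer(bd_start), bd_end = as.integer(bd_end))
}

#' Per-gene traveling ratios from a coverage track
#'
#' For each gene, computes the RNAPII density over the promoter-proximal
#' window (default -30 to +300 bp of the TSS, strand-aware) and over the
#' remaining gene body (from +300 bp to the TES), and their ratio
#' `tr = (promoter + pseudocount) / (body + pseudocount)`. Genes whose
#' body would be empty (TES within the promoter window), whose windows
#' fall outside the coverage extent, or whose body density is zero at
#' `pseudocount = 0` are excluded with a reason rather than silently
#' dropped.
#'
#' @param track an `RleList` coverage track (e.g. RNAPII ChIP).
#' @param genes gene-model data.frame.
#' @param pseudocount nonnegative density added to both numerator and
#'   denominator (default 0: zero-density genes are excluded instead).
#' @param upstream,downstream promoter window in bp around the TSS
#'   (defaults 30 and 300).
#' @return a data.frame with `gene_id`, `promoter_density`,
#'   `body_density`, `tr`, `excluded`, `reason`.
#' @export
traveling_ratio <- function(track, genes, pseudocount = 0,
                            upstream = 30L, downstream = 300L) {
  genes <- validate_genes(genes)
  w <- .gene_windows(genes, upstream, downstream)
  n <- nrow(w)
  out <- data.frame(gene_id = w$gene_id,
                    promoter_density = NA_real_, body_density = NA_real_,
                    tr = NA_real_, excluded = FALSE, reason = "")
  short <- w$bd_end < w$bd_start
  out$excluded[short] <- TRUE
  out$reason[short] <- "body_shorter_than_promoter_window"
  ext <- vapply(names(track), function(ch) length(track[[ch]]), integer(1))
  oob <- !short & (!(w$chrom %in% names(track)) | w$pw_start < 1L |
                     w$bd_start < 1L |
                     pmax(w$pw_end, w$bd_end) > ext[w$chrom])
  oob[is.na(oob)] <- TRUE
  out$excluded[oob & !short] <- TRUE
  out$reason[oob & !short] <- "window_outside_coverage"
  ok <- !out$excluded
  for (ch in unique(w$chrom[ok])) {
    i <- which(ok & w$chrom == ch)
    out$promoter_density[i] <-
      interval_density(track, ch, w$pw_start[i], w$pw_end[i])
    out$body_density[i] <-
      interval_density(track, ch, w$bd_start[i], w$bd_end[i])
  }
  zero <- ok & (out$body_density + pseudocount) == 0
  out$excluded[zero] <- TRUE
  out$reason[zero] <- "zero_body_density"
  calc <- ok & !zero
  out$tr[calc] <- (out$promoter_density[calc] + pseudocount) /
    (out$body_density[calc] + pseudocount)
  out
}

#' Ratio of traveling ratios (RoTR) between two tracks
#'
#' Joins two [traveling_ratio()] tables by gene and forms
#' `rotr = tr_num / tr_den` for genes where both are defined. The default
#' use is ChIP over matched input within one condition; the same function
#' serves the mutant-over-wild-type mode.
#'
#' @param tr_num,tr_den data.frames from [traveling_ratio()] (e.g. ChIP
#'   and input).
#' @return a data.frame `gene_id`, `tr_num`, `tr_den`, `rotr`, restricted
#'   to genes with both ratios defined.
#' @export
ratio_of_traveling_ratios <- function(tr_num, tr_den) {
  m <- merge(tr_num[!tr_num$excluded & !is.na(tr_num$tr),
                    c("gene_id", "tr")],
             tr_den[!tr_den$excluded & !is.na(tr_den$tr) & tr_den$tr > 0,
                    c("gene_id", "tr")],
             by = "gene_id", suffixes = c("_num", "_den"))
  data.frame(gene_id = m$gene_id, tr_num = m$tr_num, tr_den = m$tr_den,
             rotr = m$tr_num / m$tr_den)
}

#' Call active genes from promoter-proximal RNAPII signal
#'
#' A gene is called active when its promoter-window ChIP density reaches
#' `min_promoter_density` and its ChIP/input promoter enrichment reaches
#' `enrichment_threshold`. This is an explicit stand-in for a "clear
#' RNAPII peak at the promoter" criterion.
#'
#' @param chip,input `RleList` coverage tracks.
#' @param genes gene-model data.frame.
#' @param enrichment_threshold minimum ChIP/input promoter density ratio
#'   (default 2).
#' @param min_promoter_density minimum ChIP promoter density, signal per
#'   bp (default 0.25).
#' @param pseudocount added to the input density in the enrichment ratio
#'   (default 0.01).
#' @inheritParams traveling_ratio
#' @return character vector of active `gene_id`s.
#' @export
call_active_genes <- function(chip, input, genes, enrichment_threshold = 2,
                              min_promoter_density = 0.25, pseudocount = 0.01,
                              upstream = 30L, downstream = 300L) {
  if (enrichment_threshold <= 0 || min_promoter_density <= 0) {
    stop("thresholds must be > 0")
  }
  tc <- traveling_ratio(chip, genes, upstream = upstream,
                        downstream = downstream)
  ti <- traveling_ratio(input, genes, upstream = upstream,
                        downstream = downstream)
  pd_chip <- setNames(tc$promoter_density, tc$gene_id)
  pd_in <- setNames(ti$promoter_density, ti$gene_id)[tc$gene_id]
  ok <- !is.na(pd_chip) & !is.na(pd_in) &
    pd_chip >= min_promoter_density &
    pd_chip / (pd_in + pseudocount) >= enrichment_threshold
  tc$gene_id[ok]
}

# Rebin a numeric vector to k bins by averaging; exact for constants.
.rebin <- function(v, k) {
  n <- length(v)
  edges <- floor(seq_len(k) * n / k)
  lo <- c(1L, edges[-k] + 1L)
  vapply(seq_len(k), function(j) mean(v[lo[j]:edges[j]]), numeric(1))
}

#' Strand-oriented average metagene coverage profile
#'
#' Each gene's coverage from `flank_bp` upstream of the TSS to `flank_bp`
#' downstream of the TES is oriented in the direction of transcription;
#' the body is rescaled to `n_body_bins` bins and each flank to
#' `n_flank_bins`; the profile is the per-bin mean across genes. Genes
#' shorter than `n_body_bins` bp or whose extended window leaves the
#' coverage extent are skipped (their ids are returned).
#'
#' @param track an `RleList` coverage track.
#' @param genes gene-model data.frame (must yield at least one usable gene).
#' @param n_body_bins bins over the gene body (default 60).
#' @param flank_bp flank size in bp (default 2000).
#' @param n_flank_bins bins per flank (default 20).
#' @return a list with `profile` (data.frame `bin`, `region`
#'   (`upstream`/`body`/`downstream`), `mean_signal`), `n_genes`, and
#'   `skipped` gene ids.
#' @export
metagene_profile <- function(track, genes, n_body_bins = 60, flank_bp = 2000,
                             n_flank_bins = 20) {
  genes <- validate_genes(genes)
  if (nrow(genes) == 0L) stop("empty gene list")
  ext <- vapply(names(track), function(ch) length(track[[ch]]), integer(1))
  mats <- list()
  skipped <- character()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lo <- min(g$tss, g$tes) - flank_bp
    hi <- max(g$tss, g$tes) + flank_bp
    if (!(g$chrom %in% names(track)) || lo < 1L || hi > ext[g$chrom] ||
        g$length_bp < n_body_bins) {
      skipped <- c(skipped, g$gene_id)
      next
    }
    v <- as.numeric(Views(track[[g$chrom]], lo, hi)[[1L]])
    if (g$strand == "-") v <- rev(v)
    up <- v[seq_len(flank_bp)]
    body <- v[(flank_bp + 1L):(flank_bp + g$length_bp)]
    down <- v[(flank_bp + g$length_bp + 1L):length(v)]
    mats[[g$gene_id]] <- c(.rebin(up, n_flank_bins), .rebin(body, n_body_bins),
                           .rebin(down, n_flank_bins))
  }
  if (!length(mats)) stop("no usable genes for the metagene profile")
  prof <- colMeans(do.call(rbind, mats))
  region <- rep(c("upstream", "body", "downstream"),
                c(n_flank_bins, n_body_bins, n_flank_bins))
  list(profile = data.frame(bin = seq_along(prof), region = region,
                            mean_signal = prof),
       n_genes = length(mats), skipped = skipped)
}

#' Empirical cumulative curve of a statistic, in percent of genes
#'
#' @param values numeric vector (at least one value).
#' @return data.frame `value`, `percent` — sorted unique values with the
#'   percent of observations less than or equal to each; the final
#'   percent is 100.
#' @export
cumulative_curve <- function(values) {
  if (!length(values)) stop("need at least one value")
  vs <- sort(values)
  pct <- 100 * seq_along(vs) / length(vs)
  keep <- !duplicated(vs, fromLast = TRUE)
  data.frame(value = vs[keep], percent = pct[keep])
}
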