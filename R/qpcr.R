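# ChIP-qPCR and DRIP-qPCR quantification: the 2^-ddCt relative fold,
# percent input, fold enrichment versus the IgG control, and
# normalization to a negative-control region (as with SNRPN in DRIP
# assays). All transforms are exact closed forms of mean Ct values;
# technical replicates are averaged first and flagged when they spread
# more than `max_replicate_range` cycles.

#' Relative fold change by the 2^-ddCt method
#'
#' `ddCt = (ct_target_test - ct_ref_test) - (ct_target_ctrl -
#' ct_ref_ctrl)` and the fold change is `2^-ddCt`.
#'
#' @param ct_target_test,ct_ref_test mean Ct of the target and reference
#'   amplicons in the test sample.
#' @param ct_target_ctrl,ct_ref_ctrl the same in the control sample.
#' @return fold change (1 when ddCt = 0).
#' @export
ddct_fold <- function(ct_target_test, ct_ref_test, ct_target_ctrl,
                      ct_ref_ctrl) {
  args <- c(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(args))) stop("all Ct means must be defined")
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Percent input from IP and input Ct values
#'
#' The input Ct is first adjusted for the fraction of chromatin used as
#' input (an input of 1% is `log2(100)` cycles "ahead" of the total), and
#' the immunoprecipitated DNA is expressed as a percentage of that total:
#' `100 * 2^((ct_input - log2(1/input_fraction)) - ct_ip)`.
#'
#' @param ct_ip mean Ct of the immunoprecipitate.
#' @param ct_input mean Ct of the input aliquot.
#' @param input_fraction fraction of chromatin used as input, in (0, 1]
#'   (default 0.01, i.e. a 1% input).
#' @return percent of input (vectorized).
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction = 0.01) {
  if (any(input_fraction <= 0 | input_fraction > 1)) {
    stop("input_fraction must be in (0, 1]")
  }
  100 * 2^((ct_input - log2(1 / input_fraction)) - ct_ip)
}

#' Fold enrichment of a specific antibody over the IgG control
#'
#' Both signals are percent-input values, so the input fraction cancels.
#' A zero or negative IgG signal gives `NA` (flagged upstream) rather
#' than an infinite ratio.
#'
#' @param percent_specific,percent_igg percent-input signals.
#' @return ratio, `NA` where `percent_igg <= 0`.
#' @export
fold_enrichment_vs_igg <- function(percent_specific, percent_igg) {
  n <- max(length(percent_specific), length(percent_igg))
  num <- rep_len(percent_specific, n)
  den <- rep_len(percent_igg, n)
  ifelse(den > 0, num / den, NA_real_)
}

#' DRIP signal relative to a negative-control region
#'
#' Both values must already be input-normalized (percent input); the
#' result is the target signal divided by the signal at the negative
#' control region within the same sample.
#'
#' @param percent_target,percent_negctrl percent-input signals.
#' @return ratio, `NA` where the negative-control signal is <= 0.
#' @export
drip_relative <- function(percent_target, percent_negctrl) {
  n <- max(length(percent_target), length(percent_negctrl))
  num <- rep_len(percent_target, n)
  den <- rep_len(percent_negctrl, n)
  ifelse(den > 0, num / den, NA_real_)
}

#' Summarize a qPCR Ct table into figure-ready quantities
#'
#' Technical replicates are averaged per (sample, region, antibody);
#' means whose replicate range exceeds `max_replicate_range` cycles are
#' flagged. For each sample and region the function reports percent
#' input for the specific antibody and for IgG, the specific/IgG fold
#' enrichment, and — when `negctrl_region` is given — the DRIP-style
#' value relative to the negative-control region within the same sample.
#'
#' @param ct a validated Ct data.frame (see [read_ct_table()]).
#' @param negctrl_region optional region id used as the within-sample
#'   negative control.
#' @param max_replicate_range flag threshold on the within-triplicate Ct
#'   range, in cycles (default 0.5).
#' @return data.frame with one row per sample x region:
#'   `percent_input_specific`, `percent_input_igg`, `fold_vs_igg`,
#'   `relative_to_negctrl` (NA without a control), `flagged`.
#' @export
summarize_qpcr <- function(ct, negctrl_region = NULL,
                           max_replicate_range = 0.5) {
  ct <- validate_ct_table(ct)
  key <- interaction(ct$sample, ct$region, ct$antibody, drop = TRUE)
  agg <- do.call(rbind, lapply(split(ct, key), function(d) {
    data.frame(sample = d$sample[1L], region = d$region[1L],
               antibody = d$antibody[1L], ct_mean = mean(d$ct),
               ct_range = diff(range(d$ct)),
               input_fraction = d$input_fraction[1L])
  }))
  get1 <- function(s, r, ab, col) {
    v <- agg[[col]][agg$sample == s & agg$region == r & agg$antibody == ab]
    if (length(v)) v[1L] else NA_real_
  }
  combos <- unique(agg[, c("sample", "region")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    s <- combos$sample[i]; r <- combos$region[i]
    ct_in <- get1(s, r, "input", "ct_mean")
    frac <- get1(s, r, "input", "input_fraction")
    ct_sp <- get1(s, r, "specific", "ct_mean")
    ct_igg <- get1(s, r, "IgG", "ct_mean")
    psp <- if (is.na(ct_sp) || is.na(ct_in)) NA_real_ else
      percent_input(ct_sp, ct_in, frac)
    pig <- if (is.na(ct_igg) || is.na(ct_in)) NA_real_ else
      percent_input(ct_igg, ct_in, frac)
    rng <- max(agg$ct_range[agg$sample == s & agg$region == r])
    data.frame(sample = s, region = r,
               percent_input_specific = psp, percent_input_igg = pig,
               fold_vs_igg = fold_enrichment_vs_igg(psp, pig),
               relative_to_negctrl = NA_real_,
               flagged = rng > max_replicate_range)
  }))
  if (!is.null(negctrl_region)) {
    for (s in unique(out$sample)) {
      neg <- out$percent_input_specific[out$sample == s &
                                          out$region == negctrl_region]
      if (length(neg) == 1L && !is.na(neg)) {
        i <- out$sample == s
        out$relative_to_negctrl[i] <-
          drip_relative(out$percent_input_specific[i], neg)
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Mean and standard error across biological replicates
#'
#' Summarizes per-experiment ratio estimates the way qPCR panels are
#' reported: mean plus or minus SEM of independent experiments.
#'
#' @param values numeric vector, one value per independent experiment.
#' @return list with `mean`, `sem` (`NA` for a single experiment), `n`.
#' @export
replicate_sem <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  list(mean = mean(values),
       sem = if (n > 1L) sd(values) / sqrt(n) else NA_real_,
       n = n)
}
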