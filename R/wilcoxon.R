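# Two-sided Wilcoxon rank-sum (Mann-Whitney) comparison used for all TR /
# RoTR distribution contrasts. Small samples (both n <= 8) are handled by
# exact enumeration of every assignment of the pooled values to the two
# groups, which stays correct in the presence of ties — the situation in
# which the classical exact null distribution does not apply. Larger
# samples use the tie-corrected normal approximation with mid-ranks.

#' Wilcoxon rank-sum comparison of two samples
#'
#' Computes the Mann-Whitney U statistic for sample `a` and a two-sided
#' p-value: by full enumeration of all `choose(n1 + n2, n1)` group
#' assignments when both samples have at most `exact_max` observations
#' (ties included), otherwise by the normal approximation with mid-ranks
#' and the tie-corrected variance (no continuity correction). When every
#' pooled value is identical the p-value is 1.
#'
#' @param a,b numeric vectors, each with at least one value.
#' @param exact_max largest per-sample size at which the exact
#'   enumeration is used (default 8).
#' @return a list with `statistic` (U for sample `a`), `p_value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
compare_distributions <- function(a, b, exact_max = 8) {
  if (!length(a) || !length(b)) stop("both samples need >= 1 value")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    sets <- combn(n, n1)
    usum <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(usum <= u_obs + eps),
                        mean(usum >= u_obs - eps)))
    return(list(statistic = u_obs, p_value = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(list(statistic = u_obs, p_value = 1, method = "normal"))
  z <- (u_obs - mu) / sqrt(v)
  list(statistic = u_obs, p_value = 2 * pnorm(-abs(z)), method = "normal")
}
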