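# Exact Wilcoxon signed-rank test ------------------------------------------------

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of paired differences. Zero differences are dropped
#' (Wilcoxon's rule) and tied absolute differences receive mid-ranks. For
#' `n <= 25` remaining pairs the p-value is exact, computed by enumerating
#' the full signed-rank distribution (dynamic programming over doubled ranks,
#' which are integers even under mid-ranking); above that a normal
#' approximation with continuity and tie correction is used.
#'
#' @param acc_a,acc_b numeric vectors of equal length (e.g. per-subject
#'   accuracies of two classifiers), paired by position.
#' @return list with `statistic` (V = sum of ranks of positive differences),
#'   `p_value`, `n_effective`, `method`.
#' @export
wilcoxon_signed_rank <- function(acc_a, acc_b) {
  stopifnot(length(acc_a) == length(acc_b))
  if (length(acc_a) < 6) stop("need at least 6 pairs", call. = FALSE)
  d <- acc_a - acc_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero; test is degenerate", call. = FALSE)
  r <- rank(abs(d)) # mid-ranks for ties
  v <- sum(r[d > 0])
  if (n <= 25) {
    # doubled ranks are integers even with .5 mid-ranks
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    # counts[w + 1] = number of sign patterns with doubled statistic w
    counts <- numeric(tot + 1)
    counts[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(tot + 1 - ri)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    v2 <- as.integer(round(2 * v))
    p_le <- sum(probs[seq_len(v2 + 1)])
    p_ge <- sum(probs[seq(v2 + 1, tot + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = v, p_value = p, n_effective = n, method = method)
}
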