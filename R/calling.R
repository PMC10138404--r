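#' Q score of a base call
#'
#' `Q = 10 * log10(p / (1 - p))` where `p` is the probability that the base
#' was called correctly.  A filter at Q >= 20 therefore keeps only calls that
#' are correct with probability at least 100/101 (> 99%).
#'
#' @param p_correct Probability of a correct call, strictly in (0, 1).
#' @return Q score (real).
#' @export
q_score <- function(p_correct) {
  if (any(p_correct <= 0 | p_correct >= 1))
    stop("p_correct must be strictly between 0 and 1")
  10 * log10(p_correct / (1 - p_correct))
}

#' Invert a Q score to a correct-call probability
#'
#' @param q Q score.
#' @return `10^(q/10) / (1 + 10^(q/10))`.
#' @export
invert_q <- function(q) {
  r <- 10^(q / 10)
  r / (1 + r)
}

#' Estimate the empirical false-positive rate from non-CG methylation
#'
#' In vertebrate genomes essentially all true methylation is CG, so apparent
#' methylation at CHG/CHH sites measures the combined error rate (incomplete
#' bisulfite conversion plus miscalls).  The rate is the pooled fraction of
#' methylated reads over all covered non-CG cytosines:
#' `rate = (n_mCHH + n_mCHG) / n_depth`.
#'
#' @param calls A calls `data.frame` (one sample).
#' @return List of class `gm_fp_rate` with `n_mCHG, n_mCHH, n_depth, rate`.
#' @export
estimate_false_positive_rate <- function(calls) {
  chg <- calls$context == "CHG"
  chh <- calls$context == "CHH"
  n_depth <- sum(calls$depth[chg | chh])
  if (n_depth == 0)
    stop("no covered non-CG sites: false-positive rate undefined")
  fp <- list(n_mCHG = sum(calls$meth_count[chg]),
             n_mCHH = sum(calls$meth_count[chh]),
             n_depth = n_depth)
  fp$rate <- (fp$n_mCHG + fp$n_mCHH) / fp$n_depth
  class(fp) <- "gm_fp_rate"
  fp
}

#' @export
print.gm_fp_rate <- function(x, ...) {
  cat(sprintf("non-CG false-positive rate: %.4f%% (%d methylated / %d reads)\n",
              100 * x$rate, x$n_mCHG + x$n_mCHH, x$n_depth))
  invisible(x)
}

#' Upper-tail binomial p-value for a methylation call
#'
#' `P(X >= meth_count)` for `X ~ Binomial(depth, rate)`: the probability of
#' seeing at least the observed number of methylated reads if the site were
#' unmethylated and all apparent methylation came from the error background.
#'
#' @param meth_count,depth Observed methylated reads and total reads.
#' @param rate Background (false-positive) rate.
#' @return p-value(s), vectorised.
#' @export
binomial_tail_p <- function(meth_count, depth, rate) {
  pbinom(meth_count - 1, depth, rate, lower.tail = FALSE)
}

#' Call methylcytosines by the binomial test
#'
#' For each covered cytosine, tests whether the methylated-read count exceeds
#' what the empirical false-positive background explains, at significance
#' `alpha` (99% confidence by default).  Sites with fewer than `min_depth`
#' reads are excluded from all downstream statistics regardless of p-value.
#' If the call table carries a `q` column (per-site base-call Q score), sites
#' with `q < min_q` are filtered out first.
#'
#' @param calls A calls `data.frame` (one sample).
#' @param fp A `gm_fp_rate` from [estimate_false_positive_rate()], or a bare
#'   rate in (0, 1).
#' @param alpha Per-site significance threshold (default 0.01).
#' @param min_depth Minimum read depth for inclusion (default 4).
#' @param min_q Q-score filter applied when a `q` column is present.
#' @return The calls with added columns `p_value`, `pass_depth`, `is_mc`
#'   (class `gm_mc_calls`).
#' @export
call_mc <- function(calls, fp, alpha = 0.01, min_depth = 4, min_q = 20) {
  rate <- if (inherits(fp, "gm_fp_rate")) fp$rate else fp
  if (!is.numeric(rate) || rate <= 0 || rate >= 1)
    stop("false-positive rate must be strictly between 0 and 1")
  if ("q" %in% names(calls)) calls <- calls[calls$q >= min_q, , drop = FALSE]
  calls$p_value <- binomial_tail_p(calls$meth_count, calls$depth, rate)
  calls$pass_depth <- calls$depth >= min_depth
  calls$is_mc <- calls$pass_depth & calls$p_value < alpha
  class(calls) <- c("gm_mc_calls", "data.frame")
  calls
}

#' @export
print.gm_mc_calls <- function(x, ...) {
  cat(sprintf("%d cytosine calls (%d pass depth filter, %d called mC)\n",
              nrow(x), sum(x$pass_depth), sum(x$is_mc)))
  invisible(x)
}
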