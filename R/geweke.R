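#' Conditional Geweke index of causality in the time domain
#'
#' Tests whether channel `source` has a direct influence on channel `target`
#' given `conditioning`, under a linear autoregressive model truncated at lag
#' `p`. Two nested regressions of the target's present on the past are
#' compared: the full one includes the past of all three channels, the
#' reduced one omits the source. The index is the log-ratio of their
#' residual variances,
#' \deqn{F_{Y \to X | Z} = \ln(\Sigma'_{xx} / \Sigma_{xx}),}
#' and `(N - p) F` is asymptotically chi-square with `p` degrees of freedom
#' (the number of excluded lag coefficients) under the no-causality null.
#'
#' Channels are mean-centered; regressions are per-equation ordinary least
#' squares without intercept.
#'
#' @param ts Numeric matrix, channels in rows (3 x N).
#' @param target,source,conditioning Distinct channel indices in 1..3.
#' @param p Lag order (10 for MAR-generated data, 3 for the LIF network data).
#' @param cp Optional precomputed [lagged_crossprods()] object for `ts`
#'   (internal reuse).
#' @return A `geweke_result`: list with `F`, `sigma_full`, `sigma_reduced`,
#'   `df`, `n_obs`, `scaled_stat`, `p_value`.
#' @export
geweke_index <- function(ts, target, source, conditioning, p, cp = NULL) {
  idx <- c(target, source, conditioning)
  if (anyDuplicated(idx) || !all(idx %in% 1:3))
    stop("target, source and conditioning must be distinct channels in 1..3", call. = FALSE)
  if (is.null(cp)) cp <- lagged_crossprods(ts, p)
  full <- normal_solve(cp, lag_cols(sort(c(target, source, conditioning)), p), target)
  red  <- normal_solve(cp, lag_cols(sort(c(target, conditioning)), p), target)
  n <- cp$n
  sigma_full <- full$rss / n
  sigma_red  <- red$rss / n
  if (sigma_full <= 0)
    stop("zero full-model residual variance: Geweke statistic undefined", call. = FALSE)
  F <- log(sigma_red / sigma_full)
  scaled <- n * F
  structure(list(F = F, sigma_full = sigma_full, sigma_reduced = sigma_red,
                 df = p, n_obs = n, scaled_stat = scaled,
                 p_value = stats::pchisq(scaled, df = p, lower.tail = FALSE),
                 degenerate = full$degenerate || red$degenerate),
            class = "geweke_result")
}

#' @export
print.geweke_result <- function(x, ...) {
  cat(sprintf("<geweke_result> F = %.6g  scaled = %.6g  df = %d  p = %.4g\n",
              x$F, x$scaled_stat, x$df, x$p_value))
  invisible(x)
}

#' Per-edge Granger causality scores for one example (GCA baseline)
#'
#' Computes the conditional Geweke index for each of the 6 ordered channel
#' pairs (conditioning on the remaining channel) and converts each p-value
#' into an edge score `1 - p`, monotone in the evidence for causality and
#' bounded in \[0, 1\] so scores pool across examples for ROC analysis.
#'
#' @param ts Numeric 3 x N matrix.
#' @param p Lag order.
#' @return Data frame with one row per ordered pair in [edge_order()] order:
#'   `from`, `to`, `F`, `p_value`, `score`, `df`, `n_obs`.
#' @export
gca_edge_scores <- function(ts, p) {
  cp <- lagged_crossprods(ts, p)
  eo <- edge_order(3L)
  rows <- lapply(seq_len(nrow(eo)), function(k) {
    from <- eo[k, "from"]; to <- eo[k, "to"]
    cond <- setdiff(1:3, c(from, to))
    g <- geweke_index(ts, target = to, source = from, conditioning = cond, p = p, cp = cp)
    data.frame(from = from, to = to, F = g$F, p_value = g$p_value,
               score = 1 - g$p_value, df = g$df, n_obs = g$n_obs)
  })
  do.call(rbind, rows)
}
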