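#' Trial-averaged cross-correlogram of a channel pair
#'
#' Per example, both channels are mean-centered and their normalized
#' cross-correlation is computed over lags `-max_lag .. +max_lag`; the
#' correlograms are then averaged across examples. Sign convention: for the
#' pair `(X, Y)` a *positive* lag means Y lags (follows) X, so a causal
#' X -> Y transmission with latency d peaks at `+d` ms.
#'
#' @param dataset An `ec_dataset` (all examples share a sampling interval).
#' @param pair Length-2 integer vector of channel indices, e.g. `c(1, 2)`
#'   for (X, Y).
#' @param max_lag Maximal lag, ms.
#' @param normalization `"coefficient"` (Pearson correlation per lag, values
#'   in \[-1, 1\]) or `"raw"` (mean product of the centered series).
#' @return A `cross_correlogram`: list with `lags` (ms), `mean_values`,
#'   `sd_values`, `pair`, `n_examples`, `normalization`.
#' @export
cross_correlogram <- function(dataset, pair, max_lag = 50,
                              normalization = c("coefficient", "raw")) {
  normalization <- match.arg(normalization)
  if (length(dataset$examples) == 0) stop("empty dataset", call. = FALSE)
  dt <- dataset$examples[[1]]$sampling_interval
  if (is.null(dt)) dt <- 1
  L <- round(max_lag / dt)
  lags <- (-L):L
  vals <- vapply(dataset$examples, function(e)
    xcorr_pair(e$ts[pair[1], ], e$ts[pair[2], ], L, normalization),
    numeric(2 * L + 1))
  vals <- matrix(vals, nrow = 2 * L + 1)
  structure(list(lags = lags * dt,
                 mean_values = rowMeans(vals),
                 sd_values = apply(vals, 1, stats::sd),
                 pair = pair, n_examples = length(dataset$examples),
                 normalization = normalization),
            class = "cross_correlogram")
}

# cross-correlation of centered x, y at lag k (samples): cor(x[t], y[t+k])
xcorr_pair <- function(x, y, L, normalization) {
  x <- x - mean(x); y <- y - mean(y)
  N <- length(x)
  denom <- if (normalization == "coefficient")
    sqrt(sum(x^2) * sum(y^2)) else N
  if (denom == 0) return(rep(0, 2 * L + 1))
  vapply((-L):L, function(k) {
    if (k >= 0) sum(x[1:(N - k)] * y[(1 + k):N]) / denom
    else sum(x[(1 - k):N] * y[1:(N + k)]) / denom
  }, 0)
}

#' @export
print.cross_correlogram <- function(x, ...) {
  cat("<cross_correlogram> pair", paste(x$pair, collapse = "-"), "over",
      x$n_examples, "examples; peak at", peak_lag(x), "ms\n")
  invisible(x)
}

#' Lag of the correlogram peak
#'
#' @param correlogram A `cross_correlogram`.
#' @return Lag (ms) of the maximum mean value; ties broken toward the
#'   smallest absolute lag. A flat correlogram triggers a warning and
#'   returns 0.
#' @export
peak_lag <- function(correlogram) {
  v <- correlogram$mean_values
  if (diff(range(v)) == 0) {
    warning("flat correlogram: degenerate peak")
    return(0)
  }
  cand <- which(v == max(v))
  correlogram$lags[cand[which.min(abs(correlogram$lags[cand]))]]
}

#' Geweke p-value distribution across a dataset
#'
#' Computes the conditional Geweke p-value of a directed channel pair for
#' every example (optionally restricted to one configuration), and tests
#' the sample against Uniform(0, 1) with a Kolmogorov-Smirnov test. Under
#' no causal link the distribution should be uniform; under a true link it
#' piles up at small p.
#'
#' @param dataset An `ec_dataset`.
#' @param pair `c(from, to)` channel indices; the remaining channel
#'   conditions.
#' @param p Lag order for the autoregressions.
#' @param config_filter Optional 0-based class index; only matching
#'   examples are used.
#' @param n_bins Bins for the log10(p) histogram.
#' @return A `pvalue_summary`: `p_values`, `ks_stat`, `ks_p`,
#'   `log_histogram`, `pair`, `n_failed`.
#' @export
pvalue_distribution <- function(dataset, pair, p, config_filter = NULL,
                                n_bins = 20L) {
  ex <- dataset$examples
  if (!is.null(config_filter))
    ex <- Filter(function(e) e$config$class_index == config_filter, ex)
  if (length(ex) == 0) stop("no examples after filtering", call. = FALSE)
  cond <- setdiff(1:3, pair)
  n_failed <- 0L
  pv <- vapply(ex, function(e) {
    out <- tryCatch(
      geweke_index(e$ts, target = pair[2], source = pair[1],
                   conditioning = cond, p = p)$p_value,
      error = function(err) NA_real_)
    out
  }, 0)
  n_failed <- sum(is.na(pv))
  pv <- pv[!is.na(pv)]
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  lp <- log10(pmax(pv, 1e-300))
  h <- graphics::hist(lp, breaks = n_bins, plot = FALSE)
  structure(list(p_values = pv, ks_stat = unname(ks$statistic),
                 ks_p = ks$p.value,
                 log_histogram = list(mids = h$mids, counts = h$counts),
                 pair = pair, n_failed = n_failed),
            class = "pvalue_summary")
}

#' @export
print.pvalue_summary <- function(x, ...) {
  cat(sprintf("<pvalue_summary> pair %d->%d, n = %d, KS = %.3f (p = %.3g)\n",
              x$pair[1], x$pair[2], length(x$p_values), x$ks_stat, x$ks_p))
  invisible(x)
}

#' Export a correlogram to CSV
#'
#' @param correlogram A `cross_correlogram`.
#' @param path Output file.
#' @export
write_correlogram_csv <- function(correlogram, path) {
  utils::write.csv(data.frame(lag_ms = correlogram$lags,
                              mean = correlogram$mean_values,
                              sd = correlogram$sd_values),
                   path, row.names = FALSE)
  invisible(path)
}
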