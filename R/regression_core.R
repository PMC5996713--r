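# Shared least-squares machinery for the Geweke index and the causality
# feature space. Both modules must produce identical residual variances on
# identical inputs, so they go through this single code path.

# Precompute the cross-products of the lagged design for a centered
# M x N timeseries at lag order p. Columns are channel-major: channel m
# occupies columns (m-1)*p + (1..p), lag 1 first.
lagged_crossprods <- function(ts, p) {
  stopifnot(is.matrix(ts), p >= 1)
  M <- nrow(ts); N <- ncol(ts)
  if (N <= 3 * p + 1)
    stop("timeseries too short (N = ", N, ") for lag order p = ", p, call. = FALSE)
  ts <- ts - rowMeans(ts)
  n <- N - p
  X <- matrix(0, n, M * p)
  for (m in seq_len(M)) for (l in seq_len(p))
    X[, (m - 1L) * p + l] <- ts[m, (p + 1L - l):(N - l)]
  Y <- t(ts[, (p + 1L):N, drop = FALSE])
  list(M = M, p = p, n = n,
       XtX = crossprod(X), XtY = crossprod(X, Y), yty = colSums(Y^2))
}

# Column indices of the lag block for a set of channels.
lag_cols <- function(channels, p) {
  p <- as.integer(p)
  as.vector(vapply(as.integer(channels), function(m) (m - 1L) * p + seq_len(p),
                   integer(p)))
}

# Solve the normal equations on a column subset; minimum-norm via SVD when
# rank-deficient. Returns rss (guarded at 0) and a degeneracy flag.
normal_solve <- function(cp, cols, target) {
  G <- cp$XtX[cols, cols, drop = FALSE]
  g <- cp$XtY[cols, target]
  sv <- svd(G)
  tol <- max(dim(G)) * max(sv$d, 0) * .Machine$double.eps
  pos <- sv$d > tol
  degenerate <- any(!pos)
  dinv <- ifelse(pos, 1 / sv$d, 0)
  b <- sv$v %*% (dinv * crossprod(sv$u, g))
  rss <- cp$yty[target] - 2 * sum(b * g) + sum(b * (G %*% b))
  list(coef = drop(b), rss = max(rss, 0), degenerate = degenerate)
}

# In-sample mean squared error and R^2 of regressing `target` on the past of
# `causes` (all channels centered; no intercept).
scenario_fit_cp <- function(cp, target, causes) {
  fit <- normal_solve(cp, lag_cols(causes, cp$p), target)
  mse <- fit$rss / cp$n
  tss <- cp$yty[target]
  r2 <- if (tss > 0) 1 - fit$rss / tss else 0
  list(mse = mse, r2 = r2, degenerate = fit$degenerate)
}
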