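#' Parameters of the MAR signal/noise generator
#'
#' The generated observable is the mixture `X = (1 - gamma) * Xs + gamma * Xn`
#' of two independent stationary order-`p` multivariate autoregressions with
#' diagonal standard-normal innovations: `Xs` carries the causal structure
#' (its lag-coefficient support is restricted to the generating
#' configuration plus the diagonal), `Xn` is a diagonal noise process.
#'
#' @param p Model order (maximal time lag), default 10.
#' @param gamma Noise mixing weight in \[0, 1\], default 0.25.
#' @param coeff_low,coeff_high Bounds of the uniform corruption applied to
#'   the nonzero entries of the configuration matrix (signs are random);
#'   draws with absolute value below `coeff_min` are redrawn.
#' @param coeff_min Minimal absolute coefficient magnitude, default 0.1.
#' @param an_scale Magnitude bound for the diagonal noise-model
#'   coefficients, default 0.5.
#' @param stability_margin Maximum allowed companion-matrix spectral radius
#'   (< 1), default 0.9.
#' @param max_attempts Rejection-sampling budget for stationarity.
#' @return List of class `mar_params`.
#' @export
mar_params <- function(p = 10L, gamma = 0.25, coeff_low = -0.6, coeff_high = 0.6,
                       coeff_min = 0.1, an_scale = 0.5, stability_margin = 0.9,
                       max_attempts = 50L) {
  stopifnot(p >= 1, gamma >= 0, gamma <= 1, stability_margin < 1,
            coeff_low <= coeff_high)
  structure(list(p = as.integer(p), gamma = gamma, coeff_low = coeff_low,
                 coeff_high = coeff_high, coeff_min = coeff_min,
                 an_scale = an_scale, stability_margin = stability_margin,
                 max_attempts = as.integer(max_attempts)),
            class = "mar_params")
}

# Spectral radius of the companion matrix of lag matrices B(1..p), where the
# recursion is X(t) = sum_tau B[[tau]] %*% X(t - tau) + eps(t).
companion_spectral_radius <- function(B) {
  p <- length(B); M <- nrow(B[[1]])
  C <- matrix(0, M * p, M * p)
  for (tau in seq_len(p)) C[seq_len(M), (tau - 1) * M + seq_len(M)] <- B[[tau]]
  if (p > 1) C[(M + 1):(M * p), seq_len(M * (p - 1))] <- diag(M * (p - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

draw_signal_lags <- function(config, params) {
  M <- config$M; p <- params$p
  support <- config$A == 1 | diag(M) == 1
  lapply(seq_len(p), function(tau) {
    A <- matrix(0, M, M)
    k <- sum(support)
    draws <- numeric(k)
    for (i in seq_len(k)) {
      repeat {
        v <- stats::runif(1, params$coeff_low, params$coeff_high)
        if (abs(v) >= params$coeff_min) break
      }
      draws[i] <- v
    }
    A[support] <- draws
    A
  })
}

#' Sample MAR coefficients encoding a causal configuration
#'
#' Signal lag matrices `As(tau)` have support restricted to the nonzero
#' entries of the configuration plus the diagonal (an autoregression needs
#' own-past terms); entries are uniform draws per [mar_params()]. Noise lag
#' matrices `An(tau)` are diagonal uniform draws. Both processes are
#' rejection-sampled for stationarity; a draw whose companion spectral
#' radius exceeds the margin is shrunk geometrically per lag
#' (`As(tau) <- s^tau As(tau)`, which scales the companion eigenvalues by
#' `s`) onto a radius drawn uniformly in \[0.4, margin\] — at order 10 an
#' unshrunk draw is essentially never stationary, so pure rejection would
#' not terminate.
#'
#' @param config A `causal_config`.
#' @param params A `mar_params`.
#' @param seed Optional integer seed.
#' @return List of class `mar_coefficients` with `As`, `An` (lists of
#'   `p` M x M matrices), `p`, and the achieved spectral radii.
#' @export
sample_mar_coefficients <- function(config, params = mar_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stabilize <- function(B) {
    for (attempt in seq_len(params$max_attempts)) {
      rho <- companion_spectral_radius(B)
      if (rho <= params$stability_margin && rho > 0) return(list(B = B, rho = rho))
      if (rho > 0) {
        target <- stats::runif(1, 0.4, params$stability_margin)
        s <- target / rho
        B <- lapply(seq_along(B), function(tau) B[[tau]] * s^tau)
      }
    }
    stop("stationarity not achieved after ", params$max_attempts, " attempts",
         call. = FALSE)
  }
  As <- stabilize(draw_signal_lags(config, params))
  M <- config$M
  An_raw <- lapply(seq_len(params$p), function(tau)
    diag(stats::runif(M, -params$an_scale, params$an_scale), M))
  An <- stabilize(An_raw)
  structure(list(As = As$B, An = An$B, p = params$p,
                 rho_signal = As$rho, rho_noise = An$rho),
            class = "mar_coefficients")
}

# One stationary MAR path: X(t) = sum_tau B[[tau]]^T X(t - tau) + eps, eps
# diagonal standard normal; burn-in dropped.
mar_recursion <- function(B, M, N, burn) {
  p <- length(B)
  total <- N + burn
  Bt <- lapply(B, t)
  X <- matrix(0, M, total)
  eps <- matrix(stats::rnorm(M * total), M, total)
  X[, seq_len(p)] <- eps[, seq_len(p)]
  for (t in (p + 1):total) {
    acc <- eps[, t]
    for (tau in seq_len(p)) acc <- acc + Bt[[tau]] %*% X[, t - tau]
    X[, t] <- acc
  }
  X[, (burn + 1):total, drop = FALSE]
}

#' Generate one MAR example
#'
#' Simulates the signal and noise recursions with independent standard
#' normal innovations, discards a burn-in of `10 * p` steps, and mixes them
#' as `X = (1 - gamma) Xs + gamma Xn`.
#'
#' @param config A `causal_config`.
#' @param params A `mar_params`.
#' @param N Number of timepoints (default 6000).
#' @param seed Optional integer seed.
#' @param coefficients Optional pre-sampled `mar_coefficients` (fresh ones
#'   are drawn when `NULL`).
#' @return An `ec_example`: list with `ts` (M x N), `config`, `components`
#'   (`xs`, `xn`), and `meta`.
#' @export
mar_generate <- function(config, params = mar_params(), N = 6000L, seed = NULL,
                         coefficients = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (N <= params$p) stop("`N` must exceed the model order", call. = FALSE)
  if (is.null(coefficients)) coefficients <- sample_mar_coefficients(config, params)
  burn <- 10L * params$p
  xs <- mar_recursion(coefficients$As, config$M, N, burn)
  xn <- mar_recursion(coefficients$An, config$M, N, burn)
  ts <- (1 - params$gamma) * xs + params$gamma * xn
  if (any(!is.finite(ts))) stop("non-finite values in generated MAR series", call. = FALSE)
  structure(list(ts = ts, config = config, components = list(xs = xs, xn = xn),
                 meta = list(generator = "MAR", p = params$p, gamma = params$gamma,
                             seed = seed, rho_signal = coefficients$rho_signal,
                             rho_noise = coefficients$rho_noise)),
            class = "ec_example")
}

#' Generate a balanced MAR dataset
#'
#' `n_per_config` examples for every configuration of the catalog, each with
#' freshly sampled coefficients; per-example seeds are derived from the
#' master seed so generation order (or parallel generation) does not affect
#' any example.
#'
#' @param catalog A `dag_catalog` (M = 3).
#' @param n_per_config Examples per configuration.
#' @param params A `mar_params`.
#' @param N Timepoints per example.
#' @param seed Master seed.
#' @return An `ec_dataset` with `generator = "MAR"`.
#' @export
generate_mar_dataset <- function(catalog, n_per_config, params = mar_params(),
                                 N = 6000L, seed = 1L) {
  examples <- vector("list", length(catalog) * n_per_config)
  k <- 0L
  for (cf in catalog$configurations) for (r in seq_len(n_per_config)) {
    k <- k + 1L
    examples[[k]] <- mar_generate(cf, params, N, seed = derive_seed(seed, k))
    examples[[k]]$components <- NULL  # keep the dataset light
  }
  new_dataset(examples, "MAR", catalog,
              params = list(p = params$p, gamma = params$gamma, N = N, seed = seed))
}

# Deterministic per-example seed derivation (stays within 32-bit range).
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

new_dataset <- function(examples, generator, catalog, params) {
  structure(list(examples = examples, generator = generator,
                 catalog_ordering = catalog$ordering_rule, catalog = catalog,
                 params = params, schema_version = 1L),
            class = "ec_dataset")
}

#' @export
print.ec_dataset <- function(x, ...) {
  cat("<ec_dataset>", length(x$examples), "examples, generator =", x$generator, "\n")
  invisible(x)
}

#' @export
print.ec_example <- function(x, ...) {
  cat("<ec_example>", nrow(x$ts), "x", ncol(x$ts), "timeseries,",
      x$meta$generator, "generator, class", x$config$class_index, "\n")
  invisible(x)
}

#' Class labels of a dataset
#'
#' @param dataset An `ec_dataset`.
#' @return Integer vector of 0-based class indices, one per example.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$examples, function(e) e$config$class_index, 0L)
}
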