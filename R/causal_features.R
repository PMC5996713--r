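#' The seven causality scenarios for one effect channel
#'
#' For each channel taken as the effect, seven candidate cause-sets are
#' scored: the effect alone, each other channel alone, each pair containing
#' the effect, the remaining pair, and all three channels. For the effect
#' `x` and channels ordered x, y, z this is
#' \{x\}, \{y\}, \{z\}, \{x,y\}, \{x,z\}, \{y,z\}, \{x,y,z\}.
#'
#' @param M Number of channels; only `M = 3` is supported.
#' @return List of 21 scenarios, effect-major; each a list with `effect`
#'   (channel index) and `causes` (sorted channel indices).
#' @export
scenario_list <- function(M = 3L) {
  if (M != 3L) stop("only M = 3 causality scenarios are supported", call. = FALSE)
  out <- list()
  for (e in 1:3) {
    o <- setdiff(1:3, e)
    sets <- list(e, o[1], o[2], sort(c(e, o[1])), sort(c(e, o[2])), o, 1:3)
    for (s in sets) out[[length(out) + 1L]] <- list(effect = e, causes = s)
  }
  out
}

#' Goodness of fit of one causality scenario
#'
#' Ordinary least-squares regression (no intercept, channels mean-centered)
#' of the effect channel at time t on the `p` most recent past values of
#' every cause channel, over all usable timesteps.
#'
#' @param ts Numeric 3 x N matrix.
#' @param scenario A scenario from [scenario_list()], or a list with
#'   `effect` and `causes`.
#' @param p Lag order.
#' @return List with in-sample `mse`, `r2` and a `degenerate` flag (set when
#'   the design is rank-deficient and the minimum-norm solution was used).
#' @export
fit_scenario <- function(ts, scenario, p) {
  cp <- lagged_crossprods(ts, p)
  scenario_fit_cp(cp, scenario$effect, scenario$causes)
}

#' Conditional Granger causality index score
#'
#' In-sample analogue of the Geweke index: log-ratio of the residual
#' variance of the regression omitting `source` over the full three-channel
#' regression for `effect`. Shares the estimator with [geweke_index()], so
#' the two agree exactly on identical inputs.
#'
#' @param ts Numeric 3 x N matrix.
#' @param effect,source,conditioning Distinct channel indices.
#' @param p Lag order.
#' @param cap Scores are clipped at `+/- cap` (guards against a zero
#'   residual variance in degenerate inputs).
#' @return The gci score (a non-negative log variance ratio, up to numerical
#'   tolerance).
#' @export
conditional_gci <- function(ts, effect, source, conditioning, p, cap = 1e6) {
  g <- geweke_index(ts, target = effect, source = source,
                    conditioning = conditioning, p = p)
  max(min(g$F, cap), -cap)
}

# gci source/conditioning assignments, effect-major: for each effect, each
# non-effect channel as source (ascending), the remaining one conditioning.
gci_slots <- function() {
  out <- list()
  for (e in 1:3) {
    o <- setdiff(1:3, e)
    out[[length(out) + 1L]] <- list(effect = e, source = o[1], conditioning = o[2])
    out[[length(out) + 1L]] <- list(effect = e, source = o[2], conditioning = o[1])
  }
  out
}

base_feature_values <- function(cp) {
  scen <- scenario_list(3L)
  fits <- lapply(scen, function(s) scenario_fit_cp(cp, s$effect, s$causes))
  mse <- vapply(fits, `[[`, 0, "mse")
  r2 <- vapply(fits, `[[`, 0, "r2")
  gci <- vapply(gci_slots(), function(sl) {
    full <- normal_solve(cp, lag_cols(1:3, cp$p), sl$effect)
    red <- normal_solve(cp, lag_cols(sort(c(sl$effect, sl$conditioning)), cp$p), sl$effect)
    sf <- full$rss / cp$n; sr <- red$rss / cp$n
    if (sf <= 0) return(1e6 * (sr > 0))
    max(min(log(sr / sf), 1e6), -1e6)
  }, 0)
  list(mse = mse, r2 = r2, gci = gci)
}

#' Encode a 3-channel timeseries into the 627-feature causality vector
#'
#' Base block (48 values): for each effect channel, the in-sample mean
#' squared error (21) and coefficient of determination (21) of the seven
#' causality scenarios of [scenario_list()], plus the six conditional
#' Granger-index scores. Feature engineering: the square root of the
#' absolute value, the square and the cube of every base feature (144), and
#' all pairwise products within each score family (210 mse + 210 R^2 +
#' 15 gci = 435). Total 48 + 144 + 435 = 627.
#'
#' @param ts Numeric 3 x N matrix.
#' @param p Lag order (10 for MAR data, 3 for LIF network data).
#' @return Named numeric vector of length 627, ordered per [feature_layout()].
#' @export
encode_features <- function(ts, p) {
  cp <- lagged_crossprods(ts, p)
  b <- base_feature_values(cp)
  base <- c(b$mse, b$r2, b$gci)
  powers <- c(sqrt(abs(base)), base^2, base^3)
  prods <- c(pair_products(b$mse), pair_products(b$r2), pair_products(b$gci))
  v <- c(base, powers, prods)
  names(v) <- feature_layout()$name
  if (any(!is.finite(v)))
    stop("non-finite feature values produced; degenerate input?", call. = FALSE)
  v
}

#' Base causality scores only (no feature engineering)
#'
#' The 48 raw score values: 21 scenario mean-squared errors, 21 scenario
#' coefficients of determination, and 6 conditional Granger-index scores.
#'
#' @param ts Numeric 3 x N matrix.
#' @param p Lag order.
#' @return Named numeric vector of length 48.
#' @export
encode_base_features <- function(ts, p) {
  cp <- lagged_crossprods(ts, p)
  b <- base_feature_values(cp)
  v <- c(b$mse, b$r2, b$gci)
  names(v) <- feature_layout()$name[1:48]
  v
}

pair_products <- function(x) {
  k <- length(x)
  out <- numeric(k * (k - 1) / 2)
  idx <- 1L
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    out[idx] <- x[i] * x[j]; idx <- idx + 1L
  }
  out
}

#' Layout of the 627-dimensional feature vector
#'
#' @return Data frame with columns `index`, `family` (`mse`, `r2`, `gci`,
#'   their power transforms, and within-family products), and `name`.
#' @export
feature_layout <- function() {
  chan <- c("x", "y", "z")
  scen <- scenario_list(3L)
  scen_name <- vapply(scen, function(s)
    paste0(paste(chan[s$causes], collapse = ""), ">", chan[s$effect]), "")
  gci_name <- vapply(gci_slots(), function(sl)
    paste0(chan[sl$source], ">", chan[sl$effect], "|", chan[sl$conditioning]), "")
  base_names <- c(paste0("mse_", scen_name), paste0("r2_", scen_name),
                  paste0("gci_", gci_name))
  base_family <- rep(c("mse", "r2", "gci"), c(21, 21, 6))
  pw <- function(tag) paste0(tag, "_", base_names)
  prod_names <- function(nm, tag) {
    k <- length(nm); out <- character(k * (k - 1) / 2); idx <- 1L
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      out[idx] <- paste0(tag, "_", i, "x", j); idx <- idx + 1L
    }
    out
  }
  name <- c(base_names, pw("sqrt"), pw("sq"), pw("cube"),
            prod_names(base_names[1:21], "prod_mse"),
            prod_names(base_names[22:42], "prod_r2"),
            prod_names(base_names[43:48], "prod_gci"))
  family <- c(base_family, paste0("sqrt_", base_family), paste0("sq_", base_family),
              paste0("cube_", base_family),
              rep(c("prod_mse", "prod_r2", "prod_gci"), c(210, 210, 15)))
  data.frame(index = seq_along(name), family = family, name = name)
}
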