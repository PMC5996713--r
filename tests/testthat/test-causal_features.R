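test_that("scenario table matches the 7 cause-sets per effect", {
  sc <- scenario_list(3)
  expect_length(sc, 21)
  x_rows <- Filter(function(s) s$effect == 1, sc)
  expect_equal(lapply(x_rows, `[[`, "causes"),
               list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L), 1:3),
               ignore_attr = TRUE)
  expect_equal(x_rows[[4]]$causes, c(1L, 2L))  # scenario 4 for x: causes {x, y}
  expect_error(scenario_list(4), "M = 3")
})

test_that("fit_scenario matches a brute-force lm oracle and the AR(1) closed form", {
  set.seed(12)
  ts <- matrix(rnorm(3 * 500), 3)
  p <- 4
  for (scen in list(list(effect = 1, causes = 2L), list(effect = 2, causes = c(1L, 3L)),
                    list(effect = 3, causes = 1:3))) {
    got <- fit_scenario(ts, scen, p)
    # oracle: explicit lagged design + lm without intercept on centered data
    tc <- ts - rowMeans(ts)
    N <- ncol(tc)
    X <- do.call(cbind, lapply(scen$causes, function(m)
      sapply(1:p, function(l) tc[m, (p + 1 - l):(N - l)])))
    y <- tc[scen$effect, (p + 1):N]
    fit <- lm.fit(X, y)
    expect_rel_equal(got$mse, mean(fit$residuals^2), 1e-10)
    expect_rel_equal(got$r2, 1 - sum(fit$residuals^2) / sum(y^2), 1e-10)
  }
  # AR(1) with a = 0.9: R^2 -> 0.81 at large N
  set.seed(13)
  n <- 30000
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), n))
  tsa <- rbind(x, matrix(rnorm(2 * n), 2))
  got <- fit_scenario(tsa, list(effect = 1, causes = 1L), p = 1)
  expect_rel_equal(got$r2, 0.81, 0.03)
})

test_that("mse nesting monotonicity holds on arbitrary inputs", {
  set.seed(21)
  for (rep in 1:5) {
    ts <- matrix(rnorm(3 * 300), 3)
    m1 <- fit_scenario(ts, list(effect = 1, causes = 1L), 3)$mse
    m2 <- fit_scenario(ts, list(effect = 1, causes = c(1L, 2L)), 3)$mse
    m3 <- fit_scenario(ts, list(effect = 1, causes = 1:3), 3)$mse
    expect_gte(m1, m2 - 1e-12)
    expect_gte(m2, m3 - 1e-12)
  }
})

test_that("conditional_gci equals the geweke F on identical inputs", {
  set.seed(33)
  ts <- matrix(rnorm(3 * 700), 3)
  for (p in c(3, 10)) {
    slots <- effconn:::gci_slots()
    for (sl in slots) {
      gci <- conditional_gci(ts, sl$effect, sl$source, sl$conditioning, p)
      F <- geweke_index(ts, sl$effect, sl$source, sl$conditioning, p)$F
      expect_lt(abs(gci - F), 1e-8 * max(abs(F), 1))
    }
  }
})

test_that("encode_features has the documented 627-dimensional structure", {
  lay <- feature_layout()
  expect_equal(nrow(lay), 627)
  expect_equal(sum(lay$family %in% c("mse", "r2", "gci")), 48)
  expect_equal(as.integer(table(lay$family)[c("mse", "r2", "gci")]), c(21L, 21L, 6L))
  expect_equal(sum(grepl("^prod_", lay$family)), 435)
  expect_equal(sum(startsWith(lay$family, "sqrt_")) +
               sum(startsWith(lay$family, "sq_")) +
               sum(startsWith(lay$family, "cube_")), 144)
  expect_equal(choose(21, 2) + choose(21, 2) + choose(6, 2), 435)

  set.seed(44)
  ts <- matrix(rnorm(3 * 400), 3)
  v <- encode_features(ts, 3)
  expect_length(v, 627)
  expect_true(all(is.finite(v)))
  expect_identical(v, encode_features(ts, 3))
  # engineered blocks are consistent with the base block
  base <- v[1:48]
  expect_equal(unname(v[49:96]), unname(sqrt(abs(base))))
  expect_equal(unname(v[97:144]), unname(base^2))
  expect_equal(unname(v[145:192]), unname(base^3))
  expect_equal(unname(v[193]), unname(base[1] * base[2]))
})

test_that("base features are equivariant under channel relabeling", {
  set.seed(55)
  ts <- matrix(rnorm(3 * 350), 3)
  perm <- c(2, 3, 1)    # new channel m is old channel perm[m]
  v1 <- encode_features(ts, 3)
  v2 <- encode_features(ts[perm, ], 3)
  lay <- feature_layout()
  # map scenario labels of the permuted encoding back to original channels
  relabel <- function(nm) {
    chars <- strsplit(nm, "")[[1]]
    paste(vapply(chars, function(ch) {
      i <- match(ch, c("x", "y", "z"))
      if (is.na(i)) ch else c("x", "y", "z")[perm[i]]
    }, ""), collapse = "")
  }
  norm_name <- function(nm) {
    # sort cause letters so "yx>z" == "xy>z"; leave gci names positional
    parts <- strsplit(nm, ">", fixed = TRUE)[[1]]
    paste0(paste(sort(strsplit(parts[1], "")[[1]]), collapse = ""), ">", parts[2])
  }
  for (fam in c("mse", "r2")) {
    i1 <- which(lay$family == fam)
    n1 <- vapply(sub(paste0(fam, "_"), "", lay$name[i1]), norm_name, "")
    n2 <- vapply(sub(paste0(fam, "_"), "", lay$name[i1]), function(nm)
      norm_name(relabel(nm)), "")
    expect_equal(unname(v2[i1][match(n1, n2)]), unname(v1[i1]), tolerance = 1e-10)
  }
})
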