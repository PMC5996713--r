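make_gaussian_problem <- function(n_per_class, n_classes = 25, d = 40, sep = 6,
                                  seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(n_classes * d, sd = sep), n_classes, d)
  labels <- rep(0:(n_classes - 1), each = n_per_class)
  feats <- centers[labels + 1, ] + matrix(rnorm(length(labels) * d),
                                          length(labels), d)
  list(features = feats, labels = labels)
}

test_that("classifier separates well-separated Gaussian classes", {
  pr <- make_gaussian_problem(16, seed = 1)
  is_test <- (seq_along(pr$labels) - 1) %% 16 >= 12   # 12 train / 4 test per class
  model <- train_classifier(pr$features[!is_test, ], pr$labels[!is_test], seed = 3)
  post <- predict_posterior(model, pr$features[is_test, ])
  pred <- model$classes[max.col(post)]
  expect_gt(mean(pred == pr$labels[is_test]), 0.95)
  expect_equal(rowSums(post), rep(1, nrow(post)), tolerance = 1e-9)
})

test_that("repeated single example per class is memorized; permuted labels give chance", {
  pr <- make_gaussian_problem(1, seed = 4)
  # one distinct example per class, each repeated twice in training
  reps <- rbind(pr$features, pr$features)
  rlab <- c(pr$labels, pr$labels)
  model <- train_classifier(reps, rlab, lambda = 1, seed = 1)
  post <- predict_posterior(model, pr$features)
  expect_equal(model$classes[max.col(post)], pr$labels)
  pr2 <- make_gaussian_problem(16, seed = 5)
  is_test <- (seq_along(pr2$labels) - 1) %% 16 >= 12
  set.seed(6)
  perm_labels <- pr2$labels
  perm_labels[!is_test] <- sample(perm_labels[!is_test])
  model2 <- train_classifier(pr2$features[!is_test, ], perm_labels[!is_test], seed = 7)
  post2 <- predict_posterior(model2, pr2$features[is_test, ])
  acc <- mean(model2$classes[max.col(post2)] == pr2$labels[is_test])
  expect_lt(acc, 0.15)  # chance is 1/25
})

test_that("posterior edge scores marginalize the catalog correctly", {
  cat3 <- fix_catalog()
  post_empty <- numeric(25); post_empty[1] <- 1   # class 0 is the empty DAG
  expect_equal(as.vector(posterior_edge_scores(post_empty, cat3)), rep(0, 6))
  chain <- named_config("chain", cat3)
  post_chain <- numeric(25); post_chain[chain$class_index + 1] <- 1
  sc <- as.vector(posterior_edge_scores(post_chain, cat3))
  eo <- edge_order(3)
  expect_equal(sc, vapply(seq_len(6), function(k)
    as.numeric(chain$A[eo[k, 1], eo[k, 2]]), 0))
  # uniform posterior: score = fraction of the 25 DAGs containing the edge,
  # counted independently here
  uni <- as.vector(posterior_edge_scores(rep(1 / 25, 25), cat3))
  frac <- vapply(seq_len(6), function(k)
    mean(vapply(cat3$configurations, function(cf) cf$A[eo[k, 1], eo[k, 2]] == 1L,
                TRUE)), 0)
  expect_equal(uni, frac, tolerance = 1e-12)
  expect_true(all(uni >= 0 & uni <= 1))
})

test_that("pooled ROC: perfect, random, monotone-invariance, degenerate input", {
  set.seed(11)
  labels <- matrix(rbinom(600, 1, 0.3), ncol = 6)
  perfect <- pooled_roc(labels + 0, labels)
  expect_equal(perfect$auc, 1.0)
  rand <- pooled_roc(matrix(runif(600), ncol = 6), labels)
  expect_lt(abs(rand$auc - 0.5), 0.1)
  scores <- matrix(runif(600), ncol = 6)
  r1 <- pooled_roc(scores, labels)
  r2 <- pooled_roc(sqrt(scores), labels)  # strictly monotone transform
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
  expect_true(all(diff(r1$fpr) >= 0) && all(diff(r1$tpr) >= 0))
  expect_error(pooled_roc(runif(6), rep(1, 6)), "single class")
  withboot <- pooled_roc(scores, labels, n_boot = 50, seed = 2)
  expect_true(is.finite(withboot$auc_ci) && withboot$auc_ci > 0)
})

test_that("tpr_at_fpr interpolates curves as expected", {
  labels <- matrix(rep(c(0, 1), 300), ncol = 6)
  perfect <- pooled_roc(labels + 0, labels)
  expect_equal(tpr_at_fpr(perfect, 0.1), 1.0)
  set.seed(13)
  n <- 20000
  rand <- pooled_roc(runif(n), rbinom(n, 1, 0.5))
  expect_lt(abs(tpr_at_fpr(rand, 0.1) - 0.1), 0.03)
})

test_that("stratified folds are balanced, class-covering, and deterministic", {
  labels <- rep(0:24, each = 2)  # 50 balanced examples
  f <- effconn:::stratified_folds(labels, 5, seed = 1)
  expect_equal(as.integer(table(f)), rep(10L, 5))
  for (k in 1:5)
    expect_setequal(unique(labels[f != k]), 0:24)
  f2 <- effconn:::stratified_folds(labels, 5, seed = 1)
  expect_identical(f, f2)
  expect_error(effconn:::stratified_folds(c(0, 0, 1), 3, seed = 1),
               "stratification")
})

test_that("cross-validated and transfer evaluation run end-to-end on MAR data", {
  cat3 <- fix_catalog()
  fz <- featurize_dataset(fix_mar_mini(), 10)
  expect_equal(dim(fz$features), c(75, 627))
  cv <- crossval_evaluate(fz, cat3, folds = 3, seed = 2, n_boot = 25)
  expect_gt(cv$roc$auc, 0.6)       # causal structure is learnable
  expect_length(cv$fold_auc, 3)
  expect_true(all(cv$scores >= 0 & cv$scores <= 1))
  cv2 <- crossval_evaluate(fz, cat3, folds = 3, seed = 2, n_boot = 25)
  expect_identical(cv$roc$auc, cv2$roc$auc)  # seeded determinism
  tr <- transfer_evaluate(fz, fz, cat3, seed = 2, n_boot = 0)
  expect_gt(tr$roc$auc, cv$roc$auc - 0.05)   # in-sample transfer at least as good
  gca <- gca_evaluate(fix_mar_mini(), p = 10, n_boot = 0)
  expect_gt(gca$roc$auc, 0.55)
})
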