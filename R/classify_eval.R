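#' Featurize every example of a dataset
#'
#' @param dataset An `ec_dataset`.
#' @param p Lag order for the feature encoder (10 for MAR data, 3 for NN
#'   data, matching the generators' temporal structure).
#' @return List with `features` (n x 627 matrix), `labels` (0-based class
#'   indices), `edge_labels` (n x 6 binary matrix in [edge_order()] order),
#'   and `p`.
#' @export
featurize_dataset <- function(dataset, p) {
  n <- length(dataset$examples)
  feats <- matrix(NA_real_, n, 627)
  for (k in seq_len(n))
    feats[k, ] <- encode_features(dataset$examples[[k]]$ts, p)
  colnames(feats) <- feature_layout()$name
  list(features = feats, labels = dataset_labels(dataset),
       edge_labels = edge_label_matrix(dataset), p = p)
}

#' True directed-edge labels of a dataset
#'
#' @param dataset An `ec_dataset`.
#' @return n x 6 binary matrix; column k is edge k of [edge_order()].
#' @export
edge_label_matrix <- function(dataset) {
  eo <- edge_order(3L)
  t(vapply(dataset$examples, function(e)
    vapply(seq_len(nrow(eo)), function(k) e$config$A[eo[k, 1], eo[k, 2]], 0L),
    integer(nrow(eo))))
}

# 25 x 6 containment matrix: entry (c, k) = 1 iff catalog class c contains
# directed edge k of edge_order().
edge_membership <- function(catalog) {
  eo <- edge_order(catalog$M)
  t(vapply(catalog$configurations, function(cf)
    vapply(seq_len(nrow(eo)), function(k) cf$A[eo[k, 1], eo[k, 2]], 0L),
    integer(nrow(eo))))
}

#' Train the 25-class causality classifier
#'
#' Multinomial logistic regression with an L2 (ridge) penalty over the
#' 627-dimensional feature space. Features are standardized with training
#' statistics stored in the model (applied to any later input, so there is
#' no leakage across splits). The penalty strength is selected on the
#' training data by small-fold cross-validated deviance over a fixed grid.
#'
#' @param features n x 627 numeric matrix.
#' @param labels 0-based class indices (up to 25 classes).
#' @param lambda Penalty grid (glmnet's per-observation scale); when it has
#'   more than one value the best is chosen by stratified-holdout
#'   multinomial log-loss on the training data.
#' @param seed Seed controlling the internal holdout split.
#' @param clip Standardized features are winsorized at `+/- clip` standard
#'   deviations (the power and product features have extremely heavy tails
#'   that otherwise stall the optimizer; a purely numerical safeguard).
#' @param holdout_frac Fraction of each class held out for penalty
#'   selection.
#' @return A `causality_classifier`: glmnet fit, chosen lambda,
#'   standardization parameters, and class coding.
#' @export
train_classifier <- function(features, labels, lambda = 10^seq(2, -3, length.out = 11),
                             seed = 1L, clip = 8, holdout_frac = 0.2) {
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2) stop("need at least two classes", call. = FALSE)
  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- clip_features(scale(features, center = ctr, scale = scl), clip)
  y <- factor(labels)
  lambda <- sort(lambda, decreasing = TRUE)
  best <- lambda[1]
  min_class <- min(table(y))
  # penalty selection needs >= 2 training members per class after the holdout
  if (length(lambda) > 1 && min_class >= 3) {
    set.seed(seed)
    hold <- unlist(lapply(split(seq_along(y), y), function(i)
      sample(i, min(length(i) - 2L, max(1, round(length(i) * holdout_frac))))))
    sel_fit <- glmnet::glmnet(xs[-hold, , drop = FALSE], y[-hold],
                              family = "multinomial", alpha = 0, lambda = lambda,
                              standardize = FALSE, maxit = 2e5)
    pr <- stats::predict(sel_fit, xs[hold, , drop = FALSE], type = "response")
    yh <- as.integer(factor(y[hold], levels = levels(y)))
    ll <- apply(pr, 3, function(P)
      -mean(log(pmax(P[cbind(seq_along(hold), yh)], 1e-12))))
    best <- sel_fit$lambda[which.min(ll)]
  }
  fit <- glmnet::glmnet(xs, y, family = "multinomial", alpha = 0, lambda = lambda,
                        standardize = FALSE, maxit = 2e5)
  structure(list(fit = fit, lambda = best, center = ctr, scale = scl,
                 clip = clip, classes = as.integer(levels(y))),
            class = "causality_classifier")
}

clip_features <- function(xs, clip) {
  xs[xs > clip] <- clip
  xs[xs < -clip] <- -clip
  xs
}

#' @export
print.causality_classifier <- function(x, ...) {
  cat("<causality_classifier>", length(x$classes), "classes,",
      length(x$center), "features, lambda =", signif(x$lambda, 3), "\n")
  invisible(x)
}

#' Class posteriors for new examples
#'
#' @param model A `causality_classifier`.
#' @param features n x 627 matrix.
#' @return n x n_classes matrix of posterior probabilities (rows sum to 1),
#'   columns named by 0-based class index.
#' @export
predict_posterior <- function(model, features) {
  xs <- clip_features(scale(features, center = model$center, scale = model$scale),
                      model$clip)
  pr <- stats::predict(model$fit, newx = xs, s = model$lambda, type = "response")
  pr <- pr[, , 1, drop = FALSE]
  dim(pr) <- dim(pr)[1:2]
  if (any(!is.finite(pr)))
    stop("non-finite class posteriors (penalty too weak for this data?)",
         call. = FALSE)
  pr <- pr / rowSums(pr)
  colnames(pr) <- model$classes
  pr
}

#' Per-edge scores from class posteriors
#'
#' The score of a directed edge is the total posterior mass of the catalog
#' classes containing that edge -- the marginal probability of the edge
#' under the classifier's posterior over the 25 DAGs.
#'
#' @param posterior n x 25 posterior matrix (columns in catalog order) or a
#'   single posterior vector.
#' @param catalog The `dag_catalog` the classifier was trained against.
#' @return n x 6 matrix of edge scores in \[0, 1\], columns in
#'   [edge_order()] order.
#' @export
posterior_edge_scores <- function(posterior, catalog) {
  if (is.null(dim(posterior))) posterior <- matrix(posterior, 1)
  E <- edge_membership(catalog)
  posterior %*% E
}

#' Pooled per-edge ROC curve with bootstrap AUC interval
#'
#' Every directed edge of every example is one binary detection decision;
#' scores are pooled, the threshold sweeps the unique score values, and the
#' AUC is the trapezoidal integral. The bootstrap resamples examples (not
#' individual edges), respecting the within-example dependence of the six
#' decisions.
#'
#' @param scores n x 6 score matrix (or vector).
#' @param labels n x 6 binary label matrix (or vector) aligned with
#'   `scores`.
#' @param n_boot Bootstrap replicates for the AUC interval (0 disables).
#' @param seed Seed for the bootstrap.
#' @return A `roc_curve`: list with `fpr`, `tpr`, `thresholds`, `auc`,
#'   `auc_ci` (half-width of the central 95% bootstrap interval), and
#'   `n_pooled`.
#' @export
pooled_roc <- function(scores, labels, n_boot = 0L, seed = 1L) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1)
  if (is.null(dim(labels))) labels <- matrix(labels, ncol = 1)
  stopifnot(all(dim(scores) == dim(labels)))
  curve <- roc_points(as.vector(scores), as.vector(labels))
  auc_ci <- NA_real_
  if (n_boot > 0) {
    set.seed(seed)
    n <- nrow(scores)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      roc_auc(as.vector(scores[idx, , drop = FALSE]),
              as.vector(labels[idx, , drop = FALSE]))
    }, 0)
    qs <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
    auc_ci <- (qs[2] - qs[1]) / 2
  }
  structure(c(curve, list(auc_ci = auc_ci, n_pooled = length(scores))),
            class = "roc_curve")
}

# ROC by threshold sweep over unique scores; trapezoidal AUC.
roc_points <- function(s, y) {
  pos <- sum(y == 1); neg <- sum(y == 0)
  if (pos == 0 || neg == 0)
    stop("ROC undefined: pooled labels contain a single class", call. = FALSE)
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; y <- y[ord]
  keep <- c(diff(s) != 0, TRUE)  # last index of each tied block
  tp <- cumsum(y == 1)[keep]
  fp <- cumsum(y == 0)[keep]
  tpr <- c(0, tp / pos); fpr <- c(0, fp / neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, s[keep]), auc = auc)
}

roc_auc <- function(s, y) roc_points(s, y)$auc

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> auc = %.4f%s, %d pooled decisions\n", x$auc,
              if (is.finite(x$auc_ci)) sprintf(" +/- %.4f", x$auc_ci) else "",
              x$n_pooled))
  invisible(x)
}

#' True-positive rate at a target false-positive rate
#'
#' @param curve A `roc_curve`.
#' @param fpr Target false-positive rate in \[0, 1\].
#' @return Linearly interpolated TPR.
#' @export
tpr_at_fpr <- function(curve, fpr) {
  stats::approx(curve$fpr, curve$tpr, xout = fpr, ties = "ordered", rule = 2)$y
}

# Stratified fold assignment with rotating per-class offsets, so folds stay
# balanced even when a class has fewer members than folds; errors if any
# fold would miss a class during training.
stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  assign <- integer(length(labels))
  classes <- sort(unique(labels))
  for (ci in seq_along(classes)) {
    idx <- sample(which(labels == classes[ci]))
    assign[idx] <- ((ci - 1L + seq_along(idx) - 1L) %% folds) + 1L
  }
  for (f in seq_len(folds)) {
    train_classes <- unique(labels[assign != f])
    if (length(setdiff(unique(labels), train_classes)) > 0)
      stop("stratification error: a class is absent from training fold ", f,
           call. = FALSE)
  }
  assign
}

#' Cross-validated pooled-edge evaluation of the supervised method
#'
#' Stratified k-fold split; per fold the classifier is trained on the
#' training portion (standardization included) and produces posterior edge
#' scores on the held-out portion; all held-out edge decisions are pooled
#' into a single ROC.
#'
#' @param featurized Output of [featurize_dataset()].
#' @param catalog The generating `dag_catalog`.
#' @param folds Number of folds (default 5).
#' @param lambda Penalty grid passed to [train_classifier()].
#' @param seed Seed (fold assignment, penalty selection, bootstrap).
#' @param n_boot Bootstrap replicates for the pooled AUC interval.
#' @return List with `roc` (pooled `roc_curve`), `fold_auc`, `scores`,
#'   `edge_labels`, and `fold` assignment.
#' @export
crossval_evaluate <- function(featurized, catalog, folds = 5L,
                              lambda = 10^seq(2, -3, length.out = 11), seed = 1L, n_boot = 200L) {
  labels <- featurized$labels
  fold <- stratified_folds(labels, folds, seed)
  n <- length(labels)
  scores <- matrix(NA_real_, n, 6)
  for (f in seq_len(folds)) {
    tr <- fold != f
    model <- train_classifier(featurized$features[tr, , drop = FALSE], labels[tr],
                              lambda = lambda, seed = seed + f)
    post <- predict_posterior(model, featurized$features[!tr, , drop = FALSE])
    full_post <- expand_posterior(post, model$classes, length(catalog))
    scores[!tr, ] <- posterior_edge_scores(full_post, catalog)
  }
  roc <- pooled_roc(scores, featurized$edge_labels, n_boot = n_boot, seed = seed)
  fold_auc <- vapply(seq_len(folds), function(f)
    roc_auc(as.vector(scores[fold == f, ]),
            as.vector(featurized$edge_labels[fold == f, ])), 0)
  list(roc = roc, fold_auc = fold_auc, scores = scores,
       edge_labels = featurized$edge_labels, fold = fold)
}

# Posterior columns cover the classes seen in training; re-embed into the
# full catalog width (absent classes get mass 0).
expand_posterior <- function(post, classes, n_classes) {
  full <- matrix(0, nrow(post), n_classes)
  full[, classes + 1L] <- post
  full
}

#' Train-on-A / test-on-B transfer evaluation
#'
#' Trains on one generator's featurized dataset and scores another's. The
#' two generators emit features on wildly different numeric scales (LFP
#' proxies are sums of currents over hundreds of cells, MAR series are
#' unit-variance), so by default the test features are standardized with
#' their own population statistics -- a label-free domain adaptation
#' without which a linear model trained on one scale is meaningless on the
#' other. Disable with `adapt_scale = FALSE`.
#'
#' @param featurized_train,featurized_test Outputs of [featurize_dataset()]
#'   (each with its dataset-appropriate lag order).
#' @param catalog Shared `dag_catalog`.
#' @param lambda,seed,n_boot As in [crossval_evaluate()].
#' @param adapt_scale Standardize test features by test-population
#'   statistics (default `TRUE`).
#' @return List with `roc`, `scores`, `edge_labels`, `model`.
#' @export
transfer_evaluate <- function(featurized_train, featurized_test, catalog,
                              lambda = 10^seq(2, -3, length.out = 11), seed = 1L,
                              n_boot = 200L, adapt_scale = TRUE) {
  model <- train_classifier(featurized_train$features, featurized_train$labels,
                            lambda = lambda, seed = seed)
  pred_model <- model
  if (adapt_scale) {
    pred_model$center <- colMeans(featurized_test$features)
    scl <- apply(featurized_test$features, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    pred_model$scale <- scl
  }
  post <- predict_posterior(pred_model, featurized_test$features)
  full_post <- expand_posterior(post, model$classes, length(catalog))
  scores <- posterior_edge_scores(full_post, catalog)
  roc <- pooled_roc(scores, featurized_test$edge_labels, n_boot = n_boot, seed = seed)
  list(roc = roc, scores = scores, edge_labels = featurized_test$edge_labels,
       model = model)
}

#' GCA baseline evaluation on a dataset
#'
#' Conditional Geweke edge scores (`1 - p`) for every example, pooled into
#' the same per-edge ROC construction used for the supervised method.
#'
#' @param dataset An `ec_dataset`.
#' @param p Lag order.
#' @param n_boot,seed Bootstrap settings for the AUC interval.
#' @return List with `roc`, `scores`, `edge_labels`.
#' @export
gca_evaluate <- function(dataset, p, n_boot = 200L, seed = 1L) {
  n <- length(dataset$examples)
  scores <- matrix(NA_real_, n, 6)
  for (k in seq_len(n))
    scores[k, ] <- gca_edge_scores(dataset$examples[[k]]$ts, p)$score
  labels <- edge_label_matrix(dataset)
  list(roc = pooled_roc(scores, labels, n_boot = n_boot, seed = seed),
       scores = scores, edge_labels = labels)
}
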