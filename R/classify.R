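ND_CLASSES <- c("CO", "AD", "PD", "FTD", "DLB")

#' Model specification for the five-class boosted-tree classifier
#'
#' Hyperparameters of the gradient-boosted tree ensemble: multiclass
#' objective with per-class probability output and multiclass log-loss
#' metric; 300 boosting rounds for CSF models and 400 for plasma; maximum
#' tree depth 20; learning rate 0.05; minimum of 10 samples per leaf;
#' fixed seed 42. The class-label order `(CO, AD, PD, FTD, DLB)` is fixed
#' and serialized with the model; argmax ties break in this order.
#'
#' @param fluid `"csf"` (300 rounds) or `"plasma"` (400 rounds).
#' @param n_rounds,max_depth,learning_rate,min_samples_leaf,seed Override
#'   individual hyperparameters.
#' @return List of class `nd_model_spec`.
#' @export
model_spec <- function(fluid = c("csf", "plasma"),
                       n_rounds = NULL,
                       max_depth = 20,
                       learning_rate = 0.05,
                       min_samples_leaf = 10,
                       seed = 42L) {
  fluid <- match.arg(fluid)
  if (is.null(n_rounds)) n_rounds <- if (fluid == "csf") 300L else 400L
  stopifnot(n_rounds > 0, max_depth > 0, learning_rate > 0,
            min_samples_leaf > 0)
  structure(list(fluid = fluid, n_rounds = as.integer(n_rounds),
                 max_depth = max_depth, learning_rate = learning_rate,
                 min_samples_leaf = min_samples_leaf, seed = as.integer(seed),
                 class_labels = ND_CLASSES),
            class = "nd_model_spec")
}

#' Stratified 70/30 train/test split
#'
#' Splits samples into train and test partitions at `train_fraction` within
#' each class label, preserving class distributions. Deterministic given the
#' seed.
#'
#' @param labels Character vector of class labels.
#' @param train_fraction Fraction per class assigned to training
#'   (default 0.70).
#' @param seed RNG seed.
#' @return List of class `split_plan` with integer index vectors `train`
#'   and `test` (disjoint, exhaustive).
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 42L) {
  set.seed(seed)
  train <- integer(0)
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    if (length(idx) < 4)
      warning("stratified_split: class '", lab, "' has fewer than 4 samples")
    n_train <- round(train_fraction * length(idx))
    train <- c(train, sort(sample(idx, n_train)))
  }
  train <- sort(train)
  structure(list(train = train,
                 test = setdiff(seq_along(labels), train),
                 train_fraction = train_fraction, seed = seed),
            class = "split_plan")
}

# squared euclidean distances between rows of a and rows of b
row_dist2 <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' SMOTE oversampling
#'
#' Synthesizes minority-class samples by interpolation: a random same-class
#' donor and one of its `k` nearest same-class neighbours are combined as
#' `x + u * (neighbour - x)` with `u ~ U(0,1)`, until every class reaches
#' the majority count. Requires a complete (no `NA`) feature matrix.
#'
#' @param x Numeric matrix (samples x features), complete.
#' @param labels Class labels.
#' @param k_neighbors Neighbour count (default 5), automatically reduced to
#'   `class size - 1` for tiny classes (with a warning).
#' @param seed RNG seed.
#' @return List: `x` (original rows then synthetic rows), `labels`,
#'   `synthetic` (logical flag per row).
#' @export
smote <- function(x, labels, k_neighbors = 5, seed = 42L) {
  if (anyNA(x)) stop("smote: feature matrix must be complete")
  set.seed(seed)
  counts <- table(labels)
  if (any(counts < 2)) stop("smote: every class needs at least 2 samples")
  n_max <- max(counts)
  new_x <- list(); new_lab <- character(0)
  for (lab in names(counts)) {
    need <- n_max - counts[[lab]]
    if (need == 0) next
    rows <- which(labels == lab)
    k <- min(k_neighbors, length(rows) - 1)
    if (k < k_neighbors)
      warning("smote: class '", lab, "' too small for k=", k_neighbors,
              "; using k=", k)
    sub <- x[rows, , drop = FALSE]
    d2 <- row_dist2(sub, sub)
    diag(d2) <- Inf
    nn <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
    donors <- sample(length(rows), need, replace = TRUE)
    mates <- nn[cbind(donors, sample(k, need, replace = TRUE))]
    u <- stats::runif(need)
    synth <- sub[donors, , drop = FALSE] +
      u * (sub[mates, , drop = FALSE] - sub[donors, , drop = FALSE])
    new_x[[lab]] <- synth
    new_lab <- c(new_lab, rep(lab, need))
  }
  xx <- rbind(x, do.call(rbind, c(new_x, list(matrix(0, 0, ncol(x))))))
  rownames(xx) <- NULL
  list(x = xx, labels = c(labels, new_lab),
       synthetic = c(rep(FALSE, length(labels)), rep(TRUE, length(new_lab))))
}

#' Tomek links
#'
#' A Tomek link is a pair of mutual nearest neighbours from different
#' classes: ambiguous samples sitting on the decision boundary. Both members
#' of every link are flagged for removal.
#'
#' @param x Complete numeric matrix.
#' @param labels Class labels.
#' @return Integer vector of row indices participating in a link.
#' @export
tomek_links <- function(x, labels) {
  if (nrow(x) < 2) return(integer(0))
  d2 <- row_dist2(x, x)
  diag(d2) <- Inf
  nn <- apply(d2, 1, which.min)
  link <- which(nn[nn] == seq_along(nn) & labels != labels[nn])
  sort(unique(c(link, nn[link])))
}

#' SMOTE + Tomek-link rebalancing of the training set
#'
#' Equalizes class counts with [smote()], then removes every member of a
#' cross-class Tomek link to clean the decision boundary. Applied to
#' training data only; the test partition is never touched. Missing entries
#' are filled with the per-class, per-feature training median *inside this
#' step only* (interpolation needs complete vectors); prediction later
#' passes missing values through natively.
#'
#' @param x Training feature matrix (samples x selected analytes).
#' @param labels Training class labels.
#' @param k_neighbors SMOTE neighbour count.
#' @param seed RNG seed.
#' @param impute Fill missing entries with the class median before SMOTE
#'   (default TRUE).
#' @return List: `x`, `labels`, and class-count bookkeeping
#'   (`counts_before`, `counts_after_smote`, `counts_after`).
#' @export
rebalance_smote_tomek <- function(x, labels, k_neighbors = 5, seed = 42L,
                                  impute = TRUE) {
  if (impute && anyNA(x)) {
    for (lab in unique(labels)) {
      rows <- which(labels == lab)
      sub <- x[rows, , drop = FALSE]
      med <- apply(sub, 2, stats::median, na.rm = TRUE)
      med[is.na(med)] <- 0
      miss <- which(is.na(sub), arr.ind = TRUE)
      if (nrow(miss)) sub[miss] <- med[miss[, 2]]
      x[rows, ] <- sub
    }
  }
  before <- table(labels)
  sm <- smote(x, labels, k_neighbors = k_neighbors, seed = seed)
  after_smote <- table(sm$labels)
  drop <- tomek_links(sm$x, sm$labels)
  keep <- setdiff(seq_len(nrow(sm$x)), drop)
  list(x = sm$x[keep, , drop = FALSE], labels = sm$labels[keep],
       counts_before = before, counts_after_smote = after_smote,
       counts_after = table(sm$labels[keep]))
}

#' Multiclass logarithmic loss
#'
#' `-(1/N) sum_i sum_k y_ik ln p_ik`: the average negative log probability
#' assigned to the true class. A uniform five-class predictor scores
#' `ln 5 ~ 1.609`; a perfect one scores 0.
#'
#' @param truth Character vector of true labels.
#' @param probs Probability matrix with class columns.
#' @param eps Clipping floor for probabilities.
#' @return Nonnegative scalar.
#' @export
multiclass_logloss <- function(truth, probs, eps = 1e-15) {
  stopifnot(all(truth %in% colnames(probs)))
  p <- probs[cbind(seq_along(truth), match(truth, colnames(probs)))]
  -mean(log(pmin(pmax(p, eps), 1)))
}

#' Train the five-class boosted-tree model
#'
#' Fits a gradient-boosted decision-tree ensemble with a multiclass
#' softmax-probability objective under the hyperparameters in
#' [model_spec()]. Sparse missing entries are handled natively by the tree
#' learner (default split directions); a feature column missing in *every*
#' training row is rejected. Training is single-threaded and deterministic
#' given the seed.
#'
#' @param x Training matrix (samples x selected features, fixed column
#'   order).
#' @param labels Training labels among the five classes.
#' @param spec A [model_spec()].
#' @return Object of class `nd_booster`: `booster`, `spec`,
#'   `feature_names`, `class_labels`, `train_logloss`.
#' @export
train_model <- function(x, labels, spec = model_spec()) {
  stopifnot(inherits(spec, "nd_model_spec"))
  if (!all(labels %in% spec$class_labels))
    stop("labels outside the trained classes: ",
         paste(setdiff(labels, spec$class_labels), collapse = ", "))
  all_missing <- colSums(!is.na(x)) == 0
  if (any(all_missing))
    stop("fully missing analytes are not supported: ",
         paste(colnames(x)[all_missing], collapse = ", "))
  y <- match(labels, spec$class_labels) - 1L
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  params <- list(objective = "multi:softprob",
                 num_class = length(spec$class_labels),
                 eval_metric = "mlogloss",
                 max_depth = spec$max_depth,
                 eta = spec$learning_rate,
                 min_child_weight = spec$min_samples_leaf,
                 nthread = 1, seed = spec$seed)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = spec$n_rounds, verbose = 0)
  probs <- stats::predict(booster, dtrain)
  probs <- probs / rowSums(probs)
  colnames(probs) <- spec$class_labels
  structure(list(booster = booster, spec = spec,
                 feature_names = colnames(x),
                 class_labels = spec$class_labels,
                 train_logloss = multiclass_logloss(labels, probs)),
            class = "nd_booster")
}

# align a prediction matrix to the model's stored feature order
align_features <- function(model, x) {
  missing_cols <- setdiff(model$feature_names, colnames(x))
  if (length(missing_cols))
    stop("missing required feature columns: ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(colnames(x), model$feature_names)
  if (length(extra))
    warning("ignoring ", length(extra), " extra feature columns")
  x[, model$feature_names, drop = FALSE]
}

#' Predict class probabilities
#'
#' Returns the per-sample probability vector over the five classes (rows on
#' the unit simplex) and the argmax class, ties broken by class-label order.
#' Missing values pass through the trees natively; no imputation, no
#' retraining.
#'
#' @param model An `nd_booster` (or [nd_fit()] model).
#' @param x Matrix whose columns cover the model's features.
#' @return List: `probs` (n x 5 matrix, columns `CO, AD, PD, FTD, DLB`),
#'   `class` (character vector).
#' @export
predict_probs <- function(model, x) {
  if (inherits(model, "nd_model")) model <- model$fit
  x <- align_features(model, x)
  probs <- stats::predict(model$booster,
                          xgboost::xgb.DMatrix(x, nthread = 1))
  probs <- probs / rowSums(probs)   # exact simplex in double precision
  colnames(probs) <- model$class_labels
  rownames(probs) <- rownames(x)
  cls <- model$class_labels[max.col(probs, ties.method = "first")]
  list(probs = probs, class = cls)
}

#' Zero-shot application to unseen diagnostic groups
#'
#' Scores samples from diagnostic categories outside the five trained
#' classes with the frozen model (no retraining, no imputation) and
#' summarizes each group's probability profile: per-class mean probability
#' with a percentile bootstrap 95% CI, and the fraction of the group
#' assigned (argmax) to each class. Mixed profiles (e.g. a group whose mean
#' p_PD and p_AD both dominate) indicate co-pathology signatures.
#'
#' @param model An `nd_booster` or [nd_fit()] model.
#' @param x Feature matrix for the zero-shot samples.
#' @param group_labels Group label per row of `x`.
#' @param n_boot Bootstrap resamples for the CI (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame of class `zero_shot_summary`: one row per group x
#'   class with `n`, `mean_prob`, `ci_lo`, `ci_hi`, `frac_assigned`.
#' @export
zero_shot_apply <- function(model, x, group_labels, n_boot = 1000,
                            seed = 42L) {
  pr <- predict_probs(model, x)
  set.seed(seed)
  out <- list()
  for (g in unique(group_labels)) {
    rows <- which(group_labels == g)
    if (length(rows) == 0) next
    p <- pr$probs[rows, , drop = FALSE]
    means <- colMeans(p)
    if (length(rows) > 1) {
      boots <- replicate(n_boot, colMeans(
        p[sample(length(rows), replace = TRUE), , drop = FALSE]))
      ci <- apply(boots, 1, stats::quantile, c(0.025, 0.975))
    } else {
      ci <- rbind(means, means)
    }
    assigned <- factor(pr$class[rows], levels = colnames(p))
    out[[g]] <- data.frame(group = g, class = colnames(p),
                           n = length(rows), mean_prob = unname(means),
                           ci_lo = unname(ci[1, ]), ci_hi = unname(ci[2, ]),
                           frac_assigned = as.numeric(table(assigned)) /
                             length(rows),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("zero_shot_summary", "data.frame")
  res
}

#' Fit the five-class neurodegenerative-disease classifier
#'
#' The package's central modelling function. Given a feature matrix of
#' selected, normalized analytes and a diagnostic label per sample, it
#' (1) makes a stratified 70/30 train/test split, (2) rebalances the
#' training partition with SMOTE + Tomek-link removal, (3) trains the
#' gradient-boosted tree ensemble under [model_spec()], and (4) scores the
#' held-out test partition. The test partition is never rebalanced,
#' imputed, or otherwise altered.
#'
#' @param x Numeric matrix, samples x selected analytes (normalized scale).
#' @param labels Diagnostic label per sample, among `CO, AD, PD, FTD, DLB`.
#' @param spec A [model_spec()].
#' @param train_fraction Training fraction for the stratified split.
#' @param rebalance Apply SMOTE + Tomek to the training partition
#'   (default TRUE).
#' @param k_neighbors SMOTE neighbour count.
#' @param split_seed Seed for the split (the model seed lives in `spec`).
#' @return Object of class `nd_model`: `fit` (`nd_booster`), `split`
#'   ([stratified_split()] plan), `rebalance` bookkeeping, `test_probs`,
#'   `test_class`, `test_labels`, `train_logloss`.
#' @seealso [predict.nd_model()], [summary.nd_model()], [zero_shot_apply()]
#' @examples
#' \donttest{
#' cfg <- sim_config(n_per_class = c(CO = 40, AD = 40, PD = 40, FTD = 12,
#'                                   DLB = 12),
#'                   n_analytes = 60, seed = 7)
#' ds <- simulate_study(cfg)
#' norm <- normalize_matrix(ds$rfu)
#' fit <- nd_fit(norm$values, ds$metadata$diagnosis,
#'               spec = model_spec(n_rounds = 50))
#' summary(fit)
#' }
#' @export
nd_fit <- function(x, labels, spec = model_spec(), train_fraction = 0.7,
                   rebalance = TRUE, k_neighbors = 5, split_seed = 42L) {
  stopifnot(is.matrix(x), length(labels) == nrow(x))
  plan <- stratified_split(labels, train_fraction, split_seed)
  x_train <- x[plan$train, , drop = FALSE]
  y_train <- labels[plan$train]
  reb <- NULL
  if (rebalance) {
    reb <- rebalance_smote_tomek(x_train, y_train, k_neighbors = k_neighbors,
                                 seed = spec$seed)
    x_train <- reb$x
    y_train <- reb$labels
  }
  fit <- train_model(x_train, y_train, spec)
  x_test <- x[plan$test, , drop = FALSE]
  pr <- predict_probs(fit, x_test)
  structure(list(fit = fit, spec = spec, split = plan,
                 rebalance = reb[c("counts_before", "counts_after_smote",
                                   "counts_after")],
                 test_probs = pr$probs, test_class = pr$class,
                 test_labels = labels[plan$test],
                 train_logloss = fit$train_logloss),
            class = "nd_model")
}

#' @export
print.nd_model <- function(x, ...) {
  cat("nd_model: five-class boosted-tree classifier\n")
  cat(sprintf("  features: %d analytes; rounds: %d, depth: %d, eta: %g\n",
              length(x$fit$feature_names), x$spec$n_rounds,
              x$spec$max_depth, x$spec$learning_rate))
  cat(sprintf("  train: %d samples (%s rebalanced), test: %d\n",
              length(x$split$train),
              if (is.null(x$rebalance)) "not" else "SMOTE+Tomek",
              length(x$split$test)))
  cat(sprintf("  training log loss: %.4f\n", x$train_logloss))
  invisible(x)
}

#' Predict method for nd_model
#'
#' @param object An [nd_fit()] model.
#' @param newdata Feature matrix; defaults to scoring the held-out test
#'   partition stored in the model.
#' @param ... Unused.
#' @return List with `probs` (simplex rows) and `class` (argmax labels).
#' @export
predict.nd_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(list(probs = object$test_probs, class = object$test_class))
  predict_probs(object$fit, newdata)
}

#' Summarize held-out performance of an nd_model
#'
#' @param object An [nd_fit()] model.
#' @param ... Passed to [multiclass_metrics()].
#' @return A `class_metrics` object for the test partition.
#' @export
summary.nd_model <- function(object, ...) {
  multiclass_metrics(object$test_labels, object$test_probs, ...)
}

#' Plot held-out one-vs-rest ROC curves
#'
#' @param x An [nd_fit()] model.
#' @param ... Passed to [plot()].
#' @return Invisibly, the per-class AUCs.
#' @export
plot.nd_model <- function(x, ...) {
  classes <- intersect(colnames(x$test_probs), unique(x$test_labels))
  cols <- stats::setNames(seq_along(classes) + 1, classes)
  aucs <- numeric(0)
  first <- TRUE
  for (cl in classes) {
    r <- pROC::roc(response = as.numeric(x$test_labels == cl),
                   predictor = x$test_probs[, cl],
                   quiet = TRUE, direction = "<", levels = c(0, 1))
    aucs[cl] <- as.numeric(pROC::auc(r))
    plot(r, add = !first, col = cols[cl], ...)
    first <- FALSE
  }
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC %.2f)", classes, aucs),
                   col = cols, lwd = 2, bty = "n")
  invisible(aucs)
}
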