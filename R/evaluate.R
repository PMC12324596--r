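#' One-vs-rest ROC AUC
#'
#' @param scores Numeric scores (higher = more positive).
#' @param positive Logical or 0/1 vector of true positives.
#' @return AUC in \[0, 1\]; `NA` when only one class is present.
#' @export
auc_roc <- function(scores, positive) {
  positive <- as.numeric(positive)
  if (length(unique(positive)) < 2) return(NA_real_)
  r <- pROC::roc(response = positive, predictor = scores, quiet = TRUE,
                 direction = "<", levels = c(0, 1))
  as.numeric(pROC::auc(r))
}

#' One-vs-rest precision-recall AUC (average precision)
#'
#' Average precision: `sum_k (R_k - R_{k-1}) P_k` over descending score
#' thresholds, the standard step-function summary of the PR curve.
#'
#' @inheritParams auc_roc
#' @return Average precision in \[0, 1\]; `NA` with no positives.
#' @export
auc_pr <- function(scores, positive) {
  positive <- as.numeric(positive)
  n_pos <- sum(positive == 1)
  if (n_pos == 0 || n_pos == length(positive)) return(NA_real_)
  ord <- order(-scores)
  y <- positive[ord]; s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # evaluate only at the last index of each tied score block
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

binary_prf <- function(pred_pos, true_pos) {
  tp <- sum(pred_pos & true_pos)
  precision <- if (sum(pred_pos) == 0) 0 else tp / sum(pred_pos)
  recall <- if (sum(true_pos) == 0) NA_real_ else tp / sum(true_pos)
  f1 <- if (is.na(recall) || precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Multiclass performance metrics
#'
#' Per class: one-vs-rest AUC-ROC and AUC-PR using the class's probability
#' column as the score, and precision/recall/F1 from argmax assignments.
#' Overall: accuracy, balanced accuracy (mean recall over present classes),
#' macro AUC (unweighted mean of per-class AUCs), weighted AUC (weighted by
#' test-set class prevalence), macro F1. Classes absent from `truth` are
#' skipped with a record. Optional percentile bootstrap CIs.
#'
#' @param truth True labels.
#' @param probs Probability matrix with class columns.
#' @param n_boot Bootstrap resamples for 95% CIs on the overall metrics
#'   (0 = none).
#' @param seed Bootstrap seed.
#' @return List of class `class_metrics`: `per_class` (data.frame),
#'   `overall` (named vector), `skipped_classes`, optional `ci`.
#' @export
multiclass_metrics <- function(truth, probs, n_boot = 0, seed = 42L) {
  stopifnot(length(truth) == nrow(probs))
  if (length(unique(truth)) < 2)
    stop("multiclass_metrics: truth contains a single class")
  classes <- colnames(probs)
  present <- classes[classes %in% unique(truth)]
  skipped <- setdiff(classes, present)
  pred <- classes[max.col(probs, ties.method = "first")]

  per_class <- do.call(rbind, lapply(present, function(cl) {
    pos <- truth == cl
    prf <- binary_prf(pred == cl, pos)
    data.frame(class = cl, n = sum(pos),
               auc_roc = auc_roc(probs[, cl], pos),
               auc_pr = auc_pr(probs[, cl], pos),
               precision = prf["precision"], recall = prf["recall"],
               f1 = prf["f1"], row.names = NULL, stringsAsFactors = FALSE)
  }))

  prev <- per_class$n / length(truth)
  overall <- c(accuracy = mean(pred == truth),
               balanced_accuracy = mean(per_class$recall),
               macro_auc = mean(per_class$auc_roc),
               weighted_auc = sum(per_class$auc_roc * prev) / sum(prev),
               macro_f1 = mean(per_class$f1))

  out <- list(per_class = per_class, overall = overall,
              skipped_classes = skipped)
  if (n_boot > 0) {
    set.seed(seed)
    n <- length(truth)
    boot <- replicate(n_boot, {
      idx <- sample(n, replace = TRUE)
      if (length(unique(truth[idx])) < 2) return(c(NA, NA))
      m <- multiclass_metrics(truth[idx], probs[idx, , drop = FALSE])
      m$overall[c("macro_auc", "accuracy")]
    })
    out$ci <- apply(boot, 1, stats::quantile, c(0.025, 0.975), na.rm = TRUE)
    colnames(out$ci) <- c("macro_auc", "accuracy")
  }
  class(out) <- "class_metrics"
  out
}

#' @export
print.class_metrics <- function(x, ...) {
  cat("Held-out multiclass performance\n")
  print(transform(x$per_class,
                  auc_roc = round(auc_roc, 3), auc_pr = round(auc_pr, 3),
                  precision = round(precision, 3),
                  recall = round(recall, 3), f1 = round(f1, 3)),
        row.names = FALSE)
  cat(sprintf("accuracy %.4f | balanced accuracy %.4f | macro AUC %.4f | weighted AUC %.4f | macro F1 %.4f\n",
              x$overall["accuracy"], x$overall["balanced_accuracy"],
              x$overall["macro_auc"], x$overall["weighted_auc"],
              x$overall["macro_f1"]))
  if (length(x$skipped_classes))
    cat("classes absent from truth (skipped):",
        paste(x$skipped_classes, collapse = ", "), "\n")
  invisible(x)
}

#' One-vs-all binarization of the five-class output
#'
#' A sample is predicted positive for the target class iff that class has
#' its highest probability (argmax); every argmax-other sample is negative.
#' The five positive sets therefore partition the samples. For AUC the
#' target-class probability column is the score.
#'
#' @param probs Probability matrix.
#' @param truth True labels.
#' @param target_class The class of interest.
#' @return List: `pred_positive` (logical), `true_positive` (logical),
#'   `metrics` (named vector: auc, accuracy, precision, recall, f1).
#' @export
binarize_one_vs_all <- function(probs, truth, target_class) {
  stopifnot(target_class %in% colnames(probs))
  pred <- colnames(probs)[max.col(probs, ties.method = "first")]
  pred_pos <- pred == target_class
  true_pos <- truth == target_class
  prf <- binary_prf(pred_pos, true_pos)
  metrics <- c(auc = auc_roc(probs[, target_class], true_pos),
               accuracy = mean(pred_pos == true_pos), prf)
  list(pred_positive = pred_pos, true_positive = true_pos, metrics = metrics)
}

#' Benchmark logistic regression on a single biomarker
#'
#' The comparison standard for the proteomic classifier: logistic regression
#' of AD-vs-CO status on age, sex (F = 0, M = 1) and one binary biomarker
#' (negative = 0, positive = 1), on complete cases only, with a stratified
#' 70/30 split and test-set metrics.
#'
#' @param meta data.frame with `diagnosis` (`"CO"`/`"AD"` rows used), `age`,
#'   `sex` (0/1), and the marker column.
#' @param marker Name of the binary marker column (e.g. `"ptau217_status"`).
#' @param seed Split seed.
#' @return List of class `benchmark_logistic`: `model` (the [stats::glm()]
#'   fit), `metrics` (auc, accuracy, balanced_accuracy, macro_f1 on the test
#'   split), `n_train`, `n_test`.
#' @export
benchmark_logistic <- function(meta, marker = "ptau217_status", seed = 42L) {
  stopifnot(marker %in% names(meta))
  df <- meta[meta$diagnosis %in% c("CO", "AD"), ]
  df <- df[stats::complete.cases(df[, c("age", "sex", marker)]), ]
  df$y <- as.numeric(df$diagnosis == "AD")
  df$marker <- as.numeric(df[[marker]])
  if (length(unique(df$marker)) < 2)
    stop("benchmark_logistic: marker is constant")
  plan <- stratified_split(df$diagnosis, 0.7, seed)
  train <- df[plan$train, ]; test <- df[plan$test, ]
  fit <- stats::glm(y ~ age + sex + marker, family = stats::binomial(),
                    data = train, control = list(maxit = 1000))
  p <- stats::predict(fit, newdata = test, type = "response")
  pred <- p > 0.5
  prf_pos <- binary_prf(pred, test$y == 1)
  prf_neg <- binary_prf(!pred, test$y == 0)
  rec_pos <- mean(pred[test$y == 1])
  rec_neg <- mean(!pred[test$y == 0])
  metrics <- c(auc = auc_roc(p, test$y),
               accuracy = mean(pred == (test$y == 1)),
               balanced_accuracy = mean(c(rec_pos, rec_neg)),
               macro_f1 = mean(c(prf_pos["f1"], prf_neg["f1"])))
  structure(list(model = fit, metrics = metrics,
                 n_train = nrow(train), n_test = nrow(test)),
            class = "benchmark_logistic")
}

#' Reclassification cross-tabulation
#'
#' Within each original diagnostic label, cross-tabulates the model's
#' predicted class against a stratifying variable (e.g. AT status or
#' pTau217 status), with missing strata collected in an `"unknown"` column.
#' Used to ask, e.g., whether clinically labelled controls that the model
#' reclassifies as AD are enriched for biomarker positivity.
#'
#' @param original Original labels (may include non-trained labels such as
#'   OT or MCI).
#' @param predicted Predicted classes.
#' @param strata Stratifying variable aligned to samples (`NA` allowed).
#' @return List of class `reclass_crosstab`: per original label, `counts`
#'   (predicted x stratum table) and `row_pct`; plus `total_n`.
#' @export
reclassification_crosstab <- function(original, predicted, strata) {
  stopifnot(length(original) == length(predicted),
            length(original) == length(strata))
  strata <- as.character(strata)
  strata[is.na(strata)] <- "unknown"
  out <- list()
  for (g in unique(original)) {
    rows <- original == g
    tab <- table(predicted = predicted[rows], stratum = strata[rows])
    pct <- prop.table(tab, margin = 1) * 100
    out[[g]] <- list(counts = tab, row_pct = pct)
  }
  structure(list(groups = out, total_n = length(original)),
            class = "reclass_crosstab")
}

#' Concordance between class probabilities and external phenotypes
#'
#' For continuous phenotypes: two-sided Pearson correlation against each
#' probability column. For ordinal phenotypes: rank-sum (Mann-Whitney) test
#' between two groups, or a Kruskal-Wallis omnibus across three or more
#' (with pairwise rank-sum follow-ups when the omnibus p < 0.05), chosen
#' because disease-probability distributions are typically non-normal.
#' Group means with standard errors are tabulated alongside every test.
#'
#' @param probs Probability matrix (columns = classes).
#' @param phenotypes data.frame of phenotype columns, rows aligned to
#'   `probs`.
#' @param types Named character vector mapping each phenotype column to
#'   `"continuous"` or `"ordinal"`.
#' @return data.frame of class `concordance_result`: `phenotype`,
#'   `probability`, `test`, `statistic`, `p`, `estimate` (Pearson r where
#'   applicable), `group_summary` (text `mean +/- SEM` by group). Pairwise
#'   follow-ups are stored in the `"pairwise"` attribute. Phenotypes with
#'   fewer than 3 paired observations are skipped with a record.
#' @export
concordance_stats <- function(probs, phenotypes, types) {
  stopifnot(all(names(phenotypes) %in% names(types)))
  rows <- list()
  pairwise <- list()
  for (ph in names(phenotypes)) {
    v <- phenotypes[[ph]]
    for (cl in colnames(probs)) {
      p_col <- probs[, cl]
      ok <- !is.na(v) & !is.na(p_col)
      if (sum(ok) < 3) {
        rows[[length(rows) + 1]] <- data.frame(
          phenotype = ph, probability = cl, test = "skipped",
          statistic = NA_real_, p = NA_real_, estimate = NA_real_,
          group_summary = "insufficient data", stringsAsFactors = FALSE)
        next
      }
      if (types[[ph]] == "continuous") {
        ct <- stats::cor.test(v[ok], p_col[ok])
        rows[[length(rows) + 1]] <- data.frame(
          phenotype = ph, probability = cl, test = "pearson",
          statistic = unname(ct$statistic), p = ct$p.value,
          estimate = unname(ct$estimate), group_summary = "",
          stringsAsFactors = FALSE)
      } else {
        g <- factor(v[ok])
        sem <- tapply(p_col[ok], g, function(z)
          stats::sd(z) / sqrt(length(z)))
        mu <- tapply(p_col[ok], g, mean)
        summ <- paste(sprintf("%s: %.3f+/-%.3f", levels(g), mu, sem),
                      collapse = "; ")
        if (nlevels(g) < 2) next
        if (nlevels(g) == 2) {
          wt <- stats::wilcox.test(p_col[ok] ~ g)
          rows[[length(rows) + 1]] <- data.frame(
            phenotype = ph, probability = cl, test = "rank_sum",
            statistic = unname(wt$statistic), p = wt$p.value,
            estimate = NA_real_, group_summary = summ,
            stringsAsFactors = FALSE)
        } else {
          kw <- stats::kruskal.test(p_col[ok], g)
          rows[[length(rows) + 1]] <- data.frame(
            phenotype = ph, probability = cl, test = "kruskal_wallis",
            statistic = unname(kw$statistic), p = kw$p.value,
            estimate = NA_real_, group_summary = summ,
            stringsAsFactors = FALSE)
          if (!is.na(kw$p.value) && kw$p.value < 0.05) {
            pw <- stats::pairwise.wilcox.test(p_col[ok], g,
                                              p.adjust.method = "BH")
            pairwise[[paste(ph, cl, sep = ":")]] <- pw$p.value
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pairwise") <- pairwise
  class(out) <- c("concordance_result", "data.frame")
  out
}

#' Welch's t-test of a phenotype between predicted classes
#'
#' For approximately normal phenotypes, compares the phenotype between two
#' predicted-class groups with the unequal-variance t-test.
#'
#' @param phenotype Numeric phenotype vector.
#' @param predicted Predicted class per sample.
#' @param classes Length-2 vector of predicted classes to contrast.
#' @return [stats::t.test()] result (Welch).
#' @export
welch_by_class <- function(phenotype, predicted, classes = c("CO", "AD")) {
  a <- phenotype[predicted == classes[1]]
  b <- phenotype[predicted == classes[2]]
  stats::t.test(a, b, var.equal = FALSE)
}
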