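#' Tree-exact Shapley attributions for the fitted classifier
#'
#' Computes exact per-sample, per-analyte, per-class Shapley values for the
#' tree ensemble (tree-path-dependent expectations, no reference dataset),
#' on the model's margin (pre-softmax) scale, where tree-exact Shapley
#' values are additive. For every sample and class the attributions satisfy
#' the efficiency identity: sum over analytes of phi plus the class base
#' value equals the model's margin output.
#'
#' @param model An `nd_booster` or [nd_fit()] model.
#' @param x Feature matrix whose columns match the model's features.
#' @return Object of class `shap_tensor`: `values` (sample x analyte x
#'   class array of phi), `base_values` (per-class expected margin),
#'   `model_outputs` (sample x class margin matrix).
#' @export
shap_attributions <- function(model, x) {
  if (inherits(model, "nd_model")) model <- model$fit
  x <- align_features(model, x)
  dm <- xgboost::xgb.DMatrix(x, nthread = 1)
  contrib <- stats::predict(model$booster, dm, predcontrib = TRUE)
  # contributions arrive as sample x class x (feature + bias)
  k <- length(model$class_labels)
  p <- length(model$feature_names)
  stopifnot(length(dim(contrib)) == 3, dim(contrib)[3] == p + 1)
  values <- aperm(contrib[, , seq_len(p), drop = FALSE], c(1, 3, 2))
  dimnames(values) <- list(rownames(x), model$feature_names,
                           model$class_labels)
  base <- contrib[1, , p + 1]
  margins <- stats::predict(model$booster, dm, outputmargin = TRUE)
  colnames(margins) <- model$class_labels
  structure(list(values = values,
                 base_values = stats::setNames(base, model$class_labels),
                 model_outputs = margins),
            class = "shap_tensor")
}

#' @export
print.shap_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("shap_tensor: %d samples x %d analytes x %d classes\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Overall analyte importance from Shapley values
#'
#' `I_i = (1/K) sum_k (1/N) sum_n |phi_{n,i,k}|`: the mean absolute Shapley
#' value across both samples and classes, ranked descending (ties broken by
#' analyte identifier).
#'
#' @param t A [shap_attributions()] tensor.
#' @return data.frame of class `importance_ranking`: `analyte`,
#'   `importance`, `rank`, sorted by rank.
#' @export
overall_importance <- function(t) {
  stopifnot(inherits(t, "shap_tensor"), length(t$values) > 0)
  imp <- apply(abs(t$values), 2, mean)   # mean over samples and classes
  ids <- dimnames(t$values)[[2]]
  ord <- order(-imp, ids)
  out <- data.frame(analyte = ids[ord], importance = unname(imp[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Per-class Shapley ranking and value export
#'
#' Ranks analytes by mean absolute Shapley value within one class and
#' exports the per-sample values for the top analytes (e.g. for beeswarm
#' plotting).
#'
#' @param t A [shap_attributions()] tensor.
#' @param class One of the five class labels.
#' @param top_n Number of analytes to report (default 20; clipped to the
#'   number of analytes with a warning).
#' @return List: `table` (data.frame `analyte`, `mean_abs_shap`, `rank`) and
#'   `values` (samples x top_n matrix of per-sample phi for this class).
#' @export
per_class_ranking <- function(t, class, top_n = 20) {
  stopifnot(inherits(t, "shap_tensor"))
  classes <- dimnames(t$values)[[3]]
  if (!class %in% classes)
    stop("unknown class '", class, "'")
  phi <- t$values[, , class, drop = FALSE][, , 1]
  if (is.null(dim(phi))) phi <- matrix(phi, nrow = dim(t$values)[1])
  imp <- colMeans(abs(phi))
  ids <- dimnames(t$values)[[2]]
  if (top_n > length(ids)) {
    warning("top_n clipped to ", length(ids), " analytes")
    top_n <- length(ids)
  }
  ord <- order(-imp, ids)[seq_len(top_n)]
  list(table = data.frame(analyte = ids[ord], mean_abs_shap = unname(imp[ord]),
                          rank = seq_len(top_n), stringsAsFactors = FALSE),
       values = phi[, ord, drop = FALSE])
}
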