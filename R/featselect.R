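#' Covariate-adjusted differential abundance for one disease
#'
#' Per analyte, ordinary least squares of the normalized intensity on a
#' disease-status indicator plus age, sex and the first two principal
#' components, over that disease's cases and the shared control set only:
#' `protein ~ status + age + sex + PC1 + PC2`. The same controls are reused
#' for every disease contrast.
#'
#' @param m Normalized [proteomic_matrix()].
#' @param meta data.frame with `sample_id`, `diagnosis`, `age`, `sex`
#'   aligned to (a superset of) the matrix samples.
#' @param pcs Sample x >=2 matrix of PC scores (rownames = sample ids), e.g.
#'   from [pca_scores()].
#' @param disease Case label (e.g. `"AD"`).
#' @param control Control label (default `"CO"`).
#' @return data.frame of class `daa_result`: `analyte`, `disease`, `beta`
#'   (status coefficient, z-scored log10 scale), `se`, `p` (two-sided),
#'   `fdr` (Benjamini-Hochberg, reported, not used for selection), `n_cases`,
#'   `n_controls`, `n_used`. Analytes with fewer than 10 usable observations
#'   get `NA` statistics and are flagged in the `skipped` column.
#' @export
differential_abundance <- function(m, meta, pcs, disease, control = "CO") {
  meta <- meta[match(sample_ids(m), meta$sample_id), ]
  keep <- meta$diagnosis %in% c(disease, control)
  if (sum(meta$diagnosis == disease, na.rm = TRUE) == 0 ||
      sum(meta$diagnosis == control, na.rm = TRUE) == 0)
    stop("differential_abundance: need both cases and controls")
  pcs <- pcs[match(sample_ids(m), rownames(pcs)), 1:2, drop = FALSE]
  covar_ok <- !is.na(meta$age) & !is.na(meta$sex) &
    !is.na(pcs[, 1]) & !is.na(pcs[, 2])
  keep <- which(keep & covar_ok)

  status <- as.numeric(meta$diagnosis[keep] == disease)
  if (length(unique(status)) < 2)
    stop("differential_abundance: status has no contrast after filtering")
  X <- cbind(status = status, age = meta$age[keep], sex = meta$sex[keep],
             pc1 = pcs[keep, 1], pc2 = pcs[keep, 2])
  Y <- m$values[keep, , drop = FALSE]

  ids <- analyte_ids(m)
  out <- data.frame(analyte = ids, disease = disease, beta = NA_real_,
                    se = NA_real_, p = NA_real_, fdr = NA_real_,
                    n_cases = NA_integer_, n_controls = NA_integer_,
                    n_used = NA_integer_, skipped = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_along(ids)) {
    y <- Y[, j]
    ok <- !is.na(y)
    if (sum(ok) < 10 || length(unique(X[ok, "status"])) < 2) {
      out$skipped[j] <- TRUE
      next
    }
    df <- data.frame(y = y[ok], X[ok, , drop = FALSE])
    fit <- stats::lm(y ~ status + age + sex + pc1 + pc2, data = df)
    cf <- summary(fit)$coefficients
    out$beta[j] <- cf["status", 1]
    out$se[j] <- cf["status", 2]
    out$p[j] <- cf["status", 4]
    out$n_cases[j] <- sum(X[ok, "status"] == 1)
    out$n_controls[j] <- sum(X[ok, "status"] == 0)
    out$n_used[j] <- sum(ok)
  }
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("daa_result", "data.frame")
  out
}

#' Union of nominally significant analytes across diseases
#'
#' @param results List of [differential_abundance()] results (one per
#'   disease).
#' @param alpha Nominal, unadjusted significance threshold (default 0.05).
#' @return Character vector of analyte ids significant (`p < alpha`) for at
#'   least one disease. Warns when empty.
#' @export
union_hits <- function(results, alpha = 0.05) {
  stopifnot(length(results) >= 1)
  hits <- unique(unlist(lapply(results, function(r)
    r$analyte[!is.na(r$p) & r$p < alpha])))
  if (length(hits) == 0)
    warning("union_hits: no analyte reached nominal significance")
  hits
}

#' Variance threshold filter
#'
#' Retains candidate analytes whose variance over non-missing values exceeds
#' `threshold` (strictly). Variance uses the population convention
#' (denominator n), matching the usual minimal-variability screen on
#' already-normalized features.
#'
#' @param m Normalized [proteomic_matrix()].
#' @param candidates Character vector of analyte ids (subset of the matrix).
#' @param threshold Variance threshold (default 0.01).
#' @return Character vector of retained analyte ids.
#' @export
variance_filter <- function(m, candidates, threshold = 0.01) {
  stopifnot(all(candidates %in% analyte_ids(m)))
  v <- m$values[, candidates, drop = FALSE]
  pop_var <- apply(v, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(0)
    mean((x - mean(x))^2)
  })
  candidates[pop_var > threshold]
}

#' ANOVA F-test top-k feature ranking
#'
#' Per analyte, the one-way ANOVA F statistic across the five diagnostic
#' classes (ratio of between-group to within-group variance) over
#' non-missing values; the top `k` analytes by F are selected. Ties are
#' broken by analyte identifier order.
#'
#' @param m Normalized [proteomic_matrix()].
#' @param labels Character vector of class labels aligned to matrix samples.
#' @param candidates Analyte ids to rank (default: all).
#' @param k Number of features to select (400 is the CSF default, 700
#'   plasma).
#' @return data.frame of class `feature_ranking`: `analyte`, `F`, `rank`,
#'   `selected`, sorted by rank; attribute `"k"`.
#' @export
ftest_select_k <- function(m, labels, candidates = analyte_ids(m), k) {
  stopifnot(all(candidates %in% analyte_ids(m)),
            length(labels) == nrow(m$values))
  tab <- table(labels)
  if (any(tab < 2))
    stop("ftest_select_k: every class needs at least 2 samples (",
         paste(names(tab)[tab < 2], collapse = ", "), ")")
  if (k > length(candidates))
    stop("ftest_select_k: k exceeds the number of candidate analytes")
  v <- m$values[, candidates, drop = FALSE]
  f <- function(x) {
    ok <- !is.na(x)
    y <- x[ok]; g <- labels[ok]
    ng <- tapply(y, g, length)
    ng <- ng[!is.na(ng)]
    if (length(ng) < 2 || any(ng < 2)) return(NA_real_)
    gm <- tapply(y, g, mean)[names(ng)]
    grand <- mean(y)
    ssb <- sum(ng * (gm - grand)^2)
    ssw <- sum((y - gm[as.character(g)])^2)
    df1 <- length(ng) - 1
    df2 <- length(y) - length(ng)
    if (ssw == 0) return(Inf)
    (ssb / df1) / (ssw / df2)
  }
  Fstat <- apply(v, 2, f)
  ord <- order(-Fstat, candidates, na.last = TRUE)
  out <- data.frame(analyte = candidates[ord], F = Fstat[ord],
                    rank = seq_along(ord),
                    selected = seq_along(ord) <= k,
                    stringsAsFactors = FALSE)
  attr(out, "k") <- k
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' Three-stage feature-selection cascade
#'
#' Runs [differential_abundance()] for each disease against the shared
#' controls, takes the union of nominal hits, applies the variance
#' threshold, and ranks the survivors by ANOVA F, selecting the top `k`.
#'
#' @inheritParams differential_abundance
#' @param k Number of features to select.
#' @param diseases Case labels contrasted against `control`.
#' @param alpha Nominal significance threshold for the union step.
#' @param var_threshold Variance threshold.
#' @return List of class `feature_selection`: `daa` (per-disease results),
#'   `union` (nominal hits), `variance_kept`, `ranking`
#'   ([ftest_select_k()] output), `selected` (character vector, length `k`).
#' @export
select_features <- function(m, meta, pcs, k,
                            diseases = c("AD", "PD", "FTD", "DLB"),
                            control = "CO", alpha = 0.05,
                            var_threshold = 0.01) {
  daa <- lapply(diseases, function(d)
    differential_abundance(m, meta, pcs, d, control))
  names(daa) <- diseases
  hits <- union_hits(daa, alpha)
  kept <- variance_filter(m, hits, var_threshold)
  meta <- meta[match(sample_ids(m), meta$sample_id), ]
  core <- meta$diagnosis %in% c(control, diseases)
  ranking <- ftest_select_k(pm_subset(m, i = which(core)),
                            meta$diagnosis[core], kept,
                            k = min(k, length(kept)))
  structure(list(daa = daa, union = hits, variance_kept = kept,
                 ranking = ranking,
                 selected = ranking$analyte[ranking$selected]),
            class = "feature_selection")
}
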