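#' Quality-control configuration
#'
#' Thresholds for the analyte/sample QC cascade. Defaults follow standard
#' practice for aptamer proteomics: analytes are dropped when >= 85% of
#' samples fall below the limit of detection (plasma only), when calibration
#' scale factors deviate by more than 0.5 across plates, or when the median
#' coefficient of variation exceeds 0.15; per-analyte outliers beyond the
#' Tukey fences are masked; call-rate filtering runs in two passes (65%,
#' then 85% after recomputation), each over analytes then samples.
#'
#' @param fluid `"csf"` or `"plasma"`. CSF skips the LOD filter (protein
#'   abundance in CSF is low, so buffer-based detection limits are not
#'   applied); plasma applies it.
#' @param lod_fail_fraction Analyte removed if at least this fraction of
#'   samples reads below its LOD.
#' @param lod_sd_multiplier LOD = buffer mean + this multiple of the buffer
#'   SD (sample SD, n-1 denominator).
#' @param sf_max_deviation Maximum allowed cross-plate scale-factor
#'   deviation (strictly greater is removed).
#' @param cv_max Maximum allowed median CV (strictly greater is removed).
#' @param call_rate_pass1,call_rate_pass2 Call-rate thresholds for the two
#'   passes (strictly below is removed); pass2 must be >= pass1.
#' @param quantile_type Quantile convention for Q1/Q3 in the outlier mask
#'   (passed to [stats::quantile()]; default 7, linear interpolation).
#' @param iqr_scale Scale on which outlier fences are computed: `"log10"`
#'   (default) or `"raw"`. RFU intensities are approximately log-normal, so
#'   fences on the log scale are symmetric and flag technical artifacts
#'   rather than the skewed upper tail of every analyte.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(fluid = c("csf", "plasma"),
                      lod_fail_fraction = 0.85,
                      lod_sd_multiplier = 2,
                      sf_max_deviation = 0.5,
                      cv_max = 0.15,
                      call_rate_pass1 = 0.65,
                      call_rate_pass2 = 0.85,
                      quantile_type = 7,
                      iqr_scale = c("log10", "raw")) {
  fluid <- match.arg(fluid)
  iqr_scale <- match.arg(iqr_scale)
  stopifnot(lod_fail_fraction >= 0, lod_fail_fraction <= 1,
            call_rate_pass1 >= 0, call_rate_pass1 <= 1,
            call_rate_pass2 >= call_rate_pass1, call_rate_pass2 <= 1)
  structure(list(fluid = fluid, apply_lod = (fluid == "plasma"),
                 lod_fail_fraction = lod_fail_fraction,
                 lod_sd_multiplier = lod_sd_multiplier,
                 sf_max_deviation = sf_max_deviation, cv_max = cv_max,
                 call_rate_pass1 = call_rate_pass1,
                 call_rate_pass2 = call_rate_pass2,
                 quantile_type = quantile_type, iqr_scale = iqr_scale),
            class = "qc_config")
}

#' Analyte annotations for QC
#'
#' @param analyte_ids Character vector of analyte identifiers.
#' @param is_human_target Logical: does the aptamer target a human protein?
#' @param scale_factor_range Max absolute cross-plate deviation of the
#'   calibration scale factor.
#' @param median_cv Median coefficient of variation across replicates.
#' @param buffer Optional buffer-well matrix (wells x analytes, columns named
#'   by analyte) used by the LOD filter.
#' @return List of class `analyte_annotations` with `table` (data.frame) and
#'   `buffer`.
#' @export
analyte_annotations <- function(analyte_ids,
                                is_human_target = TRUE,
                                scale_factor_range = 0,
                                median_cv = 0,
                                buffer = NULL) {
  tab <- data.frame(analyte_id = analyte_ids,
                    is_human_target = rep_len(is_human_target, length(analyte_ids)),
                    scale_factor_range = rep_len(scale_factor_range, length(analyte_ids)),
                    median_cv = rep_len(median_cv, length(analyte_ids)),
                    stringsAsFactors = FALSE)
  if (any(tab$median_cv < 0, na.rm = TRUE)) stop("median_cv must be >= 0")
  structure(list(table = tab, buffer = buffer), class = "analyte_annotations")
}

qc_record <- function(step, level, id, statistic, value, threshold, decision) {
  n <- length(id)
  data.frame(step = rep_len(step, n), level = rep_len(level, n), id = id,
             statistic = rep_len(statistic, n), value = value,
             threshold = rep_len(threshold, n), decision = decision,
             stringsAsFactors = FALSE)
}

empty_report <- function() {
  qc_record(character(0), character(0), character(0), character(0),
            numeric(0), numeric(0), character(0))
}

#' Limit-of-detection filter (plasma)
#'
#' Per analyte, LOD = mean(buffer) + `lod_sd_multiplier` * SD(buffer) over
#' that analyte's blank wells; readings below LOD are non-detections. The
#' analyte is removed when the fraction of samples below its LOD reaches
#' `lod_fail_fraction`. In CSF mode the filter is skipped and the input is
#' returned unchanged with a skip record.
#'
#' @param m A [proteomic_matrix()].
#' @param annotations An [analyte_annotations()] carrying `buffer`.
#' @param config A [qc_config()].
#' @return List with `matrix` (filtered [proteomic_matrix()]) and `report`
#'   (decision ledger data.frame).
#' @export
lod_filter <- function(m, annotations, config) {
  if (!config$apply_lod) {
    rep0 <- qc_record("lod_filter", "analyte", "*", "skipped_csf", NA_real_,
                      NA_real_, "skipped")
    return(list(matrix = m, report = rep0))
  }
  buffer <- annotations$buffer
  ids <- analyte_ids(m)
  if (is.null(buffer) || !all(ids %in% colnames(buffer)))
    stop("LOD filter requires buffer values for every analyte")
  buffer <- buffer[, ids, drop = FALSE]
  lod <- colMeans(buffer) + config$lod_sd_multiplier * apply(buffer, 2, stats::sd)
  below <- sweep(m$values, 2, lod, `<`)
  frac_fail <- colMeans(below, na.rm = TRUE)
  frac_fail[is.nan(frac_fail)] <- 0
  removed <- frac_fail >= config$lod_fail_fraction
  report <- qc_record("lod_filter", "analyte", ids, "lod_fail_fraction",
                      frac_fail, config$lod_fail_fraction,
                      ifelse(removed, "removed", "retained"))
  list(matrix = pm_subset(m, j = which(!removed)), report = report)
}

#' Annotation-based analyte filters (human target, scale factor, CV)
#'
#' Removes analytes that target non-human proteins, whose calibration scale
#' factors deviate by more than `sf_max_deviation` across plates, or whose
#' median CV exceeds `cv_max`. Both numeric comparisons are strict: values
#' exactly at the threshold are retained.
#'
#' @inheritParams lod_filter
#' @return List with `matrix` and `report`.
#' @export
annotation_filters <- function(m, annotations, config) {
  ids <- analyte_ids(m)
  tab <- annotations$table
  if (!all(ids %in% tab$analyte_id))
    stop("annotations must cover all analytes")
  tab <- tab[match(ids, tab$analyte_id), ]
  bad_human <- !tab$is_human_target
  bad_sf <- tab$scale_factor_range > config$sf_max_deviation
  bad_cv <- tab$median_cv > config$cv_max
  report <- rbind(
    qc_record("annotation_filters", "analyte", ids, "is_human_target",
              as.numeric(tab$is_human_target), NA_real_,
              ifelse(bad_human, "removed", "retained")),
    qc_record("annotation_filters", "analyte", ids, "scale_factor_range",
              tab$scale_factor_range, config$sf_max_deviation,
              ifelse(!bad_human & bad_sf, "removed", "retained")),
    qc_record("annotation_filters", "analyte", ids, "median_cv",
              tab$median_cv, config$cv_max,
              ifelse(!bad_human & !bad_sf & bad_cv, "removed", "retained")))
  keep <- !(bad_human | bad_sf | bad_cv)
  list(matrix = pm_subset(m, j = which(keep)), report = report)
}

#' Mask per-analyte IQR outliers
#'
#' Per analyte, values strictly outside \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\]
#' (quantiles over that analyte's non-missing values, convention
#' `quantile_type`) are replaced with `NA`. With the default
#' `iqr_scale = "log10"` fences are computed on log10 intensities, the
#' scale on which RFU spreads are symmetric; `"raw"` computes them on the
#' values as given. Analytes with fewer than 4 non-missing values are
#' skipped with a record.
#'
#' @inheritParams lod_filter
#' @return List with `matrix` and `report` (one record per analyte with the
#'   count of masked entries).
#' @export
iqr_outlier_mask <- function(m, config) {
  v <- m$values
  use_log <- config$iqr_scale == "log10"
  if (use_log && any(!is.na(v) & v <= 0)) {
    warning("iqr_outlier_mask: nonpositive values present; ",
            "computing fences on the raw scale")
    use_log <- FALSE
  }
  ids <- analyte_ids(m)
  n_masked <- integer(ncol(v))
  skipped <- logical(ncol(v))
  for (j in seq_len(ncol(v))) {
    x <- if (use_log) log10(v[, j]) else v[, j]
    ok <- !is.na(x)
    if (sum(ok) < 4) { skipped[j] <- TRUE; next }
    q <- stats::quantile(x[ok], c(0.25, 0.75), type = config$quantile_type,
                         names = FALSE)
    iqr <- q[2] - q[1]
    out <- ok & (x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr)
    n_masked[j] <- sum(out)
    v[out, j] <- NA_real_
  }
  report <- qc_record("iqr_outlier_mask", "analyte", ids, "n_masked",
                      as.numeric(n_masked), NA_real_,
                      ifelse(skipped, "skipped",
                             ifelse(n_masked > 0, "masked", "retained")))
  m$values <- v
  list(matrix = m, report = report)
}

# one call-rate sweep at a threshold; level-specific removal
cr_sweep <- function(m, threshold, level, step) {
  cr <- call_rates(m)
  if (level == "analyte") {
    rates <- cr$analyte; ids <- analyte_ids(m)
  } else {
    rates <- cr$sample; ids <- sample_ids(m)
  }
  removed <- rates < threshold
  report <- qc_record(step, level, ids, "call_rate", rates, threshold,
                      ifelse(removed, "removed", "retained"))
  m <- if (level == "analyte") pm_subset(m, j = which(!removed))
       else pm_subset(m, i = which(!removed))
  list(matrix = m, report = report)
}

#' Two-pass call-rate filter
#'
#' Pass 1 removes analytes with call rate below `call_rate_pass1`, then
#' samples below the same threshold. Call rates are then recomputed on the
#' reduced matrix and a stricter `call_rate_pass2` threshold is applied,
#' again analytes then samples. All comparisons are strict (`<`).
#'
#' @inheritParams lod_filter
#' @return List with `matrix` and `report`.
#' @export
call_rate_filter <- function(m, config) {
  if (nrow(m$values) == 0 || ncol(m$values) == 0)
    stop("call_rate_filter: empty matrix")
  s1 <- cr_sweep(m, config$call_rate_pass1, "analyte", "call_rate_pass1")
  s2 <- cr_sweep(s1$matrix, config$call_rate_pass1, "sample", "call_rate_pass1")
  s3 <- cr_sweep(s2$matrix, config$call_rate_pass2, "analyte", "call_rate_pass2")
  s4 <- cr_sweep(s3$matrix, config$call_rate_pass2, "sample", "call_rate_pass2")
  out <- s4$matrix
  if (nrow(out$values) == 0 || ncol(out$values) == 0)
    stop("call_rate_filter: all samples or analytes filtered out")
  list(matrix = out,
       report = rbind(s1$report, s2$report, s3$report, s4$report))
}

#' Run the full QC cascade
#'
#' Fixed order within one sweep: annotation filters (human target / scale
#' factor / CV) and LOD, then IQR outlier masking, then the two-pass
#' call-rate filter. Masking precedes call-rate computation so masked
#' outliers count as missing. Because removing samples or masking entries
#' changes the quantiles the next sweep would see, the cascade is repeated
#' until the matrix stabilizes (almost always 1-2 sweeps), making the whole
#' pipeline a fixed point: running it on its own output changes nothing.
#'
#' @inheritParams lod_filter
#' @param max_iter Safety cap on stabilization sweeps.
#' @return List with `matrix` and the concatenated `report` ledger (a
#'   `sweep` column records the sweep index).
#' @export
qc_pipeline <- function(m, annotations, config, max_iter = 10) {
  reports <- list()
  for (iter in seq_len(max_iter)) {
    a <- annotation_filters(m, annotations, config)
    l <- lod_filter(a$matrix, annotations, config)
    i <- iqr_outlier_mask(l$matrix, config)
    c4 <- call_rate_filter(i$matrix, config)
    rep <- rbind(a$report, l$report, i$report, c4$report)
    rep$sweep <- iter
    reports[[iter]] <- rep
    stable <- identical(c4$matrix$values, m$values)
    m <- c4$matrix
    if (stable) break
  }
  list(matrix = m, report = do.call(rbind, reports))
}

#' Harmonize matrices from different panels
#'
#' Restricts every matrix to the intersection of analyte sets, concatenates
#' samples, and re-applies the stricter call-rate analyte filter
#' (`call_rate_pass2`) on the combined matrix.
#'
#' @param matrices List of [proteomic_matrix()] objects.
#' @param config A [qc_config()].
#' @return List with `matrix` and `report`.
#' @export
harmonize_panels <- function(matrices, config) {
  stopifnot(length(matrices) >= 1)
  common <- Reduce(intersect, lapply(matrices, analyte_ids))
  if (length(common) == 0)
    stop("harmonize_panels: no shared analytes across panels")
  parts <- lapply(matrices, function(m) m$values[, common, drop = FALSE])
  combined <- proteomic_matrix(do.call(rbind, parts),
                               batch = unlist(lapply(matrices, `[[`, "batch")),
                               panel = unlist(lapply(matrices, `[[`, "panel")))
  cr_sweep(combined, config$call_rate_pass2, "analyte", "harmonize_call_rate")
}

#' Log10 + batchwise z-score normalization
#'
#' Takes log10 of all present values, then within each batch centers and
#' scales every analyte to mean 0 / SD 1 over its non-missing entries.
#' Analytes constant within a batch are set to 0 there (recorded in the
#' `"constant_in_batch"` attribute).
#'
#' @param m A [proteomic_matrix()] of strictly positive RFU values.
#' @return A normalized [proteomic_matrix()].
#' @export
normalize_matrix <- function(m) {
  v <- m$values
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("nonpositive value at sample '%s', analyte '%s'",
                 rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]))
  v <- log10(v)
  const <- list()
  for (b in unique(m$batch)) {
    rows <- which(m$batch == b)
    sub <- v[rows, , drop = FALSE]
    mu <- colMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 2, stats::sd, na.rm = TRUE)
    zero <- is.na(sdv) | sdv == 0
    sdv[zero] <- 1
    sub <- sweep(sweep(sub, 2, mu, `-`), 2, sdv, `/`)
    sub[, zero] <- ifelse(is.na(sub[, zero]), NA_real_, 0)
    v[rows, ] <- sub
    if (any(zero))
      const[[b]] <- colnames(v)[zero]
  }
  m$values <- v
  attr(m, "constant_in_batch") <- const
  m
}

#' Principal-component scores for diagnostics and covariates
#'
#' PCA on the normalized matrix; missing values are substituted by the
#' per-analyte mean for this computation only (never written back).
#' The first two scores serve as PC1/PC2 covariates in
#' [differential_abundance()].
#'
#' @param m A normalized [proteomic_matrix()].
#' @param k Number of components to return (>= 2).
#' @param fit_rows Optional integer vector: fit the PCA on these samples
#'   only (e.g. the training partition, preventing leakage) and project all
#'   samples onto the fitted axes. Default: fit on all samples.
#' @return Numeric matrix (samples x k) of scores for *all* samples, with
#'   attribute `"prop_var"` giving the proportion of variance per component
#'   and `"rotation"` the loadings (for projecting further samples).
#' @export
pca_scores <- function(m, k = 2, fit_rows = NULL) {
  v <- m$values
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(v))
  if (length(fit_rows) < 2) stop("pca_scores: need at least 2 samples")
  # mean substitution (from the fitted rows) for this diagnostic only
  mu <- colMeans(v[fit_rows, , drop = FALSE], na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (any(miss)) v[miss, j] <- mu[j]
  }
  keep <- apply(v[fit_rows, , drop = FALSE], 2, stats::sd) > 0
  pc <- stats::prcomp(v[fit_rows, keep, drop = FALSE], center = TRUE,
                      scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- sweep(v[, keep, drop = FALSE], 2, pc$center) %*% rot
  rownames(scores) <- rownames(m$values)
  attr(scores, "prop_var") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  attr(scores, "rotation") <- rot
  attr(scores, "center") <- pc$center
  attr(scores, "kept_analytes") <- colnames(m$values)[keep]
  scores
}
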