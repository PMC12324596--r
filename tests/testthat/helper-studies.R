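# Shared study runs, memoized so several test files can reuse one heavy fit.
.study_cache <- new.env(parent = emptyenv())

# The strong-signal study conditions: per-disease effects of 1.0 log10 unit
# on 20 analytes (5 shared by all diseases), residual SD 0.3, 200 samples
# for CO/AD/PD and 30 for the rare FTD/DLB classes, 3 batches, modest
# missingness and injected outliers; zero-shot groups: PDD as a 0.7 PD +
# 0.3 AD mixture, plus a "control" population of which 20% silently carry
# the full AD effect profile.
strong_config <- function(seed = 101L) {
  sim_config(
    n_per_class = c(CO = 200, AD = 200, PD = 200, FTD = 30, DLB = 30),
    n_analytes = 500, n_batches = 3, batch_shift_sd = 0.2,
    n_affected = c(AD = 20, PD = 20, FTD = 20, DLB = 20), n_shared = 5,
    effect_size = 1.0, noise_sd = 0.3,
    missing_rate = 0.02, outlier_rate = 0.005,
    zero_shot = list(
      PDD = list(n = 30, weights = c(PD = 0.7, AD = 0.3)),
      CO_clean = list(n = 400, weights = c(AD = 0)),
      CO_atrisk = list(n = 100, weights = c(AD = 1))),
    seed = seed)
}

strong_study <- function() {
  if (is.null(.study_cache$strong)) {
    cfg <- strong_config()
    ds <- simulate_study(cfg)
    .study_cache$strong <- list(
      cfg = cfg, ds = ds,
      study = nd_pipeline(ds, k = 130, qc_cfg = qc_config("csf"),
                          spec = model_spec("csf")))
  }
  .study_cache$strong
}

# Zero-effect study: same scale, no disease signal anywhere.
null_study <- function() {
  if (is.null(.study_cache$null)) {
    cfg <- sim_config(
      n_per_class = c(CO = 200, AD = 200, PD = 200, FTD = 200, DLB = 200),
      n_analytes = 500, n_batches = 3, batch_shift_sd = 0.2,
      effect_size = 0, noise_sd = 0.3, seed = 202L)
    ds <- simulate_study(cfg)
    norm <- normalize_matrix(ds$rfu)
    pcs <- pca_scores(norm, 2)
    meta <- ds$metadata
    daa <- differential_abundance(norm, meta, pcs, "AD")
    fit <- nd_fit(norm$values, meta$diagnosis, spec = model_spec("csf"),
                  split_seed = 11L)
    .study_cache$null <- list(cfg = cfg, ds = ds, daa = daa, fit = fit)
  }
  .study_cache$null
}

# small dense proteomic matrix with known values
toy_matrix <- function(values, ...) proteomic_matrix(values, ...)

# O(n^2) Mann-Whitney pair-counting AUC oracle (ties count 1/2)
auc_pairs <- function(scores, positive) {
  pos <- scores[positive == 1]
  neg <- scores[positive == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# brute-force OLS via the normal equations (independent of stats::lm)
ols_oracle <- function(y, X) {
  X1 <- cbind(1, X)
  XtX <- t(X1) %*% X1
  beta <- solve(XtX, t(X1) %*% y)
  res <- y - X1 %*% beta
  df <- length(y) - ncol(X1)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  t <- beta / se
  p <- 2 * stats::pt(-abs(t), df)
  list(beta = beta[, 1], se = se, p = p[, 1])
}
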