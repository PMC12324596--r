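make_pm <- function(v, ...) proteomic_matrix(v, ...)

test_that("LOD filter follows the buffer mean + 2 SD rule", {
  # buffer [10, 12, 8]: mean 10, sample SD 2 -> LOD 14
  v <- matrix(13, nrow = 20, ncol = 1, dimnames = list(NULL, "a1"))
  v[19:20, 1] <- 15                       # 18 of 20 below 14 = 90% >= 85%
  buffer <- matrix(c(10, 12, 8), 3, 1, dimnames = list(NULL, "a1"))
  ann <- analyte_annotations("a1", buffer = buffer)
  res <- lod_filter(make_pm(v), ann, qc_config("plasma"))
  expect_equal(ncol(res$matrix$values), 0)
  expect_equal(res$report$value, 0.9)

  # 16 of 20 below = 80% < 85% -> retained
  v2 <- v; v2[15:20, 1] <- 15
  res2 <- lod_filter(make_pm(v2), ann, qc_config("plasma"))
  expect_equal(ncol(res2$matrix$values), 1)

  # all samples at/above LOD -> retained with fail fraction 0
  v3 <- matrix(14, 20, 1, dimnames = list(NULL, "a1"))
  res3 <- lod_filter(make_pm(v3), ann, qc_config("plasma"))
  expect_equal(res3$report$value, 0)
  expect_equal(res3$report$decision, "retained")

  # CSF mode: identity plus a skip record
  res4 <- lod_filter(make_pm(v), ann, qc_config("csf"))
  expect_identical(res4$matrix$values, make_pm(v)$values)
  expect_equal(res4$report$decision, "skipped")

  # plasma without buffer values is an input error
  expect_error(lod_filter(make_pm(v), analyte_annotations("a1"),
                          qc_config("plasma")), "buffer")
})

test_that("annotation filters use strict thresholds", {
  v <- matrix(100, 5, 4, dimnames = list(NULL, paste0("a", 1:4)))
  ann <- analyte_annotations(paste0("a", 1:4),
                             is_human_target = c(TRUE, TRUE, TRUE, FALSE),
                             scale_factor_range = c(0.5, 0.51, 0, 0),
                             median_cv = c(0.15, 0.1, 0.16, 0.1))
  res <- annotation_filters(make_pm(v), ann, qc_config("csf"))
  # a1: SF exactly 0.5 and CV exactly 0.15 -> retained (strict >)
  # a2: SF 0.51 -> removed; a3: CV 0.16 -> removed; a4: non-human -> removed
  expect_equal(analyte_ids(res$matrix), "a1")
  removed <- unique(res$report$id[res$report$decision == "removed"])
  expect_setequal(removed, c("a2", "a3", "a4"))
})

test_that("IQR mask matches hand-computed type-7 fences", {
  # raw-scale convention: [1..9, 100] -> Q1 = 3.25, Q3 = 7.75, IQR = 4.5,
  # fences [-3.5, 14.5] -> only 100 masked
  v <- matrix(c(1:9, 100), 10, 1, dimnames = list(NULL, "a1"))
  res <- iqr_outlier_mask(make_pm(v), qc_config("csf", iqr_scale = "raw"))
  expect_equal(sum(is.na(res$matrix$values)), 1)
  expect_true(is.na(res$matrix$values[10, 1]))
  expect_equal(res$report$value, 1)

  # default log10-scale fences reach the same decision on this analyte
  resl <- iqr_outlier_mask(make_pm(v), qc_config("csf"))
  expect_true(is.na(resl$matrix$values[10, 1]))
  expect_equal(sum(is.na(resl$matrix$values)), 1)

  # constant analyte: IQR 0, nothing strictly outside
  vc <- matrix(5, 4, 1, dimnames = list(NULL, "a1"))
  resc <- iqr_outlier_mask(make_pm(vc), qc_config("csf"))
  expect_equal(sum(is.na(resc$matrix$values)), 0)

  # masked entries stay masked and are excluded from the quantiles
  vm <- matrix(c(1:9, 100, NA, NA), 12, 1, dimnames = list(NULL, "a1"))
  resm <- iqr_outlier_mask(make_pm(vm), qc_config("csf", iqr_scale = "raw"))
  expect_equal(sum(is.na(resm$matrix$values)), 3)

  # fewer than 4 observed values: skipped with record
  vs <- matrix(c(1, 2, 3, NA, NA), 5, 1, dimnames = list(NULL, "a1"))
  ress <- iqr_outlier_mask(make_pm(vs), qc_config("csf"))
  expect_equal(ress$report$decision, "skipped")
})

test_that("two-pass call-rate filter removes at 65% then 85%", {
  # 10 analytes wide so that removing bad analytes/samples leaves every
  # remaining rate untouched; a1 at 12/20 = 0.60, a2 at 16/20 = 0.80
  set.seed(1)
  v <- matrix(stats::runif(20 * 10, 10, 100), 20, 10,
              dimnames = list(paste0("s", 1:20), paste0("a", 1:10)))
  v[1:8, 1] <- NA                          # a1: pass-1 removal
  v[1:4, 2] <- NA                          # a2: survives pass 1 only
  res <- call_rate_filter(make_pm(v), qc_config("csf"))
  rep1 <- res$report
  expect_false("a1" %in% analyte_ids(res$matrix))  # 0.60 < 0.65, pass 1
  expect_false("a2" %in% analyte_ids(res$matrix))  # 0.80 < 0.85, pass 2
  expect_true("a3" %in% analyte_ids(res$matrix))
  expect_equal(nrow(res$matrix$values), 20)        # no sample falls below
  expect_equal(rep1$step[rep1$id == "a1" & rep1$decision == "removed"],
               "call_rate_pass1")
  expect_equal(rep1$step[rep1$id == "a2" & rep1$decision == "removed"],
               "call_rate_pass2")

  # fully observed matrix passes through unchanged
  vf <- matrix(1:12 + 0.5, 4, 3,
               dimnames = list(paste0("s", 1:4), paste0("a", 1:3)))
  resf <- call_rate_filter(make_pm(vf), qc_config("csf"))
  expect_identical(resf$matrix$values, vf)

  # everything filtered is an explicit error
  vna <- matrix(NA_real_, 4, 3, dimnames = list(NULL, paste0("a", 1:3)))
  vna[1, 1] <- 1
  expect_error(call_rate_filter(make_pm(vna), qc_config("csf")), "filtered")
})

test_that("panel harmonization intersects analytes and re-filters", {
  v1 <- matrix(stats::runif(50, 10, 100), 10, 5,
               dimnames = list(paste0("s", 1:10), c("a", "b", "c", "d", "e")))
  v2 <- matrix(stats::runif(50, 10, 100), 10, 5,
               dimnames = list(paste0("t", 1:10), c("c", "d", "e", "f", "g")))
  res <- harmonize_panels(list(make_pm(v1), make_pm(v2)), qc_config("csf"))
  expect_setequal(analyte_ids(res$matrix), c("c", "d", "e"))
  expect_equal(nrow(res$matrix$values), 20)

  # combined call rate 84/100 < 0.85 -> removed after intersection
  v3 <- matrix(stats::runif(100 * 2, 10, 100), 100, 2,
               dimnames = list(sprintf("u%03d", 1:100), c("c", "h")))
  v3[1:16, 1] <- NA
  res2 <- harmonize_panels(list(make_pm(v3[, c("c", "h")])),
                           qc_config("csf"))
  expect_false("c" %in% analyte_ids(res2$matrix))

  expect_error(harmonize_panels(list(make_pm(v1[, 1:2, drop = FALSE]),
                                     make_pm(v2[, 4:5, drop = FALSE])),
                                qc_config("csf")),
               "no shared analytes")
})

test_that("normalization is log10 then batchwise z-score", {
  set.seed(2)
  v <- 10^matrix(stats::rnorm(60 * 4, 3, 0.4), 60, 4,
                 dimnames = list(NULL, paste0("a", 1:4)))
  batch <- rep(c("b1", "b2"), each = 30)
  m <- normalize_matrix(make_pm(v, batch = batch))
  for (b in c("b1", "b2")) {
    sub <- m$values[batch == b, ]
    expect_equal(unname(colMeans(sub)), rep(0, 4), tolerance = 1e-12)
    expect_equal(unname(apply(sub, 2, sd)), rep(1, 4), tolerance = 1e-12)
  }
  # brute-force z of a single cell
  lx <- log10(v[batch == "b1", 2])
  expect_equal(m$values[1, 2], (lx[1] - mean(lx)) / sd(lx))

  # nonpositive values are an input error naming the offender
  vbad <- v; vbad[3, 2] <- 0
  expect_error(normalize_matrix(make_pm(vbad, batch = batch)), "a2")

  # analytes constant within a batch are zeroed and recorded
  vconst <- v; vconst[batch == "b1", 1] <- 100
  mc <- normalize_matrix(make_pm(vconst, batch = batch))
  expect_true(all(mc$values[batch == "b1", 1] == 0))
  expect_equal(attr(mc, "constant_in_batch")$b1, "a1")
})

test_that("PCA scores behave as diagnostics expect", {
  set.seed(3)
  # rank-1 structure plus tiny noise: PC1 explains > 99%
  u <- stats::rnorm(40); w <- stats::rnorm(10)
  v <- outer(u, w) + matrix(stats::rnorm(400, 0, 1e-3), 40, 10)
  colnames(v) <- paste0("a", 1:10)
  sc <- pca_scores(make_pm(v), k = 3)
  expect_gt(attr(sc, "prop_var")[1], 0.99)
  # orthogonality of score vectors
  expect_lt(abs(stats::cor(sc[, 1], sc[, 2])), 1e-8)

  # batchwise z-scoring removes batch separation from leading PCs
  cfg <- sim_config(n_per_class = c(CO = 50, AD = 50, PD = 50, FTD = 10,
                                    DLB = 10),
                    n_analytes = 100, n_batches = 3, batch_shift_sd = 0.5,
                    effect_size = 0, seed = 5)
  ds <- simulate_dataset(cfg)
  norm <- normalize_matrix(ds$rfu)
  sc2 <- pca_scores(norm, 2)
  fit <- stats::aov(sc2[, 1] ~ factor(norm$batch))
  ss <- summary(fit)[[1]][["Sum Sq"]]
  expect_lt(ss[1] / sum(ss), 0.05)

  expect_error(pca_scores(make_pm(v[1, , drop = FALSE])), "2 samples")
})

test_that("QC cascade is idempotent and monotone in thresholds", {
  cfg <- sim_config(n_per_class = c(CO = 30, AD = 30, PD = 30, FTD = 8,
                                    DLB = 8),
                    n_analytes = 60,
                    n_affected = c(AD = 6, PD = 6, FTD = 6, DLB = 6),
                    n_shared = 2, missing_rate = 0.05,
                    outlier_rate = 0.01, seed = 21)
  ds <- inject_artifacts(simulate_dataset(cfg), cfg)
  ann <- analyte_annotations(analyte_ids(ds$rfu), buffer = ds$buffer)
  qc1 <- qc_pipeline(ds$rfu, ann, qc_config("csf"))
  qc2 <- qc_pipeline(qc1$matrix, ann, qc_config("csf"))
  expect_identical(qc2$matrix$values, qc1$matrix$values)

  # raising the call-rate threshold removes a superset of analytes
  lo <- call_rate_filter(ds$rfu, qc_config("csf", call_rate_pass1 = 0.6,
                                           call_rate_pass2 = 0.8))
  hi <- call_rate_filter(ds$rfu, qc_config("csf", call_rate_pass1 = 0.7,
                                           call_rate_pass2 = 0.9))
  expect_true(all(analyte_ids(hi$matrix) %in% analyte_ids(lo$matrix)))
  expect_true(all(sample_ids(hi$matrix) %in% sample_ids(lo$matrix)))

  # ledger conservation: in = out + removed, for analytes and samples
  rep <- qc1$report
  removed_an <- unique(rep$id[rep$level == "analyte" &
                                rep$decision == "removed"])
  removed_sa <- unique(rep$id[rep$level == "sample" &
                                rep$decision == "removed"])
  expect_equal(ncol(ds$rfu$values),
               ncol(qc1$matrix$values) + length(removed_an))
  expect_equal(nrow(ds$rfu$values),
               nrow(qc1$matrix$values) + length(removed_sa))
  # every removed analyte has exactly one removing record
  tab <- table(rep$id[rep$decision == "removed" & rep$level == "analyte"])
  expect_true(all(tab == 1))
})
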