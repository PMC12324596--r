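#' Configuration for the synthetic proteomic study generator
#'
#' Defines a simulated multi-cohort aptamer-proteomics study. Intensities are
#' generated additively on the log10 scale (analyte baseline plus batch
#' offset, disease effects, age/sex terms and Gaussian noise), then
#' anti-logged to the RFU scale, which makes the downstream linear
#' differential-abundance model correctly specified under the simulator.
#'
#' @param n_per_class Named integer vector of samples per diagnostic class.
#'   Names must include the five core labels `CO, AD, PD, FTD, DLB` (zeros
#'   allowed). Defaults reflect a study where FTD and DLB are rare.
#' @param n_analytes Number of analytes (aptamers).
#' @param n_batches Number of batches/cohorts; samples are assigned uniformly.
#' @param batch_shift_sd SD (log10 units) of additive per-batch, per-analyte
#'   offsets.
#' @param n_affected Named vector: number of analytes carrying an effect for
#'   each disease (`AD, PD, FTD, DLB`).
#' @param n_shared Number of analytes affected by *all* diseases (a subset of
#'   each disease's affected set); must not exceed any `n_affected` entry.
#' @param effect_size Absolute per-analyte disease effect, log10 units. Signs
#'   are drawn at random per analyte-disease pair.
#' @param age_slope,sex_effect Covariate effects in log10 units (slope per
#'   year of age; additive male-vs-female shift), each applied to a random
#'   10% of analytes.
#' @param age_range Uniform range for simulated ages (years).
#' @param noise_sd Residual SD, log10 units.
#' @param missing_rate,outlier_rate Fractions of entries masked missing /
#'   replaced by extreme values by [inject_artifacts()].
#' @param outlier_factor Injected outliers are set to `outlier_factor` times
#'   the analyte's upper Tukey fence (Q3 + 1.5 IQR) on the RFU scale.
#' @param n_buffer_wells Number of blank (buffer) wells per analyte; buffer
#'   log10 intensities sit ~2 decades below the analyte baseline.
#' @param biomarker_spec List describing the CSF biomarker mixtures: for each
#'   of `abeta42` and `ptau`, `mean_normal`, `mean_path`, `sd`, and a named
#'   per-class `path_fraction` (probability of the pathological component:
#'   *low* Abeta42, *high* pTau).
#' @param zero_shot Named list of zero-shot groups never used in training,
#'   each `list(n = <count>, weights = <named weights over core diseases>)`;
#'   the group's proteomic effect vector is the convex mixture of the trained
#'   classes' effect vectors (e.g. PDD = 0.7 PD + 0.3 AD).
#' @param seed Integer RNG seed; the whole dataset is deterministic given the
#'   config including this seed.
#'
#' @return An object of class `sim_config` (validated list).
#' @seealso [simulate_dataset()], [inject_artifacts()],
#'   [simulate_biomarkers()], [simulate_study()]
#' @export
sim_config <- function(n_per_class = c(CO = 200, AD = 200, PD = 200, FTD = 30, DLB = 30),
                       n_analytes = 500,
                       n_batches = 3,
                       batch_shift_sd = 0.2,
                       n_affected = c(AD = 20, PD = 20, FTD = 20, DLB = 20),
                       n_shared = 5,
                       effect_size = 1.0,
                       age_slope = 0.002,
                       sex_effect = 0.1,
                       age_range = c(50, 90),
                       noise_sd = 0.3,
                       missing_rate = 0,
                       outlier_rate = 0,
                       outlier_factor = 10,
                       n_buffer_wells = 10,
                       biomarker_spec = list(
                         abeta42 = list(mean_normal = 1000, mean_path = 450, sd = 120),
                         ptau = list(mean_normal = 20, mean_path = 60, sd = 8),
                         path_fraction = c(CO = 0.15, AD = 0.95, PD = 0.25,
                                           FTD = 0.25, DLB = 0.40)),
                       zero_shot = list(),
                       seed = 1L) {
  core <- c("CO", "AD", "PD", "FTD", "DLB")
  if (!all(core %in% names(n_per_class)))
    stop("n_per_class must name all of ", paste(core, collapse = ", "))
  n_per_class <- n_per_class[core]
  if (any(n_per_class < 0) || n_analytes < 1 || n_batches < 1)
    stop("counts must be nonnegative (n_analytes, n_batches >= 1)")
  diseases <- c("AD", "PD", "FTD", "DLB")
  if (!all(diseases %in% names(n_affected)))
    stop("n_affected must name AD, PD, FTD, DLB")
  n_affected <- n_affected[diseases]
  if (n_shared > min(n_affected))
    stop("configuration error: shared-analyte overlap (", n_shared,
         ") exceeds a per-disease affected count")
  if (sum(pmax(n_affected - n_shared, 0)) + n_shared > n_analytes)
    stop("affected sets do not fit into n_analytes")
  if (missing_rate < 0 || missing_rate > 1 || outlier_rate < 0 || outlier_rate > 1)
    stop("rates must lie in [0, 1]")
  pf <- biomarker_spec$path_fraction
  if (any(pf < 0 | pf > 1)) stop("mixing fractions must lie in [0, 1]")
  for (g in names(zero_shot)) {
    zs <- zero_shot[[g]]
    if (is.null(zs$n) || is.null(zs$weights) ||
        !all(names(zs$weights) %in% diseases))
      stop("zero_shot groups need n and named weights over ",
           paste(diseases, collapse = ", "))
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic proteomic dataset
#'
#' Draws the clean (artifact-free) dataset under a [sim_config()]:
#' log10 RFU = analyte baseline + batch offset + disease effect + age/sex
#' terms + Gaussian noise, anti-logged to the RFU scale. Buffer (blank) wells
#' are drawn from a low-intensity distribution independent of disease.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_dataset`:
#'   \describe{
#'     \item{rfu}{[proteomic_matrix()] of strictly positive RFU values}
#'     \item{metadata}{data.frame: `sample_id, diagnosis, age, sex, batch, panel`}
#'     \item{buffer}{buffer-well matrix (`n_buffer_wells` x analytes)}
#'     \item{truth}{ground truth: `labels`, `effect_matrix` (analyte x
#'       disease, log10 units), `affected_sets`, covariate flags}
#'   }
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  diseases <- c("AD", "PD", "FTD", "DLB")

  n_core <- config$n_per_class
  zs_n <- vapply(config$zero_shot, function(z) as.integer(z$n), integer(1))
  labels <- c(rep(names(n_core), n_core),
              rep(names(config$zero_shot), zs_n))
  n <- length(labels)
  if (n == 0) stop("no samples requested")
  p <- config$n_analytes
  an_ids <- sprintf("apt%04d", seq_len(p))

  # affected sets: a shared block hit by all diseases, then disjoint
  # disease-specific blocks
  shared <- seq_len(config$n_shared)
  offset <- config$n_shared
  affected_sets <- list()
  effect_matrix <- matrix(0, p, length(diseases),
                          dimnames = list(an_ids, diseases))
  for (d in diseases) {
    n_own <- config$n_affected[[d]] - config$n_shared
    own <- if (n_own > 0) offset + seq_len(n_own) else integer(0)
    offset <- offset + max(n_own, 0)
    idx <- c(shared, own)
    affected_sets[[d]] <- idx
    signs <- sample(c(-1, 1), length(idx), replace = TRUE)
    effect_matrix[idx, d] <- signs * config$effect_size
  }

  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- stats::rbinom(n, 1, 0.5)                    # 1 = male
  batch <- sample(paste0("batch", seq_len(config$n_batches)), n, replace = TRUE)

  baseline <- stats::runif(p, 2, 4)
  batch_offsets <- matrix(stats::rnorm(config$n_batches * p, 0,
                                       config$batch_shift_sd),
                          config$n_batches, p,
                          dimnames = list(paste0("batch",
                                                 seq_len(config$n_batches)),
                                          an_ids))
  age_flag <- stats::rbinom(p, 1, 0.10)
  sex_flag <- stats::rbinom(p, 1, 0.10)

  # per-sample effect vector: core classes use their column, zero-shot groups
  # a convex mixture of the trained-class columns
  eff_for <- function(lab) {
    if (lab %in% diseases) return(effect_matrix[, lab])
    if (lab == "CO") return(numeric(p))
    w <- config$zero_shot[[lab]]$weights
    as.vector(effect_matrix[, names(w), drop = FALSE] %*% w)
  }
  eff_by_label <- vapply(unique(labels), eff_for, numeric(p))

  mean_age <- mean(config$age_range)
  logx <- matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
  logx <- logx + rep(baseline, each = n)
  logx <- logx + batch_offsets[batch, , drop = FALSE]
  logx <- logx + t(eff_by_label[, labels, drop = FALSE])
  logx <- logx + outer(age - mean_age, age_flag * config$age_slope)
  logx <- logx + outer(sex, sex_flag * config$sex_effect)

  rfu <- 10^logx
  rownames(rfu) <- sprintf("s%05d", seq_len(n))
  colnames(rfu) <- an_ids

  buffer <- 10^matrix(stats::rnorm(config$n_buffer_wells * p,
                                   rep(baseline - 2, each = config$n_buffer_wells),
                                   0.1),
                      config$n_buffer_wells, p, dimnames = list(NULL, an_ids))

  metadata <- data.frame(sample_id = rownames(rfu), diagnosis = labels,
                         age = age, sex = sex, batch = batch, panel = "panel1",
                         stringsAsFactors = FALSE)
  truth <- list(labels = stats::setNames(labels, rownames(rfu)),
                effect_matrix = effect_matrix,
                affected_sets = affected_sets,
                baseline = baseline, batch_offsets = batch_offsets,
                age_flag = age_flag, sex_flag = sex_flag)
  structure(list(rfu = proteomic_matrix(rfu, batch = batch),
                 metadata = metadata, buffer = buffer, truth = truth),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset\n")
  print(x$rfu)
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$metadata$diagnosis)),
                                  table(x$metadata$diagnosis)), collapse = " "),
      "\n")
  invisible(x)
}

#' Inject missingness and outliers into a synthetic dataset
#'
#' Masks a random `missing_rate` fraction of entries and replaces a random
#' `outlier_rate` fraction with extreme values (`outlier_factor` times the
#' analyte's upper Tukey fence, so they land beyond Q3 + 1.5 IQR and are
#' catchable by [iqr_outlier_mask()]). Ground truth is untouched except for
#' recording the injected index sets.
#'
#' @param ds A `synthetic_dataset` from [simulate_dataset()].
#' @param config The same [sim_config()].
#' @return The dataset with artifacts applied; `truth$missing_idx` and
#'   `truth$outlier_idx` record linear indices of injected entries.
#' @export
inject_artifacts <- function(ds, config) {
  stopifnot(inherits(ds, "synthetic_dataset"), inherits(config, "sim_config"))
  if (config$missing_rate == 0 && config$outlier_rate == 0) {
    ds$truth$missing_idx <- integer(0)
    ds$truth$outlier_idx <- integer(0)
    return(ds)
  }
  set.seed(config$seed + 1L)
  v <- ds$rfu$values
  nv <- length(v)
  idx <- sample.int(nv, round((config$missing_rate + config$outlier_rate) * nv))
  n_miss <- round(config$missing_rate * nv)
  miss_idx <- idx[seq_len(n_miss)]
  out_idx <- if (n_miss > 0) idx[-seq_len(n_miss)] else idx
  if (length(out_idx)) {
    col_of <- (out_idx - 1L) %/% nrow(v) + 1L
    q <- apply(v, 2, stats::quantile, probs = c(0.25, 0.75), na.rm = TRUE)
    fence <- q[2, ] + 1.5 * (q[2, ] - q[1, ])
    v[out_idx] <- config$outlier_factor * fence[col_of]
  }
  v[miss_idx] <- NA_real_
  ds$rfu$values <- v
  ds$truth$missing_idx <- miss_idx
  ds$truth$outlier_idx <- out_idx
  ds
}

#' Simulate CSF biomarker levels (Abeta42, pTau)
#'
#' Each sample draws Abeta42 and pTau from a class-conditional two-component
#' Gaussian mixture: with the class's pathological fraction it draws from the
#' pathological component (low Abeta42 / high pTau), otherwise from the
#' normal one. True component membership is stored in the ground truth so
#' mixture-model recovery can be scored.
#'
#' @param ds A `synthetic_dataset`.
#' @param config The same [sim_config()]; see `biomarker_spec`.
#' @return The dataset with `metadata` gaining `abeta42` and `ptau` columns
#'   and `truth$biomarker_component` (data.frame of logical `abeta42_path`,
#'   `ptau_path`).
#' @export
simulate_biomarkers <- function(ds, config) {
  stopifnot(inherits(ds, "synthetic_dataset"), inherits(config, "sim_config"))
  spec <- config$biomarker_spec
  if (spec$abeta42$mean_normal == spec$abeta42$mean_path ||
      spec$ptau$mean_normal == spec$ptau$mean_path)
    stop("configuration error: biomarker component means must differ")
  set.seed(config$seed + 2L)
  labs <- ds$metadata$diagnosis
  pf <- spec$path_fraction
  # zero-shot or unknown labels fall back to the CO fraction
  frac <- ifelse(labs %in% names(pf), pf[labs], pf[["CO"]])
  n <- length(labs)
  ab_path <- stats::runif(n) < frac
  pt_path <- stats::runif(n) < frac
  draw <- function(m, path) {
    mu <- ifelse(path, m$mean_path, m$mean_normal)
    stats::rnorm(n, mu, m$sd)
  }
  ds$metadata$abeta42 <- draw(spec$abeta42, ab_path)
  ds$metadata$ptau <- draw(spec$ptau, pt_path)
  ds$truth$biomarker_component <- data.frame(abeta42_path = ab_path,
                                             ptau_path = pt_path,
                                             row.names = ds$metadata$sample_id)
  ds
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: [simulate_dataset()] then [inject_artifacts()] then
#' [simulate_biomarkers()].
#'
#' @param config A [sim_config()].
#' @return A `synthetic_dataset`.
#' @export
simulate_study <- function(config) {
  simulate_biomarkers(inject_artifacts(simulate_dataset(config), config), config)
}
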