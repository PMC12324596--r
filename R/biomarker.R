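#' Dichotomize a biomarker by a two-component Gaussian mixture
#'
#' Fits a univariate two-component Gaussian mixture (equal- and
#' unequal-variance models, best BIC) to continuous biomarker levels and
#' assigns each sample to the component with the higher posterior
#' probability. "Positive" means the *elevated* component when
#' `direction = "high_is_positive"` (pTau) and the *low* component when
#' `direction = "low_is_positive"` (Abeta42: low levels indicate amyloid
#' pathology). The crossing threshold between the two component densities is
#' reported for audit; assignment itself is by maximum posterior.
#'
#' @param levels Numeric vector of biomarker measurements (`NA` allowed;
#'   at least 30 non-missing values required).
#' @param direction `"high_is_positive"` or `"low_is_positive"`.
#' @return List of class `gmm_dichotomy`: `positive` (logical per input,
#'   `NA` where missing), `posterior_high` (posterior probability of the
#'   high-mean component), `threshold` (density crossing point between the
#'   component means), `means`, `sds`, `proportions` (low component first),
#'   `unimodal_warning` (TRUE when component means are closer than half the
#'   pooled SD).
#' @importFrom mclust Mclust mclustBIC
#' @export
gmm_dichotomize <- function(levels, direction = c("high_is_positive",
                                                  "low_is_positive")) {
  direction <- match.arg(direction)
  ok <- !is.na(levels)
  if (sum(ok) < 30)
    stop("gmm_dichotomize: need at least 30 non-missing values")
  x <- levels[ok]
  if (stats::sd(x) == 0) {
    # degenerate: a single point mass; everyone in one component
    warning("gmm_dichotomize: data effectively unimodal (constant)")
    positive <- rep(NA, length(levels))
    positive[ok] <- (direction == "low_is_positive")
    return(structure(list(positive = positive,
                          posterior_high = ifelse(ok, 0, NA_real_),
                          threshold = x[1], means = c(x[1], x[1]),
                          sds = c(0, 0), proportions = c(1, 0),
                          unimodal_warning = TRUE),
                     class = "gmm_dichotomy"))
  }
  fit <- Mclust(x, G = 2, modelNames = c("E", "V"), verbose = FALSE)
  if (is.null(fit))
    stop("gmm_dichotomize: mixture fit did not converge")
  mu <- fit$parameters$mean
  sigma <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sigma) == 1) sigma <- rep(sigma, 2)
  pro <- fit$parameters$pro
  ord <- order(mu)                       # low component first
  mu <- mu[ord]; sigma <- sigma[ord]; pro <- pro[ord]
  post_high <- fit$z[, ord[2]]

  pooled_sd <- sqrt(sum(pro * sigma^2))
  unimodal <- abs(diff(mu)) < 0.5 * pooled_sd
  if (unimodal)
    warning("gmm_dichotomize: component means within 0.5 pooled SD; ",
            "data may be unimodal")

  # crossing point: where the weighted component densities are equal,
  # searched between the component means
  f <- function(t) pro[1] * stats::dnorm(t, mu[1], max(sigma[1], 1e-12)) -
                   pro[2] * stats::dnorm(t, mu[2], max(sigma[2], 1e-12))
  threshold <- if (mu[1] < mu[2] && sign(f(mu[1])) != sign(f(mu[2]))) {
    stats::uniroot(f, c(mu[1], mu[2]))$root
  } else mean(mu)

  high <- post_high > 0.5
  positive <- rep(NA, length(levels))
  positive[ok] <- if (direction == "high_is_positive") high else !high
  ph <- rep(NA_real_, length(levels)); ph[ok] <- post_high
  structure(list(positive = positive, posterior_high = ph,
                 threshold = threshold, means = unname(mu),
                 sds = unname(sigma), proportions = unname(pro),
                 unimodal_warning = unimodal),
            class = "gmm_dichotomy")
}

#' @export
print.gmm_dichotomy <- function(x, ...) {
  cat(sprintf("gmm_dichotomy: components N(%.3g, %.3g) / N(%.3g, %.3g), threshold %.4g\n",
              x$means[1], x$sds[1], x$means[2], x$sds[2], x$threshold))
  cat(sprintf("  positive: %d of %d (%s)\n", sum(x$positive, na.rm = TRUE),
              sum(!is.na(x$positive)),
              if (x$unimodal_warning) "UNIMODAL WARNING" else "ok"))
  invisible(x)
}

#' Assign amyloid/tau (AT) status from CSF biomarkers
#'
#' A status comes from Abeta42 (low component = A+), T status from pTau
#' (high component = T+). Samples missing a marker get `"unknown"` for that
#' axis. A+T+ individuals carry both amyloid and tau pathology; A-T- have
#' minimal plaque and tangle burden.
#'
#' @param panel data.frame with columns `abeta42` and/or `ptau` (numeric,
#'   `NA` allowed); one row per sample.
#' @return data.frame with columns `A`, `T` (each `"+"`, `"-"` or
#'   `"unknown"`), `at` (combined label, `NA` when either side unknown),
#'   `posterior_A`, `posterior_T` (posterior probability of the pathological
#'   component), plus attributes `"gmm_abeta42"` / `"gmm_ptau"` carrying the
#'   fitted [gmm_dichotomize()] objects.
#' @export
assign_at_status <- function(panel) {
  n <- nrow(panel)
  out <- data.frame(A = rep("unknown", n), T = rep("unknown", n),
                    at = rep(NA_character_, n),
                    posterior_A = rep(NA_real_, n),
                    posterior_T = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (!is.null(panel$abeta42) && sum(!is.na(panel$abeta42)) >= 30) {
    g <- gmm_dichotomize(panel$abeta42, "low_is_positive")
    out$A <- ifelse(is.na(g$positive), "unknown", ifelse(g$positive, "+", "-"))
    out$posterior_A <- 1 - g$posterior_high   # pathological = low component
    attr(out, "gmm_abeta42") <- g
  }
  if (!is.null(panel$ptau) && sum(!is.na(panel$ptau)) >= 30) {
    g <- gmm_dichotomize(panel$ptau, "high_is_positive")
    out$T <- ifelse(is.na(g$positive), "unknown", ifelse(g$positive, "+", "-"))
    out$posterior_T <- g$posterior_high
    attr(out, "gmm_ptau") <- g
  }
  known <- out$A != "unknown" & out$T != "unknown"
  out$at[known] <- paste0("A", out$A[known], "T", out$T[known])
  out
}

#' Training eligibility from diagnosis and biomarker status
#'
#' Encodes the biomarker-confirmation rules for assembling the training set.
#' CSF: AD cases must be A+T+ and controls A-T-; PD, FTD and DLB enter on
#' clinical diagnosis alone (no validated fluid biomarkers exist for them).
#' Plasma: AD cases need at least one positive among the available markers
#' (CSF AT status, amyloid PET, plasma pTau217); controls must be negative
#' on the available markers (`co_rule = "all_available"`, default) or on at
#' least one (`"any_one"`). Everything else --- intermediate AT profiles,
#' missing confirmation for AD/CO, zero-shot labels --- is `benchmark_only`.
#'
#' @param meta data.frame with `diagnosis` and, for plasma, optional binary
#'   `ptau217_status` / `amyloid_pet_status` columns (1 = positive, `NA` =
#'   unavailable).
#' @param at Output of [assign_at_status()] aligned to `meta` rows (may be
#'   `NULL` when no CSF biomarkers exist).
#' @param fluid `"csf"` or `"plasma"`.
#' @param co_rule Plasma control rule (see above).
#' @return Character vector, `"core_train"` or `"benchmark_only"` per sample.
#' @export
training_eligibility <- function(meta, at = NULL,
                                 fluid = c("csf", "plasma"),
                                 co_rule = c("all_available", "any_one")) {
  fluid <- match.arg(fluid)
  co_rule <- match.arg(co_rule)
  n <- nrow(meta)
  dx <- meta$diagnosis
  if (is.null(at))
    at <- data.frame(A = rep("unknown", n), T = rep("unknown", n))
  clinical_only <- dx %in% c("PD", "FTD", "DLB")

  if (fluid == "csf") {
    ok_ad <- dx == "AD" & at$A == "+" & at$T == "+"
    ok_co <- dx == "CO" & at$A == "-" & at$T == "-"
    elig <- ifelse(ok_ad | ok_co | clinical_only, "core_train",
                   "benchmark_only")
    return(elig)
  }

  # plasma: evidence matrix over {CSF AT, amyloid PET, pTau217};
  # intermediate AT profiles are treated as unavailable evidence
  at_pos <- ifelse(at$A == "+" & at$T == "+", 1,
                   ifelse(at$A == "-" & at$T == "-", 0, NA))
  pet <- if (!is.null(meta$amyloid_pet_status)) meta$amyloid_pet_status else rep(NA, n)
  pt217 <- if (!is.null(meta$ptau217_status)) meta$ptau217_status else rep(NA, n)
  ev <- cbind(at_pos, pet, pt217)
  n_avail <- rowSums(!is.na(ev))
  n_pos <- rowSums(ev == 1, na.rm = TRUE)
  n_neg <- rowSums(ev == 0, na.rm = TRUE)

  ok_ad <- dx == "AD" & n_pos >= 1
  ok_co <- dx == "CO" & n_avail > 0 &
    (if (co_rule == "all_available") n_neg == n_avail else n_neg >= 1)
  ifelse(ok_ad | ok_co | clinical_only, "core_train", "benchmark_only")
}
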