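sep_fixture <- function(n_per = 40, seed = 77, effect = 2.0) {
  set.seed(seed)
  classes <- c("CO", "AD", "PD", "FTD", "DLB")
  labels <- rep(classes, each = n_per)
  n <- length(labels)
  p <- 25
  centers <- matrix(0, 5, p)
  for (i in 1:5) centers[i, ((i - 1) * 5 + 1):(i * 5)] <- effect
  x <- centers[match(labels, classes), ] +
    matrix(stats::rnorm(n * p, 0, 0.2), n, p)
  colnames(x) <- paste0("f", 1:p)
  list(x = x, labels = labels)
}

test_that("stratified split is 70/30 per class and deterministic", {
  labels <- rep(c("CO", "AD", "PD", "FTD", "DLB"), c(10, 20, 30, 40, 100))
  s1 <- stratified_split(labels, 0.7, seed = 7)
  s2 <- stratified_split(labels, 0.7, seed = 7)
  expect_identical(s1, s2)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_setequal(c(s1$train, s1$test), seq_along(labels))
  for (lab in unique(labels)) {
    n_lab <- sum(labels == lab)
    n_train <- sum(labels[s1$train] == lab)
    expect_lte(abs(n_train - 0.7 * n_lab), 1)
  }
  expect_equal(sum(labels[s1$train] == "CO"), 7)
  expect_warning(stratified_split(c(rep("A", 4), "B", "B"), 0.7, 1),
                 "fewer than 4")
})

test_that("SMOTE equalizes counts with convex synthetic rows", {
  set.seed(8)
  x <- matrix(stats::rnorm(218 * 4), 218, 4)
  labels <- rep(c("CO", "AD", "PD", "FTD", "DLB"),
                c(100, 50, 50, 10, 8))
  sm <- suppressWarnings(smote(x, labels, k_neighbors = 5, seed = 8))
  expect_true(all(table(sm$labels) == 100))
  # every synthetic FTD row lies on a segment between two original FTD rows
  orig <- x[labels == "FTD", ]
  synth <- sm$x[sm$synthetic & sm$labels == "FTD", , drop = FALSE]
  on_segment <- function(s) {
    for (i in 1:(nrow(orig) - 1)) for (j in (i + 1):nrow(orig)) {
      d <- orig[j, ] - orig[i, ]
      r <- s - orig[i, ]
      u <- sum(r * d) / sum(d * d)
      if (u >= -1e-9 && u <= 1 + 1e-9 &&
          sqrt(sum((r - u * d)^2)) < 1e-8) return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(synth, 1, on_segment)))
  # tiny classes reduce k with a warning; singleton classes error
  expect_warning(smote(x[1:13, ], rep(c("A", "B"), c(10, 3)),
                       k_neighbors = 5, seed = 1), "k=2")
  expect_error(smote(x[1:11, ], rep(c("A", "B"), c(10, 1)), seed = 1),
               "at least 2")
  expect_error(smote(rbind(x, NA)[c(1:10, 219), ], rep(c("A", "B"), c(10, 1))),
               "complete")
})

test_that("Tomek links flag only cross-class mutual nearest neighbours", {
  # two tight, well-separated clusters: no links
  x <- rbind(matrix(stats::rnorm(20, 0, 0.1), 10, 2),
             matrix(stats::rnorm(20, 10, 0.1), 10, 2))
  labels <- rep(c("A", "B"), each = 10)
  expect_length(tomek_links(x, labels), 0)
  # plant one ambiguous cross-class pair between the clusters
  x2 <- rbind(x, c(5, 5), c(5.01, 5))
  labels2 <- c(labels, "A", "B")
  expect_setequal(tomek_links(x2, labels2), c(21, 22))
})

test_that("rebalancing equalizes the training classes and imputes internally", {
  fx <- sep_fixture()
  x <- fx$x
  x[sample(length(x), 50)] <- NA
  reb <- suppressWarnings(
    rebalance_smote_tomek(x, fx$labels, k_neighbors = 5, seed = 1))
  expect_false(anyNA(reb$x))
  expect_true(all(reb$counts_after_smote == max(table(fx$labels))))
  expect_lte(nrow(reb$x), sum(reb$counts_after_smote))
})

test_that("training reaches near-zero loss on separable classes", {
  # 200 samples per class, effects of 1.5 against noise SD 0.2
  fx <- sep_fixture(n_per = 200, effect = 1.5)
  spec <- model_spec("csf")   # full 300-round CSF specification
  fit <- train_model(fx$x, fx$labels, spec)
  expect_lt(fit$train_logloss, 0.05)
  pr <- predict_probs(fit, fx$x)
  expect_gt(mean(pr$class == fx$labels), 0.99)
})

test_that("log loss has its analytic anchors", {
  truth <- rep(c("CO", "AD", "PD", "FTD", "DLB"), each = 2)
  uniform <- matrix(0.2, 10, 5,
                    dimnames = list(NULL, c("CO", "AD", "PD", "FTD", "DLB")))
  expect_equal(multiclass_logloss(truth, uniform), log(5))
  perfect <- matrix(0, 10, 5,
                    dimnames = list(NULL, c("CO", "AD", "PD", "FTD", "DLB")))
  perfect[cbind(1:10, match(truth, colnames(perfect)))] <- 1
  expect_equal(multiclass_logloss(truth, perfect), 0)
})

test_that("probability outputs live on the simplex with ordered tie-break", {
  fx <- sep_fixture(n_per = 20)
  fit <- train_model(fx$x, fx$labels, model_spec(n_rounds = 40))
  pr <- predict_probs(fit, fx$x)
  expect_true(all(abs(rowSums(pr$probs) - 1) < 1e-9))
  expect_true(all(pr$probs >= 0 & pr$probs <= 1))
  # documented argmax behaviour: (0.1,0.6,0.2,0.05,0.05) -> AD;
  # exact tie (0.5,0.5,0,0,0) -> CO, the first label in the fixed order
  probs <- rbind(c(0.1, 0.6, 0.2, 0.05, 0.05), c(0.5, 0.5, 0, 0, 0))
  colnames(probs) <- c("CO", "AD", "PD", "FTD", "DLB")
  cls <- colnames(probs)[max.col(probs, ties.method = "first")]
  expect_equal(cls, c("AD", "CO"))
  b <- binarize_one_vs_all(probs, c("AD", "CO"), "AD")
  expect_equal(b$pred_positive, c(TRUE, FALSE))
})

test_that("feature-contract errors are explicit", {
  fx <- sep_fixture(n_per = 10)
  x_bad <- fx$x
  x_bad[, 3] <- NA
  expect_error(train_model(x_bad, fx$labels, model_spec(n_rounds = 5)),
               "fully missing.*f3")
  fit <- train_model(fx$x, fx$labels, model_spec(n_rounds = 5))
  expect_error(predict_probs(fit, fx$x[, -1]), "missing required")
  x_extra <- cbind(fx$x, junk = 1)
  expect_warning(predict_probs(fit, x_extra), "extra")
  expect_error(train_model(fx$x, sub("DLB", "XX", fx$labels),
                           model_spec(n_rounds = 5)), "outside")
})

test_that("training is deterministic under fixed seed and single thread", {
  fx <- sep_fixture(n_per = 15)
  f1 <- train_model(fx$x, fx$labels, model_spec(n_rounds = 30))
  f2 <- train_model(fx$x, fx$labels, model_spec(n_rounds = 30))
  expect_identical(predict_probs(f1, fx$x)$probs,
                   predict_probs(f2, fx$x)$probs)
})

test_that("nd_fit leaves the test partition untouched by rebalancing", {
  fx <- sep_fixture(n_per = 20)
  m1 <- nd_fit(fx$x, fx$labels, model_spec(n_rounds = 30), rebalance = TRUE)
  m2 <- nd_fit(fx$x, fx$labels, model_spec(n_rounds = 30), rebalance = FALSE)
  expect_identical(m1$split$test, m2$split$test)
  expect_identical(fx$x[m1$split$test, ], fx$x[m2$split$test, ])
  expect_equal(m1$test_labels, m2$test_labels)
})

test_that("zero-shot summaries cover groups, CIs and edge cases", {
  fx <- sep_fixture(n_per = 20)
  fit <- train_model(fx$x, fx$labels, model_spec(n_rounds = 40))
  zs <- zero_shot_apply(fit, fx$x[1:7, ], c(rep("G1", 6), "G2"),
                        n_boot = 100)
  expect_setequal(unique(zs$group), c("G1", "G2"))
  for (g in c("G1", "G2")) {
    sub <- zs[zs$group == g, ]
    expect_equal(sum(sub$mean_prob), 1, tolerance = 1e-9)
    expect_equal(sum(sub$frac_assigned), 1, tolerance = 1e-12)
  }
  # singleton group: mean equals that sample's vector, degenerate CI
  g2 <- zs[zs$group == "G2", ]
  pr <- predict_probs(fit, fx$x[7, , drop = FALSE])$probs
  expect_equal(g2$mean_prob, unname(pr[1, ]))
  expect_equal(g2$ci_lo, g2$ci_hi)
})
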