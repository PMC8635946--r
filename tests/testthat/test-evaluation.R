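test_that("auc_score matches brute-force pair counting, with ties at 1/2", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(auc_score(c(0.5, 0.5), c(1, 0)), 0.5)
  for (seed in 1:10) {
    set.seed(seed)
    scores <- sample(seq(0, 1, by = 0.1), 20, replace = TRUE)
    labels <- rbinom(20, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(auc_score(scores, labels), auc_bruteforce(scores, labels))
  }
  expect_error(auc_score(c(1, 2), c(1, 1)), "negative")
  # independent library cross-check
  set.seed(99)
  s <- runif(50); l <- rbinom(50, 1, 0.3); l[1:2] <- c(0, 1)
  expect_equal(auc_score(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE))))
})

test_that("aupr_score matches the threshold-sweep oracle", {
  expect_equal(aupr_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # a single positive ranked last among k items
  k <- 7
  expect_equal(aupr_score(seq(k, 1), c(rep(0, k - 1), 1)), 1 / k)
  for (seed in 1:10) {
    set.seed(seed)
    scores <- sample(seq(0, 1, by = 0.1), 20, replace = TRUE)
    labels <- rbinom(20, 1, 0.4)
    if (sum(labels) == 0) labels[1] <- 1
    expect_equal(aupr_score(scores, labels), aupr_bruteforce(scores, labels))
  }
  expect_error(aupr_score(c(1, 2), c(0, 0)), "positive")
})

test_that("ranking metrics are invariant to monotone score transforms", {
  set.seed(21)
  scores <- runif(30)
  labels <- rbinom(30, 1, 0.3)
  labels[1:2] <- c(0, 1)
  for (f in list(function(x) 2 * x + 3, exp, function(x) x^3)) {
    expect_equal(auc_score(f(scores), labels), auc_score(scores, labels))
    expect_equal(aupr_score(f(scores), labels), aupr_score(scores, labels))
  }
})

test_that("thresholded metrics match hand confusion arithmetic", {
  # fixture with TP=6, FP=8, TN=120, FN=1 after taking the top 14 of 135
  labels <- c(rep(1, 6), rep(0, 8), rep(0, 120), 1)
  scores <- c(seq(135, 122), seq(121, 2), 1)
  tm <- thresholded_metrics(scores, labels, top_fraction = 14 / 135)
  expect_equal(tm$tp, 6); expect_equal(tm$fp, 8)
  expect_equal(tm$tn, 120); expect_equal(tm$fn, 1)
  expect_equal(tm$sensitivity, 100 * 6 / 7)
  expect_equal(tm$precision, 100 * 6 / 14)
  expect_equal(tm$specificity, 100 * 120 / 128)
  expect_equal(tm$accuracy, 100 * 126 / 135)
  # exact ceiling arithmetic: 200 pairs at 1% -> 2 predicted positives
  set.seed(1)
  tm2 <- thresholded_metrics(runif(200), rbinom(200, 1, 0.1), 0.01)
  expect_equal(tm2$tp + tm2$fp, 2)
  # perfect predictions at the exact positive rate
  lab <- c(rep(1, 5), rep(0, 95))
  tm3 <- thresholded_metrics(lab, lab, 0.05)
  expect_equal(c(tm3$accuracy, tm3$sensitivity, tm3$specificity, tm3$precision),
               rep(100, 4))
})

test_that("thresholded sensitivity is nondecreasing in the top fraction", {
  set.seed(22)
  scores <- runif(100)
  labels <- rbinom(100, 1, 0.2)
  sens <- vapply(c(0.01, 0.05, 0.1, 0.3, 1),
                 function(f) thresholded_metrics(scores, labels, f)$sensitivity,
                 numeric(1))
  expect_true(all(diff(sens) >= 0))
})

test_that("pair folds partition all pairs exactly once, reproducibly", {
  sim <- simulate_dti(15, 10, density = 0.1, seed = 3)
  f1 <- dtifusion:::make_pair_folds(sim$dataset$Y, 10, seed = 7)
  f2 <- dtifusion:::make_pair_folds(sim$dataset$Y, 10, seed = 7)
  expect_identical(f1, f2)
  expect_equal(length(f1), 150)
  expect_true(all(f1 %in% 1:10))
  # stratification: positives spread across folds
  flat <- as.vector(t(sim$dataset$Y))
  pos_per_fold <- table(f1[flat == 1])
  expect_lte(max(pos_per_fold) - min(pos_per_fold), 1)
  expect_false(identical(f1, dtifusion:::make_pair_folds(sim$dataset$Y, 10, 8)))
})

test_that("cross_validate returns a coherent, reproducible report", {
  sim <- simulate_dti(20, 12, density = 0.12, hide_fraction = 0, seed = 4)
  cfg <- dti_config(n_folds = 3, seed = 5, top_fraction = 0.05,
                    fusion_weights = c(1 / 3, 1 / 3, 1 / 3))
  rep1 <- cross_validate(sim$dataset, cfg)
  rep2 <- cross_validate(sim$dataset, cfg)
  expect_identical(glance(rep1), glance(rep2))
  expect_equal(sum(rep1$per_fold$n_test), 240)
  expect_equal(rep1$auc, mean(rep1$per_fold$auc))
  expect_equal(rep1$aupr, mean(rep1$per_fold$aupr))
  expect_true(all(rep1$per_fold$auc >= 0 & rep1$per_fold$auc <= 1))
  expect_true(rep1$accuracy >= 0 && rep1$accuracy <= 100)
  expect_s3_class(tidy(rep1), "tbl_df")
  expect_s3_class(autoplot(rep1), "ggplot")
})

test_that("held-out scores never depend on the held-out label", {
  sim <- simulate_dti(15, 10, density = 0.12, hide_fraction = 0, seed = 9)
  ds <- sim$dataset
  cfg <- dti_config(fusion_weights = c(1 / 3, 1 / 3, 1 / 3))
  folds <- dtifusion:::make_pair_folds(ds$Y, 5, seed = 2)
  test_idx <- which(folds == 1)
  base <- dtifusion:::score_fold(ds, test_idx, cfg)
  set.seed(31)
  for (probe in sample(seq_along(test_idx), 5)) {
    flipped <- ds
    flat <- as.vector(t(flipped$Y))
    flat[test_idx[probe]] <- 1 - flat[test_idx[probe]]
    flipped$Y <- matrix(flat, nrow(ds$Y), ncol(ds$Y), byrow = TRUE,
                        dimnames = dimnames(ds$Y))
    flipped_scores <- dtifusion:::score_fold(flipped, test_idx, cfg)
    expect_identical(flipped_scores[probe], base[probe])
  }
})

test_that("drug-wise folds hold out whole drug rows", {
  sim <- simulate_dti(12, 8, density = 0.15, hide_fraction = 0, seed = 10)
  cfg <- dti_config(n_folds = 3, cv_mode = "drug", seed = 2,
                    fusion_weights = c(1 / 3, 1 / 3, 1 / 3))
  rep <- suppressWarnings(cross_validate(sim$dataset, cfg))
  expect_equal(sum(rep$per_fold$n_test) %% 8, 0)
  expect_true(all(rep$per_fold$n_test %% 8 == 0))
})
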