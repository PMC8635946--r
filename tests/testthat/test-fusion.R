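test_that("screening lets a similar drug inherit its neighbour's target", {
  # d1 interacts with t1; d2 is highly similar to d1 and inherits t1
  Y <- matrix(c(1, 0, 0, 0), 2, byrow = TRUE,
              dimnames = list(c("d1", "d2"), c("t1", "t2")))
  S_d <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(c("d1", "d2"), c("d1", "d2")))
  S_t <- diag(2); dimnames(S_t) <- list(c("t1", "t2"), c("t1", "t2"))
  ds <- dti_dataset(Y, S_d, S_t)
  scr <- similarity_screen(ds, dti_config(theta_sim = 0.7))
  expect_equal(scr$Y1["d2", "t1"], 1)
  expect_equal(sum(scr$Y1), 2)
  expect_equal(scr$added$drug_id, "d2")
  expect_equal(scr$added$target_id, "t1")
  # threshold above every off-diagonal similarity: nothing happens
  scr2 <- similarity_screen(ds, dti_config(theta_sim = 0.95))
  expect_identical(scr2$Y1, Y)
  expect_equal(nrow(scr2$added), 0)
})

test_that("screening matches the exhaustive double-loop oracle", {
  for (seed in 1:6) {
    ds <- toy_dataset(n = 10, m = 8, seed = seed, density = 0.25)
    for (theta in c(0.5, 0.7, 0.9)) {
      scr <- similarity_screen(ds, dti_config(theta_sim = theta))
      expect_identical(scr$Y1, screen_bruteforce(ds$Y, ds$S_d, theta))
      # never deletes a known positive
      expect_true(all(scr$Y1 >= ds$Y))
      expect_equal(nrow(scr$added), sum(scr$Y1) - sum(ds$Y))
    }
  }
})

test_that("top-k screening qualifies exactly each drug's k nearest neighbours", {
  ds <- toy_dataset(n = 6, m = 5, seed = 4, density = 0.3)
  scr <- similarity_screen(ds, dti_config(screen_top_k = 1))
  # oracle: each drug inherits from its single most similar other drug
  Y1 <- ds$Y
  for (b in seq_len(6)) {
    sims <- ds$S_d[b, ]; sims[b] <- -Inf
    a <- which.max(sims)
    Y1[b, ds$Y[a, ] == 1] <- 1
  }
  expect_identical(scr$Y1, Y1)
})

test_that("min-max normalization maps to [0,1] and zeroes constants", {
  M <- matrix(c(2, 4, 6, 3), 2)
  expect_equal(minmax_normalize(M), (M - 2) / 4)
  expect_equal(minmax_normalize(matrix(5, 2, 2)), matrix(0, 2, 2))
  B <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(minmax_normalize(B), B)
})

test_that("weighted fusion is a convex elementwise combination", {
  set.seed(2)
  mats <- list(matrix(runif(6), 2), matrix(runif(6), 2), matrix(runif(6), 2))
  w <- c(0.5, 0.3, 0.2)
  fused <- weighted_fuse(mats, w)
  norm <- lapply(mats, minmax_normalize)
  oracle <- w[1] * norm[[1]] + w[2] * norm[[2]] + w[3] * norm[[3]]
  expect_equal(fused, oracle)
  # convex hull bound
  lo <- pmin(norm[[1]], pmin(norm[[2]], norm[[3]]))
  hi <- pmax(norm[[1]], pmax(norm[[2]], norm[[3]]))
  expect_true(all(fused >= lo - 1e-12 & fused <= hi + 1e-12))
  # single source, weight 1
  expect_equal(weighted_fuse(mats[1], 1), norm[[1]])
  # invalid weights
  expect_error(weighted_fuse(mats, c(0.5, 0.5)), "one weight per")
  expect_error(weighted_fuse(mats, c(0.5, 0.4, 0.2)), "sum to 1")
})

test_that("equal-weight fusion equals the average baseline", {
  set.seed(3)
  mats <- list(matrix(runif(12), 3), matrix(runif(12), 3), matrix(runif(12), 3))
  fused <- weighted_fuse(mats, rep(1 / 3, 3))
  ave <- Reduce(`+`, lapply(mats, minmax_normalize)) / 3
  expect_equal(fused, ave)
})

test_that("vote fusion implements per-cell majority", {
  B <- function(v) matrix(v, 1)
  # (1,1,0) -> 1; (1,0,0) -> 0, via sources binarized at half the cells
  m1 <- B(c(1, 1, 0, 0)); m2 <- B(c(1, 0, 1, 0)); m3 <- B(c(0, 1, 1, 0))
  out <- vote_fuse(list(m1, m2, m3), binarize_fraction = 0.5)
  expect_equal(out, B(c(1, 1, 1, 0)))
  expect_error(vote_fuse(list(m1, m2), 0.5), "odd")
  # identical binary sources pass through
  expect_equal(vote_fuse(list(m1, m1, m1), 0.5), m1)
  # random fixture vs exhaustive per-cell majority oracle
  set.seed(8)
  mats <- lapply(1:3, function(i) matrix(runif(40), 5))
  frac <- 0.3
  bin <- lapply(mats, dtifusion:::binarize_top, frac)
  oracle <- matrix(0, 5, 8)
  for (i in 1:5) for (j in 1:8) {
    oracle[i, j] <- (bin[[1]][i, j] + bin[[2]][i, j] + bin[[3]][i, j] >= 2) * 1
  }
  expect_equal(vote_fuse(mats, frac), oracle)
})

test_that("performance weights favour an oracle source and sum to 1", {
  sim <- standard_benchmark(2)
  truth <- sim$Y_true
  fns <- list(
    oracle = function(ds) truth,
    noise1 = function(ds) {
      set.seed(1); matrix(runif(length(ds$Y)), nrow(ds$Y))
    },
    noise2 = function(ds) {
      set.seed(2); matrix(runif(length(ds$Y)), nrow(ds$Y))
    }
  )
  w <- performance_weights(sim$dataset, fns, inner_folds = 3, seed = 1)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(names(which.max(w)), "oracle")
  # identical sources get equal weights
  w2 <- performance_weights(sim$dataset, list(a = fns$oracle, b = fns$oracle),
                            inner_folds = 3, seed = 1)
  expect_equal(unname(w2), c(0.5, 0.5))
})

test_that("all-zero inner AUPRs fall back to equal weights with a warning", {
  ds <- toy_dataset(n = 6, m = 5, seed = 9, density = 0.3)
  ds$Y[] <- 0   # no positives: every inner fold is skipped, all AUPRs stay 0
  zero <- function(ds) matrix(0, nrow(ds$Y), ncol(ds$Y))
  expect_warning(
    w <- performance_weights(ds, list(a = zero, b = zero), 2, 1),
    "equal weights"
  )
  expect_equal(unname(w), c(0.5, 0.5))
})

test_that("training-matrix revision promotes the top unlabeled pairs", {
  set.seed(5)
  Y <- matrix(rbinom(20, 1, 0.3), 5, 4)
  S <- matrix(runif(20), 5, 4)
  # sort-based oracle over unlabeled pairs (row-major, ties by position)
  flatY <- as.vector(t(Y)); flatS <- as.vector(t(S))
  unlab <- which(flatY == 0)
  kk <- ceiling(0.1 * length(unlab))
  sel <- unlab[order(-flatS[unlab], unlab)][seq_len(kk)]
  oracle <- flatY; oracle[sel] <- 1
  oracle <- matrix(oracle, 5, 4, byrow = TRUE)
  rev <- revise_training_matrix(Y, S, 0.1)
  expect_equal(rev$revised, oracle)
  expect_equal(nrow(rev$added), kk)
  expect_true(all(rev$revised >= Y))
  # fraction 0 is the identity
  expect_equal(revise_training_matrix(Y, S, 0)$revised, Y)
  expect_error(revise_training_matrix(Y, S, 1.5), "select_fraction")
})

test_that("revision sets are nested in the selection fraction", {
  set.seed(6)
  Y <- matrix(rbinom(48, 1, 0.2), 8, 6)
  S <- matrix(runif(48), 8, 6)
  prev <- NULL
  for (f in c(0.05, 0.1, 0.2, 0.5)) {
    added <- revise_training_matrix(Y, S, f)$added
    keys <- paste(added$drug, added$target)
    if (!is.null(prev)) expect_true(all(prev %in% keys))
    prev <- keys
  }
})

test_that("zero-score pairs are never promoted", {
  Y <- matrix(0, 2, 2)
  S <- matrix(c(0, 0, 0.4, 0), 2, byrow = TRUE)
  rev <- revise_training_matrix(Y, S, 1)
  expect_equal(sum(rev$revised), 1)
  expect_equal(rev$added$score, 0.4)
})
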