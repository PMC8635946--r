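#' Screen unlabeled pairs by drug similarity
#'
#' If drug `a` is highly similar to drug `b` (`S_d(a, b) >= theta_sim`, or `a`
#' is among `b`'s `screen_top_k` most similar drugs) and `a` is known to
#' interact with target `t` while the pair `(b, t)` is unlabeled, the pair is
#' assumed to interact and is added to the positives. Propagation is
#' single-step: inherited interactions are not propagated further.
#'
#' @param dataset a [dti_dataset].
#' @param config a [dti_config]; uses `theta_sim` or `screen_top_k`.
#' @return A list with `Y1` (the binary revised matrix, `Y1 >= Y` elementwise)
#'   and `added`, a tibble of the added pairs (`drug_id`, `target_id`, `drug`,
#'   `target`, `similarity` of the closest donor drug).
#' @export
similarity_screen <- function(dataset, config = dti_config()) {
  stopifnot(inherits(dataset, "dti_dataset"))
  S <- dataset$S_d
  Y <- dataset$Y
  n <- nrow(Y)
  A <- matrix(FALSE, n, n)
  if (!is.null(config$screen_top_k)) {
    k <- min(config$screen_top_k, n - 1L)
    for (b in seq_len(n)) {
      sims <- S[b, ]
      sims[b] <- -Inf
      A[b, order(sims, decreasing = TRUE)[seq_len(k)]] <- TRUE
    }
  } else {
    A <- S >= config$theta_sim
    diag(A) <- FALSE
  }
  # donor similarity for each unlabeled pair: max over similar drugs a with Y(a,t)=1
  donor <- matrix(0, n, ncol(Y))
  for (b in seq_len(n)) {
    donors <- which(A[b, ])
    if (length(donors)) {
      donor[b, ] <- apply(S[b, donors] * Y[donors, , drop = FALSE], 2, max)
    }
  }
  add <- donor > 0 & Y == 0
  Y1 <- Y
  Y1[add] <- 1
  idx <- which(add, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  added <- tibble::tibble(
    drug_id = dataset$drug_ids[idx[, 1]],
    target_id = dataset$target_ids[idx[, 2]],
    drug = as.integer(idx[, 1]),
    target = as.integer(idx[, 2]),
    similarity = donor[idx]
  )
  list(Y1 = Y1, added = added)
}

#' Min-max normalization of a score matrix
#'
#' Affine map onto `[0, 1]`; a constant matrix maps to all zeros.
#'
#' @param M numeric matrix with finite entries.
#' @return The normalized matrix.
#' @export
minmax_normalize <- function(M) {
  stopifnot(all(is.finite(M)))
  rng <- range(M)
  if (rng[1] == rng[2]) return(M * 0)
  (M - rng[1]) / (rng[2] - rng[1])
}

#' Weighted fusion of score matrices
#'
#' `Y_final = sum_i alpha_i * normalize(Y_i)`, with each source min-max
#' normalized first so that binary, probability-scaled and RLS-scaled sources
#' contribute on a common `[0, 1]` scale.
#'
#' @param score_matrices list of equally shaped score matrices.
#' @param weights numeric weights in `[0, 1]` summing to 1 (one per source).
#' @return The fused score matrix.
#' @export
weighted_fuse <- function(score_matrices, weights) {
  k <- length(score_matrices)
  if (length(weights) != k) stop("need one weight per score matrix")
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  dims <- lapply(score_matrices, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("score matrices must share a shape")
  }
  out <- matrix(0, dims[[1]][1], dims[[1]][2])
  for (i in seq_len(k)) out <- out + weights[i] * minmax_normalize(score_matrices[[i]])
  dimnames(out) <- dimnames(score_matrices[[1]])
  out
}

#' Majority-vote fusion of score matrices
#'
#' Each source is binarized at its own top `binarize_fraction` of pairs
#' (ties broken by score, then row, then column); a pair is fused to 1 when a
#' strict majority of sources vote 1.
#'
#' @param score_matrices list of an odd number (>= 3) of score matrices.
#' @param binarize_fraction fraction of pairs each source calls positive.
#' @return A binary fused matrix.
#' @export
vote_fuse <- function(score_matrices, binarize_fraction = 0.01) {
  k <- length(score_matrices)
  if (k < 3 || k %% 2 == 0) stop("vote fusion needs an odd number (>= 3) of sources")
  votes <- Reduce(`+`, lapply(score_matrices, binarize_top, binarize_fraction))
  out <- (votes >= ceiling((k + 1) / 2)) * 1
  dimnames(out) <- dimnames(score_matrices[[1]])
  out
}

# Binary matrix marking the top ceiling(fraction * n * m) pairs of M,
# ties broken by (score desc, row, column).
binarize_top <- function(M, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  N <- length(M)
  kk <- ceiling(fraction * N)
  flat <- as.vector(t(M))          # row-major: index order = (row, col) lexicographic
  ord <- order(-flat, seq_len(N))
  out <- numeric(N)
  out[ord[seq_len(kk)]] <- 1
  matrix(out, nrow(M), ncol(M), byrow = TRUE)
}

#' Performance-based fusion weights
#'
#' Estimates each source's area under the precision-recall curve by inner
#' pair-wise cross-validation on the training data only (held-out positives
#' are masked to 0 before each source is run) and sets
#' `alpha_i = AUPR_i / sum_j AUPR_j`, so the better-performing source
#' contributes more to the fusion.
#'
#' @param dataset the training [dti_dataset].
#' @param score_fns named list of functions, each mapping a masked
#'   `dti_dataset` to a score matrix.
#' @param inner_folds number of inner folds (default 3).
#' @param seed seed for the inner fold assignment.
#' @return A named weight vector summing to 1.
#' @export
performance_weights <- function(dataset, score_fns, inner_folds = 3, seed = 1) {
  stopifnot(length(score_fns) >= 2)
  folds <- make_pair_folds(dataset$Y, inner_folds, seed)
  auprs <- numeric(length(score_fns))
  Yflat <- as.vector(t(dataset$Y))
  for (f in seq_len(inner_folds)) {
    test_idx <- which(folds == f)
    if (length(unique(Yflat[test_idx])) < 2) next
    masked <- mask_pairs(dataset, test_idx)
    for (s in seq_along(score_fns)) {
      scores <- as.vector(t(score_fns[[s]](masked)))
      auprs[s] <- auprs[s] + aupr_score(scores[test_idx], Yflat[test_idx])
    }
  }
  if (sum(auprs) == 0) {
    warning("all inner-CV AUPRs are zero; falling back to equal weights")
    w <- rep(1 / length(score_fns), length(score_fns))
  } else {
    w <- auprs / sum(auprs)
  }
  names(w) <- names(score_fns)
  w
}

#' Revise the training interaction matrix from a fused score
#'
#' Promotes the top `select_fraction` of *unlabeled* pairs, ranked by the
#' fused score (ties broken by row then column), to positives. Known
#' positives are never removed. Pairs whose score is exactly 0 are never
#' promoted, even if the quota is not filled.
#'
#' @param Y the original binary interaction matrix.
#' @param Y_final the fused score matrix (same shape).
#' @param select_fraction fraction of unlabeled pairs to promote, in `[0, 1]`.
#' @return A list with `revised` (binary matrix, `revised >= Y`) and `added`,
#'   a tibble audit of the promoted pairs (`drug`, `target`, `score`, `rank`).
#' @export
revise_training_matrix <- function(Y, Y_final, select_fraction = 0.01) {
  stopifnot(all(dim(Y) == dim(Y_final)))
  if (select_fraction < 0 || select_fraction > 1) {
    stop("select_fraction must lie in [0, 1]")
  }
  flatY <- as.vector(t(Y))
  flatS <- as.vector(t(Y_final))
  unlab <- which(flatY == 0)
  kk <- if (select_fraction == 0) 0L else ceiling(select_fraction * length(unlab))
  ord <- unlab[order(-flatS[unlab], unlab)]
  ord <- ord[flatS[ord] > 0]
  sel <- ord[seq_len(min(kk, length(ord)))]
  revised <- flatY
  revised[sel] <- 1
  revised <- matrix(revised, nrow(Y), ncol(Y), byrow = TRUE,
                    dimnames = dimnames(Y))
  m <- ncol(Y)
  added <- tibble::tibble(
    drug = as.integer((sel - 1) %/% m + 1),
    target = as.integer((sel - 1) %% m + 1),
    score = flatS[sel],
    rank = seq_along(sel)
  )
  list(revised = revised, added = added)
}
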