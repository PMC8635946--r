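#' Transition matrix of the drug-target heterogeneous network
#'
#' Builds the row-stochastic transition matrix
#' `W = [W_TT W_TD; W_DT W_DD]` over the `m + n` nodes of the two-layer
#' network (targets first, then drugs). For an entity with at least one
#' interaction, the intra-layer block row is `(1 - lambda)` times the
#' row-normalized similarity and the inter-layer row is `lambda` times the
#' row-normalized interaction profile; with no interactions the full mass
#' stays in the similarity layer. A node with no similarity mass and no
#' interactions gets a self-loop, so every row sums to exactly 1.
#'
#' @param dataset a [dti_dataset] (its `Y` may be a screening-revised matrix).
#' @param jump_lambda inter-layer jump probability in `[0, 1]`.
#' @return A list with the full matrix `W` (`(m+n) x (m+n)`), the four blocks
#'   `W_TT`, `W_TD`, `W_DT`, `W_DD`, and `jump_lambda`.
#' @export
build_transition <- function(dataset, jump_lambda = 0.5) {
  stopifnot(inherits(dataset, "dti_dataset"),
            jump_lambda >= 0, jump_lambda <= 1)
  Y <- dataset$Y
  S_d <- dataset$S_d
  S_t <- dataset$S_t
  if (min(S_d) < 0 || min(S_t) < 0) stop("negative similarity entries")
  n <- nrow(Y); m <- ncol(Y)

  block_rows <- function(S, A, lambda) {
    # rows over [similarity layer | interaction layer]
    ssum <- rowSums(S); asum <- rowSums(A)
    intra <- matrix(0, nrow(S), ncol(S))
    inter <- matrix(0, nrow(A), ncol(A))
    for (i in seq_len(nrow(S))) {
      if (ssum[i] > 0 && asum[i] > 0) {
        intra[i, ] <- (1 - lambda) * S[i, ] / ssum[i]
        inter[i, ] <- lambda * A[i, ] / asum[i]
      } else if (ssum[i] > 0) {
        intra[i, ] <- S[i, ] / ssum[i]
      } else if (asum[i] > 0) {
        inter[i, ] <- A[i, ] / asum[i]
      } else {
        intra[i, i] <- 1
      }
    }
    list(intra = intra, inter = inter)
  }

  tb <- block_rows(S_t, t(Y), jump_lambda)
  db <- block_rows(S_d, Y, jump_lambda)
  W <- rbind(cbind(tb$intra, tb$inter), cbind(db$inter, db$intra))
  node_ids <- c(dataset$target_ids, dataset$drug_ids)
  dimnames(W) <- list(node_ids, node_ids)
  list(W = W, W_TT = tb$intra, W_TD = tb$inter, W_DT = db$inter,
       W_DD = db$intra, jump_lambda = jump_lambda)
}

#' Random walk with restart
#'
#' Iterates `p <- (1 - c) W' p + c p0` until the norm of the difference
#' between successive iterates does not exceed `tol`.
#'
#' @param W row-stochastic transition matrix (or the list from
#'   [build_transition()]).
#' @param p0 restart vector (sums to 1).
#' @param restart_c restart probability in `(0, 1]`.
#' @param tol stopping tolerance on `||p_{t+1} - p_t||` (default `1e-10`).
#' @param max_iter iteration cap; exceeding it is an error reporting the final
#'   gap.
#' @return The stationary vector `p` with attributes `iterations` and `gap`.
#' @export
rwr_walk <- function(W, p0, restart_c = 0.7, tol = 1e-10, max_iter = 10000) {
  if (is.list(W)) W <- W$W
  stopifnot(restart_c > 0, restart_c <= 1, abs(sum(p0) - 1) < 1e-10)
  Wt <- t(W)
  p <- p0
  for (it in seq_len(max_iter)) {
    p_new <- (1 - restart_c) * as.vector(Wt %*% p) + restart_c * p0
    gap <- sqrt(sum((p_new - p)^2))
    p <- p_new
    if (gap <= tol) {
      attr(p, "iterations") <- it
      attr(p, "gap") <- gap
      return(p)
    }
  }
  stop("random walk did not converge in ", max_iter,
       " iterations (final gap ", format(gap), ")")
}

#' Restart vector for a drug seed
#'
#' `p0 = [(1 - eta) u0; eta v0]` over the `m + n` network nodes (targets
#' first): `v0` is the indicator of the seed drug and `u0` is the drug's known
#' interaction profile normalized to sum 1, or uniform over all targets when
#' the profile is empty.
#'
#' @param dataset a [dti_dataset].
#' @param drug_index seed drug (row index of `Y`).
#' @param eta drug-block seed mass, in `(0, 1)`.
#' @return A probability vector of length `m + n`.
#' @export
restart_vector <- function(dataset, drug_index, eta = 0.5) {
  stopifnot(inherits(dataset, "dti_dataset"), eta > 0, eta < 1)
  n <- nrow(dataset$Y); m <- ncol(dataset$Y)
  if (drug_index < 1 || drug_index > n) stop("drug_index out of range")
  prof <- unname(dataset$Y[drug_index, ])
  u0 <- if (sum(prof) > 0) prof / sum(prof) else rep(1 / m, m)
  v0 <- numeric(n)
  v0[drug_index] <- 1
  c((1 - eta) * u0, eta * v0)
}

#' Random-walk-with-restart score matrix
#'
#' Runs one restart walk per drug seed on the heterogeneous network; row `i`
#' of the returned matrix is the target-block of that walk's stationary
#' vector, i.e. the stationary probability of ending at each target when
#' restarting around drug `i` (the pipeline's second source).
#'
#' @param dataset a [dti_dataset] (possibly screening-revised).
#' @param config a [dti_config]; uses `restart_c`, `eta`, `jump_lambda`,
#'   `rwr_tol`, `rwr_max_iter`.
#' @return The `n x m` score matrix.
#' @export
rwr_score <- function(dataset, config = dti_config()) {
  stopifnot(inherits(dataset, "dti_dataset"))
  tm <- build_transition(dataset, config$jump_lambda)
  n <- nrow(dataset$Y); m <- ncol(dataset$Y)
  out <- matrix(0, n, m, dimnames = dimnames(dataset$Y))
  for (i in seq_len(n)) {
    p0 <- restart_vector(dataset, i, config$eta)
    p <- rwr_walk(tm$W, p0, config$restart_c, config$rwr_tol, config$rwr_max_iter)
    out[i, ] <- p[seq_len(m)]
  }
  out
}
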