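#' Weighted-nearest-neighbour interaction profile for a new drug
#'
#' A drug with no known interactions gets an inferred profile
#' `sum_i w_i * y_i`, where the training drugs are sorted by decreasing
#' similarity to the new drug and `w_i = decay^(rank_i - 1)`.
#'
#' @param similarities similarity of the new drug to each training drug.
#' @param Y training interaction matrix (one row per training drug).
#' @param decay geometric decay `T` in `(0, 1]`.
#' @param normalize cap the inferred profile at 1 (default `TRUE`).
#' @return A numeric interaction-profile vector of length `ncol(Y)`.
#' @export
wnn_profile <- function(similarities, Y, decay = 0.7, normalize = TRUE) {
  Y <- as.matrix(Y)
  stopifnot(length(similarities) == nrow(Y), decay > 0, decay <= 1)
  if (nrow(Y) == 0) stop("empty training set")
  ord <- order(similarities, decreasing = TRUE)
  w <- decay^(seq_along(ord) - 1)
  profile <- as.vector(crossprod(Y[ord, , drop = FALSE], w))
  if (normalize) profile <- pmin(pmax(profile, 0), 1)
  profile
}

#' Regularized least-squares prediction
#'
#' Computes `K (K + sigma I)^{-1} y` by a symmetric linear solve (no explicit
#' inverse).
#'
#' @param K square symmetric kernel matrix.
#' @param y numeric label vector conformable with `K`.
#' @param sigma nonnegative ridge parameter.
#' @return The prediction vector.
#' @export
rls_predict <- function(K, y, sigma) {
  K <- as.matrix(K)
  stopifnot(nrow(K) == ncol(K), length(y) == nrow(K), sigma >= 0)
  as.vector(K %*% solve(K + sigma * diag(nrow(K)), y))
}

#' Kronecker-kernel regularized least squares over all drug-target pairs
#'
#' Scores every pair jointly with the pair kernel `K = K_d %x% K_t`. The
#' `n*m x n*m` system is never formed: with `K_d = V_d L V_d'` and
#' `K_t = V_t M V_t'`, the prediction is
#' `V_d [ (L_i M_j / (L_i M_j + sigma)) * (V_d' Y V_t) ] V_t'`.
#' Negative kernel eigenvalues are clipped at zero.
#'
#' @param K_d drug kernel (`n x n`, symmetric).
#' @param K_t target kernel (`m x m`, symmetric).
#' @param Y interaction (label) matrix, `n x m`.
#' @param sigma nonnegative ridge parameter.
#' @return The `n x m` prediction matrix.
#' @export
kron_rls <- function(K_d, K_t, Y, sigma) {
  Y <- as.matrix(Y)
  stopifnot(nrow(K_d) == ncol(K_d), nrow(K_t) == ncol(K_t),
            nrow(Y) == nrow(K_d), ncol(Y) == nrow(K_t), sigma >= 0)
  if (max(abs(K_d - t(K_d))) > 1e-8 || max(abs(K_t - t(K_t))) > 1e-8) {
    stop("kron_rls requires symmetric kernels")
  }
  ed <- psd_eigen(K_d, "drug kernel")
  et <- psd_eigen(K_t, "target kernel")
  lm <- outer(ed$values, et$values)
  filt <- lm / (lm + sigma)
  filt[lm + sigma == 0] <- 0
  Z <- crossprod(ed$vectors, Y %*% et$vectors)
  out <- ed$vectors %*% (filt * Z) %*% t(et$vectors)
  dimnames(out) <- dimnames(Y)
  out
}

#' WNN-GIP score matrix
#'
#' The WNN-GIP scorer: all-zero interaction rows (new drugs) are first
#' completed with [wnn_profile()]; GIP kernels are built from the completed
#' matrix and convex-combined with the chemical/genomic similarities; the
#' completed matrix is then scored by Kronecker RLS.
#'
#' @param dataset a [dti_dataset] (possibly already revised by screening).
#' @param config a [dti_config]; uses `alpha_d`, `alpha_t`, `gamma_scale`,
#'   `sigma`, `wnn_decay`, `wnn_targets`.
#' @return The `n x m` score matrix (the pipeline's third source).
#' @export
wnn_gip_score <- function(dataset, config = dti_config()) {
  stopifnot(inherits(dataset, "dti_dataset"))
  Yw <- complete_profiles(dataset$Y, dataset$S_d, config$wnn_decay)
  if (config$wnn_targets) {
    Yw <- t(complete_profiles(t(Yw), dataset$S_t, config$wnn_decay))
  }
  K_d <- combine_kernels(dataset$S_d, gip_kernel(Yw, config$gamma_scale),
                         config$alpha_d)
  K_t <- combine_kernels(dataset$S_t, gip_kernel(t(Yw), config$gamma_scale),
                         config$alpha_t)
  kron_rls(K_d, K_t, Yw, config$sigma)
}

# Replace all-zero rows of Y with their WNN profiles (leave-self-out).
complete_profiles <- function(Y, S, decay) {
  empty <- which(rowSums(Y) == 0)
  if (length(empty) == 0 || length(empty) == nrow(Y)) {
    if (length(empty) == nrow(Y)) stop("every interaction profile is empty")
    return(Y)
  }
  out <- Y
  for (i in empty) {
    out[i, ] <- wnn_profile(S[i, -i], Y[-i, , drop = FALSE], decay)
  }
  out
}
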