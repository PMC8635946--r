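#' Gaussian interaction profile (GIP) kernel
#'
#' Computes the Gaussian kernel over the rows of an interaction-profile
#' matrix: `K(i, j) = exp(-gamma * ||y_i - y_j||^2)` with the bandwidth
#' normalized by the mean squared profile norm,
#' `gamma = gamma_scale / mean(||y_i||^2)`. Rows are drug (or target)
#' interaction profiles; pass `t(Y)` for the target-side kernel.
#'
#' @param profiles numeric matrix whose rows are interaction profiles.
#' @param gamma_scale positive bandwidth multiplier (default 1).
#' @return A symmetric unit-diagonal kernel matrix with entries in `(0, 1]`.
#' @export
gip_kernel <- function(profiles, gamma_scale = 1) {
  profiles <- as.matrix(profiles)
  stopifnot(nrow(profiles) >= 1, gamma_scale > 0)
  sq_norms <- rowSums(profiles^2)
  denom <- mean(sq_norms)
  if (denom == 0) {
    stop("all interaction profiles are zero; the GIP bandwidth is undefined ",
         "(complete new-entity profiles with wnn_profile() first)")
  }
  gamma <- gamma_scale / denom
  # ||y_i - y_j||^2 = ||y_i||^2 + ||y_j||^2 - 2 <y_i, y_j>
  d2 <- outer(sq_norms, sq_norms, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0
  K <- exp(-gamma * d2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  K
}

#' Convex combination of a similarity matrix with a GIP kernel
#'
#' The combined drug kernel is
#' `K_d = alpha * K_chemical + (1 - alpha) * K_GIP_d`; the target kernel uses
#' the genomic (sequence) similarity in place of the chemical one.
#'
#' @param K_sim chemical or genomic similarity matrix.
#' @param K_gip GIP kernel of the same entities.
#' @param alpha weight of the similarity matrix, in `[0, 1]`.
#' @return The elementwise convex combination (symmetric).
#' @export
combine_kernels <- function(K_sim, K_gip, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (!all(dim(K_sim) == dim(K_gip))) {
    stop("kernel shape mismatch: ", paste(dim(K_sim), collapse = "x"),
         " vs ", paste(dim(K_gip), collapse = "x"))
  }
  alpha * K_sim + (1 - alpha) * K_gip
}

# Eigendecomposition with negative eigenvalues clipped at zero. Chemical
# similarity matrices are often not PSD; clipping is applied only where a
# solver needs PSD kernels (Kronecker RLS), and is reported.
psd_eigen <- function(K, label = "kernel") {
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    message("clipping ", sum(e$values < 0), " negative eigenvalue(s) of the ",
            label, " (smallest: ", format(min(e$values)), ")")
  }
  e$values[e$values < 0] <- 0
  e
}
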