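#' Generate a synthetic DTI dataset with planted hidden interactions
#'
#' Draws drug and target latent vectors from a standard normal; similarities
#' are Gaussian kernels of the latent vectors (bandwidth = the median pairwise
#' latent distance, so the similarity scale is dimension-free); the true
#' interactions are the top `density * n * m` pairs of the latent inner
#' product plus Gaussian noise. A fraction of the true positives is hidden
#' (set to 0 in the observed matrix): these hidden pairs are the recovery
#' targets every scorer is benchmarked on. Because similar entities share
#' latent factors — and therefore targets — the screening, walk and kernel
#' scorers can recover the hidden pairs in principle.
#'
#' @param n_drugs,m_targets grid dimensions.
#' @param latent_dim latent-factor dimension (default 8).
#' @param density fraction of pairs that truly interact, in `(0, 1)`.
#' @param hide_fraction fraction of true positives masked in the observed
#'   matrix, in `[0, 1)`.
#' @param noise_sd standard deviation of the noise added to the latent scores.
#' @param seed integer seed; the same seed gives a bit-identical dataset.
#' @return A list with `dataset` (a [dti_dataset] holding the observed
#'   matrix), `Y_true` (the full planted truth), `hidden`, a tibble of the
#'   hidden positive pairs (`drug`, `target`), and the flat row-major indices
#'   `hidden_idx`.
#' @export
simulate_dti <- function(n_drugs = 60, m_targets = 30, latent_dim = 8,
                         density = 0.05, hide_fraction = 0.2,
                         noise_sd = 0.1, seed = 1) {
  stopifnot(n_drugs >= 2, m_targets >= 2, latent_dim >= 1,
            density > 0, density < 1, hide_fraction >= 0, hide_fraction < 1,
            noise_sd >= 0)
  n_true <- round(density * n_drugs * m_targets)
  if (n_true < 1) stop("infeasible density: no true interactions")
  rs <- make_rng(seed)
  draws <- with_rng(rs, {
    U <- matrix(stats::rnorm(n_drugs * latent_dim), n_drugs)
    V <- matrix(stats::rnorm(m_targets * latent_dim), m_targets)
    E <- matrix(stats::rnorm(n_drugs * m_targets), n_drugs)
    list(U = U, V = V, E = E)
  })
  U <- draws$U; V <- draws$V

  S_d <- latent_similarity(U)
  S_t <- latent_similarity(V)
  signal <- tcrossprod(U, V) + noise_sd * draws$E
  flat <- as.vector(t(signal))
  ord <- order(-flat, seq_along(flat))
  true_idx <- sort(ord[seq_len(n_true)])
  n_obs <- round(n_true * (1 - hide_fraction))
  hidden_idx <- if (n_obs < n_true) {
    keep <- with_rng(rs, sample(n_true, n_obs))
    sort(true_idx[-keep])
  } else integer(0)

  flatY <- numeric(n_drugs * m_targets)
  flatY[true_idx] <- 1
  Y_true <- matrix(flatY, n_drugs, m_targets, byrow = TRUE)
  flatY[hidden_idx] <- 0
  Y <- matrix(flatY, n_drugs, m_targets, byrow = TRUE)

  drug_ids <- sprintf("D%03d", seq_len(n_drugs))
  target_ids <- sprintf("T%03d", seq_len(m_targets))
  dimnames(Y) <- list(drug_ids, target_ids)
  dimnames(Y_true) <- list(drug_ids, target_ids)
  dimnames(S_d) <- list(drug_ids, drug_ids)
  dimnames(S_t) <- list(target_ids, target_ids)

  list(
    dataset = dti_dataset(Y, S_d, S_t),
    Y_true = Y_true,
    hidden = tibble::tibble(
      drug = as.integer((hidden_idx - 1) %/% m_targets + 1),
      target = as.integer((hidden_idx - 1) %% m_targets + 1)
    ),
    hidden_idx = hidden_idx
  )
}

# Gaussian-kernel similarity of latent row vectors, bandwidth = median
# pairwise distance. Unit diagonal, symmetric, entries in (0, 1].
latent_similarity <- function(X) {
  D2 <- as.matrix(stats::dist(X))^2
  med2 <- stats::median(D2[upper.tri(D2)])
  S <- exp(-D2 / (2 * med2))
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

# Run `expr` under an isolated, resumable RNG stream (the caller's
# .Random.seed is untouched).
with_rng <- function(rs, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  if (is.null(rs$state)) set.seed(rs$seed) else assign(".Random.seed", rs$state, envir = globalenv())
  out <- force(expr)
  rs$state <- get(".Random.seed", globalenv())
  out
}

#' Synthetic dataset at the nuclear-receptor benchmark's printed shape
#'
#' Convenience wrapper around [simulate_dti()] at 54 drugs x 26 targets with
#' the density chosen so the planted truth has exactly 90 interactions —
#' the shape and sparsity of the smallest of the four gold-standard datasets
#' (nuclear receptors), for smoke tests at a realistic scale.
#'
#' @param seed integer seed.
#' @param hide_fraction fraction of planted positives hidden (default 0.2).
#' @return As [simulate_dti()].
#' @export
nr_like <- function(seed = 1, hide_fraction = 0.2) {
  simulate_dti(n_drugs = 54, m_targets = 26, latent_dim = 8,
               density = 90 / (54 * 26), hide_fraction = hide_fraction,
               noise_sd = 0.1, seed = seed)
}

#' The package's standard planted-recovery benchmark specification
#'
#' One 60 x 30 dataset per seed with latent dimension 8, interaction density
#' 0.05, 20% of true positives hidden, and noise 0.1 — the conditions every
#' recovery benchmark in the package uses.
#'
#' @param seed integer seed.
#' @return As [simulate_dti()].
#' @export
standard_benchmark <- function(seed) {
  simulate_dti(n_drugs = 60, m_targets = 30, latent_dim = 8, density = 0.05,
               hide_fraction = 0.2, noise_sd = 0.1, seed = seed)
}
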