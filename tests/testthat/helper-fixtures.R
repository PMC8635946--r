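# Shared fixture builders (all generated in code; no stored data).

# Random symmetric PSD kernel with unit-ish scale.
random_psd <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  K <- crossprod(A) / n
  (K + t(K)) / 2
}

# Small labeled dti_dataset with controllable interactions.
toy_dataset <- function(n = 4, m = 3, seed = 1, density = 0.3) {
  set.seed(seed)
  drug_ids <- sprintf("D%d", seq_len(n))
  target_ids <- sprintf("T%d", seq_len(m))
  Y <- matrix(as.numeric(rbinom(n * m, 1, density)), n, m,
              dimnames = list(drug_ids, target_ids))
  if (sum(Y) == 0) Y[1, 1] <- 1
  mk_sim <- function(k, ids) {
    X <- matrix(rnorm(k * 3), k)
    S <- exp(-as.matrix(dist(X))^2 / 4)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    dimnames(S) <- list(ids, ids)
    S
  }
  dti_dataset(Y, mk_sim(n, drug_ids), mk_sim(m, target_ids))
}

# toy_dataset variant where every drug and target has >= 1 interaction, so
# no NII/WNN profile substitution is triggered.
toy_dataset_full <- function(n = 4, m = 3, seed = 1, density = 0.4) {
  ds <- toy_dataset(n, m, seed, density)
  Y <- ds$Y
  for (i in which(rowSums(Y) == 0)) Y[i, 1 + (i %% m)] <- 1
  for (j in which(colSums(Y) == 0)) Y[1 + (j %% n), j] <- 1
  dti_dataset(Y, ds$S_d, ds$S_t)
}

# Brute-force Kronecker RLS on the full n*m x n*m system (dense solve),
# independent of the eigendecomposition fast path.
kron_rls_bruteforce <- function(K_d, K_t, Y, sigma) {
  K <- kronecker(K_d, K_t)          # pair (d, t) at row-major index (d-1)*m + t
  y <- as.vector(t(Y))
  yhat <- K %*% solve(K + sigma * diag(nrow(K)), y)
  matrix(yhat, nrow(Y), ncol(Y), byrow = TRUE)
}

# O(P*N) pair-counting AUC oracle (ties count one half).
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive threshold-sweep AUPR oracle: precision/recall recomputed from
# scratch at every distinct score, step-integrated over recall.
aupr_bruteforce <- function(scores, labels) {
  P <- sum(labels == 1)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  prev_recall <- 0
  for (th in thresholds) {
    pred <- scores >= th
    tp <- sum(pred & labels == 1)
    precision <- tp / sum(pred)
    recall <- tp / P
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Exhaustive double-loop screening oracle.
screen_bruteforce <- function(Y, S, theta) {
  Y1 <- Y
  storage.mode(Y1) <- "double"
  n <- nrow(Y)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a != b && S[a, b] >= theta) {
      for (t in seq_len(ncol(Y))) {
        if (Y[a, t] == 1 && Y[b, t] == 0) Y1[b, t] <- 1
      }
    }
  }
  Y1
}
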