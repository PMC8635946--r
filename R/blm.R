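#' Neighbour-based inferred interaction profile
#'
#' For an entity with no known interactions, infers a profile as the
#' similarity-weighted mean of the training profiles,
#' `beta * sum_i s_i y_i / sum_i s_i`, so BLM local models can still be
#' trained for new drugs and targets.
#'
#' @param similarities similarity of the entity to each training entity.
#' @param Y_block training interaction matrix (one row per training entity).
#' @param beta weight of the inferred profile, in `[0, 1]`.
#' @return A profile vector with entries in `[0, beta]`.
#' @export
nii_profile <- function(similarities, Y_block, beta = 1) {
  Y_block <- as.matrix(Y_block)
  stopifnot(length(similarities) == nrow(Y_block), beta >= 0, beta <= 1)
  s <- sum(similarities)
  if (s == 0) {
    warning("all similarities are zero; inferred profile is zero")
    return(numeric(ncol(Y_block)))
  }
  beta * as.vector(crossprod(Y_block, similarities)) / s
}

#' Bipartite-local-model scores with neighbour-based profile inferring
#'
#' For each pair, a drug-side local model (RLS over the targets, labels = the
#' drug's interaction row, kernel `K_t`) and a target-side local model (RLS
#' over the drugs, labels = the target's column, kernel `K_d`) each produce a
#' score; the two sides are combined by `max` (default) or `mean`. Entities
#' with empty label vectors get a [nii_profile()] substitute first.
#'
#' @param train_Y binary training interaction matrix (typically the revised
#'   matrix).
#' @param K_d drug kernel (`n x n`).
#' @param K_t target kernel (`m x m`).
#' @param config a [dti_config]; uses `blm_sigma`, `blm_combine`, `nii_beta`.
#' @return The `n x m` score matrix.
#' @export
blm_score <- function(train_Y, K_d, K_t, config = dti_config()) {
  train_Y <- as.matrix(train_Y)
  n <- nrow(train_Y); m <- ncol(train_Y)
  stopifnot(nrow(K_d) == n, ncol(K_d) == n, nrow(K_t) == m, ncol(K_t) == m)
  sigma <- config$blm_sigma
  beta <- config$nii_beta

  Yd <- train_Y
  for (i in which(rowSums(train_Y) == 0)) {
    Yd[i, ] <- nii_profile(K_d[i, -i], train_Y[-i, , drop = FALSE], beta)
  }
  Yt <- train_Y
  for (j in which(colSums(train_Y) == 0)) {
    Yt[, j] <- nii_profile(K_t[j, -j], t(train_Y)[-j, , drop = FALSE], beta)
  }
  # H y solves the local RLS for label vector y; stacking over entities:
  H_t <- K_t %*% solve(K_t + sigma * diag(m))
  H_d <- K_d %*% solve(K_d + sigma * diag(n))
  drug_side <- Yd %*% t(H_t)
  target_side <- H_d %*% Yt
  out <- switch(config$blm_combine,
    max = pmax(drug_side, target_side),
    mean = (drug_side + target_side) / 2
  )
  dimnames(out) <- dimnames(train_Y)
  out
}

#' Run the full multisource weighted-fusion prediction pipeline
#'
#' The end-to-end chain: (1) screen unlabeled pairs by drug similarity to get
#' the binary revision `Y1`; (2) score all pairs on the screened network with
#' random walk with restart (`Y2`) and WNN-GIP (`Y3`); (3) fuse the three
#' sources — performance-weighted by default, equal-weight average or
#' majority vote as alternatives; (4) promote the top-scoring unlabeled pairs
#' into the training matrix; (5) train BLM-NII on the revised matrix for the
#' final scores. With `method = "sim"`, `"rs"` or `"ws"` the revision is
#' driven by that single source instead of the fusion.
#'
#' @param dataset a [dti_dataset].
#' @param config a [dti_config].
#' @return An object of class `dti_prediction`: `scores` (final `n x m` BLM
#'   score matrix) plus every intermediate for audit — `Y1`, `Y2`, `Y3`,
#'   `Y_final`, `revised_Y`, `screen_added`, `revision_added`, `weights`, and
#'   the `config` used.
#' @export
predict_pipeline <- function(dataset, config = dti_config()) {
  stopifnot(inherits(dataset, "dti_dataset"))
  scr <- similarity_screen(dataset, config)
  ds_rev <- dataset
  ds_rev$Y <- scr$Y1

  Y1 <- NULL; Y2 <- NULL; Y3 <- NULL; weights <- NULL
  if (config$method %in% c("fused", "sim")) Y1 <- scr$Y1
  if (config$method %in% c("fused")) {
    Y2 <- rwr_score(ds_rev, config)
    Y3 <- wnn_gip_score(ds_rev, config)
  } else if (config$method == "rs") {
    Y2 <- rwr_score(dataset, config)
  } else if (config$method == "ws") {
    Y3 <- wnn_gip_score(dataset, config)
  }

  if (config$method == "fused") {
    sources <- list(SIM = Y1, RS = Y2, WS = Y3)
    Y_final <- switch(config$fusion_mode,
      weighted = {
        weights <- if (!is.null(config$fusion_weights)) {
          stats::setNames(config$fusion_weights, names(sources))
        } else {
          performance_weights(dataset, source_functions(config),
                              config$inner_folds, config$seed)
        }
        weighted_fuse(sources, weights)
      },
      ave = {
        weights <- stats::setNames(rep(1 / 3, 3), names(sources))
        weighted_fuse(sources, weights)
      },
      vote = vote_fuse(sources, config$select_fraction +
                         sum(scr$Y1) / length(scr$Y1))
    )
  } else {
    Y_final <- minmax_normalize(switch(config$method, sim = Y1, rs = Y2, ws = Y3))
  }

  rev <- revise_training_matrix(dataset$Y, Y_final, config$select_fraction)
  K_d <- combine_kernels(dataset$S_d,
                         gip_kernel(fallback_profiles(rev$revised),
                                    config$gamma_scale),
                         config$alpha_d)
  K_t <- combine_kernels(dataset$S_t,
                         gip_kernel(fallback_profiles(t(rev$revised)),
                                    config$gamma_scale),
                         config$alpha_t)
  scores <- blm_score(rev$revised, K_d, K_t, config)
  structure(
    list(scores = scores, Y1 = Y1, Y2 = Y2, Y3 = Y3, Y_final = Y_final,
         revised_Y = rev$revised, screen_added = scr$added,
         revision_added = rev$added, weights = weights, config = config),
    class = "dti_prediction"
  )
}

# The three source scorers as functions of a (masked) dataset, for the inner
# cross-validation behind the performance weights. Each source runs on the
# screening-revised matrix, mirroring the outer pipeline.
source_functions <- function(config) {
  list(
    SIM = function(ds) similarity_screen(ds, config)$Y1,
    RS = function(ds) {
      scr <- similarity_screen(ds, config)
      ds$Y <- scr$Y1
      rwr_score(ds, config)
    },
    WS = function(ds) {
      scr <- similarity_screen(ds, config)
      ds$Y <- scr$Y1
      wnn_gip_score(ds, config)
    }
  )
}

# GIP kernels are undefined when every profile is zero (possible in heavily
# masked folds); fall back to an uninformative constant profile so the
# combined kernel degenerates gracefully to the similarity matrix side.
fallback_profiles <- function(Y) {
  if (all(Y == 0)) Y + 1 else Y
}

#' @export
print.dti_prediction <- function(x, ...) {
  cat("<dti_prediction> ", nrow(x$scores), " drugs x ", ncol(x$scores),
      " targets; method = ", x$config$method, sep = "")
  if (!is.null(x$weights)) {
    cat("; weights = ", paste(sprintf("%s %.3f", names(x$weights), x$weights),
                              collapse = ", "), sep = "")
  }
  cat("\n  screening added ", nrow(x$screen_added),
      " pair(s); revision promoted ", nrow(x$revision_added), " pair(s)\n",
      sep = "")
  invisible(x)
}

#' Tidy a prediction into one row per drug-target pair
#'
#' @param x a `dti_prediction`.
#' @param ... unused.
#' @return A tibble with `drug_id`, `target_id`, the final `score`, and the
#'   fused score `fused`.
#' @export
tidy.dti_prediction <- function(x, ...) {
  n <- nrow(x$scores); m <- ncol(x$scores)
  tibble::tibble(
    drug_id = rep(rownames(x$scores), each = m),
    target_id = rep(colnames(x$scores), times = n),
    score = as.vector(t(x$scores)),
    fused = as.vector(t(x$Y_final))
  )
}

#' Heatmap of the final prediction scores
#'
#' @param object a `dti_prediction`.
#' @param ... unused.
#' @return A ggplot tile map of the score matrix.
#' @export
autoplot.dti_prediction <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target_id, y = .data$drug_id,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "target", y = "drug", fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
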