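#' Area under the ROC curve
#'
#' Trapezoidal AUC, computed as the Mann-Whitney statistic with midranks so
#' tied scores count one half.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1), same length.
#' @return The AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0) stop("auc_score needs at least one positive and one negative")
  r <- rank(scores)
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Area under the precision-recall curve
#'
#' Step-wise PR area: scores are swept from the highest threshold down (tied
#' scores enter together) and precision is integrated over the recall
#' increments.
#'
#' @inheritParams auc_score
#' @return The AUPR in `(0, 1]`.
#' @export
aupr_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  P <- sum(labels == 1)
  if (P == 0) stop("aupr_score needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(l)[grp_end]
  n_pred <- grp_end
  precision <- tp / n_pred
  recall <- tp / P
  sum(diff(c(0, recall)) * precision)
}

#' Confusion metrics after top-fraction thresholding
#'
#' Sorts all predictions, calls the top `ceiling(top_fraction * N)` pairs
#' positive (ties broken by score then original index, i.e. row-major pair
#' order when scores come from a flattened matrix) and compares with the
#' labels.
#'
#' @inheritParams auc_score
#' @param top_fraction fraction of pairs predicted positive, in `(0, 1]`.
#' @return A one-row tibble with `accuracy`, `sensitivity`, `specificity`,
#'   `precision` as percentages, plus the confusion counts `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
thresholded_metrics <- function(scores, labels, top_fraction = 0.01) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)),
            top_fraction > 0, top_fraction <= 1)
  N <- length(scores)
  kk <- ceiling(top_fraction * N)
  ord <- order(-scores, seq_len(N))
  pred <- numeric(N)
  pred[ord[seq_len(kk)]] <- 1
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  pct <- function(a, b) if (b == 0) NA_real_ else 100 * a / b
  tibble::tibble(
    accuracy = pct(tp + tn, N),
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    precision = pct(tp, tp + fp),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

# Stratified fold assignment over the n*m pairs (row-major flattening):
# positives and unlabeled pairs are shuffled separately and dealt round-robin.
make_pair_folds <- function(Y, n_folds, seed) {
  flat <- as.vector(t(Y))
  folds <- integer(length(flat))
  rs <- make_rng(seed)
  for (cls in c(1, 0)) {
    idx <- which(flat == cls)
    idx <- idx[sample_int(rs, length(idx))]
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

# Fold assignment over drugs or targets (for new-entity CV modes).
make_entity_folds <- function(n_entities, n_folds, seed) {
  rs <- make_rng(seed)
  perm <- sample_int(rs, n_entities)
  folds <- integer(n_entities)
  folds[perm] <- rep_len(seq_len(n_folds), n_entities)
  folds
}

# Local RNG stream so evaluation seeding never disturbs the caller's RNG.
make_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  env$seed <- as.integer(seed)
  env
}

sample_int <- function(rs, n) with_rng(rs, sample.int(n))

# Mask a set of flat (row-major) pair indices to 0 in the training matrix.
mask_pairs <- function(dataset, pair_idx) {
  flat <- as.vector(t(dataset$Y))
  flat[pair_idx] <- 0
  Y <- matrix(flat, nrow(dataset$Y), ncol(dataset$Y), byrow = TRUE,
              dimnames = dimnames(dataset$Y))
  ds <- dataset
  ds$Y <- Y
  ds
}

#' Cross-validated evaluation of the prediction pipeline
#'
#' Pair-wise cross-validation as used for gold-standard DTI benchmarks: all
#' `n * m` pairs are partitioned into folds (stratified by label); for each
#' fold the held-out positives are masked to 0 in the training matrix (the
#' positive-unlabeled convention: a held-out pair looks exactly like an
#' unlabeled one), the full pipeline is retrained on the masked dataset, and
#' the held-out pairs are scored. Drug-wise and target-wise modes hold out
#' whole rows/columns instead (the new-drug / new-target scenarios).
#'
#' @param dataset a [dti_dataset].
#' @param config a [dti_config]; `n_folds`, `cv_mode`, `method`,
#'   `top_fraction` and `seed` control the protocol.
#' @return An object of class `dti_eval` with aggregate `auc`, `aupr`,
#'   `accuracy`, `sensitivity`, `specificity`, `precision` (means over folds)
#'   and a `per_fold` tibble. Folds whose held-out labels are single-class are
#'   skipped with a warning.
#' @export
cross_validate <- function(dataset, config = dti_config()) {
  stopifnot(inherits(dataset, "dti_dataset"))
  n <- nrow(dataset$Y); m <- ncol(dataset$Y)
  Yflat <- as.vector(t(dataset$Y))
  fold_sets <- switch(config$cv_mode,
    pair = {
      folds <- make_pair_folds(dataset$Y, config$n_folds, config$seed)
      lapply(seq_len(config$n_folds), function(f) which(folds == f))
    },
    drug = {
      folds <- make_entity_folds(n, config$n_folds, config$seed)
      lapply(seq_len(config$n_folds), function(f) {
        drugs <- which(folds == f)
        as.vector(outer((drugs - 1) * m, seq_len(m), "+"))
      })
    },
    target = {
      folds <- make_entity_folds(m, config$n_folds, config$seed)
      lapply(seq_len(config$n_folds), function(f) {
        targets <- which(folds == f)
        as.vector(outer((seq_len(n) - 1) * m, targets, "+"))
      })
    }
  )
  rows <- list()
  for (f in seq_along(fold_sets)) {
    test_idx <- fold_sets[[f]]
    lab <- Yflat[test_idx]
    if (length(unique(lab)) < 2) {
      warning("fold ", f, " has a single class; skipped")
      next
    }
    scores <- score_fold(dataset, test_idx, config)
    tm <- thresholded_metrics(scores, lab, config$top_fraction)
    rows[[length(rows) + 1]] <- tibble::tibble(
      fold = f,
      auc = auc_score(scores, lab),
      aupr = aupr_score(scores, lab),
      accuracy = tm$accuracy, sensitivity = tm$sensitivity,
      specificity = tm$specificity, precision = tm$precision,
      n_test = length(test_idx), n_test_pos = sum(lab)
    )
  }
  if (!length(rows)) stop("every fold was single-class; cannot evaluate")
  per_fold <- do.call(rbind, rows)
  structure(
    list(
      auc = mean(per_fold$auc), aupr = mean(per_fold$aupr),
      accuracy = mean(per_fold$accuracy), sensitivity = mean(per_fold$sensitivity),
      specificity = mean(per_fold$specificity), precision = mean(per_fold$precision),
      per_fold = per_fold, top_fraction = config$top_fraction,
      n_folds = config$n_folds, cv_mode = config$cv_mode,
      method = config$method, seed = config$seed
    ),
    class = "dti_eval"
  )
}

# Score the held-out pairs of one fold: mask them in training, run the
# configured pipeline, return the held-out scores (row-major order of
# test_idx). Training never sees the held-out labels, only zeros.
score_fold <- function(dataset, test_idx, config) {
  masked <- mask_pairs(dataset, test_idx)
  pred <- predict_pipeline(masked, config)
  as.vector(t(pred$scores))[test_idx]
}

#' @export
print.dti_eval <- function(x, ...) {
  cat("<dti_eval> ", x$n_folds, "-fold (", x$cv_mode, "-wise), method = ",
      x$method, "\n", sep = "")
  cat(sprintf("  AUC %.4f  AUPR %.4f\n", x$auc, x$aupr))
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  precision %.2f%% (top %.1f%%)\n",
              x$accuracy, x$sensitivity, x$specificity, x$precision,
              100 * x$top_fraction))
  invisible(x)
}

#' Tidy a cross-validation report into per-fold rows
#'
#' @param x a `dti_eval`.
#' @param ... unused.
#' @return The per-fold tibble (one row per evaluated fold).
#' @export
#' @importFrom generics tidy
tidy.dti_eval <- function(x, ...) x$per_fold

#' One-row summary of a cross-validation report
#'
#' @param x a `dti_eval`.
#' @param ... unused.
#' @return A one-row tibble of the aggregate metrics.
#' @export
#' @importFrom generics glance
glance.dti_eval <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, aupr = x$aupr, accuracy = x$accuracy,
    sensitivity = x$sensitivity, specificity = x$specificity,
    precision = x$precision, n_folds = x$n_folds,
    folds_evaluated = nrow(x$per_fold), cv_mode = x$cv_mode,
    method = x$method, top_fraction = x$top_fraction, seed = x$seed
  )
}

#' Plot per-fold cross-validation metrics
#'
#' @param object a `dti_eval`.
#' @param ... unused.
#' @return A ggplot of per-fold AUC and AUPR with the aggregate means.
#' @export
autoplot.dti_eval <- function(object, ...) {
  pf <- object$per_fold
  df <- rbind(
    data.frame(fold = pf$fold, metric = "AUC", value = pf$auc),
    data.frame(fold = pf$fold, metric = "AUPR", value = pf$aupr)
  )
  means <- data.frame(metric = c("AUC", "AUPR"),
                      value = c(object$auc, object$aupr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = means,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "fold", y = NULL,
                  title = sprintf("%d-fold cross-validation (%s)",
                                  object$n_folds, object$method)) +
    ggplot2::theme_minimal()
}
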