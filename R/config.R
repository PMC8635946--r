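#' Pipeline configuration
#'
#' Collects every tunable of the prediction pipeline in one validated object.
#' All downstream functions take the relevant parameters from a `dti_config`.
#'
#' @param alpha_d weight of the chemical similarity in the combined drug kernel
#'   `K_d = alpha_d * S_d + (1 - alpha_d) * K_GIP_d`; in `[0, 1]`.
#' @param alpha_t same for the target kernel.
#' @param gamma_scale multiplier on the GIP kernel bandwidth (the bandwidth is
#'   `gamma_scale` divided by the mean squared interaction-profile norm).
#' @param sigma ridge regularization of the Kronecker RLS predictor; `>= 0`.
#' @param wnn_decay geometric decay `T` of the weighted-nearest-neighbour
#'   profile weights `w_i = T^(rank - 1)`; in `(0, 1]`.
#' @param wnn_targets also complete all-zero target columns with WNN profiles
#'   (the symmetric treatment; off by default).
#' @param restart_c restart probability of the random walk; in `(0, 1]`.
#' @param eta seed-mass split between the target block (`1 - eta`) and the
#'   drug block (`eta`) of the restart vector; in `(0, 1)`.
#' @param jump_lambda probability of jumping between the drug and target
#'   layers of the heterogeneous network; in `[0, 1]`.
#' @param rwr_tol walk stopping tolerance on the norm of successive iterates.
#' @param rwr_max_iter iteration cap of the walk.
#' @param theta_sim drug-similarity screening threshold; in `[0, 1]`. Ignored
#'   when `screen_top_k` is set.
#' @param screen_top_k optional integer: screen through each drug's `top_k`
#'   most similar drugs instead of a threshold.
#' @param fusion_mode `"weighted"` (performance-weighted), `"ave"` (equal
#'   weights) or `"vote"` (per-source binarization + majority vote).
#' @param fusion_weights optional fixed weight vector (length 3, sums to 1);
#'   overrides the inner cross-validated performance weights.
#' @param inner_folds folds of the inner cross-validation that estimates the
#'   per-source AUPR used for performance weighting.
#' @param select_fraction fraction of unlabeled pairs promoted to positives
#'   when revising the training matrix; in `[0, 1]`.
#' @param blm_sigma ridge regularization of the BLM local models; `>= 0`.
#' @param blm_combine how the drug-side and target-side local-model scores are
#'   combined: `"max"` or `"mean"`.
#' @param nii_beta weight of the inferred interaction profile substituted for
#'   entities with no known interactions; in `[0, 1]`.
#' @param top_fraction fraction of pairs called positive when thresholding
#'   predictions for the confusion metrics; in `(0, 1]`.
#' @param n_folds cross-validation folds.
#' @param cv_mode cross-validation granularity: `"pair"` (default), `"drug"`
#'   or `"target"`.
#' @param method which score feeds the revision: `"fused"` (full pipeline) or
#'   a single source, `"sim"`, `"rs"`, `"ws"`.
#' @param seed integer seed for every stochastic step.
#' @return A validated list of class `dti_config`.
#' @export
dti_config <- function(alpha_d = 0.5, alpha_t = 0.5, gamma_scale = 1,
                       sigma = 1, wnn_decay = 0.7, wnn_targets = FALSE,
                       restart_c = 0.7, eta = 0.5, jump_lambda = 0.5,
                       rwr_tol = 1e-10, rwr_max_iter = 10000,
                       theta_sim = 0.7, screen_top_k = NULL,
                       fusion_mode = c("weighted", "ave", "vote"),
                       fusion_weights = NULL, inner_folds = 3,
                       select_fraction = 0.01, blm_sigma = 1,
                       blm_combine = c("max", "mean"), nii_beta = 1,
                       top_fraction = 0.01, n_folds = 10,
                       cv_mode = c("pair", "drug", "target"),
                       method = c("fused", "sim", "rs", "ws"),
                       seed = 1L) {
  cfg <- list(
    alpha_d = alpha_d, alpha_t = alpha_t, gamma_scale = gamma_scale,
    sigma = sigma, wnn_decay = wnn_decay, wnn_targets = isTRUE(wnn_targets),
    restart_c = restart_c, eta = eta, jump_lambda = jump_lambda,
    rwr_tol = rwr_tol, rwr_max_iter = as.integer(rwr_max_iter),
    theta_sim = theta_sim,
    screen_top_k = if (is.null(screen_top_k)) NULL else as.integer(screen_top_k),
    fusion_mode = match.arg(fusion_mode),
    fusion_weights = fusion_weights, inner_folds = as.integer(inner_folds),
    select_fraction = select_fraction, blm_sigma = blm_sigma,
    blm_combine = match.arg(blm_combine), nii_beta = nii_beta,
    top_fraction = top_fraction, n_folds = as.integer(n_folds),
    cv_mode = match.arg(cv_mode), method = match.arg(method),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "dti_config")
}

validate_config <- function(cfg) {
  in_range <- function(x, lo, hi, name, lo_open = FALSE, hi_open = FALSE) {
    ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
      (if (lo_open) x > lo else x >= lo) &&
      (if (hi_open) x < hi else x <= hi)
    if (!ok) stop(name, " must be in ", if (lo_open) "(" else "[", lo, ", ",
                  hi, if (hi_open) ")" else "]", call. = FALSE)
  }
  in_range(cfg$alpha_d, 0, 1, "alpha_d")
  in_range(cfg$alpha_t, 0, 1, "alpha_t")
  in_range(cfg$gamma_scale, 0, Inf, "gamma_scale", lo_open = TRUE)
  in_range(cfg$sigma, 0, Inf, "sigma")
  in_range(cfg$wnn_decay, 0, 1, "wnn_decay", lo_open = TRUE)
  in_range(cfg$restart_c, 0, 1, "restart_c", lo_open = TRUE)
  in_range(cfg$eta, 0, 1, "eta", lo_open = TRUE, hi_open = TRUE)
  in_range(cfg$jump_lambda, 0, 1, "jump_lambda")
  in_range(cfg$rwr_tol, 0, Inf, "rwr_tol", lo_open = TRUE)
  in_range(cfg$theta_sim, 0, 1, "theta_sim")
  in_range(cfg$select_fraction, 0, 1, "select_fraction")
  in_range(cfg$blm_sigma, 0, Inf, "blm_sigma")
  in_range(cfg$nii_beta, 0, 1, "nii_beta")
  in_range(cfg$top_fraction, 0, 1, "top_fraction", lo_open = TRUE)
  if (cfg$rwr_max_iter < 1) stop("rwr_max_iter must be >= 1", call. = FALSE)
  if (cfg$inner_folds < 2) stop("inner_folds must be >= 2", call. = FALSE)
  if (cfg$n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  if (!is.null(cfg$screen_top_k) && cfg$screen_top_k < 1) {
    stop("screen_top_k must be a positive integer", call. = FALSE)
  }
  if (!is.null(cfg$fusion_weights)) {
    w <- cfg$fusion_weights
    if (!is.numeric(w) || any(w < 0 | w > 1)) {
      stop("fusion_weights must lie in [0, 1]", call. = FALSE)
    }
    if (abs(sum(w) - 1) > 1e-12) {
      stop("fusion_weights must sum to 1", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Read a configuration from a YAML file, with overrides
#'
#' @param path YAML file whose keys are [dti_config()] arguments. `NULL` reads
#'   nothing and returns the defaults (plus overrides).
#' @param overrides named list applied on top of the file values; this is how
#'   command-line flags take precedence over the config file.
#' @return A `dti_config`.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  }
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), names(formals(dti_config)))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(dti_config, vals)
}

#' @export
print.dti_config <- function(x, ...) {
  cat("<dti_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat("  ", k, ": ", if (is.null(v)) "NULL" else paste(format(v), collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}
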