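#' Construct and validate a drug-target interaction dataset
#'
#' A `dti_dataset` bundles the three matrices of a gold-standard DTI dataset:
#' the binary interaction matrix `Y` (drugs in rows, targets in columns), the
#' drug-drug chemical similarity matrix `S_d`, and the target-target sequence
#' similarity matrix `S_t`. All axes are aligned by identifier.
#'
#' @param Y binary numeric matrix, `n_drugs x m_targets`, with drug identifiers
#'   as rownames and target identifiers as colnames.
#' @param S_d drug similarity matrix, `n x n`, entries in `[0, 1]`, symmetric,
#'   unit diagonal, with matching drug identifiers on both axes.
#' @param S_t target similarity matrix, `m x m`, same constraints.
#'
#' @details Similarity matrices asymmetric by at most `1e-8` are symmetrized as
#'   `(S + t(S)) / 2` with a warning; larger asymmetry is an error. Both
#'   similarity matrices are reordered so their axes follow the row/column
#'   order of `Y`.
#'
#' @return An object of class `dti_dataset`: a list with elements `drug_ids`,
#'   `target_ids`, `Y`, `S_d`, `S_t`.
#' @export
#' @examples
#' Y <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("D1", "D2"), c("T1", "T2")))
#' S <- diag(2) * 0.5 + 0.5
#' dimnames(S) <- list(c("D1", "D2"), c("D1", "D2"))
#' St <- S
#' dimnames(St) <- list(c("T1", "T2"), c("T1", "T2"))
#' ds <- dti_dataset(Y, S, St)
dti_dataset <- function(Y, S_d, S_t) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  drug_ids <- rownames(Y)
  target_ids <- colnames(Y)
  if (is.null(drug_ids) || is.null(target_ids)) {
    stop("Y must carry drug identifiers as rownames and target identifiers as colnames")
  }
  if (anyDuplicated(drug_ids)) {
    stop("duplicate drug identifiers: ",
         paste(unique(drug_ids[duplicated(drug_ids)]), collapse = ", "))
  }
  if (anyDuplicated(target_ids)) {
    stop("duplicate target identifiers: ",
         paste(unique(target_ids[duplicated(target_ids)]), collapse = ", "))
  }
  if (!all(Y %in% c(0, 1))) {
    stop("interaction matrix must be binary (entries in {0, 1})")
  }
  S_d <- align_similarity(S_d, drug_ids, "drug")
  S_t <- align_similarity(S_t, target_ids, "target")
  structure(
    list(drug_ids = drug_ids, target_ids = target_ids,
         Y = Y, S_d = S_d, S_t = S_t),
    class = "dti_dataset"
  )
}

# Reorder a similarity matrix to `ids`, validate symmetry / diagonal / range.
align_similarity <- function(S, ids, axis) {
  S <- as.matrix(S)
  if (is.null(rownames(S)) || is.null(colnames(S))) {
    stop(axis, " similarity matrix must be labeled on both axes")
  }
  missing_ids <- setdiff(ids, rownames(S))
  extra_ids <- setdiff(rownames(S), ids)
  if (length(missing_ids) || length(extra_ids)) {
    stop(axis, " identifier mismatch; missing: [",
         paste(missing_ids, collapse = ", "), "], unexpected: [",
         paste(extra_ids, collapse = ", "), "]")
  }
  if (!identical(sort(rownames(S)), sort(colnames(S)))) {
    stop(axis, " similarity matrix row and column labels differ")
  }
  S <- S[ids, ids, drop = FALSE]
  asym <- max(abs(S - t(S)))
  if (asym > 1e-8) {
    stop(axis, " similarity matrix asymmetric beyond tolerance (max |S - t(S)| = ",
         format(asym), ")")
  }
  if (asym > 0) {
    warning(axis, " similarity matrix symmetrized (max asymmetry ", format(asym), ")")
    S <- (S + t(S)) / 2
  }
  if (max(abs(diag(S) - 1)) > 1e-8) {
    stop(axis, " similarity matrix diagonal must equal 1")
  }
  diag(S) <- 1
  if (min(S) < -1e-12 || max(S) > 1 + 1e-8) {
    stop(axis, " similarity entries must lie in [0, 1]")
  }
  S
}

#' @export
print.dti_dataset <- function(x, ...) {
  st <- dataset_stats(x)
  cat("<dti_dataset> ", st$n_drugs, " drugs x ", st$m_targets, " targets; ",
      st$known_interactions, " known interactions, ",
      st$unknown_pairs, " unknown pairs\n", sep = "")
  invisible(x)
}

#' Summary counts for a DTI dataset
#'
#' @param dataset a [dti_dataset].
#' @return A one-row tibble with `n_drugs`, `m_targets`, `known_interactions`
#'   (sum of the interaction matrix) and `unknown_pairs` (all remaining pairs).
#' @export
dataset_stats <- function(dataset) {
  stopifnot(inherits(dataset, "dti_dataset"))
  n <- nrow(dataset$Y)
  m <- ncol(dataset$Y)
  known <- sum(dataset$Y)
  tibble::tibble(
    n_drugs = n, m_targets = m,
    known_interactions = known,
    unknown_pairs = n * m - known
  )
}

#' Read a DTI dataset from labeled tab-separated matrix files
#'
#' Reads the interaction, drug-similarity and target-similarity matrices from
#' the flat-file dialect used by the Yamanishi gold-standard datasets: one
#' header row of column labels (an optional leading corner cell is tolerated),
#' one leading column of row labels, tab-separated numeric values.
#'
#' @param interaction_path path to the interaction matrix file.
#' @param drug_sim_path path to the drug similarity matrix file.
#' @param target_sim_path path to the target similarity matrix file.
#' @param drugs_as_rows whether the interaction file lists drugs as rows
#'   (`TRUE`, default) or as columns (`FALSE`; the matrix is transposed on
#'   read). Internally drugs are always rows.
#' @return A validated [dti_dataset]. Row/column orders of the similarity
#'   files are realigned to the interaction matrix by identifier.
#' @export
read_dataset <- function(interaction_path, drug_sim_path, target_sim_path,
                         drugs_as_rows = TRUE) {
  Y <- read_labeled_matrix(interaction_path)
  if (!drugs_as_rows) Y <- t(Y)
  S_d <- read_labeled_matrix(drug_sim_path)
  S_t <- read_labeled_matrix(target_sim_path)
  dti_dataset(Y, S_d, S_t)
}

#' Write a DTI dataset as labeled tab-separated matrix files
#'
#' Writes `interactions.tsv`, `drug_similarity.tsv` and `target_similarity.tsv`
#' in the same dialect [read_dataset()] consumes, at full numeric precision so
#' a read/write round trip is bit-exact.
#'
#' @param dataset a [dti_dataset].
#' @param directory output directory (created if absent).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "dti_dataset"))
  if (length(dataset$drug_ids) == 0 || length(dataset$target_ids) == 0) {
    stop("refusing to write a dataset with an empty drug or target list")
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    interactions = file.path(directory, "interactions.tsv"),
    drug_similarity = file.path(directory, "drug_similarity.tsv"),
    target_similarity = file.path(directory, "target_similarity.tsv")
  )
  write_labeled_matrix(dataset$Y, paths[["interactions"]])
  write_labeled_matrix(dataset$S_d, paths[["drug_similarity"]])
  write_labeled_matrix(dataset$S_t, paths[["target_similarity"]])
  invisible(paths)
}

#' Read a labeled numeric matrix from a tab-separated file
#'
#' @param path file with a header row of column labels (optional corner cell)
#'   and a leading column of row labels.
#' @return A numeric matrix with dimnames.
#' @export
read_labeled_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("matrix file too short: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  body <- cells[-1]
  width <- length(body[[1]])
  # header may or may not carry the corner cell above the row-label column
  if (length(header) == width) {
    col_ids <- header[-1]
  } else if (length(header) == width - 1) {
    col_ids <- header
  } else {
    stop("header width inconsistent with body in ", path)
  }
  if (any(lengths(body) != width)) stop("ragged rows in ", path)
  row_ids <- vapply(body, `[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1]), numeric(width - 1L))
  )
  if (anyNA(vals)) stop("non-numeric matrix entries in ", path)
  M <- if (is.matrix(vals)) t(vals) else matrix(vals, nrow = length(body))
  dimnames(M) <- list(row_ids, col_ids)
  M
}

#' Write a labeled numeric matrix as a tab-separated file
#'
#' @param M numeric matrix with dimnames.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_labeled_matrix <- function(M, path) {
  stopifnot(is.matrix(M), !is.null(rownames(M)), !is.null(colnames(M)))
  header <- paste(c("", colnames(M)), collapse = "\t")
  rows <- vapply(seq_len(nrow(M)), function(i) {
    paste(c(rownames(M)[i], sprintf("%.17g", M[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
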