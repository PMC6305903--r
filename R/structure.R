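#' Eigendecomposition of a correlation matrix
#'
#' Solves `C v_i = lambda_i v_i` for a fully valid symmetric correlation
#' matrix. Eigenvalues are returned in descending order with orthonormal
#' eigenvectors; for a unit-diagonal matrix their sum equals the trace `n`.
#' Empirical correlation matrices are positive semidefinite, so
#' nonnegativity of the eigenvalues is asserted up to a relative tolerance.
#'
#' @param C A `correlation_matrix` with no masked entries, or a plain
#'   symmetric matrix.
#' @return An object of class `eigen_structure` with `values` (descending)
#'   and `vectors` (columns aligned with `values`).
#' @export
eigendecompose <- function(C) {
  m <- as_valid_matrix(C)
  e <- eigen(m, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values[1L]), 1)
  if (min(e$values) < -tol) {
    warning("correlation matrix is not positive semidefinite within tolerance")
  }
  structure(list(values = e$values, vectors = e$vectors),
            class = "eigen_structure")
}

# unwrap a correlation_matrix, insisting on full validity
as_valid_matrix <- function(C) {
  if (inherits(C, "correlation_matrix")) {
    if (!all(C$valid_mask)) {
      stop("correlation matrix has masked (invalid) entries; ",
           "exclude the invalid units first, e.g. with drop_invalid_units()")
    }
    C$values
  } else {
    stopifnot(is.matrix(C), nrow(C) == ncol(C))
    C
  }
}

#' Drop units with any masked pair from a correlation matrix
#'
#' @param C A `correlation_matrix`.
#' @return A fully valid `correlation_matrix` restricted to units whose
#'   pairs are all defined.
#' @export
drop_invalid_units <- function(C) {
  stopifnot(inherits(C, "correlation_matrix"))
  keep <- diag(C$valid_mask)
  correlation_matrix_object(C$values[keep, keep, drop = FALSE], C$bin_width,
                            C$kind, C$valid_mask[keep, keep, drop = FALSE],
                            C$neuron_ids[keep])
}

#' Cluster ordering of a correlation matrix
#'
#' Leaf order of an agglomerative dendrogram built with Ward linkage on the
#' rows of `C` (diagonal set to 0 before linkage, Euclidean distance), which
#' exposes intra-correlated groups as contiguous blocks when the matrix is
#' displayed in this order. Deterministic for a fixed input.
#'
#' @param C A fully valid `correlation_matrix` or symmetric matrix, n >= 2.
#' @return Integer permutation of `1..n` (row indices in display order).
#' @export
cluster_order <- function(C) {
  m <- as_valid_matrix(C)
  if (nrow(m) < 2L) stop("at least two units are required")
  diag(m) <- 0
  stats::hclust(stats::dist(m), method = "ward.D2")$order
}

#' Upper-triangle vector of a correlation matrix
#'
#' Flattens the strict upper triangle in fixed row-major order
#' (`(1,2), (1,3), ..., (1,n), (2,3), ...`), omitting the duplicate
#' symmetric entries and the unit diagonal.
#'
#' @param C A fully valid `correlation_matrix` or symmetric matrix.
#' @return Numeric vector of length `n (n - 1) / 2`.
#' @export
vectorize_upper <- function(C) {
  m <- as_valid_matrix(C)
  # row-major upper triangle of a symmetric matrix = column-major lower
  m[lower.tri(m)]
}

#' Rebuild a symmetric matrix from its upper-triangle vector
#'
#' Inverse of [vectorize_upper()] given the diagonal values.
#'
#' @param v Upper-triangle vector of length `n (n - 1) / 2`.
#' @param diag_value Value placed on the diagonal (default 1).
#' @return Symmetric `n x n` matrix.
#' @export
matrix_from_upper <- function(v, diag_value = 1) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(n - round(n)) > 1e-9) stop("vector length is not n(n-1)/2")
  n <- as.integer(round(n))
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Correlation-structure similarity of two matrices
#'
#' The normalized absolute scalar product
#' `|c1 . c2| / (||c1|| ||c2||)` of the two upper-triangle vectors: 1 for
#' identical correlation structures, 0 for perpendicular ones. The measure
#' is sensitive to the neuron labeling, so both matrices must describe the
#' same neuron population in the same order.
#'
#' @param C1,C2 Fully valid `correlation_matrix` objects (or symmetric
#'   matrices) of equal dimension and labeling.
#' @return Similarity score in `[0, 1]`.
#' @export
similarity <- function(C1, C2) {
  check_same_labeling(C1, C2)
  v1 <- vectorize_upper(C1); v2 <- vectorize_upper(C2)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero upper-triangle vector: similarity undefined")
  abs(sum(v1 * v2)) / (n1 * n2)
}

check_same_labeling <- function(C1, C2) {
  d1 <- nrow(as_valid_matrix(C1)); d2 <- nrow(as_valid_matrix(C2))
  if (d1 != d2) stop("correlation matrices must have the same dimension")
  if (inherits(C1, "correlation_matrix") && inherits(C2, "correlation_matrix") &&
      !identical(C1$neuron_ids, C2$neuron_ids)) {
    stop("correlation matrices must share the neuron labeling")
  }
  invisible(TRUE)
}

#' Permutation surrogate test for correlation-structure similarity
#'
#' Null distribution of [similarity()] obtained by randomly relabeling the
#' neurons of the second matrix (joint row and column permutation)
#' `n_permutations` times. Relabeling destroys any shared structure while
#' preserving the entry distribution, so the observed score is referenced
#' against the null as `z = (score - null_mean) / null_sd`.
#'
#' For structureless (e.g. homogeneous) matrices the null is degenerate
#' (`null_sd = 0`); this is detected and reported via `degenerate = TRUE`
#' and a `z` of `+Inf` rather than a division by zero.
#'
#' @param C1,C2 As in [similarity()].
#' @param n_permutations Number of neuron-order shuffles (default 10000).
#'   Below 100 a warning is recorded in the result.
#' @param seed Integer seed making the shuffle sequence reproducible.
#' @return An object of class `similarity_result` with fields `score`,
#'   `null_mean`, `null_sd`, `z`, `n_permutations`, `seed`, `degenerate`
#'   and `warnings`.
#' @export
surrogate_similarity_null <- function(C1, C2, n_permutations = 10000L,
                                      seed = 1L) {
  check_same_labeling(C1, C2)
  n_permutations <- as.integer(n_permutations)
  stopifnot(n_permutations >= 1L)
  m1 <- as_valid_matrix(C1); m2 <- as_valid_matrix(C2)
  warnings <- character(0)
  if (n_permutations < 100L) {
    warnings <- "fewer than 100 permutations: null estimate is unstable"
  }
  score <- similarity(m1, m2)
  n <- nrow(m1)
  perms <- with_seed(seed, {
    matrix(vapply(seq_len(n_permutations),
                  function(i) sample.int(n), integer(n)),
           nrow = n_permutations, ncol = n, byrow = TRUE)
  })
  null_scores <- perm_similarity_core(m1, m2, perms - 1L)
  null_mean <- mean(null_scores)
  null_sd <- stats::sd(null_scores)
  if (n_permutations == 1L) null_sd <- 0
  degenerate <- null_sd == 0
  z <- if (degenerate) Inf else (score - null_mean) / null_sd
  structure(list(score = score, null_mean = null_mean, null_sd = null_sd,
                 z = z, n_permutations = n_permutations,
                 seed = as.integer(seed), degenerate = degenerate,
                 warnings = warnings),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("similarity %.4f; null %.4f +/- %.4f (%d permutations, seed %d); z = %.2f%s\n",
              x$score, x$null_mean, x$null_sd, x$n_permutations, x$seed, x$z,
              if (x$degenerate) " [degenerate null]" else ""))
  invisible(x)
}

#' Serialize a similarity result to JSON
#' @param x A `similarity_result`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
similarity_result_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "similarity_result"))
  out <- x
  class(out) <- NULL
  if (is.infinite(out$z)) out$z <- "Inf"
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
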