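# Similarity and distance primitives: Tanimoto on bit vectors (also used as
# an SVM/GP kernel) and Euclidean distance on descriptor vectors.

#' Tanimoto coefficient between two bit vectors
#'
#' `tn = j / (k + m - j)` where `j` is the number of shared on-bits and
#' `k`, `m` the on-bit counts of each fingerprint. The degenerate case of
#' two all-zero fingerprints is defined as 0, with a warning.
#'
#' @param a,b Binary vectors of equal length.
#' @return A number in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  assert_that(length(a) == length(b), "fingerprint length mismatch")
  j <- sum(a * b)
  k <- sum(a); m <- sum(b)
  d <- k + m - j
  if (d == 0) {
    warning("both fingerprints are empty; Tanimoto defined as 0")
    return(0)
  }
  j / d
}

#' Tanimoto similarity matrix between two sets of fingerprints
#'
#' Vectorized pairwise Tanimoto; also serves as the precomputed Gram matrix
#' for Tanimoto-kernel models (the Tanimoto/Jaccard coefficient is a valid
#' positive semi-definite kernel on bit vectors).
#'
#' @param A,B Binary matrices with molecules in rows and the same number of
#'   columns. `B` defaults to `A`.
#' @return `nrow(A) x nrow(B)` matrix of similarities. Pairs of all-zero
#'   rows yield 0.
#' @export
tanimoto_matrix <- function(A, B = A) {
  assert_that(is.matrix(A) && is.matrix(B) && ncol(A) == ncol(B),
              "fingerprint matrices must share the same width")
  assert_that(all(A %in% c(0, 1)) && all(B %in% c(0, 1)),
              "fingerprint matrices must be binary")
  J <- A %*% t(B)
  D <- outer(rowSums(A), rowSums(B), "+") - J
  G <- J / D
  G[D == 0] <- 0
  G
}

#' Tanimoto kernel Gram matrix
#'
#' Alias of [tanimoto_matrix()] named for its role as the kernel of the
#' Tanimoto-SVM and Tanimoto-GP models.
#'
#' @inheritParams tanimoto_matrix
#' @return Gram matrix `G[i, j] = tn(A_i, B_j)`.
#' @export
tanimoto_kernel <- function(A, B = A) {
  tanimoto_matrix(A, B)
}

#' Euclidean distance between descriptor vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative distance.
#' @export
euclidean_dist <- function(a, b) {
  assert_that(length(a) == length(b), "descriptor width mismatch")
  sqrt(sum((a - b)^2))
}
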