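#' Per-family loading matrix G with G G' = A
#'
#' Factors each family block of the additive relationship matrix through its
#' spectral decomposition \eqn{A_f = U_f S_f U_f^T} and sets
#' \eqn{G_f = U_f S_f^{1/2}}, so that \eqn{G_f G_f^T = A_f}. Replacing the
#' correlated polygenic effect \eqn{\rho \sim N(0, \sigma^2_g A)} by
#' \eqn{G u} with \eqn{u \sim N(0, \sigma^2_g I)} leaves the phenotypic
#' covariance \eqn{\sigma^2_g G G^T + \sigma^2_e I = \sigma^2_g A +
#' \sigma^2_e I} unchanged while the random effects become independent.
#' For a symmetric positive semi-definite block the spectral and singular
#' value decompositions coincide; the symmetric eigendecomposition is used
#' for numerical stability. Only the product \eqn{G_f G_f^T} is contractual:
#' eigenvector sign and order are implementation details.
#'
#' Eigenvalues in `[-tol, 0)` are clamped to zero (pedigree relationship
#' blocks are exactly PSD; the tolerance absorbs floating-point noise only);
#' an eigenvalue below `-tol` raises an error naming the family.
#'
#' @param A additive relationship matrix, block-diagonal under `off`.
#' @param off [family_offsets] describing the block structure.
#' @param tol non-negativity tolerance for eigenvalues (default `1e-8`).
#' @return Object of class `loading_matrix`: list with `blocks` (per-family
#'   `G_f`), `d` (per-family eigenvalues of `A_f`, clamped), `offsets`,
#'   `ids`, `families`.
#' @examples
#' A <- matrix(c(1, .5, .5, 1), 2)
#' off <- structure(list(offsets = c(1L, 3L), n_fam = 1L, N = 2L,
#'                       families = "f1"), class = "family_offsets")
#' G <- block_decompose(A, off)
#' reconstruction_error(G, A)  # ~ 0
#' @export
block_decompose <- function(A, off, tol = 1e-8) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), inherits(off, "family_offsets"))
  if (nrow(A) != off$N)
    stop("relationship matrix dimension ", nrow(A),
         " does not match offsets N = ", off$N)
  if (max(abs(A - t(A))) > 1e-10) stop("relationship matrix is not symmetric")
  blocks <- vector("list", off$n_fam)
  dlist <- vector("list", off$n_fam)
  for (f in seq_len(off$n_fam)) {
    idx <- off$offsets[f]:(off$offsets[f + 1L] - 1L)
    Af <- A[idx, idx, drop = FALSE]
    eg <- eigen(Af, symmetric = TRUE)
    d <- eg$values
    if (any(d < -tol))
      stop(sprintf("block not PSD: family '%s' has eigenvalue %.3g",
                   off$families[f], min(d)))
    d[d < 0] <- 0
    blocks[[f]] <- eg$vectors %*% diag(sqrt(d), length(d))
    dlist[[f]] <- d
  }
  structure(list(blocks = blocks, d = dlist, offsets = off,
                 ids = rownames(A), families = off$families),
            class = "loading_matrix")
}

#' Assemble a loading matrix as a dense or sparse matrix
#'
#' @param G a `loading_matrix`.
#' @param sparse return a `Matrix::bdiag` sparse block-diagonal matrix.
#' @return n-by-n matrix with the same ordering as the relationship matrix.
#' @export
loading_as_matrix <- function(G, sparse = FALSE) {
  stopifnot(inherits(G, "loading_matrix"))
  if (sparse) {
    M <- Matrix::bdiag(G$blocks)
    dimnames(M) <- list(G$ids, G$ids)
    return(M)
  }
  n <- G$offsets$N
  M <- matrix(0, n, n, dimnames = list(G$ids, G$ids))
  for (f in seq_along(G$blocks)) {
    idx <- G$offsets$offsets[f]:(G$offsets$offsets[f + 1L] - 1L)
    M[idx, idx] <- G$blocks[[f]]
  }
  M
}

#' Maximum reconstruction error of a loading matrix
#'
#' @param G a `loading_matrix` (or plain matrix).
#' @param A the relationship matrix it should factor.
#' @return `max(abs(G %*% t(G) - A))`.
#' @export
reconstruction_error <- function(G, A) {
  M <- if (inherits(G, "loading_matrix")) loading_as_matrix(G) else G
  if (!all(dim(M) == dim(A)))
    stop("shape mismatch: G is ", nrow(M), "x", ncol(M),
         ", A is ", nrow(A), "x", ncol(A))
  max(abs(M %*% t(M) - A))
}

#' @export
print.loading_matrix <- function(x, ...) {
  cat(sprintf("loading matrix: %d individuals in %d family blocks\n",
              x$offsets$N, x$offsets$n_fam))
  invisible(x)
}
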