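#' Vectorization and half-vectorization
#'
#' `vec()` stacks the columns of a matrix; `vech()` stacks the columns of
#' the lower triangle (including the diagonal) of a square matrix.  Both
#' follow the Magnus--Neudecker (column-major) convention, which is the
#' convention assumed by all Jacobian formulas in this package.
#'
#' @param A a numeric matrix (square for `vech`).
#' @return a numeric vector of length `n*m` (`vec`) or `n(n+1)/2` (`vech`).
#' @seealso [duplication_matrix()], [elimination_matrix()],
#'   [commutation_matrix()]
#' @export
#' @examples
#' A <- matrix(c(1, 2, 2, 5), 2, 2)
#' vec(A)   # 1 2 2 5
#' vech(A)  # 1 2 5
vec <- function(A) {
  as.vector(as.matrix(A))
}

#' @rdname vec
#' @export
vech <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("vech() requires a square matrix")
  A[lower.tri(A, diag = TRUE)]
}

#' Duplication, elimination and commutation matrices
#'
#' Constant 0/1 matrices relating `vec` and `vech`:
#' `duplication_matrix(n)` is the \eqn{n^2 \times n(n+1)/2} matrix
#' \eqn{D_n} with \eqn{D_n \mathrm{vech}(A) = \mathrm{vec}(A)} for
#' symmetric \eqn{A}; `elimination_matrix(n)` is the
#' \eqn{n(n+1)/2 \times n^2} matrix \eqn{L_n} with
#' \eqn{L_n \mathrm{vec}(A) = \mathrm{vech}(A)}; and
#' `commutation_matrix(n)` is the \eqn{n^2 \times n^2} matrix \eqn{K_n}
#' with \eqn{K_n \mathrm{vec}(A) = \mathrm{vec}(A^\top)}.
#'
#' @param n matrix dimension, a positive integer.
#' @return a base numeric matrix of zeros and ones.
#' @export
duplication_matrix <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  m <- n * (n + 1L) / 2L
  D <- matrix(0, n * n, m)
  k <- 0L
  for (j in seq_len(n)) {
    for (i in j:n) {
      k <- k + 1L
      D[(j - 1L) * n + i, k] <- 1
      D[(i - 1L) * n + j, k] <- 1
    }
  }
  D
}

#' @rdname duplication_matrix
#' @export
elimination_matrix <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  m <- n * (n + 1L) / 2L
  L <- matrix(0, m, n * n)
  k <- 0L
  for (j in seq_len(n)) {
    for (i in j:n) {
      k <- k + 1L
      L[k, (j - 1L) * n + i] <- 1
    }
  }
  L
}

#' @rdname duplication_matrix
#' @export
commutation_matrix <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  K <- matrix(0, n * n, n * n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K[(i - 1L) * n + j, (j - 1L) * n + i] <- 1
    }
  }
  K
}

# Moore-Penrose inverse of the duplication matrix; D has orthogonal
# columns so (D'D) is diagonal and the pinv is cheap.
dup_pinv <- function(n) {
  D <- duplication_matrix(n)
  solve(crossprod(D), t(D))
}
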