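#' Build the structural matrices C and Psi
#'
#' Maps a parameter vector onto the path-coefficient matrix `C` (with
#' `C[j, i]` the direct effect of variable `i` on variable `j`) and the
#' error covariance matrix `Psi`.  Labels shared across edges produce
#' identical entries at every tagged position; labels in
#' `spec$fixed` take their fixed values.
#'
#' @param spec a [model_spec()] object.
#' @param theta numeric vector of free parameter values, either named
#'   by label or unnamed in canonical `c(labels_F, labels_P)` order.
#' @param check_pd check that `Psi` is positive definite (Cholesky
#'   factorization with tolerance `1e-10` on the smallest squared
#'   pivot).  Default `TRUE`.
#' @return an object of class `dosem_matrices`: a list with elements
#'   `C`, `Psi`, `variables`, `theta` and `spec`.
#' @export
#' @examples
#' fx <- illustration_fixture()
#' m <- build_matrices(fx$spec, fx$theta)
#' m$C["Y3", "X2"]  # c_yx = -0.6
build_matrices <- function(spec, theta, check_pd = TRUE) {
  stopifnot(inherits(spec, "dosem_spec"))
  theta <- theta_canonical(spec, theta)
  values <- c(theta, spec$fixed)
  n <- spec$n
  vars <- spec$variables
  idx <- stats::setNames(seq_len(n), vars)

  C <- matrix(0, n, n, dimnames = list(vars, vars))
  for (k in seq_len(nrow(spec$directed))) {
    C[idx[[spec$directed$to[k]]], idx[[spec$directed$from[k]]]] <-
      values[[spec$directed$label[k]]]
  }
  Psi <- matrix(0, n, n, dimnames = list(vars, vars))
  for (k in seq_len(nrow(spec$bidirected))) {
    i <- idx[[spec$bidirected$v1[k]]]
    j <- idx[[spec$bidirected$v2[k]]]
    Psi[i, j] <- values[[spec$bidirected$label[k]]]
    Psi[j, i] <- values[[spec$bidirected$label[k]]]
  }

  if (check_pd) assert_psi_pd(Psi)

  structure(
    list(C = C, Psi = Psi, variables = vars, theta = theta, spec = spec),
    class = "dosem_matrices"
  )
}

assert_psi_pd <- function(Psi) {
  ch <- tryCatch(chol(Psi), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch))^2 <= 1e-10)
    dosem_error("psi_not_pd", "Psi is not positive definite")
  invisible(ch)
}

#' Model-implied covariance matrix
#'
#' The reduced form \eqn{V = (I - C)^{-1} \varepsilon} implies the
#' covariance matrix \eqn{\Sigma = (I-C)^{-1} \Psi (I-C)^{-\top}} of
#' the observed variables.
#'
#' @param mats a `dosem_matrices` object from [build_matrices()], or a
#'   list with elements `C` and `Psi`.
#' @return the \eqn{n \times n} model-implied covariance matrix.
#' @export
#' @examples
#' fx <- illustration_fixture()
#' Sigma <- model_implied_covariance(build_matrices(fx$spec, fx$theta))
#' sqrt(Sigma["X2", "X2"])  # 11.54: implied sd of insulin at t = 2
model_implied_covariance <- function(mats) {
  B <- reduced_form(mats$C)
  S <- B %*% mats$Psi %*% t(B)
  S <- (S + t(S)) / 2
  dimnames(S) <- dimnames(mats$Psi)
  S
}

# (I - C)^{-1}; for a recursive model I - C is unipotent under a
# topological permutation, hence always invertible.
reduced_form <- function(C) {
  n <- nrow(C)
  B <- tryCatch(solve(diag(n) - C), error = function(e) NULL)
  if (is.null(B)) dosem_error("singular", "(I - C) is singular")
  B
}

#' Constant Jacobians of vec(C) and vec(Psi) in theta
#'
#' Because entries of `C` and `Psi` are (possibly repeated) copies of
#' individual parameters, the derivative matrices
#' \eqn{\partial\,\mathrm{vec}\,C / \partial\theta^\top} and
#' \eqn{\partial\,\mathrm{vec}\,\Psi / \partial\theta^\top} are
#' constant 0/1 pattern matrices.  They are the plumbing for every
#' closed-form Jacobian in the package: each column marks the
#' positions (column-major) occupied by one label, with off-diagonal
#' covariance labels marking both `(i, j)` and `(j, i)`.
#'
#' @param spec a [model_spec()] object.
#' @return a list with `dvecC` and `dvecPsi`, both
#'   \eqn{n^2 \times (q+p)} with columns named by label.
#' @export
derivative_structure <- function(spec) {
  stopifnot(inherits(spec, "dosem_spec"))
  n <- spec$n
  labels <- theta_labels(spec)
  k <- length(labels)
  idx <- stats::setNames(seq_len(n), spec$variables)
  col <- stats::setNames(seq_len(k), labels)

  dvecC <- matrix(0, n * n, k, dimnames = list(NULL, labels))
  for (e in seq_len(nrow(spec$directed))) {
    lab <- spec$directed$label[e]
    if (!lab %in% labels) next  # fixed label: not a free parameter
    i <- idx[[spec$directed$to[e]]]   # row of C
    j <- idx[[spec$directed$from[e]]] # column of C
    dvecC[(j - 1L) * n + i, col[[lab]]] <- 1
  }

  dvecPsi <- matrix(0, n * n, k, dimnames = list(NULL, labels))
  for (e in seq_len(nrow(spec$bidirected))) {
    lab <- spec$bidirected$label[e]
    if (!lab %in% labels) next
    i <- idx[[spec$bidirected$v1[e]]]
    j <- idx[[spec$bidirected$v2[e]]]
    dvecPsi[(j - 1L) * n + i, col[[lab]]] <- 1
    dvecPsi[(i - 1L) * n + j, col[[lab]]] <- 1
  }

  list(dvecC = dvecC, dvecPsi = dvecPsi)
}
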