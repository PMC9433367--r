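#' Causal effect functions
#'
#' The causal effect functions map the parameters `theta` of the
#' model-implied joint distribution onto features of the
#' interventional distribution ("causal quantities"):
#' \describe{
#'   \item{`g1`}{interventional mean vector
#'     \eqn{(I - I_N C)^{-1} 1_I x} (length \eqn{n}); depends only on
#'     the structural parameters.}
#'   \item{`g2`}{half-vectorized interventional covariance matrix
#'     \eqn{\mathrm{vech}(T_1 \Psi T_1')} (length \eqn{n(n+1)/2}).}
#'   \item{`g3`}{interventional density of the non-interventional
#'     vector at a point `v_N` (scalar).}
#'   \item{`g4`}{interventional interval probability
#'     \eqn{P(y^{low} \le Y \le y^{up} | do(x))} (scalar).}
#' }
#' They are thin, differentiable re-expressions of the intervention
#' machinery: values agree exactly with [interventional_moments()],
#' [interventional_pdf()] and [interval_probability()].
#'
#' @param spec a [model_spec()] object.
#' @param theta free parameter values (named, or canonical order).
#' @param intv a [intervention()] object (carries the levels `x`).
#' @param v_N evaluation point for `g3`, ordered like the ascending
#'   non-interventional index set.
#' @param outcomes outcome subset for `g4` (names or indexes).
#' @param lower,upper interval bounds for `g4`.
#' @return `g1` an \eqn{n}-vector, `g2` a vector of length
#'   \eqn{n(n+1)/2}, `g3` and `g4` scalars.
#' @export
#' @examples
#' fx <- illustration_fixture()
#' iv <- intervention(fx$spec, c(X2 = 11.54))
#' g1(fx$spec, fx$theta, iv)["Y3"]  # -6.92
g1 <- function(spec, theta, intv) {
  mats <- build_matrices(spec, theta, check_pd = FALSE)
  tr <- transformation_matrices(mats, intv)
  mu <- drop(tr$a1 %*% intv$x)
  if (length(intv$I) == 0L) mu <- rep(0, spec$n)
  stats::setNames(mu, spec$variables)
}

#' @rdname g1
#' @export
g2 <- function(spec, theta, intv) {
  mats <- build_matrices(spec, theta, check_pd = FALSE)
  dist <- interventional_moments(mats, intv)
  vech(dist$cov)
}

#' @rdname g1
#' @export
g3 <- function(spec, theta, intv, v_N) {
  mats <- build_matrices(spec, theta)
  dist <- interventional_moments(mats, intv)
  interventional_pdf(dist, v_N)
}

#' @rdname g1
#' @export
g4 <- function(spec, theta, intv, outcomes, lower, upper) {
  mats <- build_matrices(spec, theta)
  dist <- interventional_moments(mats, intv)
  interval_probability(dist, outcomes, lower, upper)
}

#' Closed-form Jacobians of the causal effect functions
#'
#' Jacobian matrices \eqn{\partial g / \partial \theta^\top} with
#' respect to the full free parameter vector
#' \eqn{\theta = (\theta_F, \theta_P)}.  Parameters a quantity does not
#' depend on get exact zero columns (e.g. the interventional mean has
#' zero derivative in all covariance parameters), so no column
#' selection is needed before use; a mask of the structurally nonzero
#' columns can be obtained by checking for all-zero columns.
#'
#' The formulas chain the constant patterns of
#' [derivative_structure()] through Kronecker-product identities and,
#' for the density and probability, through the moments
#' \eqn{(\mu, \Sigma)} of the interventional distribution.
#' `jacobian_g4` is available for a single outcome variable only.
#'
#' @inheritParams g1
#' @param outcome single outcome variable for `jacobian_g4`.
#' @return a matrix with one row per element of the quantity
#'   (\eqn{n}, \eqn{n(n+1)/2}, 1, 1 rows respectively) and
#'   \eqn{q + p} labelled columns.
#' @export
jacobian_g1 <- function(spec, theta, intv) {
  mats <- build_matrices(spec, theta, check_pd = FALSE)
  ds <- derivative_structure(spec)
  sel <- selection_matrices(spec$n, intv)
  M <- diag(spec$n) - sel$I_N %*% mats$C
  Minv <- solve(M)
  a1x <- Minv %*% sel$one_I %*% intv$x
  if (length(intv$I) == 0L) a1x <- matrix(0, spec$n, 1L)
  J <- (t(a1x) %x% (Minv %*% sel$I_N)) %*% ds$dvecC
  rownames(J) <- spec$variables
  J
}

#' @rdname jacobian_g1
#' @export
jacobian_g2 <- function(spec, theta, intv) {
  mats <- build_matrices(spec, theta, check_pd = FALSE)
  ds <- derivative_structure(spec)
  sel <- selection_matrices(spec$n, intv)
  n <- spec$n
  Minv <- solve(diag(n) - sel$I_N %*% mats$C)
  T1 <- Minv %*% sel$I_N
  V <- T1 %*% mats$Psi %*% t(T1)
  K <- commutation_matrix(n)
  L <- elimination_matrix(n)
  G2C <- (diag(n * n) + K) %*% (V %x% T1)
  G2P <- T1 %x% T1
  L %*% (G2C %*% ds$dvecC + G2P %*% ds$dvecPsi)
}

#' @rdname jacobian_g1
#' @export
jacobian_g3 <- function(spec, theta, intv, v_N) {
  mats <- build_matrices(spec, theta)
  dist <- interventional_moments(mats, intv)
  n <- spec$n
  N <- intv$N
  muN <- dist$mean[N]
  SN <- dist$cov[N, N, drop = FALSE]
  if (length(v_N) != length(N))
    dosem_error("bad_query", "v_N must have one value per non-interventional variable")
  f <- gaussian_pdf(v_N, muN, SN)
  SNinv <- chol2inv(chol(SN))
  r <- as.numeric(v_N - muN)
  G3mu <- t(r) %*% SNinv                                     # 1 x (n-K)
  G3Sig <- 0.5 * ((t(r) %x% t(r)) %*% (SNinv %x% SNinv) -
                    t(vec(SNinv)))                           # 1 x (n-K)^2
  sel <- selection_matrices(n, intv)
  Dn <- duplication_matrix(n)
  Jg1 <- jacobian_g1(spec, theta, intv)
  Jg2 <- jacobian_g2(spec, theta, intv)
  top <- t(sel$one_N) %*% Jg1
  bottom <- (t(sel$one_N) %x% t(sel$one_N)) %*% Dn %*% Jg2
  drop(f) * (G3mu %*% top + G3Sig %*% bottom)
}

#' @rdname jacobian_g1
#' @export
jacobian_g4 <- function(spec, theta, intv, outcome, lower, upper) {
  if (length(outcome) != 1L)
    dosem_error("unsupported",
                "jacobian_g4 supports a single outcome variable only")
  mats <- build_matrices(spec, theta)
  dist <- interventional_moments(mats, intv)
  j <- resolve_outcomes(dist, outcome)
  n <- spec$n
  mu <- dist$mean[j]
  s2 <- dist$cov[j, j]
  s <- sqrt(s2)
  zu <- (upper - mu) / s
  zl <- (lower - mu) / s
  phi_u <- if (is.finite(zu)) stats::dnorm(zu) else 0
  phi_l <- if (is.finite(zl)) stats::dnorm(zl) else 0
  G4mu <- -(phi_u - phi_l) / s
  G4s2 <- -(phi_u * (if (is.finite(zu)) zu else 0) -
              phi_l * (if (is.finite(zl)) zl else 0)) / (2 * s2)
  Dn <- duplication_matrix(n)
  Jg1 <- jacobian_g1(spec, theta, intv)
  Jg2 <- jacobian_g2(spec, theta, intv)
  G4mu * Jg1[j, , drop = FALSE] +
    G4s2 * (Dn %*% Jg2)[(j - 1L) * n + j, , drop = FALSE]
}

#' Delta-method asymptotic covariance of a causal quantity
#'
#' First-order propagation
#' \eqn{\mathrm{AV}(\sqrt{N}\hat\gamma) = J\,\mathrm{AV}(\sqrt{N}\hat\theta)\,J'}
#' of the asymptotic covariance of the parameter estimator through the
#' Jacobian of a causal effect function.
#'
#' @param jacobian an \eqn{r \times (q+p)} Jacobian matrix.
#' @param av_theta the \eqn{(q+p) \times (q+p)} asymptotic covariance
#'   of \eqn{\sqrt{N}\hat\theta} (see [av_theta_ml()]).
#' @return the \eqn{r \times r} asymptotic covariance of
#'   \eqn{\sqrt{N}\hat\gamma}.
#' @export
delta_av <- function(jacobian, av_theta) {
  jacobian <- as.matrix(jacobian)
  if (ncol(jacobian) != nrow(av_theta))
    dosem_error("bad_query", "Jacobian and AV(theta) are not conformable")
  AV <- jacobian %*% av_theta %*% t(jacobian)
  (AV + t(AV)) / 2
}

#' Delta-method inference for a causal quantity
#'
#' Combines a point value, its Jacobian and the asymptotic covariance
#' of the parameter estimator into asymptotic standard errors,
#' z-values and normal-theory confidence intervals.
#'
#' @param value numeric vector: the causal quantity \eqn{\hat\gamma}.
#' @param jacobian its Jacobian in `theta` (rows match `value`).
#' @param av_theta asymptotic covariance of \eqn{\sqrt{N}\hat\theta}.
#' @param N sample size.
#' @param level confidence level (default 0.95; the exact normal
#'   quantile is used).
#' @return a data frame with columns `value`, `ase`, `z`, `lower`,
#'   `upper`.
#' @export
delta_inference <- function(value, jacobian, av_theta, N, level = 0.95) {
  AV <- delta_av(jacobian, av_theta)
  ase <- sqrt(pmax(diag(AV), 0) / N)
  zq <- stats::qnorm((1 + level) / 2)
  data.frame(
    value = as.numeric(value),
    ase = ase,
    z = as.numeric(value) / ase,
    lower = as.numeric(value) - zq * ase,
    upper = as.numeric(value) + zq * ase,
    row.names = if (!is.null(names(value))) names(value) else NULL
  )
}
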