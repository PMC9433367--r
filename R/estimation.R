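#' Sample moments for covariance-structure fitting
#'
#' Builds the sample covariance matrix from raw data (columns are
#' centered at load time; means are discarded, since the model has no
#' mean structure) or wraps a user-supplied covariance matrix.
#'
#' @param data a data frame or matrix of observations (rows = units,
#'   columns = observed variables matching the model's variable
#'   names), or `NULL` when `S` is given.
#' @param S optional sample covariance matrix.
#' @param N sample size (required with `S`).
#' @param denominator `"N"` (maximum-likelihood convention, default)
#'   or `"N-1"` for the unbiased divisor; applies only when computing
#'   from `data`.
#' @return an object of class `dosem_moments` with elements `S`, `N`
#'   and `variables`.
#' @export
sample_moments <- function(data = NULL, S = NULL, N = NULL,
                           denominator = c("N", "N-1")) {
  denominator <- match.arg(denominator)
  if (is.null(S)) {
    X <- as.matrix(data)
    storage.mode(X) <- "double"
    N <- nrow(X)
    X <- scale(X, center = TRUE, scale = FALSE)
    div <- if (denominator == "N") N else N - 1L
    S <- crossprod(X) / div
    vars <- colnames(X)
  } else {
    S <- as.matrix(S)
    if (is.null(N)) dosem_error("bad_data", "N is required with a covariance input")
    vars <- colnames(S)
  }
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
    dosem_error("bad_data", "sample covariance matrix is not symmetric")
  S <- (S + t(S)) / 2
  if (N <= nrow(S))
    dosem_error("bad_data", "sample size must exceed the number of variables")
  structure(list(S = S, N = as.integer(N), variables = vars),
            class = "dosem_moments")
}

# d vec Sigma / d theta' (n^2 x (q+p)):
# Sigma = B Psi B' with B = (I-C)^{-1}, so
# dSigma = B dC Sigma + Sigma dC' B' + B dPsi B'.
dvec_sigma <- function(spec, theta, ds = derivative_structure(spec)) {
  mats <- build_matrices(spec, theta, check_pd = FALSE)
  B <- reduced_form(mats$C)
  Sigma <- B %*% mats$Psi %*% t(B)
  K <- commutation_matrix(spec$n)
  ((Sigma %x% B) + (B %x% Sigma) %*% K) %*% ds$dvecC +
    (B %x% B) %*% ds$dvecPsi
}

#' Jacobian of the model-implied covariance structure
#'
#' The \eqn{n(n+1)/2 \times (q+p)} matrix
#' \eqn{\Delta = \partial\,\mathrm{vech}\,\Sigma(\theta) / \partial\theta^\top}.
#' Columns of equality-constrained (shared) labels are the sums of the
#' per-position derivatives.  `Delta` drives both the analytic ML
#' gradient and the rank-based local identification check.
#'
#' @inheritParams g1
#' @return the Jacobian matrix with columns named by label.
#' @export
delta_sigma <- function(spec, theta) {
  J <- elimination_matrix(spec$n) %*% dvec_sigma(spec, theta)
  colnames(J) <- theta_labels(spec)
  J
}

# ML discrepancy and its analytic gradient.
fml_value <- function(spec, theta, S, logdetS) {
  mats <- tryCatch(build_matrices(spec, theta, check_pd = FALSE),
                   error = function(e) NULL)
  if (is.null(mats)) return(NULL)
  B <- reduced_form(mats$C)
  Sigma <- B %*% mats$Psi %*% t(B)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Sinv <- chol2inv(ch)
  F <- 2 * sum(log(diag(ch))) + sum(Sinv * S) - logdetS - nrow(S)
  list(F = F, Sigma = Sigma, Sigma_inv = Sinv)
}

fml_gradient <- function(spec, theta, S, cache = NULL, logdetS = NULL,
                         ds = derivative_structure(spec)) {
  if (is.null(cache)) cache <- fml_value(spec, theta, S, logdetS)
  if (is.null(cache)) return(NULL)
  W <- cache$Sigma_inv %*% (cache$Sigma - S) %*% cache$Sigma_inv
  drop(t(dvec_sigma(spec, theta, ds)) %*% vec(W))
}

default_start <- function(spec, S) {
  theta <- stats::setNames(rep(0, spec$q + spec$p), theta_labels(spec))
  svar <- diag(S)
  idx <- stats::setNames(seq_len(spec$n), spec$variables)
  # error variances from sample variances; covariances stay 0
  for (k in seq_len(nrow(spec$bidirected))) {
    lab <- spec$bidirected$label[k]
    if (!lab %in% spec$labels_P) next
    if (spec$bidirected$v1[k] == spec$bidirected$v2[k])
      theta[lab] <- svar[idx[[spec$bidirected$v1[k]]]]
  }
  theta
}

#' Maximum-likelihood fit of a linear ADMG model
#'
#' Estimates the free parameters by minimizing the normal-theory ML
#' discrepancy
#' \eqn{F_{ML}(\theta) = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma(\theta)^{-1}) - \log|S| - n}
#' between the model-implied and the sample covariance matrix, using
#' quasi-Newton iterations with the analytic gradient followed by
#' Fisher-scoring polish, from a default start (path coefficients 0,
#' error variances at the sample variances, covariances 0) plus
#' jittered multi-starts drawn under a fixed internal seed to guard
#' against local minima.
#'
#' @param spec a [model_spec()] object.
#' @param sample a [sample_moments()] object (or a data frame, which
#'   is passed through `sample_moments()`).
#' @param start optional starting values (named or canonical order).
#' @param multistart number of jittered extra starts (default 5).
#' @param information `"expected"` (default) or `"observed"`, passed
#'   to [av_theta_ml()].
#' @return an object of class `dosem_fit`: `theta` (estimates),
#'   `av_theta`, `ase`, `z`, `F_ML`, `converged` (gradient max-norm
#'   below `1e-8`), `gradient_norm`, `identification` (see
#'   [local_identification()]), `N`, `S`, `spec`.
#' @export
#' @examples
#' fx <- illustration_fixture()
#' Sigma <- model_implied_covariance(build_matrices(fx$spec, fx$theta))
#' fit <- ml_fit(fx$spec, sample_moments(S = Sigma, N = 100))
#' max(abs(fit$theta - fx$theta)) < 1e-6  # perfect-fit fixed point
ml_fit <- function(spec, sample, start = NULL, multistart = 5,
                   information = c("expected", "observed")) {
  information <- match.arg(information)
  if (!inherits(sample, "dosem_moments")) sample <- sample_moments(sample)
  S <- sample$S
  if (!is.null(sample$variables) &&
      !identical(unname(sample$variables), unname(spec$variables))) {
    if (!all(spec$variables %in% sample$variables))
      dosem_error("bad_data", "data columns do not match model variables")
    S <- S[spec$variables, spec$variables]
  }
  logdetS <- determinant(S, logarithm = TRUE)$modulus
  if (!is.finite(logdetS))
    dosem_error("bad_data", "sample covariance matrix is singular")
  logdetS <- as.numeric(logdetS)

  labels <- theta_labels(spec)
  s0 <- if (is.null(start)) default_start(spec, S) else theta_canonical(spec, start)
  starts <- list(s0)
  if (multistart > 1L) {
    jit <- with_preserved_seed(20240915, {
      lapply(seq_len(multistart - 1L), function(i) {
        s0 + stats::rnorm(length(s0), 0, 0.1 * pmax(abs(s0), 1))
      })
    })
    starts <- c(starts, jit)
  }

  ds <- derivative_structure(spec)
  big <- 1e10
  fn <- function(th) {
    v <- fml_value(spec, stats::setNames(th, labels), S, logdetS)
    if (is.null(v) || !is.finite(v$F)) big else v$F
  }
  gr <- function(th) {
    g <- fml_gradient(spec, stats::setNames(th, labels), S,
                      logdetS = logdetS, ds = ds)
    if (is.null(g) || any(!is.finite(g))) rep(0, length(th)) else g
  }

  best <- NULL
  for (st in starts) {
    # Fisher scoring from the start is fast and usually sufficient;
    # fall back to quasi-Newton when it stalls away from a stationary
    # point, then polish again.
    th <- fisher_polish(spec, st, S, logdetS, ds = ds)
    g <- fml_gradient(spec, th, S, logdetS = logdetS, ds = ds)
    if (is.null(g) || max(abs(g)) > 1e-8) {
      opt <- tryCatch(
        stats::optim(th, fn, gr, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(opt))
        th <- fisher_polish(spec, stats::setNames(opt$par, labels),
                            S, logdetS, ds = ds)
    }
    Fv <- fn(th)
    if (is.null(best) || Fv < best$F) best <- list(theta = th, F = Fv)
  }
  if (is.null(best))
    dosem_error("no_convergence", "all optimization starts failed")

  theta_hat <- best$theta
  g <- fml_gradient(spec, theta_hat, S, logdetS = logdetS, ds = ds)
  gnorm <- max(abs(g))
  converged <- is.finite(gnorm) && gnorm < 1e-8

  # Psi at the solution must be a proper covariance matrix
  mats <- build_matrices(spec, theta_hat, check_pd = TRUE)

  ident <- local_identification(spec, theta = theta_hat)
  av <- NULL; ase <- NULL; zval <- NULL
  if (ident$locally_identified) {
    av <- av_theta_ml(spec, theta_hat, information = information, S = S)
    ase <- sqrt(diag(av) / sample$N)
    zval <- theta_hat / ase
  } else {
    warning("model is not locally identified at the solution; ",
            "no asymptotic covariance computed")
  }
  if (!converged)
    warning(sprintf("gradient max-norm %.2e at solution (tolerance 1e-8)",
                    gnorm))

  structure(
    list(theta = theta_hat, av_theta = av, ase = ase, z = zval,
         F_ML = best$F, converged = converged, gradient_norm = gnorm,
         identification = ident, N = sample$N, S = S, spec = spec,
         Sigma = model_implied_covariance(mats)),
    class = "dosem_fit"
  )
}

# Fisher-scoring refinement: Newton steps on the expected curvature
# Delta' D'(Sigma^-1 x Sigma^-1) D Delta with step halving.
fisher_polish <- function(spec, theta, S, logdetS, maxit = 100L,
                          ds = derivative_structure(spec)) {
  labels <- names(theta)
  Dn <- duplication_matrix(spec$n)
  Ln <- elimination_matrix(spec$n)
  cur <- fml_value(spec, theta, S, logdetS)
  if (is.null(cur)) return(theta)
  g <- fml_gradient(spec, theta, S, cache = cur, ds = ds)
  if (is.null(g)) return(theta)
  for (it in seq_len(maxit)) {
    gnorm <- max(abs(g))
    if (gnorm < 1e-11) break
    Delta <- Ln %*% dvec_sigma(spec, theta, ds)
    Wv <- cur$Sigma_inv %x% cur$Sigma_inv
    H <- t(Delta) %*% t(Dn) %*% Wv %*% Dn %*% Delta
    step <- tryCatch(solve(H + diag(1e-12, nrow(H)), g),
                     error = function(e) NULL)
    if (is.null(step)) break
    # accept a damped step when it lowers F or, once F sits at its
    # floating-point floor, when it still shrinks the gradient
    improved <- FALSE
    lam <- 1
    for (h in 1:30) {
      cand <- stats::setNames(theta - lam * step, labels)
      v <- fml_value(spec, cand, S, logdetS)
      if (!is.null(v) && is.finite(v$F) && v$F <= cur$F + 1e-13) {
        gc_ <- fml_gradient(spec, cand, S, cache = v, ds = ds)
        if (!is.null(gc_) &&
            (v$F < cur$F - 1e-13 || max(abs(gc_)) < gnorm)) {
          theta <- cand
          cur <- v
          g <- gc_
          improved <- TRUE
          break
        }
      }
      lam <- lam / 2
    }
    if (!improved) break
  }
  theta
}

#' Normal-theory asymptotic covariance of the ML estimator
#'
#' The expected-information form
#' \eqn{\mathrm{AV}(\sqrt{N}\hat\theta) = 2\,[\Delta^\top D_n^\top (\Sigma^{-1} \otimes \Sigma^{-1}) D_n \Delta]^{-1}}
#' with \eqn{\Delta = \partial\,\mathrm{vech}\,\Sigma / \partial\theta^\top}
#' evaluated at `theta` (the standard covariance-structure ML result).
#' With `information = "observed"` the curvature of the discrepancy at
#' the supplied sample covariance `S` is used instead (central finite
#' differences of the analytic gradient).
#'
#' @inheritParams g1
#' @param information `"expected"` (default) or `"observed"`.
#' @param S sample covariance matrix; required for the observed form.
#' @return the \eqn{(q+p) \times (q+p)} asymptotic covariance matrix
#'   of \eqn{\sqrt{N}\hat\theta}.
#' @export
av_theta_ml <- function(spec, theta, information = c("expected", "observed"),
                        S = NULL) {
  information <- match.arg(information)
  theta <- theta_canonical(spec, theta)
  if (information == "expected") {
    mats <- build_matrices(spec, theta, check_pd = FALSE)
    Sigma <- model_implied_covariance(mats)
    Sinv <- chol2inv(chol(Sigma))
    Dn <- duplication_matrix(spec$n)
    Delta <- delta_sigma(spec, theta)
    info <- t(Delta) %*% t(Dn) %*% (Sinv %x% Sinv) %*% Dn %*% Delta
  } else {
    if (is.null(S))
      dosem_error("bad_data", "observed information requires the sample S")
    logdetS <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
    k <- length(theta)
    info <- matrix(0, k, k)
    h <- 1e-5 * pmax(abs(theta), 1)
    for (i in seq_len(k)) {
      up <- theta; up[i] <- up[i] + h[i]
      dn <- theta; dn[i] <- dn[i] - h[i]
      gu <- fml_gradient(spec, up, S, logdetS = logdetS)
      gd <- fml_gradient(spec, dn, S, logdetS = logdetS)
      info[i, ] <- (gu - gd) / (2 * h[i])
    }
    info <- (info + t(info)) / 2
  }
  av <- tryCatch(2 * solve(info), error = function(e) NULL)
  if (is.null(av))
    dosem_error("not_identified", "singular information matrix")
  av <- (av + t(av)) / 2
  dimnames(av) <- list(theta_labels(spec), theta_labels(spec))
  av
}

#' Numeric local identification check
#'
#' A parameter vector is locally identified from the covariance
#' structure when the Jacobian \eqn{\Delta} of
#' \eqn{\mathrm{vech}\,\Sigma(\theta)} has full column rank
#' \eqn{q + p}.  The rank is evaluated at several random parameter
#' draws (to avoid unlucky points) using a singular-value threshold of
#' `max(dim) * eps * sigma_max * 1e3`, and identification is declared
#' only when every draw agrees; when supplied, the check is also run
#' at `theta`.  For rank-deficient models the labels loading on the
#' null space are reported.
#'
#' @param spec a [model_spec()] object.
#' @param theta optional parameter value at which to check in
#'   addition to the random draws.
#' @param draws number of random parameter draws (default 5).
#' @param seed seed for the draws (fixed default so reports are
#'   reproducible).
#' @return list with `locally_identified`, `delta_rank` (the minimum
#'   rank observed), `n_free` (\eqn{q+p}), `ranks` per draw, and
#'   `deficient_labels`.
#' @export
local_identification <- function(spec, theta = NULL, draws = 5, seed = 171) {
  k <- spec$q + spec$p
  thetas <- with_preserved_seed(seed, {
    lapply(seq_len(draws), function(i) {
      stats::setNames(
        c(stats::runif(spec$q, -1, 1), stats::runif(spec$p, 0.5, 2)),
        theta_labels(spec))
    })
  })
  if (!is.null(theta)) thetas <- c(list(theta_canonical(spec, theta)), thetas)

  ranks <- integer(length(thetas))
  deficient <- character(0)
  for (i in seq_along(thetas)) {
    D <- delta_sigma(spec, thetas[[i]])
    sv <- svd(D, nu = 0L, nv = k)
    tol <- max(dim(D)) * .Machine$double.eps * max(sv$d) * 1e3
    ranks[i] <- sum(sv$d > tol)
    if (ranks[i] < k) {
      null_cols <- sv$v[, (ranks[i] + 1L):k, drop = FALSE]
      loaded <- apply(abs(null_cols) > 1e-8, 1L, any)
      deficient <- union(deficient, theta_labels(spec)[loaded])
    }
  }
  list(
    locally_identified = all(ranks == k),
    delta_rank = min(ranks),
    n_free = k,
    ranks = ranks,
    deficient_labels = deficient
  )
}

#' @export
print.dosem_fit <- function(x, ...) {
  cat("Covariance-based ML fit (N = ", x$N, ")\n", sep = "")
  cat("  F_ML = ", format(x$F_ML, digits = 6),
      ";  converged: ", x$converged,
      ";  locally identified: ", x$identification$locally_identified,
      "\n", sep = "")
  tab <- data.frame(estimate = x$theta)
  if (!is.null(x$ase)) {
    tab$ase <- x$ase
    tab$z <- x$z
  }
  print(round(tab, 4))
  invisible(x)
}
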