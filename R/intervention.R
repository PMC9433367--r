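#' Define a do-type intervention
#'
#' An intervention fixes a subset of variables to constant levels,
#' replacing their structural equations (modularity: all other
#' equations are unchanged).  Interventional indexes are stored in
#' ascending order, with `x` re-ordered to match; the complement set N
#' is ascending as well.
#'
#' @param spec a [model_spec()] object, or an integer giving the number
#'   of variables when `do` uses numeric indexes.
#' @param do named numeric vector of interventional levels, e.g.
#'   `c(X2 = 11.54)` (names are variable names, or 1-based indexes
#'   given as names when `spec` is an integer).  An empty vector gives
#'   the observational (no-intervention) case.
#' @return an object of class `dosem_intervention` with elements
#'   `I` (ascending interventional indexes), `x` (matching levels),
#'   `N` (ascending complement), `n` and `variables`.
#' @export
#' @examples
#' fx <- illustration_fixture()
#' intervention(fx$spec, c(X2 = 11.54))
intervention <- function(spec, do = numeric(0)) {
  if (inherits(spec, "dosem_spec")) {
    n <- spec$n
    vars <- spec$variables
  } else {
    n <- as.integer(spec)
    vars <- NULL
  }
  do <- unlist(do)
  if (length(do) == 0L) {
    I <- integer(0); x <- numeric(0)
  } else {
    if (is.null(names(do)) || any(names(do) == ""))
      dosem_error("bad_intervention", "'do' must be a named vector")
    if (!is.null(vars)) {
      unknown <- setdiff(names(do), vars)
      if (length(unknown))
        dosem_error("bad_intervention", paste0(
          "unknown variable in intervention: ",
          paste(unknown, collapse = ", ")))
      I <- match(names(do), vars)
    } else {
      I <- as.integer(names(do))
    }
    if (anyDuplicated(I))
      dosem_error("bad_intervention", "duplicate intervention target")
    if (any(I < 1L | I > n))
      dosem_error("bad_intervention", "intervention index out of range")
    ord <- order(I)
    I <- I[ord]
    x <- as.numeric(do)[ord]
  }
  structure(
    list(I = I, x = x, N = setdiff(seq_len(n), I), n = n, variables = vars),
    class = "dosem_intervention"
  )
}

#' Selection matrices of an intervention
#'
#' Zero-one matrices extracting interventional and non-interventional
#' coordinates: `one_I` (\eqn{n \times K_x}) holds the unit vectors of
#' the interventional indexes, `one_N` those of the complement, and
#' `I_N = one_N one_N'` is the diagonal indicator of the
#' non-interventional set.
#'
#' @param n number of variables.
#' @param intv a [intervention()] object.
#' @return list with `one_I`, `one_N` and `I_N`.
#' @export
selection_matrices <- function(n, intv) {
  stopifnot(inherits(intv, "dosem_intervention"))
  if (intv$n != n)
    dosem_error("bad_intervention", "intervention was built for a different n")
  E <- diag(n)
  one_I <- E[, intv$I, drop = FALSE]
  one_N <- E[, intv$N, drop = FALSE]
  list(one_I = one_I, one_N = one_N, I_N = one_N %*% t(one_N))
}

#' Transformation matrices of the mutilated system
#'
#' Under `do(x)` the reduced form is
#' \eqn{V | do(x) = T_1 \varepsilon + a_1 x} with
#' \eqn{T_1 = (I - I_N C)^{-1} I_N} (rank \eqn{n - K_x}) and
#' \eqn{a_1 = (I - I_N C)^{-1} 1_I}; the non-interventional subvector
#' uses \eqn{T_2 = 1_N' T_1} and \eqn{a_2 = 1_N' a_1}.  Rows of `T1`
#' at interventional indexes are exactly zero (those variables carry
#' no randomness under the intervention).
#'
#' @param mats a `dosem_matrices` object from [build_matrices()].
#' @param intv a [intervention()] object.
#' @return list with `T1`, `a1`, `T2`, `a2` and `Minv`
#'   (\eqn{(I - I_N C)^{-1}}).
#' @export
transformation_matrices <- function(mats, intv) {
  n <- nrow(mats$C)
  sel <- selection_matrices(n, intv)
  M <- diag(n) - sel$I_N %*% unname(mats$C)
  Minv <- solve(M)
  T1 <- Minv %*% sel$I_N
  T1[intv$I, ] <- 0  # exact, by construction of the mutilated system
  a1 <- Minv %*% sel$one_I
  list(
    T1 = T1,
    a1 = a1,
    T2 = t(sel$one_N) %*% T1,
    a2 = t(sel$one_N) %*% a1,
    Minv = Minv
  )
}

#' Moments of the interventional distribution
#'
#' Closed-form first and second moments of \eqn{V | do(x)}: mean
#' \eqn{a_1 x} and covariance \eqn{T_1 \Psi T_1'}.  The covariance is
#' an \eqn{n \times n} singular matrix of rank \eqn{n - K_x}, with
#' exactly zero rows and columns at the interventional indexes, and
#' does not depend on `x`.
#'
#' @param mats a `dosem_matrices` object.
#' @param intv a [intervention()] object.
#' @return an object of class `dosem_intdist` with elements `mean`,
#'   `cov`, `rank`, the cached transformation matrices `T1`, `a1`,
#'   `T2`, `a2`, and the intervention.
#' @export
#' @examples
#' fx <- illustration_fixture()
#' m <- build_matrices(fx$spec, fx$theta)
#' d <- interventional_moments(m, intervention(fx$spec, c(X2 = 11.54)))
#' d$mean["Y3"]      # -6.92 mg/dl
#' d$cov["Y3", "Y3"] # 1096.39
interventional_moments <- function(mats, intv) {
  tr <- transformation_matrices(mats, intv)
  mu <- drop(tr$a1 %*% intv$x)
  if (length(intv$I) == 0L) mu <- rep(0, intv$n)
  V <- tr$T1 %*% mats$Psi %*% t(tr$T1)
  V[intv$I, ] <- 0
  V[, intv$I] <- 0
  V <- (V + t(V)) / 2
  vars <- mats$variables
  names(mu) <- vars
  dimnames(V) <- list(vars, vars)
  structure(
    list(
      mean = mu, cov = V, rank = intv$n - length(intv$I),
      T1 = tr$T1, a1 = tr$a1, T2 = tr$T2, a2 = tr$a2,
      intervention = intv, variables = vars
    ),
    class = "dosem_intdist"
  )
}

#' @export
print.dosem_intdist <- function(x, ...) {
  K <- length(x$intervention$I)
  cat("Interventional distribution: singular Gaussian of rank ",
      x$rank, " in dimension ", x$intervention$n, "\n", sep = "")
  if (K) {
    lab <- if (!is.null(x$variables)) x$variables[x$intervention$I]
           else x$intervention$I
    cat("  do(", paste(lab, "=", signif(x$intervention$x, 6),
                       collapse = ", "), ")\n", sep = "")
  }
  cat("  mean:\n"); print(signif(x$mean, 6))
  invisible(x)
}

# Resolve outcome names/indexes and check they are non-interventional.
resolve_outcomes <- function(dist, outcomes) {
  if (is.character(outcomes)) {
    if (is.null(dist$variables))
      dosem_error("bad_query", "model has no variable names")
    iy <- match(outcomes, dist$variables)
    if (anyNA(iy))
      dosem_error("bad_query", paste0(
        "unknown outcome variable: ",
        paste(outcomes[is.na(iy)], collapse = ", ")))
  } else {
    iy <- as.integer(outcomes)
  }
  bad <- intersect(iy, dist$intervention$I)
  if (length(bad))
    dosem_error("bad_query",
                "outcome variables must not be intervention targets")
  iy
}

#' Marginal interventional distribution of a set of outcomes
#'
#' Selects the rows/columns of the interventional mean and covariance
#' for outcome variables \eqn{Y \subseteq V_N}; the resulting
#' \eqn{K_y \times K_y} covariance block is nonsingular.
#'
#' @param dist a `dosem_intdist` object.
#' @param outcomes variable names or indexes, disjoint from the
#'   intervention targets.
#' @return list with `mean` (length \eqn{K_y}) and `cov`
#'   (\eqn{K_y \times K_y}).
#' @export
marginal_interventional <- function(dist, outcomes) {
  iy <- resolve_outcomes(dist, outcomes)
  list(mean = dist$mean[iy], cov = dist$cov[iy, iy, drop = FALSE])
}

#' Interventional density
#'
#' Evaluates the (nonsingular) Gaussian density of the interventional
#' distribution of a set of non-interventional variables at a point.
#' With `outcomes = NULL` the density of the full non-interventional
#' vector \eqn{v_N} is returned.
#'
#' @param dist a `dosem_intdist` object.
#' @param v numeric vector: the evaluation point, ordered like
#'   `outcomes` (or like the ascending complement set when `outcomes`
#'   is `NULL`).
#' @param outcomes optional outcome subset (names or indexes).
#' @return the density value (scalar).
#' @export
interventional_pdf <- function(dist, v, outcomes = NULL) {
  if (is.null(outcomes)) outcomes <- dist$intervention$N
  mom <- marginal_interventional(dist, outcomes)
  if (length(v) != length(mom$mean))
    dosem_error("bad_query", "evaluation point has the wrong length")
  gaussian_pdf(v, mom$mean, mom$cov)
}

gaussian_pdf <- function(v, mu, S) {
  k <- length(mu)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch))
    dosem_error("singular", "singular covariance block in density")
  z <- backsolve(ch, v - mu, transpose = TRUE)
  exp(-0.5 * sum(z^2) - sum(log(diag(ch))) - 0.5 * k * log(2 * pi))
}

#' Interventional interval (rectangle) probability
#'
#' Probability that outcome variables fall in
#' \eqn{[y^{low}, y^{up}]} under `do(x)`.  For a single outcome this
#' is the difference of two normal cdf values; for several outcomes a
#' deterministic quadrature rule for multivariate normal rectangle
#' probabilities is used (absolute accuracy about `1e-6`).
#'
#' @param dist a `dosem_intdist` object.
#' @param outcomes outcome subset (names or indexes).
#' @param lower,upper numeric bounds, recycled to the number of
#'   outcomes; infinite values allowed.
#' @return the probability (scalar).
#' @export
#' @examples
#' fx <- illustration_fixture()
#' d <- interventional_moments(build_matrices(fx$spec, fx$theta),
#'                             intervention(fx$spec, c(X2 = 11.54)))
#' interval_probability(d, "Y3", -40, 80)  # 0.8368
interval_probability <- function(dist, outcomes, lower, upper) {
  mom <- marginal_interventional(dist, outcomes)
  k <- length(mom$mean)
  lower <- rep_len(as.numeric(lower), k)
  upper <- rep_len(as.numeric(upper), k)
  if (any(lower >= upper))
    dosem_error("bad_query", "bounds must satisfy lower < upper")
  gaussian_rectangle(lower, upper, mom$mean, mom$cov)
}

gaussian_rectangle <- function(lower, upper, mu, S) {
  if (length(mu) == 1L) {
    s <- sqrt(S[1L, 1L])
    return(unname(stats::pnorm((upper - mu) / s) -
                    stats::pnorm((lower - mu) / s)))
  }
  as.numeric(mvtnorm::pmvnorm(
    lower = lower, upper = upper, mean = as.numeric(mu), sigma = S,
    algorithm = mvtnorm::Miwa(steps = 512)
  ))
}

#' Average treatment effect
#'
#' The ATE of `do(x)` versus `do(x_prime)` on a single outcome is the
#' interventional mean difference \eqn{\imath_j' a_1 (x - x')}; in a
#' linear model it is the total-path coefficient times the level
#' contrast.
#'
#' @param mats a `dosem_matrices` object.
#' @param outcome outcome variable (name or index).
#' @param treatment treated variable (name or index).
#' @param x,x_prime the two treatment levels being contrasted.
#' @return the ATE (scalar).
#' @export
#' @examples
#' fx <- illustration_fixture()
#' m <- build_matrices(fx$spec, fx$theta)
#' average_treatment_effect(m, "Y3", "X2", 1, 0)  # -0.6
average_treatment_effect <- function(mats, outcome, treatment, x, x_prime) {
  vars <- mats$variables
  j <- if (is.character(outcome)) match(outcome, vars) else as.integer(outcome)
  i <- if (is.character(treatment)) match(treatment, vars) else as.integer(treatment)
  if (anyNA(c(i, j)))
    dosem_error("bad_query", "unknown outcome or treatment variable")
  if (i == j)
    dosem_error("bad_query", "treatment and outcome must differ")
  intv <- intervention(nrow(mats$C), stats::setNames(0, i))
  tr <- transformation_matrices(mats, intv)
  unname(tr$a1[j, 1L]) * (x - x_prime)
}

#' Gaussian conditional distribution (seeing, not doing)
#'
#' Standard Gaussian conditioning on a joint covariance matrix, as a
#' contrast to the interventional distribution: the conditional mean
#' is linear in the conditioning values with slope
#' \eqn{\Sigma_{yg}\Sigma_{gg}^{-1}} and the conditional covariance is
#' the Schur complement.  Conditioning on nothing returns the marginal
#' distribution of the outcomes.
#'
#' @param Sigma joint covariance matrix (e.g. from
#'   [model_implied_covariance()]).
#' @param given conditioning variables (names or indexes); may be
#'   empty.
#' @param values optional conditioning values; when supplied the
#'   conditional mean vector is returned as well.
#' @param outcomes outcome variables; defaults to the complement of
#'   `given`.
#' @return list with `slope` (\eqn{K_y \times K_g}), `cov`
#'   (conditional covariance), and `mean` if `values` was given.
#' @export
#' @examples
#' fx <- illustration_fixture()
#' Sigma <- model_implied_covariance(build_matrices(fx$spec, fx$theta))
#' cd <- conditional_distribution(Sigma, "X2", outcomes = "Y3")
#' cd$slope  # 1.76: regression of glucose on observed insulin
conditional_distribution <- function(Sigma, given, values = NULL,
                                     outcomes = NULL) {
  vars <- rownames(Sigma)
  to_idx <- function(v) {
    if (is.character(v)) {
      i <- match(v, vars)
      if (anyNA(i)) dosem_error("bad_query", "unknown variable name")
      i
    } else as.integer(v)
  }
  g <- if (missing(given) || length(given) == 0L) integer(0) else to_idx(given)
  y <- if (is.null(outcomes)) setdiff(seq_len(nrow(Sigma)), g) else to_idx(outcomes)
  if (length(intersect(g, y)))
    dosem_error("bad_query", "outcomes overlap the conditioning set")

  Syy <- Sigma[y, y, drop = FALSE]
  if (length(g) == 0L) {
    out <- list(slope = matrix(0, length(y), 0L), cov = Syy)
    if (!is.null(values)) out$mean <- rep(0, length(y))
    return(out)
  }
  Sgg <- Sigma[g, g, drop = FALSE]
  ch <- tryCatch(chol(Sgg), error = function(e) NULL)
  if (is.null(ch))
    dosem_error("singular", "singular conditioning block")
  slope <- t(backsolve(ch, backsolve(ch, t(Sigma[y, g, drop = FALSE]),
                                     transpose = TRUE)))
  ccov <- Syy - slope %*% Sigma[g, y, drop = FALSE]
  ccov <- (ccov + t(ccov)) / 2
  out <- list(slope = slope, cov = ccov)
  if (!is.null(values)) out$mean <- drop(slope %*% as.numeric(values))
  out
}

#' Optimal single-dose intervention level
#'
#' Searches for the interventional level `x` of a single treatment
#' variable that maximizes the probability that a single outcome falls
#' in `[lower, upper]`.  Because the interventional mean is linear in
#' `x` (slope \eqn{b}) while the interventional variance does not
#' depend on `x`, the optimum places the mean at the interval midpoint
#' whenever \eqn{b \neq 0}; the numerical search is cross-checked
#' against this closed form.  A zero slope makes the objective flat,
#' which is reported via `flat = TRUE` rather than an arbitrary level.
#'
#' @param mats a `dosem_matrices` object.
#' @param treatment single treatment variable (name or index).
#' @param outcome single outcome variable (name or index).
#' @param lower,upper finite interval bounds for the outcome.
#' @param search numeric length-2 search interval for the level.
#' @return list with `x_star`, `p_star`, `slope`, `sigma2`, `flat`.
#' @export
optimal_intervention_level <- function(mats, treatment, outcome,
                                       lower, upper,
                                       search = c(-100, 100)) {
  vars <- mats$variables
  i <- if (is.character(treatment)) match(treatment, vars) else as.integer(treatment)
  j <- if (is.character(outcome)) match(outcome, vars) else as.integer(outcome)
  if (anyNA(c(i, j)) || i == j)
    dosem_error("bad_query", "invalid treatment/outcome pair")
  intv <- intervention(nrow(mats$C), stats::setNames(1, i))
  dist <- interventional_moments(mats, intv)
  b <- unname(dist$a1[j, 1L])   # interventional mean per unit dose
  s2 <- unname(dist$cov[j, j])  # dose-independent interventional variance
  optimal_dose_gaussian(b, s2, lower, upper, search)
}

#' @describeIn optimal_intervention_level Low-level search given the
#'   interventional mean coefficient `slope` (mean at dose `x` is
#'   `slope * x`) and the interventional variance `sigma2`; useful when
#'   those two numbers come from elsewhere (e.g. estimates reported by an earlier fit).
#' @param slope interventional mean per unit dose.
#' @param sigma2 interventional variance of the outcome.
#' @export
optimal_dose_gaussian <- function(slope, sigma2, lower, upper,
                                  search = c(-100, 100)) {
  stopifnot(is_number(slope), is_number(sigma2), sigma2 > 0,
            is_number(lower), is_number(upper), lower < upper)
  s <- sqrt(sigma2)
  objective <- function(x) {
    mu <- slope * x
    stats::pnorm((upper - mu) / s) - stats::pnorm((lower - mu) / s)
  }
  if (slope == 0) {
    warning("zero dose-response slope: success probability is flat in x")
    return(list(x_star = NA_real_, p_star = objective(0),
                slope = slope, sigma2 = sigma2, flat = TRUE))
  }
  opt <- stats::optimize(objective, interval = sort(search),
                         maximum = TRUE, tol = 1e-8)
  x_star <- opt$maximum
  # closed form: mean at the interval midpoint
  x_closed <- (lower + upper) / 2 / slope
  if (x_closed >= min(search) && x_closed <= max(search) &&
      objective(x_closed) >= opt$objective) {
    x_star <- x_closed
  }
  list(x_star = x_star, p_star = objective(x_star),
       slope = slope, sigma2 = sigma2, flat = FALSE)
}
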