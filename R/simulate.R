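#' Simulate data from a linear ADMG model
#'
#' `simulate_observational()` draws i.i.d. rows from the model-implied
#' joint distribution by sampling \eqn{\varepsilon \sim N_n(0, \Psi)}
#' and applying the reduced form \eqn{V = (I-C)^{-1}\varepsilon}.
#' `simulate_interventional()` draws from the mutilated system under
#' `do(x)`, \eqn{V = I_N C V + I_N \varepsilon + 1_I x}: the
#' interventional columns are constant at their levels and the
#' remaining columns follow the closed-form interventional
#' distribution.
#'
#' The error draw uses the lower-triangular Cholesky factor of `Psi`,
#' so a given seed reproduces the same table byte for byte, and the
#' observational and interventional runs of one seed share the same
#' underlying error realizations.
#'
#' @param spec a [model_spec()] object.
#' @param theta free parameter values.
#' @param N number of rows (units) to draw.
#' @param seed optional integer seed; when given, the caller's RNG
#'   state is left untouched.
#' @param intv a [intervention()] object (for the interventional
#'   sampler).
#' @return a data frame with `N` rows and one column per variable.
#' @export
#' @examples
#' fx <- illustration_fixture()
#' head(simulate_observational(fx$spec, fx$theta, N = 5, seed = 1))
simulate_observational <- function(spec, theta, N, seed = NULL) {
  mats <- build_matrices(spec, theta)
  B <- reduced_form(mats$C)
  eps <- draw_errors(mats$Psi, N, seed)
  out <- eps %*% t(B)
  colnames(out) <- spec$variables
  as.data.frame(out)
}

#' @rdname simulate_observational
#' @export
simulate_interventional <- function(spec, theta, N, intv, seed = NULL) {
  stopifnot(inherits(intv, "dosem_intervention"))
  mats <- build_matrices(spec, theta)
  tr <- transformation_matrices(mats, intv)
  eps <- draw_errors(mats$Psi, N, seed)
  shift <- drop(tr$a1 %*% intv$x)
  if (length(intv$I) == 0L) shift <- rep(0, spec$n)
  out <- eps %*% t(tr$T1) + matrix(shift, N, spec$n, byrow = TRUE)
  colnames(out) <- spec$variables
  as.data.frame(out)
}

draw_errors <- function(Psi, N, seed) {
  Lt <- assert_psi_pd(Psi)  # upper-triangular factor, Psi = t(Lt) %*% Lt
  Z <- with_preserved_seed(seed, {
    matrix(stats::rnorm(N * nrow(Psi)), N, nrow(Psi))
  })
  Z %*% Lt
}

#' The six-variable insulin-glucose panel example
#'
#' A cross-lagged panel model of mean-centered blood insulin
#' (`X1, X2, X3`, mcIU/ml) and blood glucose (`Y1, Y2, Y3`, mg/dl)
#' measured at three occasions.  Cross-lagged and autoregressive path
#' coefficients are time-constant (labels `c_xx`, `c_xy`, `c_yx`,
#' `c_yy` are each shared across the two transitions), the
#' contemporaneous insulin-glucose confounding at occasions 2 and 3
#' shares `psi_xy`, and the error structure carries serial
#' covariances.  The parameter values are the population values the
#' data-generating process of the accompanying examples uses
#' (e.g. a direct insulin-to-glucose effect `c_yx = -0.6`).
#'
#' @return list with `spec` (a [model_spec()]) and `theta` (named
#'   population values, \eqn{q = 4} structural and \eqn{p = 10}
#'   covariance parameters).
#' @export
#' @examples
#' fx <- illustration_fixture()
#' fx$spec
illustration_fixture <- function() {
  spec <- model_spec(
    variables = c("X1", "Y1", "X2", "Y2", "X3", "Y3"),
    directed = list(
      c("X1", "X2", "c_xx"),
      c("Y1", "X2", "c_xy"),
      c("X1", "Y2", "c_yx"),
      c("Y1", "Y2", "c_yy"),
      c("X2", "X3", "c_xx"),
      c("Y2", "X3", "c_xy"),
      c("X2", "Y3", "c_yx"),
      c("Y2", "Y3", "c_yy")
    ),
    bidirected = list(
      c("X1", "X1", "psi_x1x1"),
      c("Y1", "Y1", "psi_y1y1"),
      c("X1", "Y1", "psi_x1y1"),
      c("X2", "X2", "psi_xx"),
      c("X3", "X3", "psi_xx"),
      c("Y2", "Y2", "psi_yy"),
      c("Y3", "Y3", "psi_yy"),
      c("X2", "Y2", "psi_xy"),
      c("X3", "Y3", "psi_xy"),
      c("X1", "X2", "psi_x1x2"),
      c("X2", "X3", "psi_x2x3"),
      c("Y1", "Y2", "psi_y1y2"),
      c("Y2", "Y3", "psi_y2y3")
    )
  )
  theta <- c(
    c_xx = 0.05, c_xy = 0.4, c_yx = -0.6, c_yy = 1.2,
    psi_x1x1 = 131.76, psi_y1y1 = 632.94, psi_x1y1 = 254.12,
    psi_xx = 20, psi_yy = 40, psi_xy = 3,
    psi_x1x2 = 15, psi_x2x3 = 2, psi_y1y2 = 35, psi_y2y3 = 10
  )
  list(spec = spec, theta = theta)
}
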