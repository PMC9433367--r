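test_that("selection matrices extract the intervened coordinates", {
  sel <- selection_matrices(6, do_x2)
  expect_equal(drop(sel$one_I), c(0, 0, 1, 0, 0, 0))
  expect_equal(diag(sel$I_N), c(1, 1, 0, 1, 1, 1))
  expect_equal(crossprod(sel$one_I), matrix(1, 1, 1))
  expect_equal(sel$I_N, sel$one_N %*% t(sel$one_N))

  none <- intervention(6)
  sel0 <- selection_matrices(6, none)
  expect_equal(sel0$one_N, diag(6))
  expect_equal(sel0$I_N, diag(6))

  two <- intervention(3, c("1" = 0, "3" = 0))
  sel2 <- selection_matrices(3, two)
  expect_equal(drop(sel2$one_N), c(0, 1, 0))
  expect_equal(diag(sel2$I_N), c(0, 1, 0))

  expect_error(intervention(3, c("1" = 0, "1" = 1)),
               class = "dosem_bad_intervention")
  expect_error(intervention(3, c("4" = 0)),
               class = "dosem_bad_intervention")
})

test_that("transformation matrices carry the total-effect pathways", {
  tr <- transformation_matrices(fixture_mats, do_x2)
  # a1: unit entry for X2 itself, then one-step effects on X3 and Y3
  expect_equal(drop(tr$a1), c(0, 0, 1, 0, 0.05, -0.6),
               ignore_attr = TRUE)
  expect_equal(tr$T2, tr$T1[do_x2$N, ])
  expect_equal(drop(tr$a2), drop(tr$a1)[do_x2$N], ignore_attr = TRUE)

  # no pathways: C = 0 collapses T1 to the selection pattern
  spec0 <- model_spec(c("A", "B"),
                      bidirected = list(c("A", "A", "sa"), c("B", "B", "sb")))
  m0 <- build_matrices(spec0, c(sa = 1, sb = 1))
  iv0 <- intervention(spec0, c(A = 2))
  tr0 <- transformation_matrices(m0, iv0)
  sel0 <- selection_matrices(2, iv0)
  expect_equal(tr0$T1, sel0$I_N)
  expect_equal(tr0$a1, sel0$one_I)
})

test_that("T1 and T2 have rank n - K_x on randomized recursive models", {
  for (seed in 1:20) {
    rm_ <- random_model(n = sample(3:8, 1), seed = seed + 100)
    n <- rm_$spec$n
    K <- sample(seq_len(n - 1), 1)
    targets <- sort(sample(seq_len(n), K))
    iv <- intervention(n, setNames(rnorm(K), targets))
    m <- build_matrices(rm_$spec, rm_$theta, check_pd = FALSE)
    tr <- transformation_matrices(m, iv)
    tol <- max(dim(tr$T1)) * .Machine$double.eps * 100
    rank_T1 <- sum(svd(tr$T1)$d > tol)
    rank_T2 <- sum(svd(tr$T2)$d > tol)
    expect_equal(rank_T1, n - K)
    expect_equal(rank_T2, n - K)
  }
})

test_that("modularity: only the intervened equations are altered", {
  tr <- transformation_matrices(fixture_mats, do_x2)
  sel <- selection_matrices(6, do_x2)
  mutilated <- sel$I_N %*% fixture_mats$C
  expect_true(all(mutilated[do_x2$I, ] == 0))
  expect_equal(mutilated[do_x2$N, ], fixture_mats$C[do_x2$N, ],
               ignore_attr = TRUE)
  # intervened rows of T1 are exactly zero: no randomness under do()
  expect_true(all(tr$T1[do_x2$I, ] == 0))
})

test_that("interventional moments match the closed panel-model values", {
  d <- interventional_moments(fixture_mats, do_x2)
  expect_equal(d$cov["Y3", "Y3"], 1096.3855, tolerance = 1e-4 / 1096)
  expect_equal(d$mean[["Y3"]], -6.92, tolerance = 5e-3 / 6.92)
  expect_equal(d$rank, 5)
  expect_true(all(d$cov[do_x2$I, ] == 0) && all(d$cov[, do_x2$I] == 0))
  expect_equal(d$mean[["X2"]], 11.54)

  # observational limit
  d0 <- interventional_moments(fixture_mats, intervention(fixture$spec))
  expect_equal(unname(d0$mean), rep(0, 6))
  expect_equal(d0$cov, fixture_Sigma, tolerance = 1e-12)

  # covariance is bitwise independent of the interventional level
  d2 <- interventional_moments(fixture_mats,
                               intervention(fixture$spec, c(X2 = -123.456)))
  expect_identical(d$cov, d2$cov)
})

test_that("marginal interventional distribution selects consistent blocks", {
  d <- interventional_moments(fixture_mats, do_x2)
  mom <- marginal_interventional(d, "Y3")
  expect_equal(mom$mean[["Y3"]], -0.6 * 11.54)
  expect_equal(mom$cov[1, 1], 1096.3855, tolerance = 1e-4)

  allN <- marginal_interventional(d, do_x2$N)
  expect_equal(unname(allN$mean), drop(d$a2 %*% do_x2$x))
  expect_equal(unname(allN$cov),
               unname(d$T2 %*% fixture_mats$Psi %*% t(d$T2)),
               tolerance = 1e-12)
  expect_true(min(eigen(allN$cov, symmetric = TRUE,
                        only.values = TRUE)$values) > 0)

  expect_error(marginal_interventional(d, "X2"), class = "dosem_bad_query")
})

test_that("interventional density matches the univariate closed form", {
  # reference estimates (mean coefficient, variance) from an N = 100 fit
  mu <- -0.5217 * 11.54
  s2 <- 1007.2180
  expect_equal(dnorm(0, mu, sqrt(s2)), 0.0123, tolerance = 5e-5 / 0.0123)

  d <- interventional_moments(fixture_mats, do_x2)
  f <- interventional_pdf(d, 0, "Y3")
  expect_equal(f, dnorm(0, -6.924, sqrt(d$cov["Y3", "Y3"])))

  # density at the mean is the Gaussian mode 1 / sqrt(2 pi sigma^2)
  f_mode <- interventional_pdf(d, d$mean[["Y3"]], "Y3")
  expect_equal(f_mode, 1 / sqrt(2 * pi * d$cov["Y3", "Y3"]))

  # full-dimensional density integrates to one over the outcome margin
  int <- integrate(function(y) sapply(y, function(yy)
    interventional_pdf(d, yy, "Y3")), -500, 500, rel.tol = 1e-10)
  expect_equal(int$value, 1, tolerance = 1e-8)
})

test_that("interval probabilities reproduce the treatment-success values", {
  d <- interventional_moments(fixture_mats, do_x2)
  expect_equal(interval_probability(d, "Y3", -40, 80), 0.8368,
               tolerance = 1e-4 / 0.8368)
  expect_equal(interval_probability(d, "Y3", -Inf, Inf), 1)

  # reference N = 100 estimates as inputs
  p_est <- pnorm((80 + 0.5217 * 11.54) / sqrt(1007.218)) -
    pnorm((-40 + 0.5217 * 11.54) / sqrt(1007.218))
  expect_equal(p_est, 0.8545, tolerance = 1e-4 / 0.8545)

  # monotone in the bounds
  p1 <- interval_probability(d, "Y3", -40, 60)
  p2 <- interval_probability(d, "Y3", -40, 80)
  p3 <- interval_probability(d, "Y3", -60, 80)
  expect_true(p1 <= p2 && p2 <= p3)

  # bivariate rectangle against an independent simulation oracle
  dat <- simulate_interventional(fixture$spec, fixture$theta, 1e5, do_x2,
                                 seed = 7)
  lo <- c(-5, -40); up <- c(15, 80)
  p_mc <- mean(dat$X3 >= lo[1] & dat$X3 <= up[1] &
                 dat$Y3 >= lo[2] & dat$Y3 <= up[2])
  p_an <- interval_probability(d, c("X3", "Y3"), lo, up)
  se <- sqrt(p_an * (1 - p_an) / 1e5)
  expect_lt(abs(p_mc - p_an), 4 * se)
})

test_that("average treatment effects follow linear path tracing", {
  expect_equal(average_treatment_effect(fixture_mats, "Y3", "X2", 1, 0), -0.6)
  expect_equal(average_treatment_effect(fixture_mats, "Y3", "X2", 5, 5), 0)
  expect_equal(average_treatment_effect(fixture_mats, "Y3", "X2", 11.54, 0),
               -0.6 * 11.54)

  chain <- model_spec(c("V1", "V2", "V3"),
                      directed = list(c("V1", "V2", "a"), c("V2", "V3", "b")),
                      bidirected = list(c("V1", "V1", "s1"), c("V2", "V2", "s2"),
                                        c("V3", "V3", "s3")))
  mc <- build_matrices(chain, c(a = 0.7, b = -0.3, s1 = 1, s2 = 1, s3 = 1))
  expect_equal(average_treatment_effect(mc, "V3", "V1", 1, 0), 0.7 * -0.3)
  expect_error(average_treatment_effect(mc, "V1", "V1", 1, 0),
               class = "dosem_bad_query")
})

test_that("conditioning (seeing) differs from intervening (doing)", {
  cd <- conditional_distribution(fixture_Sigma, "X2", outcomes = "Y3")
  expect_equal(cd$slope[1, 1], 1.76, tolerance = 5e-3 / 1.76)
  expect_equal(cd$cov[1, 1], 353.99, tolerance = 5e-3 / 354)

  cd_val <- conditional_distribution(fixture_Sigma, "X2", values = 11.54,
                                     outcomes = "Y3")
  expect_equal(cd_val$mean, 1.76 * 11.54, tolerance = 1e-2)

  # conditioning on nothing returns the marginal
  cd0 <- conditional_distribution(fixture_Sigma, character(0),
                                  outcomes = "Y3", values = numeric(0))
  expect_equal(cd0$cov[1, 1], 766.91, tolerance = 5e-3 / 767)
  expect_equal(cd0$mean, 0)

  # independence: diagonal covariance gives zero slope
  Dg <- diag(c(2, 3)); dimnames(Dg) <- list(c("A", "B"), c("A", "B"))
  cdi <- conditional_distribution(Dg, "A", outcomes = "B")
  expect_equal(cdi$slope[1, 1], 0)
  expect_equal(cdi$cov[1, 1], 3)
})

test_that("optimal dose places the interventional mean at the midpoint", {
  # reference N = 100 estimates reproduce the documented optimum
  o <- optimal_dose_gaussian(-0.5217, 1007.2180, -40, 80)
  expect_equal(o$x_star, -38.3, tolerance = 0.05 / 38.3)
  expect_equal(o$p_star, 0.94, tolerance = 5e-3 / 0.94)
  expect_equal(o$x_star, (80 - 40) / 2 / -0.5217, tolerance = 1e-6)

  # population slope: closed-form midpoint argument
  o2 <- optimal_dose_gaussian(-0.6, 1096.3855, -40, 80)
  expect_equal(o2$x_star, -100 / 3, tolerance = 1e-6)

  # symmetric bounds around zero are maximized by no dose
  o3 <- optimal_dose_gaussian(-0.6, 1096.3855, -50, 50)
  expect_equal(o3$x_star, 0, tolerance = 1e-6)

  # flat objective is flagged, not silently located
  expect_warning(o4 <- optimal_dose_gaussian(0, 100, -40, 80))
  expect_true(o4$flat)
  expect_true(is.na(o4$x_star))

  # model-based wrapper agrees with the low-level search
  om <- optimal_intervention_level(fixture_mats, "X2", "Y3", -40, 80)
  expect_equal(om$slope, -0.6)
  expect_equal(om$sigma2, 1096.3855, tolerance = 1e-4)
  expect_equal(om$x_star, -100 / 3, tolerance = 1e-6)
})
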