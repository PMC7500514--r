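test_that("reliability stars follow the posterior-mass thresholds", {
  expect_equal(classify_reliability(0.03), "*")
  expect_equal(classify_reliability(0.0004), "***")
  expect_equal(classify_reliability(0.004), "**")
  expect_equal(classify_reliability(0.5), "none")
  expect_equal(classify_reliability(0.05), "none")  # strict inequality
  expect_equal(classify_reliability(c(0, 0.2)), c("***", "none"))
  expect_error(classify_reliability(0.7), "0.5")
  expect_error(classify_reliability(-0.1), "0.5")
})

test_that("specs are validated", {
  expect_error(bivariate_spec("a", "a"), "differ")
  expect_error(bivariate_spec("a", "b", chains = 1), "2 chains")
  expect_error(bivariate_spec("a", "b", iter = 100, burnin = 100), "burnin")
})

test_that("Gibbs conditionals match the conjugate closed form at fixed variances", {
  co <- binned(percent_cohort(n = 4, seed = 90,
                              regions = c("A", "B"),
                              slope = c(-0.6, -0.6)), k = 4)
  psi <- diag(c(4, 0.09, 4, 0.09))
  theta <- diag(c(1, 1)) * 0.8
  spec <- bivariate_spec("A", "B", iter = 6000, burnin = 1000,
                         seed = 5, include_sex = FALSE)
  fit <- fit_bivariate(co, spec, psi_fixed = psi, theta_fixed = theta)
  # closed form: beta | y ~ N((X'V^-1 X)^-1 X'V^-1 y, .) with V built from
  # the fixed Psi and Theta, jointly over both regions
  fr <- lgctraj:::bivariate_frame(co, spec)
  q <- ncol(fr$X)
  A <- matrix(0, 2 * q, 2 * q)
  rhs <- numeric(2 * q)
  for (i in seq_len(fr$nsub)) {
    sel <- which(fr$subj == i - 1)
    ni <- length(sel)
    Z <- cbind(1, fr$ctime[sel])
    Zt <- rbind(cbind(Z, matrix(0, ni, 2)), cbind(matrix(0, ni, 2), Z))
    V <- Zt %*% psi %*% t(Zt) + kronecker(theta, diag(ni))
    W <- solve(V)
    Xt <- rbind(cbind(fr$X[sel, , drop = FALSE], matrix(0, ni, q)),
                cbind(matrix(0, ni, q), fr$X[sel, , drop = FALSE]))
    A <- A + t(Xt) %*% W %*% Xt
    rhs <- rhs + drop(t(Xt) %*% W %*% c(fr$yA[sel], fr$yB[sel]))
  }
  beta_closed <- solve(A, rhs)
  beta_mcmc <- colMeans(fit$draws[, seq_len(2 * q)])
  mc_se <- apply(fit$draws[, seq_len(2 * q)], 2, sd) /
    sqrt(nrow(fit$draws) / 20)  # conservative ESS guess
  expect_true(all(abs(beta_mcmc - beta_closed) < 4 * mc_se + 1e-3))
})

test_that("a shared latent process yields a slope correlation near one", {
  # region B = region A's latent trajectory + independent noise
  des <- cohort_design(n_subjects = 500, seed = 91)
  tru <- region_truth("A", intercept_65 = 100, slope = -0.6,
                      random_slope_sd = 0.45, residual_sd = 0)
  co <- generate_cohort(des, tru)  # noise-free latent trajectories
  co$scale <- "percent_of_intercept65"
  obs <- co$observations
  set.seed(92)
  latent <- obs$A
  obs$A <- latent + rnorm(nrow(obs), 0, 0.8)
  obs$B <- latent + rnorm(nrow(obs), 0, 0.8)
  co$observations <- obs
  co$regions <- c("A", "B")
  co <- binned(co)
  fit <- fit_bivariate(co, bivariate_spec("A", "B", iter = 2500,
                                          burnin = 1250, seed = 9))
  expect_gt(fit$rho_ss_median, 0.9)
  expect_equal(fit$reliability, "***")
})

test_that("the slope-slope correlation is invariant to swapping the regions", {
  co <- binned(percent_cohort(n = 120, seed = 93, regions = c("A", "B"),
                              slope = c(-0.6, -0.6), random_slope_sd = 0.45,
                              residual_sd = 0.8,
                              slope_corr = matrix(c(1, .6, .6, 1), 2)))
  f1 <- fit_bivariate(co, bivariate_spec("A", "B", iter = 3000,
                                         burnin = 1500, seed = 4))
  f2 <- fit_bivariate(co, bivariate_spec("B", "A", iter = 3000,
                                         burnin = 1500, seed = 4))
  expect_equal(f1$rho_ss_median, f2$rho_ss_median, tolerance = 0.05)
  # each Psi draw is positive definite: correlations bounded by 1
  expect_true(all(abs(fit_draw_cor(f1)) <= 1))
})

test_that("plausible values recover the realized person-specific slopes", {
  co <- binned(percent_cohort(n = 150, seed = 94, regions = c("A", "B"),
                              slope = c(-0.6, -0.6),
                              random_slope_sd = 0.5, residual_sd = 0.5,
                              retention_final = 1,
                              slope_corr = matrix(c(1, .5, .5, 1), 2)))
  fit <- fit_bivariate(co, bivariate_spec("A", "B", iter = 2500,
                                          burnin = 1250, seed = 6))
  ps <- plausible_slopes(fit, "A")
  u1 <- attr(co, "random_effects")$u1[, "A"]
  pos <- as.integer(sub("S", "", fit$subjects))
  expect_gt(cor(ps$mean, u1[pos]), 0.8)
  expect_error(plausible_slopes(fit, "nope"), "not part")
})

test_that("a baseline-only subject's plausible slope reverts to the prior SD", {
  co <- percent_cohort(n = 120, seed = 95, regions = c("A", "B"),
                       slope = c(-0.6, -0.6), random_slope_sd = 0.5,
                       residual_sd = 0.6, retention_final = 1,
                       intercept_slope_corr = 0,
                       slope_corr = matrix(c(1, .4, .4, 1), 2))
  obs <- co$observations
  lone <- obs$subject_id[1]
  co$observations <- obs[obs$subject_id != lone | obs$time_years == 0, ]
  co <- binned(co)
  fit <- fit_bivariate(co, bivariate_spec("A", "B", iter = 3000,
                                          burnin = 1500, seed = 8))
  ps <- plausible_slopes(fit, "A")
  pv_sd <- sd(ps$draws[lone, ])
  marg_sd <- sqrt(median(fit$draws[, "sA.sA"]))
  expect_equal(pv_sd, marg_sd, tolerance = 0.25)
  # and informative subjects are much more concentrated
  typical <- median(apply(ps$draws, 1, sd))
  expect_lt(typical, 0.8 * pv_sd)
})
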