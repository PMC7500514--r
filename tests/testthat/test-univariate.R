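test_that("noise-free data reproduce the generating fixed effects with G ~ 0", {
  co <- zero_noise_cohort(n = 30, slope = -0.5, seed = 12)
  scaled <- scale_to_percent(co)
  fit <- fit_univariate(scaled, growth_model_spec("r1"))
  expect_equal(unname(fit$beta["time"]), -0.5, tolerance = 0.01)
  # percent scaling is relative to the sample's fitted intercept, so the
  # recovered coefficients carry a small multiplicative wobble at modest n
  expect_equal(unname(fit$beta["age_c:time"]), -0.02, tolerance = 0.01)
  expect_lt(max(abs(fit$G)), 1e-6)
  expect_lt(fit$sigma2, 1e-6)
})

test_that("the marginal likelihood equals a direct multivariate-normal oracle", {
  co <- percent_cohort(n = 5, seed = 21)
  fit <- fit_univariate(co, growth_model_spec("r1"))
  d <- fit$data
  # oracle: one joint density over the block-diagonal covariance of all
  # subjects stacked, built naively
  X <- model.matrix(~ age_c + age_c2 + icv_z + time + time:age_c +
                      time:icv_z, d)
  r <- d$y - drop(X %*% fit$beta)
  n <- nrow(d)
  V <- diag(fit$sigma2, n)
  for (id in unique(d$subject_id)) {
    sel <- which(d$subject_id == id)
    Z <- cbind(1, d$time[sel])
    V[sel, sel] <- V[sel, sel] + Z %*% fit$G %*% t(Z)
  }
  ll_oracle <- -0.5 * (n * log(2 * pi) + determinant(V)$modulus +
                         drop(t(r) %*% solve(V) %*% r))
  expect_equal(fit$loglik, as.numeric(ll_oracle), tolerance = 1e-8)
  # per-subject contributions sum to the total
  expect_equal(sum(fit$loglik_by_subject), fit$loglik, tolerance = 1e-10)
})

test_that("the reported log-likelihood matches lme4 at the ML estimate", {
  co <- percent_cohort(n = 60, seed = 22)
  fit <- fit_univariate(co, growth_model_spec("r1"))
  lfit <- lme4::lmer(y ~ age_c + age_c2 + icv_z + time + time:age_c +
                       time:icv_z + (1 + time | subject_id),
                     data = fit$data, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(logLik(lfit)), tolerance = 1e-6)
})

test_that("with G = 0 the marginal likelihood reduces to the OLS likelihood", {
  co <- percent_cohort(n = 40, seed = 23)
  spec <- growth_model_spec("r1")
  fit <- fit_univariate(co, spec)
  d <- fit$data
  ols <- lm(y ~ age_c + age_c2 + icv_z + time + time:age_c + time:icv_z,
            data = d)
  s2 <- mean(resid(ols)^2)  # ML variance estimate
  ll <- marginal_loglik(d, coef(ols), matrix(0, 2, 2), s2, spec)
  expect_equal(ll$total, as.numeric(logLik(ols)), tolerance = 1e-8)
})

test_that("fixed effects profile to the generalized-least-squares closed form", {
  co <- percent_cohort(n = 80, seed = 24)
  fit <- fit_univariate(co, growth_model_spec("r1"))
  d <- fit$data
  X <- model.matrix(~ age_c + age_c2 + icv_z + time + time:age_c +
                      time:icv_z, d)
  A <- matrix(0, ncol(X), ncol(X))
  b <- numeric(ncol(X))
  for (id in unique(d$subject_id)) {
    sel <- which(d$subject_id == id)
    Z <- cbind(1, d$time[sel])
    W <- solve(Z %*% fit$G %*% t(Z) + diag(fit$sigma2, length(sel)))
    A <- A + t(X[sel, , drop = FALSE]) %*% W %*% X[sel, , drop = FALSE]
    b <- b + drop(t(X[sel, , drop = FALSE]) %*% W %*% d$y[sel])
  }
  beta_gls <- solve(A, b)
  expect_equal(unname(fit$beta), unname(beta_gls), tolerance = 1e-4)
})

test_that("conditional slopes are shrunken relative to the marginal slope variance", {
  for (s in 1:3) {
    co <- percent_cohort(n = 150, seed = 30 + s, random_slope_sd = 0.4)
    fit <- fit_univariate(co, growth_model_spec("r1"))
    expect_lte(var(fit$ranef_mean[, "slope"]), fit$G[2, 2] + 1e-10)
  }
})

test_that("parameters are recovered on a single large synthetic cohort", {
  co <- percent_cohort(n = 500, seed = 41, slope = -0.784,
                       slope_x_entryage = -0.040, random_slope_sd = 0.441)
  fit <- fit_univariate(co, growth_model_spec("r1"))
  se_slope <- sqrt(fit$vcov_beta["time", "time"])
  expect_lt(abs(fit$beta["time"] - (-0.784)), 2 * se_slope)
  expect_lt(abs(fit$random_slope_sd - 0.441) / 0.441, 0.25)
})

test_that("slope_at_age is the linear combination of slope and interaction", {
  fit <- structure(list(beta = c(time = -0.556, "age_c:time" = -0.010)),
                   class = "growth_fit")
  expect_equal(slope_at_age(fit, 65), -0.556)
  expect_equal(slope_at_age(fit, 85), -0.756)
  expect_warning(slope_at_age(fit, 90), "range")
  fit$beta["age_c:time"] <- 0
  expect_equal(slope_at_age(fit, 70), slope_at_age(fit, 80))
})

test_that("the random-slope LRT handles boundary and error cases", {
  co <- percent_cohort(n = 80, seed = 50, random_slope_sd = 0.4)
  full <- fit_univariate(co, growth_model_spec("r1"))
  red <- fit_univariate(co, growth_model_spec("r1", random_slope = FALSE))
  lrt <- lrt_random_slope(full, red)
  expect_gte(lrt$statistic, 0)
  expect_lte(lrt$p_value, 1)
  # identical log-likelihoods: statistic 0, p = 1
  lrt0 <- lrt_random_slope(full, full)
  expect_equal(lrt0$statistic, 0)
  expect_equal(lrt0$p_value, 1)
  # reversed ordering beyond tolerance is an optimizer failure
  expect_error(lrt_random_slope(red, full), "lower likelihood")
  # REML fits are rejected
  fr <- full; fr$spec$reml <- TRUE
  expect_error(lrt_random_slope(fr, red), "ML")
})

test_that("the sex-extended model detects a planted sex-by-slope difference", {
  # build a cohort where men decline 0.4 %/yr faster
  co <- percent_cohort(n = 231, seed = 60, residual_sd = 0.8)
  obs <- co$observations
  obs$r1 <- obs$r1 - 0.4 * obs$time_years * (obs$sex == "M")
  co$observations <- obs
  st <- sex_effect_test(co, growth_model_spec("r1"))
  expect_lt(st$p_value, 0.05)
  expect_equal(st$df, 2)
  # degenerate single-sex cohort is refused
  co$observations$sex <- "M"
  expect_error(sex_effect_test(co, growth_model_spec("r1")), "one sex")
})

test_that("a rank-deficient fixed-effect design is reported with column names", {
  co <- percent_cohort(n = 30, seed = 70)
  co$observations$entry_age <- 70  # constant age: age terms collinear
  expect_error(fit_univariate(co, growth_model_spec("r1")),
               "collinear")
})
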