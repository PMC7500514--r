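#' Specification of a univariate growth model
#'
#' The base model for one region's percent-scaled volume `y` is
#' \deqn{y_{ij} = \beta_0 + \beta_a a_i + \beta_{a2} a_i^2 + \beta_v v_i
#'   + (\beta_s + \beta_{sa} a_i + \beta_{sv} v_i) t_{ij}
#'   + u_{0i} + u_{1i} t_{ij} + e_{ij}}
#' with entry-age centered at 65 (`a`), ICV standardized (`v`), time in
#' study `t` in years, random effects \eqn{(u_0, u_1) \sim N(0, G)} and
#' residuals \eqn{e \sim N(0, \sigma^2)}. `\beta_s` is therefore the annual
#' change at entry-age 65 and mean ICV, in percent of the age-65 volume.
#'
#' The sex extension adds male-indicator terms `sex`, `sex:entry-age`,
#' `sex:entry-age^2`, `sex:slope`, and `sex:slope:entry-age` (female is the
#' reference level). The squared sex-by-age term is the interaction of sex
#' with the quadratic age term; for a binary indicator the literal square of
#' the product is algebraically identical.
#'
#' @param region region (response) column name.
#' @param sex_extension add the sex terms described above.
#' @param random_slope include a random slope (with intercept-slope
#'   covariance); `FALSE` keeps the random intercept only.
#' @param reml use REML instead of ML. ML is the default so that
#'   likelihood-ratio tests on variance components and nested fixed-effect
#'   comparisons are coherent.
#' @param use_binned_time fit on the binned times (`time_bin` column from
#'   [assign_bins()]) instead of exact times, i.e. the time-window
#'   latent-growth variant.
#' @return an object of class `growth_model_spec`.
#' @export
growth_model_spec <- function(region,
                              sex_extension = FALSE,
                              random_slope = TRUE,
                              reml = FALSE,
                              use_binned_time = FALSE) {
  structure(list(region = region, sex_extension = sex_extension,
                 random_slope = random_slope, reml = reml,
                 use_binned_time = use_binned_time),
            class = "growth_model_spec")
}

# model frame shared by all fitting routines
growth_model_frame <- function(cohort, spec) {
  obs <- cohort$observations
  if (!spec$region %in% cohort$regions) {
    stop("region '", spec$region, "' not in cohort")
  }
  tvar <- if (isTRUE(spec$use_binned_time)) {
    if (is.null(obs$time_bin)) {
      stop("use_binned_time = TRUE but no time_bin column; ",
           "call assign_bins() first")
    }
    obs$time_bin
  } else obs$time_years
  d <- data.frame(
    subject_id = obs$subject_id,
    y = obs[[spec$region]],
    time = tvar,
    age_c = obs$entry_age - 65,
    icv_z = (obs$icv - mean(obs$icv)) / stats::sd(obs$icv),
    sexM = as.numeric(obs$sex == "M"))
  d$age_c2 <- d$age_c^2
  d[!is.na(d$y), , drop = FALSE]
}

growth_fixed_formula <- function(spec) {
  rhs <- "age_c + age_c2 + icv_z + time + time:age_c + time:icv_z"
  if (isTRUE(spec$sex_extension)) {
    rhs <- paste(rhs, "+ sexM + sexM:age_c + sexM:age_c2",
                 "+ sexM:time + sexM:time:age_c")
  }
  rhs
}

growth_formula <- function(spec, drop_sex_slope = FALSE) {
  rhs <- growth_fixed_formula(spec)
  if (drop_sex_slope) {
    rhs <- gsub("\\+ sexM:time \\+ sexM:time:age_c", "", rhs)
  }
  re <- if (isTRUE(spec$random_slope)) "(1 + time | subject_id)"
        else "(1 | subject_id)"
  stats::as.formula(paste("y ~", rhs, "+", re))
}

# lmer with quiet retries over optimizers; returns the fit (with a
# convergence note attached) or NULL when every attempt errors
fit_lmer_quiet <- function(formula, data, reml = FALSE) {
  optimizers <- c("nloptwrap", "bobyqa", "Nelder_Mead")
  notes <- character(0)
  for (opt in optimizers) {
    res <- tryCatch(
      withCallingHandlers(
        lme4::lmer(formula, data = data, REML = reml,
                   control = lme4::lmerControl(
                     optimizer = opt,
                     check.conv.singular = "ignore",
                     calc.derivs = FALSE)),
        warning = function(w) {
          notes <<- c(notes, conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) {
        notes <<- c(notes, conditionMessage(e))
        NULL
      })
    if (!is.null(res)) {
      attr(res, "convergence_notes") <- notes
      attr(res, "optimizer_used") <- opt
      return(res)
    }
  }
  NULL
}

# checks the fixed-effect design for rank deficiency, naming the columns
check_fixed_rank <- function(spec, d) {
  X <- model.matrix(stats::as.formula(paste("~", growth_fixed_formula(spec))),
                    d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  invisible(X)
}

#' Fit a univariate linear random-slope growth model
#'
#' Maximum-likelihood (default) fit of the model described in
#' [growth_model_spec()], using all and only each subject's observed waves
#' (full-information under MAR). On degenerate, noise-free data where the
#' mixed-model optimizer cannot proceed, the fit falls back to pooled
#' ordinary least squares with the random-effect covariance fixed at zero,
#' which is the limiting ML solution.
#'
#' @param cohort a [cohort()], normally percent-scaled.
#' @param spec a [growth_model_spec()].
#' @return an object of class `growth_fit` with fixed effects (estimates,
#'   covariance, Wald 95% CIs), the random-effect covariance `G` (with SDs
#'   and correlation), residual variance `sigma2`, the total log-likelihood
#'   and per-subject contributions, per-subject conditional random-effect
#'   means and covariances, and a convergence report.
#' @export
fit_univariate <- function(cohort, spec) {
  if (cohort$scale != "percent_of_intercept65") {
    warning("cohort is not percent-scaled; slope units are raw per year")
  }
  d <- growth_model_frame(cohort, spec)
  if (isTRUE(spec$sex_extension) && length(unique(d$sexM)) < 2) {
    stop("sex_extension requires both sexes in the cohort")
  }
  check_fixed_rank(spec, d)
  n_per <- table(d$subject_id)
  if (mean(n_per >= 2) < 0.5) {
    stop("a majority of subjects needs >= 2 observations")
  }

  fit <- fit_lmer_quiet(growth_formula(spec), d, reml = spec$reml)
  if (!is.null(fit)) {
    beta <- lme4::fixef(fit)
    Vbeta <- as.matrix(vcov(fit))
    vc <- lme4::VarCorr(fit)$subject_id
    if (isTRUE(spec$random_slope)) {
      G <- matrix(as.numeric(vc[1:2, 1:2]), 2, 2,
                  dimnames = list(c("intercept", "slope"),
                                  c("intercept", "slope")))
    } else {
      G <- matrix(c(as.numeric(vc[1, 1]), 0, 0, 0), 2, 2,
                  dimnames = list(c("intercept", "slope"),
                                  c("intercept", "slope")))
    }
    sigma2 <- stats::sigma(fit)^2
    converged <- TRUE
    notes <- attr(fit, "convergence_notes")
    optimizer <- attr(fit, "optimizer_used")
  } else {
    # degenerate fallback: pooled OLS, G = 0 (zero-noise limit)
    ols <- lm(stats::as.formula(paste("y ~", growth_fixed_formula(spec))),
              data = d)
    beta <- coef(ols)
    Vbeta <- vcov(ols)
    G <- matrix(0, 2, 2, dimnames = list(c("intercept", "slope"),
                                         c("intercept", "slope")))
    sigma2 <- mean(resid(ols)^2)
    converged <- TRUE
    notes <- "mixed-model optimizer failed; pooled OLS fallback with G = 0"
    optimizer <- "ols_fallback"
  }

  ll <- marginal_loglik(d, beta, G, sigma2, spec)
  re <- conditional_ranef(d, beta, G, sigma2, spec)
  z <- qnorm(0.975)
  ci <- cbind(lower = beta - z * sqrt(diag(Vbeta)),
              upper = beta + z * sqrt(diag(Vbeta)))

  structure(list(
    beta = beta, vcov_beta = Vbeta, ci = ci,
    G = G,
    random_intercept_sd = sqrt(G[1, 1]),
    random_slope_sd = sqrt(G[2, 2]),
    intercept_slope_corr = if (G[1, 1] > 0 && G[2, 2] > 0)
      G[1, 2] / sqrt(G[1, 1] * G[2, 2]) else NA_real_,
    sigma2 = sigma2,
    loglik = ll$total, loglik_by_subject = ll$by_subject,
    ranef_mean = re$mean, ranef_cov = re$cov,
    convergence = list(converged = converged, optimizer = optimizer,
                       notes = notes),
    spec = spec, data = d,
    n_subjects = length(unique(d$subject_id)),
    n_obs = nrow(d)), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> region '", x$spec$region, "', ", x$n_subjects,
      " subjects, ", x$n_obs, " obs, ",
      if (x$spec$reml) "REML" else "ML", "\n", sep = "")
  cat("  slope at age 65: ", signif(unname(x$beta["time"]), 4),
      "  slope x entry-age: ",
      signif(unname(x$beta["age_c:time"]), 4), "\n", sep = "")
  cat("  random slope SD: ", signif(x$random_slope_sd, 4),
      "  residual SD: ", signif(sqrt(x$sigma2), 4),
      "  logLik: ", round(x$loglik, 2), "\n", sep = "")
  invisible(x)
}

# fixed-effect design matrix for a prepared model frame
growth_design <- function(d, spec) {
  model.matrix(stats::as.formula(paste("~", growth_fixed_formula(spec))), d)
}

#' Marginal log-likelihood of a growth model, by subject
#'
#' Evaluates, at given parameter values, the multivariate-normal marginal
#' likelihood \eqn{y_i \sim N(X_i \beta, Z_i G Z_i' + \sigma^2 I)} subject
#' by subject, by direct construction of each subject's covariance matrix.
#' The sum over subjects equals the model log-likelihood; the per-subject
#' terms are the likelihood contributions used by the influence
#' diagnostics.
#'
#' @param d model frame from the fit (columns `y`, `time`, covariates,
#'   `subject_id`).
#' @param beta fixed effects (in design-matrix order).
#' @param G 2x2 random-effect covariance (intercept, slope).
#' @param sigma2 residual variance.
#' @param spec the [growth_model_spec()].
#' @return list with `total` and named vector `by_subject`.
#' @export
marginal_loglik <- function(d, beta, G, sigma2, spec) {
  X <- growth_design(d, spec)
  r <- d$y - drop(X %*% beta)
  ids <- unique(d$subject_id)
  by_subject <- setNames(numeric(length(ids)), ids)
  s2 <- max(sigma2, 1e-12)
  for (i in seq_along(ids)) {
    sel <- d$subject_id == ids[i]
    Zi <- cbind(1, d$time[sel])
    Vi <- Zi %*% G %*% t(Zi) + diag(s2, sum(sel))
    ch <- chol(Vi)
    ri <- r[sel]
    w <- backsolve(ch, ri, transpose = TRUE)
    by_subject[i] <- -0.5 * (sum(sel) * log(2 * pi) +
                               2 * sum(log(diag(ch))) + sum(w^2))
  }
  list(total = sum(by_subject), by_subject = by_subject)
}

# conditional (shrunken) random-effect distributions per subject;
# uses the marginal form E[u|y] = G Z' V^{-1} r, valid also when G is
# singular (boundary fits)
conditional_ranef <- function(d, beta, G, sigma2, spec) {
  X <- growth_design(d, spec)
  r <- d$y - drop(X %*% beta)
  ids <- unique(d$subject_id)
  m <- matrix(0, length(ids), 2,
              dimnames = list(ids, c("intercept", "slope")))
  covs <- vector("list", length(ids))
  names(covs) <- ids
  s2 <- max(sigma2, 1e-12)
  for (i in seq_along(ids)) {
    sel <- d$subject_id == ids[i]
    Zi <- cbind(1, d$time[sel])
    Vi <- Zi %*% G %*% t(Zi) + diag(s2, sum(sel))
    K <- G %*% t(Zi) %*% solve(Vi)
    m[i, ] <- drop(K %*% r[sel])
    covs[[i]] <- G - K %*% Zi %*% G
  }
  list(mean = m, cov = covs)
}

#' Population slope at a given entry-age
#'
#' Returns \eqn{\hat\beta_s + \hat\beta_{sa} (age - 65)}, the expected
#' annual change (% of age-65 volume) for a subject entering the study at
#' `age`.
#'
#' @param fit a [fit_univariate()] result.
#' @param age entry-age in years; a warning is issued outside the study
#'   range 64-87.
#' @return percent per year, vectorized over `age`.
#' @export
slope_at_age <- function(fit, age) {
  if (any(age < 64 | age > 87)) {
    warning("age outside the study entry-age range 64-87; extrapolating")
  }
  unname(fit$beta["time"] + fit$beta["age_c:time"] * (age - 65))
}

#' Likelihood-ratio test for the random slope
#'
#' Compares the full fit (random intercept and slope, with their
#' covariance) to the reduced fit (random intercept only) on the same data.
#' Removing the slope variance and the covariance places one parameter on
#' the boundary, so the reference distribution is the 50:50 mixture of
#' chi-square(1) and chi-square(2); at statistic 0 the p-value is 1.
#'
#' @param fit_full,fit_reduced [fit_univariate()] results with and without
#'   the random slope, fitted by ML on identical data.
#' @param tol tolerance for a slightly negative statistic before it is
#'   treated as an optimizer failure.
#' @return list with `statistic`, `p_value`, and the component
#'   log-likelihoods, of class `lgctraj_lrt`.
#' @export
lrt_random_slope <- function(fit_full, fit_reduced, tol = 1e-4) {
  if (isTRUE(fit_full$spec$reml) || isTRUE(fit_reduced$spec$reml)) {
    stop("likelihood-ratio tests require ML fits (reml = FALSE)")
  }
  if (fit_full$n_obs != fit_reduced$n_obs) {
    stop("fits are not on the same data")
  }
  stat <- 2 * (fit_full$loglik - fit_reduced$loglik)
  if (stat < -tol) {
    stop("full model has lower likelihood than reduced model (",
         signif(stat, 4), "); optimizer failure")
  }
  stat <- max(stat, 0)
  p <- 0.5 * pchisq(stat, df = 1, lower.tail = FALSE) +
    0.5 * pchisq(stat, df = 2, lower.tail = FALSE)
  structure(list(statistic = stat, p_value = p,
                 loglik_full = fit_full$loglik,
                 loglik_reduced = fit_reduced$loglik,
                 reference = "0.5*chisq(1) + 0.5*chisq(2)"),
            class = "lgctraj_lrt")
}

#' @export
print.lgctraj_lrt <- function(x, ...) {
  cat("<lgctraj_lrt> statistic = ", signif(x$statistic, 5),
      ", reference ", x$reference, ", p = ", signif(x$p_value, 4),
      "\n", sep = "")
  invisible(x)
}

#' Test for sex differences in the slope
#'
#' Likelihood-ratio test (2 df chi-square) of the sex-extended model against
#' the same model without the `sex:slope` and `sex:slope:entry-age` terms,
#' i.e. of whether men and women differ in their annual change or in its
#' dependence on entry-age.
#'
#' @param cohort a percent-scaled [cohort()].
#' @param spec a [growth_model_spec()]; its `sex_extension` flag is forced
#'   on for the full model.
#' @return list with `statistic`, `p_value`, `df`, and the two fits, of
#'   class `lgctraj_lrt`.
#' @export
sex_effect_test <- function(cohort, spec = growth_model_spec(cohort$regions[1])) {
  spec$sex_extension <- TRUE
  d <- growth_model_frame(cohort, spec)
  if (length(unique(d$sexM)) < 2) {
    stop("sex effect is undefined: only one sex present in the cohort")
  }
  fit_full <- fit_univariate(cohort, spec)
  dfull <- fit_full$data
  red_formula <- growth_formula(spec, drop_sex_slope = TRUE)
  red <- fit_lmer_quiet(red_formula, dfull, reml = FALSE)
  if (is.null(red)) stop("reduced sex model failed to fit")
  ll_red <- as.numeric(logLik(red))
  stat <- max(0, 2 * (fit_full$loglik - ll_red))
  p <- pchisq(stat, df = 2, lower.tail = FALSE)
  structure(list(statistic = stat, p_value = p, df = 2,
                 loglik_full = fit_full$loglik, loglik_reduced = ll_red,
                 reference = "chisq(2)", fit_full = fit_full),
            class = "lgctraj_lrt")
}
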