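#' Specification of a bivariate Bayesian growth model
#'
#' Joint latent growth model for two regions A and B with per-subject
#' random intercepts and slopes for each region, a free 4x4 random-effect
#' covariance (intercept-intercept, intercept-slope and slope-slope
#' associations), and a 2x2 within-occasion residual covariance shared
#' across occasions. Slope loadings are the binned times from
#' [assign_bins()] (the time-window approach); exact times can be used by
#' setting `use_binned_time = FALSE`. Covariates on both intercepts and
#' slopes: entry-age (centered at 65), entry-age squared (intercepts only),
#' ICV (standardized), and optionally sex.
#'
#' Priors follow the Mplus Bayesian defaults: Normal(0, 1e10) on all
#' fixed effects and the improper Inverse-Wishart(0, -p-1) on covariance
#' matrices, which corresponds to a flat prior on their elements. With tiny
#' variance components this improper prior can degenerate; `prior =
#' "proper"` (or the automatic fallback in [fit_bivariate()]) substitutes a
#' weakly-informative proper Inverse-Wishart(eps*I, p+1).
#'
#' @param region_a,region_b the two region names (must differ).
#' @param chains number of MCMC chains (>= 2).
#' @param iter iterations per chain (including burn-in).
#' @param burnin burn-in per chain; default half.
#' @param thin_pv thinning interval for stored plausible-value draws.
#' @param seed integer seed.
#' @param prior `"improper"` (Mplus default) or `"proper"`.
#' @param prior_eps scale of the proper fallback prior.
#' @param include_sex include the sex covariate.
#' @param use_binned_time use binned (`TRUE`, default) or exact times.
#' @param rhat_threshold potential-scale-reduction threshold above which the
#'   fit is flagged non-converged.
#' @return an object of class `bivariate_spec`.
#' @export
bivariate_spec <- function(region_a, region_b,
                           chains = 2, iter = 20000, burnin = iter %/% 2,
                           thin_pv = 10, seed = 1,
                           prior = c("improper", "proper"),
                           prior_eps = 1e-3,
                           include_sex = TRUE,
                           use_binned_time = TRUE,
                           rhat_threshold = 1.05) {
  prior <- match.arg(prior)
  if (identical(region_a, region_b)) stop("region_a and region_b must differ")
  if (chains < 2) stop("at least 2 chains are required")
  if (burnin >= iter) stop("burnin must be < iter")
  structure(list(region_a = region_a, region_b = region_b,
                 chains = as.integer(chains), iter = as.integer(iter),
                 burnin = as.integer(burnin), thin_pv = as.integer(thin_pv),
                 seed = as.integer(seed), prior = prior,
                 prior_eps = prior_eps, include_sex = include_sex,
                 use_binned_time = use_binned_time,
                 rhat_threshold = rhat_threshold),
            class = "bivariate_spec")
}

# design pieces shared by the sampler: one row per occasion with both
# regions observed; columns [1, age, age2, icv, (sex), c, c*age, c*icv,
# (c*sex)] where c is the (binned) time
bivariate_frame <- function(cohort, spec) {
  obs <- cohort$observations
  for (r in c(spec$region_a, spec$region_b)) {
    if (!r %in% cohort$regions) stop("region '", r, "' not in cohort")
  }
  ctime <- if (isTRUE(spec$use_binned_time)) {
    if (is.null(obs$time_bin)) {
      stop("use_binned_time = TRUE but no time_bin column; ",
           "call assign_bins() first")
    }
    obs$time_bin
  } else obs$time_years
  yA <- obs[[spec$region_a]]
  yB <- obs[[spec$region_b]]
  keep <- !is.na(yA) & !is.na(yB)
  age <- obs$entry_age - 65
  icv <- (obs$icv - mean(obs$icv)) / stats::sd(obs$icv)
  sexM <- as.numeric(obs$sex == "M")
  Xi <- cbind(1, age, age^2, icv)
  Xs <- cbind(1, age, icv)
  if (isTRUE(spec$include_sex)) {
    Xi <- cbind(Xi, sexM)
    Xs <- cbind(Xs, sexM)
  }
  X <- cbind(Xi, ctime * Xs)
  int_names <- c("intercept", "entry_age", "entry_age2", "icv",
                 if (spec$include_sex) "sex")
  slo_names <- paste0("slope", c("", "_x_entryage", "_x_icv",
                                 if (spec$include_sex) "_x_sex"))
  colnames(X) <- c(int_names, slo_names)
  ids <- unique(obs$subject_id)
  list(X = X[keep, , drop = FALSE], ctime = ctime[keep],
       yA = yA[keep], yB = yB[keep],
       subj = match(obs$subject_id, ids)[keep] - 1L,
       ids = ids, nsub = length(ids))
}

#' Fit the bivariate growth model by Gibbs sampling
#'
#' Runs a blocked Gibbs sampler alternating conjugate draws of (a) the
#' fixed effects of both regions jointly, (b) each subject's random
#' intercept/slope 4-vector, (c) the 4x4 random-effect covariance
#' (inverse-Wishart), and (d) the 2x2 within-occasion residual covariance
#' (inverse-Wishart). Subjects contribute only their observed occasions
#' (full-information under MAR); occasions missing either region are
#' omitted, since the within-occasion residual association is defined on
#' complete pairs. Two or more chains are run; split-chain
#' potential scale reduction (R-hat) is reported per parameter and the fit
#' is flagged non-converged above the threshold.
#'
#' If sampling under the improper prior degenerates (non-positive-definite
#' or non-finite covariance draws), the sampler automatically falls back to
#' the weakly-informative proper prior and records `prior_fallback = TRUE`.
#'
#' @param cohort a percent-scaled [cohort()] (binned via [assign_bins()]
#'   unless the spec uses exact times).
#' @param spec a [bivariate_spec()].
#' @param psi_fixed,theta_fixed optional fixed values of the random-effect /
#'   residual covariance; when supplied those blocks are not sampled (used
#'   for validating the conjugate conditionals against closed forms).
#' @return an object of class `bivariate_fit`: posterior draws (fixed
#'   effects, the 10 unique elements of Psi, the 3 of Theta, and the
#'   slope-slope correlation `rho_ss`), posterior summaries with the
#'   minority-side mass `m` and its reliability star, per-subject
#'   plausible-value draws, R-hat values, and convergence flags.
#' @export
fit_bivariate <- function(cohort, spec, psi_fixed = NULL, theta_fixed = NULL) {
  fr <- bivariate_frame(cohort, spec)
  q <- ncol(fr$X)

  # initial values: per-region least squares; moment-based covariances
  betaA0 <- qr.coef(qr(fr$X), fr$yA)
  betaB0 <- qr.coef(qr(fr$X), fr$yB)
  rA <- fr$yA - drop(fr$X %*% betaA0)
  rB <- fr$yB - drop(fr$X %*% betaB0)
  v0 <- stats::var(cbind(rA, rB))
  psi0 <- if (is.null(psi_fixed)) {
    diag(c(max(v0[1, 1] / 2, 1e-2), 0.05, max(v0[2, 2] / 2, 1e-2), 0.05))
  } else psi_fixed
  theta0 <- if (is.null(theta_fixed)) v0 / 2 + diag(1e-3, 2) else theta_fixed

  run <- function(prior) {
    chains <- vector("list", spec$chains)
    for (ch in seq_len(spec$chains)) {
      set.seed(spec$seed + 1000 * ch)
      res <- gibbs_bivariate_chain(
        fr$X, fr$ctime, fr$yA, fr$yB, fr$subj, fr$nsub,
        spec$iter, spec$burnin, spec$thin_pv,
        proper_prior = identical(prior, "proper"),
        prior_eps = spec$prior_eps,
        betaA_init = betaA0, betaB_init = betaB0,
        psi_init = psi0, theta_init = theta0,
        sample_psi = is.null(psi_fixed),
        sample_theta = is.null(theta_fixed))
      if (!isTRUE(res$ok)) return(structure(list(), failed = TRUE))
      chains[[ch]] <- res
    }
    chains
  }

  prior_used <- spec$prior
  chains <- run(prior_used)
  prior_fallback <- FALSE
  if (isTRUE(attr(chains, "failed"))) {
    if (identical(prior_used, "improper")) {
      prior_used <- "proper"
      prior_fallback <- TRUE
      chains <- run(prior_used)
    }
    if (isTRUE(attr(chains, "failed"))) {
      stop("bivariate Gibbs sampler degenerated even under the proper prior")
    }
  }

  psi_names <- outer(c("iA", "sA", "iB", "sB"), c("iA", "sA", "iB", "sB"),
                     paste, sep = ".")
  psi_cols <- psi_names[upper.tri(psi_names, diag = TRUE)]
  # C++ stores row-major upper triangle; reproduce that order
  psi_cols <- c("iA.iA", "iA.sA", "iA.iB", "iA.sB", "sA.sA", "sA.iB",
                "sA.sB", "iB.iB", "iB.sB", "sB.sB")

  per_chain <- lapply(chains, function(res) {
    colnames(res$betaA) <- paste0("A.", colnames(fr$X))
    colnames(res$betaB) <- paste0("B.", colnames(fr$X))
    colnames(res$psi) <- psi_cols
    colnames(res$theta) <- c("eA.eA", "eA.eB", "eB.eB")
    rho <- res$psi[, "sA.sB"] /
      sqrt(res$psi[, "sA.sA"] * res$psi[, "sB.sB"])
    cbind(res$betaA, res$betaB, res$psi, res$theta, rho_ss = rho)
  })
  draws <- do.call(rbind, per_chain)

  rhat <- apply(
    simplify2array(lapply(per_chain, identity)), 2,
    function(m) split_rhat(m))
  names(rhat) <- colnames(draws)

  # plausible-value draws (thinned), subjects x 4 x draws
  pv <- abind_cube(lapply(chains, function(res) {
    res$pv[, , seq_len(res$n_pv), drop = FALSE]
  }))
  dimnames(pv) <- list(fr$ids, c("iA", "sA", "iB", "sB"), NULL)

  rho <- draws[, "rho_ss"]
  m <- minority_mass(rho)
  summ <- data.frame(
    parameter = colnames(draws),
    median = apply(draws, 2, median),
    lower95 = apply(draws, 2, quantile, 0.025, names = FALSE),
    upper95 = apply(draws, 2, quantile, 0.975, names = FALSE),
    rhat = rhat[colnames(draws)],
    row.names = NULL)

  converged <- all(is.finite(rhat)) && max(rhat) < spec$rhat_threshold

  structure(list(
    spec = spec, draws = draws, summary = summ,
    plausible_values = pv,
    rho_ss_median = unname(median(rho)),
    rho_ss_ci = unname(quantile(rho, c(0.025, 0.975))),
    minority_mass = m,
    reliability = classify_reliability(m),
    rhat = rhat, converged = converged,
    prior_used = prior_used, prior_fallback = prior_fallback,
    subjects = fr$ids,
    n_obs = length(fr$yA)), class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat("<bivariate_fit> ", x$spec$region_a, " ~ ", x$spec$region_b,
      " (", length(x$subjects), " subjects, ", x$n_obs, " occasions)\n",
      sep = "")
  cat("  slope-slope correlation: median ", signif(x$rho_ss_median, 3),
      " [", signif(x$rho_ss_ci[1], 3), ", ", signif(x$rho_ss_ci[2], 3),
      "], m = ", signif(x$minority_mass, 3),
      " (", x$reliability, ")\n", sep = "")
  cat("  prior: ", x$prior_used,
      if (x$prior_fallback) " (fallback from improper)" else "",
      "; max R-hat ", signif(max(x$rhat), 4),
      if (x$converged) "" else "  ** not converged **", "\n", sep = "")
  invisible(x)
}

# posterior mass on the minority side of zero
minority_mass <- function(draws) {
  min(mean(draws > 0), mean(draws < 0))
}

# split-chain potential scale reduction; m is draws x chains
split_rhat <- function(m) {
  n <- nrow(m)
  half <- n %/% 2
  seqs <- do.call(cbind, lapply(seq_len(ncol(m)), function(j) {
    cbind(m[seq_len(half), j], m[(n - half + 1):n, j])
  }))
  if (stats::var(as.numeric(seqs)) < 1e-300) return(1)
  nn <- nrow(seqs)
  means <- colMeans(seqs)
  vars <- apply(seqs, 2, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (W < 1e-300) return(Inf)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# bind cubes (a x b x n_i) along the third dimension without abind
abind_cube <- function(lst) {
  d12 <- dim(lst[[1]])[1:2]
  n3 <- sum(vapply(lst, function(x) dim(x)[3], numeric(1)))
  out <- array(NA_real_, c(d12, n3))
  at <- 0
  for (x in lst) {
    k <- dim(x)[3]
    out[, , at + seq_len(k)] <- x
    at <- at + k
  }
  out
}

#' Reliability stars for a posterior minority mass
#'
#' Classifies the posterior mass `m` on the minority side of zero:
#' `"***"` if m < 0.0005, `"**"` if m < 0.005, `"*"` if m < 0.05,
#' `"none"` otherwise.
#'
#' @param m posterior mass in `[0, 0.5]`; vectorized.
#' @return character vector of `"none"`, `"*"`, `"**"`, `"***"`.
#' @export
classify_reliability <- function(m) {
  if (any(!is.finite(m)) || any(m < 0) || any(m > 0.5 + 1e-12)) {
    stop("minority mass m must lie in [0, 0.5]")
  }
  out <- rep("none", length(m))
  out[m < 0.05] <- "*"
  out[m < 0.005] <- "**"
  out[m < 0.0005] <- "***"
  out
}

#' Plausible values of the random slopes
#'
#' Extracts, for one of the fitted regions, each subject's retained
#' posterior draws of the person-specific random slope (deviation from the
#' covariate-predicted slope), together with their means.
#'
#' @param fit a [fit_bivariate()] result.
#' @param region one of the two fitted regions.
#' @return list with `draws` (subjects x retained draws) and `mean`
#'   (named per-subject vector).
#' @export
plausible_slopes <- function(fit, region) {
  stopifnot(inherits(fit, "bivariate_fit"))
  slot <- if (identical(region, fit$spec$region_a)) "sA"
          else if (identical(region, fit$spec$region_b)) "sB"
          else stop("region '", region, "' is not part of this fit")
  draws <- fit$plausible_values[, slot, ]
  list(draws = draws, mean = rowMeans(draws))
}
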