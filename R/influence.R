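#' Subject-level influence diagnostics
#'
#' Computes, for every subject, Cook's distance on the fixed effects and the
#' subject's marginal log-likelihood contribution at the full-data estimate:
#' \deqn{D_i = (\hat\beta - \hat\beta_{(-i)})' \,
#'   \widehat{Cov}(\hat\beta)^{-1} (\hat\beta - \hat\beta_{(-i)}) / p}
#' with `p` the number of fixed effects and the covariance taken at the
#' full-data fit. `method = "refit"` obtains \eqn{\hat\beta_{(-i)}} from an
#' exact case-deletion refit of the whole model; `method = "onestep"` is a
#' faster approximation that re-solves only the generalized-least-squares
#' equations for \eqn{\beta} with the variance components held at the
#' full-data estimates.
#'
#' A deletion refit that fails to converge leaves that subject's Cook's
#' distance `NA` and flags it indeterminate -- it is never silently dropped.
#'
#' @param cohort a percent-scaled [cohort()].
#' @param spec a [growth_model_spec()]; influence screening conventionally
#'   uses the time-window (binned) variant, controlled by its
#'   `use_binned_time` flag.
#' @param method `"refit"` (exact) or `"onestep"` (approximation).
#' @param cooks_threshold1,loglik_threshold1 first exclusion rule:
#'   `cooks_d > 0.5` and contribution `< -7.5`.
#' @param cooks_threshold2,loglik_threshold2 second exclusion rule:
#'   `cooks_d > 1` and contribution `< -4`.
#' @return a data.frame of class `influence_report` with per-subject
#'   `cooks_d`, `loglik_contribution`, `indeterminate`, `rule_triggered`
#'   (`"none"`, `"rule1"`, `"rule2"`) and `excluded`; the full-data fit and
#'   the thresholds are attached as attributes.
#' @export
influence_measures <- function(cohort, spec,
                               method = c("refit", "onestep"),
                               cooks_threshold1 = 0.5,
                               loglik_threshold1 = -7.5,
                               cooks_threshold2 = 1,
                               loglik_threshold2 = -4) {
  method <- match.arg(method)
  fit <- fit_univariate(cohort, spec)
  d <- fit$data
  ids <- unique(d$subject_id)
  p <- length(fit$beta)
  Vinv <- solve(fit$vcov_beta)
  cooks <- setNames(rep(NA_real_, length(ids)), ids)
  indeterminate <- setNames(rep(FALSE, length(ids)), ids)

  if (method == "refit") {
    for (i in seq_along(ids)) {
      di <- d[d$subject_id != ids[i], , drop = FALSE]
      refit <- fit_lmer_quiet(growth_formula(fit$spec), di,
                              reml = fit$spec$reml)
      if (is.null(refit)) {
        indeterminate[i] <- TRUE
        next
      }
      delta <- fit$beta - lme4::fixef(refit)
      cooks[i] <- drop(t(delta) %*% Vinv %*% delta) / p
    }
  } else {
    # GLS downdate at fixed variance components: remove subject i's
    # block from the normal equations X' V^-1 X beta = X' V^-1 y
    X <- growth_design(d, fit$spec)
    A <- matrix(0, p, p)
    bvec <- numeric(p)
    Ai <- vector("list", length(ids))
    bi <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      sel <- d$subject_id == ids[i]
      Zi <- cbind(1, d$time[sel])
      Vi <- Zi %*% fit$G %*% t(Zi) + diag(max(fit$sigma2, 1e-12), sum(sel))
      Wi <- solve(Vi)
      Xi <- X[sel, , drop = FALSE]
      Ai[[i]] <- t(Xi) %*% Wi %*% Xi
      bi[[i]] <- drop(t(Xi) %*% Wi %*% d$y[sel])
      A <- A + Ai[[i]]
      bvec <- bvec + bi[[i]]
    }
    for (i in seq_along(ids)) {
      beta_i <- tryCatch(solve(A - Ai[[i]], bvec - bi[[i]]),
                         error = function(e) NULL)
      if (is.null(beta_i)) {
        indeterminate[i] <- TRUE
        next
      }
      delta <- fit$beta - beta_i
      cooks[i] <- drop(t(delta) %*% Vinv %*% delta) / p
    }
  }

  report <- data.frame(
    subject_id = ids,
    cooks_d = unname(cooks),
    loglik_contribution = unname(fit$loglik_by_subject[ids]),
    indeterminate = unname(indeterminate),
    stringsAsFactors = FALSE)
  report$rule_triggered <- exclusion_rule(
    report$cooks_d, report$loglik_contribution,
    cooks_threshold1, loglik_threshold1,
    cooks_threshold2, loglik_threshold2)
  report$excluded <- report$rule_triggered != "none"
  structure(report,
            class = c("influence_report", "data.frame"),
            fit = fit, method = method,
            thresholds = c(cooks1 = cooks_threshold1,
                           loglik1 = loglik_threshold1,
                           cooks2 = cooks_threshold2,
                           loglik2 = loglik_threshold2))
}

# the two-branch exclusion rule; NA influence never triggers a rule
exclusion_rule <- function(cooks_d, loglik,
                           c1 = 0.5, l1 = -7.5, c2 = 1, l2 = -4) {
  rule <- rep("none", length(cooks_d))
  r1 <- !is.na(cooks_d) & cooks_d > c1 & loglik < l1
  r2 <- !is.na(cooks_d) & cooks_d > c2 & loglik < l2
  rule[r2] <- "rule2"
  rule[r1 & !r2] <- "rule1"
  rule
}

#' Apply the influence exclusion rule to a cohort
#'
#' Removes the subjects flagged by the two-branch rule: Cook's distance
#' above 0.5 with a log-likelihood contribution below -7.5, or Cook's
#' distance above 1 with a contribution below -4 (thresholds as recorded in
#' the report). Returns the filtered cohort with an audit log of the
#' removed subjects attached as attribute `"exclusion_audit"`.
#'
#' @param cohort the [cohort()] the report was computed on.
#' @param report an [influence_measures()] report.
#' @return the filtered cohort.
#' @export
apply_exclusion <- function(cohort, report) {
  stopifnot(inherits(report, "influence_report"))
  out_ids <- report$subject_id[report$excluded]
  audit <- report[report$excluded | report$indeterminate, , drop = FALSE]
  obs <- cohort$observations
  cohort$observations <- obs[!obs$subject_id %in% out_ids, , drop = FALSE]
  attr(cohort, "exclusion_audit") <- audit
  if (length(out_ids) > 0) validate_cohort(cohort)
  cohort
}
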