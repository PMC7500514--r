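#' Rescale regions to percent of their age-65 intercept
#'
#' For each region, fits a linear random-intercept/random-slope model to the
#' raw volumes with level covariates entry-age (centered at 65),
#' (entry-age)^2 and ICV (grand-mean centered, per SD), plus a fixed time
#' slope, and divides the region's values by the fitted population
#' intercept -- the expected volume at entry-age 65 and mean ICV --
#' multiplied by 100. After scaling, 100 means "the age-65 volume" and slope
#' parameters are in percent of the age-65 volume per year.
#'
#' Rescaling an already-scaled cohort is idempotent up to fit tolerance:
#' the newly fitted intercept is ~100 so values barely change.
#'
#' @param cohort a [cohort()].
#' @param regions regions to scale; default all.
#' @return the cohort with scaled region columns,
#'   `scale = "percent_of_intercept65"`, and the fitted intercepts recorded
#'   in `$intercepts`.
#' @export
scale_to_percent <- function(cohort, regions = NULL) {
  if (is.null(regions)) regions <- cohort$regions
  miss <- setdiff(regions, cohort$regions)
  if (length(miss) > 0) {
    stop("unknown regions: ", paste(miss, collapse = ", "))
  }
  obs <- cohort$observations
  d <- data.frame(
    subject_id = obs$subject_id,
    time = obs$time_years,
    age_c = obs$entry_age - 65,
    icv_z = (obs$icv - mean(obs$icv)) / stats::sd(obs$icv))
  intercepts <- setNames(numeric(length(regions)), regions)
  for (r in regions) {
    d$y <- obs[[r]]
    dd <- d[!is.na(d$y), , drop = FALSE]
    fit <- fit_lmer_quiet(
      y ~ age_c + I(age_c^2) + icv_z + time + (1 + time | subject_id),
      data = dd, reml = FALSE)
    if (is.null(fit)) stop("intercept model failed to fit for region ", r)
    b0 <- unname(lme4::fixef(fit)["(Intercept)"])
    if (!is.finite(b0) || b0 <= 0) {
      stop("non-positive fitted intercept for region ", r, " (", b0, ")")
    }
    obs[[r]] <- obs[[r]] / b0 * 100
    intercepts[r] <- b0
  }
  cohort$observations <- obs
  cohort$scale <- "percent_of_intercept65"
  old <- cohort$intercepts
  cohort$intercepts <- if (is.null(old)) intercepts else c(old, intercepts)
  cohort
}
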