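#' Design of a synthetic longitudinal cohort
#'
#' Captures the study design being emulated: sample size, planned measurement
#' waves with small timing jitter, a minority extra wave near 3 years,
#' entry-age distribution (truncated normal), sex split, intracranial volume
#' (ICV) distribution, and missing-at-random (MAR) dropout thinning the
#' sample to a target retention at the final wave.
#'
#' Dropout is a per-follow-up-wave logistic hazard on the standardized mean
#' of the subject's volumes at the previous *observed* wave and on
#' standardized entry-age; the hazard intercept is calibrated numerically so
#' the expected retention at the final planned wave equals
#' `retention_final`. Once a wave is missed, all later waves are missed
#' (monotone dropout).
#'
#' @param n_subjects number of subjects at baseline.
#' @param wave_times planned years since baseline, strictly increasing, first
#'   element 0.
#' @param time_jitter_sd SD (years) of Gaussian jitter on follow-up times;
#'   baseline is always exactly 0.
#' @param extra_wave_time,extra_wave_fraction a minority of subjects gets an
#'   additional wave near `extra_wave_time` years (default 3), emulating an
#'   extra follow-up offered to a subset.
#' @param entry_age_range,entry_age_mean,entry_age_sd truncated-normal
#'   entry-age distribution (years).
#' @param female_fraction proportion of female subjects.
#' @param icv_mean,icv_sd intracranial volume distribution (mm^3).
#' @param retention_final target proportion of subjects still observed at the
#'   final planned wave.
#' @param dropout_beta_vol,dropout_beta_age MAR logit coefficients on the
#'   standardized previous observed mean volume and on standardized
#'   entry-age.
#' @param seed integer seed used by [generate_cohort()].
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = 231,
                          wave_times = c(0, 1, 2, 4),
                          time_jitter_sd = 0.1,
                          extra_wave_time = 3,
                          extra_wave_fraction = 24 / 231,
                          entry_age_range = c(64, 87),
                          entry_age_mean = 70.8,
                          entry_age_sd = 5,
                          female_fraction = 113 / 231,
                          icv_mean = 1.45e6,
                          icv_sd = 1.4e5,
                          retention_final = 0.72,
                          dropout_beta_vol = -0.5,
                          dropout_beta_age = 0.3,
                          seed = 1L) {
  stopifnot(n_subjects >= 1, length(wave_times) >= 2)
  if (wave_times[1] != 0 || is.unsorted(wave_times, strictly = TRUE)) {
    stop("wave_times must start at 0 and be strictly increasing")
  }
  if (!(retention_final > 0 && retention_final <= 1)) {
    stop("retention_final must be in (0, 1]")
  }
  if (entry_age_mean < entry_age_range[1] ||
      entry_age_mean > entry_age_range[2]) {
    stop("entry_age_mean must lie inside entry_age_range")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), wave_times = wave_times,
    time_jitter_sd = time_jitter_sd, extra_wave_time = extra_wave_time,
    extra_wave_fraction = extra_wave_fraction,
    entry_age_range = entry_age_range, entry_age_mean = entry_age_mean,
    entry_age_sd = entry_age_sd, female_fraction = female_fraction,
    icv_mean = icv_mean, icv_sd = icv_sd,
    retention_final = retention_final,
    dropout_beta_vol = dropout_beta_vol,
    dropout_beta_age = dropout_beta_age,
    seed = as.integer(seed)), class = "cohort_design")
}

#' Generative truth for a set of regions
#'
#' Per-region parameters of the linear random-intercept/random-slope model on
#' the percent-of-age-65-intercept scale, plus the cross-region correlation
#' matrix of the random slopes. Fixed effects: `intercept_65` is the region's
#' raw volume (mm^3) at entry-age 65 and mean ICV; `beta_entry_age`,
#' `beta_entry_age2` act on the level per year (and squared year) of
#' entry-age beyond 65; `beta_icv` acts on the level per SD of ICV; `slope`
#' is the annual change (% of age-65 volume) at entry-age 65;
#' `slope_x_entryage` adjusts the slope per year of entry-age;
#' `slope_x_icv` per SD of ICV. Random effects: intercept SD (%), slope SD
#' (%/yr), their within-region correlation, and the residual SD (%).
#'
#' All scalar arguments recycle across regions.
#'
#' @param regions character vector of region names.
#' @param intercept_65 mm^3 at age 65.
#' @param beta_entry_age,beta_entry_age2,beta_icv level fixed effects (%).
#' @param slope annual change at entry-age 65 (%/yr).
#' @param slope_x_entryage slope change per year of entry-age (%/yr/yr).
#' @param slope_x_icv slope change per SD of ICV (%/yr).
#' @param random_intercept_sd,random_slope_sd random-effect SDs (%, %/yr).
#' @param intercept_slope_corr within-region intercept-slope correlation.
#' @param residual_sd within-subject residual SD (%).
#' @param slope_corr regions x regions correlation matrix of the random
#'   slopes; must be symmetric positive semi-definite with unit diagonal.
#' @return an object of class `region_truth` (a data.frame with the matrix
#'   attached as attribute `slope_corr`).
#' @export
region_truth <- function(regions,
                         intercept_65 = 5000,
                         beta_entry_age = -0.3,
                         beta_entry_age2 = -0.01,
                         beta_icv = 1.0,
                         slope = -0.6,
                         slope_x_entryage = -0.02,
                         slope_x_icv = 0,
                         random_intercept_sd = 8,
                         random_slope_sd = 0.3,
                         intercept_slope_corr = -0.1,
                         residual_sd = 1.0,
                         slope_corr = NULL) {
  R <- length(regions)
  if (is.null(slope_corr)) slope_corr <- diag(R)
  slope_corr <- as.matrix(slope_corr)
  if (!isTRUE(all.equal(dim(slope_corr), c(R, R))) ||
      max(abs(slope_corr - t(slope_corr))) > 1e-8 ||
      max(abs(diag(slope_corr) - 1)) > 1e-8) {
    stop("slope_corr must be a symmetric ", R, "x", R,
         " matrix with unit diagonal")
  }
  if (min(eigen(slope_corr, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8) {
    stop("slope_corr is not positive semi-definite")
  }
  d <- data.frame(
    region = regions,
    intercept_65 = rep_len(intercept_65, R),
    beta_entry_age = rep_len(beta_entry_age, R),
    beta_entry_age2 = rep_len(beta_entry_age2, R),
    beta_icv = rep_len(beta_icv, R),
    slope = rep_len(slope, R),
    slope_x_entryage = rep_len(slope_x_entryage, R),
    slope_x_icv = rep_len(slope_x_icv, R),
    random_intercept_sd = rep_len(random_intercept_sd, R),
    random_slope_sd = rep_len(random_slope_sd, R),
    intercept_slope_corr = rep_len(intercept_slope_corr, R),
    residual_sd = rep_len(residual_sd, R),
    stringsAsFactors = FALSE)
  if (any(d$random_intercept_sd < 0) || any(d$random_slope_sd < 0) ||
      any(d$residual_sd < 0)) {
    stop("SD parameters must be >= 0")
  }
  if (any(abs(d$intercept_slope_corr) > 1)) {
    stop("intercept_slope_corr must be in [-1, 1]")
  }
  structure(d, slope_corr = slope_corr,
            class = c("region_truth", "data.frame"))
}

# symmetric PSD square root (tolerates zero eigenvalues, used for exact
# degenerate cases such as all-SDs-zero or correlation 1)
psd_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1)) {
    stop("random-effect covariance is not positive semi-definite")
  }
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# joint covariance of (u0_1..u0_R, u1_1..u1_R): slopes coupled across
# regions by slope_corr, intercepts independent across regions,
# intercept-slope correlation within region only
random_effect_cov <- function(truth) {
  R <- nrow(truth)
  Rm <- attr(truth, "slope_corr")
  sd0 <- truth$random_intercept_sd
  sd1 <- truth$random_slope_sd
  S <- matrix(0, 2 * R, 2 * R)
  S[1:R, 1:R] <- diag(sd0^2, R)
  S[R + 1:R, R + 1:R] <- outer(sd1, sd1) * Rm
  for (r in seq_len(R)) {
    S[r, R + r] <- S[R + r, r] <-
      truth$intercept_slope_corr[r] * sd0[r] * sd1[r]
  }
  S
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws subject covariates, observation times, region volumes from the
#' linear random-intercept/random-slope model described by `truth`, and then
#' applies calibrated MAR dropout. Volumes are generated on the percent
#' scale (100 = the region's age-65 volume) and converted to mm^3 via each
#' region's `intercept_65`, so the returned cohort is on the raw scale and
#' the percent scaling step has real work to do.
#'
#' The per-subject true slopes (fixed part plus random deviation, %/yr) are
#' attached as attribute `"true_slopes"` (subjects x regions), and the raw
#' random-effect draws as `"random_effects"`.
#'
#' @param design a [cohort_design()].
#' @param truth a [region_truth()].
#' @return a raw-scale [cohort()].
#' @export
generate_cohort <- function(design, truth) {
  stopifnot(inherits(design, "cohort_design"), inherits(truth, "region_truth"))
  set.seed(design$seed)
  n <- design$n_subjects
  R <- nrow(truth)
  regions <- truth$region

  # subject covariates
  lo <- design$entry_age_range[1]; hi <- design$entry_age_range[2]
  entry_age <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      a <- rnorm(1, design$entry_age_mean, design$entry_age_sd)
      if (a >= lo && a <= hi) { entry_age[i] <- a; break }
    }
  }
  sex <- ifelse(runif(n) < design$female_fraction, "F", "M")
  icv <- rnorm(n, design$icv_mean, design$icv_sd)
  icv_z <- (icv - design$icv_mean) / design$icv_sd
  age_c <- entry_age - 65

  # observation times: baseline exact, follow-ups jittered, minority extra
  # wave near extra_wave_time
  follow <- design$wave_times[-1]
  has_extra <- runif(n) < design$extra_wave_fraction
  times <- vector("list", n)
  for (i in seq_len(n)) {
    tt <- follow + rnorm(length(follow), 0, design$time_jitter_sd)
    tt <- pmax(tt, 0.25)
    if (has_extra[i]) {
      tt <- c(tt, design$extra_wave_time +
                rnorm(1, 0, design$time_jitter_sd))
    }
    times[[i]] <- sort(tt)
  }

  # random effects and true slopes
  S <- random_effect_cov(truth)
  Z <- matrix(rnorm(n * 2 * R), n, 2 * R)
  U <- Z %*% psd_sqrt(S)
  u0 <- U[, seq_len(R), drop = FALSE]
  u1 <- U[, R + seq_len(R), drop = FALSE]
  true_slopes <- sweep(u1, 2, truth$slope, "+") +
    outer(age_c, truth$slope_x_entryage) + outer(icv_z, truth$slope_x_icv)
  colnames(true_slopes) <- regions
  colnames(u0) <- colnames(u1) <- regions

  # percent-scale trajectories per planned occasion
  level <- matrix(100, n, R) +
    outer(age_c, truth$beta_entry_age) +
    outer(age_c^2, truth$beta_entry_age2) +
    outer(icv_z, truth$beta_icv) + u0

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tt <- c(0, times[[i]])
    nt <- length(tt)
    pct <- matrix(level[i, ], nt, R, byrow = TRUE) +
      outer(tt, true_slopes[i, ]) +
      matrix(rnorm(nt * R), nt, R) %*% diag(truth$residual_sd, R)
    vol <- sweep(pct / 100, 2, truth$intercept_65, "*")
    colnames(vol) <- regions
    rows[[i]] <- data.frame(
      subject_id = sprintf("S%03d", i), time_years = tt,
      entry_age = entry_age[i], sex = sex[i], icv = icv[i],
      vol, check.names = FALSE, stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, rows)
  rownames(obs) <- NULL

  obs <- apply_mar_dropout(obs, design, regions)

  out <- cohort(obs, regions = regions, scale = "raw_mm3")
  attr(out, "true_slopes") <- true_slopes
  attr(out, "random_effects") <- list(u0 = u0, u1 = u1)
  attr(out, "provenance") <- list(design = unclass(design),
                                  truth = as.list(as.data.frame(truth)),
                                  seed = design$seed)
  out
}

# MAR dropout: per-follow-up-wave logistic hazard on standardized previous
# observed mean volume and standardized entry-age; intercept calibrated by
# root finding so expected retention at the final planned wave equals the
# design target. The extra (~3-year) wave is kept iff the subject is still
# in the study at the final planned wave preceding it -- dropout is decided
# at planned waves only, keeping missingness monotone.
apply_mar_dropout <- function(obs, design, regions) {
  if (design$retention_final >= 1) return(obs)
  ids <- unique(obs$subject_id)
  n <- length(ids)
  follow <- design$wave_times[-1]
  n_fu <- length(follow)

  # mean volume per row, standardized region-wise then averaged
  volmat <- as.matrix(obs[, regions, drop = FALSE])
  volz <- scale(volmat)
  mvol <- rowMeans(volz)
  age1 <- obs$entry_age[!duplicated(obs$subject_id)]
  agez <- as.numeric(scale(age1))

  # planned-wave index of each row within subject (by time order, with the
  # extra wave excluded from the hazard process)
  split_rows <- split(seq_len(nrow(obs)), obs$subject_id)[ids]
  planned <- lapply(split_rows, function(rr) {
    tt <- obs$time_years[rr]
    ord <- order(tt)
    rr <- rr[ord]; tt <- tt[ord]
    # match each planned wave to the nearest observation time
    sel <- integer(length(design$wave_times))
    used <- rep(FALSE, length(tt))
    for (w in seq_along(design$wave_times)) {
      d <- abs(tt - design$wave_times[w]); d[used] <- Inf
      sel[w] <- which.min(d); used[sel[w]] <- TRUE
    }
    list(rows = rr, planned_idx = sel, all_idx = seq_along(tt))
  })

  # previous observed mean volume per follow-up wave (value at previous
  # planned wave; under monotone dropout it is observed whenever the hazard
  # for the current wave is evaluated)
  prev_vol <- matrix(0, n, n_fu)
  for (i in seq_len(n)) {
    p <- planned[[i]]
    prev_rows <- p$rows[p$planned_idx[seq_len(n_fu)]]
    prev_vol[i, ] <- mvol[prev_rows]
  }

  lin <- design$dropout_beta_vol * prev_vol +
    matrix(design$dropout_beta_age * agez, n, n_fu)
  retention_at <- function(alpha) {
    mean(apply(1 - plogis(alpha + lin), 1, prod))
  }
  f <- function(alpha) retention_at(alpha) - design$retention_final
  if (f(-20) < 0 || f(20) > 0) {
    stop("retention_final is infeasible under the dropout model")
  }
  alpha <- uniroot(f, c(-20, 20), tol = 1e-10)$root

  haz <- plogis(alpha + lin)
  keep_rows <- rep(TRUE, nrow(obs))
  for (i in seq_len(n)) {
    p <- planned[[i]]
    drop_from <- Inf
    for (w in seq_len(n_fu)) {
      if (rbinom(1, 1, haz[i, w]) == 1) { drop_from <- w; break }
    }
    if (is.finite(drop_from)) {
      tt <- obs$time_years[p$rows]
      # drop the planned wave and everything at or after it (incl. extra)
      drop_planned_t <- tt[p$planned_idx[drop_from + 1]]
      keep_rows[p$rows[tt >= drop_planned_t - 1e-9]] <- FALSE
      # extra wave between earlier planned waves survives only if before
      # the dropout wave's planned time
    }
  }
  obs[keep_rows, , drop = FALSE]
}
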