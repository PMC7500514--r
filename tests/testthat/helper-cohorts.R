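# shared fixture builders; everything is generated in code at test time

# small deterministic cohort with no noise at all: every trajectory lies
# exactly on its fixed-effect line
zero_noise_cohort <- function(n = 4, regions = "r1", slope = -0.5,
                              intercept_65 = 5000, seed = 3) {
  des <- cohort_design(n_subjects = n, wave_times = c(0, 1, 2, 4),
                       time_jitter_sd = 0, extra_wave_fraction = 0,
                       retention_final = 1, seed = seed)
  tru <- region_truth(regions, intercept_65 = intercept_65, slope = slope,
                      random_intercept_sd = 0, random_slope_sd = 0,
                      intercept_slope_corr = 0, residual_sd = 0)
  generate_cohort(des, tru)
}

# study-shaped cohort generated directly on the percent scale
# (intercept_65 = 100 makes raw mm^3 coincide with percent of the age-65
# volume), for tests that do not exercise the scaling stage itself
percent_cohort <- function(n = 231, seed = 1, regions = "r1", slope = -0.6,
                           random_slope_sd = 0.3, slope_corr = NULL,
                           residual_sd = 1, retention_final = 0.72,
                           slope_x_entryage = -0.02, ...) {
  des <- cohort_design(n_subjects = n, retention_final = retention_final,
                       seed = seed)
  tru <- region_truth(regions, intercept_65 = 100, slope = slope,
                      random_slope_sd = random_slope_sd,
                      slope_x_entryage = slope_x_entryage,
                      residual_sd = residual_sd,
                      slope_corr = slope_corr, ...)
  co <- generate_cohort(des, tru)
  co$scale <- "percent_of_intercept65"
  co
}

# binned version for latent-growth fitting
binned <- function(co, k = 11) {
  assign_bins(co, kmedian_bins(co$observations$time_years, k = k))
}

# brute-force L1 cost of clustering sorted x into contiguous groups given
# split points; oracle for the k-median dynamic program
l1_partition_cost <- function(x, starts) {
  x <- sort(x)
  bounds <- c(starts, length(x) + 1L)
  sum(vapply(seq_along(starts), function(j) {
    seg <- x[bounds[j]:(bounds[j + 1] - 1L)]
    sum(abs(seg - median(seg)))
  }, numeric(1)))
}

best_partition_cost <- function(x, k) {
  n <- length(sort(x))
  if (k == 1) return(l1_partition_cost(x, 1L))
  splits <- utils::combn(2:n, k - 1, simplify = FALSE)
  min(vapply(splits, function(s) l1_partition_cost(x, c(1L, s)), numeric(1)))
}

# slope-slope correlation per retained draw of a bivariate fit
fit_draw_cor <- function(fit) {
  fit$draws[, "sA.sB"] /
    sqrt(fit$draws[, "sA.sA"] * fit$draws[, "sB.sB"])
}

# minimal stand-in bivariate fit (only what build_slope_matrix needs)
fake_bivariate_fit <- function(region_a, region_b, subjects, mean_a, mean_b,
                               n_draws = 5) {
  pv <- array(0, c(length(subjects), 4, n_draws),
              dimnames = list(subjects, c("iA", "sA", "iB", "sB"), NULL))
  pv[, "sA", ] <- matrix(mean_a, length(subjects), n_draws)
  pv[, "sB", ] <- matrix(mean_b, length(subjects), n_draws)
  structure(list(spec = list(region_a = region_a, region_b = region_b),
                 subjects = subjects, plausible_values = pv),
            class = "bivariate_fit")
}
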