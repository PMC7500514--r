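test_that("zero-noise generation is an exact deterministic function of covariates", {
  co <- zero_noise_cohort(n = 4)
  obs <- co$observations
  a <- obs$entry_age - 65
  z <- (obs$icv - 1.45e6) / 1.4e5
  expected_pct <- 100 - 0.3 * a - 0.01 * a^2 + 1 * z +
    (-0.5 - 0.02 * a) * obs$time_years
  expect_equal(obs$r1, expected_pct / 100 * 5000, tolerance = 1e-12)
  # same design + seed reproduces bit for bit
  co2 <- zero_noise_cohort(n = 4)
  expect_identical(co$observations, co2$observations)
  # every subject observed at all four planned waves
  expect_equal(nrow(obs), 16)
  expect_true(all(tapply(obs$time_years, obs$subject_id,
                         function(t) identical(sort(t), c(0, 1, 2, 4)))))
})

test_that("generator reproduces its own random-slope SD (self-check)", {
  des <- cohort_design(n_subjects = 2000, seed = 1)
  tru <- region_truth("r1", random_slope_sd = 0.441)
  co <- generate_cohort(des, tru)
  u1 <- attr(co, "random_effects")$u1
  expect_lt(abs(sd(u1[, "r1"]) - 0.441) / 0.441, 0.05)
})

test_that("MAR dropout hits the target wave-4 retention", {
  frac <- vapply(1:3, function(s) {
    co <- generate_cohort(cohort_design(n_subjects = 231, seed = s),
                          region_truth("r1"))
    obs <- co$observations
    mean(tapply(obs$time_years, obs$subject_id,
                function(t) any(t > 3.4)))
  }, numeric(1))
  expect_true(all(frac >= 0.67 & frac <= 0.77))
})

test_that("dropout is monotone in the planned waves", {
  co <- generate_cohort(cohort_design(n_subjects = 400, seed = 9),
                        region_truth("r1"))
  pat <- tapply(co$observations$time_years, co$observations$subject_id,
                function(t) {
    # presence of each planned follow-up (1, 2, 4 years)
    c(any(abs(t - 1) < 0.5), any(abs(t - 2) < 0.5), any(t > 3.4))
  })
  ok <- vapply(pat, function(p) all(diff(as.integer(p)) <= 0) || all(p),
               logical(1))
  expect_true(all(ok))
})

test_that("dropout is MAR: missingness is independent of the unobserved wave given history", {
  # same seed with retention 1 regenerates the identical complete volumes,
  # because dropout randomness is consumed after the trajectories
  des_full <- cohort_design(n_subjects = 3000, retention_final = 1, seed = 17)
  # strong volume dependence so the observed-history arm of the check has
  # power; the trajectories themselves are unaffected by dropout settings
  des_drop <- cohort_design(n_subjects = 3000, retention_final = 0.72,
                            seed = 17, dropout_beta_vol = -2)
  tru <- region_truth("r1", intercept_65 = 100)
  full <- generate_cohort(des_full, tru)$observations
  drop <- generate_cohort(des_drop, tru)$observations
  w4_full <- full[full$time_years > 3.4, ]
  w2_full <- full[abs(full$time_years - 2) < 0.5, ]
  observed4 <- tapply(drop$time_years, drop$subject_id,
                      function(t) any(t > 3.4))
  observed2 <- tapply(drop$time_years, drop$subject_id,
                      function(t) any(abs(t - 2) < 0.5))
  d <- data.frame(id = w4_full$subject_id, y4 = w4_full$r1,
                  age = w4_full$entry_age)
  d$miss <- !observed4[d$id]
  d$y2 <- w2_full$r1[match(d$id, w2_full$subject_id)]
  # condition on being at risk at wave 4 (observed through wave 2), where
  # the dropout hazard is a function of y2 and age only
  d <- d[observed2[d$id], ]
  fit <- suppressWarnings(
    glm(miss ~ y2 + age + y4, family = binomial, data = d))
  z4 <- summary(fit)$coefficients["y4", "z value"]
  expect_lt(abs(z4), 3)
  # while the observed history is genuinely predictive
  z2 <- summary(fit)$coefficients["y2", "z value"]
  expect_lt(z2, -3)
})

test_that("cross-region slope correlations converge to the requested matrix", {
  R <- matrix(c(1, 0.7, 0.2,
                0.7, 1, -0.3,
                0.2, -0.3, 1), 3, 3)
  des <- cohort_design(n_subjects = 5000, seed = 2)
  tru <- region_truth(c("a", "b", "c"), random_slope_sd = c(0.4, 0.3, 0.5),
                      slope_corr = R)
  co <- generate_cohort(des, tru)
  emp <- cor(attr(co, "random_effects")$u1)
  expect_lt(max(abs(emp - R)), 0.05)
})

test_that("invalid designs and truths are rejected", {
  expect_error(cohort_design(wave_times = c(1, 2)), "start at 0")
  expect_error(cohort_design(retention_final = 0), "retention")
  expect_error(cohort_design(entry_age_mean = 90), "entry_age_mean")
  badR <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(region_truth(c("a", "b", "c"), slope_corr = badR),
               "positive semi-definite")
  expect_error(region_truth("a", random_slope_sd = -1), "SD")
  # retention infeasible: age effect so strong that old subjects always
  # drop regardless of the calibrated intercept
  des <- cohort_design(n_subjects = 100, dropout_beta_age = 60,
                       retention_final = 0.99, seed = 1)
  expect_error(generate_cohort(des, region_truth("a")), "infeasible")
})

test_that("a minority of subjects gets an extra wave near 3 years", {
  co <- generate_cohort(cohort_design(n_subjects = 500, retention_final = 1,
                                      seed = 11),
                        region_truth("r1"))
  obs <- co$observations
  has3 <- tapply(obs$time_years, obs$subject_id,
                 function(t) any(abs(t - 3) < 0.45))
  expect_gt(mean(has3), 0.05)
  expect_lt(mean(has3), 0.18)
})

test_that("cohort round-trips through the delimited writer/reader", {
  co <- percent_cohort(n = 12, seed = 4)
  tmp <- tempfile(fileext = ".tsv")
  write_cohort(co, tmp)
  back <- read_cohort(tmp)
  expect_equal(back$regions, co$regions)
  expect_equal(back$scale, co$scale)
  expect_equal(back$observations$r1, co$observations$r1, tolerance = 1e-9)
  expect_true(file.exists(paste0(tmp, ".yml")))
})
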