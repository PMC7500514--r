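test_that("the slope matrix is the mean of means over contributing fits", {
  subjects <- sprintf("S%03d", 1:5)
  f1 <- fake_bivariate_fit("A", "B", subjects, mean_a = 1:5, mean_b = 11:15)
  f2 <- fake_bivariate_fit("A", "C", subjects, mean_a = 3:7, mean_b = 21:25)
  sm <- build_slope_matrix(list(f1, f2))
  # region A appears in both fits: column is the average of the two means
  expect_equal(unname(sm[, "A"]), (1:5 + 3:7) / 2)
  # regions B and C appear once: columns equal that fit's means exactly
  expect_equal(unname(sm[, "B"]), 11:15)
  expect_equal(unname(sm[, "C"]), 21:25)
  expect_equal(attr(sm, "provenance")$A, c(1L, 2L))
  expect_error(build_slope_matrix(list(f1), regions = c("A", "Z")),
               "none of the fits")
})

test_that("identical plausible-value means collapse to that common value", {
  subjects <- sprintf("S%03d", 1:4)
  f1 <- fake_bivariate_fit("A", "B", subjects, rep(2, 4), rep(2, 4))
  f2 <- fake_bivariate_fit("A", "B", subjects, rep(2, 4), rep(2, 4))
  sm <- build_slope_matrix(list(f1, f2))
  expect_true(all(sm == 2))
})

test_that("covariate adjustment residualizes exactly", {
  co <- percent_cohort(n = 60, seed = 110)
  subj <- subject_table(co)
  subjects <- subj$subject_id
  icv_z <- (subj$icv - mean(subj$icv)) / sd(subj$icv)
  f <- fake_bivariate_fit("A", "B", subjects,
                          mean_a = 2 * icv_z,          # pure ICV artifact
                          mean_b = rnorm(length(subjects)))
  sm <- build_slope_matrix(list(f))
  adj <- adjust_covariates(sm, co)
  expect_lt(max(abs(adj[, "A"])), 1e-10)
  # residual columns are orthogonal to every covariate
  D <- cbind(icv_z, as.numeric(subj$sex == "M"), subj$entry_age)
  expect_lt(max(abs(t(D) %*% adj)), 1e-8)
  expect_true(attr(adj, "adjusted"))
  expect_error(adjust_covariates(adj, co), "already")
  # rank-deficient design (single-sex cohort) is refused
  co2 <- co
  co2$observations$sex <- "F"
  expect_error(adjust_covariates(sm, co2), "rank")
})

test_that("PCA has exact structure on diagonal covariance", {
  set.seed(5)
  n <- 400
  m <- cbind(a = rnorm(n, sd = 3), b = rnorm(n, sd = 2), c = rnorm(n, sd = 1))
  sm <- structure(m, adjusted = TRUE, class = c("slope_matrix", "matrix"))
  p <- pca_slopes(sm)
  expect_equal(sum(p$proportion), 1)
  expect_true(all(diff(p$eigenvalues) <= 0))
  # components align with the coordinate axes, ordered by variance
  expect_gt(abs(p$loadings["a", "PC1"]), 0.99)
  expect_gt(abs(p$loadings["b", "PC2"]), 0.99)
  # sign convention: dominant loading positive
  expect_gt(p$loadings["a", "PC1"], 0)
  # scores reproduce the centered data in the rotated basis
  expect_equal(unname(p$scores %*% t(p$loadings)),
               unname(sweep(m, 2, colMeans(m))), tolerance = 1e-10)
})

test_that("a low-rank slope structure is recovered", {
  set.seed(6)
  n <- 300
  f1 <- rnorm(n); f2 <- rnorm(n)
  load1 <- c(1, 0.8, 0.6, 0.4, 0.2)
  load2 <- c(0, 0.3, -0.5, 0.7, -0.2)
  m <- outer(f1, load1) + outer(f2, load2) +
    matrix(rnorm(n * 5, sd = 0.05), n, 5)
  colnames(m) <- paste0("r", 1:5)
  sm <- structure(m, adjusted = TRUE, class = c("slope_matrix", "matrix"))
  p <- pca_slopes(sm, var_target = 0.85)
  expect_gt(p$cumulative[2], 0.95)
  expect_lte(p$n_components, 2)
})

test_that("PCA is invariant to subject and region permutations up to sign", {
  set.seed(7)
  m <- matrix(rnorm(200 * 4), 200, 4,
              dimnames = list(NULL, c("w", "x", "y", "z")))
  m[, 2] <- m[, 1] * 0.7 + m[, 2] * 0.3
  sm <- structure(m, adjusted = TRUE, class = c("slope_matrix", "matrix"))
  p1 <- pca_slopes(sm)
  perm <- structure(m[sample(nrow(m)), c(3, 1, 4, 2)], adjusted = TRUE,
                    class = c("slope_matrix", "matrix"))
  p2 <- pca_slopes(perm)
  expect_equal(p1$eigenvalues, p2$eigenvalues, tolerance = 1e-10)
  expect_equal(abs(p1$loadings[c(3, 1, 4, 2), ]), abs(p2$loadings),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("degenerate inputs warn but do not fail", {
  m <- cbind(a = rnorm(10), b = rep(1, 10))
  sm <- structure(m, adjusted = TRUE, class = c("slope_matrix", "matrix"))
  expect_warning(pca_slopes(sm), "constant")
  sm2 <- structure(matrix(rnorm(6), 2, 3), adjusted = TRUE,
                   class = c("slope_matrix", "matrix"))
  expect_warning(pca_slopes(sm2), "fewer subjects")
  sm3 <- structure(matrix(rnorm(20), 10, 2), adjusted = FALSE,
                   class = c("slope_matrix", "matrix"))
  expect_warning(pca_slopes(sm3), "not covariate-adjusted")
})
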