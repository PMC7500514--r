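#' Build the subjects-by-regions matrix of person-specific slopes
#'
#' For each subject and region, averages the plausible-value means over
#' every bivariate fit that contains the region ("mean of the means"). This
#' simple estimator is biased toward attenuated correlations -- the
#' documented trade-off of a one-number-per-person summary -- but retains
#' the covariance pattern.
#'
#' @param fits list of [fit_bivariate()] results on the same cohort.
#' @param regions regions to include; default all regions present in the
#'   fits.
#' @return an object of class `slope_matrix`: a subjects x regions matrix
#'   (units %/yr) with attributes `provenance` (which fits contributed per
#'   region) and `adjusted = FALSE`.
#' @export
build_slope_matrix <- function(fits, regions = NULL) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "bivariate_fit")))
  fit_regions <- lapply(fits, function(f) c(f$spec$region_a, f$spec$region_b))
  all_regions <- unique(unlist(fit_regions))
  if (is.null(regions)) regions <- all_regions
  subjects <- fits[[1]]$subjects
  same <- vapply(fits, function(f) identical(f$subjects, subjects),
                 logical(1))
  if (!all(same)) stop("fits are not on the same subjects")

  values <- matrix(NA_real_, length(subjects), length(regions),
                   dimnames = list(subjects, regions))
  provenance <- setNames(vector("list", length(regions)), regions)
  for (r in regions) {
    contributing <- which(vapply(fit_regions, function(x) r %in% x,
                                 logical(1)))
    if (length(contributing) == 0) {
      stop("region '", r, "' appears in none of the fits")
    }
    means <- vapply(contributing, function(j) {
      plausible_slopes(fits[[j]], r)$mean
    }, numeric(length(subjects)))
    values[, r] <- rowMeans(as.matrix(means))
    provenance[[r]] <- contributing
  }
  structure(values, provenance = provenance, adjusted = FALSE,
            class = c("slope_matrix", "matrix"))
}

#' Adjust slope estimates for covariates
#'
#' Replaces each region's column by the residuals of its least-squares
#' regression on an intercept, ICV (standardized), sex, and entry-age.
#' Residual columns are exactly orthogonal to the covariate design, so the
#' downstream PCA reflects slope variation not attributable to these
#' covariates.
#'
#' @param matrix a [build_slope_matrix()] result (unadjusted).
#' @param cohort the [cohort()] supplying the covariates.
#' @return the adjusted `slope_matrix` (attribute `adjusted = TRUE`).
#' @export
adjust_covariates <- function(matrix, cohort) {
  stopifnot(inherits(matrix, "slope_matrix"))
  if (isTRUE(attr(matrix, "adjusted"))) {
    stop("slope matrix is already adjusted")
  }
  subj <- subject_table(cohort)
  idx <- match(rownames(matrix), subj$subject_id)
  if (anyNA(idx)) stop("slope-matrix subjects missing from cohort")
  D <- cbind(1,
             icv = (subj$icv[idx] - mean(subj$icv)) / stats::sd(subj$icv),
             sex = as.numeric(subj$sex[idx] == "M"),
             entry_age = subj$entry_age[idx])
  if (qr(D)$rank < ncol(D)) {
    stop("rank-deficient covariate design (constant sex or age?)")
  }
  res <- lm.fit(D, matrix)$residuals
  dimnames(res) <- dimnames(matrix)
  structure(res, provenance = attr(matrix, "provenance"), adjusted = TRUE,
            class = c("slope_matrix", "matrix"))
}

#' PCA of the person-specific slope covariance
#'
#' Eigendecomposition of the column covariance matrix of the (adjusted)
#' slope matrix -- covariance, not correlation, PCA: the percent scaling
#' already puts regions on comparable scales, and regions with large slope
#' variability should weigh more. Components are signed so that each one's
#' largest-magnitude loading is positive, making results deterministic
#' under subject or region reordering.
#'
#' @param matrix a [slope_matrix], normally adjusted.
#' @param var_target cumulative explained-variance target used to report
#'   `n_components` (default 0.85).
#' @return an object of class `pca_result` with `eigenvalues`,
#'   `proportion`, `cumulative`, `loadings` (regions x components),
#'   `scores` (subjects x components), and `n_components`.
#' @export
pca_slopes <- function(matrix, var_target = 0.85) {
  stopifnot(inherits(matrix, "slope_matrix"))
  if (!isTRUE(attr(matrix, "adjusted"))) {
    warning("slope matrix is not covariate-adjusted")
  }
  if (nrow(matrix) < ncol(matrix)) {
    warning("fewer subjects than regions; trailing components are degenerate")
  }
  sds <- apply(matrix, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant slope column(s): ",
            paste(colnames(matrix)[sds == 0], collapse = ", "))
  }
  S <- cov(matrix)
  e <- eigen(S, symmetric = TRUE)
  values <- pmax(e$values, 0)
  L <- e$vectors
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(colnames(matrix), paste0("PC", seq_len(ncol(L))))
  centered <- scale(matrix, center = TRUE, scale = FALSE)
  scores <- centered %*% L
  prop <- values / sum(values)
  cum <- cumsum(prop)
  structure(list(eigenvalues = values, proportion = prop,
                 cumulative = cum, loadings = L, scores = scores,
                 n_components = which(cum >= var_target)[1]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(length(x$eigenvalues), 8)
  cat("<pca_result> ", length(x$eigenvalues), " components; ",
      x$n_components, " reach the variance target\n", sep = "")
  tab <- data.frame(eigenvalue = round(x$eigenvalues[1:k], 4),
                    proportion = round(x$proportion[1:k], 3),
                    cumulative = round(x$cumulative[1:k], 3))
  rownames(tab) <- paste0("PC", 1:k)
  print(tab)
  invisible(x)
}
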