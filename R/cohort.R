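#' Longitudinal cohort container
#'
#' A `cohort` holds long-format longitudinal observations of regional brain
#' volumes together with subject-level covariates. One row per subject and
#' measurement occasion; a missing wave is an absent row, not a sentinel
#' value. Volumes are either raw (`"raw_mm3"`) or expressed as percent of the
#' region's fitted population intercept at entry-age 65
#' (`"percent_of_intercept65"`, see [scale_to_percent()]).
#'
#' @param observations data.frame with columns `subject_id`, `time_years`,
#'   `entry_age`, `sex` (`"F"`/`"M"`), `icv`, and one numeric column per
#'   region.
#' @param regions character vector naming the region columns. Defaults to all
#'   columns not among the standard ones.
#' @param scale `"raw_mm3"` or `"percent_of_intercept65"`.
#' @param intercepts named numeric vector of fitted age-65 intercepts used in
#'   scaling (only meaningful for percent-scaled cohorts).
#' @return An object of class `cohort`.
#' @export
cohort <- function(observations,
                   regions = NULL,
                   scale = c("raw_mm3", "percent_of_intercept65"),
                   intercepts = NULL) {
  scale <- match.arg(scale)
  std_cols <- c("subject_id", "time_years", "entry_age", "sex", "icv",
                "time_bin")
  missing_cols <- setdiff(std_cols[1:5], names(observations))
  if (length(missing_cols) > 0) {
    stop("observations lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(regions)) {
    regions <- setdiff(names(observations), std_cols)
  }
  if (length(regions) == 0) stop("cohort has no region columns")
  observations$subject_id <- as.character(observations$subject_id)
  obj <- structure(
    list(observations = observations, regions = regions,
         scale = scale, intercepts = intercepts),
    class = "cohort")
  validate_cohort(obj)
  obj
}

#' Validate a cohort
#'
#' Checks the structural invariants: a baseline (`time_years == 0`) row for
#' every subject, no duplicated (subject, time) pairs, entry-age at least 64,
#' non-negative times, and constant subject-level covariates within subject.
#'
#' @param x a [cohort()].
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_cohort <- function(x) {
  obs <- x$observations
  if (any(obs$time_years < 0)) stop("time_years must be >= 0")
  key <- paste(obs$subject_id, signif(obs$time_years, 12))
  if (anyDuplicated(key)) stop("duplicate (subject_id, time_years) rows")
  has_bl <- tapply(obs$time_years, obs$subject_id, function(t) any(t == 0))
  if (!all(has_bl)) {
    stop("subjects without a baseline (time_years == 0) row: ",
         paste(head(names(has_bl)[!has_bl]), collapse = ", "))
  }
  if (any(obs$entry_age < 64)) stop("entry_age must be >= 64")
  if (!all(obs$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  for (v in c("entry_age", "sex", "icv")) {
    nuniq <- tapply(obs[[v]], obs$subject_id,
                    function(z) length(unique(z)))
    if (any(nuniq > 1)) stop("covariate '", v, "' varies within subject")
  }
  miss <- setdiff(x$regions, names(obs))
  if (length(miss) > 0) {
    stop("region columns absent from observations: ",
         paste(miss, collapse = ", "))
  }
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  obs <- x$observations
  cat("<cohort> ", length(unique(obs$subject_id)), " subjects, ",
      nrow(obs), " observations, ", length(x$regions), " regions [",
      x$scale, "]\n", sep = "")
  cat("  regions: ", paste(head(x$regions, 8), collapse = ", "),
      if (length(x$regions) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort a [cohort()].
#' @return integer count of distinct subjects.
#' @export
n_subjects <- function(cohort) {
  length(unique(cohort$observations$subject_id))
}

#' Subject-level covariate table
#'
#' One row per subject with `subject_id`, `entry_age`, `sex`, `icv`, in the
#' order of first appearance.
#'
#' @param cohort a [cohort()].
#' @return data.frame with one row per subject.
#' @export
subject_table <- function(cohort) {
  obs <- cohort$observations
  first <- !duplicated(obs$subject_id)
  out <- obs[first, c("subject_id", "entry_age", "sex", "icv")]
  rownames(out) <- NULL
  out
}

#' Write a cohort to delimited text with a sidecar config
#'
#' The observation table is written as a tab-separated file; a YAML sidecar
#' (`<path>.yml`) records the scale, the region list, the fitted scaling
#' intercepts, and (for synthetic cohorts) the generating design, truth and
#' seed, so that a run can be reproduced from the files alone.
#'
#' @param cohort a [cohort()].
#' @param path output file path for the table.
#' @param sidecar path for the YAML sidecar; default `<path>.yml`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sidecar = paste0(path, ".yml")) {
  utils::write.table(cohort$observations, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- list(scale = cohort$scale, regions = cohort$regions)
  if (!is.null(cohort$intercepts)) {
    meta$intercepts <- as.list(cohort$intercepts)
  }
  prov <- attr(cohort, "provenance")
  if (!is.null(prov)) meta$provenance <- prov
  yaml::write_yaml(meta, sidecar)
  invisible(path)
}

#' Read a cohort from delimited text
#'
#' Reads a long-format table written by [write_cohort()] (or any compatible
#' tab/comma-delimited file with header). If the YAML sidecar exists it
#' supplies the scale and the region list; otherwise all non-standard columns
#' are taken as regions and the scale defaults to raw.
#'
#' @param path file path.
#' @param sidecar path of the YAML sidecar; default `<path>.yml`.
#' @param sep field separator; default tab.
#' @return a [cohort()].
#' @export
read_cohort <- function(path, sidecar = paste0(path, ".yml"), sep = "\t") {
  obs <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  regions <- NULL
  scale <- "raw_mm3"
  intercepts <- NULL
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    regions <- unlist(meta$regions)
    if (!is.null(meta$scale)) scale <- meta$scale
    if (!is.null(meta$intercepts)) intercepts <- unlist(meta$intercepts)
  }
  cohort(obs, regions = regions, scale = scale, intercepts = intercepts)
}
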