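#' Run the full decline-trajectory pipeline
#'
#' Orchestrates simulate/ingest -> percent scaling -> time binning ->
#' influence QC -> univariate fits -> 20-year extrapolation with bootstrap
#' -> bivariate models -> slope-matrix PCA from a single structured
#' configuration, writing publication-style delimited tables plus a
#' manifest with checksums. Every table carries the configuration hash in a
#' leading comment line, and re-running with the same configuration and
#' seed reproduces all summary outputs bit for bit.
#'
#' The configuration is a named list (or the path of a YAML file) with
#' elements:
#' \describe{
#'   \item{seed}{integer, mandatory; drives every stochastic stage.}
#'   \item{output_dir}{directory for the run artifacts.}
#'   \item{input}{path of a cohort table to ingest, or}
#'   \item{simulate}{list with `design` and `truth` argument lists for
#'     [cohort_design()] / [region_truth()].}
#'   \item{stages}{subset of `c("qc", "fit", "extrapolate", "bivariate",
#'     "pca")`; scaling and binning always run. Later stages require their
#'     prerequisites (`pca` needs `bivariate`).}
#'   \item{bins}{list: `k` (default automatic selection).}
#'   \item{qc}{list: `method`, thresholds passed to
#'     [influence_measures()].}
#'   \item{bootstrap}{list: `B` (default 200).}
#'   \item{bivariate}{list: `chains`, `iter`, `burnin`, `thin_pv`,
#'     `prior`, `include_sex`.}
#'   \item{pca}{list: `var_target` (default 0.85).}
#' }
#'
#' @param config named list or YAML file path.
#' @return (invisibly) a list of the in-memory stage results plus the
#'   manifest; artifacts are written under `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config$seed is mandatory")
  if (is.null(config$output_dir)) stop("config$output_dir is required")
  stages <- config$stages %||%
    c("qc", "fit", "extrapolate", "bivariate", "pca")
  bad <- setdiff(stages, c("qc", "fit", "extrapolate", "bivariate", "pca"))
  if (length(bad) > 0) stop("unknown stages: ", paste(bad, collapse = ", "))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  cfg_path <- file.path(config$output_dir, "config.yml")
  yaml::write_yaml(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log_lines <- c(paste0("lgctraj run, config hash ", cfg_hash),
                 paste0("seed: ", config$seed),
                 paste0("stages: ", paste(stages, collapse = ", ")))
  results <- list(config_hash = cfg_hash)

  write_table <- function(df, name) {
    path <- file.path(config$output_dir, name)
    con <- file(path, "w")
    writeLines(paste0("# config_hash: ", cfg_hash), con)
    suppressWarnings(utils::write.table(
      df, con, sep = "\t", row.names = FALSE, quote = FALSE))
    close(con)
    path
  }
  fail <- function(stage, e) {
    manifest_partial(config$output_dir, cfg_hash)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  }

  # --- ingest / simulate -------------------------------------------------
  cohort <- tryCatch({
    if (!is.null(config$input)) {
      read_cohort(config$input)
    } else if (!is.null(config$simulate)) {
      des <- do.call(cohort_design,
                     c(config$simulate$design %||% list(),
                       list(seed = config$seed)))
      tru <- do.call(build_truth_from_config,
                     list(config$simulate$truth %||% list()))
      generate_cohort(des, tru)
    } else stop("config needs either 'input' or 'simulate'")
  }, error = function(e) fail("ingest", e))
  write_cohort(cohort, file.path(config$output_dir, "cohort_raw.tsv"))
  log_lines <- c(log_lines, paste0("cohort: ", n_subjects(cohort),
                                   " subjects, ",
                                   length(cohort$regions), " regions"))

  # --- scaling and binning (always) -------------------------------------
  cohort <- tryCatch(scale_to_percent(cohort),
                     error = function(e) fail("scale", e))
  binning <- tryCatch(
    kmedian_bins(cohort$observations$time_years,
                 k = config$bins$k %||% NULL),
    error = function(e) fail("bins", e))
  cohort <- assign_bins(cohort, binning)
  write_cohort(cohort, file.path(config$output_dir, "cohort_scaled.tsv"))
  write_table(data.frame(bin = seq_along(binning$bin_values),
                         value_years = binning$bin_values),
              "time_bins.tsv")
  results$binning <- binning
  log_lines <- c(log_lines,
                 paste0("scaling intercepts: ",
                        paste(sprintf("%s=%.1f", names(cohort$intercepts),
                                      cohort$intercepts), collapse = ", ")),
                 paste0("time bins (k=", binning$k, "): ",
                        paste(signif(binning$bin_values, 4),
                              collapse = ", ")))

  regions <- cohort$regions
  per_region_cohort <- setNames(rep(list(cohort), length(regions)), regions)

  # --- influence QC ------------------------------------------------------
  if ("qc" %in% stages) {
    qc_args <- config$qc %||% list()
    reports <- tryCatch(lapply(regions, function(r) {
      do.call(influence_measures,
              c(list(cohort = cohort,
                     spec = growth_model_spec(r, use_binned_time = TRUE)),
                qc_args))
    }), error = function(e) fail("qc", e))
    names(reports) <- regions
    qc_tab <- do.call(rbind, lapply(regions, function(r) {
      cbind(region = r, as.data.frame(reports[[r]]))
    }))
    write_table(qc_tab, "qc_influence.tsv")
    for (r in regions) {
      per_region_cohort[[r]] <- apply_exclusion(cohort, reports[[r]])
      nex <- sum(reports[[r]]$excluded)
      if (nex > 0) {
        log_lines <- c(log_lines, paste0(
          "qc: excluded ", nex, " subject(s) for region ", r, ": ",
          paste(reports[[r]]$subject_id[reports[[r]]$excluded],
                collapse = ", ")))
      }
    }
    results$qc <- reports
  }

  # --- univariate fits ---------------------------------------------------
  if ("fit" %in% stages) {
    fit_rows <- tryCatch(lapply(regions, function(r) {
      co <- per_region_cohort[[r]]
      full <- fit_univariate(co, growth_model_spec(r))
      red <- fit_univariate(co, growth_model_spec(r, random_slope = FALSE))
      lrt <- lrt_random_slope(full, red)
      sex <- sex_effect_test(co, growth_model_spec(r))
      data.frame(
        region = r,
        slope = unname(full$beta["time"]),
        slope_lower = unname(full$ci["time", "lower"]),
        slope_upper = unname(full$ci["time", "upper"]),
        slope_x_entryage = unname(full$beta["age_c:time"]),
        sxe_lower = unname(full$ci["age_c:time", "lower"]),
        sxe_upper = unname(full$ci["age_c:time", "upper"]),
        loss20 = loss20_from_fit(full),
        random_slope_sd = full$random_slope_sd,
        random_slope_p = lrt$p_value,
        sex_p = sex$p_value)
    }), error = function(e) fail("fit", e))
    fit_tab <- do.call(rbind, fit_rows)
    write_table(fit_tab, "fit_summary.tsv")
    results$fit_summary <- fit_tab
  }

  # --- extrapolation bootstrap ------------------------------------------
  if ("extrapolate" %in% stages) {
    B <- config$bootstrap$B %||% 200
    extra <- tryCatch(
      bootstrap_loss20(cohort, regions, B = B,
                       seed = config$seed + 101L),
      error = function(e) fail("extrapolate", e))
    write_table(data.frame(region = names(extra$estimate),
                           loss20 = extra$estimate,
                           ci_lower = extra$ci["lower", ],
                           ci_upper = extra$ci["upper", ]),
                "extrapolation.tsv")
    write_table(cbind(region = rownames(extra$pairwise_mass),
                      as.data.frame(extra$pairwise_mass)),
                "pairwise_mass.tsv")
    results$extrapolation <- extra
  }

  # --- bivariate models --------------------------------------------------
  if ("bivariate" %in% stages) {
    bv <- config$bivariate %||% list()
    pairs <- utils::combn(regions, 2, simplify = FALSE)
    fits <- tryCatch(lapply(seq_along(pairs), function(j) {
      pr <- pairs[[j]]
      spec <- bivariate_spec(
        pr[1], pr[2],
        chains = bv$chains %||% 2,
        iter = bv$iter %||% 4000,
        burnin = bv$burnin %||% ((bv$iter %||% 4000) %/% 2),
        thin_pv = bv$thin_pv %||% 10,
        seed = config$seed + 200L + j,
        prior = bv$prior %||% "improper",
        include_sex = bv$include_sex %||% TRUE)
      fit_bivariate(cohort, spec)
    }), error = function(e) fail("bivariate", e))
    summ <- do.call(rbind, lapply(fits, function(f) {
      data.frame(region_a = f$spec$region_a, region_b = f$spec$region_b,
                 rho_ss_median = f$rho_ss_median,
                 rho_lower = f$rho_ss_ci[1], rho_upper = f$rho_ss_ci[2],
                 minority_mass = f$minority_mass,
                 reliability = f$reliability,
                 prior = f$prior_used, converged = f$converged,
                 max_rhat = max(f$rhat))
    }))
    write_table(summ, "bivariate_summary.tsv")
    rho <- matrix(1, length(regions), length(regions),
                  dimnames = list(regions, regions))
    stars <- matrix("", length(regions), length(regions),
                    dimnames = list(regions, regions))
    for (f in fits) {
      a <- f$spec$region_a; b <- f$spec$region_b
      rho[a, b] <- rho[b, a] <- f$rho_ss_median
      stars[a, b] <- stars[b, a] <-
        ifelse(f$reliability == "none", "", f$reliability)
    }
    write_table(cbind(region = regions, as.data.frame(rho)),
                "rho_ss_medians.tsv")
    write_table(cbind(region = regions, as.data.frame(stars)),
                "rho_ss_stars.tsv")
    results$bivariate <- fits
  }

  # --- slope matrix and PCA ---------------------------------------------
  if ("pca" %in% stages) {
    if (!"bivariate" %in% stages) {
      stop("pipeline stage 'pca' requires stage 'bivariate'")
    }
    pca_res <- tryCatch({
      sm <- build_slope_matrix(results$bivariate)
      sm_adj <- adjust_covariates(sm, cohort)
      list(matrix = sm_adj, pca = pca_slopes(
        sm_adj, var_target = config$pca$var_target %||% 0.85))
    }, error = function(e) fail("pca", e))
    write_table(cbind(subject_id = rownames(pca_res$matrix),
                      as.data.frame(unclass(pca_res$matrix))),
                "slope_matrix.tsv")
    p <- pca_res$pca
    write_table(data.frame(component = seq_along(p$eigenvalues),
                           eigenvalue = p$eigenvalues,
                           proportion = p$proportion,
                           cumulative = p$cumulative),
                "pca_variance.tsv")
    write_table(cbind(region = rownames(p$loadings),
                      as.data.frame(p$loadings)), "pca_loadings.tsv")
    write_table(cbind(subject_id = rownames(p$scores),
                      as.data.frame(p$scores)), "pca_scores.tsv")
    results$pca <- p
    results$slope_matrix <- pca_res$matrix
  }

  writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))
  results$manifest <- manifest_partial(config$output_dir, cfg_hash)
  invisible(results)
}

# writes (and returns) the manifest of everything currently in the output
# directory, with md5 checksums
manifest_partial <- function(output_dir, cfg_hash) {
  files <- setdiff(list.files(output_dir), "manifest.tsv")
  man <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(output_dir, files))),
    stringsAsFactors = FALSE)
  path <- file.path(output_dir, "manifest.tsv")
  con <- file(path, "w")
  writeLines(paste0("# config_hash: ", cfg_hash), con)
  utils::write.table(man, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  man
}

# region_truth() from a plain config list; slope_corr may come in as a list
# of rows (YAML matrix)
build_truth_from_config <- function(truth) {
  if (is.null(truth$regions)) {
    truth$regions <- paste0("region_", 1:5)
  }
  if (!is.null(truth$slope_corr) && !is.matrix(truth$slope_corr)) {
    truth$slope_corr <- do.call(rbind, lapply(truth$slope_corr, unlist))
  }
  do.call(region_truth, truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
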