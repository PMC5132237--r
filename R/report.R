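#' Default analysis configuration
#'
#' One list governs every tunable of the pipeline: the spline smoothing
#' parameter, the SEP chord tolerance, the age and feature of the median
#' split, the minimum per-age sample size, and the RLS thresholds of the
#' conditional correlation screen.
#'
#' @param spar smoothing parameter for trajectory fitting.
#' @param split_age replicative age of the median split.
#' @param split_feature feature used for the split.
#' @param min_n minimum cells per reported age in correlation screens.
#' @param sep_epsilon chord-distance tolerance of the SEP detector.
#' @param sep_on_fitted call the SEP on smoothed duration profiles.
#' @param conditional_min_rls RLS thresholds of the conditional screen.
#' @param concentration_ages representative ages for the
#'   concentration-size regressions.
#' @return named list of class `cellspan_config`.
#' @export
analysis_config <- function(spar = 0.5, split_age = 5,
                            split_feature = "fold_increase", min_n = 10,
                            sep_epsilon = 0.02, sep_on_fitted = FALSE,
                            conditional_min_rls = c(8, 12, 16, 18),
                            concentration_ages = c(7, 13)) {
  structure(as.list(environment()), class = "cellspan_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path a `.yaml`/`.yml` (requires the yaml package) or `.json` file.
#' @return a [analysis_config()] list.
#' @export
read_analysis_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the yaml package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- analysis_config()
  bad <- setdiff(names(vals), names(cfg))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(vals)] <- vals
  cfg
}

#' Run the full lifespan analysis on a dataset
#'
#' Executes the whole pipeline — summary counts, raw start/end-size
#' correlations, trajectory fitting, SEP detection, per-age correlation
#' screens, the median-split survival comparison with log-rank test and
#' time-to-age rank-sum test, and (when a fluorescence channel is present)
#' the reporter analyses — and collects every number in one report bundle.
#'
#' @param dataset a [life_history_dataset()].
#' @param config a [analysis_config()].
#' @param seed optional integer recorded in the provenance block (the
#'   analysis itself is deterministic).
#' @return list of class `report_bundle`; see the elements' own names.
#'   Fluorescence blocks are `NULL`, with a warning, when the channel is
#'   absent.
#' @export
run_full_analysis <- function(dataset, config = analysis_config(), seed = NULL) {
  summ <- dataset_summary(dataset)
  cohort <- fit_cohort(dataset, spar = config$spar,
                       sep_epsilon = config$sep_epsilon,
                       sep_on_fitted = config$sep_on_fitted)
  cells <- cohort$cells

  # raw-size correlations are assessed before any smoothing
  size_corr <- list(
    start_vs_rls = pearson_r(cells$start_size, cells$rls),
    end_vs_rls = pearson_r(cells$end_size, cells$rls))
  sep_ok <- !is.na(cells$sep_age)
  sep_corr <- if (sum(sep_ok) >= 3 && sd(cells$sep_age[sep_ok]) > 0)
    pearson_r(cells$sep_size[sep_ok], cells$sep_age[sep_ok]) else NA_real_

  corr_all <- per_age_lifespan_correlation(cohort, "fold_increase",
                                           min_n = config$min_n)
  corr_pre <- per_age_lifespan_correlation(cohort, "fold_increase",
                                           min_n = config$min_n,
                                           exclude_post_sep = TRUE)

  split <- median_split_at_age(cohort, config$split_age, config$split_feature)
  rls <- setNames(cells$rls, cells$cell_id)
  ev <- setNames(cells$death_observed, cells$cell_id)
  km_less <- km_estimate(rls[split$less_ids], ev[split$less_ids])
  km_more <- km_estimate(rls[split$more_ids], ev[split$more_ids])
  lr <- logrank_test(rls[split$less_ids], rls[split$more_ids],
                     ev[split$less_ids], ev[split$more_ids])
  pct <- percent_median_difference(km_less$median_rls, km_more$median_rls)

  id2cell <- setNames(dataset$cells,
                      vapply(dataset$cells, function(c) c$cell_id, character(1)))
  tta <- function(ids) vapply(id2cell[ids], time_to_age, numeric(1),
                              n = config$split_age)
  rs <- ranksum_test(tta(split$less_ids), tta(split$more_ids))

  fluor <- NULL
  if (cohort$has_fluorescence) {
    conc_corr <- per_age_lifespan_correlation(cohort, "concentration",
                                              min_n = config$min_n)
    conds <- lapply(config$conditional_min_rls, function(mr)
      conditional_age_correlation(cohort, "concentration", min_rls = mr,
                                  min_n = config$min_n))
    names(conds) <- paste0("min_rls_", config$conditional_min_rls)
    cs <- lapply(config$concentration_ages, function(a)
      tryCatch(concentration_size_relation(cohort, a, min_n = config$min_n),
               error = function(e) NULL))
    names(cs) <- paste0("age_", config$concentration_ages)
    fluor <- list(per_age_correlation = conc_corr,
                  conditional = conds,
                  concentration_size = cs,
                  fold_summary = fluorescence_fold_summary(cohort,
                                                          min_n = config$min_n))
  } else {
    warning("dataset '", dataset$name,
            "' has no fluorescence channel; reporter analyses skipped",
            call. = FALSE)
  }

  structure(list(
    summary = summ,
    cohort = cohort,
    size_correlations = size_corr,
    sep_size_age_correlation = sep_corr,
    per_age_correlation = corr_all,
    per_age_correlation_pre_sep = corr_pre,
    split = split,
    km = list(less = km_less, more = km_more),
    logrank = lr,
    percent_median_difference = pct,
    time_to_age_ranksum = rs,
    fluorescence = fluor,
    provenance = list(dataset = dataset$name, source = dataset$source,
                      config = unclass(config), seed = seed,
                      package_version = as.character(packageVersion("cellspan")))
  ), class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  print(x$summary)
  cat(sprintf("start-size vs RLS r = %.3f; end-size vs RLS r = %.3f\n",
              x$size_correlations$start_vs_rls, x$size_correlations$end_vs_rls))
  if (!is.na(x$sep_size_age_correlation))
    cat(sprintf("SEP size vs SEP age r = %.4f\n", x$sep_size_age_correlation))
  a5 <- x$per_age_correlation[x$per_age_correlation$age == x$split$age, ]
  if (nrow(a5))
    cat(sprintf("fold-increase vs RLS at age %d: r = %.3f (n = %d)\n",
                a5$age, a5$r, a5$n))
  cat(sprintf("median split at age %d (threshold %.3f): %d / %d cells\n",
              x$split$age, x$split$threshold, x$split$n_less, x$split$n_more))
  cat(sprintf("KM medians %g vs %g (%+d%%), log-rank p = %.3g\n",
              x$km$less$median_rls, x$km$more$median_rls,
              x$percent_median_difference, x$logrank$p_value))
  cat(sprintf("time to age %d, rank-sum p = %.3g\n",
              x$split$age, x$time_to_age_ranksum$p_value))
  if (!is.null(x$fluorescence)) {
    for (nm in names(x$fluorescence$concentration_size)) {
      cs <- x$fluorescence$concentration_size[[nm]]
      if (!is.null(cs))
        cat(sprintf("concentration vs size at age %d: r = %.3f (slope %.3g)\n",
                    cs$age, cs$r, cs$slope))
    }
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits `report.json` (every statistic, plus provenance), and CSV tables
#' `corr_by_age.csv`, `survival.csv` and `sep.csv`.
#'
#' @param bundle a [run_full_analysis()] result.
#' @param dir output directory, created if needed.
#' @return invisibly, the directory.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  corr <- rbind(
    cbind(subset = "all", bundle$per_age_correlation),
    cbind(subset = "pre_sep", bundle$per_age_correlation_pre_sep))
  if (!is.null(bundle$fluorescence))
    corr <- rbind(corr, cbind(subset = "concentration",
                              bundle$fluorescence$per_age_correlation))
  write.csv(corr, file.path(dir, "corr_by_age.csv"), row.names = FALSE)

  surv <- rbind(cbind(group = "less", bundle$km$less$curve),
                cbind(group = "more", bundle$km$more$curve))
  write.csv(surv, file.path(dir, "survival.csv"), row.names = FALSE)

  sep <- bundle$cohort$cells[, c("cell_id", "sep_age", "sep_status",
                                 "sep_chord_distance", "sep_size")]
  write.csv(sep, file.path(dir, "sep.csv"), row.names = FALSE)

  json <- list(
    schema = "cellspan-report/1",
    summary = unclass(bundle$summary),
    size_correlations = bundle$size_correlations,
    sep_size_age_correlation = bundle$sep_size_age_correlation,
    per_age_correlation = bundle$per_age_correlation,
    per_age_correlation_pre_sep = bundle$per_age_correlation_pre_sep,
    split = bundle$split[c("age", "feature", "threshold", "n_less", "n_more")],
    km_median_less = bundle$km$less$median_rls,
    km_median_more = bundle$km$more$median_rls,
    logrank = unclass(bundle$logrank),
    percent_median_difference = bundle$percent_median_difference,
    time_to_age_ranksum = unclass(bundle$time_to_age_ranksum),
    fluorescence = if (!is.null(bundle$fluorescence)) list(
      per_age_correlation = bundle$fluorescence$per_age_correlation,
      conditional = bundle$fluorescence$conditional,
      concentration_size = bundle$fluorescence$concentration_size,
      fold_summary = bundle$fluorescence$fold_summary),
    provenance = bundle$provenance)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null", na = "null")
  invisible(dir)
}
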