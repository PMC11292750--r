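# Orchestration: simulate -> compute -> validate, with a manifest that
# makes a run reproducible (config hash + seed + input digests).

DEFAULT_PREDICTORS <- c("age", "sex", "nihss", "aspects", "recanalization",
                        "icu")

SUBGROUP_FACTORS <- c(age = "continuous", sex = "flag",
                      diabetes = "flag", ihd = "flag", af = "flag",
                      hypertension = "flag", nihss = "continuous",
                      aspects = "continuous", recanalization = "flag",
                      eni = "flag", sich = "flag", icu = "flag")

#' Comparative-validity report for a cohort
#'
#' Runs the full battery on a cohort with computed DAOH: cohort summary
#' (Table-1 analog, including the mRS distribution and functional
#' independence), prognostic-factor correlations of DAOH with age, NIHSS
#' and ASPECTS, the overall DAOH-mRS Spearman correlation in the standard
#' and death-recoded variants, the subgroup median table, ROC
#' discrimination of DAOH for the mRS cutpoints 0--3, and multivariable
#' logistic models for the two dichotomized outcomes (mRS <= 2 and
#' DAOH > `daoh_threshold`) with listwise deletion and c-statistics.
#' Degenerate statistics (e.g. a constant score distribution) are reported
#' as unavailable with the reason, never as a hard failure of the report.
#'
#' @param patients patients table (see [generate_cohort()]).
#' @param episodes episodes table.
#' @param horizon DAOH horizon in days.
#' @param daoh_threshold dichotomy for the DAOH logistic model (good
#'   outcome = DAOH strictly greater), default 70.
#' @param predictors model covariates, default
#'   age, sex, NIHSS, ASPECTS, recanalization, ICU admission.
#' @return list of report sections (also serialisable to JSON).
#' @export
validity_report <- function(patients, episodes, horizon = 90L,
                            daoh_threshold = 70,
                            predictors = DEFAULT_PREDICTORS) {
  daoh_std <- compute_daoh_cohort(patients, episodes, horizon, "standard")
  daoh_dz <- compute_daoh_cohort(patients, episodes, horizon, "death_zero")
  d <- patients
  d$daoh <- daoh_std$daoh[match(d$patient_id, daoh_std$patient_id)]
  d$daoh_death_zero <- daoh_dz$daoh[match(d$patient_id, daoh_dz$patient_id)]
  d$eni <- derive_eni(d$nihss, d$nihss_24h)
  d$sex_male <- d$sex == "male"

  safe <- function(expr) {
    tryCatch(expr, error = function(e) list(unavailable = conditionMessage(e)))
  }
  mrs_sum <- mrs_distribution_summary(d$mrs90)
  summary <- list(
    n = nrow(d),
    median_age = stats::median(d$age, na.rm = TRUE),
    median_nihss = stats::median(d$nihss, na.rm = TRUE),
    median_aspects = stats::median(d$aspects, na.rm = TRUE),
    median_daoh = stats::median(d$daoh),
    daoh_iqr = as.numeric(stats::quantile(d$daoh, c(0.25, 0.75))),
    deaths_90d = sum(!is.na(d$death_day) &
                       d$death_day < d$index_day + horizon),
    mrs_counts = mrs_sum$counts,
    fi_count = mrs_sum$fi_count,
    fi_percent = mrs_sum$fi_percent)

  prognostic <- list(
    age = safe(spearman_cor(d$daoh, d$age)),
    nihss = safe(spearman_cor(d$daoh, d$nihss)),
    aspects = safe(spearman_cor(d$daoh, d$aspects)))

  correlation <- list(
    standard = safe(spearman_cor(d$daoh, d$mrs90)),
    death_zero = safe(spearman_cor(d$daoh_death_zero, d$mrs90)),
    death_zero_recode_n = sum(d$daoh_death_zero == 0 & d$daoh > 0,
                              na.rm = TRUE))

  fac <- SUBGROUP_FACTORS
  fac <- fac[names(fac) %in% names(d)]
  names(fac)[names(fac) == "sex"] <- "sex_male"
  subgroups <- safe(subgroup_table(d, fac))

  roc <- lapply(0:3, function(k) {
    r <- safe(roc_auc(d$daoh, dichotomize_mrs(d$mrs90, k)))
    c(list(cutpoint = k), r)
  })

  dd <- d
  dd$mrs_le_2 <- dichotomize_mrs(dd$mrs90, 2)
  dd$daoh_gt_thr <- dd$daoh > daoh_threshold
  models <- list(
    mrs_le_2 = safe(fit_logistic(dd, "mrs_le_2",
                                 sub("^sex$", "sex_male", predictors))),
    daoh_gt_threshold = safe(fit_logistic(dd, "daoh_gt_thr",
                                          sub("^sex$", "sex_male",
                                              predictors))))

  list(summary = summary, prognostic = prognostic,
       correlation = correlation, subgroups = subgroups, roc = roc,
       models = models,
       settings = list(horizon = horizon, daoh_threshold = daoh_threshold,
                       predictors = predictors))
}

#' DAOH histogram, optionally stratified
#'
#' Counts patients per integer DAOH bin 0..horizon, overall or within
#' strata: mRS category, age group (at the cohort median), NIHSS group, or
#' ASPECTS group. Counts are conserved across stratification choices
#' (strata sum to the total), apart from records missing the stratifier.
#'
#' @param daoh data frame from [compute_daoh_cohort()].
#' @param patients patients table (needed for stratifiers other than
#'   `"none"`).
#' @param stratifier one of `"none"`, `"mrs"`, `"age_group"`,
#'   `"nihss_group"`, `"aspects_group"`.
#' @return data frame `stratum`, `daoh`, `count` (zero-count bins omitted).
#' @export
export_distribution <- function(daoh, patients = NULL,
                                stratifier = c("none", "mrs", "age_group",
                                               "nihss_group",
                                               "aspects_group")) {
  stratifier <- match.arg(stratifier)
  strat <- if (stratifier == "none") {
    rep("all", nrow(daoh))
  } else {
    if (is.null(patients)) stop("patients table required for stratifier")
    v <- patients[[switch(stratifier, mrs = "mrs90", age_group = "age",
                          nihss_group = "nihss", aspects_group = "aspects")]]
    v <- v[match(daoh$patient_id, patients$patient_id)]
    if (stratifier == "mrs") {
      paste0("mrs_", v)
    } else {
      med <- stats::median(v, na.rm = TRUE)
      ifelse(is.na(v), NA, ifelse(v >= med, sprintf("ge_%g", med),
                                  sprintf("lt_%g", med)))
    }
  }
  keep <- !is.na(strat)
  tab <- as.data.frame(table(stratum = strat[keep], daoh = daoh$daoh[keep]),
                       stringsAsFactors = FALSE)
  tab$daoh <- as.integer(tab$daoh)
  tab <- tab[tab$Freq > 0, ]
  names(tab)[3] <- "count"
  rownames(tab) <- NULL
  tab[order(tab$stratum, tab$daoh), ]
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full simulate/compute/validate pipeline
#'
#' Either simulates a cohort from a configuration or loads existing
#' `patients.csv`/`episodes.csv`, computes DAOH in the requested variant,
#' runs the validity battery, and writes `daoh.csv`, `report.json`,
#' `roc_curves.csv` and `manifest.json` into the output directory.
#' Deterministic given the configuration seed.
#'
#' @param config a `daoh_config`, or path to a YAML config file.
#' @param out_dir output directory (created).
#' @param input_dir optional directory with existing cohort tables; when
#'   given, no simulation is performed.
#' @param horizon,variant DAOH settings for `daoh.csv`.
#' @return the report list, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(config = NULL, out_dir, input_dir = NULL,
                         horizon = 90L,
                         variant = c("standard", "death_zero")) {
  variant <- match.arg(variant)
  if (is.character(config)) config <- read_config(config)
  if (is.null(config) && is.null(input_dir)) {
    stop("either a configuration (to simulate) or an input directory is required")
  }
  cohort <- if (!is.null(input_dir)) {
    read_cohort(input_dir)
  } else {
    generate_cohort(config)
  }
  if (is.null(config)) config <- cohort$config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  daoh <- compute_daoh_cohort(cohort$patients, cohort$episodes,
                              horizon = horizon, variant = variant)
  utils::write.csv(daoh, file.path(out_dir, "daoh.csv"), row.names = FALSE,
                   na = "")

  report <- validity_report(cohort$patients, cohort$episodes,
                            horizon = horizon)
  curves <- do.call(rbind, lapply(report$roc, function(r) {
    if (!is.null(r$unavailable)) return(NULL)
    data.frame(cutpoint = r$cutpoint, fpr = r$curve$fpr, tpr = r$curve$tpr)
  }))
  if (!is.null(curves)) {
    utils::write.csv(curves, file.path(out_dir, "roc_curves.csv"),
                     row.names = FALSE)
  }
  report_out <- report
  report_out$roc <- lapply(report_out$roc, function(r) {
    r$curve <- NULL
    r
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("daoh90")),
    seed = if (!is.null(config)) config$seed else NA,
    config_hash = if (!is.null(config)) config_hash(config) else NA,
    horizon = horizon, variant = variant,
    input_digests = if (!is.null(input_dir)) {
      as.list(tools::md5sum(c(file.path(input_dir, "patients.csv"),
                              file.path(input_dir, "episodes.csv"))))
    } else NULL,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(report_out, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
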