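# Synthetic stroke-registry generator. The registry it emulates is an
# administrative feed: one index admission per patient (the reperfusion
# hospitalization), possible noncontiguous readmissions and rehabilitation
# stays inside the 90-day window, deaths in and out of hospital, and an
# mRS-90 tied to a latent stroke-severity variable, so that the DAOH-mRS
# relationship can be induced at a chosen strength and recovered.

FACILITY_TYPES <- c("acute", "rehab", "residential")
TOAST_LEVELS <- c("cardioembolic", "laa", "other", "svo", "undetermined")
INTERVENTIONS <- c("evt", "ivt_evt", "ivt")

#' Configuration of the synthetic registry generator
#'
#' All parameters of the generative model, validated. Defaults are
#' calibrated so the marginals loosely resemble a national reperfusion
#' cohort: median NIHSS about 14, median ASPECTS about 8, roughly 15%
#' 90-day mortality, a median index stay of about 5 days (hence a DAOH
#' mode near 85), and an mRS-90 distribution with around half the cohort
#' functionally independent.
#'
#' @param n_patients cohort size (>= 1).
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @param severity_loadings named numeric: contribution of the
#'   standardized covariates (`nihss`, `age`, `aspects`) to latent
#'   severity. Higher NIHSS/age and lower ASPECTS increase severity under
#'   the defaults.
#' @param noise_sd residual severity noise SD (>= 0).
#' @param los_log_mean,los_log_sd index length-of-stay parameters on the
#'   log-day scale (`los_log_sd` > 0).
#' @param los_severity_gain increase in log-LOS per unit severity.
#' @param readmission_rate_base expected 90-day readmissions at severity 0
#'   (>= 0); `readmission_severity_gain` scales the log-intensity.
#' @param readmission_severity_gain see above.
#' @param death_logit_intercept,death_logit_slope logistic model for death
#'   within 90 days as a function of severity.
#' @param mrs_cutpoints six strictly increasing ordered-logit thresholds
#'   partitioning the latent scale into the seven mRS categories.
#' @param missingness_rates named probabilities of completely-at-random
#'   missingness per field. Recanalization is additionally missing by
#'   structure in patients without an angiogram (IVT-only).
#' @return validated list of class `daoh_config`.
#' @export
generator_config <- function(n_patients = 1278L,
                             seed,
                             severity_loadings = c(nihss = 1.3, age = 0.35,
                                                   aspects = -0.35),
                             noise_sd = 0.35,
                             los_log_mean = log(7),
                             los_log_sd = 0.55,
                             los_severity_gain = 0.6,
                             readmission_rate_base = 1.0,
                             readmission_severity_gain = 1.3,
                             death_logit_intercept = -3.0,
                             death_logit_slope = 1.7,
                             mrs_cutpoints = c(-1.95, -0.55, 0.55, 1.9,
                                               3.7, 5.0),
                             missingness_rates = c(aspects = 0.21,
                                                   nihss_24h = 0.02,
                                                   diabetes = 0.006,
                                                   ihd = 0.006,
                                                   af = 0.005,
                                                   hypertension = 0.006,
                                                   toast_category = 0.01,
                                                   sich = 0.03,
                                                   icu = 0.005)) {
  cfg <- list(n_patients = n_patients, seed = seed,
              severity_loadings = severity_loadings, noise_sd = noise_sd,
              los_log_mean = los_log_mean, los_log_sd = los_log_sd,
              los_severity_gain = los_severity_gain,
              readmission_rate_base = readmission_rate_base,
              readmission_severity_gain = readmission_severity_gain,
              death_logit_intercept = death_logit_intercept,
              death_logit_slope = death_logit_slope,
              mrs_cutpoints = mrs_cutpoints,
              missingness_rates = missingness_rates)
  class(cfg) <- "daoh_config"
  validate_config(cfg)
  cfg
}

#' @rdname generator_config
#' @param config object to validate.
#' @export
validate_config <- function(config) {
  bad <- function(field, why) {
    stop("invalid generator configuration: field '", field, "' ", why)
  }
  num1 <- function(field) {
    v <- config[[field]]
    if (is.null(v) || length(v) != 1L || !is.numeric(v) || is.na(v)) {
      bad(field, "must be a single number")
    }
    v
  }
  n <- num1("n_patients")
  if (n < 1 || n != round(n)) bad("n_patients", "must be a positive integer")
  s <- num1("seed")
  if (s != round(s)) bad("seed", "must be an integer")
  if (num1("noise_sd") < 0) bad("noise_sd", "must be nonnegative")
  num1("los_log_mean")
  if (num1("los_log_sd") <= 0) bad("los_log_sd", "must be positive")
  num1("los_severity_gain")
  if (num1("readmission_rate_base") < 0) {
    bad("readmission_rate_base", "must be nonnegative")
  }
  num1("readmission_severity_gain")
  num1("death_logit_intercept"); num1("death_logit_slope")
  cp <- config$mrs_cutpoints
  if (length(cp) != 6L || any(is.na(cp)) || any(diff(cp) <= 0)) {
    bad("mrs_cutpoints", "must be 6 strictly increasing values")
  }
  mr <- config$missingness_rates
  if (length(mr) > 0L &&
      (is.null(names(mr)) || any(is.na(mr)) || any(mr < 0 | mr > 1))) {
    bad("missingness_rates", "must be named probabilities in [0,1]")
  }
  sl <- config$severity_loadings
  if (length(sl) > 0L && (is.null(names(sl)) || any(is.na(sl)))) {
    bad("severity_loadings", "must be a named numeric vector")
  }
  if (!all(names(sl) %in% c("nihss", "age", "aspects"))) {
    bad("severity_loadings",
        "may only load on 'nihss', 'age', 'aspects'")
  }
  invisible(config)
}

#' Read a generator configuration from a key:value text file
#'
#' YAML-formatted; all fields of [generator_config()] accepted, `seed`
#' mandatory. Unknown keys are a schema error.
#'
#' @param path file path.
#' @return validated `daoh_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(generator_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(raw$seed)) stop("configuration must specify 'seed'")
  for (f in c("severity_loadings", "missingness_rates")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$mrs_cutpoints)) {
    raw$mrs_cutpoints <- as.numeric(unlist(raw$mrs_cutpoints))
  }
  do.call(generator_config, raw)
}

#' @rdname read_config
#' @param config a `daoh_config` to serialise.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (!is.null(names(x))) as.list(x) else x), path, precision = 15)
  invisible(path)
}

# standardization constants for the latent-severity z-scores; fixed (not
# per-sample) so a loading has the same meaning at any cohort size
SEVERITY_SCALE <- list(age = c(70, 13), nihss = c(14, 7.5),
                       aspects = c(8, 1.6))

#' Generate a synthetic stroke cohort
#'
#' Draws covariates, a latent severity score, an index admission with
#' severity-dependent length of stay, severity-dependent readmissions and
#' rehabilitation stays placed disjointly in the 90-day window, deaths in
#' or out of hospital with a uniformly placed death day, an mRS-90 from an
#' ordered-logit model on severity (forced to 6 exactly when the patient
#' died within 90 days), and completely-at-random missingness.
#' Deterministic given the seed.
#'
#' @param config a `daoh_config` from [generator_config()].
#' @return object of class `daoh_cohort`: list with `patients` (one row per
#'   patient incl. `true_severity`, retained for recovery testing),
#'   `episodes`, and `config`.
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  n <- as.integer(config$n_patients)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(config$seed))

  id <- sprintf("P%05d", seq_len(n))
  index_day <- sample.int(365L, n, replace = TRUE) - 1L
  age <- pmin(100L, pmax(18L, as.integer(round(stats::rnorm(n, 70, 13)))))
  sex <- ifelse(stats::runif(n) < 0.56, "male", "female")
  nihss <- pmin(42L, pmax(0L, as.integer(round(stats::rnorm(n, 13.8, 7.5)))))
  aspects <- pmax(0L, 10L - as.integer(stats::rpois(n, 2)))
  diabetes <- stats::runif(n) < 0.19
  ihd <- stats::runif(n) < 0.18
  af <- stats::runif(n) < 0.46
  hypertension <- stats::runif(n) < 0.63
  toast_category <- sample(TOAST_LEVELS, n, replace = TRUE,
                           prob = c(0.48, 0.20, 0.04, 0.04, 0.24))
  intervention <- sample(INTERVENTIONS, n, replace = TRUE,
                         prob = c(0.41, 0.38, 0.21))

  z <- function(x, nm) (x - SEVERITY_SCALE[[nm]][1]) / SEVERITY_SCALE[[nm]][2]
  S <- stats::rnorm(n, 0, config$noise_sd)
  for (nm in names(config$severity_loadings)) {
    S <- S + config$severity_loadings[[nm]] * z(get(nm), nm)
  }

  # recanalization only observable with an angiogram (EVT-treated);
  # success is less likely in severe strokes
  has_angio <- intervention %in% c("evt", "ivt_evt")
  recanalization <- rep(NA, n)
  recanalization[has_angio] <-
    stats::runif(sum(has_angio)) < stats::plogis(2.2 - 0.3 * S[has_angio])
  icu <- stats::runif(n) < stats::plogis(-2.6 + 0.9 * S)
  sich <- stats::runif(n) < stats::plogis(-3.8 + 0.6 * S)

  # 24-h NIHSS: proportional improvement, larger after recanalization,
  # smaller with residual severity
  impr_logit <- stats::rnorm(n, -0.7 + 0.6 * ifelse(is.na(recanalization),
                                                    0.5, recanalization)
                             - 0.4 * S, 1.1)
  nihss_24h <- pmin(42L, pmax(0L, as.integer(round(
    nihss * (1 - stats::plogis(impr_logit))))))

  p_death <- stats::plogis(config$death_logit_intercept +
                             config$death_logit_slope * S)
  died <- stats::runif(n) < p_death
  death_day <- rep(NA_integer_, n)
  death_day[died] <- index_day[died] +
    as.integer(floor(stats::runif(sum(died), 0, 90)))

  los <- pmax(1L, as.integer(round(stats::rlnorm(
    n, config$los_log_mean + config$los_severity_gain * S,
    config$los_log_sd))))

  mrs90 <- integer(n)
  latent <- S + stats::rlogis(n)
  cat_ol <- vapply(latent, function(l) sum(l > config$mrs_cutpoints),
                   numeric(1))
  mrs90 <- as.integer(pmin(cat_ol, 5L))   # survivors never score 6
  mrs90[died] <- 6L

  episodes <- .make_episodes(id, index_day, los, S, died, death_day, config)

  patients <- data.frame(
    patient_id = id, index_day = index_day, age = age, sex = sex,
    nihss = nihss, nihss_24h = nihss_24h, aspects = aspects,
    diabetes = diabetes, ihd = ihd, af = af, hypertension = hypertension,
    toast_category = toast_category, intervention = intervention,
    recanalization = recanalization, icu = icu, sich = sich,
    death_day = death_day, mrs90 = mrs90, true_severity = S,
    stringsAsFactors = FALSE)

  for (f in names(config$missingness_rates)) {
    if (!f %in% names(patients)) next
    hit <- stats::runif(n) < config$missingness_rates[[f]]
    patients[[f]][hit] <- NA
  }

  structure(list(patients = patients, episodes = episodes, config = config),
            class = "daoh_cohort")
}

# Length-of-stay parameters (log-day scale) for post-index stays by
# facility: brief acute readmissions, multi-week inpatient rehabilitation,
# longer residential-care spells.
READMIT_LOS <- list(acute = c(log(4), 0.6), rehab = c(log(25), 0.4),
                    residential = c(log(30), 0.4))

# Index episode plus disjoint readmissions within [index, index + 90).
# Readmission placement is best-effort rejection sampling: a draw that
# would overlap an existing stay is dropped. Abutting stays (same-day
# transfers, e.g. acute to rehab) are allowed; the engine merges them.
.make_episodes <- function(id, index_day, los, S, died, death_day, config) {
  n <- length(id)
  k <- stats::rpois(n, config$readmission_rate_base *
                      exp(config$readmission_severity_gain * S))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    starts <- index_day[i]; ends <- index_day[i] + los[i]; facs <- "acute"
    win_end <- index_day[i] + 90L
    lim <- if (died[i]) min(win_end, death_day[i] + 1L) else win_end
    if (k[i] > 0L && ends[1] < lim) {
      for (j in seq_len(k[i])) {
        ra <- ends[1] +
          as.integer(floor(stats::runif(1, 0, max(1, lim - ends[1]))))
        fac <- sample(FACILITY_TYPES, 1, prob = c(0.45, 0.45, 0.10))
        lp <- READMIT_LOS[[fac]]
        rlos <- pmax(1L, as.integer(round(stats::rlnorm(1, lp[1], lp[2]))))
        rd <- ra + rlos
        # half-open disjointness against already-placed stays
        if (ra < lim && all(rd <= starts | ra >= ends)) {
          starts <- c(starts, ra); ends <- c(ends, rd); facs <- c(facs, fac)
        }
      }
    }
    out[[i]] <- data.frame(patient_id = id[i], admit_day = starts,
                           discharge_day = ends, facility_type = facs,
                           stringsAsFactors = FALSE)
  }
  ep <- do.call(rbind, out)
  ep <- ep[order(ep$patient_id, ep$admit_day), ]
  rownames(ep) <- NULL
  ep
}

PATIENT_COLUMNS <- c("patient_id", "index_day", "age", "sex", "nihss",
                     "nihss_24h", "aspects", "diabetes", "ihd", "af",
                     "hypertension", "toast_category", "intervention",
                     "recanalization", "icu", "sich", "death_day", "mrs90",
                     "true_severity")
EPISODE_COLUMNS <- c("patient_id", "admit_day", "discharge_day",
                     "facility_type")

#' Write / read a cohort as delimited text tables
#'
#' `write_cohort()` writes `patients.csv` and `episodes.csv` into a
#' directory, missing values as empty fields. `read_cohort()` reads them
#' back, validating the schema (unknown or missing columns are an error),
#' referential integrity (every episode's patient must exist), and the
#' index-admission invariant (every patient has an episode starting on the
#' index day). The round trip is field-for-field exact.
#'
#' @param cohort a `daoh_cohort`.
#' @param path directory to write into (created if absent).
#' @return `write_cohort()` the path, invisibly; `read_cohort()` a
#'   `daoh_cohort` (with `config = NULL` unless a `config.yaml` is present).
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "daoh_cohort"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  patients <- cohort$patients
  if ("true_severity" %in% names(patients)) {
    # full double precision so the text round trip is bit-exact
    patients$true_severity <- sprintf("%.17g", patients$true_severity)
  }
  utils::write.csv(patients, file.path(path, "patients.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$episodes, file.path(path, "episodes.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(cohort$config)) {
    write_config(cohort$config, file.path(path, "config.yaml"))
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  pfile <- file.path(path, "patients.csv")
  efile <- file.path(path, "episodes.csv")
  for (f in c(pfile, efile)) {
    if (!file.exists(f)) stop("missing input file: ", f)
  }
  patients <- .read_table(pfile, PATIENT_COLUMNS)
  episodes <- .read_table(efile, EPISODE_COLUMNS)
  validate_cohort_tables(patients, episodes)
  cfile <- file.path(path, "config.yaml")
  config <- if (file.exists(cfile)) read_config(cfile) else NULL
  structure(list(patients = patients, episodes = episodes, config = config),
            class = "daoh_cohort")
}

.read_table <- function(file, expected) {
  nf <- utils::count.fields(file, sep = ",", quote = "\"")
  badln <- which(nf != nf[1])
  if (length(badln) > 0L) {
    stop("parse error in ", file, ": wrong field count at line ", badln[1])
  }
  tab <- tryCatch(
    utils::read.csv(file, stringsAsFactors = FALSE,
                    na.strings = "", colClasses = NA),
    error = function(e) stop("parse error in ", file, ": ",
                             conditionMessage(e)))
  unknown <- setdiff(names(tab), expected)
  if (length(unknown) > 0L) {
    stop("schema error in ", file, ": unknown column(s) ",
         paste(unknown, collapse = ", "))
  }
  miss <- setdiff(setdiff(expected, "true_severity"), names(tab))
  if (length(miss) > 0L) {
    stop("schema error in ", file, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  for (col in intersect(c("diabetes", "ihd", "af", "hypertension",
                          "recanalization", "icu", "sich"), names(tab))) {
    tab[[col]] <- as.logical(tab[[col]])
  }
  tab
}

#' Check cohort table invariants
#'
#' Referential integrity, uniqueness of patient ids, presence of an index
#' episode per patient, and the mRS-6/death consistency rule (mRS-90 is 6
#' if and only if the patient died within 90 days of the index day);
#' violations are reported as errors, never silently repaired.
#'
#' @param patients,episodes cohort tables.
#' @return `TRUE` invisibly.
#' @export
validate_cohort_tables <- function(patients, episodes) {
  if (anyDuplicated(patients$patient_id)) {
    stop("schema error: duplicated patient_id")
  }
  orphan <- setdiff(episodes$patient_id, patients$patient_id)
  if (length(orphan) > 0L) {
    stop("referential-integrity error: episodes for unknown patient id(s) ",
         paste(utils::head(orphan, 5), collapse = ", "))
  }
  has_index <- vapply(seq_len(nrow(patients)), function(i) {
    any(episodes$patient_id == patients$patient_id[i] &
          episodes$admit_day == patients$index_day[i])
  }, logical(1))
  if (!all(has_index)) {
    stop("schema error: no index episode (admission on index_day) for ",
         paste(utils::head(patients$patient_id[!has_index], 5),
               collapse = ", "))
  }
  if ("mrs90" %in% names(patients)) {
    dead90 <- !is.na(patients$death_day) &
      patients$death_day < patients$index_day + 90
    bad <- !is.na(patients$mrs90) & ((patients$mrs90 == 6) != dead90)
    if (any(bad)) {
      stop("consistency error: mRS-90 of 6 must coincide with death within ",
           "90 days (patients ",
           paste(utils::head(patients$patient_id[bad], 5), collapse = ", "),
           ")")
    }
  }
  invisible(TRUE)
}
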