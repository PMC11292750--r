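#' Merge hospital episodes into disjoint intervals
#'
#' Collapses a patient's admission intervals into a sorted, pairwise-disjoint
#' set under the half-open day convention `[admit_day, discharge_day)`.
#' Overlapping intervals are merged, and so are abutting ones (next admission
#' on the previous discharge day), since a same-day transfer -- e.g. acute
#' ward to rehabilitation -- is continuous institutional care. The total
#' number of covered days is preserved except where overlap is removed.
#'
#' @param episodes data frame with integer columns `admit_day` and
#'   `discharge_day` (and optionally `patient_id`, which must be constant).
#'   Zero-length episodes (`admit_day == discharge_day`) are permitted and
#'   cover no days.
#' @return data frame with columns `admit_day`, `discharge_day`, sorted by
#'   `admit_day`, pairwise disjoint and non-abutting. Idempotent and
#'   invariant to the input row order.
#' @examples
#' normalize_intervals(data.frame(admit_day = c(0, 3), discharge_day = c(5, 8)))
#' @export
normalize_intervals <- function(episodes) {
  stopifnot(is.data.frame(episodes))
  if (!all(c("admit_day", "discharge_day") %in% names(episodes))) {
    stop("episodes must have columns 'admit_day' and 'discharge_day'")
  }
  if ("patient_id" %in% names(episodes) &&
      length(unique(episodes$patient_id)) > 1L) {
    stop("normalize_intervals() operates on one patient at a time; got ",
         length(unique(episodes$patient_id)), " patient ids")
  }
  if (nrow(episodes) == 0L) {
    return(data.frame(admit_day = integer(0), discharge_day = integer(0)))
  }
  if (any(episodes$discharge_day < episodes$admit_day)) {
    stop("episode with discharge_day < admit_day")
  }
  a <- as.integer(episodes$admit_day)
  d <- as.integer(episodes$discharge_day)
  o <- order(a, d)
  a <- a[o]; d <- d[o]
  out_a <- a[1L]; out_d <- d[1L]
  if (length(a) > 1L) {
    for (i in 2L:length(a)) {
      k <- length(out_a)
      if (a[i] <= out_d[k]) {          # overlap or same-day transfer: merge
        out_d[k] <- max(out_d[k], d[i])
      } else {
        out_a <- c(out_a, a[i]); out_d <- c(out_d, d[i])
      }
    }
  }
  data.frame(admit_day = out_a, discharge_day = out_d)
}

#' Compute days alive and out of hospital for one patient
#'
#' Counts the status of every day in the half-open window
#' `[index_day, index_day + horizon)`. Each day has exactly one status with
#' priority dead > in-hospital > home: days on or after `death_day` are dead;
#' days covered by a merged episode interval (clipped to the window and
#' truncated at death) are in-hospital; the remainder are home days, i.e.
#' DAOH. The admission day counts as in-hospital and the discharge day as
#' out (half-open convention); the death day itself counts as dead.
#'
#' Episodes ending on or before the index day are pre-index history: they are
#' ignored with a warning. Episodes straddling the index day are clipped to
#' the window.
#'
#' @param patient one-row data frame (or list) with `patient_id`,
#'   `index_day`, and `death_day` (`NA` if the patient did not die).
#' @param episodes data frame of this patient's episodes (`admit_day`,
#'   `discharge_day`; a `patient_id` column, if present, is checked).
#' @param horizon follow-up window length in days, default 90.
#' @param variant `"standard"` counts home days; `"death_zero"` additionally
#'   recodes any patient who died before the end of the window to a score of
#'   0 (the post-hoc recoding used when death shortly after discharge should
#'   not accrue home days).
#' @return one-row data frame: `patient_id`, `horizon`, `days_in_hospital`,
#'   `days_dead`, `daoh`, `variant`. In the standard variant
#'   `daoh + days_in_hospital + days_dead == horizon` always holds.
#' @examples
#' p <- data.frame(patient_id = "p1", index_day = 0, death_day = NA)
#' e <- data.frame(admit_day = 0, discharge_day = 5)
#' compute_daoh(p, e)  # daoh = 85
#' @export
compute_daoh <- function(patient, episodes, horizon = 90L,
                         variant = c("standard", "death_zero")) {
  variant <- match.arg(variant)
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L) stop("horizon must be a positive integer")
  index_day <- as.integer(patient$index_day)
  death_day <- suppressWarnings(as.integer(patient$death_day))
  if (length(death_day) == 0L) death_day <- NA_integer_
  if (is.na(index_day)) stop("patient has no index_day")
  if (!is.na(death_day) && death_day < index_day) {
    stop("death_day precedes index_day for patient ", patient$patient_id)
  }
  if ("patient_id" %in% names(episodes) && nrow(episodes) > 0L &&
      !all(episodes$patient_id == patient$patient_id)) {
    stop("episodes do not all belong to patient ", patient$patient_id)
  }

  win_start <- index_day
  win_end <- index_day + horizon                      # exclusive
  alive_end <- if (is.na(death_day)) win_end else min(win_end, death_day)
  days_dead <- win_end - alive_end

  if (nrow(episodes) > 0L) {
    pre <- episodes$discharge_day <= index_day
    if (any(pre & episodes$admit_day < index_day)) {
      warning(sum(pre & episodes$admit_day < index_day),
              " pre-index episode(s) ignored for patient ",
              patient$patient_id)
    }
    episodes <- episodes[!pre | episodes$admit_day >= index_day, ,
                         drop = FALSE]
  }
  iv <- normalize_intervals(episodes[, c("admit_day", "discharge_day"),
                                     drop = FALSE])
  lo <- pmax(iv$admit_day, win_start)
  hi <- pmin(iv$discharge_day, alive_end)
  days_in_hospital <- sum(pmax(0L, hi - lo))

  daoh <- horizon - days_in_hospital - days_dead
  if (variant == "death_zero" && !is.na(death_day) && death_day < win_end) {
    daoh <- 0L
  }
  data.frame(patient_id = patient$patient_id, horizon = horizon,
             days_in_hospital = as.integer(days_in_hospital),
             days_dead = as.integer(days_dead), daoh = as.integer(daoh),
             variant = variant, stringsAsFactors = FALSE)
}

#' Brute-force day-by-day DAOH verifier
#'
#' Walks every day of the follow-up window and classifies it literally
#' (dead if on/after the death day; in hospital if inside any raw episode
#' interval under the half-open convention; home otherwise), then counts.
#' Intended as an independent check on [compute_daoh()]: it shares only the
#' day-status definition, not the interval arithmetic.
#'
#' @inheritParams compute_daoh
#' @return one-row data frame with the same columns as [compute_daoh()].
#' @export
daoh_oracle <- function(patient, episodes, horizon = 90L,
                        variant = c("standard", "death_zero")) {
  variant <- match.arg(variant)
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L) stop("horizon must be a positive integer")
  index_day <- as.integer(patient$index_day)
  death_day <- suppressWarnings(as.integer(patient$death_day))
  if (length(death_day) == 0L) death_day <- NA_integer_
  if (!is.na(death_day) && death_day < index_day) {
    stop("death_day precedes index_day for patient ", patient$patient_id)
  }
  days <- seq.int(index_day, index_day + horizon - 1L)
  status <- rep("home", horizon)
  for (i in seq_len(nrow(episodes))) {
    inside <- days >= episodes$admit_day[i] & days < episodes$discharge_day[i]
    status[inside] <- "hospital"
  }
  if (!is.na(death_day)) status[days >= death_day] <- "dead"
  daoh <- sum(status == "home")
  if (variant == "death_zero" && !is.na(death_day) &&
      death_day < index_day + horizon) {
    daoh <- 0L
  }
  data.frame(patient_id = patient$patient_id, horizon = horizon,
             days_in_hospital = sum(status == "hospital"),
             days_dead = sum(status == "dead"), daoh = as.integer(daoh),
             variant = variant, stringsAsFactors = FALSE)
}

#' Compute DAOH for a whole cohort
#'
#' Applies [compute_daoh()] to every patient in a patients/episodes table
#' pair, after checking referential integrity: no duplicated patient ids, no
#' episodes referencing unknown patients, and at least one episode per
#' patient (every cohort member has an index admission by definition).
#'
#' @param patients data frame with one row per patient (`patient_id`,
#'   `index_day`, `death_day`).
#' @param episodes data frame of all episodes (`patient_id`, `admit_day`,
#'   `discharge_day`).
#' @inheritParams compute_daoh
#' @return data frame with one [compute_daoh()] row per patient, in the
#'   order of `patients`.
#' @export
compute_daoh_cohort <- function(patients, episodes, horizon = 90L,
                                variant = c("standard", "death_zero")) {
  variant <- match.arg(variant)
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicated patient_id in patients table: ",
         paste(unique(patients$patient_id[duplicated(patients$patient_id)]),
               collapse = ", "))
  }
  orphan <- setdiff(episodes$patient_id, patients$patient_id)
  if (length(orphan) > 0L) {
    stop("episodes reference unknown patient ids: ",
         paste(orphan, collapse = ", "))
  }
  missing_ep <- setdiff(patients$patient_id, episodes$patient_id)
  if (length(missing_ep) > 0L) {
    stop("patients without any episode (index admission mandatory): ",
         paste(missing_ep, collapse = ", "))
  }
  ep_split <- split(episodes, episodes$patient_id)
  out <- lapply(seq_len(nrow(patients)), function(i) {
    p <- patients[i, , drop = FALSE]
    compute_daoh(p, ep_split[[as.character(p$patient_id)]],
                 horizon = horizon, variant = variant)
  })
  do.call(rbind, out)
}

#' Early neurological improvement from NIHSS scores
#'
#' ENI is a drop of at least 8 NIHSS points between hospital admission and
#' 24 hours, or a 24-hour score of 0 or 1. Vectorised; returns `NA` where
#' either score is missing.
#'
#' @param nihss_admission,nihss_24h integer NIHSS scores in 0--42 (or `NA`).
#' @return logical vector.
#' @examples
#' derive_eni(14, 6)   # TRUE (drop of 8)
#' derive_eni(14, 8)   # FALSE
#' @export
derive_eni <- function(nihss_admission, nihss_24h) {
  chk <- function(x, nm) {
    if (any(!is.na(x) & (x < 0 | x > 42))) {
      stop(nm, " outside 0-42")
    }
  }
  chk(nihss_admission, "nihss_admission"); chk(nihss_24h, "nihss_24h")
  ifelse(is.na(nihss_admission) | is.na(nihss_24h), NA,
         (nihss_admission - nihss_24h >= 8) | (nihss_24h <= 1))
}
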