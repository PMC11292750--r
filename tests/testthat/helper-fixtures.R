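# Shared fixtures: random single-patient records with messy episode sets
# (overlaps, abutments, pre-index history, in/out-of-hospital deaths) for
# exercising the interval engine against the day-by-day oracle.

random_patient_case <- function() {
  index_day <- sample(0:300, 1)
  n_ep <- sample(0:5, 1)
  episodes <- if (n_ep == 0) {
    data.frame(admit_day = integer(0), discharge_day = integer(0))
  } else {
    a <- index_day + sample(-20:80, n_ep, replace = TRUE)
    len <- sample(0:30, n_ep, replace = TRUE)
    data.frame(admit_day = a, discharge_day = a + len)
  }
  death_day <- if (runif(1) < 0.3) index_day + sample(0:120, 1) else NA
  horizon <- sample(1:90, 1)
  list(patient = data.frame(patient_id = "px", index_day = index_day,
                            death_day = death_day),
       episodes = episodes, horizon = horizon)
}

toy_patient <- function(id = "p1", index_day = 0, death_day = NA) {
  data.frame(patient_id = id, index_day = index_day, death_day = death_day,
             stringsAsFactors = FALSE)
}

toy_episodes <- function(id, admit, discharge) {
  data.frame(patient_id = id, admit_day = admit, discharge_day = discharge,
             stringsAsFactors = FALSE)
}

# Table-1-style mRS category counts expanded to a score vector
mrs_from_counts <- function(counts) {
  rep(0:6, times = counts)
}
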