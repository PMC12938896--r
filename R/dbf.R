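# Distant brain failure (DBF): detection of new-lesion events and their
# extent (count, volume), latency, and velocity (BMV / vBMV).

#' Confirm new lesions on repeat imaging
#'
#' A lesion first appearing after baseline is confirmed when it is still
#' present on the next assessment; a lesion appearing only at the terminal
#' assessment stays pending. With
#' `cfg$require_new_lesion_confirmation = FALSE` appearance alone confirms.
#' Once confirmed, the progression/DBF event is dated at first appearance.
#'
#' @param course a `patient_course`
#' @param cfg an [assessment_config()]
#' @return data.frame with columns `lesion_id`, `first_seen_index`,
#'   `first_seen_day`, `confirmed`, `pending` (one row per new-on-study
#'   lesion)
#' @export
confirm_new_lesions <- function(course, cfg = assessment_config()) {
  les <- course$lesions[course$lesions$is_new_on_study, , drop = FALSE]
  nt <- n_assessments(course)
  if (nrow(les) == 0L)
    return(data.frame(lesion_id = character(), first_seen_index = integer(),
                      first_seen_day = integer(), confirmed = logical(),
                      pending = logical(), stringsAsFactors = FALSE))
  first_idx <- lesion_first_index(course, les$lesion_id)
  meas <- course$measurements
  present_at <- function(id, t) {
    r <- meas[meas$lesion_id == id & meas$assessment_index == t, ]
    nrow(r) > 0L && isTRUE(r$present[1L])
  }
  confirmed <- pending <- logical(nrow(les))
  for (i in seq_len(nrow(les))) {
    t0 <- first_idx[i]
    if (!cfg$require_new_lesion_confirmation) {
      confirmed[i] <- TRUE
    } else if (t0 >= nt - 1L) {
      pending[i] <- TRUE # terminal appearance: no repeat scan yet
    } else {
      confirmed[i] <- present_at(les$lesion_id[i], t0 + 1L)
    }
  }
  data.frame(lesion_id = les$lesion_id, first_seen_index = first_idx,
             first_seen_day = course$assessment_days[first_idx + 1L],
             confirmed = confirmed, pending = pending,
             stringsAsFactors = FALSE)
}

#' Detect distant-brain-failure events
#'
#' A DBF event is the (confirmed) appearance of one or more new lesions at
#' an assessment after `reference_day`; lesions appearing simultaneously
#' merge into one event. Event volume sums each lesion's volume at first
#' appearance, using the recorded volume when supplied and the sphere proxy
#' \eqn{\pi/6\,d^3} otherwise.
#'
#' @param course a `patient_course`
#' @param cfg an [assessment_config()]
#' @param reference_day day offset anchoring the analysis (course baseline
#'   or a treatment start); only lesions first seen after it count
#' @param include_pending also count unconfirmed terminal-assessment
#'   appearances (default FALSE)
#' @return data.frame of events ordered by day: `event_day`, `count`,
#'   `volume_mm3`, `confirmed`, and a `lesion_ids` list column
#' @export
detect_dbf_events <- function(course, cfg = assessment_config(),
                              reference_day = course$assessment_days[1L],
                              include_pending = FALSE) {
  conf <- confirm_new_lesions(course, cfg)
  conf <- conf[conf$first_seen_day > reference_day, , drop = FALSE]
  keep <- conf$confirmed | (include_pending & conf$pending)
  conf <- conf[keep, , drop = FALSE]
  if (nrow(conf) == 0L)
    return(data.frame(event_day = integer(), count = integer(),
                      volume_mm3 = numeric(), confirmed = logical(),
                      lesion_ids = I(list()), stringsAsFactors = FALSE))
  out <- lapply(sort(unique(conf$first_seen_day)), function(day) {
    rows <- conf[conf$first_seen_day == day, ]
    vols <- vapply(seq_len(nrow(rows)), function(i)
      volume_at(course, rows$lesion_id[i], rows$first_seen_index[i]),
      numeric(1))
    data.frame(event_day = day, count = nrow(rows), volume_mm3 = sum(vols),
               confirmed = all(rows$confirmed),
               lesion_ids = I(list(rows$lesion_id)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Extent of distant brain failure
#'
#' @param events event data.frame from [detect_dbf_events()]
#' @return list with `total_new_lesions` and `total_volume_mm3`
#' @export
dbf_extent <- function(events) {
  list(total_new_lesions = sum(events$count),
       total_volume_mm3 = sum(events$volume_mm3))
}

#' Distant-brain-failure latency
#'
#' Mean interval between consecutive DBF events anchored at the reference
#' day, i.e. (last event day - reference day) / number of events. A patient
#' with a new lesion every 4 months over 12 months has a latency of 4
#' months; a patient with a single event at 12 months, 12 months.
#'
#' @param events event data.frame from [detect_dbf_events()]
#' @param reference_day anchoring day offset
#' @return latency in days, or `NA_real_` when there are no events
#' @export
dbf_latency <- function(events, reference_day) {
  k <- nrow(events)
  if (k == 0L) return(NA_real_)
  (max(events$event_day) - reference_day) / k
}

#' Brain metastasis velocity (BMV)
#'
#' Cumulative number of new brain metastases per year of follow-up from the
#' reference day.
#'
#' @param summary a `dbf_summary` (or any list with `total_new_lesions`)
#' @param reference_day anchoring day offset
#' @param last_followup_day last follow-up day (> reference_day)
#' @return lesions per year
#' @export
bmv <- function(summary, reference_day, last_followup_day) {
  years <- .followup_years(reference_day, last_followup_day)
  summary$total_new_lesions / years
}

#' Volumetric brain metastasis velocity (vBMV)
#'
#' Cumulative new-lesion volume (at first appearance) per year of follow-up.
#'
#' @inheritParams bmv
#' @return mm^3 per year
#' @export
vbmv <- function(summary, reference_day, last_followup_day) {
  years <- .followup_years(reference_day, last_followup_day)
  summary$total_volume_mm3 / years
}

.followup_years <- function(reference_day, last_followup_day) {
  if (last_followup_day <= reference_day)
    stop("follow-up interval must be positive", call. = FALSE)
  (last_followup_day - reference_day) / DAYS_PER_YEAR
}

#' Summarise distant brain failure for a course
#'
#' Detects events and computes extent, latency, and velocities in one pass.
#'
#' @inheritParams detect_dbf_events
#' @param last_followup_day last follow-up day (defaults to the final
#'   assessment)
#' @return a `dbf_summary` list: `events`, `total_new_lesions`,
#'   `total_volume_mm3`, `latency_days`, `latency_months`, `bmv_per_year`,
#'   `vbmv_mm3_per_year`, `reference_day`, `last_followup_day`
#' @export
dbf_summary <- function(course, cfg = assessment_config(),
                        reference_day = course$assessment_days[1L],
                        last_followup_day = max(course$assessment_days),
                        include_pending = FALSE) {
  events <- detect_dbf_events(course, cfg, reference_day, include_pending)
  ext <- dbf_extent(events)
  lat <- dbf_latency(events, reference_day)
  s <- list(events = events,
            total_new_lesions = ext$total_new_lesions,
            total_volume_mm3 = ext$total_volume_mm3,
            latency_days = lat,
            latency_months = days_to_months(lat),
            reference_day = reference_day,
            last_followup_day = last_followup_day)
  if (last_followup_day > reference_day) {
    s$bmv_per_year <- bmv(s, reference_day, last_followup_day)
    s$vbmv_mm3_per_year <- vbmv(s, reference_day, last_followup_day)
  } else {
    s$bmv_per_year <- NA_real_
    s$vbmv_mm3_per_year <- NA_real_
  }
  structure(s, class = "dbf_summary")
}

#' @export
print.dbf_summary <- function(x, ...) {
  cat(sprintf(
    "<dbf_summary> %d event(s), %d new lesion(s), %.1f mm^3; latency %s months; BMV %.2f /yr; vBMV %.1f mm^3/yr\n",
    nrow(x$events), x$total_new_lesions, x$total_volume_mm3,
    if (is.na(x$latency_months)) "NA" else sprintf("%.2f", x$latency_months),
    x$bmv_per_year, x$vbmv_mm3_per_year))
  invisible(x)
}
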