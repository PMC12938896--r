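# Patient clinical status: Karnofsky performance score (KPS) deterioration
# rules and the brain-specific-symptoms (BSS) 0..5 ordinal scale.
#
# BSS grades neurologic symptom severity: 0 none; 1 mild, no intervention;
# 2 moderate, non-invasive intervention; 3 severe, limiting self care;
# 4 life-threatening; 5 death from neurologic decline.

.check_kps <- function(x, what) {
  if (any(is.na(x)) || !all(x %in% seq(0L, 100L, 10L)))
    stop(what, " must be a KPS score in {0,10,...,100}", call. = FALSE)
}

.check_bss <- function(x, what) {
  if (any(is.na(x)) || !all(x %in% 0:5))
    stop(what, " must be a BSS score in 0..5", call. = FALSE)
}

#' KPS deterioration rule
#'
#' A current score marks deterioration relative to the starting score when
#' any of the three clauses fires: a drop from 90-100 to 70 or below; a drop
#' of at least 20 points from a starting score of 80 or below; or any drop
#' to 50 or below.
#'
#' @param baseline_kps starting KPS score (reference)
#' @param current_kps current KPS score
#' @return logical
#' @export
#' @examples
#' kps_deteriorated(90, 70) # TRUE
#' kps_deteriorated(90, 80) # FALSE
kps_deteriorated <- function(baseline_kps, current_kps) {
  .check_kps(baseline_kps, "baseline_kps")
  .check_kps(current_kps, "current_kps")
  (baseline_kps >= 90L & current_kps <= 70L) |
    (baseline_kps <= 80L & baseline_kps - current_kps >= 20L) |
    (current_kps <= 50L)
}

#' BSS worsening rule
#'
#' Worsening is a rise of at least `cfg$bss_worsen_delta` points over the
#' reference score (default 1, the minimal detectable change on the scale).
#'
#' @param reference_bss reference BSS score (0..5)
#' @param current_bss current BSS score (0..5)
#' @param cfg an [assessment_config()]
#' @return logical
#' @export
bss_worsened <- function(reference_bss, current_bss, cfg = assessment_config()) {
  .check_bss(reference_bss, "reference_bss")
  .check_bss(current_bss, "current_bss")
  (current_bss - reference_bss) >= cfg$bss_worsen_delta
}

# clinical observation row at 0-based assessment t, or NULL
.clinical_at <- function(course, t) {
  cl <- course$clinical
  row <- cl[cl$assessment_index == t, , drop = FALSE]
  if (nrow(row) == 0L) NULL else row[1L, ]
}

#' Clinical state at one assessment
#'
#' Compares the observation at assessment `t` against the course (or window)
#' baseline observation. The state is `"worse"` iff the KPS deterioration
#' rule or the BSS worsening rule fires for a metric selected by
#' `cfg$status_metric` and the decline is not attributed to a non-CNS cause
#' (comorbidity, toxicity, steroid change); otherwise
#' `"stable_or_improved"`. Assessments without an observation are treated as
#' stable.
#'
#' @param course a `patient_course`
#' @param t 0-based assessment index
#' @param cfg an [assessment_config()]
#' @return `"stable_or_improved"` or `"worse"`
#' @export
clinical_state <- function(course, t, cfg = assessment_config()) {
  ev <- .status_eval_one(course, t, cfg)
  if (ev$combined_worse) "worse" else "stable_or_improved"
}

.status_eval_one <- function(course, t, cfg) {
  ref <- if (nrow(course$clinical)) course$clinical[1L, ] else NULL
  cur <- .clinical_at(course, t)
  kps_worse <- bss_worse <- NA
  attributed <- FALSE
  if (!is.null(cur) && !is.null(ref)) {
    attributed <- isTRUE(cur$decline_attributed_to_non_cns)
    if (cfg$status_metric %in% c("kps", "both") &&
        !is.na(ref$kps) && !is.na(cur$kps))
      kps_worse <- kps_deteriorated(ref$kps, cur$kps)
    if (cfg$status_metric %in% c("bss", "both") &&
        !is.na(ref$bss) && !is.na(cur$bss))
      bss_worse <- bss_worsened(ref$bss, cur$bss, cfg)
  }
  combined <- (isTRUE(kps_worse) || isTRUE(bss_worse)) && !attributed
  list(assessment_index = t, kps_worse = kps_worse, bss_worse = bss_worse,
       combined_worse = combined, attribution_excluded = attributed)
}

#' Per-assessment clinical status evaluation
#'
#' Applies [clinical_state()] at every assessment and returns the component
#' verdicts: whether KPS deteriorated, whether BSS worsened, the combined
#' verdict, and whether a decline was discounted as non-CNS.
#'
#' @inheritParams clinical_state
#' @return data.frame with one row per assessment
#' @export
status_evaluation <- function(course, cfg = assessment_config()) {
  rows <- lapply(seq_len(n_assessments(course)) - 1L, function(t) {
    ev <- .status_eval_one(course, t, cfg)
    data.frame(assessment_index = t,
               kps_worse = if (is.na(ev$kps_worse)) NA else ev$kps_worse,
               bss_worse = if (is.na(ev$bss_worse)) NA else ev$bss_worse,
               combined_worse = ev$combined_worse,
               attribution_excluded = ev$attribution_excluded)
  })
  do.call(rbind, rows)
}
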