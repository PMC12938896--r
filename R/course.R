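# Domain model for longitudinal brain-metastases patient courses.
#
# A course is a plain list of data.frames (lesions, treatments, measurements,
# clinical) keyed by 0-based assessment indices, with assessment days given as
# integer offsets from the baseline scan (index 0).

#' @name ranobm-constants
#' @title Time and category constants
#' @description Fixed conversions and enumerations used throughout the package.
#'   One month is 30.44 days and one year 365.25 days, so latencies and
#'   velocities derived from day offsets are reproducible.
#' @keywords internal
NULL

DAYS_PER_MONTH <- 30.44
DAYS_PER_YEAR <- 365.25

QUALITATIVE_STATES <- c("stable", "improved", "unequivocal_progression",
                        "absent", "not_assessed")
MODALITIES <- c("SRS", "FSRT", "WBRT", "surgery", "systemic")
FOCAL_MODALITIES <- c("SRS", "FSRT", "surgery")
STEROID_STATES <- c("none", "stable", "decreased", "increased")
RESPONSE_CATEGORIES <- c("CR", "PR", "SD", "PD", "NE")
POLICIES <- c("A1", "A2", "ARx")

# small tolerance for threshold comparisons on measured millimetres
.EPS <- 1e-9

#' Convert months to integer study days
#'
#' Uses the fixed conversion 1 month = 30.44 days, rounded to whole days.
#'
#' @param m months (numeric vector)
#' @return integer day offsets
#' @export
#' @examples
#' months_to_days(c(3, 12))
months_to_days <- function(m) as.integer(round(m * DAYS_PER_MONTH))

#' Convert study days to months
#'
#' @param d days (numeric vector)
#' @return months as `d / 30.44`
#' @export
days_to_months <- function(d) d / DAYS_PER_MONTH

#' Volume of a sphere with a given diameter
#'
#' Volume proxy used when a lesion carries only its longest diameter:
#' \eqn{v = \pi/6 \, d^3}.
#'
#' @param d diameter in mm (non-negative numeric vector)
#' @return volume in mm^3
#' @export
#' @examples
#' sphere_volume_from_diameter(10) # ~523.6 mm^3
sphere_volume_from_diameter <- function(d) {
  if (!is.numeric(d) || any(is.na(d)) || any(d < 0))
    stop("diameter must be non-negative", call. = FALSE)
  pi / 6 * d^3
}

#' Assemble a patient course
#'
#' Builds the container holding everything known about one patient:
#' the assessment-day grid, the lesion registry, treatment events,
#' per-assessment lesion measurements, and clinical observations.
#' The constructor normalises column types and derives the lesion registry
#' from the measurements when one is not supplied; it does not validate
#' invariants (see [validate_course()]).
#'
#' @param patient_id identifier string
#' @param assessment_days strictly increasing integer day offsets; index 0 is
#'   the baseline scan
#' @param measurements data.frame with columns `lesion_id`,
#'   `assessment_index` (0-based), `longest_diameter_mm`,
#'   `perpendicular_diameter_mm` (optional, NA allowed), `volume_mm3`
#'   (optional), `present` (logical), `qualitative_state`
#' @param lesions optional data.frame with `lesion_id`, `first_seen_day`,
#'   `is_new_on_study`; derived from measurements when NULL
#' @param treatments optional data.frame with `treatment_id`, `modality`,
#'   `start_day`, `targeted_lesion_ids` (list column of character vectors;
#'   empty vector = non-focal treatment acting on all lesions)
#' @param clinical optional data.frame with `assessment_index`, `kps`, `bss`,
#'   `steroid_state`, `decline_attributed_to_non_cns`
#' @return an object of class `patient_course`
#' @export
patient_course <- function(patient_id, assessment_days, measurements,
                           lesions = NULL, treatments = NULL, clinical = NULL) {
  assessment_days <- as.integer(assessment_days)
  measurements <- .normalize_measurements(measurements)
  if (is.null(lesions))
    lesions <- .derive_lesions(measurements, assessment_days)
  lesions$lesion_id <- as.character(lesions$lesion_id)
  lesions$first_seen_day <- as.integer(lesions$first_seen_day)
  if (is.null(lesions$is_new_on_study))
    lesions$is_new_on_study <- lesions$first_seen_day > assessment_days[1L]
  treatments <- .normalize_treatments(treatments)
  clinical <- .normalize_clinical(clinical)
  structure(list(
    patient_id = as.character(patient_id),
    assessment_days = assessment_days,
    lesions = lesions,
    treatments = treatments,
    measurements = measurements,
    clinical = clinical
  ), class = "patient_course")
}

.normalize_measurements <- function(m) {
  m <- as.data.frame(m, stringsAsFactors = FALSE)
  m$lesion_id <- as.character(m$lesion_id)
  m$assessment_index <- as.integer(m$assessment_index)
  m$longest_diameter_mm <- as.numeric(m$longest_diameter_mm)
  if (is.null(m$perpendicular_diameter_mm)) m$perpendicular_diameter_mm <- NA_real_
  m$perpendicular_diameter_mm <- as.numeric(m$perpendicular_diameter_mm)
  if (is.null(m$volume_mm3)) m$volume_mm3 <- NA_real_
  m$volume_mm3 <- as.numeric(m$volume_mm3)
  if (is.null(m$present)) m$present <- m$longest_diameter_mm > 0
  m$present <- as.logical(m$present)
  if (is.null(m$qualitative_state))
    m$qualitative_state <- ifelse(m$present, "stable", "absent")
  m$qualitative_state <- as.character(m$qualitative_state)
  m[order(m$assessment_index, m$lesion_id),
    c("lesion_id", "assessment_index", "longest_diameter_mm",
      "perpendicular_diameter_mm", "volume_mm3", "present",
      "qualitative_state"),
    drop = FALSE]
}

.derive_lesions <- function(measurements, assessment_days) {
  ids <- unique(measurements$lesion_id)
  first_idx <- vapply(ids, function(id)
    min(measurements$assessment_index[measurements$lesion_id == id]), integer(1))
  data.frame(
    lesion_id = ids,
    first_seen_day = assessment_days[first_idx + 1L],
    is_new_on_study = first_idx > 0L,
    stringsAsFactors = FALSE
  )
}

.normalize_treatments <- function(tr) {
  if (is.null(tr) || NROW(tr) == 0L)
    return(data.frame(treatment_id = character(), modality = character(),
                      start_day = integer(),
                      targeted_lesion_ids = I(list()),
                      stringsAsFactors = FALSE))
  tr <- as.data.frame(tr, stringsAsFactors = FALSE)
  tr$treatment_id <- as.character(tr$treatment_id)
  tr$modality <- as.character(tr$modality)
  tr$start_day <- as.integer(tr$start_day)
  if (is.null(tr$targeted_lesion_ids))
    tr$targeted_lesion_ids <- I(rep(list(character()), nrow(tr)))
  tr$targeted_lesion_ids <- I(lapply(tr$targeted_lesion_ids, as.character))
  tr[order(tr$start_day, tr$treatment_id), , drop = FALSE]
}

.normalize_clinical <- function(cl) {
  if (is.null(cl) || NROW(cl) == 0L)
    return(data.frame(assessment_index = integer(), kps = integer(),
                      bss = integer(), steroid_state = character(),
                      decline_attributed_to_non_cns = logical(),
                      stringsAsFactors = FALSE))
  cl <- as.data.frame(cl, stringsAsFactors = FALSE)
  cl$assessment_index <- as.integer(cl$assessment_index)
  if (is.null(cl$kps)) cl$kps <- NA_integer_
  cl$kps <- as.integer(cl$kps)
  if (is.null(cl$bss)) cl$bss <- NA_integer_
  cl$bss <- as.integer(cl$bss)
  if (is.null(cl$steroid_state)) cl$steroid_state <- "none"
  cl$steroid_state <- as.character(cl$steroid_state)
  if (is.null(cl$decline_attributed_to_non_cns))
    cl$decline_attributed_to_non_cns <- FALSE
  cl$decline_attributed_to_non_cns <- as.logical(cl$decline_attributed_to_non_cns)
  cl[order(cl$assessment_index), , drop = FALSE]
}

#' @export
print.patient_course <- function(x, ...) {
  cat(sprintf("<patient_course> %s: %d assessments (day %d..%d), %d lesions, %d treatments\n",
              x$patient_id, length(x$assessment_days),
              min(x$assessment_days), max(x$assessment_days),
              nrow(x$lesions), nrow(x$treatments)))
  invisible(x)
}

#' Number of assessments in a course
#' @param course a `patient_course`
#' @return integer count
#' @export
n_assessments <- function(course) length(course$assessment_days)

# 0-based index of the assessment at which a lesion is first seen.
lesion_first_index <- function(course, lesion_id) {
  fsd <- course$lesions$first_seen_day[match(lesion_id, course$lesions$lesion_id)]
  # first assessment day >= first_seen_day (normally an exact match)
  vapply(fsd, function(d) {
    idx <- which(course$assessment_days >= d)
    if (length(idx) == 0L) length(course$assessment_days) else idx[1L] - 1L
  }, integer(1))
}

# Longest-diameter matrix: lesions x assessments (0-based columns t = j - 1).
# NA before a lesion's first appearance; 0 for an absent lesion or a missing
# record after first appearance.
ld_matrix <- function(course) {
  ids <- course$lesions$lesion_id
  nt <- n_assessments(course)
  m <- matrix(NA_real_, nrow = length(ids), ncol = nt,
              dimnames = list(ids, NULL))
  first <- lesion_first_index(course, ids)
  for (i in seq_along(ids))
    if (first[i] < nt) m[i, (first[i] + 1L):nt] <- 0
  meas <- course$measurements
  if (nrow(meas))
    m[cbind(match(meas$lesion_id, ids), meas$assessment_index + 1L)] <-
      ifelse(meas$present, meas$longest_diameter_mm, 0)
  m
}

# Longest diameters for given lesions at 0-based assessment t (0 if absent,
# missing, or not yet seen).
ld_at <- function(course, lesion_ids, t, ldm = NULL) {
  if (is.null(ldm)) ldm <- ld_matrix(course)
  if (length(lesion_ids) == 0L) return(numeric(0))
  v <- ldm[match(lesion_ids, rownames(ldm)), t + 1L]
  v[is.na(v)] <- 0
  unname(v)
}

# Lesion volume at 0-based assessment t: recorded volume when supplied,
# otherwise the sphere proxy from the longest diameter.
volume_at <- function(course, lesion_id, t) {
  meas <- course$measurements
  row <- meas[meas$lesion_id == lesion_id & meas$assessment_index == t, ]
  if (nrow(row) == 0L || !row$present[1L]) return(0)
  if (!is.na(row$volume_mm3[1L])) return(row$volume_mm3[1L])
  sphere_volume_from_diameter(row$longest_diameter_mm[1L])
}

# ids of lesions already seen at 0-based assessment t
lesions_seen_by <- function(course, t) {
  course$lesions$lesion_id[lesion_first_index(course, course$lesions$lesion_id) <= t]
}

#' Validate a patient course
#'
#' Checks every structural invariant of the course model and returns a
#' character vector of human-readable violations (empty when the course is
#' well formed). Validation never throws; callers that require a valid
#' course (e.g. [assess_course()]) raise the aggregated report themselves.
#'
#' Checked invariants include: strictly increasing assessment days;
#' measurement indices within range; non-negative diameters with
#' perpendicular <= longest; absent lesions measured as 0 mm; at most one
#' measurement per lesion per assessment and none before the lesion's
#' first-seen day; unique lesion ids with `is_new_on_study` consistent with
#' `first_seen_day`; treatment modalities known, targeted ids known, and
#' focal treatments (SRS/FSRT/surgery) carrying a non-empty target set;
#' clinical scores on their scales (KPS in 0,10,...,100; BSS in 0..5 with 5
#' terminal) with at least one score per observation.
#'
#' @param course a `patient_course`
#' @return character vector of violation descriptions; `character(0)` if valid
#' @export
validate_course <- function(course) {
  v <- character()
  say <- function(...) v <<- c(v, sprintf(...))
  days <- course$assessment_days
  nt <- length(days)
  if (nt < 1L) say("course has no assessments")
  if (nt > 1L && any(diff(days) <= 0))
    say("assessment_days not strictly increasing at position(s) %s",
        paste(which(diff(days) <= 0) + 1L, collapse = ","))

  les <- course$lesions
  if (anyDuplicated(les$lesion_id))
    say("duplicate lesion_id: %s",
        paste(unique(les$lesion_id[duplicated(les$lesion_id)]), collapse = ","))
  bad_new <- les$is_new_on_study != (les$first_seen_day > days[1L])
  if (any(bad_new))
    say("lesion %s: is_new_on_study inconsistent with first_seen_day",
        paste(les$lesion_id[bad_new], collapse = ","))

  meas <- course$measurements
  for (i in seq_len(nrow(meas))) {
    r <- meas[i, ]
    who <- sprintf("measurement (lesion %s, assessment %d)", r$lesion_id,
                   r$assessment_index)
    if (r$assessment_index < 0L || r$assessment_index >= nt)
      say("%s: assessment_index out of range (course has %d assessments)", who, nt)
    if (is.na(r$longest_diameter_mm) || r$longest_diameter_mm < 0)
      say("%s: longest_diameter_mm missing or negative", who)
    if (!is.na(r$perpendicular_diameter_mm)) {
      if (r$perpendicular_diameter_mm < 0)
        say("%s: perpendicular_diameter_mm negative", who)
      else if (!is.na(r$longest_diameter_mm) &&
               r$perpendicular_diameter_mm > r$longest_diameter_mm + .EPS)
        say("%s: perpendicular exceeds longest diameter", who)
    }
    if (!is.na(r$volume_mm3) && r$volume_mm3 < 0)
      say("%s: volume_mm3 negative", who)
    if (identical(r$present, FALSE) && !is.na(r$longest_diameter_mm) &&
        r$longest_diameter_mm != 0)
      say("%s: present=FALSE requires longest_diameter_mm = 0", who)
    if (!r$qualitative_state %in% QUALITATIVE_STATES)
      say("%s: unknown qualitative_state '%s'", who, r$qualitative_state)
    if (!r$lesion_id %in% les$lesion_id)
      say("%s: lesion_id not in lesion registry", who)
  }
  dup <- duplicated(meas[c("lesion_id", "assessment_index")])
  if (any(dup))
    say("more than one measurement for lesion %s at assessment %s",
        paste(meas$lesion_id[dup], collapse = ","),
        paste(meas$assessment_index[dup], collapse = ","))
  ok_idx <- meas$assessment_index >= 0L & meas$assessment_index < nt &
    meas$lesion_id %in% les$lesion_id
  if (any(ok_idx)) {
    m2 <- meas[ok_idx, ]
    fsd <- les$first_seen_day[match(m2$lesion_id, les$lesion_id)]
    early <- days[m2$assessment_index + 1L] < fsd
    if (any(early))
      say("lesion %s measured at assessment %s before its first_seen_day",
          paste(m2$lesion_id[early], collapse = ","),
          paste(m2$assessment_index[early], collapse = ","))
  }

  tr <- course$treatments
  for (i in seq_len(nrow(tr))) {
    r <- tr[i, ]
    who <- sprintf("treatment %s", r$treatment_id)
    if (!r$modality %in% MODALITIES)
      say("%s: unknown modality '%s'", who, r$modality)
    tgt <- r$targeted_lesion_ids[[1L]]
    unknown <- setdiff(tgt, les$lesion_id)
    if (length(unknown))
      say("%s: targeted lesion(s) %s not in registry", who,
          paste(unknown, collapse = ","))
    if (r$modality %in% FOCAL_MODALITIES && length(tgt) == 0L)
      say("%s: focal modality %s requires a non-empty targeted set", who, r$modality)
  }

  cl <- course$clinical
  for (i in seq_len(nrow(cl))) {
    r <- cl[i, ]
    who <- sprintf("clinical observation at assessment %d", r$assessment_index)
    if (r$assessment_index < 0L || r$assessment_index >= nt)
      say("%s: assessment_index out of range", who)
    if (is.na(r$kps) && is.na(r$bss))
      say("%s: at least one of kps, bss must be present", who)
    if (!is.na(r$kps) && !(r$kps %in% seq(0L, 100L, 10L)))
      say("%s: kps %d not in {0,10,...,100}", who, r$kps)
    if (!is.na(r$bss) && (r$bss < 0L || r$bss > 5L))
      say("%s: bss %d not in 0..5", who, r$bss)
    if (!r$steroid_state %in% STEROID_STATES)
      say("%s: unknown steroid_state '%s'", who, r$steroid_state)
  }
  if (nrow(cl)) {
    term <- cl[!is.na(cl$bss) & cl$bss == 5L, ]
    if (nrow(term) && any(term$assessment_index < max(cl$assessment_index)))
      say("bss=5 (death from neurologic decline) only allowed at the terminal observation")
  }
  v
}

# stop with an aggregated validation report unless the course is valid
assert_valid_course <- function(course) {
  v <- validate_course(course)
  if (length(v))
    stop("invalid patient course:\n  - ", paste(v, collapse = "\n  - "),
         call. = FALSE)
  invisible(course)
}
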