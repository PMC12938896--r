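# Target / non-target lesion designation policies.
#
# Three policies are implemented:
#   A1  - up to max_targets measurable lesions fixed on the baseline scan;
#         everything else, including later lesions, is non-target forever.
#   A2  - starts as A1; a measurable new lesion is added while fewer than
#         max_targets targets exist, otherwise it replaces the smallest
#         current target if strictly larger at the current assessment.
#   ARx - treatment-based: every treated lesion is target from the
#         assessment at which its treatment's targeting is recorded, with
#         no count limit and no measurability threshold.
# Under A2 and ARx the baseline and nadir sums of longest diameters (SLD)
# are reset whenever target-set composition changes.

#' Is a lesion measurement measurable disease?
#'
#' Measurable disease requires the longest diameter to reach
#' `cfg$measurable_longest_mm` and, when a perpendicular diameter is
#' recorded, that it reaches `cfg$measurable_perp_mm`.
#'
#' @param m one row of a course's `measurements` data.frame (the lesion must
#'   be present)
#' @param cfg an [assessment_config()]
#' @return logical
#' @export
is_measurable <- function(m, cfg) {
  if (!isTRUE(as.logical(m$present)))
    stop("is_measurable() called on an absent lesion", call. = FALSE)
  ld_ok <- m$longest_diameter_mm >= cfg$measurable_longest_mm - .EPS
  perp <- m$perpendicular_diameter_mm
  perp_ok <- is.na(perp) || perp >= cfg$measurable_perp_mm - .EPS
  isTRUE(ld_ok && perp_ok)
}

# measurable lesion ids at 0-based assessment t
.measurable_ids_at <- function(course, t, cfg) {
  meas <- course$measurements
  rows <- meas[meas$assessment_index == t & meas$present, , drop = FALSE]
  if (nrow(rows) == 0L) return(character())
  keep <- vapply(seq_len(nrow(rows)), function(i) is_measurable(rows[i, ], cfg),
                 logical(1))
  rows$lesion_id[keep]
}

# order ids by diameter (descending) with lexicographic id tie-break
.order_by_size <- function(ids, diam) ids[order(-diam, ids)]

# assemble a designation_timeline from per-assessment target sets
.finish_timeline <- function(course, policy, targets) {
  nt <- n_assessments(course)
  ldm <- ld_matrix(course)
  slds <- vapply(seq_len(nt) - 1L,
                 function(t) sum(ld_at(course, targets[[t + 1L]], t, ldm)),
                 numeric(1))
  nontargets <- lapply(seq_len(nt) - 1L, function(t)
    sort(setdiff(lesions_seen_by(course, t), targets[[t + 1L]])))
  changed <- logical(nt)
  if (nt > 1L)
    for (t in 2:nt)
      changed[t] <- !setequal(targets[[t]], targets[[t - 1L]])
  baseline <- nadir <- numeric(nt)
  reset_at <- integer(nt) # 0-based index of the epoch-opening assessment
  last_reset <- 1L
  for (t in seq_len(nt)) {
    if (t == 1L || changed[t]) last_reset <- t
    reset_at[t] <- last_reset - 1L
    baseline[t] <- slds[last_reset]
    nadir[t] <- min(slds[last_reset:t])
  }
  structure(list(
    policy = policy,
    assessment_days = course$assessment_days,
    targets = targets,
    nontargets = nontargets,
    composition_changed = changed,
    sld_mm = slds,
    baseline_sld_mm = baseline,
    nadir_sld_mm = nadir,
    reset_index = reset_at
  ), class = "designation_timeline")
}

#' @export
print.designation_timeline <- function(x, ...) {
  cat(sprintf("<designation_timeline> policy %s over %d assessments\n",
              x$policy, length(x$targets)))
  df <- data.frame(
    day = x$assessment_days,
    n_targets = lengths(x$targets),
    n_nontargets = lengths(x$nontargets),
    sld_mm = round(x$sld_mm, 2),
    baseline_sld = round(x$baseline_sld_mm, 2),
    nadir_sld = round(x$nadir_sld_mm, 2),
    reset = x$composition_changed
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Designate target and non-target lesions
#'
#' Dispatches to [designate_a1()], [designate_a2()], or [designate_arx()]
#' according to `cfg$policy` and returns the per-assessment designation
#' timeline with baseline/nadir SLD bookkeeping.
#'
#' @param course a valid `patient_course`
#' @param cfg an [assessment_config()]
#' @return a `designation_timeline`: per assessment, the ordered target-id
#'   set, the non-target set, a composition-change flag, the SLD, and the
#'   epoch baseline and nadir SLD
#' @export
designate <- function(course, cfg = assessment_config()) {
  switch(cfg$policy,
         A1 = designate_a1(course, cfg),
         A2 = designate_a2(course, cfg),
         ARx = designate_arx(course, cfg),
         stop("unknown policy ", cfg$policy, call. = FALSE))
}

# baseline target selection shared by A1 and A2: the largest measurable
# baseline lesions, ties broken by lexicographic lesion_id
.baseline_targets <- function(course, cfg) {
  ids <- .measurable_ids_at(course, 0L, cfg)
  if (length(ids) == 0L) return(character())
  diam <- ld_at(course, ids, 0L)
  utils::head(.order_by_size(ids, diam), cfg$max_targets)
}

#' @rdname designate
#' @description `designate_a1()`: up to `max_targets` measurable lesions are
#'   fixed on the baseline scan (largest first); all other lesions, including
#'   those appearing later, remain non-target for the whole course.
#' @export
designate_a1 <- function(course, cfg = assessment_config()) {
  base <- .baseline_targets(course, cfg)
  targets <- rep(list(base), n_assessments(course))
  .finish_timeline(course, "A1", targets)
}

#' @rdname designate
#' @description `designate_a2()`: starts as A1; at an assessment where new
#'   measurable lesions appear they are added while fewer than `max_targets`
#'   targets exist, otherwise each (largest first) replaces the smallest
#'   current target when strictly larger at the current assessment. Replaced
#'   lesions are evaluated qualitatively (non-target) from then on, and any
#'   composition change resets the baseline and nadir SLD.
#' @export
designate_a2 <- function(course, cfg = assessment_config()) {
  nt <- n_assessments(course)
  ldm <- ld_matrix(course)
  cur <- .baseline_targets(course, cfg)
  retired <- character() # ex-targets: qualitative from now on
  targets <- vector("list", nt)
  targets[[1L]] <- cur
  first_idx <- lesion_first_index(course, course$lesions$lesion_id)
  names(first_idx) <- course$lesions$lesion_id
  if (nt > 1L) for (t in 1:(nt - 1L)) {
    new_ids <- names(first_idx)[first_idx == t]
    new_meas <- intersect(new_ids, .measurable_ids_at(course, t, cfg))
    for (nl in .order_by_size(new_meas, ld_at(course, new_meas, t, ldm))) {
      if (length(cur) < cfg$max_targets) {
        cur <- c(cur, nl)
      } else {
        d <- ld_at(course, cur, t, ldm)
        victims <- cur[d <= min(d) + .EPS]
        victim <- victims[order(victims, decreasing = TRUE)][1L]
        if (ld_at(course, nl, t, ldm) > min(d) + .EPS) {
          retired <- c(retired, victim)
          cur <- c(setdiff(cur, victim), nl)
        }
      }
    }
    targets[[t + 1L]] <- cur
  }
  .finish_timeline(course, "A2", targets)
}

#' @rdname designate
#' @description `designate_arx()`: treatment-based designation. A lesion is
#'   target from the assessment whose scan precedes (or coincides with) the
#'   start of a treatment targeting it, with no limit on target count and no
#'   measurability gate. Focal treatments (SRS/FSRT/surgery) target their
#'   listed lesions; non-focal treatments (WBRT, systemic) target every
#'   lesion present at treatment start and every lesion appearing while the
#'   treatment is ongoing (a non-focal treatment runs until the next
#'   non-focal treatment starts). Untreated lesions stay non-target.
#' @export
designate_arx <- function(course, cfg = assessment_config()) {
  nt <- n_assessments(course)
  days <- course$assessment_days
  ids <- course$lesions$lesion_id
  first_idx <- lesion_first_index(course, ids)
  names(first_idx) <- ids
  # 0-based index of the last assessment at or before a day (the
  # pre-treatment scan); treatments before baseline map to the baseline scan
  pre_scan <- function(day) max(0L, findInterval(day, days) - 1L)

  start_idx <- rep(NA_integer_, length(ids))
  names(start_idx) <- ids
  note <- function(id, idx) {
    idx <- max(idx, first_idx[[id]]) # never target before first seen
    if (is.na(start_idx[[id]]) || idx < start_idx[[id]])
      start_idx[[id]] <<- idx
  }
  tr <- course$treatments
  nonfocal_days <- sort(tr$start_day[!tr$modality %in% FOCAL_MODALITIES])
  for (i in seq_len(nrow(tr))) {
    r <- tr[i, ]
    if (r$modality %in% FOCAL_MODALITIES) {
      for (id in r$targeted_lesion_ids[[1L]]) note(id, pre_scan(r$start_day))
    } else {
      tgt <- r$targeted_lesion_ids[[1L]]
      if (length(tgt)) {
        for (id in tgt) note(id, pre_scan(r$start_day))
      } else {
        # acts on all lesions present at start, plus arrivals while ongoing
        upto <- nonfocal_days[nonfocal_days > r$start_day]
        end_day <- if (length(upto)) upto[1L] else Inf
        scan0 <- pre_scan(r$start_day)
        for (id in ids) {
          fsd <- course$lesions$first_seen_day[match(id, ids)]
          if (fsd <= r$start_day) note(id, scan0)
          else if (fsd < end_day) note(id, first_idx[[id]])
        }
      }
    }
  }
  targets <- lapply(seq_len(nt) - 1L, function(t)
    sort(ids[!is.na(start_idx) & start_idx <= t]))
  .finish_timeline(course, "ARx", targets)
}

#' Sum of longest diameters of the target lesions
#'
#' @param course a `patient_course`
#' @param timeline a `designation_timeline` for that course
#' @param t 0-based assessment index
#' @return SLD in mm (absent lesions contribute 0; empty target set gives 0)
#' @export
sld <- function(course, timeline, t) {
  sum(ld_at(course, timeline$targets[[t + 1L]], t))
}
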