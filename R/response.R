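# RANO-BM response classification.
#
# Overall response at a timepoint combines five components:
#   target lesions   CR: none | PR: SLD -30% vs baseline | PD: SLD +20% vs
#                    nadir AND >=5 mm increase in >=1 lesion diameter
#   non-target       CR: none | PR/SD: stable or improved | PD: unequivocal
#                    progression
#   new lesions      CR/PR/SD: none | PD: present (confirmed)
#   corticosteroids  CR: none | PR/SD: stable or decreased | PD: n/a
#   clinical status  CR/PR/SD: stable or improved | PD: worse
# CR/PR/SD require ALL of their column's conditions; PD requires ANY of its
# triggers. A timepoint matching no column is Not Evaluable (NE).

.CAT_RANK <- c(CR = 1L, PR = 2L, SD = 3L, PD = 4L)

#' Target-lesion response category at one assessment
#'
#' Applies the target-lesion row of the classification to the designated
#' target set: CR when every target lesion has disappeared; PD when the SLD
#' rose by at least `pd_increase_frac` over the epoch nadir AND at least one
#' target lesion gained `pd_abs_increase_mm` over its own nadir (under
#' `pd_rule = "absolute_2p5mm"`, a single-lesion gain of `absolute_pd_mm`
#' alone suffices); PR when the SLD fell by at least `pr_decrease_frac`
#' from the epoch baseline and PD did not fire; otherwise SD. An empty
#' target set is NE. Baselines, nadirs, and per-lesion nadirs are taken
#' within the current designation epoch (since the last composition reset).
#'
#' @param course a `patient_course`
#' @param timeline a `designation_timeline` for the course
#' @param t 0-based assessment index
#' @param cfg an [assessment_config()]
#' @return one of `"CR" "PR" "SD" "PD" "NE"`
#' @export
target_category <- function(course, timeline, t, cfg = assessment_config()) {
  .target_category_detail(course, timeline, t, cfg, ld_matrix(course))$category
}

.target_category_detail <- function(course, timeline, t, cfg, ldm) {
  tg <- timeline$targets[[t + 1L]]
  if (length(tg) == 0L)
    return(list(category = "NE", reasons = "target_set_empty"))
  sld_t <- timeline$sld_mm[t + 1L]
  baseline <- timeline$baseline_sld_mm[t + 1L]
  nadir <- timeline$nadir_sld_mm[t + 1L]
  rt <- timeline$reset_index[t + 1L]
  lds <- ld_at(course, tg, t, ldm)
  if (all(lds <= .EPS))
    return(list(category = "CR", reasons = "target_cr_all_absent"))
  # per-lesion gain over the lesion's nadir within the current epoch
  gains <- vapply(tg, function(id) {
    traj <- vapply(rt:t, function(s) ld_at(course, id, s, ldm), numeric(1))
    ld_at(course, id, t, ldm) - min(traj)
  }, numeric(1))
  pd <- if (cfg$pd_rule == "relative_20pct") {
    sld_t >= (1 + cfg$pd_increase_frac) * nadir - .EPS &&
      any(gains >= cfg$pd_abs_increase_mm - .EPS)
  } else {
    any(gains >= cfg$absolute_pd_mm - .EPS)
  }
  if (pd) {
    rsn <- if (cfg$pd_rule == "relative_20pct")
      sprintf("target_pd_sld_plus_%.0fpct_and_lesion_gain_%.1fmm",
              100 * (sld_t / max(nadir, .EPS) - 1), max(gains))
    else sprintf("target_pd_absolute_lesion_gain_%.1fmm", max(gains))
    return(list(category = "PD", reasons = rsn))
  }
  if (sld_t <= (1 - cfg$pr_decrease_frac) * baseline + .EPS)
    return(list(category = "PR",
                reasons = sprintf("target_pr_sld_minus_%.0fpct",
                                  100 * (1 - sld_t / max(baseline, .EPS)))))
  list(category = "SD", reasons = "target_sd")
}

#' Per-lesion response categories along one trajectory
#'
#' Applies the target-lesion thresholds to a single lesion's longest
#' diameter: CR when absent (0 mm), PD when the diameter rose by
#' `pd_increase_frac` over the lesion nadir with an absolute gain of
#' `pd_abs_increase_mm` (or the absolute rule), PR when it fell by
#' `pr_decrease_frac` from the lesion's first measurement, else SD. For a
#' single-lesion patient this coincides with the overall target category.
#'
#' @param trajectory numeric vector of longest diameters per assessment;
#'   `NA` before the lesion is first seen (those entries come back NE)
#' @param cfg an [assessment_config()]
#' @return character vector of categories, one per assessment
#' @export
#' @examples
#' lesion_category(c(20, 10, 4))       # SD PR PR
#' lesion_category(c(10, 6, 18))       # SD PR PD
lesion_category <- function(trajectory, cfg = assessment_config()) {
  out <- rep("NE", length(trajectory))
  seen <- which(!is.na(trajectory))
  if (length(seen) == 0L) return(out)
  first <- seen[1L]
  baseline <- trajectory[first]
  for (t in first:length(trajectory)) {
    v <- trajectory[t]
    if (is.na(v)) { out[t] <- "NE"; next }
    nadir <- min(trajectory[first:t], na.rm = TRUE)
    gain <- v - nadir
    if (v <= .EPS) out[t] <- "CR"
    else if ((cfg$pd_rule == "relative_20pct" &&
              v >= (1 + cfg$pd_increase_frac) * nadir - .EPS &&
              gain >= cfg$pd_abs_increase_mm - .EPS) ||
             (cfg$pd_rule == "absolute_2p5mm" &&
              gain >= cfg$absolute_pd_mm - .EPS)) out[t] <- "PD"
    else if (v <= (1 - cfg$pr_decrease_frac) * baseline + .EPS) out[t] <- "PR"
    else out[t] <- "SD"
  }
  out
}

#' Combine the five components into the overall category
#'
#' Walks the classification grid: PD when ANY progression trigger fires
#' (target PD, unequivocal non-target progression, confirmed new lesions,
#' or clinical worsening); otherwise the first of CR, PR, SD whose column
#' conditions ALL hold; otherwise NE. CR requires no steroids and no
#' residual non-target disease; PR/SD require stable-or-decreased steroids.
#' An unconfirmed (pending) new lesion does not trigger PD but blocks
#' CR/PR/SD, yielding NE until the repeat scan adjudicates it.
#'
#' @param target target-lesion category (`"CR" "PR" "SD" "PD" "NE"`)
#' @param nontarget_state `"none"`, `"stable_or_improved"`,
#'   `"unequivocal_progression"`, or `"not_assessed"`
#' @param new_lesions_present any new lesion first seen at this assessment?
#' @param new_lesions_confirmed any such lesion confirmed on repeat imaging?
#' @param steroid_state `"none"`, `"stable"`, `"decreased"`, `"increased"`
#' @param clinical `"stable_or_improved"` or `"worse"`
#' @param cfg an [assessment_config()] (reserved; the grid itself is fixed)
#' @return list with `category` and `reasons` (fired-rule identifiers)
#' @export
overall_response <- function(target, nontarget_state,
                             new_lesions_present, new_lesions_confirmed,
                             steroid_state, clinical,
                             cfg = assessment_config()) {
  reasons <- character()
  if (target == "PD") reasons <- c(reasons, "pd_target")
  if (nontarget_state == "unequivocal_progression")
    reasons <- c(reasons, "pd_nontarget_progression")
  if (new_lesions_confirmed) reasons <- c(reasons, "pd_new_lesion_confirmed")
  if (clinical == "worse") reasons <- c(reasons, "pd_clinical_worse")
  if (length(reasons))
    return(list(category = "PD", reasons = reasons))

  no_new <- !new_lesions_present
  steroids_ok <- steroid_state %in% c("none", "stable", "decreased")
  clin_ok <- clinical == "stable_or_improved"
  if (target == "CR" && nontarget_state == "none" && no_new &&
      steroid_state == "none" && clin_ok)
    return(list(category = "CR", reasons = "cr_all_conditions"))
  if (target %in% c("CR", "PR") &&
      nontarget_state %in% c("none", "stable_or_improved") &&
      no_new && steroids_ok && clin_ok)
    return(list(category = "PR", reasons = "pr_all_conditions"))
  if (target %in% c("CR", "PR", "SD") &&
      nontarget_state %in% c("none", "stable_or_improved") &&
      no_new && steroids_ok && clin_ok)
    return(list(category = "SD", reasons = "sd_all_conditions"))
  why <- c(
    if (target == "NE") "ne_target_not_evaluable",
    if (!steroids_ok) "ne_steroids_increased",
    if (new_lesions_present && !new_lesions_confirmed) "ne_new_lesion_pending",
    if (nontarget_state == "not_assessed") "ne_nontarget_not_assessed")
  list(category = "NE",
       reasons = if (length(why)) why else "ne_no_column_matches")
}

# non-target qualitative state at 0-based assessment t
.nontarget_state_at <- function(course, timeline, t) {
  nts <- timeline$nontargets[[t + 1L]]
  if (length(nts) == 0L) return("none")
  meas <- course$measurements
  rows <- meas[meas$lesion_id %in% nts & meas$assessment_index == t, , drop = FALSE]
  if (nrow(rows) == 0L) return("not_assessed")
  present <- rows[rows$present, , drop = FALSE]
  if (nrow(present) == 0L) return("none") # all non-target disease resolved
  states <- present$qualitative_state
  if (any(states == "unequivocal_progression")) return("unequivocal_progression")
  if (all(states == "not_assessed")) return("not_assessed")
  "stable_or_improved"
}

# full per-timepoint evaluation (internal; assess_course orchestrates)
.timepoint_response <- function(course, timeline, t, cfg, conf, ldm) {
  tc <- .target_category_detail(course, timeline, t, cfg, ldm)
  nts <- .nontarget_state_at(course, timeline, t)
  new_here <- conf[conf$first_seen_index == t, , drop = FALSE]
  new_present <- nrow(new_here) > 0L
  new_confirmed <- any(new_here$confirmed)
  cl_row <- .clinical_at(course, t)
  steroid <- if (is.null(cl_row)) "none" else cl_row$steroid_state
  clin <- clinical_state(course, t, cfg)
  ov <- overall_response(tc$category, nts, new_present, new_confirmed,
                         steroid, clin, cfg)
  list(assessment_index = t,
       day = course$assessment_days[t + 1L],
       target_category = tc$category,
       nontarget_state = nts,
       new_lesions_present = new_present,
       new_lesions_confirmed = new_confirmed,
       steroid_state = steroid,
       clinical_state = clin,
       overall = ov$category,
       reasons = c(tc$reasons, ov$reasons))
}

#' Assess a full patient course
#'
#' Runs lesion designation under `cfg$policy`, evaluates every timepoint
#' against the classification grid, derives per-lesion categories, the best
#' overall response (CR > PR > SD > PD, NE ignored), time to progression
#' (first assessment day with overall PD), the mixed-response fractions over
#' final per-lesion categories, a per-lesion vs overall discrepancy flag,
#' and the distant-brain-failure summary anchored at baseline.
#'
#' The discrepancy flag is raised when the overall course never reaches PD
#' while some lesion's final category is PD (masked progression), or when
#' the overall course reaches PD while at least half of the lesions end in
#' CR or PR (masked control).
#'
#' @param course a valid `patient_course`
#' @param cfg an [assessment_config()]
#' @return an `assessment_report` with elements `patient_id`, `policy`,
#'   `timepoints` (data.frame), `timeline`, `lesions` (per-lesion category
#'   matrix and final categories with baseline/nadir), `best_overall`,
#'   `time_to_progression_days`, `mixed_response_fractions`,
#'   `discrepancy_flag`, `n_baseline_lesions`, `dbf`, `audit_log`
#' @export
assess_course <- function(course, cfg = assessment_config()) {
  assert_valid_course(course)
  timeline <- designate(course, cfg)
  conf <- confirm_new_lesions(course, cfg)
  ldm <- ld_matrix(course)
  nt <- n_assessments(course)

  tps <- lapply(seq_len(nt) - 1L, function(t)
    .timepoint_response(course, timeline, t, cfg, conf, ldm))
  timepoints <- do.call(rbind, lapply(tps, function(x)
    data.frame(assessment_index = x$assessment_index, day = x$day,
               target_category = x$target_category,
               nontarget_state = x$nontarget_state,
               new_lesions_present = x$new_lesions_present,
               new_lesions_confirmed = x$new_lesions_confirmed,
               steroid_state = x$steroid_state,
               clinical_state = x$clinical_state,
               overall = x$overall, stringsAsFactors = FALSE)))

  # per-lesion categories from each lesion's diameter trajectory
  ids <- course$lesions$lesion_id
  lesion_cats <- matrix("NE", nrow = length(ids), ncol = nt,
                        dimnames = list(ids, NULL))
  lesion_base <- lesion_nadir <- final_cat <- rep(NA, length(ids))
  names(final_cat) <- ids
  for (i in seq_along(ids)) {
    traj <- ldm[ids[i], ]
    lesion_cats[i, ] <- lesion_category(traj, cfg)
    if (any(!is.na(traj))) {
      lesion_base[i] <- traj[which(!is.na(traj))[1L]]
      lesion_nadir[i] <- min(traj, na.rm = TRUE)
      last <- max(which(!is.na(traj)))
      final_cat[i] <- lesion_cats[i, last]
    }
  }

  post <- if (nt > 1L) timepoints$overall[-1L] else timepoints$overall
  ranked <- post[post %in% names(.CAT_RANK)]
  best <- if (length(ranked)) names(.CAT_RANK)[min(.CAT_RANK[ranked])] else "NE"
  pd_days <- timepoints$day[timepoints$overall == "PD" &
                              timepoints$assessment_index > 0L]
  ttp <- if (length(pd_days)) pd_days[1L] else NA_integer_

  assessed <- final_cat[!is.na(final_cat) & final_cat != "NE"]
  mix <- if (length(assessed))
    as.list(table(factor(assessed, levels = RESPONSE_CATEGORIES[1:4])) /
              length(assessed))
  else as.list(stats::setNames(rep(0, 4), RESPONSE_CATEGORIES[1:4]))
  mix <- lapply(mix, as.numeric)

  ever_pd <- any(timepoints$overall == "PD")
  masked_prog <- !ever_pd && any(assessed == "PD")
  masked_ctrl <- ever_pd && length(assessed) > 0L &&
    mean(assessed %in% c("CR", "PR")) >= 0.5
  discrepancy <- masked_prog || masked_ctrl

  dbf <- dbf_summary(course, cfg)

  audit <- unlist(lapply(tps, function(x)
    sprintf("t=%d day=%d %s", x$assessment_index, x$day, x$reasons)))
  resets <- which(timeline$composition_changed) - 1L
  if (length(resets))
    audit <- c(audit, sprintf("t=%d day=%d designation_reset",
                              resets, course$assessment_days[resets + 1L]))

  structure(list(
    patient_id = course$patient_id,
    policy = cfg$policy,
    config = unclass(cfg),
    timepoints = timepoints,
    timeline = timeline,
    lesions = list(categories = lesion_cats,
                   final = final_cat,
                   baseline_mm = stats::setNames(lesion_base, ids),
                   nadir_mm = stats::setNames(lesion_nadir, ids)),
    best_overall = best,
    time_to_progression_days = ttp,
    mixed_response_fractions = mix,
    discrepancy_flag = discrepancy,
    n_baseline_lesions = sum(.present_at0(course)),
    dbf = dbf,
    audit_log = sort(audit)
  ), class = "assessment_report")
}

# lesions recorded present at baseline
.present_at0 <- function(course) {
  meas <- course$measurements
  ids <- course$lesions$lesion_id
  vapply(ids, function(id) {
    r <- meas[meas$lesion_id == id & meas$assessment_index == 0L, ]
    nrow(r) > 0L && isTRUE(r$present[1L])
  }, logical(1))
}

#' @export
print.assessment_report <- function(x, ...) {
  cat(sprintf("<assessment_report> %s under policy %s\n", x$patient_id, x$policy))
  print(x$timepoints, row.names = FALSE)
  cat(sprintf("best overall: %s; time to progression: %s days; discrepancy: %s\n",
              x$best_overall,
              ifelse(is.na(x$time_to_progression_days), "-",
                     x$time_to_progression_days),
              x$discrepancy_flag))
  fr <- unlist(x$mixed_response_fractions)
  fr <- fr[fr > 0]
  if (length(fr))
    cat("final per-lesion fractions:",
        paste(sprintf("%s %.2f", names(fr), fr), collapse = ", "), "\n")
  print(x$dbf)
  invisible(x)
}

#' Windowed (re-baselined) assessment
#'
#' Re-anchors the course at `window_start_day` (which must be an assessment
#' day) and assesses the sub-course in isolation: lesions present at the
#' window start become that window's initial lesions, lesions first seen
#' inside the window are new, treatments starting before the window are
#' dropped, and clinical status is referenced to the window-start
#' observation. This is how a single treatment period (e.g. from one
#' systemic-therapy start to the next failure) is evaluated inside a
#' multi-treatment course.
#'
#' @param course a valid `patient_course`
#' @param window_start_day assessment day opening the window
#' @param window_end_day optional last day (defaults to end of course)
#' @param cfg an [assessment_config()]
#' @return an `assessment_report` for the sub-course, with a `window`
#'   element recording the anchor days
#' @export
windowed_assessment <- function(course, window_start_day,
                                window_end_day = NULL,
                                cfg = assessment_config()) {
  days <- course$assessment_days
  if (!window_start_day %in% days)
    stop("window_start_day must coincide with an assessment day", call. = FALSE)
  end <- if (is.null(window_end_day)) max(days) else window_end_day
  keep <- which(days >= window_start_day & days <= end) # 1-based
  if (length(keep) < 2L)
    stop("window contains fewer than 2 assessments; nothing to assess",
         call. = FALSE)
  old_idx <- keep - 1L
  remap <- stats::setNames(seq_along(keep) - 1L, old_idx)

  meas <- course$measurements
  meas <- meas[meas$assessment_index %in% old_idx, , drop = FALSE]
  meas$assessment_index <- unname(remap[as.character(meas$assessment_index)])

  les <- course$lesions
  les <- les[les$first_seen_day <= end, , drop = FALSE]
  les$first_seen_day <- pmax(0L, les$first_seen_day - as.integer(window_start_day))
  les$is_new_on_study <- les$first_seen_day > 0L
  les <- les[les$lesion_id %in% meas$lesion_id | les$first_seen_day == 0L, ,
             drop = FALSE]

  tr <- course$treatments
  tr <- tr[tr$start_day >= window_start_day & tr$start_day <= end, , drop = FALSE]
  tr$start_day <- tr$start_day - as.integer(window_start_day)

  cl <- course$clinical
  cl <- cl[cl$assessment_index %in% old_idx, , drop = FALSE]
  cl$assessment_index <- unname(remap[as.character(cl$assessment_index)])

  sub <- patient_course(
    patient_id = sprintf("%s@%d", course$patient_id, window_start_day),
    assessment_days = days[keep] - window_start_day,
    measurements = meas, lesions = les, treatments = tr, clinical = cl)
  rep <- assess_course(sub, cfg)
  rep$window <- list(start_day = window_start_day, end_day = end)
  rep
}
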