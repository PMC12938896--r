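#' Assessment configuration
#'
#' Bundles every tunable threshold of the classification together with the
#' lesion-designation policy. Defaults follow the RANO-BM criteria:
#' measurable disease at >=10 mm longest and >=5 mm perpendicular diameter,
#' at most five target lesions, partial response at a >=30% drop in the sum
#' of longest diameters (SLD) relative to baseline, progression at a >=20%
#' SLD rise over nadir with a >=5 mm single-lesion increase, and new-lesion
#' confirmation on a repeat scan. The alternative progression rule
#' (`pd_rule = "absolute_2p5mm"`) replaces the relative SLD clause with a
#' 2.5 mm absolute single-lesion increase over nadir, as proposed for
#' repeat-radiosurgery cohorts; `measurable_longest_mm = 5` reproduces the
#' lowered measurability threshold proposed for thin-slice MRI.
#'
#' @param measurable_longest_mm measurable-disease longest-diameter threshold (mm)
#' @param measurable_perp_mm measurable-disease perpendicular threshold (mm)
#' @param max_targets maximum number of target lesions (policies A1/A2)
#' @param pr_decrease_frac fractional SLD decrease from baseline for PR
#' @param pd_increase_frac fractional SLD increase over nadir for PD
#' @param pd_abs_increase_mm absolute single-lesion increase over nadir
#'   required alongside the relative SLD clause (mm)
#' @param pd_rule `"relative_20pct"` (default) or `"absolute_2p5mm"`
#' @param absolute_pd_mm single-lesion increase over nadir defining PD under
#'   the absolute rule (mm)
#' @param require_new_lesion_confirmation require new lesions to persist on
#'   the next scan before they count as progression events
#' @param bss_worsen_delta minimal brain-specific-symptoms score increase
#'   counted as clinical worsening
#' @param status_metric clinical-status metric(s) consulted: `"kps"`,
#'   `"bss"`, or `"both"`
#' @param policy lesion-designation policy: `"A1"` (fixed baseline targets),
#'   `"A2"` (sequential add/replace), or `"ARx"` (treatment-based)
#' @return an `assessment_config` list
#' @export
#' @examples
#' assessment_config(policy = "ARx")
assessment_config <- function(measurable_longest_mm = 10,
                              measurable_perp_mm = 5,
                              max_targets = 5L,
                              pr_decrease_frac = 0.30,
                              pd_increase_frac = 0.20,
                              pd_abs_increase_mm = 5,
                              pd_rule = c("relative_20pct", "absolute_2p5mm"),
                              absolute_pd_mm = 2.5,
                              require_new_lesion_confirmation = TRUE,
                              bss_worsen_delta = 1L,
                              status_metric = c("both", "kps", "bss"),
                              policy = c("A1", "A2", "ARx")) {
  pd_rule <- match.arg(pd_rule)
  status_metric <- match.arg(status_metric)
  policy <- match.arg(policy)
  cfg <- list(
    measurable_longest_mm = as.numeric(measurable_longest_mm),
    measurable_perp_mm = as.numeric(measurable_perp_mm),
    max_targets = as.integer(max_targets),
    pr_decrease_frac = as.numeric(pr_decrease_frac),
    pd_increase_frac = as.numeric(pd_increase_frac),
    pd_abs_increase_mm = as.numeric(pd_abs_increase_mm),
    pd_rule = pd_rule,
    absolute_pd_mm = as.numeric(absolute_pd_mm),
    require_new_lesion_confirmation = isTRUE(require_new_lesion_confirmation),
    bss_worsen_delta = as.integer(bss_worsen_delta),
    status_metric = status_metric,
    policy = policy
  )
  stopifnot(cfg$measurable_longest_mm > 0, cfg$measurable_perp_mm > 0,
            cfg$max_targets >= 1L, cfg$pd_abs_increase_mm > 0,
            cfg$absolute_pd_mm > 0, cfg$bss_worsen_delta >= 1L)
  if (cfg$pr_decrease_frac <= 0 || cfg$pr_decrease_frac >= 1 ||
      cfg$pd_increase_frac <= 0 || cfg$pd_increase_frac >= 1)
    stop("pr_decrease_frac and pd_increase_frac must lie in (0,1)", call. = FALSE)
  structure(cfg, class = "assessment_config")
}

#' @export
print.assessment_config <- function(x, ...) {
  cat(sprintf(
    "<assessment_config> policy=%s, measurable>=%gx%g mm, max_targets=%d,\n  PR: SLD -%.0f%% vs baseline; PD: %s; new-lesion confirmation: %s\n",
    x$policy, x$measurable_longest_mm, x$measurable_perp_mm, x$max_targets,
    100 * x$pr_decrease_frac,
    if (x$pd_rule == "relative_20pct")
      sprintf("SLD +%.0f%% vs nadir and >=%g mm in one lesion",
              100 * x$pd_increase_frac, x$pd_abs_increase_mm)
    else sprintf(">=%g mm absolute increase over lesion nadir", x$absolute_pd_mm),
    if (x$require_new_lesion_confirmation) "required" else "off"))
  invisible(x)
}

# coerce a plain list (e.g. parsed JSON config) into an assessment_config,
# rejecting unknown keys
as_assessment_config <- function(x) {
  if (inherits(x, "assessment_config")) return(x)
  known <- names(formals(assessment_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(assessment_config, x)
}
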