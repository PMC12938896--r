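# Brute-force oracle: a direct, loop-by-loop evaluation of the five-row
# response grid, written independently of the engine's code path. It takes
# the per-assessment target sets as given (designation is checked separately
# against oracle_designation_state) and recomputes sums, epochs, nadirs,
# gains, confirmations, and the grid from the raw measurement table.
# Threshold comparisons share the engine's 1e-9 measurement tolerance.

oracle_overall <- function(course, targets_list, cfg) {
  eps <- 1e-9
  meas <- course$measurements
  days <- course$assessment_days
  nt <- length(days)
  ld <- function(id, t) {
    r <- meas[meas$lesion_id == id & meas$assessment_index == t, ]
    if (nrow(r) == 0L || !r$present[1L]) 0 else r$longest_diameter_mm[1L]
  }
  first_idx <- function(id) min(meas$assessment_index[meas$lesion_id == id])
  all_ids <- course$lesions$lesion_id
  new_ids <- all_ids[course$lesions$first_seen_day > days[1L]]
  cl <- course$clinical
  ref_obs <- if (nrow(cl)) cl[which.min(cl$assessment_index), ] else NULL

  reset <- 0L
  out <- character(nt)
  for (t in 0:(nt - 1L)) {
    tg <- targets_list[[t + 1L]]
    if (t > 0L && !setequal(tg, targets_list[[t]])) reset <- t

    # --- target-lesion row
    if (length(tg) == 0L) {
      tcat <- "NE"
    } else {
      slds <- vapply(reset:t, function(s)
        sum(vapply(tg, ld, numeric(1), t = s)), numeric(1))
      lds_now <- vapply(tg, ld, numeric(1), t = t)
      if (all(lds_now <= eps)) {
        tcat <- "CR"
      } else {
        sld_t <- slds[length(slds)]
        gains <- vapply(tg, function(id)
          ld(id, t) - min(vapply(reset:t, function(s) ld(id, s), numeric(1))),
          numeric(1))
        pd <- if (cfg$pd_rule == "relative_20pct")
          sld_t >= (1 + cfg$pd_increase_frac) * min(slds) - eps &&
            any(gains >= cfg$pd_abs_increase_mm - eps)
        else any(gains >= cfg$absolute_pd_mm - eps)
        tcat <- if (pd) "PD"
        else if (sld_t <= (1 - cfg$pr_decrease_frac) * slds[1L] + eps) "PR"
        else "SD"
      }
    }

    # --- non-target row
    seen <- all_ids[vapply(all_ids, first_idx, integer(1)) <= t]
    nts <- setdiff(seen, tg)
    if (length(nts) == 0L) {
      nstate <- "none"
    } else {
      rows <- meas[meas$lesion_id %in% nts & meas$assessment_index == t, ]
      if (nrow(rows) == 0L) nstate <- "not_assessed"
      else {
        pres <- rows[rows$present, ]
        nstate <- if (nrow(pres) == 0L) "none"
        else if (any(pres$qualitative_state == "unequivocal_progression"))
          "unequivocal_progression"
        else if (all(pres$qualitative_state == "not_assessed")) "not_assessed"
        else "stable_or_improved"
      }
    }

    # --- new-lesion row (with repeat-scan confirmation)
    here <- new_ids[vapply(new_ids, first_idx, integer(1)) == t]
    new_present <- length(here) > 0L
    confirmed <- any(vapply(here, function(id) {
      if (!cfg$require_new_lesion_confirmation) return(TRUE)
      if (t >= nt - 1L) return(FALSE)
      r <- meas[meas$lesion_id == id & meas$assessment_index == t + 1L, ]
      nrow(r) > 0L && isTRUE(r$present[1L])
    }, logical(1)))

    # --- corticosteroid and clinical rows
    cur <- cl[cl$assessment_index == t, ]
    steroid <- if (nrow(cur)) cur$steroid_state[1L] else "none"
    worse <- FALSE
    if (nrow(cur) && !is.null(ref_obs)) {
      kps_w <- !is.na(ref_obs$kps) && !is.na(cur$kps[1L]) &&
        ((ref_obs$kps >= 90L && cur$kps[1L] <= 70L) ||
           (ref_obs$kps <= 80L && ref_obs$kps - cur$kps[1L] >= 20L) ||
           cur$kps[1L] <= 50L)
      bss_w <- !is.na(ref_obs$bss) && !is.na(cur$bss[1L]) &&
        (cur$bss[1L] - ref_obs$bss >= cfg$bss_worsen_delta)
      worse <- (kps_w || bss_w) &&
        !isTRUE(cur$decline_attributed_to_non_cns[1L])
    }

    # --- the grid: Any for PD, All for CR/PR/SD
    steroid_ok <- steroid %in% c("none", "stable", "decreased")
    nstate_ok <- nstate %in% c("none", "stable_or_improved")
    out[t + 1L] <-
      if (tcat == "PD" || nstate == "unequivocal_progression" ||
          confirmed || worse) "PD"
      else if (tcat == "CR" && nstate == "none" && !new_present &&
               steroid == "none" && !worse) "CR"
      else if (tcat %in% c("CR", "PR") && nstate_ok && !new_present &&
               steroid_ok && !worse) "PR"
      else if (tcat %in% c("CR", "PR", "SD") && nstate_ok && !new_present &&
               steroid_ok && !worse) "SD"
      else "NE"
  }
  out
}

# Independent recomputation of the SLD bookkeeping from the target sets and
# the raw measurements: detects resets by set comparison, sums diameters
# directly, and tracks baseline/nadir per epoch.
oracle_sld_state <- function(course, targets_list) {
  meas <- course$measurements
  nt <- length(course$assessment_days)
  ld <- function(id, t) {
    r <- meas[meas$lesion_id == id & meas$assessment_index == t, ]
    if (nrow(r) == 0L || !r$present[1L]) 0 else r$longest_diameter_mm[1L]
  }
  slds <- vapply(0:(nt - 1L), function(t)
    sum(vapply(targets_list[[t + 1L]], ld, numeric(1), t = t)), numeric(1))
  changed <- c(FALSE, vapply(seq_len(nt - 1L), function(t)
    !setequal(targets_list[[t + 1L]], targets_list[[t]]), logical(1)))
  baseline <- nadir <- numeric(nt)
  last <- 1L
  for (t in seq_len(nt)) {
    if (changed[t]) last <- t
    baseline[t] <- slds[last]
    nadir[t] <- min(slds[last:t])
  }
  data.frame(sld = slds, composition_changed = changed,
             baseline_sld = baseline, nadir_sld = nadir)
}
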