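# Seeded random small courses (<= 4 lesions, <= 6 assessments) for
# property-style tests. `clean = TRUE` produces measurable baseline lesions,
# quiet clinical observations, and no new lesions, for properties stated on
# the CR/PR/SD/PD lattice only.

random_course <- function(seed, clean = FALSE) {
  set.seed(seed)
  nt <- sample(3:6, 1)
  days <- cumsum(c(0L, sample(30:120, nt - 1, replace = TRUE)))
  n0 <- sample(1:3, 1)
  n_new <- if (clean) 0L else sample(0:1, 1)
  ids <- paste0("L", seq_len(n0))
  ld <- matrix(NA_real_, n0 + n_new, nt)
  rownames(ld) <- c(ids, if (n_new) "NL1")
  for (i in seq_len(n0)) {
    traj <- numeric(nt)
    traj[1] <- if (clean) sample(10:30, 1) else sample(5:30, 1)
    for (t in 2:nt) {
      traj[t] <- max(0, traj[t - 1] + sample(-8:8, 1))
      if (!clean && traj[t - 1] == 0 && stats::runif(1) < 0.7) traj[t] <- 0
    }
    ld[i, ] <- traj
  }
  if (n_new) {
    t0 <- sample(2:nt, 1)
    traj <- rep(NA_real_, nt)
    traj[t0] <- sample(3:15, 1)
    if (t0 < nt)
      for (t in (t0 + 1):nt) traj[t] <- max(0, traj[t - 1] + sample(-4:6, 1))
    ld[n0 + 1, ] <- traj
  }
  qual <- NULL
  if (!clean) {
    qual <- matrix(NA_character_, nrow(ld), nt)
    qual[] <- sample(c("stable", "improved", "unequivocal_progression",
                       "not_assessed"),
                     length(ld), TRUE, prob = c(.75, .1, .07, .08))
    qual[is.na(ld) | ld == 0] <- NA
  }
  clinical <- if (clean) {
    data.frame(assessment_index = 0:(nt - 1), kps = 90L, bss = 1L,
               steroid_state = "none",
               decline_attributed_to_non_cns = FALSE)
  } else {
    data.frame(
      assessment_index = 0:(nt - 1),
      kps = sample(seq(50L, 100L, 10L), nt, TRUE,
                   prob = c(.05, .1, .15, .2, .3, .2)),
      bss = sample(0:3, nt, TRUE),
      steroid_state = sample(c("none", "stable", "decreased", "increased"),
                             nt, TRUE, prob = c(.5, .3, .1, .1)),
      decline_attributed_to_non_cns = stats::runif(nt) < 0.1)
  }
  treatments <- data.frame(
    treatment_id = "SRS1", modality = "SRS", start_day = 0L,
    targeted_lesion_ids = I(list(ids)), stringsAsFactors = FALSE)
  course_from_matrix(paste0("rand", seed), months = days / 30.44, ld = ld,
                     treatments = treatments, clinical = clinical,
                     qualitative = qual)
}

# shrink all post-baseline diameters of the given lesions by a factor
shrink_lesions <- function(course, lesion_ids, lambda) {
  m <- course$measurements
  sel <- m$lesion_id %in% lesion_ids & m$assessment_index > 0L
  m$longest_diameter_mm[sel] <- m$longest_diameter_mm[sel] * lambda
  patient_course(course$patient_id, course$assessment_days, m,
                 lesions = course$lesions, treatments = course$treatments,
                 clinical = course$clinical)
}
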