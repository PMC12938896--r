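cfg <- assessment_config()

test_that("target_category applies the PR/PD thresholds to the SLD", {
  # baseline SLD 40, current 28: exactly the 30% decrease boundary -> PR
  course <- course_from_matrix("pr", months = c(0, 3),
                               ld = rbind(L1 = c(20, 14), L2 = c(20, 14)))
  tl <- designate_a1(course, cfg)
  expect_identical(target_category(course, tl, 1L, cfg), "PR")

  # nadir SLD 20 -> 24 (+20%) with one lesion +5 mm over nadir -> PD
  course <- course_from_matrix("pd", months = c(0, 3),
                               ld = rbind(L1 = c(10, 15), L2 = c(10, 9)))
  tl <- designate_a1(course, cfg)
  expect_identical(target_category(course, tl, 1L, cfg), "PD")

  # +20% SLD but max single-lesion gain 4 mm: both PD clauses required -> SD
  course <- course_from_matrix("sd", months = c(0, 3),
                               ld = rbind(L1 = c(10, 14), L2 = c(10, 10)))
  tl <- designate_a1(course, cfg)
  expect_identical(target_category(course, tl, 1L, cfg), "SD")

  # all target lesions absent -> CR; empty target set -> NE
  course <- course_from_matrix("cr", months = c(0, 3),
                               ld = rbind(L1 = c(12, 0)))
  tl <- designate_a1(course, cfg)
  expect_identical(target_category(course, tl, 1L, cfg), "CR")
  course <- course_from_matrix("ne", months = c(0, 3), ld = rbind(L1 = c(4, 4)))
  tl <- designate_a1(course, cfg)
  expect_identical(target_category(course, tl, 0L, cfg), "NE")
})

test_that("lesion_category classifies single-lesion trajectories", {
  expect_identical(lesion_category(c(20, 4), cfg), c("SD", "PR"))
  expect_identical(lesion_category(c(10, 6, 18), cfg), c("SD", "PR", "PD"))
  expect_identical(lesion_category(c(10, 10, 10), cfg), c("SD", "SD", "SD"))
  expect_identical(lesion_category(c(NA, 8, 0), cfg), c("NE", "SD", "CR"))
})

test_that("overall_response walks the grid (All for CR/PR/SD, Any for PD)", {
  ov <- function(...) overall_response(...)$category
  expect_identical(ov("CR", "none", FALSE, FALSE, "none", "stable_or_improved"),
                   "CR")
  # steroid increase without progression fits no column -> NE
  expect_identical(ov("PR", "none", FALSE, FALSE, "increased",
                      "stable_or_improved"), "NE")
  # a confirmed new lesion overrides target SD
  expect_identical(ov("SD", "stable_or_improved", TRUE, TRUE, "none",
                      "stable_or_improved"), "PD")
  # target CR with residual steroids downgrades to PR, not NE
  expect_identical(ov("CR", "none", FALSE, FALSE, "stable",
                      "stable_or_improved"), "PR")
  # pending (unconfirmed) new lesion blocks CR/PR/SD without triggering PD
  res <- overall_response("SD", "none", TRUE, FALSE, "none",
                          "stable_or_improved")
  expect_identical(res$category, "NE")
  expect_true("ne_new_lesion_pending" %in% res$reasons)
  expect_identical(ov("SD", "unequivocal_progression", FALSE, FALSE, "none",
                      "stable_or_improved"), "PD")
  expect_identical(ov("SD", "none", FALSE, FALSE, "none", "worse"), "PD")
})

test_that("new lesions are confirmed on the repeat scan and dated at appearance", {
  ld <- rbind(L1 = c(12, 11, 11), N1 = c(NA, 7, 7))
  course <- course_from_matrix("conf", months = c(0, 3, 6), ld = ld)
  conf <- confirm_new_lesions(course, cfg)
  expect_true(conf$confirmed)
  expect_identical(conf$first_seen_day, 91L)
  r <- assess_course(course, cfg)
  expect_identical(r$time_to_progression_days, 91L)

  # terminal appearance stays pending and triggers nothing
  ld <- rbind(L1 = c(12, 11, 11), N1 = c(NA, NA, 7))
  course <- course_from_matrix("pend", months = c(0, 3, 6), ld = ld)
  conf <- confirm_new_lesions(course, cfg)
  expect_false(conf$confirmed)
  expect_true(conf$pending)
  r <- assess_course(course, cfg)
  expect_false(any(r$timepoints$overall == "PD"))

  # with confirmation disabled, appearance alone confirms
  off <- assessment_config(require_new_lesion_confirmation = FALSE)
  conf <- confirm_new_lesions(course, off)
  expect_true(conf$confirmed)
})

test_that("masked progression raises the discrepancy flag (two-lesion courses)", {
  r1 <- assess_course(build_scenario("fig2_p1"), cfg)
  r2 <- assess_course(build_scenario("fig2_p2"), cfg)
  expect_true(all(r1$timepoints$overall[-1L] == "SD"))
  expect_true(all(r2$timepoints$overall[-1L] == "SD"))
  expect_false(r1$discrepancy_flag)
  expect_true(r2$discrepancy_flag)
  expect_identical(unname(r2$lesions$final["L2"]), "PD")
})

test_that("mixed-response fractions expose masked lesion control", {
  r <- assess_course(build_scenario("fig3_p2"), cfg)
  expect_identical(r$timepoints$overall[5L], "PD")
  fr <- r$mixed_response_fractions
  expect_equal(fr$CR + fr$PR, 0.8)
  expect_equal(fr$PD, 0.2)
  expect_equal(Reduce(`+`, fr), 1)
  expect_true(r$discrepancy_flag)
})

test_that("single-lesion overall equals the per-lesion category", {
  for (seed in 1:20) {
    course <- random_course(seed, clean = TRUE)
    course$measurements <- course$measurements[
      course$measurements$lesion_id == "L1", ]
    course$lesions <- course$lesions[course$lesions$lesion_id == "L1", ]
    course$treatments$targeted_lesion_ids <- I(list("L1"))
    r <- assess_course(course, cfg)
    ldm <- ranobm:::ld_matrix(course)
    expect_identical(r$timepoints$overall, lesion_category(ldm["L1", ], cfg))
  }
})

test_that("windowed assessment re-baselines at the window start", {
  f5a <- build_scenario("fig5_p1")
  w <- windowed_assessment(f5a, months_to_days(6), cfg = cfg)
  expect_identical(w$n_baseline_lesions, 1L)
  expect_identical(w$dbf$total_new_lesions, 5L)
  f5b <- build_scenario("fig5_p2")
  w <- windowed_assessment(f5b, months_to_days(6), cfg = cfg)
  expect_identical(w$n_baseline_lesions, 5L)
  expect_identical(w$dbf$total_new_lesions, 1L)

  # whole-course window reproduces assess_course
  f2 <- build_scenario("fig2_p2")
  w <- windowed_assessment(f2, 0, cfg = cfg)
  r <- assess_course(f2, cfg)
  expect_identical(w$timepoints$overall, r$timepoints$overall)
  expect_identical(w$discrepancy_flag, r$discrepancy_flag)

  expect_error(windowed_assessment(f2, 17), "assessment day")
  expect_error(windowed_assessment(f2, max(f2$assessment_days)),
               "fewer than 2")
})

test_that("engine agrees with the brute-force grid oracle on random courses", {
  for (seed in 1:60) {
    course <- random_course(seed)
    policy <- c("A1", "A2", "ARx")[seed %% 3L + 1L]
    pcfg <- assessment_config(policy = policy)
    r <- assess_course(course, pcfg)
    expect_identical(r$timepoints$overall,
                     oracle_overall(course, r$timeline$targets, pcfg),
                     info = sprintf("seed %d policy %s", seed, policy))
  }
})

test_that("shrinking target lesions never worsens the overall category", {
  rank <- c(CR = 1L, PR = 2L, SD = 3L, PD = 4L)
  for (seed in 1:30) {
    course <- random_course(seed, clean = TRUE)
    base <- assess_course(course, cfg)
    ids <- base$timeline$targets[[1L]]
    if (length(ids) == 0L) next
    for (lambda in c(0.9, 0.6, 0.3)) {
      shr <- assess_course(shrink_lesions(course, ids, lambda), cfg)
      both <- base$timepoints$overall %in% names(rank) &
        shr$timepoints$overall %in% names(rank)
      expect_true(all(rank[shr$timepoints$overall[both]] <=
                        rank[base$timepoints$overall[both]]),
                  info = sprintf("seed %d lambda %.1f", seed, lambda))
    }
  }
})

test_that("the absolute 2.5 mm rule is at least as sensitive as the default", {
  abs_cfg <- assessment_config(pd_rule = "absolute_2p5mm")
  for (seed in 1:30) {
    course <- random_course(seed)
    r_rel <- assess_course(course, cfg)
    r_abs <- assess_course(course, abs_cfg)
    pd_rel <- r_rel$timepoints$target_category == "PD"
    expect_true(all(r_abs$timepoints$target_category[pd_rel] == "PD"),
                info = paste("seed", seed))
  }
})

test_that("time to progression is non-decreasing in the absolute PD margin", {
  for (seed in 1:20) {
    course <- random_course(seed, clean = TRUE)
    never <- max(course$assessment_days) + 1L # sentinel: no progression seen
    ttp <- vapply(c(2, 5, 8), function(mm) {
      r <- assess_course(course, assessment_config(pd_abs_increase_mm = mm))
      ifelse(is.na(r$time_to_progression_days), never,
             r$time_to_progression_days)
    }, numeric(1))
    expect_true(all(diff(ttp) >= 0), info = paste("seed", seed))
  }
})
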