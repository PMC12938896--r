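cfg <- assessment_config()

trt <- function(id, modality, day, targets = character()) {
  data.frame(treatment_id = id, modality = modality, start_day = as.integer(day),
             targeted_lesion_ids = I(list(as.character(targets))),
             stringsAsFactors = FALSE)
}

test_that("is_measurable applies both diameter gates", {
  row <- function(ld, perp = NA) data.frame(
    present = TRUE, longest_diameter_mm = ld, perpendicular_diameter_mm = perp)
  expect_true(is_measurable(row(10, 5), cfg))
  expect_false(is_measurable(row(9.9, 5), cfg))
  cfg5 <- assessment_config(measurable_longest_mm = 5)
  expect_false(is_measurable(row(6, 4), cfg5))  # perpendicular gate still binds
  expect_true(is_measurable(row(6), cfg5))      # no perpendicular recorded
  expect_error(is_measurable(data.frame(present = FALSE,
                                        longest_diameter_mm = 0,
                                        perpendicular_diameter_mm = NA), cfg),
               "absent")
})

test_that("A1 fixes up to five of the largest measurable baseline lesions", {
  fig8 <- build_scenario("fig8")
  tl <- designate_a1(fig8, cfg)
  expect_true(all(lengths(tl$targets) == 5L))
  expect_identical(tl$targets[[1L]], c("B1", "B2", "B3", "B4", "B5"))
  expect_false(any(tl$composition_changed))

  solo <- course_from_matrix("solo", months = c(0, 3),
                             ld = rbind(L1 = c(12, 10)),
                             treatments = trt("S", "SRS", 0, "L1"))
  expect_identical(designate_a1(solo, cfg)$targets, list("L1", "L1"))

  # lesions appearing later never become target under A1
  late <- course_from_matrix("late", months = c(0, 3, 6),
                             ld = rbind(L1 = c(12, 11, 10),
                                        N1 = c(NA, 15, 15),
                                        N2 = c(NA, 14, 14),
                                        N3 = c(NA, 12, 12)))
  tl <- designate_a1(late, cfg)
  for (t in 1:2)
    expect_true(all(c("N1", "N2", "N3") %in% tl$nontargets[[t + 1L]]))
})

test_that("A2 add/replace follows the sequential procedure with resets", {
  # five targets of 12,11,10,10,10 mm; a new 15 mm lesion replaces the
  # lexicographically greatest of the minimal (10 mm) targets
  ld <- rbind(L1 = c(12, 12), L2 = c(11, 11), L3 = c(10, 10),
              L4 = c(10, 10), L5 = c(10, 10), N1 = c(NA, 15))
  course <- course_from_matrix("a2rep", months = c(0, 3), ld = ld)
  tl <- designate_a2(course, cfg)
  expect_setequal(tl$targets[[2L]], c("L1", "L2", "L3", "L4", "N1"))
  expect_true("L5" %in% tl$nontargets[[2L]])
  expect_true(tl$composition_changed[2L])
  expect_equal(tl$baseline_sld_mm[2L], 12 + 11 + 10 + 10 + 15)
  expect_equal(tl$nadir_sld_mm[2L], 58)

  # under five targets: the measurable new lesion is added
  ld <- rbind(L1 = c(12, 12), L2 = c(11, 11), L3 = c(10, 10), N1 = c(NA, 12))
  tl <- designate_a2(course_from_matrix("a2add", months = c(0, 3), ld = ld), cfg)
  expect_setequal(tl$targets[[2L]], c("L1", "L2", "L3", "N1"))
  expect_true(tl$composition_changed[2L])

  # below the measurability gate: non-target, no reset
  ld <- rbind(L1 = c(20, 20), L2 = c(20, 20), L3 = c(20, 20),
              L4 = c(20, 20), L5 = c(20, 20), N1 = c(NA, 8))
  tl <- designate_a2(course_from_matrix("a2small", months = c(0, 3), ld = ld), cfg)
  expect_setequal(tl$targets[[2L]], paste0("L", 1:5))
  expect_false(any(tl$composition_changed))
})

test_that("A-Rx designates every treated lesion from its pre-treatment scan", {
  fig8 <- build_scenario("fig8")
  tl <- designate_arx(fig8, cfg)
  expect_identical(lengths(tl$targets), c(7L, 10L, 10L, 10L, 10L, 12L, 12L))
  expect_true(tl$composition_changed[2L] && tl$composition_changed[6L])

  # a treated 4 mm lesion is target despite being non-measurable
  tiny <- course_from_matrix("tiny", months = c(0, 3),
                             ld = rbind(L1 = c(4, 3)),
                             treatments = trt("S", "SRS", 0, "L1"))
  expect_identical(designate_arx(tiny, cfg)$targets[[1L]], "L1")

  # appearing at assessment 2, treated after assessment 3's scan day
  course <- course_from_matrix(
    "latetrt", months = c(0, 3, 6, 9),
    ld = rbind(L0 = c(12, 10, 9, 9), N1 = c(NA, NA, 8, 8)),
    treatments = rbind(trt("S1", "SRS", 0, "L0"),
                       trt("S2", "SRS", 280, "N1")))
  tl <- designate_arx(course, cfg)
  expect_false("N1" %in% tl$targets[[3L]])
  expect_true("N1" %in% tl$targets[[4L]])
})

test_that("sld sums target diameters, absent lesions contributing zero", {
  course <- course_from_matrix("s", months = c(0, 3),
                               ld = rbind(L1 = c(12, 12), L2 = c(8, 0)))
  tl <- designate_a1(course, assessment_config(measurable_longest_mm = 5))
  expect_equal(sld(course, tl, 0L), 20)
  expect_equal(sld(course, tl, 1L), 12)
  none <- course_from_matrix("none", months = c(0, 3),
                             ld = rbind(L1 = c(4, 4))) # nothing measurable
  expect_equal(sld(none, designate_a1(none, cfg), 0L), 0)
})

test_that("policies coincide on single-lesion treated courses", {
  for (seed in 1:25) {
    course <- random_course(seed, clean = TRUE)
    course$measurements <- course$measurements[
      course$measurements$lesion_id == "L1", ]
    course$lesions <- course$lesions[course$lesions$lesion_id == "L1", ]
    course$treatments$targeted_lesion_ids <- I(list("L1"))
    tls <- lapply(c("A1", "A2", "ARx"), function(p)
      designate(course, assessment_config(policy = p)))
    for (f in c("targets", "nontargets", "composition_changed",
                "sld_mm", "baseline_sld_mm", "nadir_sld_mm"))
      expect_identical(tls[[2L]][[f]], tls[[1L]][[f]])
    for (f in c("targets", "nontargets", "composition_changed",
                "sld_mm", "baseline_sld_mm", "nadir_sld_mm"))
      expect_identical(tls[[3L]][[f]], tls[[1L]][[f]])
  }
})

test_that("A-Rx target sets are non-decreasing; A2 respects the cap", {
  for (seed in 1:30) {
    course <- random_course(seed)
    arx <- designate_arx(course, cfg)
    nt <- length(arx$targets)
    if (nt > 1L) for (t in 2:nt)
      expect_true(all(arx$targets[[t - 1L]] %in% arx$targets[[t]]))
    a2 <- designate_a2(course, cfg)
    expect_true(all(lengths(a2$targets) <= cfg$max_targets))
  }
})

test_that("baseline/nadir bookkeeping matches brute-force recomputation", {
  for (seed in 1:40) {
    course <- random_course(seed)
    for (p in c("A1", "A2", "ARx")) {
      tl <- designate(course, assessment_config(policy = p))
      oracle <- oracle_sld_state(course, tl$targets)
      expect_equal(tl$sld_mm, oracle$sld, tolerance = 1e-9)
      expect_identical(tl$composition_changed, oracle$composition_changed)
      expect_equal(tl$baseline_sld_mm, oracle$baseline_sld, tolerance = 1e-9)
      expect_equal(tl$nadir_sld_mm, oracle$nadir_sld, tolerance = 1e-9)
      # resets fire exactly when composition changes
      expect_identical(tl$composition_changed,
                       c(FALSE, diff(tl$reset_index) > 0))
    }
  }
})
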