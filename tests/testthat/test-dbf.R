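cfg <- assessment_config()

test_that("DBF events merge simultaneous lesions and order by day", {
  p1 <- build_scenario("fig6_p1")
  ev1 <- detect_dbf_events(p1, cfg, reference_day = 0)
  expect_identical(nrow(ev1), 3L)
  expect_identical(ev1$event_day, c(122L, 244L, 365L))
  expect_true(all(ev1$count == 1L))

  p2 <- build_scenario("fig6_p2")
  ev2 <- detect_dbf_events(p2, cfg, reference_day = 0)
  expect_identical(nrow(ev2), 1L)
  expect_identical(ev2$count, 6L)

  none <- course_from_matrix("quiet", months = c(0, 3),
                             ld = rbind(L1 = c(12, 10)))
  expect_identical(nrow(detect_dbf_events(none, cfg)), 0L)
})

test_that("unconfirmed terminal appearances are excluded unless requested", {
  ld <- rbind(L1 = c(12, 11, 11), N1 = c(NA, NA, 7))
  course <- course_from_matrix("pend", months = c(0, 3, 6), ld = ld)
  expect_identical(nrow(detect_dbf_events(course, cfg)), 0L)
  ev <- detect_dbf_events(course, cfg, include_pending = TRUE)
  expect_identical(nrow(ev), 1L)
  expect_false(ev$confirmed)
})

test_that("dbf_extent sums counts and sphere-proxy volumes", {
  p1 <- build_scenario("fig6_p1")
  ev <- detect_dbf_events(p1, cfg, reference_day = 0)
  ext <- dbf_extent(ev)
  expect_identical(ext$total_new_lesions, 3L)
  # three 6 mm lesions under the sphere proxy
  expect_equal(ext$total_volume_mm3, 3 * pi / 6 * 216, tolerance = 1e-9)
  ext2 <- dbf_extent(detect_dbf_events(build_scenario("fig6_p2"), cfg, 0))
  expect_identical(ext2$total_new_lesions, 6L)
  empty <- dbf_extent(detect_dbf_events(
    course_from_matrix("q", months = c(0, 3), ld = rbind(L1 = c(12, 10))), cfg))
  expect_identical(empty$total_new_lesions, 0L)
  expect_identical(empty$total_volume_mm3, 0)
})

test_that("latency is the mean inter-event interval anchored at reference", {
  ev <- data.frame(event_day = c(122L, 244L, 365L), count = 1L,
                   volume_mm3 = 0, confirmed = TRUE)
  expect_equal(days_to_months(dbf_latency(ev, 0)), 4, tolerance = 0.01)
  expect_equal(days_to_months(dbf_latency(ev[3L, ], 0)), 12, tolerance = 0.01)
  expect_equal(dbf_latency(ev[1L, ][0L, ], 0), NA_real_)
  # degenerate spacing: one event a single day after the reference
  one <- data.frame(event_day = 1L, count = 1L, volume_mm3 = 0, confirmed = TRUE)
  expect_equal(dbf_latency(one, 0), 1)
  expect_equal(days_to_months(dbf_latency(one, 0)), 1 / 30.44,
               tolerance = 1e-9)
  # equivalent form: last event day / number of events
  for (seed in 1:10) {
    set.seed(seed)
    days <- sort(sample(30:700, sample(1:5, 1)))
    evr <- data.frame(event_day = days, count = 1L, volume_mm3 = 0,
                      confirmed = TRUE)
    expect_equal(dbf_latency(evr, 0), mean(diff(c(0, days))) *
                   length(days) / length(days), tolerance = 1e-12)
    expect_equal(dbf_latency(evr, 0), max(days) / length(days),
                 tolerance = 1e-12)
  }
})

test_that("BMV and vBMV are annualised ratios with the stated linearity", {
  s3 <- list(total_new_lesions = 3, total_volume_mm3 = 0)
  expect_equal(bmv(s3, 0, 365), 3 / (365 / 365.25), tolerance = 1e-9)
  expect_equal(bmv(s3, 0, 365), 3.0, tolerance = 0.01)
  s6 <- list(total_new_lesions = 6, total_volume_mm3 = 0)
  expect_equal(bmv(s6, 0, 365), 6.0, tolerance = 0.01)
  s0 <- list(total_new_lesions = 0, total_volume_mm3 = 0)
  expect_equal(bmv(s0, 0, 500), 0)
  expect_error(bmv(s3, 100, 100), "positive")
  # halving follow-up doubles the velocity; doubling volume doubles vBMV
  sv <- list(total_new_lesions = 2, total_volume_mm3 = 523.6)
  expect_equal(bmv(sv, 0, 180), 2 * bmv(sv, 0, 360), tolerance = 1e-12)
  sv2 <- sv; sv2$total_volume_mm3 <- 2 * sv$total_volume_mm3
  expect_equal(vbmv(sv2, 0, 365), 2 * vbmv(sv, 0, 365), tolerance = 1e-12)
  # one new 10 mm lesion over a year, sphere proxy
  s1 <- list(total_new_lesions = 1,
             total_volume_mm3 = sphere_volume_from_diameter(10))
  expect_equal(vbmv(s1, 0, 365), 523.96, tolerance = 0.01)
})

test_that("later reference days see a subset of the DBF lesions", {
  for (seed in 1:15) {
    course <- random_course(seed)
    days <- course$assessment_days
    ev_all <- detect_dbf_events(course, cfg, reference_day = days[1L])
    ev_late <- detect_dbf_events(course, cfg, reference_day = days[2L])
    expect_true(all(unlist(ev_late$lesion_ids) %in% unlist(ev_all$lesion_ids)),
                info = paste("seed", seed))
  }
})

test_that("equal PD timing but distinguishable extent (paired courses)", {
  r1 <- assess_course(build_scenario("fig4_p1"), cfg)
  r2 <- assess_course(build_scenario("fig4_p2"), cfg)
  expect_identical(r1$time_to_progression_days, r2$time_to_progression_days)
  sys1 <- build_scenario("fig4_p1")$treatments
  day1 <- sys1$start_day[sys1$modality == "systemic"]
  ext1 <- dbf_extent(detect_dbf_events(build_scenario("fig4_p1"), cfg, day1))
  ext2 <- dbf_extent(detect_dbf_events(build_scenario("fig4_p2"), cfg, day1))
  expect_identical(ext1$total_new_lesions, 5L)
  expect_identical(ext2$total_new_lesions, 1L)
})

test_that("dbf_summary composes the pieces coherently", {
  s <- dbf_summary(build_scenario("fig6_p1"), cfg, reference_day = 0,
                   last_followup_day = 365)
  expect_identical(s$total_new_lesions, 3L)
  expect_equal(s$latency_months, 4, tolerance = 0.01)
  expect_equal(s$bmv_per_year, 3.0, tolerance = 0.01)
  expect_equal(s$vbmv_mm3_per_year,
               3 * sphere_volume_from_diameter(6) / (365 / 365.25),
               tolerance = 1e-6)
})
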