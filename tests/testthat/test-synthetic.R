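test_that("a noiseless stable spec yields a constant stream at baselines", {
  sp <- trajectory_spec(noise_sd = stats::setNames(rep(0, 9), mprt_params()),
                        duration = 60)
  g <- generate_patient(sp, seed = 1)
  expect_equal(g$vitals$timestamp, seq(0, 60, by = 5))
  for (p in mprt_params()) {
    expect_equal(g$vitals[[p]], rep(default_baselines()[[p]], 13), info = p)
  }
  expect_false(g$outcome$deteriorated)
})

test_that("identical (spec, seed) pairs reproduce streams bit for bit", {
  sp <- trajectory_spec(duration = 360, artifact_rate = 4,
                        missing_prob = 0.02)
  a <- generate_patient(sp, seed = 123)
  b <- generate_patient(sp, seed = 123)
  expect_identical(a, b)
  c <- generate_patient(sp, seed = 124)
  expect_false(identical(a$vitals, c$vitals))

  co1 <- generate_cohort(3, 0, sp, seed = 9)
  co2 <- generate_cohort(3, 0, sp, seed = 9)
  expect_identical(co1, co2)
})

test_that("the generator does not disturb the caller's RNG state", {
  set.seed(77)
  before <- stats::runif(1)
  set.seed(77)
  invisible(generate_patient(trajectory_spec(duration = 60), seed = 5))
  expect_identical(stats::runif(1), before)
})

test_that("noiseless three-parameter deterioration confirms HIGH at the second qualifying reading", {
  presets <- deterioration_presets(onset = 120, ramp = 120)
  sp <- trajectory_spec(noise_sd = stats::setNames(rep(0, 9), mprt_params()),
                        duration = 360,
                        deterioration = presets$copd)
  g <- generate_patient(sp, seed = 1)
  ev <- confirm_events(score_stream(g$vitals))
  inst2 <- vapply(seq_len(nrow(ev)), function(i) {
    s <- unlist(ev[i, paste0("s_", mprt_params())])
    sum(s >= 2, na.rm = TRUE) >= 3
  }, logical(1))
  first3 <- which(inst2)[1]
  expect_false(is.na(first3))
  # confirmed HIGH appears exactly one reading after instantaneous HIGH
  firsthigh <- which(ev$confirmed_mprt %in% c("HIGH", "URGENT"))[1]
  expect_equal(firsthigh, first3 + 1L)
  expect_equal(g$outcome$deterioration_time, 240)
})

test_that("cohort bookkeeping annotates deteriorating patients", {
  expect_equal(nrow(generate_cohort(0, 0, seed = 1)$vitals), 0)
  presets <- deterioration_presets(onset = 60, ramp = 60)
  det <- trajectory_spec(duration = 240, deterioration = presets$chf)
  co <- generate_cohort(10, 5, trajectory_spec(duration = 240), det,
                        seed = 3)
  expect_equal(length(unique(co$vitals$patient_id)), 15)
  expect_equal(sum(co$outcomes$deteriorated), 5)
  expect_equal(sum(!is.na(co$outcomes$deterioration_time)), 5)
  expect_true(all(co$outcomes$deterioration_time[co$outcomes$deteriorated]
                  == 120))
})

test_that("artifacts are isolated single-reading excursions", {
  sp <- trajectory_spec(noise_sd = stats::setNames(rep(0, 9), mprt_params()),
                        duration = 1440, artifact_rate = 8)
  g <- generate_patient(sp, seed = 11)
  sc <- score_stream(g$vitals)
  urgent <- which(sc$instant_mprt == "URGENT")
  expect_gt(length(urgent), 0)
  expect_true(all(diff(urgent) >= 2))  # never two in a row
})

test_that("missingness inserts NA at roughly the requested rate", {
  sp <- trajectory_spec(duration = 4320, missing_prob = 0.05)
  g <- generate_patient(sp, seed = 19)
  rate <- mean(is.na(as.matrix(g$vitals[mprt_params()])))
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("invalid trajectory specs are rejected", {
  expect_error(trajectory_spec(cadence = 0), class = "mprtws_validation_error")
  expect_error(trajectory_spec(ar = 1), class = "mprtws_validation_error")
  expect_error(trajectory_spec(duration = 100,
                               deterioration = list(onset = 60,
                                                    params = "hr",
                                                    target_score = 2,
                                                    ramp = 60)),
               class = "mprtws_validation_error")
  expect_error(trajectory_spec(deterioration = list(onset = 0,
                                                    params = "lactate",
                                                    target_score = 2,
                                                    ramp = 60)),
               class = "mprtws_validation_error")
})
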