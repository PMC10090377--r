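test_that("confirmation requires persistence over consecutive readings", {
  pol <- confirmation_policy()  # 2 readings within 10 min
  t <- c(0, 5, 10)
  expect_equal(confirm_levels(c("LOW", "HIGH", "LOW"), t, pol),
               c("LOW", "LOW", "LOW"))      # isolated spike suppressed
  expect_equal(confirm_levels(c("HIGH", "HIGH", "LOW"), t, pol),
               c("LOW", "HIGH", "LOW"))
  expect_equal(confirm_levels(c("HIGH", "URGENT"), c(0, 5), pol),
               c("LOW", "HIGH"))            # highest L with both >= L
  expect_equal(confirm_levels(character(0), numeric(0), pol), character(0))
  expect_error(confirm_levels(c("LOW", "LOW"), c(5, 0), pol),
               class = "mprtws_validation_error")
})

test_that("a gap wider than the span resets persistence", {
  pol <- confirmation_policy()
  expect_equal(confirm_levels(c("HIGH", "HIGH", "HIGH"), c(0, 5, 30), pol),
               c("LOW", "HIGH", "LOW"))
  # at a 15-min cadence with the strict 10-min span nothing confirms
  expect_equal(confirm_levels(rep("URGENT", 4), c(0, 15, 30, 45), pol),
               rep("LOW", 4))
  # the widened policy for that cadence confirms from the second reading
  pol15 <- confirmation_policy(interval = 15)
  expect_equal(pol15$max_span, 30)
  expect_equal(confirm_levels(rep("URGENT", 4), c(0, 15, 30, 45), pol15),
               c("LOW", rep("URGENT", 3)))
})

test_that("confirmed <= instantaneous; min_consecutive = 1 is the identity", {
  set.seed(41)
  pol1 <- confirmation_policy(min_consecutive = 1)
  pol2 <- confirmation_policy()
  for (i in 1:50) {
    n <- sample(1:30, 1)
    lv <- sample(mprt_levels(), n, replace = TRUE,
                 prob = c(0.7, 0.1, 0.1, 0.1))
    t <- cumsum(sample(c(5, 5, 5, 20), n, replace = TRUE))
    expect_equal(confirm_levels(lv, t, pol1), lv)
    conf <- confirm_levels(lv, t, pol2)
    expect_true(all(match(conf, mprt_levels()) <= match(lv, mprt_levels())))
    expect_equal(conf[1], "LOW")
  }
})

test_that("event counts are invariant to patient concatenation order", {
  set.seed(43)
  presets <- deterioration_presets(onset = 120, ramp = 120)
  det <- trajectory_spec(duration = 480, deterioration = presets$copd)
  co <- generate_cohort(2, 2, trajectory_spec(duration = 480), det,
                        seed = 99)
  ev <- confirm_events(score_stream(co$vitals))
  v2 <- co$vitals[order(match(co$vitals$patient_id,
                              rev(unique(co$vitals$patient_id))),
                        co$vitals$timestamp), ]
  ev2 <- confirm_events(score_stream(v2))
  expect_equal(event_counts(ev, "mprt"), event_counts(ev2, "mprt"))
  expect_equal(event_counts(ev, "news"), event_counts(ev2, "news"))
})

test_that("unscorable readings carry no confirmed level and are not counted", {
  v <- make_vitals(5)
  v[3, c("hr", "spo2", "rr", "sbp")] <- NA
  ev <- confirm_events(score_stream(v))
  expect_true(is.na(ev$confirmed_mprt[3]))
  expect_equal(sum(event_counts(ev, "mprt")), 4L)
})

test_that("resampling keeps the grid-nearest reading, ties to earlier", {
  v <- make_vitals(13)  # 0..60 by 5
  expect_equal(resample_stream(v, 5)$timestamp, v$timestamp)
  r15 <- resample_stream(v, 15)
  expect_equal(r15$timestamp, c(0, 15, 30, 45, 60))
  expect_equal(resample_stream(make_vitals(2), 30)$timestamp, 0)
  expect_error(resample_stream(v, 0), class = "mprtws_validation_error")

  # jittered stream vs exhaustive-search oracle
  set.seed(47)
  vj <- make_vitals(40)
  vj$timestamp <- sort(cumsum(stats::runif(40, 2, 8)))
  got <- resample_stream(vj, 15)$timestamp
  t0 <- vj$timestamp[1]
  grid <- seq(t0, max(vj$timestamp), by = 15)
  want <- sort(unique(vapply(grid, function(g) {
    d <- abs(vj$timestamp - g)
    vj$timestamp[which(d == min(d))[1]]
  }, numeric(1))))
  expect_equal(got, want)
})

test_that("first_alert scans for the earliest confirmed alert", {
  v <- make_vitals(4)
  ev <- confirm_events(score_stream(v))
  ev$confirmed_mprt <- c("LOW", "HIGH", "LOW", "URGENT")
  expect_equal(first_alert(ev)$first_alert_time, 5)
  expect_equal(first_alert(ev, "URGENT")$first_alert_time, 15)
  ev$confirmed_mprt <- rep("LOW", 4)
  expect_true(is.na(first_alert(ev)$first_alert_time))
  expect_error(first_alert(ev, character(0)),
               class = "mprtws_validation_error")
})
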