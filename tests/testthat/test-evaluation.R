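test_that("level shares recompute from event counts with half-up rounding", {
  d <- level_distribution(c(LOW = 85247, MEDIUM = 5924, HIGH = 624))
  expect_equal(d$percent[d$level == "LOW"], 92.9)
  expect_equal(d$percent[d$level == "HIGH"], 0.7)
  d2 <- level_distribution(c(LOW = 108782, MEDIUM = 7158, HIGH = 1491))
  expect_equal(d2$percent[d2$level == "HIGH"], 1.3)
  expect_equal(level_distribution(c(LOW = 17))$percent, 100)
  expect_error(level_distribution(c(LOW = 0, HIGH = 0)),
               class = "mprtws_validation_error")
})

test_that("round_half_up rounds ties away from zero", {
  expect_equal(round_half_up(6.45, 1), 6.5)
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(-6.45, 1), -6.5)
  expect_equal(round_half_up(58.97436), 59)
})

test_that("sensitivity is the identified fraction and is monotone", {
  expect_equal(sensitivity(23, 39), 23 / 39)
  expect_equal(sensitivity(4, 39), 4 / 39)
  expect_equal(sensitivity(0, 10), 0)
  for (a in 0:11) {
    expect_gte(sensitivity(a + 1, 12), sensitivity(a, 12))
  }
  expect_error(sensitivity(1, 0), class = "mprtws_validation_error")
  expect_error(sensitivity(5, 4), class = "mprtws_validation_error")
})

test_that("lead times use strictly-before alerts and sample SD in hours", {
  out <- data.frame(patient_id = c("A", "B", "C"),
                    deteriorated = c(TRUE, TRUE, TRUE),
                    deterioration_time = c(1200, 2400, 600))
  al <- data.frame(patient_id = c("A", "B", "C"),
                   first_alert_time = c(600, 600, 600))
  lt <- lead_times(al, out)
  # C alerted exactly at deterioration -> not identified
  expect_equal(lt$n_identified, 2L)
  expect_equal(sort(lt$per_patient$lead_h), c(10, 30))
  expect_equal(lt$mean_h, 20)
  expect_equal(lt$sd_h, sqrt(200), tolerance = 1e-12)  # 14.142...

  one <- lead_times(al[1, ], out[1, ])
  expect_equal(one$n_identified, 1L)
  expect_true(is.na(one$sd_h))

  # invariance under a global time shift
  out2 <- out; out2$deterioration_time <- out$deterioration_time + 5000
  al2 <- al; al2$first_alert_time <- al$first_alert_time + 5000
  expect_equal(lead_times(al2, out2)$mean_h, lt$mean_h)
})

test_that("chi-square comparison matches direct O/E summation", {
  a <- c(LOW = 10, HIGH = 10)
  expect_equal(compare_distributions(a, a)$statistic, 0)
  expect_equal(compare_distributions(a, a)$p_value, 1)

  r <- suppressWarnings(
    compare_distributions(c(x = 20, y = 10), c(x = 10, y = 20)))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(r$df, 1)

  set.seed(53)
  for (i in 1:50) {
    tab <- matrix(sample(5:80, 6), nrow = 2)
    ca <- stats::setNames(tab[1, ], c("L", "M", "H"))
    cb <- stats::setNames(tab[2, ], c("L", "M", "H"))
    r <- suppressWarnings(compare_distributions(ca, cb))
    expect_equal(r$statistic, chisq_oracle(tab), tolerance = 1e-10)
    expect_equal(r$df, 2)
  }
  expect_error(compare_distributions(c(a = 1), c(b = 1)),
               class = "mprtws_validation_error")
})

test_that("Fisher comparison equals exhaustive hypergeometric enumeration", {
  expect_equal(compare_identified(5, 5, 20), 1)
  expect_equal(compare_identified(3, 0, 3), 0.1, tolerance = 1e-12)
  expect_equal(compare_identified(0, 0, 7), 1)
  for (a in 0:7) {
    for (b in 0:7) {
      expect_equal(compare_identified(a, b, 7),
                   fisher_oracle(a, 7 - a, b, 7 - b),
                   tolerance = 1e-8,
                   info = sprintf("a=%d b=%d", a, b))
    }
  }
  expect_error(compare_identified(-1, 0, 5),
               class = "mprtws_validation_error")
})

test_that("attribution counts abnormal parameters among confirmed readings", {
  v <- make_vitals(4)
  v$spo2[2] <- 85       # score 3
  v$sbp[3] <- 95        # score 2
  ev <- confirm_events(score_stream(v))
  ev$confirmed_mprt <- c("LOW", "URGENT", "HIGH", "HIGH")
  a_u <- attribution(ev, "URGENT")
  expect_equal(unname(a_u["spo2"]), 1)
  expect_equal(sum(a_u), 1)  # all other parameters normal
  a_h <- attribution(ev, "HIGH")
  expect_equal(unname(a_h["sbp"]), 0.5)
  expect_warning(a0 <- attribution(ev, "MEDIUM"), "no readings")
  expect_length(a0, 0)
})

test_that("group segmentation summarizes per-patient counts by quartiles", {
  v <- do.call(rbind, lapply(1:5, function(i) make_vitals(6, paste0("P", i))))
  class(v) <- c("vitals", "data.frame")
  # patient i gets i readings with spo2 and sbp in 2-bands (i consecutive)
  for (i in 1:5) {
    rows <- which(v$patient_id == paste0("P", i))[seq_len(i)]
    v$spo2[rows] <- 93
    v$sbp[rows] <- 95
    v$dbp[rows] <- 45
  }
  ev <- confirm_events(score_stream(v))
  groups <- data.frame(patient_id = paste0("P", 1:5), group = "g")
  seg <- segment_by_group(ev, groups)
  # confirmed HIGH counts per patient: patient 1 has a lone spike -> 0,
  # patient i >= 2 confirms on readings 2..i -> i - 1 alert readings
  per <- seg$per_patient[seg$per_patient$parameter == "spo2", ]
  expect_equal(per$n_alert_readings[order(per$patient_id)], c(0, 1, 2, 3, 4))
  sm <- seg$summary[seg$summary$parameter == "spo2", ]
  expect_equal(sm$median, stats::median(c(0, 1, 2, 3, 4)))
  expect_equal(sm$q1, unname(stats::quantile(c(0, 1, 2, 3, 4), 0.25)))
  expect_equal(sm$q3, unname(stats::quantile(c(0, 1, 2, 3, 4), 0.75)))
  expect_equal(sm$n_outliers, 0)

  # identical patients -> zero IQR
  v2 <- v[v$patient_id %in% c("P3", "P4"), ]
  v2$patient_id <- rep(c("Q1", "Q2"), each = 6)
  v2$spo2 <- 93; v2$sbp <- 95; v2$dbp <- 45
  class(v2) <- c("vitals", "data.frame")
  ev2 <- confirm_events(score_stream(v2))
  seg2 <- segment_by_group(ev2, data.frame(patient_id = c("Q1", "Q2"),
                                           group = "g"))
  sm2 <- seg2$summary[seg2$summary$parameter == "sbp", ]
  expect_equal(sm2$q1, sm2$q3)

  expect_error(segment_by_group(ev, groups[1:3, ]),
               class = "mprtws_validation_error")
})
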