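#' Level distribution of confirmed events
#'
#' Counts confirmed readings per level and converts them to percentages of
#' the total over the reported level set, rounded half-up to one decimal.
#' The denominator is the sum over exactly the levels supplied, so URGENT
#' can be reported inside the total (all four MPRT-WS levels) or kept out of
#' an EWS-style Low/Medium/High breakdown by passing three-level counts.
#'
#' @param counts Named integer vector of per-level confirmed event counts
#'   (e.g. from [event_counts()], possibly subset), or a
#'   `confirmed_events` data frame together with `tool` and `levels`.
#' @param tool,levels When `counts` is an events data frame: which tool's
#'   confirmed column to tabulate and which levels form the reported set.
#' @return A data frame with columns `level`, `count`, `percent`.
#' @examples
#' level_distribution(c(LOW = 85247, MEDIUM = 5924, HIGH = 624))
#' @export
level_distribution <- function(counts, tool = "mprt", levels = NULL) {
  if (is.data.frame(counts)) {
    counts <- event_counts(counts, tool)
    if (!is.null(levels)) counts <- counts[levels]
  }
  if (sum(counts) == 0) stop_validation("no readings: empty cohort")
  data.frame(level = names(counts),
             count = as.integer(counts),
             percent = round_half_up(100 * counts / sum(counts), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Detection sensitivity
#'
#' The fraction of deteriorating patients identified by the system: patients
#' whose first confirmed alert precedes their recorded deterioration,
#' divided by all patients with recorded deterioration.
#'
#' @param n_identified Number identified (0 <= `n_identified` <=
#'   `n_deteriorated`).
#' @param n_deteriorated Number of deteriorated patients (> 0).
#' @return Fraction in `[0, 1]`.
#' @examples
#' sensitivity(23, 39)  # 0.5897...
#' @export
sensitivity <- function(n_identified, n_deteriorated) {
  if (n_deteriorated <= 0) stop_validation("n_deteriorated must be positive")
  if (n_identified < 0 || n_identified > n_deteriorated) {
    stop_validation("need 0 <= n_identified <= n_deteriorated")
  }
  n_identified / n_deteriorated
}

#' Alert lead times before deterioration
#'
#' A deteriorating patient counts as identified when their first confirmed
#' alert falls strictly before the recorded deterioration time; the lead
#' time is the gap in hours. Patients alerting only at or after
#' deterioration are not identified.
#'
#' @param alerts Data frame from [first_alert()].
#' @param outcomes Outcomes data frame ([read_outcomes()]).
#' @return A list: `per_patient` (data frame of identified patients with
#'   `lead_h`), `n_identified`, `n_deteriorated`, `sensitivity`, `mean_h`,
#'   `sd_h` (both `NA` when no or a single patient is identified,
#'   respectively).
#' @export
lead_times <- function(alerts, outcomes) {
  det <- outcomes[outcomes$deteriorated, , drop = FALSE]
  m <- merge(det, alerts, by = "patient_id", all.x = TRUE)
  ident <- !is.na(m$first_alert_time) &
    m$first_alert_time < m$deterioration_time
  lead_h <- (m$deterioration_time[ident] - m$first_alert_time[ident]) / 60
  per <- data.frame(patient_id = m$patient_id[ident], lead_h = lead_h,
                    stringsAsFactors = FALSE)
  n_id <- sum(ident)
  list(per_patient = per,
       n_identified = n_id,
       n_deteriorated = nrow(det),
       sensitivity = if (nrow(det) > 0) n_id / nrow(det) else NA_real_,
       mean_h = if (n_id > 0) mean(lead_h) else NA_real_,
       sd_h = if (n_id > 1) stats::sd(lead_h) else NA_real_)
}

#' Chi-square comparison of two level distributions
#'
#' Pearson chi-square (no continuity correction) on the 2 x k contingency
#' table of per-level event counts from two tools; k - 1 degrees of freedom.
#'
#' @param counts_a,counts_b Named count vectors over the same level set.
#' @return A list with `statistic`, `df`, `p_value`.
#' @export
compare_distributions <- function(counts_a, counts_b) {
  if (!identical(names(counts_a), names(counts_b))) {
    stop_validation("count vectors must share the same ordered level set")
  }
  tab <- rbind(counts_a, counts_b)
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Fisher exact comparison of identified-patient counts
#'
#' Two-sided Fisher exact test on the 2 x 2 table
#' (identified / not identified) x (tool A / tool B) among deteriorated
#' patients.
#'
#' @param identified_a,identified_b Patients identified by each tool.
#' @param n_deteriorated Deteriorated patients (same denominator for both).
#' @return Two-sided p-value.
#' @examples
#' compare_identified(23, 4, 39)
#' @export
compare_identified <- function(identified_a, identified_b, n_deteriorated) {
  if (identified_a < 0 || identified_b < 0) {
    stop_validation("identified counts must be non-negative")
  }
  if (identified_a > n_deteriorated || identified_b > n_deteriorated) {
    stop_validation("identified counts cannot exceed n_deteriorated")
  }
  tab <- matrix(c(identified_a, n_deteriorated - identified_a,
                  identified_b, n_deteriorated - identified_b), nrow = 2)
  if (sum(tab) == 0) return(1)
  stats::fisher.test(tab)$p.value
}

#' Per-parameter attribution of confirmed alerts
#'
#' Over the readings confirmed at a target level, the fraction in which each
#' parameter's score meets the abnormality criterion: score 3 for the URGENT
#' panel, score >= 2 otherwise (both overridable). Fractions need not sum
#' to 1 — several parameters can be abnormal in one reading.
#'
#' @param events A `confirmed_events` data frame (MPRT-WS columns).
#' @param level Target confirmed level.
#' @param min_score Abnormality criterion; default 3 for URGENT, 2 for other
#'   levels.
#' @return Named numeric vector, one fraction in `[0, 1]` per parameter;
#'   empty (with a warning) when no reading is confirmed at `level`.
#' @export
attribution <- function(events, level,
                        min_score = if (identical(level, "URGENT")) 3L else 2L) {
  i <- which(events$scorable & events$confirmed_mprt %in% level)
  if (!length(i)) {
    warning("no readings confirmed at level ", paste(level, collapse = "/"))
    return(stats::setNames(numeric(0), character(0)))
  }
  vapply(mprt_params(), function(p) {
    s <- events[[paste0("s_", p)]][i]
    mean(!is.na(s) & s >= min_score)
  }, numeric(1))
}

#' Segment alert burden by diagnosis group
#'
#' For each patient, counts the confirmed readings at the alert levels in
#' which each parameter is abnormal (score >= `min_score`), then summarizes
#' the per-patient counts within each diagnosis group by median, quartiles,
#' 1.5 x IQR whiskers, and the number of outliers beyond the whiskers.
#'
#' @param events A `confirmed_events` data frame.
#' @param groups Data frame with columns `patient_id` and `group`; every
#'   patient in `events` must carry a known label.
#' @param alert_levels Levels counting as alerts (default High/Urgent).
#' @param min_score Per-parameter abnormality criterion (default 2).
#' @return A list: `per_patient` (long data frame of patient x parameter
#'   counts with group labels) and `summary` (group x parameter median, q1,
#'   q3, whisker_low, whisker_high, n_outliers).
#' @export
segment_by_group <- function(events, groups,
                             alert_levels = c("HIGH", "URGENT"),
                             min_score = 2L) {
  if (!all(c("patient_id", "group") %in% names(groups))) {
    stop_validation("groups must have columns patient_id and group")
  }
  pids <- unique(events$patient_id)
  lab <- groups$group[match(pids, groups$patient_id)]
  if (anyNA(lab)) {
    stop_validation("unknown group label for patient '",
                    pids[which(is.na(lab))[1]], "'")
  }
  rows <- list()
  for (j in seq_along(pids)) {
    i <- which(events$patient_id == pids[j] & events$scorable &
                 events$confirmed_mprt %in% alert_levels)
    cnt <- vapply(mprt_params(), function(p) {
      s <- events[[paste0("s_", p)]][i]
      sum(!is.na(s) & s >= min_score)
    }, numeric(1))
    rows[[j]] <- data.frame(patient_id = pids[j], group = lab[j],
                            parameter = mprt_params(),
                            n_alert_readings = as.integer(cnt),
                            stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  sm <- do.call(rbind, lapply(split(per, list(per$group, per$parameter),
                                    drop = TRUE), function(d) {
    q <- stats::quantile(d$n_alert_readings, c(0.25, 0.5, 0.75), type = 7)
    iqr <- q[3] - q[1]
    wl <- q[1] - 1.5 * iqr
    wh <- q[3] + 1.5 * iqr
    data.frame(group = d$group[1], parameter = d$parameter[1],
               median = unname(q[2]), q1 = unname(q[1]), q3 = unname(q[3]),
               whisker_low = unname(wl), whisker_high = unname(wh),
               n_outliers = sum(d$n_alert_readings < wl |
                                  d$n_alert_readings > wh),
               stringsAsFactors = FALSE)
  }))
  rownames(sm) <- NULL
  list(per_patient = per, summary = sm)
}

#' Cohort evaluation report
#'
#' Assembles the full evaluation for one scored and confirmed cohort:
#' per-tool level distributions, the chi-square comparison of the two
#' distributions over Low/Medium/High, sensitivity and lead-time statistics
#' per tool, the Fisher exact comparison of identified counts, and
#' per-parameter attribution per MPRT-WS level.
#'
#' @param events A `confirmed_events` data frame holding both tools'
#'   confirmed levels.
#' @param outcomes Outcomes data frame, or `NULL` to skip
#'   sensitivity/lead-time sections.
#' @param alert_levels_mprt,alert_levels_news Levels counting as alerts for
#'   each tool.
#' @return A list of class `evaluation_report`.
#' @export
evaluate_cohort <- function(events, outcomes = NULL,
                            alert_levels_mprt = c("HIGH", "URGENT"),
                            alert_levels_news = "HIGH") {
  cm <- event_counts(events, "mprt")
  rep <- list(
    counts_mprt = cm,
    dist_mprt = level_distribution(cm[c("LOW", "MEDIUM", "HIGH")]),
    dist_mprt_all = level_distribution(cm),
    urgent_percent = round_half_up(100 * cm[["URGENT"]] / sum(cm), 1)
  )
  has_news <- "confirmed_news" %in% names(events)
  if (has_news) {
    cn <- event_counts(events, "news")
    rep$counts_news <- cn
    rep$dist_news <- level_distribution(cn)
    rep$chi2 <- compare_distributions(cm[c("LOW", "MEDIUM", "HIGH")], cn)
  }
  if (!is.null(outcomes)) {
    if (!any(outcomes$deteriorated)) {
      warning("no deteriorated patients: sensitivity section omitted")
    } else {
      lt_m <- lead_times(first_alert(events, alert_levels_mprt, "mprt"),
                         outcomes)
      rep$mprt <- lt_m
      if (has_news) {
        lt_n <- lead_times(first_alert(events, alert_levels_news, "news"),
                           outcomes)
        rep$news <- lt_n
        rep$fisher_p <- compare_identified(lt_m$n_identified,
                                           lt_n$n_identified,
                                           lt_m$n_deteriorated)
      }
    }
  }
  rep$attribution <- suppressWarnings(
    lapply(stats::setNames(nm = c("MEDIUM", "HIGH", "URGENT")),
           function(lv) attribution(events, lv))
  )
  class(rep) <- "evaluation_report"
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Cohort evaluation\n")
  cat("MPRT-WS level distribution (Low/Medium/High):\n")
  print(x$dist_mprt, row.names = FALSE)
  cat(sprintf("Urgent readings: %d (%.1f%% of all readings)\n",
              x$counts_mprt[["URGENT"]], x$urgent_percent))
  if (!is.null(x$dist_news)) {
    cat("NEWS level distribution:\n")
    print(x$dist_news, row.names = FALSE)
    cat(sprintf("Chi-square (2 x 3): %.3f, df %d, p = %.3g\n",
                x$chi2$statistic, x$chi2$df, x$chi2$p_value))
  }
  if (!is.null(x$mprt)) {
    cat(sprintf("MPRT-WS: identified %d / %d (sensitivity %s%%), lead %s +/- %s h\n",
                x$mprt$n_identified, x$mprt$n_deteriorated,
                fmt_or_na(100 * x$mprt$sensitivity),
                fmt_or_na(x$mprt$mean_h), fmt_or_na(x$mprt$sd_h)))
  }
  if (!is.null(x$news)) {
    cat(sprintf("NEWS:    identified %d / %d (sensitivity %s%%), lead %s +/- %s h\n",
                x$news$n_identified, x$news$n_deteriorated,
                fmt_or_na(100 * x$news$sensitivity),
                fmt_or_na(x$news$mean_h), fmt_or_na(x$news$sd_h)))
    cat(sprintf("Fisher exact p (identified counts): %.3g\n", x$fisher_p))
  }
  invisible(x)
}

fmt_or_na <- function(x) {
  if (is.null(x) || is.na(x)) "NA" else sprintf("%.1f", x)
}
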