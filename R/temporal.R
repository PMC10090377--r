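#' Temporal confirmation policy
#'
#' An alert level is confirmed only after it persists: the last
#' `min_consecutive` readings (including the current one) must all sit at or
#' above that level, and their timestamps must span at most `max_span`
#' minutes. The default — two consecutive readings within 10 minutes at the
#' native 5-minute cadence — suppresses single-reading artifacts while
#' delaying a true alert by one reading. At a coarser monitoring interval the
#' span should widen with the cadence; [confirmation_policy()] takes an
#' optional `interval` and sets `max_span = min_consecutive * interval` when
#' the interval exceeds the native cadence.
#'
#' @param min_consecutive Number of consecutive qualifying readings
#'   (integer, >= 1; default 2). With 1 the confirmed stream equals the
#'   instantaneous stream.
#' @param max_span Maximum span, in minutes, of the qualifying window
#'   (default 10).
#' @param interval Optional monitoring interval in minutes; when larger than
#'   5 (the native cadence), `max_span` defaults to
#'   `min_consecutive * interval`.
#' @return A list of class `confirmation_policy`.
#' @export
confirmation_policy <- function(min_consecutive = 2L, max_span = 10,
                                interval = NULL) {
  if (!is.null(interval) && interval > 5 && missing(max_span)) {
    max_span <- min_consecutive * interval
  }
  if (min_consecutive < 1) stop_validation("min_consecutive must be >= 1")
  if (max_span <= 0) stop_validation("max_span must be positive")
  structure(list(min_consecutive = as.integer(min_consecutive),
                 max_span = as.numeric(max_span)),
            class = "confirmation_policy")
}

#' Confirm a time-ordered sequence of instantaneous levels
#'
#' The confirmed level at reading *t* is the highest level *L* such that the
#' last `min_consecutive` readings (ending at *t*) all have instantaneous
#' level at or above *L* and their timestamps span at most `max_span`
#' minutes; if no level above `LOW` qualifies, the confirmed level is `LOW`.
#' The first `min_consecutive - 1` readings of a stream, and any reading
#' whose qualifying window is broken by a gap wider than `max_span`, can
#' only confirm `LOW`. Equivalently, within a qualifying window the
#' confirmed level is the minimum instantaneous level, so confirmed never
#' exceeds instantaneous.
#'
#' @param levels Character vector of instantaneous levels, time-ordered.
#' @param timestamps Numeric timestamps (minutes), strictly increasing.
#' @param policy A [confirmation_policy()].
#' @return Character vector of confirmed levels, same length as `levels`.
#' @examples
#' pol <- confirmation_policy()
#' confirm_levels(c("LOW", "HIGH", "LOW"), c(0, 5, 10), pol)   # all LOW
#' confirm_levels(c("HIGH", "HIGH", "LOW"), c(0, 5, 10), pol)  # LOW HIGH LOW
#' @export
confirm_levels <- function(levels, timestamps, policy = confirmation_policy()) {
  n <- length(levels)
  if (length(timestamps) != n) {
    stop_validation("levels and timestamps must have equal length")
  }
  if (n == 0) return(character(0))
  if (any(diff(timestamps) <= 0)) {
    stop_validation("timestamps must be strictly increasing")
  }
  bad <- !(levels %in% mprt_levels())
  if (any(bad)) {
    stop_validation("unknown level: ", levels[which(bad)[1]])
  }
  k <- policy$min_consecutive
  rk <- level_rank(levels)
  out <- rep(1L, n)
  if (k == 1L) {
    out <- rk
  } else if (n >= k) {
    idx <- k:n
    # running minimum rank over each k-window, and the window's time span
    winmin <- rk[idx]
    for (j in 1:(k - 1)) winmin <- pmin(winmin, rk[idx - j])
    span <- timestamps[idx] - timestamps[idx - (k - 1)]
    out[idx] <- ifelse(span <= policy$max_span, winmin, 1L)
  }
  rank_level(out)
}

#' Confirm scored readings and count events
#'
#' Applies [confirm_levels()] per patient over the scorable readings of a
#' scored cohort, for the MPRT-WS levels and, when present, the NEWS levels
#' (the "temporal NEWS" variant). Unscorable readings keep a missing
#' confirmed level and do not participate in any persistence window.
#'
#' @param scored A `scored_vitals` data frame from [score_stream()].
#' @param policy A [confirmation_policy()].
#' @return The input with added columns `confirmed_mprt` (and
#'   `confirmed_news` when NEWS levels are present), of class
#'   `confirmed_events`.
#' @seealso [event_counts()], [first_alert()]
#' @export
confirm_events <- function(scored, policy = confirmation_policy()) {
  out <- scored
  out$confirmed_mprt <- rep(NA_character_, nrow(out))
  has_news <- "instant_news" %in% names(scored)
  if (has_news) out$confirmed_news <- rep(NA_character_, nrow(out))
  for (pid in unique(out$patient_id)) {
    i <- which(out$patient_id == pid & out$scorable)
    if (!length(i)) next
    out$confirmed_mprt[i] <- confirm_levels(out$instant_mprt[i],
                                            out$timestamp[i], policy)
    if (has_news) {
      out$confirmed_news[i] <- confirm_levels(out$instant_news[i],
                                              out$timestamp[i], policy)
    }
  }
  class(out) <- c("confirmed_events", class(scored))
  out
}

#' Count confirmed events per level
#'
#' An event is one confirmed reading at a level; counts are taken over all
#' scorable readings of the cohort.
#'
#' @param events A `confirmed_events` data frame.
#' @param tool `"mprt"` or `"news"`.
#' @return Named integer vector over the tool's level set.
#' @export
event_counts <- function(events, tool = c("mprt", "news")) {
  tool <- match.arg(tool)
  col <- paste0("confirmed_", tool)
  if (!col %in% names(events)) {
    stop_validation("no confirmed levels for tool '", tool, "'")
  }
  lv <- if (tool == "mprt") mprt_levels() else news_levels()
  cnt <- table(factor(events[[col]][events$scorable], levels = lv))
  stats::setNames(as.integer(cnt), lv)
}

#' Down-sample a vitals stream to a coarser monitoring interval
#'
#' Retains, for each interval-aligned grid instant (anchored at each
#' patient's first reading), the reading nearest in time, breaking ties
#' toward the earlier reading. Output is time-ordered with no duplicates.
#'
#' @param vitals A `vitals` data frame.
#' @param interval Target interval in minutes (>= the native cadence).
#' @return A `vitals` data frame on the coarser grid.
#' @examples
#' \dontrun{
#' v15 <- resample_stream(v, 15)
#' }
#' @export
resample_stream <- function(vitals, interval) {
  if (!is.numeric(interval) || interval <= 0) {
    stop_validation("interval must be a positive number of minutes")
  }
  keep <- logical(nrow(vitals))
  for (pid in unique(vitals$patient_id)) {
    i <- which(vitals$patient_id == pid)
    t <- vitals$timestamp[i]
    grid <- seq(t[1], t[length(t)], by = interval)
    sel <- vapply(grid, function(g) {
      d <- abs(t - g)
      i[which(d == min(d))[1]]  # ties -> earlier reading
    }, integer(1))
    keep[unique(sel)] <- TRUE
  }
  out <- vitals[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' First confirmed alert per patient
#'
#' @param events A `confirmed_events` data frame.
#' @param alert_levels Non-empty set of levels counting as an alert
#'   (default `c("HIGH", "URGENT")`).
#' @param tool `"mprt"` or `"news"`.
#' @return A data frame with one row per patient: `patient_id` and
#'   `first_alert_time` (minutes; `NA` when the patient never alerts).
#' @export
first_alert <- function(events, alert_levels = c("HIGH", "URGENT"),
                        tool = c("mprt", "news")) {
  tool <- match.arg(tool)
  if (length(alert_levels) == 0) {
    stop_validation("alert_levels must be non-empty")
  }
  col <- paste0("confirmed_", tool)
  pids <- unique(events$patient_id)
  ft <- vapply(pids, function(pid) {
    i <- which(events$patient_id == pid & events$scorable &
                 events[[col]] %in% alert_levels)
    if (length(i)) min(events$timestamp[i]) else NA_real_
  }, numeric(1))
  data.frame(patient_id = pids, first_alert_time = unname(ft),
             stringsAsFactors = FALSE)
}
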