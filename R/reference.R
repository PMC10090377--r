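#' Published development-cohort summary counts
#'
#' The per-level confirmed event counts and patient tallies reported for the
#' MPRT-WS development cohort (361 general-ward patients monitored every
#' 5 minutes for up to 72 h, 39 of whom deteriorated), against which the
#' package's summary arithmetic can be re-checked. These are summary counts
#' only — the underlying patient streams are not distributed.
#'
#' @return A list of named count vectors and scalars:
#'   `mprt` (Low/Medium/High/Urgent confirmed events),
#'   `news` and `temporal_news` (Low/Medium/High),
#'   `mprt_15min` (Low/Medium/High at the 15-minute interval),
#'   `n_deteriorated`, `identified_mprt`, `identified_news`,
#'   `identified_mprt_15min`.
#' @seealso [reference_summary()]
#' @export
reference_counts <- function() {
  list(
    mprt = c(LOW = 85247L, MEDIUM = 5924L, HIGH = 624L, URGENT = 25635L),
    news = c(LOW = 108782L, MEDIUM = 7158L, HIGH = 1491L),
    temporal_news = c(LOW = 111931L, MEDIUM = 4755L, HIGH = 744L),
    mprt_15min = c(LOW = 88977L, MEDIUM = 5467L, HIGH = 521L),
    n_deteriorated = 39L,
    identified_mprt = 23L,
    identified_news = 4L,
    identified_mprt_15min = 22L
  )
}

#' Recompute the development-cohort summary statistics
#'
#' Runs the package's own distribution and sensitivity arithmetic over the
#' [reference_counts()]: per-tool level shares (percent of the Low/Medium/
#' High total, or of all four levels for the Urgent share) and detection
#' sensitivities. Each value is a percentage computed at call time.
#'
#' @return Named numeric vector of percentages:
#'   `sensitivity_mprtws_pct`, `sensitivity_news_pct`,
#'   `sensitivity_mprtws_15min_pct`, `mprtws_low_share_pct`,
#'   `mprtws_high_share_pct`, `news_high_share_pct`,
#'   `temporal_news_low_share_pct`, `urgent_share_pct`,
#'   `mprtws_15min_low_share_pct`.
#' @examples
#' reference_summary()[["sensitivity_mprtws_pct"]]  # 58.97...
#' @export
reference_summary <- function() {
  rc <- reference_counts()
  share <- function(counts, level) {
    d <- level_distribution(counts)
    d$percent[d$level == level]
  }
  c(
    sensitivity_mprtws_pct =
      100 * sensitivity(rc$identified_mprt, rc$n_deteriorated),
    sensitivity_news_pct =
      100 * sensitivity(rc$identified_news, rc$n_deteriorated),
    sensitivity_mprtws_15min_pct =
      100 * sensitivity(rc$identified_mprt_15min, rc$n_deteriorated),
    mprtws_low_share_pct = share(rc$mprt[c("LOW", "MEDIUM", "HIGH")], "LOW"),
    mprtws_high_share_pct = share(rc$mprt[c("LOW", "MEDIUM", "HIGH")], "HIGH"),
    news_high_share_pct = share(rc$news, "HIGH"),
    temporal_news_low_share_pct = share(rc$temporal_news, "LOW"),
    urgent_share_pct = share(rc$mprt, "URGENT"),
    mprtws_15min_low_share_pct = share(rc$mprt_15min, "LOW")
  )
}
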