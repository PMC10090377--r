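#' Score a single parameter value against its bands
#'
#' Returns the 0-3 score of the unique half-open band `[lower, upper)`
#' containing `value`. Missing values yield a missing score, not an error.
#'
#' @param value Numeric vector of parameter values (may contain `NA`).
#' @param bands A data frame of ordered bands (`lower`, `upper`, `score`) for
#'   one parameter, as held in a [load_band_table()] result.
#' @return Integer vector of scores in 0-3, `NA` where `value` is `NA`.
#' @examples
#' tab <- load_band_table(news_config())
#' score_parameter(c(70, 130, 109.999, NA), tab$bands$hr)
#' @export
score_parameter <- function(value, bands) {
  stopifnot(is.data.frame(bands), all(c("lower", "upper", "score") %in%
                                        names(bands)))
  # contiguous [lower, upper) partition: the containing band is the last one
  # whose lower bound is <= value
  idx <- findInterval(value, bands$lower)
  out <- rep(NA_integer_, length(value))
  ok <- !is.na(value)
  out[ok] <- bands$score[idx[ok]]
  out
}

#' Instantaneous MPRT-WS risk level from nine parameter scores
#'
#' Aggregates per-parameter scores into one of four levels: `URGENT` if any
#' score is 3; otherwise `HIGH` with three or more scores of at least 2,
#' `MEDIUM` with exactly two, `LOW` with at most one. Missing scores count
#' as 0.
#'
#' @param scores Integer vector (or matrix, one reading per row) of
#'   per-parameter scores in 0-3; `NA` allowed.
#' @return Character level(s), one per reading.
#' @examples
#' mprt_instant_level(c(2, 2, 1, 0, 0, 0, 0, 0, 0))  # MEDIUM
#' mprt_instant_level(c(0, 0, 0, 0, 0, 0, 0, 0, 3))  # URGENT
#' @export
mprt_instant_level <- function(scores) {
  m <- if (is.matrix(scores)) scores else matrix(scores, nrow = 1)
  if (any(!(m %in% c(NA, 0:3)))) {
    stop_validation("parameter scores must be in {0,1,2,3} or missing")
  }
  n3 <- rowSums(m == 3, na.rm = TRUE)
  n2 <- rowSums(m >= 2, na.rm = TRUE)
  lev <- ifelse(n3 >= 1, "URGENT",
                ifelse(n2 >= 3, "HIGH",
                       ifelse(n2 == 2, "MEDIUM", "LOW")))
  as.character(lev)
}

#' NEWS aggregate level and total from five parameter scores
#'
#' The NEWS total is the sum of the five parameter scores (missing scores
#' contribute 0). The level is `HIGH` when the total reaches the high
#' threshold (default 7) or any single parameter scores 3 (the "Red score"
#' rule); `MEDIUM` when the total falls in the aggregate-medium range
#' (default 5-6); otherwise `LOW`.
#'
#' @param scores Integer vector (or matrix, one reading per row) of the five
#'   NEWS parameter scores.
#' @param medium_total Length-2 integer range of MEDIUM totals.
#' @param high_total Minimum HIGH total.
#' @param red_score_high Apply the single-parameter Red-score promotion to
#'   HIGH (default `TRUE`).
#' @return A list with integer `total` and character `level`, each one
#'   element per reading.
#' @examples
#' news_level(c(3, 0, 0, 0, 0))$level  # HIGH via Red score
#' news_level(c(2, 2, 1, 0, 0))$level  # MEDIUM (total 5)
#' @export
news_level <- function(scores, medium_total = c(5L, 6L), high_total = 7L,
                       red_score_high = TRUE) {
  m <- if (is.matrix(scores)) scores else matrix(scores, nrow = 1)
  if (any(!(m %in% c(NA, 0:3)))) {
    stop_validation("parameter scores must be in {0,1,2,3} or missing")
  }
  total <- as.integer(rowSums(m, na.rm = TRUE))
  red <- rowSums(m == 3, na.rm = TRUE) >= 1
  high <- total >= high_total | (red_score_high & red)
  med <- !high & total >= medium_total[1] & total <= medium_total[2]
  list(total = total,
       level = ifelse(high, "HIGH", ifelse(med, "MEDIUM", "LOW")))
}

#' Score a cohort of vitals streams
#'
#' Applies per-parameter band scoring and instantaneous level aggregation to
#' every reading, for both MPRT-WS and (optionally) NEWS. Readings with more
#' than `max_missing` missing parameters are flagged unscorable and carry no
#' level; they are excluded from confirmation and event counts downstream.
#'
#' @param vitals A `vitals` data frame ([read_vitals()] or
#'   [generate_cohort()]).
#' @param mprt_table MPRT-WS `band_table` (default: shipped configuration).
#' @param news_table NEWS `band_table`, or `NULL` to skip the comparator.
#' @param max_missing Maximum missing parameters before a reading is
#'   unscorable (default 3).
#' @return A data frame of class `scored_vitals`: patient, timestamp, the
#'   per-parameter scores (`s_hr` ... `s_svr`), `n_missing`, `scorable`,
#'   `instant_mprt`, and when NEWS is on, `news_total` and `instant_news`.
#'   Row order matches the input.
#' @export
score_stream <- function(vitals,
                         mprt_table = load_band_table(mprtws_config()),
                         news_table = load_band_table(news_config()),
                         max_missing = 3L) {
  validate_band_table(mprt_table)
  out <- data.frame(patient_id = vitals$patient_id,
                    timestamp = vitals$timestamp,
                    stringsAsFactors = FALSE)
  smat <- matrix(NA_integer_, nrow(out), length(mprt_params()),
                 dimnames = list(NULL, mprt_params()))
  for (p in mprt_params()) {
    smat[, p] <- score_parameter(vitals[[p]], mprt_table$bands[[p]])
    out[[paste0("s_", p)]] <- smat[, p]
  }
  out$n_missing <- as.integer(rowSums(is.na(smat)))
  out$scorable <- out$n_missing <= max_missing
  out$instant_mprt <- ifelse(out$scorable, mprt_instant_level(smat),
                             NA_character_)
  if (!is.null(news_table)) {
    validate_band_table(news_table)
    nmat <- matrix(NA_integer_, nrow(out), length(news_params()),
                   dimnames = list(NULL, news_params()))
    for (p in news_params()) {
      nmat[, p] <- score_parameter(vitals[[p]], news_table$bands[[p]])
    }
    agg <- news_aggregate_rules(news_table)
    nl <- news_level(nmat, medium_total = agg$medium_total,
                     high_total = agg$high_total)
    out$news_total <- ifelse(out$scorable, nl$total, NA_integer_)
    out$instant_news <- ifelse(out$scorable, nl$level, NA_character_)
  }
  class(out) <- c("scored_vitals", "data.frame")
  out
}

news_aggregate_rules <- function(tab) {
  agg <- tab$aggregate
  list(
    medium_total = if (is.null(agg$medium_total)) c(5L, 6L)
                   else as.integer(unlist(agg$medium_total)),
    high_total = if (is.null(agg$high_total)) 7L
                 else as.integer(agg$high_total)
  )
}
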