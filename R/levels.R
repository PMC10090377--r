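#' @keywords internal
"_PACKAGE"

#' Risk levels and vital-sign parameter sets
#'
#' `mprt_levels()` returns the four MPRT-WS alert levels in increasing order
#' of severity; `news_levels()` returns the three NEWS levels. `mprt_params()`
#' and `news_params()` return the vital-sign parameter names each tool scores,
#' in the canonical column order used throughout the package.
#'
#' @return A character vector.
#' @examples
#' mprt_levels()
#' news_params()
#' @export
mprt_levels <- function() c("LOW", "MEDIUM", "HIGH", "URGENT")

#' @rdname mprt_levels
#' @export
news_levels <- function() c("LOW", "MEDIUM", "HIGH")

#' @rdname mprt_levels
#' @export
mprt_params <- function() {
  c("hr", "spo2", "rr", "sbp", "dbp", "temp", "sv", "co", "svr")
}

#' @rdname mprt_levels
#' @export
news_params <- function() c("hr", "spo2", "rr", "sbp", "temp")

# severity rank of a level; LOW = 1 ... URGENT = 4. NA stays NA.
level_rank <- function(level) {
  match(level, mprt_levels())
}

# inverse of level_rank
rank_level <- function(rank) {
  mprt_levels()[rank]
}

# parallel maximum / minimum of two level vectors by severity
level_min <- function(a, b) {
  rank_level(pmin(level_rank(a), level_rank(b)))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("mprtws_validation_error", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("mprtws_io_error", "error")))
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (half-up), the convention used for all
#' reported percentages. Base [round()] rounds half to even, which would turn
#' 0.5-boundary percentages the wrong way for report formatting.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(6.45, 1)  # 6.5, where round(6.45, 1) gives 6.4
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
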