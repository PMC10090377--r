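#' Score-band tables
#'
#' A band table maps each vital-sign parameter to an ordered set of half-open
#' intervals `[lower, upper)`, each carrying an integer score in 0-3. The
#' intervals must partition the whole real line: pairwise disjoint, no gaps,
#' first lower bound `-Inf`, last upper bound `Inf`, and at least one band per
#' parameter must score 0 (the normal range). Tables are read from YAML (or
#' JSON) configuration files with top-level keys `tool`, `units` and `bands`;
#' `-inf`/`inf` strings are accepted as open bounds.
#'
#' Two configurations ship with the package under `extdata/`:
#' `news_default.yaml`, the standard five-parameter NEWS cutoffs, and
#' `mprtws_default.yaml`, the nine-parameter MPRT-WS cutoffs (the five NEWS
#' parameters plus diastolic pressure, stroke volume, cardiac output and
#' systemic vascular resistance banded around accepted physiological normal
#' ranges).
#'
#' @param path Path to a YAML or JSON band configuration file.
#' @return An object of class `band_table`: a list with elements `tool`
#'   (character), `units` (named character), `bands` (named list of
#'   data frames with columns `lower`, `upper`, `score`), and `aggregate`
#'   (optional named list of aggregate-score rules, used by NEWS).
#' @seealso [score_parameter()], [score_stream()]
#' @examples
#' tab <- load_band_table(mprtws_config())
#' tab$bands$hr
#' @export
load_band_table <- function(path) {
  if (!file.exists(path)) {
    stop_io("band configuration file not found: ", path)
  }
  cfg <- yaml::read_yaml(path)
  for (key in c("tool", "bands")) {
    if (is.null(cfg[[key]])) {
      stop_validation("band configuration is missing top-level key '", key, "'")
    }
  }
  bands <- lapply(cfg$bands, function(pb) {
    df <- data.frame(
      lower = vapply(pb, function(b) parse_bound(b$lower), numeric(1)),
      upper = vapply(pb, function(b) parse_bound(b$upper), numeric(1)),
      score = vapply(pb, function(b) as.integer(b$score), integer(1))
    )
    df[order(df$lower), , drop = FALSE]
  })
  units <- if (is.null(cfg$units)) character() else unlist(cfg$units)
  tab <- structure(
    list(
      tool = as.character(cfg$tool),
      units = units,
      bands = bands,
      aggregate = cfg$aggregate
    ),
    class = "band_table"
  )
  validate_band_table(tab)
  tab
}

parse_bound <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- tolower(trimws(as.character(x)))
  if (x %in% c("-inf", "-infinity")) return(-Inf)
  if (x %in% c("inf", "+inf", "infinity")) return(Inf)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop_validation("cannot parse band bound: '", x, "'")
  v
}

#' Validate a band table
#'
#' Checks every `band_table` invariant: known parameter names, complete
#' parameter set for the declared tool, scores in 0-3, `lower < upper` per
#' band, and per parameter a disjoint gap-free cover of `(-Inf, Inf)` under
#' the half-open `[lower, upper)` convention, with at least one score-0 band.
#'
#' @param tab A `band_table`.
#' @return `tab`, invisibly, if valid; otherwise an error naming the
#'   offending parameter and interval.
#' @export
validate_band_table <- function(tab) {
  required <- switch(toupper(tab$tool),
    "MPRT-WS" = mprt_params(),
    "NEWS" = news_params(),
    names(tab$bands)
  )
  unknown <- setdiff(names(tab$bands), mprt_params())
  if (length(unknown)) {
    stop_validation("unknown parameter name(s) in band table: ",
                    paste(unknown, collapse = ", "))
  }
  missing <- setdiff(required, names(tab$bands))
  if (length(missing)) {
    stop_validation("band table for tool ", tab$tool,
                    " is missing parameter(s): ", paste(missing, collapse = ", "))
  }
  for (p in names(tab$bands)) {
    b <- tab$bands[[p]]
    if (!all(b$score %in% 0:3)) {
      stop_validation("parameter '", p, "': scores must be in {0,1,2,3}")
    }
    if (any(b$lower >= b$upper)) {
      i <- which(b$lower >= b$upper)[1]
      stop_validation("parameter '", p, "': empty or inverted band [",
                      b$lower[i], ", ", b$upper[i], ")")
    }
    if (b$lower[1] != -Inf || b$upper[nrow(b)] != Inf) {
      stop_validation("parameter '", p,
                      "': bands must cover (-Inf, Inf); got [",
                      b$lower[1], ", ", b$upper[nrow(b)], ")")
    }
    if (nrow(b) > 1) {
      lo <- b$lower[-1]
      up <- b$upper[-nrow(b)]
      if (any(lo < up)) {
        i <- which(lo < up)[1]
        stop_validation("parameter '", p, "': overlapping bands at [",
                        lo[i], ", ", up[i], ")")
      }
      if (any(lo > up)) {
        i <- which(lo > up)[1]
        stop_validation("parameter '", p, "': gap between bands over [",
                        up[i], ", ", lo[i], ")")
      }
    }
    if (!any(b$score == 0)) {
      stop_validation("parameter '", p, "': no normal (score 0) band")
    }
  }
  invisible(tab)
}

#' @export
print.band_table <- function(x, ...) {
  cat("Score band table:", x$tool, "\n")
  for (p in names(x$bands)) {
    b <- x$bands[[p]]
    u <- if (p %in% names(x$units)) paste0(" (", x$units[[p]], ")") else ""
    cat(sprintf("  %-5s%s: %s\n", p, u,
                paste(sprintf("[%g,%g)=%d", b$lower, b$upper, b$score),
                      collapse = " ")))
  }
  invisible(x)
}

#' Paths to the shipped band configurations
#'
#' @return Path to the default MPRT-WS (`mprtws_config()`) or NEWS
#'   (`news_config()`) YAML band configuration installed with the package.
#' @export
mprtws_config <- function() {
  system.file("extdata", "mprtws_default.yaml", package = "mprtws",
              mustWork = TRUE)
}

#' @rdname mprtws_config
#' @export
news_config <- function() {
  system.file("extdata", "news_default.yaml", package = "mprtws",
              mustWork = TRUE)
}

# representative in-band value used by the simulator when it steers a
# parameter into a band of a given score: midpoint for finite bands; for
# half-infinite bands, one adjacent-band-width beyond the finite edge.
band_target_value <- function(bands, score, direction = c("up", "down")) {
  direction <- match.arg(direction)
  cand <- bands[bands$score == score, , drop = FALSE]
  if (nrow(cand) == 0) {
    stop_validation("no band with score ", score, " in table")
  }
  cand <- cand[order(cand$lower), , drop = FALSE]
  row <- if (direction == "up") cand[nrow(cand), ] else cand[1, ]
  band_midpoint(bands, row)
}

band_midpoint <- function(bands, row) {
  if (is.finite(row$lower) && is.finite(row$upper)) {
    return((row$lower + row$upper) / 2)
  }
  widths <- bands$upper - bands$lower
  finite_w <- widths[is.finite(widths)]
  w <- if (length(finite_w)) stats::median(finite_w) else 10
  if (is.finite(row$lower)) row$lower + w else row$upper - w
}
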