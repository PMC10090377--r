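#' Read a multi-parameter vitals CSV
#'
#' Reads time-stamped vital-sign streams, one row per reading, with the exact
#' ordered columns `patient_id, timestamp, hr, spo2, rr, sbp, dbp, temp, sv,
#' co, svr`. The `timestamp` column may hold minutes since each patient's
#' stream start (non-negative reals) or ISO-8601 instants
#' (`YYYY-MM-DDTHH:MM:SS`, assumed UTC), which are converted to minutes since
#' the patient's first reading. Empty cells and `NA` mark missing vitals.
#'
#' @param path Path to the CSV file.
#' @return A data frame of class `vitals` sorted by patient then time, with
#'   numeric `timestamp` in minutes. Zero rows if the file holds only the
#'   header.
#' @details Validation errors name the offending line or patient: a
#'   non-numeric vital or unparseable timestamp reports its line number;
#'   duplicated or decreasing timestamps within one patient report the
#'   patient id. Vitals must be positive; `spo2` must not exceed 100.
#' @seealso [write_vitals()], [read_outcomes()]
#' @export
read_vitals <- function(path) {
  if (!file.exists(path)) stop_io("vitals file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"), check.names = FALSE)
  if (!identical(names(raw), vitals_columns())) {
    stop_validation("vitals CSV must have columns: ",
                    paste(vitals_columns(), collapse = ", "),
                    "; got: ", paste(names(raw), collapse = ", "))
  }
  if (nrow(raw) == 0) {
    df <- empty_vitals()
    return(df)
  }
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  if (anyNA(raw$patient_id)) {
    stop_validation("missing patient_id at line ",
                    line[which(is.na(raw$patient_id))[1]])
  }
  ts <- parse_timestamp(raw$timestamp, raw$patient_id, line)
  df <- data.frame(patient_id = raw$patient_id, timestamp = ts,
                   stringsAsFactors = FALSE)
  for (p in mprt_params()) {
    v <- suppressWarnings(as.numeric(raw[[p]]))
    bad <- which(!is.na(raw[[p]]) & is.na(v))
    if (length(bad)) {
      stop_validation("malformed value '", raw[[p]][bad[1]], "' for ", p,
                      " at line ", line[bad[1]])
    }
    neg <- which(!is.na(v) & (v <= 0 | !is.finite(v)))
    if (length(neg)) {
      stop_validation("non-positive or non-finite ", p, " at line ",
                      line[neg[1]])
    }
    if (p == "spo2" && any(v > 100, na.rm = TRUE)) {
      stop_validation("spo2 above 100 percent at line ",
                      line[which(v > 100)[1]])
    }
    df[[p]] <- v
  }
  df <- df[order(match(df$patient_id, unique(df$patient_id)), df$timestamp), ]
  rownames(df) <- NULL
  for (pid in unique(df$patient_id)) {
    t <- df$timestamp[df$patient_id == pid]
    if (any(diff(t) <= 0)) {
      stop_validation("timestamps not strictly increasing for patient '",
                      pid, "'")
    }
  }
  class(df) <- c("vitals", "data.frame")
  df
}

vitals_columns <- function() c("patient_id", "timestamp", mprt_params())

empty_vitals <- function() {
  df <- data.frame(patient_id = character(), timestamp = numeric())
  for (p in mprt_params()) df[[p]] <- numeric()
  class(df) <- c("vitals", "data.frame")
  df
}

parse_timestamp <- function(x, patient_id, line) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) {
    if (any(!is.finite(num) | num < 0)) {
      stop_validation("negative or non-finite timestamp at line ",
                      line[which(!is.finite(num) | num < 0)[1]])
    }
    return(num)
  }
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad <- which(is.na(t))
  if (length(bad)) {
    stop_validation("unparseable timestamp '", x[bad[1]], "' at line ",
                    line[bad[1]], " (expect minutes or ISO-8601)")
  }
  # minutes since each patient's first reading
  t0 <- stats::ave(as.numeric(t), patient_id, FUN = min)
  (as.numeric(t) - t0) / 60
}

#' Write vitals to CSV
#'
#' Inverse of [read_vitals()]: writes the canonical column set with `NA` for
#' missing vitals. Values round-trip to at least six significant digits.
#'
#' @param vitals A `vitals` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vitals <- function(vitals, path) {
  out <- as.data.frame(vitals)[, vitals_columns(), drop = FALSE]
  for (p in mprt_params()) out[[p]] <- signif_chr(out[[p]])
  out$timestamp <- signif_chr(out$timestamp)
  write_csv_checked(out, path)
}

signif_chr <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.8g", x))
}

write_csv_checked <- function(df, path) {
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop_io("cannot write ", path, ": ",
                           conditionMessage(ok))
  invisible(path)
}

#' Read per-patient outcome annotations
#'
#' Reads a CSV with columns `patient_id, deteriorated, deterioration_time`.
#' `deteriorated` is 0/1; `deterioration_time` (minutes since stream start,
#' or ISO-8601 converted against the patient's own first row) is required
#' exactly when `deteriorated` is 1.
#'
#' @param path Path to the outcomes CSV.
#' @return A data frame with `patient_id` (character), `deteriorated`
#'   (logical) and `deterioration_time` (numeric minutes, `NA` for stable
#'   patients).
#' @export
read_outcomes <- function(path) {
  if (!file.exists(path)) stop_io("outcomes file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"))
  need <- c("patient_id", "deteriorated", "deterioration_time")
  if (!all(need %in% names(raw))) {
    stop_validation("outcomes CSV must have columns: ",
                    paste(need, collapse = ", "))
  }
  det <- raw$deteriorated %in% c("1", "TRUE", "true")
  tm <- suppressWarnings(as.numeric(raw$deterioration_time))
  if (any(det & is.na(tm))) {
    stop_validation("deteriorated patient without deterioration_time: '",
                    raw$patient_id[which(det & is.na(tm))[1]], "'")
  }
  data.frame(patient_id = raw$patient_id, deteriorated = det,
             deterioration_time = ifelse(det, tm, NA_real_),
             stringsAsFactors = FALSE)
}

#' Write outcomes to CSV
#'
#' @param outcomes Data frame as returned by [read_outcomes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  out <- data.frame(
    patient_id = outcomes$patient_id,
    deteriorated = as.integer(outcomes$deteriorated),
    deterioration_time = outcomes$deterioration_time
  )
  write_csv_checked(out, path)
}

#' Write scored and confirmed events to CSV
#'
#' One row per scorable reading: patient, timestamp, the nine per-parameter
#' scores, the instantaneous and confirmed MPRT-WS levels, and (when present)
#' the NEWS total and levels.
#'
#' @param events A confirmed events data frame (see [confirm_events()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  write_csv_checked(as.data.frame(events), path)
}
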