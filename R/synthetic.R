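#' Trajectory specification for the vitals simulator
#'
#' Describes one synthetic wearable-vitals trajectory: stationary first-order
#' autoregressive fluctuation of the nine parameters around physiological
#' baselines, optional deterioration (affected parameters ramp linearly from
#' baseline into the midpoint of a configured target band, then hold),
#' isolated single-reading artifacts, and per-value missingness. Defaults
#' emulate a general-ward wearable feed: a reading every 5 minutes for up to
#' 72 hours.
#'
#' @param baseline Named numeric vector of per-parameter baselines. Defaults
#'   are mid-normal adult values (hr 75, spo2 97.5, rr 16, sbp 120, dbp 75,
#'   temp 36.8, sv 75, co 5.5, svr 1000).
#' @param noise_sd Named numeric vector of stationary noise SDs, in each
#'   parameter's own units.
#' @param ar Autocorrelation coefficient in `[0, 1)` of the AR(1) noise
#'   (default 0.8, giving smooth physiological drift at 5-min sampling).
#' @param cadence Sampling interval, minutes (default 5).
#' @param duration Monitoring span, minutes (default 4320 = 72 h).
#' @param artifact_rate Expected isolated single-reading artifacts per 24 h
#'   (default 0): one parameter jumps into a score-3 band for one reading
#'   and returns immediately.
#' @param missing_prob Per-parameter per-reading probability of a missing
#'   value (default 0).
#' @param deterioration `NULL` for a stable patient, else a list with
#'   `onset` (minutes), `params` (affected parameter names), `target_score`
#'   (band score each affected parameter ramps into, scalar or named),
#'   `ramp` (ramp duration, minutes) and optional `direction` (named
#'   `"up"`/`"down"`; default is the side of the baseline holding such a
#'   band, preferring up). The annotated deterioration time is
#'   `onset + ramp`.
#' @return A list of class `trajectory_spec`.
#' @seealso [generate_patient()], [generate_cohort()],
#'   [deterioration_presets()]
#' @export
trajectory_spec <- function(baseline = default_baselines(),
                            noise_sd = default_noise_sd(),
                            ar = 0.8,
                            cadence = 5,
                            duration = 4320,
                            artifact_rate = 0,
                            missing_prob = 0,
                            deterioration = NULL) {
  baseline <- merge_named(default_baselines(), baseline)
  noise_sd <- merge_named(default_noise_sd(), noise_sd)
  if (cadence <= 0) stop_validation("cadence must be positive")
  if (duration <= 0) stop_validation("duration must be positive")
  if (ar < 0 || ar >= 1) stop_validation("ar must be in [0, 1)")
  if (missing_prob < 0 || missing_prob > 1) {
    stop_validation("missing_prob must be a probability")
  }
  if (artifact_rate < 0) stop_validation("artifact_rate must be >= 0")
  if (!is.null(deterioration)) {
    d <- deterioration
    if (is.null(d$onset) || is.null(d$params) || is.null(d$ramp) ||
        is.null(d$target_score)) {
      stop_validation("deterioration needs onset, params, target_score, ramp")
    }
    if (!all(d$params %in% mprt_params())) {
      stop_validation("unknown deterioration parameter(s): ",
                      paste(setdiff(d$params, mprt_params()), collapse = ", "))
    }
    if (d$onset < 0 || d$ramp <= 0 || d$onset + d$ramp > duration) {
      stop_validation("need 0 <= onset and onset + ramp <= duration")
    }
  }
  structure(list(baseline = baseline, noise_sd = noise_sd, ar = ar,
                 cadence = cadence, duration = duration,
                 artifact_rate = artifact_rate,
                 missing_prob = missing_prob,
                 deterioration = deterioration),
            class = "trajectory_spec")
}

#' @rdname trajectory_spec
#' @export
default_baselines <- function() {
  c(hr = 75, spo2 = 97.5, rr = 16, sbp = 120, dbp = 75, temp = 36.8,
    sv = 75, co = 5.5, svr = 1000)
}

#' @rdname trajectory_spec
#' @export
default_noise_sd <- function() {
  c(hr = 3, spo2 = 0.8, rr = 1.5, sbp = 6, dbp = 4, temp = 0.15,
    sv = 4, co = 0.35, svr = 60)
}

merge_named <- function(defaults, x) {
  out <- defaults
  if (!is.null(x)) out[names(x)] <- x
  out[mprt_params()]
}

# run code under a local RNG stream without touching the caller's state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate one patient's vitals stream
#'
#' Generates a single synthetic stream under a [trajectory_spec()], plus its
#' outcome annotation. Identical `(spec, seed)` pairs reproduce the stream
#' bit for bit; the caller's random-number state is left untouched.
#'
#' @param spec A [trajectory_spec()].
#' @param seed Integer seed for this patient.
#' @param patient_id Identifier used in the output (default `"P1"`).
#' @param mprt_table Band table used to locate deterioration target bands
#'   and artifact (score 3) bands.
#' @return A list: `vitals` (a `vitals` data frame) and `outcome` (one-row
#'   outcomes data frame).
#' @export
generate_patient <- function(spec, seed, patient_id = "P1",
                             mprt_table = load_band_table(mprtws_config())) {
  stopifnot(inherits(spec, "trajectory_spec"))
  with_local_seed(seed, {
    t <- seq(0, spec$duration, by = spec$cadence)
    n <- length(t)
    vals <- matrix(NA_real_, n, length(mprt_params()),
                   dimnames = list(NULL, mprt_params()))
    for (p in mprt_params()) {
      vals[, p] <- spec$baseline[[p]] +
        ar1_noise(n, spec$ar, spec$noise_sd[[p]])
    }
    det <- spec$deterioration
    if (!is.null(det)) {
      frac <- pmin(pmax((t - det$onset) / det$ramp, 0), 1)
      for (p in det$params) {
        tgt <- det_target(det, p, spec$baseline[[p]], mprt_table)
        vals[, p] <- vals[, p] + frac * (tgt - spec$baseline[[p]])
      }
    }
    # isolated single-reading artifacts: jump into a 3-band, immediate return
    if (spec$artifact_rate > 0 && n > 2) {
      n_art <- stats::rpois(1, spec$artifact_rate * spec$duration / 1440)
      if (n_art > 0) {
        cand <- sample(2:(n - 1))
        picked <- integer(0)
        for (i in cand) {
          if (length(picked) >= n_art) break
          if (!any(abs(picked - i) <= 1)) picked <- c(picked, i)
        }
        for (i in picked) {
          p <- sample(mprt_params(), 1)
          dir <- if (any(mprt_table$bands[[p]]$score == 3 &
                           mprt_table$bands[[p]]$lower > spec$baseline[[p]]))
            "up" else "down"
          vals[i, p] <- band_target_value(mprt_table$bands[[p]], 3, dir)
        }
      }
    }
    if (spec$missing_prob > 0) {
      drop <- matrix(stats::runif(n * ncol(vals)) < spec$missing_prob,
                     n, ncol(vals))
      vals[drop] <- NA_real_
    }
    vals[vals <= 0 & !is.na(vals)] <- 0.01  # vitals are positive by contract
    vals[, "spo2"] <- pmin(vals[, "spo2"], 100)
    vit <- data.frame(patient_id = patient_id, timestamp = t,
                      stringsAsFactors = FALSE)
    for (p in mprt_params()) vit[[p]] <- vals[, p]
    class(vit) <- c("vitals", "data.frame")
    outcome <- data.frame(
      patient_id = patient_id,
      deteriorated = !is.null(det),
      deterioration_time = if (is.null(det)) NA_real_ else det$onset + det$ramp,
      stringsAsFactors = FALSE
    )
    list(vitals = vit, outcome = outcome)
  })
}

# stationary AR(1) with marginal SD sd: x_i = phi x_{i-1} + sqrt(1-phi^2) sd z
ar1_noise <- function(n, phi, sd) {
  if (sd == 0) return(numeric(n))
  z <- stats::rnorm(n)
  x <- numeric(n)
  x[1] <- sd * z[1]
  if (n > 1) {
    w <- sd * sqrt(1 - phi^2)
    for (i in 2:n) x[i] <- phi * x[i - 1] + w * z[i]
  }
  x
}

det_target <- function(det, p, baseline, tab) {
  dir <- det$direction[[p]]
  if (is.null(dir)) {
    b <- tab$bands[[p]]
    sc <- score_of(det$target_score, p)
    dir <- if (any(b$score == sc & b$lower > baseline)) "up" else "down"
  }
  band_target_value(tab$bands[[p]], score_of(det$target_score, p), dir)
}

score_of <- function(target_score, p) {
  if (length(target_score) == 1 && is.null(names(target_score))) {
    as.integer(target_score)
  } else {
    as.integer(target_score[[p]])
  }
}

#' Simulate a cohort of stable and deteriorating patients
#'
#' Per-patient seeds are derived deterministically from the master seed, so
#' an identical `(specs, seed)` call reproduces the cohort exactly.
#'
#' @param n_stable,n_deteriorating Patient counts (>= 0).
#' @param stable_spec [trajectory_spec()] for stable patients.
#' @param det_spec [trajectory_spec()] (with a `deterioration` block) for
#'   deteriorating patients.
#' @param seed Master integer seed.
#' @param mprt_table Band table passed through to [generate_patient()].
#' @return A list of class `synthetic_cohort`: `vitals` (all streams, one
#'   data frame), `outcomes`, `seed`.
#' @export
generate_cohort <- function(n_stable, n_deteriorating,
                            stable_spec = trajectory_spec(),
                            det_spec = NULL,
                            seed = 1L,
                            mprt_table = load_band_table(mprtws_config())) {
  if (n_stable < 0 || n_deteriorating < 0) {
    stop_validation("patient counts must be >= 0")
  }
  if (n_deteriorating > 0 &&
      (is.null(det_spec) || is.null(det_spec$deterioration))) {
    stop_validation("det_spec with a deterioration block is required")
  }
  n <- n_stable + n_deteriorating
  if (n == 0) {
    return(structure(list(vitals = empty_vitals(),
                          outcomes = read_outcomes_empty(), seed = seed),
                     class = "synthetic_cohort"))
  }
  seeds <- with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  vit <- vector("list", n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- if (i <= n_stable) stable_spec else det_spec
    pid <- sprintf("P%03d", i)
    g <- generate_patient(sp, seeds[i], pid, mprt_table)
    vit[[i]] <- g$vitals
    out[[i]] <- g$outcome
  }
  vitals <- do.call(rbind, vit)
  class(vitals) <- c("vitals", "data.frame")
  structure(list(vitals = vitals, outcomes = do.call(rbind, out),
                 seed = seed),
            class = "synthetic_cohort")
}

read_outcomes_empty <- function() {
  data.frame(patient_id = character(), deteriorated = logical(),
             deterioration_time = numeric(), stringsAsFactors = FALSE)
}

#' Illustrative deterioration phenotypes
#'
#' Named deterioration presets with distinct affected-parameter subsets,
#' loosely patterned on common admission diagnoses in general-ward
#' monitoring cohorts (congestive heart failure, stroke, COPD, chronic
#' kidney disease, arrhythmia). They exist to give the simulator varied,
#' multi-parameter deterioration signatures; they are illustrative only and
#' carry no clinical validity.
#'
#' @param onset Deterioration onset, minutes (default 720 = 12 h).
#' @param ramp Ramp duration, minutes (default 360 = 6 h).
#' @param target_score Band score each affected parameter ramps into
#'   (default 2).
#' @return Named list of deterioration blocks for [trajectory_spec()].
#' @export
deterioration_presets <- function(onset = 720, ramp = 360,
                                  target_score = 2L) {
  mk <- function(params, direction) {
    list(onset = onset, params = params, target_score = target_score,
         ramp = ramp, direction = direction)
  }
  list(
    chf = mk(c("sv", "co", "svr", "rr"),
             list(sv = "down", co = "down", svr = "up", rr = "up")),
    cva = mk(c("sbp", "dbp", "hr"),
             list(sbp = "up", dbp = "up", hr = "down")),
    copd = mk(c("spo2", "rr", "hr"),
              list(spo2 = "down", rr = "up", hr = "up")),
    ckd = mk(c("sbp", "dbp", "svr"),
             list(sbp = "up", dbp = "up", svr = "up")),
    arrhythmia = mk(c("hr", "sv", "co"),
                    list(hr = "up", sv = "down", co = "down"))
  )
}
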