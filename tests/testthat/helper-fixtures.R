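# Shared fixtures and independent oracles. Oracles deliberately use the
# dumbest possible algorithm (linear scans, per-element loops, exhaustive
# enumeration) so they stay independent of the vectorized implementations.

# toy heart-rate-like band list used by the scoring examples
toy_bands <- function() {
  data.frame(lower = c(-Inf, 40, 50, 90, 110, 130),
             upper = c(40, 50, 90, 110, 130, Inf),
             score = c(3L, 1L, 0L, 1L, 2L, 3L))
}

normal_values <- function() {
  c(hr = 75, spo2 = 98, rr = 16, sbp = 120, dbp = 75, temp = 36.8,
    sv = 75, co = 5.5, svr = 1000)
}

# n all-normal readings for one patient at a fixed cadence
make_vitals <- function(n, patient_id = "P1", cadence = 5, t0 = 0) {
  df <- data.frame(patient_id = rep(patient_id, n),
                   timestamp = t0 + cadence * (seq_len(n) - 1),
                   stringsAsFactors = FALSE)
  nv <- normal_values()
  for (p in mprt_params()) df[[p]] <- rep(nv[[p]], n)
  class(df) <- c("vitals", "data.frame")
  df
}

# write a band config YAML from a named list of band data frames
write_band_yaml <- function(bands, tool = "MPRT-WS",
                            path = tempfile(fileext = ".yaml"),
                            aggregate = NULL) {
  cfg <- list(tool = tool,
              bands = lapply(bands, function(b) {
                lapply(seq_len(nrow(b)), function(i) {
                  list(lower = if (is.infinite(b$lower[i])) "-inf"
                               else b$lower[i],
                       upper = if (is.infinite(b$upper[i])) "inf"
                               else b$upper[i],
                       score = b$score[i])
                })
              }))
  if (!is.null(aggregate)) cfg$aggregate <- aggregate
  yaml::write_yaml(cfg, path)
  path
}

# a degenerate all-normal config: one score-0 band per parameter
flat_bands <- function(params = mprt_params()) {
  stats::setNames(lapply(params, function(p) {
    data.frame(lower = -Inf, upper = Inf, score = 0L)
  }), params)
}

# oracle: linear scan over the band list, one value at a time
scan_score_oracle <- function(values, bands) {
  vapply(values, function(v) {
    if (is.na(v)) return(NA_integer_)
    for (i in seq_len(nrow(bands))) {
      if (v >= bands$lower[i] && v < bands$upper[i]) return(bands$score[i])
    }
    NA_integer_
  }, integer(1))
}

# oracle: the four-level aggregation rule stated directly, one vector at a
# time (any 3 -> URGENT; else by the count of scores of 2)
level_oracle <- function(scores) {
  s <- scores[!is.na(scores)]
  if (any(s == 3)) return("URGENT")
  n2 <- sum(s == 2)
  if (n2 >= 3) return("HIGH")
  if (n2 == 2) return("MEDIUM")
  "LOW"
}

# oracle: two-sided Fisher exact p by exhaustive hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(ks, function(k) {
    exp(lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1))
  }, numeric(1))
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# oracle: Pearson chi-square by direct double summation
chisq_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}
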