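# shared builders for synthetic fixtures (everything generated in code)

cs_abs <- function(a, b) abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))

# hand-built model carrying the generating truth as a fixed basis, for
# projection-identity and reconstruction round trips
truth_model <- function(truth, sim) {
  d_max <- max(sim$index$day_order)
  Tn <- length(truth$mean_fn)
  eta <- matrix(0, d_max, Tn)
  if (length(truth$day_shifts))
    for (j in seq_len(min(d_max, length(truth$day_shifts))))
      eta[j, ] <- truth$day_shifts[[j]]
  structure(list(
    T = Tn, mu = truth$mean_fn, eta = eta,
    phi1 = t(truth$phi1), lambda1 = truth$lambda1,
    phi2 = t(truth$phi2), lambda2 = truth$lambda2,
    lambda1_full = truth$lambda1, lambda2_full = truth$lambda2,
    sigma2 = truth$noise_sd^2,
    N1 = ncol(truth$phi1), N2 = ncol(truth$phi2),
    rho = sum(truth$lambda1) / (sum(truth$lambda1) + sum(truth$lambda2)),
    index = sim$index,
    config = list()), class = "mfpca_model")
}

# scripted single-participant device streams: 'segments' is a data.frame
# with day, posture, duration_s and constant per-axis count rates
scripted_streams <- function(segments, seed = 1) {
  days <- max(segments$day)
  simulate_device_streams(
    n = 1, days = days,
    params = behavior_params(schedule = segments),
    seed = seed)
}

seg <- function(day, posture, duration_s, va = 0, ha = 0, ppa = 0) {
  data.frame(day = day, posture = posture, duration_s = duration_s,
             va_cps = va, ha_cps = ha, ppa_cps = ppa,
             stringsAsFactors = FALSE)
}

# 1-second count table at constant per-minute totals, one row per second
counts_table <- function(participant, start, total_per_sec) {
  n <- length(total_per_sec)
  data.frame(participant = participant,
             timestamp = as.POSIXct(start, tz = "UTC") + seq_len(n) - 1,
             va = total_per_sec, ha = 0L, ppa = 0L,
             stringsAsFactors = FALSE)
}

# brute-force non-wear oracle on a zero/nonzero minute vector: an interval
# [i, j] is non-wear iff it starts and ends on zero minutes, contains at
# most 'tol' nonzero minutes, and spans at least 'win' minutes; report
# maximal such intervals
nonwear_oracle <- function(zero, win, tol) {
  n <- length(zero)
  best <- NULL
  for (i in seq_len(n)) {
    if (!zero[i]) next
    for (j in n:i) {
      if (!zero[j]) next
      if (j - i + 1 >= win && sum(!zero[i:j]) <= tol) {
        covered <- !is.null(best) &&
          any(best[, 1] <= i & best[, 2] >= j)
        if (!covered) best <- rbind(best, c(i, j))
        break
      }
    }
  }
  best
}
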