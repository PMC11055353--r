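#' Behavioral parameters for the device-stream simulator
#'
#' Defaults describe a free-living day of a sedentary older adult: a
#' 06:00-22:00 waking window (sleep 22:00-06:00), alternating
#' sit/stand/step segments with lognormal lengths (sitting mean ~20 min,
#' standing ~7 min, stepping ~3 min), and 1-second per-axis counts that are
#' mostly zero during sitting with sparse bursts (so minute-level sitting
#' VM is right-skewed: median far below mean), moderate while standing,
#' and high while stepping.
#'
#' @param waking_start,waking_end Clock times ("HH:MM") of the waking
#'   window; must span at least one hour.
#' @param seg_meanlog,seg_sdlog Named numeric vectors (sitting, standing,
#'   stepping) of lognormal segment-length parameters, in seconds.
#' @param burst_prob Per-second probability of a movement burst while
#'   sitting.
#' @param rate Named list of per-axis mean counts/second by posture.
#' @param schedule Optional scripted schedule overriding the random
#'   generator: data frame `day`, `posture`, `duration_s`, `va_cps`,
#'   `ha_cps`, `ppa_cps`; segments are laid out in order from the waking
#'   window start, counts are constant at the given rates, and the
#'   remainder of the window (if any) is filled with zero-count standing.
#' @return List of class `"behavior_params"`.
#' @export
behavior_params <- function(waking_start = "06:00", waking_end = "22:00",
                            seg_meanlog = c(sitting = log(1200),
                                            standing = log(420),
                                            stepping = log(180)),
                            seg_sdlog = c(sitting = 0.8, standing = 0.7,
                                          stepping = 0.6),
                            burst_prob = 0.05,
                            rate = list(sitting = c(40, 30, 30),
                                        standing = c(8, 6, 6),
                                        stepping = c(35, 25, 25)),
                            schedule = NULL) {
  structure(list(waking_start = waking_start, waking_end = waking_end,
                 seg_meanlog = seg_meanlog, seg_sdlog = seg_sdlog,
                 burst_prob = burst_prob, rate = rate, schedule = schedule),
            class = "behavior_params")
}

hm_seconds <- function(hm) {
  p <- as.integer(strsplit(hm, ":", fixed = TRUE)[[1]])
  p[1] * 3600 + p[2] * 60
}

#' Simulate raw device streams with known ground truth
#'
#' Generates, for `n` participants over `days` days each, the three input
#' tables the preprocessing chain consumes: an activPAL-style posture event
#' table covering each day without gaps or overlaps (the overnight in-bed
#' period is emitted as one long sitting event, which waking-window
#' exclusion must remove), an ActiGraph-style 1-second tri-axial count
#' table covering each full wear day, and a per-day sleep log. The
#' scripted per-day sitting-segment list is returned alongside as the
#' oracle for bout-recovery tests.
#'
#' @param n Number of participants.
#' @param days Days per participant.
#' @param params A [behavior_params()] object.
#' @param seed Integer seed (the generator is pure in `(args, seed)`).
#' @param start_date First simulated date.
#' @return List of class `"device_streams"`: `events`, `counts`, `sleep`,
#'   and `truth` (data frame of scripted sitting segments with
#'   `participant`, `day`, `start`, `duration_s`).
#' @export
simulate_device_streams <- function(n, days, params = behavior_params(),
                                    seed, start_date = as.Date("2020-06-01")) {
  n <- check_pos_int(n, "n"); days <- check_pos_int(days, "days")
  seed <- check_pos_int(seed, "seed")
  stopifnot(inherits(params, "behavior_params"))
  ws <- hm_seconds(params$waking_start); we <- hm_seconds(params$waking_end)
  if (we - ws < 3600) stop("waking window must span at least one hour")
  set.seed(seed)
  events <- list(); counts <- list(); sleep <- list(); truth <- list()
  postures <- c("sitting", "standing", "stepping")
  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", i)
    for (d in seq_len(days)) {
      day0 <- as.POSIXct(paste(start_date + (d - 1)), tz = "UTC")
      wake_s <- day0 + ws; wake_e <- day0 + we
      # sleep record for the night preceding day d, so the derived waking
      # window [bed_end, next bed_start) lands on day d itself
      sleep[[length(sleep) + 1L]] <- data.frame(
        participant = pid, date = start_date + (d - 2),
        bed_start = wake_e - 86400, bed_end = wake_s,
        stringsAsFactors = FALSE)
      # posture segments over the waking window
      if (is.null(params$schedule)) {
        segs <- NULL; t0 <- 0; total <- as.numeric(we - ws)
        po <- sample(postures, 1)
        while (t0 < total) {
          len <- round(stats::rlnorm(1, params$seg_meanlog[[po]],
                                     params$seg_sdlog[[po]]))
          len <- min(max(60, len), total - t0)  # never overshoot the window
          segs <- rbind(segs, data.frame(posture = po, duration_s = len,
                                         va_cps = NA_real_, ha_cps = NA_real_,
                                         ppa_cps = NA_real_,
                                         stringsAsFactors = FALSE))
          t0 <- t0 + len
          po <- if (po == "sitting") sample(c("standing", "stepping"), 1)
          else if (stats::runif(1) < 0.6) "sitting"
          else setdiff(c("standing", "stepping"), po)
        }
      } else {
        segs <- params$schedule[params$schedule$day == d, , drop = FALSE]
        total <- as.numeric(we - ws)
        used <- sum(segs$duration_s)
        if (used > total) stop("scripted schedule exceeds the waking window")
        if (used < total)
          segs <- rbind(segs[c("posture", "duration_s", "va_cps", "ha_cps",
                               "ppa_cps")],
                        data.frame(posture = "standing",
                                   duration_s = total - used,
                                   va_cps = 0, ha_cps = 0, ppa_cps = 0))
        segs <- segs[c("posture", "duration_s", "va_cps", "ha_cps",
                       "ppa_cps")]
      }
      seg_start <- wake_s + c(0, cumsum(segs$duration_s))[seq_len(nrow(segs))]
      events[[length(events) + 1L]] <- data.frame(
        participant = pid, start = seg_start,
        duration_s = segs$duration_s, posture = segs$posture,
        stringsAsFactors = FALSE)
      # overnight sitting event so the event table covers the full day
      events[[length(events) + 1L]] <- data.frame(
        participant = pid, start = wake_e,
        duration_s = 86400 - (we - ws),  # in bed until next waking start
        posture = "sitting", stringsAsFactors = FALSE)
      sit <- segs$posture == "sitting"
      if (any(sit))
        truth[[length(truth) + 1L]] <- data.frame(
          participant = pid, day = start_date + (d - 1),
          start = seg_start[sit], duration_s = segs$duration_s[sit],
          stringsAsFactors = FALSE)
      # 1-second counts across the full day (zeros while in bed)
      nsec <- 86400L
      va <- ha <- ppa <- integer(nsec)
      off <- as.numeric(wake_s) - as.numeric(day0)  # seconds into the day
      for (sgi in seq_len(nrow(segs))) {
        s0 <- off + c(0, cumsum(segs$duration_s))[sgi]
        idx <- s0 + seq_len(segs$duration_s[sgi])
        po <- segs$posture[sgi]
        if (!is.na(segs$va_cps[sgi])) {
          va[idx] <- segs$va_cps[sgi]
          ha[idx] <- segs$ha_cps[sgi]
          ppa[idx] <- segs$ppa_cps[sgi]
        } else {
          r <- params$rate[[po]]
          m <- length(idx)
          act <- if (po == "sitting")
            stats::runif(m) < params$burst_prob else rep(TRUE, m)
          va[idx] <- stats::rpois(m, r[1]) * act
          ha[idx] <- stats::rpois(m, r[2]) * act
          ppa[idx] <- stats::rpois(m, r[3]) * act
        }
      }
      counts[[length(counts) + 1L]] <- data.frame(
        participant = pid, timestamp = day0 + seq_len(nsec) - 1,
        va = va, ha = ha, ppa = ppa, stringsAsFactors = FALSE)
    }
  }
  bind <- function(l) { x <- do.call(rbind, l); rownames(x) <- NULL; x }
  structure(list(events = bind(events), counts = bind(counts),
                 sleep = bind(sleep),
                 truth = if (length(truth)) bind(truth) else
                   data.frame(participant = character(0),
                              day = as.Date(character(0)),
                              start = as.POSIXct(character(0), tz = "UTC"),
                              duration_s = numeric(0)),
                 seed = seed),
            class = "device_streams")
}

#' Write simulated device streams to CSV with a JSON truth sidecar
#'
#' @param streams A `"device_streams"` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_stream_tables <- function(streams, dir) {
  stopifnot(inherits(streams, "device_streams"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("events.csv", "counts.csv", "sleep.csv",
                            "truth.json"))
  utils::write.csv(streams$events, paths[1], row.names = FALSE)
  utils::write.csv(streams$counts, paths[2], row.names = FALSE)
  utils::write.csv(streams$sleep, paths[3], row.names = FALSE)
  jsonlite::write_json(list(seed = streams$seed, schedule = streams$truth),
                       paths[4], auto_unbox = TRUE, digits = NA,
                       POSIXt = "ISO8601")
  invisible(paths)
}

#' Simulate blood-pressure outcomes from subject-level scores
#'
#' Generates SBP/DBP outcomes from a linear predictor on the level-1 PC
#' scores plus optional covariates, with Gaussian noise:
#' `y = beta_0 + scores %*% beta_scores + covariates %*% beta_cov + e`.
#' The design matrix is returned so ordinary-least-squares refits can act
#' as the oracle for recovery tests.
#'
#' @param level1_scores Numeric matrix (subjects x K1).
#' @param beta Coefficient vector `c(intercept, score betas, covariate
#'   betas)`, used for both outcomes; or a list with elements `sbp` and
#'   `dbp` for outcome-specific coefficients.
#' @param covariates Optional numeric data frame / matrix (subjects x p);
#'   must be full column rank.
#' @param noise_sd Residual standard deviation (>= 0).
#' @param seed Integer seed.
#' @return List with `outcomes` (data.frame `participant`, `SBP`, `DBP`)
#'   and `design` (the model matrix including intercept).
#' @export
simulate_outcomes <- function(level1_scores, beta, covariates = NULL,
                              noise_sd = 5, seed) {
  seed <- check_pos_int(seed, "seed")
  S <- as.matrix(level1_scores)
  X <- cbind(`(Intercept)` = 1, S)
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (qr(C)$rank < ncol(C)) stop("rank-deficient covariate table")
    X <- cbind(X, C)
  }
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  if (!is.list(beta)) beta <- list(sbp = beta, dbp = beta)
  stopifnot(length(beta$sbp) == ncol(X), length(beta$dbp) == ncol(X))
  if (length(noise_sd) != 1L || noise_sd < 0)
    stop("'noise_sd' must be a single non-negative number")
  set.seed(seed)
  n <- nrow(X)
  sbp <- drop(X %*% beta$sbp) + stats::rnorm(n, sd = noise_sd)
  dbp <- drop(X %*% beta$dbp) + stats::rnorm(n, sd = noise_sd)
  ids <- rownames(S) %||% sprintf("S%03d", seq_len(n))
  list(outcomes = data.frame(participant = ids, SBP = sbp, DBP = dbp,
                             stringsAsFactors = FALSE),
       design = X)
}
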