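# Interval helpers: intervals are numeric [start, end) pairs in seconds;
# sets of intervals are 2-column matrices, assumed disjoint and ordered.

iv_intersect <- function(a, set) {
  if (!nrow(set)) return(set)
  s <- pmax(a[1], set[, 1]); e <- pmin(a[2], set[, 2])
  keep <- e > s
  cbind(s[keep], e[keep])
}

iv_subtract <- function(a, set) {
  # pieces of single interval a not covered by 'set'
  pieces <- matrix(a, ncol = 2)
  if (!nrow(set)) return(pieces)
  for (i in seq_len(nrow(set))) {
    out <- matrix(numeric(0), ncol = 2)
    for (j in seq_len(nrow(pieces))) {
      p <- pieces[j, ]
      s <- max(p[1], set[i, 1]); e <- min(p[2], set[i, 2])
      if (e <= s) { out <- rbind(out, p); next }
      if (p[1] < s) out <- rbind(out, c(p[1], s))
      if (e < p[2]) out <- rbind(out, c(e, p[2]))
    }
    pieces <- out
    if (!nrow(pieces)) break
  }
  pieces
}

iv_total <- function(set) if (nrow(set)) sum(set[, 2] - set[, 1]) else 0

#' Derive daily waking-wear windows from a sleep log
#'
#' Daily waking time is the complement of the logged in-bed interval:
#' each sleep record's interval `[bed_start, bed_end]` anchors a 24-hour
#' cycle, and the waking window runs from `bed_end` to the earlier of the
#' next record's `bed_start` and `bed_start + 24 h`. Days whose window is
#' empty (a full-day in-bed interval) are dropped, as are days with no
#' sleep record at all (no imputation). Windows are labelled by the
#' calendar date on which they start.
#'
#' @param sleep Data frame with columns `participant`, `date`,
#'   `bed_start`, `bed_end` (timestamps, timezone-naive local time).
#' @return Data frame `participant`, `day` (Date), `wake_start`,
#'   `wake_end` (POSIXct).
#' @export
derive_waking_windows <- function(sleep) {
  need <- c("participant", "date", "bed_start", "bed_end")
  if (!all(need %in% names(sleep)))
    stop("'sleep' must have columns ", paste(need, collapse = ", "))
  out <- lapply(split(sleep, sleep$participant), function(sl) {
    bs <- as_posix(sl$bed_start); be <- as_posix(sl$bed_end)
    if (any(be <= bs)) stop("bed_end must follow bed_start (participant ",
                            sl$participant[1], ")")
    o <- order(bs)
    sl <- sl[o, ]; bs <- bs[o]; be <- be[o]
    if (anyDuplicated(sl$date))
      stop("multiple sleep records on one date for participant ",
           sl$participant[1])
    n <- length(bs)
    if (n > 1 && any(bs[-1] < be[-n]))
      stop("overlapping in-bed intervals for participant ",
           sl$participant[1], " around date ",
           sl$date[which(bs[-1] < be[-n])[1] + 1])
    # waking time is the complement of sleep: up to the next logged
    # bed_start, or a 24-h cycle cap for the final record
    wake_start <- be
    wake_end <- c(bs[-1], bs[n] + 86400)
    keep <- wake_end > wake_start
    data.frame(participant = sl$participant[keep],
               day = as.Date(wake_start[keep], tz = "UTC"),
               wake_start = wake_start[keep], wake_end = wake_end[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Detect non-wear intervals from consecutive zero counts
#'
#' A parameterized consecutive-zero-minute detector in the spirit of the
#' Choi algorithm's headline parameters: maximal intervals of at least
#' `window_minutes` whose minutes are all-axis zero, allowing up to
#' `tolerance_minutes` of interior non-zero minutes, are flagged non-wear.
#' Minutes are calendar minutes of the 1-second count stream; a minute is
#' "zero" when every second of it has zero counts on all three axes.
#'
#' @param counts Data frame `participant`, `timestamp`, `va`, `ha`, `ppa`.
#' @param window_minutes Minimum interval length (default 90).
#' @param tolerance_minutes Maximum interior non-zero minutes (default 2).
#' @return Data frame `participant`, `start`, `end` (POSIXct, end
#'   exclusive); zero rows when no non-wear found.
#' @export
detect_nonwear <- function(counts, window_minutes = 90,
                           tolerance_minutes = 2) {
  empty <- data.frame(participant = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"))
  if (!nrow(counts)) return(empty)
  out <- lapply(split(counts, counts$participant), function(cc) {
    ts <- as_posix(cc$timestamp)
    minute <- floor(as.numeric(ts) / 60)
    total <- rowsum(cc$va + cc$ha + cc$ppa, minute)
    mins <- as.numeric(rownames(total))
    full <- seq(min(mins), max(mins))
    tot <- numeric(length(full))
    tot[match(mins, full)] <- total[, 1]
    zero <- tot == 0
    r <- rle(zero)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    res <- NULL
    i <- 1L
    while (i <= length(r$values)) {
      if (!r$values[i]) { i <- i + 1L; next }
      a <- starts[i]; b <- ends[i]; gap_used <- 0L; j <- i
      while (j + 2L <= length(r$values) &&
             gap_used + r$lengths[j + 1L] <= tolerance_minutes) {
        gap_used <- gap_used + r$lengths[j + 1L]
        j <- j + 2L
        b <- ends[j]
      }
      if (b - a + 1L >= window_minutes)
        res <- rbind(res, c(full[a], full[b] + 1))
      i <- j + 1L
    }
    if (is.null(res)) return(NULL)
    data.frame(participant = cc$participant[1],
               start = as.POSIXct(res[, 1] * 60, origin = "1970-01-01",
                                  tz = "UTC"),
               end = as.POSIXct(res[, 2] * 60, origin = "1970-01-01",
                                tz = "UTC"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) return(empty)
  rownames(out) <- NULL
  out
}

# aggregate per-second axis counts of one piece [s, e) to minutes with the
# fractional-minute rule: a final fraction < 30 s is dropped, otherwise its
# counts are rescaled by 60/f to approximate the last minute
minutes_from_seconds <- function(va, ha, ppa) {
  len <- length(va)
  k <- len %/% 60L
  f <- len - 60L * k
  idx <- if (k > 0) rep(seq_len(k), each = 60L) else integer(0)
  sums <- function(x) {
    full <- if (k > 0) rowsum(x[seq_len(60L * k)], idx)[, 1] else numeric(0)
    if (f >= 30L) c(full, sum(x[(60L * k + 1L):len]) * 60 / f) else full
  }
  va_m <- sums(va); ha_m <- sums(ha); ppa_m <- sums(ppa)
  data.frame(minute_index = seq_along(va_m), va_cpm = va_m, ha_cpm = ha_m,
             ppa_cpm = ppa_m,
             vm_cpm = sqrt(va_m^2 + ha_m^2 + ppa_m^2))
}

#' Extract concurrent waking-wear sitting bouts with minute-level counts
#'
#' Sitting events are intersected with the daily waking windows and any
#' non-wear intervals are removed (a sitting event split by non-wear yields
#' separate bouts); each remaining piece becomes one bout. The 1-second
#' tri-axial counts inside the bout are summed to counts per minute, the
#' fractional-minute rule is applied (final fraction < 30 s dropped,
#' otherwise rescaled by `60/f`), and the minute-level vector magnitude
#' `VM = sqrt(VA^2 + HA^2 + PPA^2)` is computed. Bouts with incomplete
#' 1-second count coverage are dropped with a warning; pieces shorter than
#' 30 s yield no retained minute and are discarded.
#'
#' @param events Data frame `participant`, `start`, `duration_s`,
#'   `posture` (`sitting`/`standing`/`stepping`).
#' @param waking_windows Output of [derive_waking_windows()].
#' @param nonwear Output of [detect_nonwear()] (may have zero rows).
#' @param counts Data frame `participant`, `timestamp`, `va`, `ha`, `ppa`.
#' @return Data frame with one row per bout-minute: `participant`, `day`,
#'   `bout_id`, `start`, `raw_length_s`, `n_minutes`, `minute_index`,
#'   `va_cpm`, `ha_cpm`, `ppa_cpm`, `vm_cpm`.
#' @export
extract_sitting_bouts <- function(events, waking_windows, nonwear, counts) {
  res <- list()
  for (p in unique(waking_windows$participant)) {
    ev <- events[events$participant == p & events$posture == "sitting", ,
                 drop = FALSE]
    if (!nrow(ev)) next
    ww <- waking_windows[waking_windows$participant == p, , drop = FALSE]
    nw <- nonwear[nonwear$participant == p, , drop = FALSE]
    nw_set <- cbind(as.numeric(as_posix(nw$start)),
                    as.numeric(as_posix(nw$end)))
    if (!nrow(nw)) nw_set <- matrix(numeric(0), ncol = 2)
    ev_start <- as.numeric(as_posix(ev$start))
    sit <- cbind(ev_start, ev_start + ev$duration_s)
    cc <- counts[counts$participant == p, , drop = FALSE]
    sec <- as.numeric(as_posix(cc$timestamp))
    for (w in seq_len(nrow(ww))) {
      win <- c(as.numeric(ww$wake_start[w]), as.numeric(ww$wake_end[w]))
      pieces <- iv_intersect(win, sit)
      bout_n <- 0L
      for (j in seq_len(nrow(pieces))) {
        for (k in seq_len(nrow(kept <- iv_subtract(pieces[j, ], nw_set)))) {
          s0 <- kept[k, 1]; e0 <- kept[k, 2]
          len <- round(e0 - s0)
          if (len < 30) next
          pos <- match(s0 + seq_len(len) - 1, sec)
          if (anyNA(pos)) {
            warning("dropping bout with missing count coverage ",
                    "(participant ", p, ", day ", ww$day[w], ")")
            next
          }
          m <- minutes_from_seconds(cc$va[pos], cc$ha[pos], cc$ppa[pos])
          if (!nrow(m)) next
          bout_n <- bout_n + 1L
          res[[length(res) + 1L]] <- data.frame(
            participant = p, day = ww$day[w],
            bout_id = sprintf("%s_%s_b%02d", p, format(ww$day[w]), bout_n),
            start = as.POSIXct(s0, origin = "1970-01-01", tz = "UTC"),
            raw_length_s = len, n_minutes = nrow(m), m,
            stringsAsFactors = FALSE, row.names = NULL)
        }
      }
    }
  }
  if (!length(res))
    return(data.frame(participant = character(0), day = as.Date(character(0)),
                      bout_id = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      raw_length_s = numeric(0), n_minutes = integer(0),
                      minute_index = integer(0), va_cpm = numeric(0),
                      ha_cpm = numeric(0), ppa_cpm = numeric(0),
                      vm_cpm = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-participant-day posture and validity summaries
#'
#' Computes, for each waking window, the concurrent sitting minutes
#' (sitting events intersected with the window, non-wear removed), the
#' standing and stepping minutes within the window, whether the day has
#' concurrent wear of both devices, and the valid-day flag: concurrent
#' wear and total daily sitting between `min_sit_minutes` and
#' `max_sit_minutes` (5 and 15 hours by default).
#'
#' @inheritParams extract_sitting_bouts
#' @param min_sit_minutes,max_sit_minutes Valid-day sitting bounds
#'   (defaults 300 and 900 minutes).
#' @return Data frame `participant`, `day`, `total_sitting_minutes`,
#'   `standing_minutes`, `stepping_minutes`, `concurrent`, `valid_day`.
#' @export
day_summaries <- function(events, waking_windows, nonwear, counts,
                          min_sit_minutes = 300, max_sit_minutes = 900) {
  out <- NULL
  for (p in unique(waking_windows$participant)) {
    ww <- waking_windows[waking_windows$participant == p, , drop = FALSE]
    ev <- events[events$participant == p, , drop = FALSE]
    nw <- nonwear[nonwear$participant == p, , drop = FALSE]
    nw_set <- if (nrow(nw)) cbind(as.numeric(as_posix(nw$start)),
                                  as.numeric(as_posix(nw$end)))
    else matrix(numeric(0), ncol = 2)
    ev_start <- as.numeric(as_posix(ev$start))
    ivs <- cbind(ev_start, ev_start + ev$duration_s)
    cc <- counts[counts$participant == p, , drop = FALSE]
    cspan <- if (nrow(cc)) {
      s <- as.numeric(as_posix(cc$timestamp))
      matrix(c(min(s), max(s) + 1), ncol = 2)
    } else matrix(numeric(0), ncol = 2)
    for (w in seq_len(nrow(ww))) {
      win <- c(as.numeric(ww$wake_start[w]), as.numeric(ww$wake_end[w]))
      mins <- vapply(c("sitting", "standing", "stepping"), function(po) {
        set <- iv_intersect(win, ivs[ev$posture == po, , drop = FALSE])
        if (po == "sitting" && nrow(set)) {
          set <- do.call(rbind, lapply(seq_len(nrow(set)), function(i)
            iv_subtract(set[i, ], nw_set)))
        }
        iv_total(set) / 60
      }, numeric(1))
      conc <- nrow(cspan) > 0 &&
        iv_total(iv_intersect(win, cspan)) > 0
      sit <- mins[["sitting"]]
      out <- rbind(out, data.frame(
        participant = p, day = ww$day[w],
        total_sitting_minutes = sit,
        standing_minutes = mins[["standing"]],
        stepping_minutes = mins[["stepping"]],
        concurrent = conc,
        valid_day = conc && sit >= min_sit_minutes && sit <= max_sit_minutes,
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Filter to valid days and valid sitting bouts
#'
#' Removes bouts on invalid days (non-concurrent wear or daily sitting
#' outside the 5-15 hour band, evaluated on total sitting before the
#' bout-length filter), then removes bouts longer than `max_bout_minutes`
#' (60 by default), and drops participants left with no valid day.
#'
#' @param bouts Bout-minute table from [extract_sitting_bouts()].
#' @param summaries Day table from [day_summaries()].
#' @param max_bout_minutes Maximum retained bout length (default 60).
#' @return List with `bouts` (filtered bout-minute table), `days` (valid
#'   day table), and `report`, a named list of exclusion counts.
#' @export
filter_valid <- function(bouts, summaries, max_bout_minutes = 60) {
  key <- function(p, d) paste(p, d, sep = "\r")
  valid <- summaries[summaries$valid_day, , drop = FALSE]
  on_valid <- key(bouts$participant, bouts$day) %in%
    key(valid$participant, valid$day)
  bouts_valid <- bouts[on_valid, , drop = FALSE]
  short <- bouts_valid$n_minutes <= max_bout_minutes
  out_bouts <- bouts_valid[short, , drop = FALSE]
  n_bout <- function(b) length(unique(b$bout_id))
  days_kept <- valid  # a valid day with no retained bout still counts as wear
  report <- list(
    n_days = nrow(summaries),
    n_valid_days = nrow(valid),
    n_days_excluded = nrow(summaries) - nrow(valid),
    n_bouts = n_bout(bouts),
    n_bouts_on_invalid_days = n_bout(bouts) - n_bout(bouts_valid),
    n_bouts_too_long = n_bout(bouts_valid) - n_bout(out_bouts),
    n_participants = length(unique(summaries$participant)),
    n_participants_retained = length(unique(valid$participant)))
  rownames(out_bouts) <- NULL
  list(bouts = out_bouts, days = days_kept, report = report)
}

#' Average daily activity summaries over valid days
#'
#' Per participant: the mean over valid days of standing, stepping and
#' non-sitting (standing + stepping) minutes, plus mean daily sitting and
#' the number of valid days. Participants with no valid day are absent.
#'
#' @param summaries Day table from [day_summaries()] (all days; only
#'   `valid_day` rows contribute).
#' @return Data frame `participant`, `n_valid_days`,
#'   `avg_daily_sitting_min`, `avg_daily_standing_min`,
#'   `avg_daily_stepping_min`, `avg_daily_nonsitting_min`.
#' @export
daily_activity_summaries <- function(summaries) {
  v <- summaries[summaries$valid_day, , drop = FALSE]
  if (!nrow(v))
    return(data.frame(participant = character(0), n_valid_days = integer(0),
                      avg_daily_sitting_min = numeric(0),
                      avg_daily_standing_min = numeric(0),
                      avg_daily_stepping_min = numeric(0),
                      avg_daily_nonsitting_min = numeric(0)))
  agg <- lapply(split(v, v$participant), function(d) data.frame(
    participant = d$participant[1],
    n_valid_days = nrow(d),
    avg_daily_sitting_min = mean(d$total_sitting_minutes),
    avg_daily_standing_min = mean(d$standing_minutes),
    avg_daily_stepping_min = mean(d$stepping_minutes),
    avg_daily_nonsitting_min = mean(d$standing_minutes + d$stepping_minutes),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Run the full device-stream preprocessing chain
#'
#' Convenience wrapper: waking windows from the sleep log, non-wear
#' detection, sitting-bout extraction with minute aggregation, day
#' summaries, valid-day/valid-bout filtering, and per-participant daily
#' activity averages.
#'
#' @param events,counts,sleep The three raw stream tables.
#' @param nonwear_window,nonwear_tolerance Passed to [detect_nonwear()].
#' @param min_sit_minutes,max_sit_minutes,max_bout_minutes Validity
#'   thresholds.
#' @return List with `bouts`, `days`, `daily`, `report`, `windows`,
#'   `nonwear`.
#' @export
preprocess_streams <- function(events, counts, sleep,
                               nonwear_window = 90, nonwear_tolerance = 2,
                               min_sit_minutes = 300, max_sit_minutes = 900,
                               max_bout_minutes = 60) {
  windows <- derive_waking_windows(sleep)
  nonwear <- detect_nonwear(counts, nonwear_window, nonwear_tolerance)
  bouts <- extract_sitting_bouts(events, windows, nonwear, counts)
  summaries <- day_summaries(events, windows, nonwear, counts,
                             min_sit_minutes, max_sit_minutes)
  filt <- filter_valid(bouts, summaries, max_bout_minutes)
  daily <- daily_activity_summaries(summaries)
  daily <- daily[daily$participant %in% filt$days$participant, , drop = FALSE]
  list(bouts = filt$bouts, days = filt$days, daily = daily,
       report = filt$report, windows = windows, nonwear = nonwear)
}
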