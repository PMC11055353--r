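test_that("waking windows are the complement of logged in-bed time", {
  sleep <- data.frame(
    participant = "P1", date = as.Date("2020-06-01"),
    bed_start = as.POSIXct("2020-05-31 22:00:00", tz = "UTC"),
    bed_end = as.POSIXct("2020-06-01 06:00:00", tz = "UTC"))
  ww <- derive_waking_windows(sleep)
  expect_equal(nrow(ww), 1L)
  expect_equal(ww$wake_start, as.POSIXct("2020-06-01 06:00:00", tz = "UTC"))
  expect_equal(ww$wake_end, as.POSIXct("2020-05-31 22:00:00", tz = "UTC") + 86400)
  expect_equal(ww$day, as.Date("2020-06-01"))

  # a full-24h in-bed interval leaves no waking window: day dropped
  allday <- data.frame(
    participant = "P1", date = as.Date("2020-06-01"),
    bed_start = as.POSIXct("2020-06-01 00:00:00", tz = "UTC"),
    bed_end = as.POSIXct("2020-06-02 00:00:00", tz = "UTC"))
  expect_equal(nrow(derive_waking_windows(allday)), 0L)

  # two nights give two disjoint windows, clipped at the next bed_start
  two <- data.frame(
    participant = "P1", date = as.Date(c("2020-06-01", "2020-06-02")),
    bed_start = as.POSIXct(c("2020-05-31 22:00:00", "2020-06-01 23:00:00"),
                           tz = "UTC"),
    bed_end = as.POSIXct(c("2020-06-01 06:00:00", "2020-06-02 07:00:00"),
                         tz = "UTC"))
  ww2 <- derive_waking_windows(two)
  expect_equal(nrow(ww2), 2L)
  expect_true(all(ww2$wake_end[1] <= ww2$wake_start[2]))
  expect_equal(as.numeric(difftime(ww2$wake_end[1], ww2$wake_start[1],
                                   units = "hours")), 17)

  # overlapping in-bed intervals name the participant
  bad <- two
  bad$bed_start[2] <- as.POSIXct("2020-06-01 05:00:00", tz = "UTC")
  expect_error(derive_waking_windows(bad), "P1")
})

test_that("non-wear detection matches a brute-force zero-run oracle", {
  win <- 90; tol <- 2
  start <- "2020-06-01 08:00:00"
  cases <- list(
    all_zero_120 = rep(0L, 120),
    bounded_89 = c(5L, rep(0L, 89), 5L),
    zeros_200_one_spike = c(5L, rep(0L, 99), 3L, rep(0L, 100), 5L))
  for (nm in names(cases)) {
    tot <- cases[[nm]]
    # one count row per second, constant within each minute
    counts <- counts_table("P1", start, rep(tot, each = 60))
    nw <- detect_nonwear(counts, win, tol)
    oracle <- nonwear_oracle(tot == 0, win, tol)
    if (is.null(oracle)) {
      expect_equal(nrow(nw), 0L, info = nm)
    } else {
      expect_equal(nrow(nw), nrow(oracle), info = nm)
      got_min <- as.numeric(difftime(nw$end, nw$start, units = "mins"))
      expect_equal(got_min, oracle[, 2] - oracle[, 1] + 1, info = nm)
    }
  }
  # the spike case merges across the tolerated nonzero minute: 200 minutes
  tot <- cases$zeros_200_one_spike
  counts <- counts_table("P1", start, rep(tot, each = 60))
  nw <- detect_nonwear(counts, win, tol)
  expect_equal(as.numeric(difftime(nw$end, nw$start, units = "mins")), 200)
  expect_equal(nrow(detect_nonwear(counts[0, ], win, tol)), 0L)
})

test_that("fractional-minute rule drops < 30 s and rescales >= 30 s", {
  # scripted sitting segments: 625 s (25 s dropped -> 10 min),
  # 640 s at constant 10 counts/s VA (40 s -> minute 11 at 600 cpm),
  # 630 s (exactly 30 s retained and rescaled x2)
  schedule <- rbind(
    seg(1, "standing", 600),
    seg(1, "sitting", 625, va = 10),
    seg(1, "standing", 600),
    seg(1, "sitting", 640, va = 10),
    seg(1, "standing", 600),
    seg(1, "sitting", 630, va = 7))
  st <- scripted_streams(schedule)
  pp <- preprocess_streams(st$events, st$counts, st$sleep,
                           min_sit_minutes = 0, max_sit_minutes = 1440)
  bouts <- pp$bouts
  per_bout <- bouts[!duplicated(bouts$bout_id), ]
  expect_equal(per_bout$n_minutes, c(10L, 11L, 11L))
  b2 <- bouts[bouts$bout_id == per_bout$bout_id[2], ]
  expect_equal(b2$va_cpm[11], 10 * 40 * (60 / 40))  # 600 cpm
  expect_equal(b2$va_cpm[1:10], rep(600, 10))
  b3 <- bouts[bouts$bout_id == per_bout$bout_id[3], ]
  expect_equal(b3$va_cpm[11], 7 * 30 * (60 / 30))   # boundary retained
  # VM dominates each axis and equals VA when other axes are zero
  expect_true(all(bouts$vm_cpm >= bouts$va_cpm))
  expect_equal(bouts$vm_cpm, bouts$va_cpm)
})

test_that("a sitting event split by non-wear yields separate bouts", {
  # 10 min sitting at 20 cps, 100 min sitting at 0 counts (non-wear),
  # then 10 min sitting at 20 cps again; waking window 06:00-22:00
  schedule <- rbind(
    seg(1, "stepping", 300, va = 30),
    seg(1, "sitting", 600, va = 20),
    seg(1, "sitting", 6000, va = 0),
    seg(1, "sitting", 600, va = 20),
    seg(1, "stepping", 300, va = 30))
  st <- scripted_streams(schedule)
  pp <- preprocess_streams(st$events, st$counts, st$sleep,
                           min_sit_minutes = 0, max_sit_minutes = 1440)
  # the 100 zero-count minutes inside the sitting block are flagged
  nw_min <- as.numeric(difftime(pp$nonwear$end, pp$nonwear$start,
                                units = "mins"))
  expect_true(100 %in% nw_min)
  per_bout <- pp$bouts[!duplicated(pp$bouts$bout_id), ]
  expect_equal(per_bout$n_minutes, c(10L, 10L))
  expect_true(all(per_bout$raw_length_s == 600))
})

test_that("valid-day and bout-length filters follow the 5-15 h / 60 min rules", {
  days <- as.Date("2020-06-01") + 0:2
  summaries <- data.frame(
    participant = c("A", "A", "B"), day = days[c(1, 2, 1)],
    total_sitting_minutes = c(294, 400, 200),  # 4.9 h invalid, 400 valid
    standing_minutes = c(100, 200, 50), stepping_minutes = c(10, 60, 5),
    concurrent = TRUE,
    valid_day = c(FALSE, TRUE, FALSE))
  mk_bout <- function(p, day, id, n) data.frame(
    participant = p, day = day, bout_id = id, n_minutes = n,
    minute_index = seq_len(n), va_cpm = 0, vm_cpm = 0)
  bouts <- rbind(mk_bout("A", days[1], "a1", 10),   # on invalid day
                 mk_bout("A", days[2], "a2", 61),   # too long
                 mk_bout("A", days[2], "a3", 60),   # retained
                 mk_bout("B", days[1], "b1", 5))    # invalid day
  f <- filter_valid(bouts, summaries)
  expect_equal(unique(f$bouts$bout_id), "a3")
  expect_equal(f$report$n_bouts_on_invalid_days, 2L)
  expect_equal(f$report$n_bouts_too_long, 1L)
  # participant B has no valid day: absent everywhere
  expect_false("B" %in% f$days$participant)
  expect_false("B" %in% f$bouts$participant)
})

test_that("daily activity summaries average over valid days", {
  s <- data.frame(
    participant = c("A", "A", "A"), day = as.Date("2020-06-01") + 0:2,
    total_sitting_minutes = c(400, 420, 500),
    standing_minutes = c(200, 240, 999),
    stepping_minutes = c(60, 60, 999),
    concurrent = TRUE, valid_day = c(TRUE, TRUE, FALSE))
  d <- daily_activity_summaries(s)
  expect_equal(d$avg_daily_nonsitting_min, (260 + 300) / 2)
  expect_equal(d$n_valid_days, 2L)
  expect_equal(nrow(daily_activity_summaries(s[s$valid_day == FALSE, ])), 0L)
})
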