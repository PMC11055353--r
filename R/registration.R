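#' Length of the ordered-bout index domain
#'
#' Sitting bouts of 1..B minutes are laid end to end, so the common
#' registration grid has `T(B) = B(B+1)/2` one-minute indices
#' (1830 for the default maximum bout length of 60 minutes).
#'
#' @param B Maximum bout length in minutes (positive integer).
#' @return Integer grid length `B(B+1)/2`.
#' @export
triangular_length <- function(B) {
  B <- check_pos_int(B, "B")
  as.integer(B * (B + 1L) / 2L)
}

#' Map (bout length, minute) to the registration index and back
#'
#' The ordered-bout domain concatenates all bout lengths `b = 1..B`; minute
#' `m` of the length-`b` bout sits at `t = b(b-1)/2 + m`. So `t = 1` is the
#' 1-minute bout, `t = 4..6` is the 3-minute bout, and minute 8 of the
#' 8-minute bout is `t = 36`.
#'
#' @param b Bout length(s) in minutes, `1 <= b <= B`.
#' @param m Minute index (indices) within the bout, `1 <= m <= b`.
#' @param t Registration index (indices), `1 <= t <= B(B+1)/2`.
#' @param B Maximum bout length (default 60).
#' @return `bout_index`: integer vector of indices `t`.
#'   `inverse_bout_index`: data.frame with columns `b` and `m`.
#' @export
bout_index <- function(b, m, B = 60L) {
  B <- check_pos_int(B, "B")
  if (length(b) == 0L || length(m) == 0L)
    stop("'b' and 'm' must be non-empty")
  bm <- vec_recycle(b, m)
  b <- bm[[1]]; m <- bm[[2]]
  if (any(b != floor(b)) || any(m != floor(m)))
    stop("'b' and 'm' must be integers")
  if (any(b < 1L) || any(b > B)) stop("'b' out of range 1..", B)
  if (any(m < 1L) || any(m > b)) stop("'m' out of range 1..b")
  as.integer(b * (b - 1L) / 2L + m)
}

#' @rdname bout_index
#' @export
inverse_bout_index <- function(t, B = 60L) {
  B <- check_pos_int(B, "B")
  if (any(t != floor(t)) || any(t < 1L) || any(t > triangular_length(B)))
    stop("'t' out of range 1..", triangular_length(B))
  b <- as.integer(ceiling((-1 + sqrt(1 + 8 * t)) / 2))
  m <- as.integer(t - b * (b - 1L) / 2L)
  data.frame(b = b, m = m)
}

#' Bout length of each registration index
#'
#' @param B Maximum bout length.
#' @return Integer vector of length `T(B)` giving the bout length that
#'   index `t` belongs to, i.e. `rep(1:B, 1:B)`.
#' @export
grid_bout_lengths <- function(B = 60L) {
  B <- check_pos_int(B, "B")
  rep.int(seq_len(B), seq_len(B))
}

#' Register one participant-day onto the ordered-bout domain
#'
#' Valid sitting bouts for a participant-day are placed on the common index
#' grid by their length: the per-minute VM counts of a length-`b` bout fill
#' indices `bout_index(b, 1..b)`. Multiple bouts of the same length are
#' averaged minute-wise; lengths not registered that day stay missing, so
#' every length-`b` block is either fully observed or fully missing.
#'
#' @param bout_minutes List of numeric vectors, one per bout, each holding
#'   that bout's per-minute VM counts (length = bout length in minutes).
#' @param B Maximum bout length (bouts longer than `B` are an error;
#'   filter upstream with [filter_valid()]).
#' @return List with `values` (numeric vector, `NA` where missing) and
#'   `mask` (logical vector, `TRUE` = observed), both of length `T(B)`.
#' @export
register_day <- function(bout_minutes, B = 60L) {
  B <- check_pos_int(B, "B")
  Tn <- triangular_length(B)
  values <- rep(NA_real_, Tn)
  if (length(bout_minutes)) {
    lens <- lengths(bout_minutes)
    if (any(lens < 1L)) stop("empty bout in 'bout_minutes'")
    if (any(lens > B)) stop("bout longer than B = ", B, " minutes")
    for (b in unique(lens)) {
      vs <- bout_minutes[lens == b]
      avg <- Reduce(`+`, vs) / length(vs)
      if (any(!is.finite(avg)) || any(avg < 0))
        stop("bout VM counts must be finite and non-negative")
      values[bout_index(b, seq_len(b), B)] <- avg
    }
  }
  list(values = values, mask = !is.na(values))
}

#' Build the registered curve matrix for all participant-days
#'
#' Registers every participant-day in a long bout-minute table onto the
#' ordered-bout domain and stacks them into the (rows x T(B)) matrix the
#' MFPCA consumes. Participant-days whose row would be entirely missing
#' (no valid bouts) are not emitted.
#'
#' @param bouts Data frame with one row per bout-minute, with columns
#'   `participant`, `day`, `bout_id`, `minute_index` and `vm_cpm`
#'   (the format produced by [extract_sitting_bouts()]).
#' @param B Maximum bout length.
#' @return List of class `"registered_matrix"`: `values` (rows x T matrix),
#'   `mask` (logical matrix), `index` (data.frame `participant`, `day`,
#'   `day_order` = within-participant day rank), and `missingness`, the
#'   bookkeeping summary from [missingness_summary()].
#' @export
build_matrix <- function(bouts, B = 60L) {
  need <- c("participant", "day", "bout_id", "minute_index", "vm_cpm")
  if (!all(need %in% names(bouts)))
    stop("'bouts' must have columns ", paste(need, collapse = ", "))
  B <- check_pos_int(B, "B")
  key <- interaction(bouts$participant, bouts$day, drop = TRUE, sep = "\r")
  keys <- levels(key)
  ids <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  index <- data.frame(participant = ids[, 1], day = ids[, 2],
                      stringsAsFactors = FALSE)
  ord <- order(index$participant, index$day)
  if (anyDuplicated(index[c("participant", "day")]))
    stop("duplicate (participant, day) rows")
  rows <- lapply(keys, function(k) {
    bd <- bouts[key == k, , drop = FALSE]
    register_day(split(bd$vm_cpm, bd$bout_id)[
      as.character(unique(bd$bout_id))], B = B)
  })
  values <- do.call(rbind, lapply(rows, `[[`, "values"))[ord, , drop = FALSE]
  mask <- do.call(rbind, lapply(rows, `[[`, "mask"))[ord, , drop = FALSE]
  index <- index[ord, , drop = FALSE]
  keep <- rowSums(mask) > 0L
  values <- values[keep, , drop = FALSE]
  mask <- mask[keep, , drop = FALSE]
  index <- index[keep, , drop = FALSE]
  rownames(values) <- rownames(mask) <- rownames(index) <- NULL
  index$day_order <- stats::ave(seq_len(nrow(index)), index$participant,
                                FUN = seq_along)
  structure(list(values = values, mask = mask, index = index,
                 missingness = missingness_summary(mask, B = B)),
            class = "registered_matrix")
}

#' Unregistered-bout and cell-level missingness bookkeeping
#'
#' For each bout length `b`, counts the participant-days that did not
#' register a `b`-minute bout (`m_b`) and reports the per-length
#' unregistered rate `m_b / n_rows` plus the overall cell-missing rate
#' `sum_b(m_b * b) / (n_rows * T(B))`.
#'
#' @param mask Logical matrix (rows x T(B)), `TRUE` = observed. Each
#'   length-`b` block of a row must be constant (block-atomic missingness).
#' @param B Maximum bout length.
#' @return List with `n_rows`, `per_bout` (data.frame `b`, `m_b`,
#'   `unregistered_rate`), `mean_unregistered_rate` (average of the per-b
#'   rates) and `overall_missing_rate` (cell-level).
#' @export
missingness_summary <- function(mask, B = 60L) {
  B <- check_pos_int(B, "B")
  Tn <- triangular_length(B)
  if (ncol(mask) != Tn)
    stop("mask has ", ncol(mask), " columns; expected T(B) = ", Tn)
  bl <- grid_bout_lengths(B)
  first <- bout_index(seq_len(B), 1L, B)
  for (b in seq_len(B)) {
    idx <- bout_index(b, seq_len(b), B)
    ok <- mask[, idx, drop = FALSE]
    if (b > 1L && any(rowSums(ok) %% b != 0L))
      stop("mask is not block-atomic for bout length ", b)
  }
  m_b <- vapply(seq_len(B),
                function(b) sum(!mask[, first[b]]), integer(1))
  n_rows <- nrow(mask)
  per_bout <- data.frame(b = seq_len(B), m_b = m_b,
                         unregistered_rate = m_b / n_rows)
  list(n_rows = n_rows,
       per_bout = per_bout,
       mean_unregistered_rate = mean(per_bout$unregistered_rate),
       overall_missing_rate = sum(m_b * seq_len(B)) / (n_rows * Tn))
}
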