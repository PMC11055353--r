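#' Classify sitting minutes as inactive or active (POPAI)
#'
#' The Posture and Physical Activity Index labels each minute within a
#' sitting bout by its vertical-axis counts: strictly below the cut-point
#' (75 cpm by default) is inactive sitting, at or above it is active
#' sitting. Minutes approximated from a rescaled final bout fraction are
#' classified on their rescaled cpm value.
#'
#' @param va_cpm Numeric vector of per-minute vertical-axis counts.
#' @param cutpoint Cut-point in counts per minute (default 75).
#' @return Logical vector, `TRUE` = inactive sitting.
#' @export
classify_minutes <- function(va_cpm, cutpoint = 75) {
  if (length(va_cpm) == 0L) return(logical(0))
  if (any(!is.finite(va_cpm)) || any(va_cpm < 0))
    stop("'va_cpm' must be finite and non-negative")
  va_cpm < cutpoint
}

#' Average daily inactive and active sitting time per participant
#'
#' Minute classifications are summed across all of a participant's valid
#' sitting bouts and divided by that participant's number of valid wear
#' days, so `inactive + active` equals average daily valid sitting
#' minutes exactly.
#'
#' @param bouts Valid bout-minute table (from [filter_valid()]), with
#'   columns `participant` and `va_cpm`.
#' @param valid_days Valid-day table with columns `participant`, `day`.
#' @param cutpoint POPAI cut-point in counts per minute (default 75).
#' @return Data frame `participant`, `avg_daily_inactive_sitting_min`,
#'   `avg_daily_active_sitting_min`, `n_valid_days`. Participants with no
#'   valid day are absent.
#' @export
popai_summary <- function(bouts, valid_days, cutpoint = 75) {
  nd <- table(unique(valid_days[c("participant", "day")])$participant)
  participants <- names(nd)[nd > 0]
  inact <- classify_minutes(bouts$va_cpm, cutpoint)
  out <- lapply(participants, function(p) {
    sel <- bouts$participant == p
    data.frame(participant = p,
               avg_daily_inactive_sitting_min = sum(inact[sel]) / nd[[p]],
               avg_daily_active_sitting_min = sum(!inact[sel]) / nd[[p]],
               n_valid_days = nd[[p]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
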