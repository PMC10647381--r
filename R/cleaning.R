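#' Cleaning configuration
#'
#' Parameters of the NN-interval cleaning stage.
#'
#' @param allowable_change Maximum relative change allowed between consecutive
#'   NN intervals, as a fraction in (0, 1). An interval must lie strictly
#'   inside `(prev * (1 - a), prev * (1 + a))` of the previously accepted
#'   interval. Default 0.15 (15%).
#' @param min_run Minimum number of NN intervals a clean segment must contain
#'   to be used for HRV; shorter runs are dropped. Default 6.
#' @param pause_ms Any RR interval at least this long is treated as a sinus
#'   pause/arrest and excludes the recording. Default 3000 ms (a conventional
#'   clinical cut-off).
#' @param afib_flag_excludes Whether a diagnosed-AFIB flag excludes the
#'   recording. Default `TRUE`.
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(allowable_change = 0.15, min_run = 6L,
                            pause_ms = 3000, afib_flag_excludes = TRUE) {
  stopifnot(allowable_change > 0, allowable_change < 1,
            min_run >= 2, pause_ms > 0)
  structure(
    list(allowable_change = allowable_change, min_run = as.integer(min_run),
         pause_ms = pause_ms, afib_flag_excludes = isTRUE(afib_flag_excludes)),
    class = "cleaning_config"
  )
}

#' Screen a recording for exclusion criteria
#'
#' Recordings from subjects with diagnosed atrial fibrillation, and recordings
#' containing a sinus pause or arrest (any RR interval of at least
#' `config$pause_ms`), are excluded from HRV processing entirely. Intervals
#' bounded by an `X` artifact marker are not pause candidates: the gap they
#' span is a detected artifact, already handled by segment cleaning.
#'
#' @param rr An RR tibble from [beats_to_rr()].
#' @param afib_diagnosed Logical flag from the dataset annotations.
#' @param config A [cleaning_config()].
#' @return A list with elements `accepted` (logical) and `reason`
#'   (`NA`, `"afib"` or `"pause"`).
#' @export
screen_recording <- function(rr, afib_diagnosed = FALSE,
                             config = cleaning_config()) {
  stopifnot(nrow(rr) > 0)
  if (isTRUE(afib_diagnosed) && config$afib_flag_excludes) {
    return(list(accepted = FALSE, reason = "afib"))
  }
  candidate <- rr$start_label != "X" & rr$end_label != "X"
  if (any(rr$rr_ms[candidate] >= config$pause_ms)) {
    return(list(accepted = FALSE, reason = "pause"))
  }
  list(accepted = TRUE, reason = NA_character_)
}

#' NN relative-change bound
#'
#' Tests whether a candidate NN interval lies strictly inside the allowed
#' relative-change band around the previously accepted interval:
#' `prev * (1 - a) < cur < prev * (1 + a)` with `a = allowable_change`.
#'
#' @param prev_ms,cur_ms Previous accepted and current NN interval (ms).
#' @param config A [cleaning_config()].
#' @return Logical (vectorised over `prev_ms`/`cur_ms`).
#' @export
nn_bound_ok <- function(prev_ms, cur_ms, config = cleaning_config()) {
  if (any(prev_ms <= 0) || any(cur_ms <= 0)) stop("intervals must be positive")
  a <- config$allowable_change
  cur_ms > prev_ms * (1 - a) & cur_ms < prev_ms * (1 + a)
}

#' Extract clean NN segments
#'
#' Scans an RR series and emits the contiguous runs of normal-to-normal
#' intervals that survive cleaning: intervals adjacent to ectopic (`A`, `V`,
#' `S`), fusion (`F`), unclassifiable (`Q`) beats or artifact markers (`X`)
#' are rejected; within a run each interval must satisfy [nn_bound_ok()]
#' against its accepted predecessor (a violating interval is discarded and the
#' following interval starts a fresh run with no baseline); runs shorter than
#' `config$min_run` intervals are dropped.
#'
#' @param rr An RR tibble from [beats_to_rr()].
#' @param config A [cleaning_config()].
#' @return A tibble with columns `segment_id`, `onset_ms`, `rr_ms`; empty
#'   (zero rows) when no run qualifies.
#' @examples
#' beats <- tibble::tibble(
#'   time_ms = cumsum(c(0, 800, 820, 1200, 810, 805, 800, 795, 790, 805, 800)),
#'   label = "N"
#' )
#' extract_nn_segments(beats_to_rr(beats))
#' @export
extract_nn_segments <- function(rr, config = cleaning_config()) {
  stopifnot(nrow(rr) > 0)
  nn_ok <- rr$start_label == "N" & rr$end_label == "N"
  ids <- nn_run_ids(rr$rr_ms, nn_ok, config$allowable_change)
  keep <- ids > 0L
  if (!any(keep)) {
    return(tibble(segment_id = integer(), onset_ms = double(), rr_ms = double()))
  }
  counts <- tabulate(ids[keep])
  long_enough <- which(counts >= config$min_run)
  keep <- keep & ids %in% long_enough
  if (!any(keep)) {
    return(tibble(segment_id = integer(), onset_ms = double(), rr_ms = double()))
  }
  old <- ids[keep]
  tibble(
    segment_id = match(old, sort(unique(old))),
    onset_ms = rr$onset_ms[keep],
    rr_ms = rr$rr_ms[keep]
  )
}
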