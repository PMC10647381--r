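#' Time-domain HRV scalar parameters
#'
#' Standard time-domain statistics of an NN-interval sequence, all in
#' milliseconds unless noted. `hrv_sdnn()` is the sample standard deviation
#' (n - 1 divisor) of the intervals; `hrv_rmssd()` the root mean square of
#' successive differences; `hrv_nn50()` the number of successive pairs
#' differing by more than 50 ms (strict); `hrv_pnn50()` that count as a
#' percentage of all successive pairs.
#'
#' All return `NA` when fewer than 2 intervals are supplied (the statistic is
#' undefined there).
#'
#' @param nn Numeric vector of NN intervals (ms).
#' @return A single numeric value (`hrv_nn50()` an integer count).
#' @examples
#' nn <- c(800, 810, 790, 805, 795)
#' hrv_sdnn(nn)   # 7.9057
#' hrv_rmssd(nn)  # 14.3614
#' @name hrv_time_domain_scalars
NULL

#' @rdname hrv_time_domain_scalars
#' @export
hrv_sdnn <- function(nn) {
  if (length(nn) < 2) return(NA_real_)
  sd(nn)
}

#' @rdname hrv_time_domain_scalars
#' @export
hrv_rmssd <- function(nn) {
  if (length(nn) < 2) return(NA_real_)
  sqrt(mean(diff(nn)^2))
}

#' @rdname hrv_time_domain_scalars
#' @export
hrv_nn50 <- function(nn) {
  if (length(nn) < 2) return(NA_integer_)
  sum(abs(diff(nn)) > 50)
}

#' @rdname hrv_time_domain_scalars
#' @export
hrv_pnn50 <- function(nn) {
  if (length(nn) < 2) return(NA_real_)
  100 * sum(abs(diff(nn)) > 50) / (length(nn) - 1)
}

#' Poincare (lag-1 return map) descriptors
#'
#' SD1 and SD2 are the minor and major axes of the Poincare ellipse, computed
#' from the standard identities `sd1 = rmssd / sqrt(2)` and
#' `sd2^2 = 2 * sdnn^2 - sd1^2` (floored at 0), with the same n - 1 divisor
#' convention as [hrv_sdnn()]. The ratio `sd1/sd2` is `NA` when SD2 is 0.
#'
#' @param nn Numeric vector of NN intervals (ms); at least 3 required.
#' @return A named list with `sd1`, `sd2`, `sd1_sd2`.
#' @export
hrv_poincare <- function(nn) {
  if (length(nn) < 3) return(list(sd1 = NA_real_, sd2 = NA_real_, sd1_sd2 = NA_real_))
  sd1 <- hrv_rmssd(nn) / sqrt(2)
  sd2 <- sqrt(max(0, 2 * hrv_sdnn(nn)^2 - sd1^2))
  list(sd1 = sd1, sd2 = sd2, sd1_sd2 = if (sd2 > 0) sd1 / sd2 else NA_real_)
}

#' SDANN and ASDNN over 5-minute bins
#'
#' Partitions a window into contiguous `bin_min`-minute bins by interval onset
#' time. SDANN is the sample standard deviation of the per-bin mean NN;
#' ASDNN the mean of the per-bin sample standard deviations. Bins holding
#' fewer than 2 intervals are skipped; both statistics are `NA` unless at
#' least 2 bins qualify.
#'
#' @param onset_ms,rr_ms Interval onsets and lengths (ms).
#' @param window_start_ms Start of the window the bins partition.
#' @param bin_min Bin length in minutes (default 5).
#' @return A named list with `sdann` and `asdnn`.
#' @export
hrv_sdann_asdnn <- function(onset_ms, rr_ms, window_start_ms = 0, bin_min = 5) {
  if (length(rr_ms) == 0) return(list(sdann = NA_real_, asdnn = NA_real_))
  bin <- floor((onset_ms - window_start_ms) / (bin_min * 60000))
  sizes <- tabulate(bin + 1L)
  ok_bins <- which(sizes >= 2L)
  if (length(ok_bins) < 2L) return(list(sdann = NA_real_, asdnn = NA_real_))
  grp <- split(rr_ms, bin)
  grp <- grp[lengths(grp) >= 2L]
  means <- vapply(grp, mean, 0)
  sds <- vapply(grp, sd, 0)
  list(sdann = sd(means), asdnn = mean(sds))
}

segment_params <- function(nn) {
  pc <- hrv_poincare(nn)
  c(sdnn = hrv_sdnn(nn), rmssd = hrv_rmssd(nn),
    nn50 = as.numeric(hrv_nn50(nn)), pnn50 = hrv_pnn50(nn),
    sd1 = pc$sd1, sd2 = pc$sd2, sd1_sd2 = pc$sd1_sd2)
}

empty_hrv_row <- function(method, reason) {
  tibble(method = method, sdnn = NA_real_, sdann = NA_real_, asdnn = NA_real_,
         rmssd = NA_real_, nn50 = NA_real_, pnn50 = NA_real_, sd1 = NA_real_,
         sd2 = NA_real_, sd1_sd2 = NA_real_, n_intervals = 0L, reason = reason)
}

#' HRV by the Average method
#'
#' Computes each scalar HRV parameter per clean segment and reports the
#' unweighted arithmetic mean across segments (so `nn50` is a real-valued mean
#' count). SDANN/ASDNN are instead computed on the window's 5-minute bins of
#' all accepted intervals, since individual segments may be shorter than a
#' bin.
#'
#' @param segments A segment tibble from [extract_nn_segments()].
#' @param window_start_ms Window start used to anchor the 5-minute bins.
#' @return A one-row tibble (`method = "A"`) with columns `sdnn`, `sdann`,
#'   `asdnn`, `rmssd`, `nn50`, `pnn50`, `sd1`, `sd2`, `sd1_sd2`,
#'   `n_intervals`, `reason`.
#' @export
hrv_average <- function(segments, window_start_ms = 0) {
  if (nrow(segments) == 0) return(empty_hrv_row("A", "no clean segments"))
  per_seg <- vapply(split(segments$rr_ms, segments$segment_id),
                    segment_params, numeric(7))
  m <- as.list(rowMeans(per_seg))
  bins <- hrv_sdann_asdnn(segments$onset_ms, segments$rr_ms, window_start_ms)
  tibble(method = "A", sdnn = m$sdnn, sdann = bins$sdann,
         asdnn = bins$asdnn, rmssd = m$rmssd, nn50 = m$nn50,
         pnn50 = m$pnn50, sd1 = m$sd1, sd2 = m$sd2,
         sd1_sd2 = m$sd1_sd2, n_intervals = nrow(segments),
         reason = NA_character_)
}

#' HRV by the Combined method
#'
#' Computes each parameter once over the concatenation of all clean segments.
#' Successive-difference statistics (RMSSD, NN50, pNN50, SD1) never take a
#' difference across a segment junction: the jump between the end of one
#' segment and the start of the next is exactly what cleaning removed, so
#' junction pairs are skipped.
#'
#' @inheritParams hrv_average
#' @return A one-row tibble (`method = "C"`) with the same columns as
#'   [hrv_average()].
#' @export
hrv_combined <- function(segments, window_start_ms = 0) {
  if (nrow(segments) == 0) return(empty_hrv_row("C", "no clean segments"))
  nn <- segments$rr_ms
  if (length(nn) < 2) return(empty_hrv_row("C", "fewer than 2 intervals"))
  same_seg <- segments$segment_id[-1] == segments$segment_id[-nrow(segments)]
  d <- diff(nn)[same_seg]
  sdnn <- sd(nn)
  rmssd <- if (length(d) > 0) sqrt(mean(d^2)) else NA_real_
  nn50 <- if (length(d) > 0) sum(abs(d) > 50) else NA_real_
  pnn50 <- if (length(d) > 0) 100 * nn50 / length(d) else NA_real_
  sd1 <- if (!is.na(rmssd)) rmssd / sqrt(2) else NA_real_
  sd2 <- if (!is.na(sd1)) sqrt(max(0, 2 * sdnn^2 - sd1^2)) else NA_real_
  bins <- hrv_sdann_asdnn(segments$onset_ms, nn, window_start_ms)
  tibble(method = "C", sdnn = sdnn, sdann = bins$sdann, asdnn = bins$asdnn,
         rmssd = rmssd, nn50 = as.numeric(nn50), pnn50 = pnn50, sd1 = sd1,
         sd2 = sd2,
         sd1_sd2 = if (!is.na(sd2) && sd2 > 0) sd1 / sd2 else NA_real_,
         n_intervals = length(nn), reason = NA_character_)
}

#' Sliding-window specification
#'
#' The study durations are 30 min (short-term), 2 h and 8 h (medium-term) and
#' 24 h (long-term); windows slide with an offset of 5 min for short/medium
#' durations and 10 min for long. Any positive window length is accepted; the
#' duration class and default offset follow the same boundaries (short up to
#' 30 min, medium up to 8 h, long beyond).
#'
#' @param w_min Window length in minutes.
#' @param s_min Sliding offset in minutes; defaults by duration class.
#' @return A list of class `window_spec` with `w_min`, `s_min`,
#'   `duration_class`.
#' @export
window_spec <- function(w_min = 30, s_min = NULL) {
  stopifnot(w_min > 0)
  duration_class <- if (w_min <= 30) "short" else if (w_min <= 480) "medium" else "long"
  s_min <- s_min %||% if (duration_class == "long") 10 else 5
  stopifnot(s_min > 0)
  structure(list(w_min = w_min, s_min = s_min, duration_class = duration_class),
            class = "window_spec")
}

#' Enumerate sliding windows
#'
#' Windows are `[k * s, k * s + w]` minutes for `k = 0, 1, ...` while the
#' window fits in the record, giving `floor((span - w) / s) + 1` windows when
#' `span >= w` and none otherwise.
#'
#' @param record_span_min Record length in minutes.
#' @param spec A [window_spec()].
#' @return A tibble with `window_id`, `start_min`, `end_min`.
#' @export
sliding_windows <- function(record_span_min, spec = window_spec()) {
  w <- spec$w_min; s <- spec$s_min
  if (record_span_min < w) {
    return(tibble(window_id = character(), start_min = double(), end_min = double()))
  }
  k <- 0:floor((record_span_min - w) / s)
  tibble(window_id = sprintf("w%03d", k), start_min = k * s, end_min = k * s + w)
}

#' Windowed HRV over a recording
#'
#' Slides windows across an RR series; within each window (membership by
#' interval onset, half-open `[start, start + w)`) the cleaning stage is
#' applied and the requested methods computed. Windows where HRV is undefined
#' are emitted with `NA` values and a reason code.
#'
#' @param rr An RR tibble from [beats_to_rr()] (already screened with
#'   [screen_recording()]).
#' @param spec A [window_spec()].
#' @param config A [cleaning_config()].
#' @param methods Character subset of `c("A", "C")`.
#' @param span_min Nominal record span in minutes; defaults to the observed
#'   span rounded up to a whole minute (Holter records have nominal
#'   durations, and the final beat falls just short of them).
#' @return A tibble with one row per (window, method): `window_id`,
#'   `start_min`, `end_min`, `method`, the HRV parameter columns of
#'   [hrv_average()], and `reason`.
#' @export
windowed_hrv <- function(rr, spec = window_spec(), config = cleaning_config(),
                         methods = c("A", "C"), span_min = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  span_min <- span_min %||% ceiling(max(rr$onset_ms + rr$rr_ms) / 60000 - 1e-9)
  wins <- sliding_windows(span_min, spec)
  if (nrow(wins) == 0) {
    return(dplyr::bind_cols(
      tibble(window_id = character(), start_min = double(), end_min = double()),
      empty_hrv_row("A", "")[0, ]
    ))
  }
  rows <- vector("list", nrow(wins) * length(methods))
  j <- 0L
  for (i in seq_len(nrow(wins))) {
    lo <- wins$start_min[i] * 60000
    hi <- wins$end_min[i] * 60000
    in_win <- rr$onset_ms >= lo & rr$onset_ms < hi
    segs <- if (any(in_win)) {
      extract_nn_segments(rr[in_win, , drop = FALSE], config)
    } else {
      tibble(segment_id = integer(), onset_ms = double(), rr_ms = double())
    }
    for (m in methods) {
      j <- j + 1L
      res <- if (m == "A") hrv_average(segs, lo) else hrv_combined(segs, lo)
      rows[[j]] <- dplyr::bind_cols(
        tibble(window_id = wins$window_id[i], start_min = wins$start_min[i],
               end_min = wins$end_min[i]),
        res
      )
    }
  }
  dplyr::bind_rows(rows)
}
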