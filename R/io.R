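#' Read beat annotations
#'
#' Reads a beat-annotation stream into a tibble with one row per annotated
#' beat. Two dialects are supported: the package's plain-text CSV dialect
#' (columns `time_ms`, `label`) and standard WFDB annotation files, whose
#' sample indices are converted to milliseconds using the record's sampling
#' frequency.
#'
#' Labels follow the AAMI beat classes `N`, `A`, `V`, `S`, `F`, `Q`, plus the
#' package's `X` pseudo-label marking the edges of a detected artifact span.
#'
#' @param path Path to the annotation file.
#' @param dialect `"csv"` (default) or `"wfdb"`.
#' @param fs Sampling frequency in Hz; required for the `wfdb` dialect.
#' @return A tibble with columns `time_ms` (numeric, strictly increasing) and
#'   `label` (character).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("time_ms,label", "0,N", "800,N", "1610,N"), f)
#' read_beat_annotations(f)
#' @export
read_beat_annotations <- function(path, dialect = c("csv", "wfdb"), fs = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  beats <- switch(dialect,
    csv = {
      df <- readr::read_csv(path, col_types = readr::cols(
        time_ms = readr::col_double(), label = readr::col_character()
      ))
      tibble(time_ms = df$time_ms, label = df$label)
    },
    wfdb = {
      if (is.null(fs)) stop("the wfdb dialect requires the sampling frequency `fs`")
      ann <- read_wfdb_annotations(path)
      tibble(time_ms = ann$sample / fs * 1000, label = ann$label)
    }
  )
  validate_beats(beats)
  beats[order(beats$time_ms), ]
}

validate_beats <- function(beats) {
  bad <- setdiff(unique(beats$label), BEAT_LABELS)
  if (length(bad) > 0) {
    stop("unknown beat label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(BEAT_LABELS, collapse = ", "), ")")
  }
  if (any(beats$time_ms < 0)) stop("negative beat times")
  d <- diff(beats$time_ms)
  if (any(d <= 0)) {
    stop("beat times not strictly increasing at index ", which(d <= 0)[1] + 1L)
  }
  invisible(beats)
}

# Minimal reader for MIT-format WFDB annotation files: a stream of 16-bit
# little-endian words; the top 6 bits are the annotation type code and the
# low 10 bits the time increment in samples. Handles the SKIP (59, +4 bytes
# of long offset), NUM (60), SUB (61), CHN (62) and AUX (63, byte-counted,
# even-padded) pseudo-codes. Stops at the 0x0000 end word.
read_wfdb_annotations <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) %% 2L != 0L) stop("truncated WFDB annotation file")
  i <- 1L
  n_words <- length(raw)
  samples <- integer(0)
  codes <- integer(0)
  t <- 0
  while (i + 1L <= n_words) {
    lo <- as.integer(raw[i]); hi <- as.integer(raw[i + 1L])
    word <- lo + 256L * hi
    i <- i + 2L
    code <- word %/% 1024L
    delta <- word %% 1024L
    if (word == 0L) break
    if (code == 59L) { # SKIP: next two words hold a 32-bit interval, high first
      if (i + 3L > n_words) stop("truncated SKIP in WFDB annotation file")
      w1 <- as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
      w2 <- as.integer(raw[i + 2L]) + 256L * as.integer(raw[i + 3L])
      i <- i + 4L
      t <- t + w1 * 65536 + w2
    } else if (code %in% c(60L, 61L, 62L)) {
      # NUM/SUB/CHN modifiers: no time advance, payload ignored
    } else if (code == 63L) { # AUX: delta = byte count, padded to even
      i <- i + delta + (delta %% 2L)
    } else {
      t <- t + delta
      samples <- c(samples, t)
      codes <- c(codes, code)
    }
  }
  keep <- !is.na(wfdb_code_to_label(codes))
  label <- wfdb_code_to_label(codes[keep])
  unknown <- codes[!keep & !codes %in% WFDB_NONBEAT_CODES]
  if (length(unknown) > 0) {
    stop("unknown beat label (WFDB annotation code ",
         paste(unique(unknown), collapse = ", "), ")")
  }
  list(sample = samples[keep], label = label)
}

# Standard MIT annotation codes -> AAMI-style labels used here.
# NOISE (14) and ARFCT (16) become X artifact markers; other non-beat codes
# (rhythm changes, comments, ...) are dropped.
WFDB_BEAT_CODE_MAP <- c(
  "1" = "N", "2" = "N", "3" = "N", "11" = "N", "34" = "N",
  "4" = "A", "8" = "A",
  "7" = "S", "9" = "S",
  "5" = "V", "10" = "V",
  "6" = "F",
  "12" = "Q", "13" = "Q", "38" = "Q",
  "14" = "X", "16" = "X"
)
WFDB_NONBEAT_CODES <- c(15L, 17L, 18L, 19L, 20L, 21L, 22L, 23L, 24L, 25L,
                        26L, 27L, 28L, 29L, 30L, 31L, 32L, 33L, 35L, 36L,
                        37L, 39L, 40L)

wfdb_code_to_label <- function(code) {
  unname(WFDB_BEAT_CODE_MAP[as.character(code)])
}

#' Derive RR intervals from beat annotations
#'
#' Converts `n` annotated beats into the `n - 1` inter-beat (RR) intervals,
#' carrying the labels of both endpoint beats so that downstream cleaning can
#' reject intervals adjacent to ectopic beats or artifact markers.
#'
#' @param beats A tibble as returned by [read_beat_annotations()].
#' @return A tibble with columns `onset_ms` (time of the interval's first
#'   beat), `rr_ms`, `start_label`, `end_label`.
#' @examples
#' beats <- tibble::tibble(time_ms = c(0, 800, 1610), label = "N")
#' beats_to_rr(beats)
#' @export
beats_to_rr <- function(beats) {
  validate_beats(beats)
  n <- nrow(beats)
  if (n < 2) stop("need at least 2 beats to form an RR series")
  tibble(
    onset_ms = beats$time_ms[-n],
    rr_ms = diff(beats$time_ms),
    start_label = beats$label[-n],
    end_label = beats$label[-1]
  )
}

#' Read a cohort metadata table
#'
#' Reads the package CSV dialect for subject metadata: columns `subject_id`,
#' `age`, `gender` (`M`/`F`), `condition` (`healthy`/`arrhythmia`),
#' `gluco_class` (`ND`/`GD`/`BD`/`unknown`) and optional `hba1c` (%).
#'
#' @param path Path to the CSV file.
#' @return A tibble, validated against the ranges above.
#' @export
read_cohort <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    age = readr::col_double(),
    gender = readr::col_character(),
    condition = readr::col_character(),
    gluco_class = readr::col_character(),
    .default = readr::col_double()
  ))
  validate_cohort(as_tibble(df))
}

validate_cohort <- function(cohort) {
  stopifnot(all(c("subject_id", "age", "gender", "condition") %in% names(cohort)))
  if (any(cohort$age <= 0 | cohort$age >= 130)) stop("age out of range (0, 130)")
  if (!all(cohort$gender %in% c("M", "F"))) stop("gender must be M or F")
  if (!all(cohort$condition %in% c("healthy", "arrhythmia"))) {
    stop("condition must be healthy or arrhythmia")
  }
  if ("gluco_class" %in% names(cohort)) {
    if (!all(cohort$gluco_class %in% c("ND", "GD", "BD", "unknown"))) {
      stop("gluco_class must be ND, GD, BD or unknown")
    }
    if ("hba1c" %in% names(cohort)) {
      bad <- cohort$gluco_class == "unknown" & !is.na(cohort$hba1c)
      if (any(bad)) stop("gluco_class 'unknown' with HbA1c present for: ",
                         paste(cohort$subject_id[bad], collapse = ", "))
    }
  }
  cohort
}

#' Write a result table to CSV
#'
#' Round-trip safe CSV writing for HRV result tables: numeric values survive a
#' write/read cycle to at least 12 significant digits.
#'
#' @param records A data frame of results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  readr::write_csv(as_tibble(records), path)
  invisible(path)
}
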