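# Age dependency coefficients the generator instantiates: average-method SDNN
# and RMSSD (ms) as linear functions of age (years), separately for healthy
# subjects and subjects with arrhythmia (the latter also used for bad glucose
# regulation, whose HRV distribution resembles the arrhythmia group's).
DEPENDENCY_COEFS <- list(
  healthy = list(sdnn = c(intercept = 60.62, slope = -0.49),
                 rmssd = c(intercept = 42.19, slope = -0.32)),
  arrhythmia = list(sdnn = c(intercept = 44.30, slope = -0.13),
                    rmssd = c(intercept = 37.71, slope = -0.046))
)

#' Synthetic cohort configuration
#'
#' Study conditions for the synthetic RR-interval cohort generator. Defaults
#' describe a realistic mixed Holter cohort: ages spanning 20-80 years,
#' balanced genders, a 15% arrhythmia fraction (the share of arrhythmia
#' subjects across the study datasets), glucose-regulation class proportions
#' ND/GD/BD = 0.53/0.18/0.29 (the imbalance seen in pooled per-window
#' classification counts), a 800 ms mean RR, a -2 ms SDNN offset for female
#' subjects, 5 ms between-subject spread of the HRV targets, a 1% ectopic
#' beat rate and 0.5 artifact spans per hour on 2-hour records.
#'
#' @param n_subjects Number of subjects.
#' @param age_range Length-2 numeric, years.
#' @param gender_balance Fraction female.
#' @param condition_mix Fraction with arrhythmia.
#' @param gluco_mix Named proportions over ND/GD/BD (must sum to 1).
#' @param mean_rr_ms Mean RR interval (ms).
#' @param gender_offset_ms Additive SDNN-target offset for female subjects
#'   (ms; negative means lower SDNN in females).
#' @param noise_sd_ms Between-subject Gaussian spread of the SDNN and RMSSD
#'   targets (ms).
#' @param ectopic_rate Per-beat probability of an ectopic (V/S) beat.
#' @param artifact_rate Expected artifact spans per hour.
#' @param record_min Record duration (minutes).
#' @param seed Integer seed; every downstream draw is a pure function of
#'   (inputs, seed).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 100, age_range = c(20, 80),
                         gender_balance = 0.5, condition_mix = 0.15,
                         gluco_mix = c(ND = 0.53, GD = 0.18, BD = 0.29),
                         mean_rr_ms = 800, gender_offset_ms = -2,
                         noise_sd_ms = 5, ectopic_rate = 0.01,
                         artifact_rate = 0.5, record_min = 120, seed = 1L) {
  stopifnot(n_subjects >= 0, length(age_range) == 2, age_range[1] < age_range[2],
            gender_balance >= 0, gender_balance <= 1,
            condition_mix >= 0, condition_mix <= 1,
            abs(sum(gluco_mix) - 1) < 1e-9,
            all(c("ND", "GD", "BD") %in% names(gluco_mix)),
            mean_rr_ms > 0, noise_sd_ms >= 0,
            ectopic_rate >= 0, ectopic_rate < 1, artifact_rate >= 0,
            record_min >= 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Subject-level HRV targets
#'
#' Draws each subject's SDNN and RMSSD targets from the condition-specific
#' age dependency lines (healthy subjects, and arrhythmia or bad-glucose-
#' regulation subjects, have different intercepts and slopes), adds the
#' female SDNN offset and a seeded Gaussian between-subject perturbation, and
#' floors targets at 3 ms. The lag-1 autocorrelation `rho` that makes an
#' AR(1) series hit both targets comes from [ar1_rho()]; a perturbation that
#' violates its validity bound is resampled (up to 100 times, then an error).
#'
#' @param subjects A subject tibble (columns `age`, `gender`, `condition`,
#'   optionally `gluco_class`).
#' @param cfg A [synth_config()]. Perturbations use `cfg$seed` unless the
#'   caller has already seeded the session (`use_seed = FALSE`).
#' @param use_seed Whether to call `set.seed(cfg$seed)` first.
#' @return `subjects` with columns `sdnn_target`, `rmssd_target`, `rho`
#'   appended.
#' @export
target_hrv <- function(subjects, cfg = synth_config(), use_seed = TRUE) {
  if (use_seed) set.seed(cfg$seed)
  stopifnot(all(subjects$age >= cfg$age_range[1] & subjects$age <= cfg$age_range[2]))
  n <- nrow(subjects)
  gl <- if ("gluco_class" %in% names(subjects)) subjects$gluco_class else rep("unknown", n)
  eq_group <- ifelse(subjects$condition == "arrhythmia" | gl == "BD",
                     "arrhythmia", "healthy")
  sdnn <- rmssd <- numeric(n)
  for (i in seq_len(n)) {
    co <- DEPENDENCY_COEFS[[eq_group[i]]]
    base_s <- co$sdnn[["intercept"]] + co$sdnn[["slope"]] * subjects$age[i] +
      if (subjects$gender[i] == "F") cfg$gender_offset_ms else 0
    base_r <- co$rmssd[["intercept"]] + co$rmssd[["slope"]] * subjects$age[i]
    for (try in 1:100) {
      s <- max(3, base_s + rnorm(1, 0, cfg$noise_sd_ms))
      r <- max(3, base_r + rnorm(1, 0, cfg$noise_sd_ms))
      if (r^2 < 4 * s^2) break
      if (try == 100) stop("could not draw valid targets (rmssd >= 2*sdnn)")
    }
    sdnn[i] <- s; rmssd[i] <- r
  }
  subjects$sdnn_target <- sdnn
  subjects$rmssd_target <- rmssd
  subjects$rho <- ar1_rho(sdnn, rmssd)
  subjects
}

#' AR(1) autocorrelation from SDNN and RMSSD targets
#'
#' For a stationary AR(1) series with marginal variance sigma^2 and lag-1
#' autocorrelation rho, the expected squared RMSSD is `2 * sigma^2 * (1 -
#' rho)`; inverting gives `rho = 1 - rmssd^2 / (2 * sdnn^2)`, valid (rho in
#' (-1, 1)) iff `rmssd < 2 * sdnn`.
#'
#' @param sdnn,rmssd Positive targets (ms); vectorised.
#' @return rho in (-1, 1).
#' @export
ar1_rho <- function(sdnn, rmssd) {
  stopifnot(all(sdnn > 0), all(rmssd > 0))
  if (any(rmssd^2 >= 4 * sdnn^2)) {
    stop("rmssd^2 must be < 4 * sdnn^2 for a valid AR(1) autocorrelation")
  }
  1 - rmssd^2 / (2 * sdnn^2)
}

#' Generate a normal-sinus-rhythm annotation stream
#'
#' Simulates RR intervals as a stationary Gaussian AR(1) process with mean
#' `mean_rr_ms`, marginal standard deviation `sdnn_target` and lag-1
#' autocorrelation `rho` (from [ar1_rho()]), truncated to the physiological
#' band [300, 2000] ms, and emits cumulative beat times labelled `N` until
#' the requested duration is covered.
#'
#' @param targets A list/row with `sdnn_target`, `rmssd_target` (or `rho`).
#' @param duration_min Record duration, minutes (>= 1).
#' @param cfg A [synth_config()] (supplies `mean_rr_ms`).
#' @param seed Integer seed; the stream is a pure function of (targets,
#'   duration, cfg, seed).
#' @return A beat tibble (`time_ms`, `label`).
#' @export
gen_rr <- function(targets, duration_min, cfg = synth_config(), seed = 1L) {
  stopifnot(duration_min >= 1)
  set.seed(seed)
  mu <- cfg$mean_rr_ms
  sigma <- targets$sdnn_target
  rho <- targets$rho %||% ar1_rho(targets$sdnn_target, targets$rmssd_target)
  duration_ms <- duration_min * 60000
  rr <- numeric(0)
  last <- NULL
  while (sum(rr) < duration_ms) {
    n <- ceiling((duration_ms - sum(rr)) / mu * 1.1) + 50
    innov <- rnorm(n, 0, sigma * sqrt(1 - rho^2))
    if (is.null(last)) innov[1] <- rnorm(1, 0, sigma) # stationary start
    z <- as.numeric(stats::filter(innov, rho, method = "recursive",
                                  init = last %||% 0))
    last <- z[n]
    rr <- c(rr, pmin(2000, pmax(300, mu + z)))
  }
  times <- cumsum(c(0, rr))
  times <- times[times <= duration_ms]
  tibble(time_ms = times, label = "N")
}

#' Inject ectopic beats
#'
#' Relabels interior beats independently with probability `ectopic_rate` as
#' `V` or `S` (equal odds) and gives each the timing signature of a premature
#' beat with compensatory pause: the preceding interval is shortened by 30%
#' and the following interval lengthened so their sum is conserved.
#'
#' @param beats A beat tibble.
#' @param ectopic_rate Per-beat probability in [0, 1).
#' @param seed Integer seed.
#' @return The modified beat tibble.
#' @export
inject_ectopics <- function(beats, ectopic_rate, seed = 1L) {
  stopifnot(ectopic_rate >= 0, ectopic_rate < 1)
  if (ectopic_rate == 0 || nrow(beats) < 3) return(beats)
  set.seed(seed)
  n <- nrow(beats)
  hit <- which(rbinom(n, 1, ectopic_rate) == 1)
  hit <- hit[hit > 1 & hit < n]
  if (length(hit) == 0) return(beats)
  kind <- sample(c("V", "S"), length(hit), replace = TRUE)
  time <- beats$time_ms
  # shifts are computed from the original times; monotonicity is preserved
  # even for adjacent ectopics since 0.7*d_i + 0.3*d_{i-1} > 0
  time[hit] <- time[hit] - 0.3 * (beats$time_ms[hit] - beats$time_ms[hit - 1])
  beats$time_ms <- time
  beats$label[hit] <- kind
  beats
}

#' Inject artifact spans
#'
#' Draws a Poisson number of artifact spans (expected `artifact_rate` per
#' hour) with uniform 5-30 s lengths and uniform starts, removes every beat
#' inside each span, and inserts `X` pseudo-beats at the span edges so that
#' cleaning treats any interval touching the span as non-NN.
#'
#' @param beats A beat tibble.
#' @param artifact_rate Expected spans per hour (>= 0).
#' @param seed Integer seed.
#' @param spans Optional two-column matrix/data frame of (start_ms, end_ms)
#'   forcing specific spans instead of random ones.
#' @return The modified beat tibble.
#' @export
inject_artifacts <- function(beats, artifact_rate, seed = 1L, spans = NULL) {
  stopifnot(artifact_rate >= 0)
  duration_ms <- max(beats$time_ms)
  if (is.null(spans)) {
    set.seed(seed)
    n_spans <- rpois(1, artifact_rate * duration_ms / 3600000)
    if (n_spans == 0) return(beats)
    len <- runif(n_spans, 5000, 30000)
    start <- runif(n_spans, 0, pmax(0, duration_ms - len))
    spans <- cbind(start, start + len)
  } else {
    spans <- as.matrix(spans)
    if (nrow(spans) == 0) return(beats)
  }
  for (i in seq_len(nrow(spans))) {
    lo <- spans[i, 1]; hi <- spans[i, 2]
    inside <- beats$time_ms > lo & beats$time_ms < hi
    beats <- beats[!inside, , drop = FALSE]
    edge <- tibble(time_ms = c(lo, hi), label = "X")
    edge <- edge[!edge$time_ms %in% beats$time_ms, , drop = FALSE]
    beats <- dplyr::arrange(dplyr::bind_rows(beats, edge), .data$time_ms)
  }
  beats
}

#' Sample a synthetic cohort
#'
#' Draws subject demographics from the configured mixes, assigns HRV targets
#' via [target_hrv()], and generates one annotation stream per subject of
#' `cfg$record_min` minutes with ectopics and artifacts injected. With
#' `balanced = TRUE` (requires `n_subjects` a multiple of 12) subjects are
#' instead enumerated over the 6 age groups x 2 genders. HbA1c values are
#' drawn per glucose class (ND ~ 5.3%, GD ~ 6.8%, BD ~ 9.5%).
#'
#' @param cfg A [synth_config()].
#' @param balanced Enumerate age-group x gender cells instead of sampling.
#' @param out_dir Optional directory; if given, writes `subjects.csv` and one
#'   `<subject_id>.csv` annotation file per subject.
#' @return A subject tibble with target columns and a `beats` list-column of
#'   annotation tibbles.
#' @export
sample_cohort <- function(cfg = synth_config(), balanced = FALSE, out_dir = NULL) {
  if (cfg$n_subjects < 1) stop("n_subjects must be >= 1")
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  if (balanced) {
    if (n %% 12 != 0) stop("balanced design needs n_subjects divisible by 12")
    cell_age <- c(25, 35, 45, 55, 65, 75) # representative age per group
    grid <- expand.grid(age = cell_age, gender = c("M", "F"),
                        stringsAsFactors = FALSE)
    reps <- n / 12
    age <- rep(grid$age, reps)
    gender <- rep(grid$gender, reps)
  } else {
    age <- runif(n, cfg$age_range[1], cfg$age_range[2])
    gender <- ifelse(runif(n) < cfg$gender_balance, "F", "M")
  }
  condition <- ifelse(runif(n) < cfg$condition_mix, "arrhythmia", "healthy")
  gluco <- sample(names(cfg$gluco_mix), n, replace = TRUE, prob = cfg$gluco_mix)
  hba1c_mean <- c(ND = 5.3, GD = 6.8, BD = 9.5)
  hba1c_sd <- c(ND = 0.3, GD = 0.5, BD = 1.2)
  hba1c <- pmax(4, rnorm(n, hba1c_mean[gluco], hba1c_sd[gluco]))
  subjects <- tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = age, gender = gender, condition = condition,
    gluco_class = gluco, hba1c = hba1c
  )
  subjects <- target_hrv(subjects, cfg, use_seed = FALSE)
  sub_seeds <- sample.int(.Machine$integer.max, n)
  subjects$beats <- purrr::map(seq_len(n), function(i) {
    b <- gen_rr(subjects[i, ], cfg$record_min, cfg, seed = sub_seeds[i])
    b <- inject_ectopics(b, cfg$ectopic_rate, seed = sub_seeds[i] %% 1000000L + 1L)
    inject_artifacts(b, cfg$artifact_rate, seed = sub_seeds[i] %% 999983L + 1L)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest <- dplyr::select(subjects, -"beats")
    write_table(manifest, file.path(out_dir, "subjects.csv"))
    purrr::walk(seq_len(n), function(i) {
      write_table(subjects$beats[[i]],
                  file.path(out_dir, paste0(subjects$subject_id[i], ".csv")))
    })
  }
  subjects
}

#' Per-subject windowed HRV over a cohort
#'
#' Runs the full per-subject pipeline -- annotation stream to RR series,
#' screening, windowed cleaning and HRV -- and aggregates each subject's
#' window-level values to their per-subject mean per parameter (the
#' aggregation used before cohort-level correlation, to avoid
#' pseudo-replication from overlapping windows).
#'
#' @param cohort A cohort tibble with a `beats` list-column (from
#'   [sample_cohort()]) or a `path` column of annotation CSV files.
#' @param spec A [window_spec()].
#' @param config A [cleaning_config()].
#' @param methods Character subset of `c("A", "C")`.
#' @return One row per subject x method: demographics plus mean `sdnn`,
#'   `sdann`, `asdnn`, `rmssd`, `nn50`, `pnn50`, `sd1`, `sd2`, `sd1_sd2`
#'   across that subject's windows (`NA`-dropped), and `n_windows`.
#' @export
cohort_hrv <- function(cohort, spec = window_spec(), config = cleaning_config(),
                       methods = c("A", "C")) {
  param_cols <- c("sdnn", "sdann", "asdnn", "rmssd", "nn50", "pnn50",
                  "sd1", "sd2", "sd1_sd2")
  meta_cols <- intersect(
    c("subject_id", "age", "gender", "condition", "gluco_class", "hba1c"),
    names(cohort)
  )
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    beats <- if ("beats" %in% names(cohort)) {
      cohort$beats[[i]]
    } else {
      read_beat_annotations(cohort$path[i])
    }
    rr <- beats_to_rr(beats)
    scr <- screen_recording(rr, afib_diagnosed = FALSE, config = config)
    if (!scr$accepted) return(NULL)
    wh <- windowed_hrv(rr, spec, config, methods)
    wh |>
      group_by(.data$method) |>
      summarise(dplyr::across(dplyr::all_of(param_cols), ~mean(.x, na.rm = TRUE)),
                n_windows = sum(!is.na(.data$sdnn)), .groups = "drop") |>
      dplyr::bind_cols(cohort[i, meta_cols])
  })
  dplyr::bind_rows(rows)
}
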