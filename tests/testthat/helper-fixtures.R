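# Build a beat tibble from RR intervals (ms) and per-beat labels.
make_beats <- function(rr, labels = "N", t0 = 0) {
  times <- t0 + cumsum(c(0, rr))
  tibble::tibble(time_ms = times, label = rep_len(labels, length(times)))
}

# Segment tibble straight from a list of NN vectors (for A/C method tests).
make_segments <- function(...) {
  runs <- list(...)
  onset <- 0
  out <- list()
  for (i in seq_along(runs)) {
    rr <- runs[[i]]
    out[[i]] <- tibble::tibble(
      segment_id = i,
      onset_ms = onset + cumsum(c(0, rr[-length(rr)])),
      rr_ms = rr
    )
    onset <- onset + sum(rr) + 5000 # a gap between segments
  }
  dplyr::bind_rows(out)
}

# Random labeled RR series for cleaning-equivalence tests: plants bound
# violations, ectopic labels and artifact markers.
random_labeled_rr <- function(n) {
  rr <- runif(n, 600, 1000)
  jumps <- runif(n) < 0.08
  rr[jumps] <- rr[jumps] * sample(c(0.4, 1.6, 2.2), sum(jumps), replace = TRUE)
  labels <- sample(c("N", "V", "S", "A", "F", "Q", "X"), n + 1, replace = TRUE,
                   prob = c(0.86, 0.04, 0.02, 0.02, 0.02, 0.02, 0.02))
  make_beats(rr, labels)
}

# Well-separated three-class HRV feature table for the CV harness.
make_gluco_features <- function(n_per_class = 40, sd = 2, seed = 1) {
  set.seed(seed)
  classes <- c("ND", "GD", "BD")
  centre <- c(ND = 45, GD = 35, BD = 25)
  labels <- rep(classes, each = n_per_class)
  tibble::tibble(
    a_sdnn = rnorm(length(labels), centre[labels], sd),
    a_rmssd = rnorm(length(labels), centre[labels] * 0.7, sd),
    c_sdnn = rnorm(length(labels), centre[labels] * 1.2, sd),
    c_rmssd = rnorm(length(labels), centre[labels] * 0.8, sd),
    gluco_class = labels
  )
}
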