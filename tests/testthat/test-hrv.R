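test_that("scalar parameters reproduce hand-checked fixtures", {
  nn <- c(800, 810, 790, 805, 795)
  expect_equal(hrv_sdnn(nn), sqrt(250 / 4), tolerance = 1e-12)
  expect_equal(hrv_rmssd(nn), sqrt(825 / 4), tolerance = 1e-12)
  expect_equal(hrv_sdnn(c(500, 700)), 200 / sqrt(2), tolerance = 1e-12)
  expect_equal(hrv_nn50(c(800, 860, 805)), 2L)
  expect_equal(hrv_pnn50(c(800, 860, 805)), 100)
  expect_equal(hrv_sdnn(rep(640, 10)), 0)
  expect_equal(hrv_rmssd(rep(640, 10)), 0)
  expect_equal(hrv_nn50(rep(640, 10)), 0L)
  expect_true(is.na(hrv_sdnn(800)))
})

test_that("poincare descriptors follow the ellipse identities", {
  nn <- c(800, 810, 790, 805, 795)
  pc <- hrv_poincare(nn)
  expect_equal(pc$sd1, 10.155048, tolerance = 1e-6)
  expect_equal(pc$sd2, 4.677072, tolerance = 1e-6)
  expect_equal(pc$sd1, hrv_rmssd(nn) / sqrt(2), tolerance = 1e-12)

  flat <- hrv_poincare(rep(700, 10))
  expect_equal(flat$sd1, 0)
  expect_equal(flat$sd2, 0)
  expect_true(is.na(flat$sd1_sd2))

  # pure alternans: all variance is short-term
  alt <- hrv_poincare(rep(c(600, 700), 25))
  expect_equal(alt$sd1, 100 / sqrt(2), tolerance = 1e-9)
  expect_lt(alt$sd2, alt$sd1 * 0.2)
})

test_that("sdann/asdnn use qualifying 5-minute bins", {
  # three 5-min bins with per-bin mean 600/610/620 and per-bin sd 5/10/15
  mk_bin <- function(mean_rr, sd_target, t0) {
    rr <- rep(c(mean_rr - sd_target, mean_rr + sd_target), 20)
    # sample sd of a +/-d alternation of even length is d / sqrt(1 - 1/(n-1))
    tibble::tibble(onset = t0 + seq(0, by = 7000, length.out = 40), rr = rr)
  }
  b1 <- mk_bin(600, 5, 0); b2 <- mk_bin(610, 10, 300000); b3 <- mk_bin(620, 15, 600000)
  d <- dplyr::bind_rows(b1, b2, b3)
  out <- hrv_sdann_asdnn(d$onset, d$rr, window_start_ms = 0)
  expect_equal(out$sdann, 10, tolerance = 1e-9)
  expect_equal(out$asdnn, mean(c(sd(b1$rr), sd(b2$rr), sd(b3$rr))), tolerance = 1e-12)

  const <- hrv_sdann_asdnn(seq(0, 599000, by = 1000), rep(600, 600))
  expect_equal(const$sdann, 0)
  expect_equal(const$asdnn, 0)

  one_bin <- hrv_sdann_asdnn(c(0, 1000, 2000), c(800, 800, 800))
  expect_true(is.na(one_bin$sdann))
})

test_that("average and combined methods agree on a single segment", {
  set.seed(21)
  for (case in 1:50) {
    rr <- runif(sample(6:60, 1), 650, 950)
    segs <- make_segments(rr)
    a <- hrv_average(segs)
    c_ <- hrv_combined(segs)
    for (col in c("sdnn", "rmssd", "nn50", "pnn50", "sd1", "sd2")) {
      expect_equal(a[[col]], c_[[col]], tolerance = 1e-12)
    }
  }
})

test_that("combined concatenation raises SDNN across level-shifted segments", {
  segs <- make_segments(rep(500, 10), rep(700, 10))
  a <- hrv_average(segs)
  c_ <- hrv_combined(segs)
  expect_equal(a$sdnn, 0)
  expect_equal(c_$sdnn, sqrt(200000 / 19), tolerance = 1e-9) # 102.598
  # junction differences are skipped: no within-segment variation at all
  expect_equal(c_$rmssd, 0)
  expect_equal(a$rmssd, 0)

  # A-method scalars are unweighted means of per-segment values
  s1 <- c(800, 810, 790, 805, 795, 800, 810)
  s2 <- c(600, 640, 610, 650, 620, 660, 630)
  ac <- hrv_average(make_segments(s1, s2))
  expect_equal(ac$rmssd, mean(c(hrv_rmssd(s1), hrv_rmssd(s2))), tolerance = 1e-12)
  expect_equal(ac$sdnn, mean(c(hrv_sdnn(s1), hrv_sdnn(s2))), tolerance = 1e-12)
})

test_that("combined SDNN dominates average SDNN on equal-length shifted segments", {
  set.seed(31)
  for (case in 1:40) {
    n <- sample(6:30, 1)
    base <- runif(n, 700, 760)
    shift <- runif(1, 50, 300)
    segs <- make_segments(base, base + shift)
    expect_gte(hrv_combined(segs)$sdnn, hrv_average(segs)$sdnn - 1e-12)
  }
})

test_that("sliding windows follow the closed-form count", {
  expect_equal(nrow(sliding_windows(120, window_spec(30, 5))), 19)
  expect_equal(nrow(sliding_windows(30, window_spec(30, 5))), 1)
  expect_equal(nrow(sliding_windows(29, window_spec(30, 5))), 0)
  for (span in c(30, 60, 121, 480, 1440)) {
    for (w in c(30, 120, 480, 1440)) {
      for (s in c(5, 10)) {
        wins <- sliding_windows(span, window_spec(w, s))
        expected <- if (span >= w) floor((span - w) / s) + 1 else 0
        expect_equal(nrow(wins), expected)
        if (nrow(wins) > 0) expect_true(all(wins$end_min <= span + 1e-9))
      }
    }
  }
})

test_that("window spec classifies durations and defaults the offset", {
  expect_equal(window_spec(30)$duration_class, "short")
  expect_equal(window_spec(30)$s_min, 5)
  expect_equal(window_spec(120)$duration_class, "medium")
  expect_equal(window_spec(480)$s_min, 5)
  expect_equal(window_spec(1440)$duration_class, "long")
  expect_equal(window_spec(1440)$s_min, 10)
})

test_that("windowed HRV emits one row per window and method", {
  rr <- beats_to_rr(make_beats(rep(800, 120 * 60000 / 800)))
  out <- windowed_hrv(rr, window_spec(30, 5))
  expect_equal(nrow(out), 19 * 2)
  expect_true(all(out$sdnn == 0))

  short <- beats_to_rr(make_beats(rep(800, 100)))
  expect_equal(nrow(windowed_hrv(short, window_spec(30, 5))), 0)
})

test_that("cleaning is local: windows away from an ectopic burst are unaffected", {
  set.seed(5)
  rr_clean <- rep(800, 9000)  # 120 min
  beats_clean <- make_beats(rr_clean)
  beats_dirty <- beats_clean
  burst <- beats_dirty$time_ms >= 40 * 60000 & beats_dirty$time_ms < 45 * 60000
  beats_dirty$label[burst][seq(1, sum(burst), by = 10)] <- "V"
  out_clean <- windowed_hrv(beats_to_rr(beats_clean), window_spec(30, 5))
  out_dirty <- windowed_hrv(beats_to_rr(beats_dirty), window_spec(30, 5))
  away <- out_clean$end_min <= 40 | out_clean$start_min >= 45
  expect_true(any(away))
  expect_equal(out_dirty$sdnn[away], out_clean$sdnn[away])
  expect_equal(out_dirty$rmssd[away], out_clean$rmssd[away])
})

test_that("all scalar parameters match the direct-formula oracle on random series", {
  set.seed(99)
  for (case in 1:300) {
    nn <- runif(sample(3:50, 1), 400, 1200)
    expect_equal(hrv_sdnn(nn), oracle_sdnn(nn), tolerance = 1e-9)
    expect_equal(hrv_rmssd(nn), oracle_rmssd(nn), tolerance = 1e-9)
    expect_equal(hrv_nn50(nn), oracle_nn50(nn))
    expect_equal(hrv_pnn50(nn), oracle_pnn50(nn), tolerance = 1e-9)
    pc <- hrv_poincare(nn)
    expect_equal(pc$sd1, oracle_sd1(nn), tolerance = 1e-9)
    expect_equal(pc$sd2, oracle_sd2(nn), tolerance = 1e-9)
  }
})
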