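# Independent direct-formula oracles, written from the definitions and kept
# deliberately naive (explicit sums and scans) so they share no code path
# with the package implementations.

oracle_sdnn <- function(nn) {
  n <- length(nn)
  m <- sum(nn) / n
  sqrt(sum((nn - m)^2) / (n - 1))
}

oracle_rmssd <- function(nn) {
  d <- nn[-1] - nn[-length(nn)]
  sqrt(sum(d^2) / length(d))
}

oracle_nn50 <- function(nn) {
  d <- nn[-1] - nn[-length(nn)]
  sum(abs(d) > 50)
}

oracle_pnn50 <- function(nn) 100 * oracle_nn50(nn) / (length(nn) - 1)

oracle_sd1 <- function(nn) oracle_rmssd(nn) / sqrt(2)

oracle_sd2 <- function(nn) sqrt(max(0, 2 * oracle_sdnn(nn)^2 - oracle_sd1(nn)^2))

oracle_sdann_asdnn <- function(onset, rr, start = 0, bin_ms = 300000) {
  bins <- split(rr, floor((onset - start) / bin_ms))
  bins <- bins[vapply(bins, length, 0L) >= 2]
  if (length(bins) < 2) return(list(sdann = NA_real_, asdnn = NA_real_))
  list(sdann = oracle_sdnn(vapply(bins, mean, 0)),
       asdnn = sum(vapply(bins, oracle_sdnn, 0)) / length(bins))
}

# Brute-force re-scan of the cleaning rule: walks the RR series index by
# index, maintaining the accepted-run state explicitly, and returns segments
# as a list of integer index vectors into rr.
oracle_segments <- function(rr_ms, start_label, end_label, a = 0.15, min_run = 6) {
  n <- length(rr_ms)
  segs <- list()
  cur <- integer(0)
  last <- NA_real_
  flush <- function() {
    if (length(cur) >= min_run) segs[[length(segs) + 1]] <<- cur
    cur <<- integer(0)
    last <<- NA_real_
  }
  for (i in seq_len(n)) {
    if (start_label[i] != "N" || end_label[i] != "N") {
      flush()
    } else if (is.na(last)) {
      cur <- i; last <- rr_ms[i]
    } else if (rr_ms[i] > last * (1 - a) && rr_ms[i] < last * (1 + a)) {
      cur <- c(cur, i); last <- rr_ms[i]
    } else {
      flush() # the violator is dropped; the next interval seeds afresh
    }
  }
  flush()
  segs
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), n - 2))
}

midrank <- function(x) {
  # average ranks on ties, built from a sort rather than rank()
  o <- order(x)
  r <- numeric(length(x))
  i <- 1
  xs <- x[o]
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && xs[j + 1] == xs[i]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

oracle_spearman <- function(x, y) oracle_pearson(midrank(x), midrank(y))

oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1); vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(statistic = tstat, p = 2 * pt(-abs(tstat), df))
}

oracle_mwu <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- midrank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
  z <- U - n1 * n2 / 2
  zc <- (z - sign(z) * 0.5) / sigma
  list(statistic = U, p = min(1, 2 * min(pnorm(zc), pnorm(zc, lower.tail = FALSE))))
}

oracle_ks <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  grid <- sort(c(a, b))
  gap <- vapply(grid, function(t) {
    abs(sum(a <= t) / n1 - sum(b <= t) / n2)
  }, 0)
  D <- max(gap)
  lam <- sqrt(n1 * n2 / (n1 + n2)) * D
  k <- 1:100
  list(statistic = D, p = min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lam^2)))))
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  conc <- 0
  for (p in pos) for (q in neg) conc <- conc + (p > q) + 0.5 * (p == q)
  conc / (length(pos) * length(neg))
}
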