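# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# naive sample-by-sample scan for negative half-waves of a filtered trace:
# returns (onset, offset) sample pairs with the duration criterion applied
oracle_negative_half_waves <- function(y, fs, dur_range = c(0.25, 1)) {
  out <- list()
  i <- 2L
  n <- length(y)
  while (i <= n) {
    if (y[i] < 0 && y[i - 1L] >= 0) {
      j <- i
      while (j < n && y[j + 1L] < 0) j <- j + 1L
      dur <- (j - i + 1L) / fs
      if (dur >= dur_range[1] && dur <= dur_range[2])
        out[[length(out) + 1L]] <- c(onset = i, offset = j)
      i <- j + 1L
    }
    i <- i + 1L
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# exact two-sided Mann-Whitney p-value by full enumeration of group
# assignments (no ties assumed)
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# exact two-sided Fisher p by enumeration of all 2x2 tables with the
# observed margins, summing probabilities <= observed (hypergeometric)
oracle_fisher_p <- function(tab) {
  m <- matrix(tab, 2, 2, byrow = TRUE)
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x)
    stats::dhyper(x, c1, n - c1, r1), 0)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# complex-sum inter-trial coherence, written out longhand
oracle_itc <- function(phases) {
  s <- 0 + 0i
  for (p in phases) s <- s + complex(modulus = 1, argument = p)
  Mod(s) / length(phases)
}

# pairwise-count probability of superiority
oracle_prob_sup <- function(a, b) {
  wins <- 0
  for (x in a) for (y in b)
    wins <- wins + (x > y) + 0.5 * (x == y)
  wins / (length(a) * length(b))
}

# a short referential recording with an injected slow wave at given anodes
make_flat_recording <- function(labels, seconds, fs = 256) {
  eeg_recording(matrix(0, length(labels), seconds * fs), labels, fs)
}

# single-stage hypnogram covering [0, seconds)
stage_hyp <- function(stage, seconds) hypnogram(stage, 0, seconds)

# segments helper that silences the below-minimum warning
quiet_segments <- function(rec, hyp, stage, ...)
  suppressWarnings(extract_segments(rec, hyp, stage, ...))
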