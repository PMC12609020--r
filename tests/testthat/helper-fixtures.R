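# Shared fixtures, built in code at test time.

tone <- function(freq_hz, fs_hz, n, phase = 0) {
  sin(2 * pi * freq_hz * (0:(n - 1)) / fs_hz + phase)
}

# A small cohort specification used by several module tests: short cycles
# and a moderate rate keep decompositions fast while preserving the band
# structure (band centres stay well inside Nyquist at 2 kHz).
small_spec <- function(n_per_group = 3, seed = 1) {
  cohort_spec(n_per_group = n_per_group, fs_hz = 2000, cycle_s = 1,
              n_cycles = 6, seed = seed)
}

# Independent brute-force DFA fluctuation: naive per-segment lm loop.
fluct_naive <- function(y, n) {
  N <- length(y)
  m <- N %/% n
  res2 <- numeric(0)
  for (s in seq_len(m)) {
    seg <- y[((s - 1) * n + 1):(s * n)]
    tt <- seq_len(n)
    fit <- lm(seg ~ tt)
    res2 <- c(res2, residuals(fit)^2)
  }
  sqrt(mean(res2))
}

# Independent exhaustive two-segment search (the breakpoint oracle).
dual_fit_naive <- function(log_n, log_f) {
  p <- length(log_n)
  best <- list(rss = Inf)
  for (i in 3:(p - 3)) {
    f1 <- lm(log_f[1:i] ~ log_n[1:i])
    f2 <- lm(log_f[(i + 1):p] ~ log_n[(i + 1):p])
    rss <- sum(residuals(f1)^2) + sum(residuals(f2)^2)
    if (rss < best$rss - 1e-15) {
      best <- list(rss = rss, i = i,
                   a1 = unname(coef(f1)[2]), a2 = unname(coef(f2)[2]))
    }
  }
  best
}

# Pairwise concordance AUC (ties count 1/2) -- oracle for roc_auc().
auc_concordance <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}
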