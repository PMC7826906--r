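# Independent reference implementations used to cross-check the package
# (deliberately naive: plain loops and string matching).

# Plain-R chain sampler drawing the same RNG stream as the package's
# compiled kernel: one uniform for the initial state, one per step.
ref_simulate <- function(p10, p01, n, seed) {
  set.seed(seed)
  peq1 <- p10 / (p10 + p01)
  x <- integer(n)
  x[1] <- as.integer(runif(1) < peq1)
  for (k in seq_len(n - 1L)) {
    u <- runif(1)
    x[k + 1L] <- if (x[k] == 0L) as.integer(u < p10) else as.integer(u >= p01)
  }
  x
}

# Overlapping word counts by substring extraction.
ref_word_counts <- function(bits, L) {
  s <- paste(bits, collapse = "")
  words <- vapply(seq_len(nchar(s) - L + 1L),
                  function(i) substr(s, i, i + L - 1L), character(1))
  table(words)
}

# Entropy rate of the two-state chain by direct formula, written out
# independently of the package's markov_itr.
ref_entropy_rate <- function(p10, p01) {
  h <- function(p) {
    if (p <= 0 || p >= 1) return(0)
    -p * log2(p) - (1 - p) * log2(1 - p)
  }
  s <- p10 + p01
  (p01 * h(p10) + p10 * h(p01)) / s
}

# Deterministic per-test parameter draws.
draw_sources <- function(n, seed = 42) {
  set.seed(seed)
  s <- runif(n, 0.05, 1.95)
  lo <- pmax(0, s - 1)
  hi <- pmin(1, s)
  p10 <- lo + (hi - lo) * runif(n, 0.05, 0.95)
  data.frame(s = s, p10 = p10, p01 = s - p10)
}
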