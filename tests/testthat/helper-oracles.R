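# Independent oracles used to check the closed forms.

# Distribution of the number of fully captured cases by exhaustive
# enumeration of every capture pattern: n cases x c mutations, each mutation
# captured independently with probability v. O(2^(n*c)); tiny inputs only.
enumerate_mechanism_pmf <- function(n, c, v) {
  n_events <- n * c
  stopifnot(n_events <= 16)
  pmf <- numeric(n + 1)
  for (pattern in 0:(2^n_events - 1)) {
    bits <- as.integer(intToBits(pattern))[seq_len(n_events)]
    p <- prod(ifelse(bits == 1, v, 1 - v))
    complete_per_case <- colSums(matrix(bits, nrow = c)) == c
    m <- sum(complete_per_case)
    pmf[m + 1] <- pmf[m + 1] + p
  }
  pmf
}

# Direct equal-budget yield comparison for a point of the ratio plane,
# using continuous n_A: the brute-force route to the favoured strategy.
direct_favoured <- function(price_ratio, hit_ratio, complexity,
                            v = 0.4, n = 10) {
  stopifnot(v * hit_ratio <= 1)
  yield_A <- n * (1 + price_ratio) * v^complexity
  yield_B <- n * (v * hit_ratio)^complexity
  scale <- max(yield_A, yield_B)
  if (abs(yield_A - yield_B) <= 1e-9 * scale) "equivalent"
  else if (yield_A > yield_B) "A" else "B"
}

example_catalog <- function() {
  list(assay("WES", 0.27, 4), assay("chip-CNV", 0.12, 1))
}
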