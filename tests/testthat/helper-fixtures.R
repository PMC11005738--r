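# small fixtures shared across test files; everything built in code

tiny_roster <- function(n = 3, fold = 25) {
  promoter_roster(sprintf("Q%d", seq_len(n)), fold^(seq(0, n - 1) / (n - 1)))
}

tiny_spec <- function(n = 3) library_spec(tiny_roster(n))

# a fast roster subset for pipeline-shaped tests that don't need all 13
fast_roster <- function(seed = 1) {
  r <- default_roster(seed)
  r[r$family %in% c("ridge", "lasso", "decision-tree", "k-neighbors"), ]
}

# simulator settings with noise and toxicity off, for exact planted checks
quiet_params <- function(noise_sd = 0, ...) {
  pathway_params(noise_sd = noise_sd, toxicity_penalty = 1, ...)
}

with_seed_local <- function(seed, code) withr::with_seed(seed, code)

# exact coupon-collector coverage probability by inclusion-exclusion:
# P(all n categories seen in m draws) = sum_j (-1)^j C(n,j) (1 - j/n)^m
exact_coverage_prob <- function(n, m) {
  j <- 0:n
  sum((-1)^j * choose(n, j) * (1 - j / n)^m)
}
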