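# The running example: a binned contig whose bins map to four B-contigs,
# compressing to b1^2 b4^3 b1^3 b3^3 b1^1 b3^1 b2^3 b3^1 (17 tokens, 8 runs).
worked_example_tokens <- function() {
  rep(c("b1", "b4", "b1", "b3", "b1", "b3", "b2", "b3"),
      times = c(2L, 3L, 3L, 3L, 1L, 1L, 3L, 1L))
}

worked_example <- function() compress_runs(worked_example_tokens())

# Random full-alphabet instance with the alphabet clamped to half the
# string length, so rejection sampling converges for every draw.
rand_rs <- function(seed, mmin = 5, mmax = 20, smax = 6) {
  with_seed <- get("with_seed", envir = asNamespace("lrsolve"))
  cfg <- with_seed(seed, {
    m <- sample(mmin:mmax, 1)
    s <- sample(2:max(2L, min(smax, m %/% 2L)), 1)
    c(m, s)
  })
  random_instance(cfg[1], cfg[2], seed = seed + 50000L)
}

# Deterministic instance with exact length m and alphabet size s (cyclic
# tokens), for tests that only probe instance shape, not content.
shaped_instance <- function(m, s) {
  stopifnot(m >= s, s >= 2 || m == s)
  compress_runs(sprintf("s%d", ((seq_len(m) - 1L) %% s) + 1L))
}

# Random LOP instance with integer weights in [1, wmax].
random_digraph <- function(n, seed, wmax = 5L) {
  with_seed <- get("with_seed", envir = asNamespace("lrsolve"))
  with_seed(seed, {
    w <- matrix(sample.int(wmax, n * n, replace = TRUE), n)
    diag(w) <- 0L
    complete_digraph(w)
  })
}

# All solver routes that must agree on small instances.
all_optima <- function(rs) {
  c(bruteforce = solve_bruteforce(rs)$total_length,
    dp = solve_dp(rs)$total_length,
    ilp_agg = solve_ilp(rs)$total_length,
    ilp_pair = solve_ilp(rs, constraint_family = "pairwise")$total_length)
}
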