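# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a uniformly random full-alphabet instance
#'
#' Tokens are drawn i.i.d. uniformly over an alphabet of `s` symbols; the
#' whole string is redrawn until every symbol occurs at least once
#' (rejection keeps the conditional distribution uniform over full-alphabet
#' strings, unlike forced placement). These are worst-case instances for
#' the reduction rules: runs are short and symbols have no locality, so
#' instances can rarely be split. Deterministic given `seed`; the caller's
#' RNG state is left untouched.
#'
#' @param m string length (`m >= s`).
#' @param s alphabet size; symbols are `s1..s<s>`.
#' @param seed integer seed.
#' @param max_tries rejection cap; configurations with `m` barely above `s`
#'   can exhaust it.
#' @return a [run_string()].
#' @export
random_instance <- function(m, s, seed, max_tries = 1000L) {
  if (m < s) stop("need m >= s for a full-alphabet string", call. = FALSE)
  if (s < 1L) stop("alphabet size must be >= 1", call. = FALSE)
  alphabet <- sprintf("s%d", seq_len(s))
  with_seed(seed, {
    for (t in seq_len(max_tries)) {
      tokens <- sample(alphabet, m, replace = TRUE)
      if (length(unique(tokens)) == s) return(compress_runs(tokens))
    }
    stop(sprintf("no full-alphabet string after %d draws (m = %d, s = %d)",
                 max_tries, m, s), call. = FALSE)
  })
}

#' Generate a planted-order instance
#'
#' Emulates the strings arising from binned, already mostly sorted assembly
#' contigs: segments of distinct symbols are concatenated in a planted
#' order, then each position is independently replaced by a uniformly
#' random other symbol with probability `noise_rate` (a wrongly mapped
#' bin). The planted order is returned as ground truth for recovery tests.
#'
#' @param n_segments number of segments (distinct symbols, `g1..g<n>`).
#' @param mean_run_length segment lengths are drawn as
#'   `max(1, rpois(mean_run_length))`.
#' @param noise_rate per-position substitution probability in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `rs` (the [run_string()]), `tokens`, and `order` (the
#'   planted symbol order).
#' @examples
#' p <- planted_instance(3, 10, noise_rate = 0, seed = 1)
#' solve_lrs(p$rs)$optimum == p$rs$m  # TRUE: no noise, no conflicts
#' @export
planted_instance <- function(n_segments, mean_run_length, noise_rate = 0,
                             seed = 1L) {
  if (noise_rate < 0 || noise_rate >= 1) {
    stop("noise_rate must be in [0, 1)", call. = FALSE)
  }
  symbols <- sprintf("g%d", seq_len(n_segments))
  with_seed(seed, {
    lens <- pmax(1L, stats::rpois(n_segments, mean_run_length))
    tokens <- rep(symbols, times = lens)
    if (noise_rate > 0 && n_segments > 1L) {
      hit <- which(stats::runif(length(tokens)) < noise_rate)
      for (p in hit) {
        tokens[p] <- sample(setdiff(symbols, tokens[p]), 1L)
      }
    }
    list(rs = compress_runs(tokens), tokens = tokens, order = symbols)
  })
}
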