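#' Brute-force reference solver
#'
#' Enumerates all 2^n subsets of runs, keeps the valid ones (through the
#' same validity check as [is_valid_selection()]) and returns a selection of
#' maximum total length. Ties are broken by the lexicographically smallest
#' index set, so the result is deterministic. Intended as the independent
#' reference for testing and for tiny instances only.
#'
#' @param rs a [run_string()].
#' @param max_runs refuse instances with more runs than this (exponential
#'   enumeration guard).
#' @return an optimal `lrs_selection`.
#' @export
solve_bruteforce <- function(rs, max_runs = 22L) {
  stopifnot(inherits(rs, "run_string"))
  n <- n_runs(rs)
  if (n > max_runs) {
    stop(sprintf(
      "instance has %d runs; brute force refuses above %d (2^n subsets)",
      n, max_runs), call. = FALSE)
  }
  if (n == 0L) return(selection(rs, integer()))
  idx <- cpp_bruteforce(sym_ids0(rs), rs$lengths, length(rs$alphabet))
  selection(rs, idx)
}
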