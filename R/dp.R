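#' Exact dynamic program for the longest run subsequence
#'
#' Subset dynamic program over pairs (run index, set of used symbols),
#' fixed-parameter tractable in the alphabet size: worst-case work is
#' O(|Sigma| * n * 2^|Sigma|). State (i, F) holds the best total length of a
#' valid run subsequence of the first i runs that ends with run i selected
#' and uses exactly the symbols in F; transitions come from the predecessor
#' sets of [predecessor_set()]. The table is computed in compiled code,
#' densely when it fits a fixed memory guard and as sparse per-column maps
#' of reachable states otherwise; both orderings give identical results.
#'
#' Tie-breaks among co-optimal solutions are deterministic: the smallest
#' predecessor index wins within a state, and the smallest run index, then
#' the smallest symbol-set key, wins globally.
#'
#' @param rs a [run_string()].
#' @param alphabet_cap refuse instances whose alphabet exceeds this size
#'   (the 2^|Sigma| table would be impractical; use [solve_ilp()] instead).
#' @return an optimal `lrs_selection`.
#' @examples
#' rs <- compress_runs(c("a", "b", "c", "a", "b", "c"))
#' solve_dp(rs)$total_length  # 4
#' @seealso [solve_ilp()], [solve_bruteforce()], [solve_lrs()]
#' @export
solve_dp <- function(rs, alphabet_cap = 25L) {
  stopifnot(inherits(rs, "run_string"))
  nsym <- length(rs$alphabet)
  if (nsym > alphabet_cap) {
    stop(sprintf(
      "alphabet too large for DP (|Sigma| = %d > cap %d); use the ILP solver",
      nsym, alphabet_cap), call. = FALSE)
  }
  if (n_runs(rs) == 0L) return(selection(rs, integer()))
  res <- cpp_solve_dp(sym_ids0(rs), rs$lengths, nsym)
  selection(rs, res$indices)
}
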