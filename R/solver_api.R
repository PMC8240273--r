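#' Solver options
#'
#' Collects the tunables of [solve_lrs()].
#'
#' @param algorithm `"auto"` picks DP or ILP per reduced leaf via
#'   [choose_algorithm()]; `"dp"`, `"ilp"` and `"bruteforce"` force one
#'   solver for every leaf.
#' @param prefix_rule,infix_rule enable the corresponding reduction rule.
#' @param hybrid_coefficient,hybrid_offset the dispatch rule prefers the ILP
#'   when the instance size is below `coefficient * (|Sigma| - offset)`;
#'   defaults 10 and 13 were calibrated empirically on random strings.
#' @param dispatch_on measure instance size as expanded string length
#'   (`"length"`, default) or as run count (`"runs"`).
#' @param dp_alphabet_cap refuse the DP above this alphabet size; in auto
#'   mode larger alphabets fall through to the ILP.
#' @param bruteforce_run_cap run cap for [solve_bruteforce()].
#' @param constraint_family ILP constraint family, see [build_ilp()].
#' @param ilp_backend MIP backend, see [bnb_backend()].
#' @param verbose emit progress messages on stderr.
#' @return a list of class `lrs_options`.
#' @export
lrs_options <- function(algorithm = c("auto", "dp", "ilp", "bruteforce"),
                        prefix_rule = TRUE, infix_rule = TRUE,
                        hybrid_coefficient = 10, hybrid_offset = 13,
                        dispatch_on = c("length", "runs"),
                        dp_alphabet_cap = 25L, bruteforce_run_cap = 22L,
                        constraint_family = c("aggregated", "pairwise"),
                        ilp_backend = bnb_backend(), verbose = FALSE) {
  structure(list(algorithm = match.arg(algorithm),
                 prefix_rule = isTRUE(prefix_rule),
                 infix_rule = isTRUE(infix_rule),
                 hybrid_coefficient = hybrid_coefficient,
                 hybrid_offset = hybrid_offset,
                 dispatch_on = match.arg(dispatch_on),
                 dp_alphabet_cap = as.integer(dp_alphabet_cap),
                 bruteforce_run_cap = as.integer(bruteforce_run_cap),
                 constraint_family = match.arg(constraint_family),
                 ilp_backend = ilp_backend,
                 verbose = isTRUE(verbose)),
            class = "lrs_options")
}

#' Hybrid algorithm dispatch
#'
#' Chooses between the two exact solvers from instance shape: the ILP when
#' the instance size is below `coefficient * (|Sigma| - offset)` (with the
#' defaults: size < 10 * (|Sigma| - 13)), otherwise the DP. The rationale is
#' complementary scaling: the ILP scales exponentially in the number of
#' runs but barely notices the alphabet, the DP scales linearly in the runs
#' but exponentially in the alphabet. Dispatch is evaluated per reduced
#' leaf, since that is what the solvers actually see. An alphabet above the
#' DP cap always falls through to the ILP.
#'
#' @param rs a [run_string()] (typically a reduced leaf).
#' @param opts an [lrs_options()] list.
#' @return `"dp"` or `"ilp"`.
#' @examples
#' choose_algorithm(random_instance(50, 20, seed = 1))   # "ilp"
#' choose_algorithm(random_instance(200, 25, seed = 1))  # "dp"
#' @export
choose_algorithm <- function(rs, opts = lrs_options()) {
  stopifnot(inherits(rs, "run_string"))
  nsym <- length(rs$alphabet)
  size <- if (opts$dispatch_on == "length") rs$m else n_runs(rs)
  if (nsym > opts$dp_alphabet_cap) return("ilp")
  if (size < opts$hybrid_coefficient * (nsym - opts$hybrid_offset)) "ilp"
  else "dp"
}

# Every symbol occurs in exactly one run: all runs are selectable with no
# solver call (this also covers n <= 1).
singleton_shortcut <- function(rs) {
  !anyDuplicated(rs$symbols)
}

solve_leaf <- function(rs, opts, log_env = NULL) {
  if (singleton_shortcut(rs)) {
    algo <- "singleton"
    sel <- selection(rs, seq_len(n_runs(rs)))
  } else {
    algo <- if (opts$algorithm == "auto") choose_algorithm(rs, opts)
            else opts$algorithm
    sel <- switch(algo,
      dp = solve_dp(rs, alphabet_cap = opts$dp_alphabet_cap),
      ilp = solve_ilp(rs, backend = opts$ilp_backend,
                      constraint_family = opts$constraint_family),
      bruteforce = solve_bruteforce(rs, max_runs = opts$bruteforce_run_cap))
  }
  if (!is.null(log_env)) {
    log_env$leaves[[length(log_env$leaves) + 1L]] <-
      list(n = n_runs(rs), m = rs$m, sigma = length(rs$alphabet),
           algorithm = algo, optimum = sel$total_length)
  }
  if (!is.null(log_env) && isTRUE(opts$verbose)) {
    message(sprintf("leaf: n=%d m=%d |Sigma|=%d -> %s (optimum %d)",
                    n_runs(rs), rs$m, length(rs$alphabet), algo,
                    sel$total_length))
  }
  sel
}

default_leaf_solver <- function(rs, opts = lrs_options()) {
  solve_leaf(rs, opts)
}

#' Solve a longest run subsequence instance end to end
#'
#' The package's main entry point. The pipeline is: (1) singleton shortcut
#' — if no symbol occurs in more than one run, all runs form the optimum
#' and no solver is invoked; (2) decomposition by the prefix and infix
#' rules ([decompose()]); (3) per-leaf exact solving with the algorithm
#' chosen by [choose_algorithm()] (or forced via `opts$algorithm`); (4)
#' reassembly of the global optimum ([reassemble()]).
#'
#' @param x a [run_string()], or a character vector of tokens (compressed
#'   automatically).
#' @param opts an [lrs_options()] list.
#' @return an object of class `lrs_result`: list with `selection` (the
#'   optimal `lrs_selection`), `optimum`, `dropped` (run indices in
#'   conflict with the optimum), `leaves` (data frame of per-leaf size,
#'   alphabet and algorithm used) and `instance`.
#' @examples
#' res <- solve_lrs(c("a", "a", "b", "a", "c", "c"))
#' res$optimum
#' res$dropped
#' @export
solve_lrs <- function(x, opts = lrs_options()) {
  rs <- if (inherits(x, "run_string")) x else compress_runs(x)
  stopifnot(inherits(opts, "lrs_options"))
  log_env <- new.env(parent = emptyenv())
  log_env$leaves <- list()
  if (singleton_shortcut(rs)) {
    sel <- solve_leaf(rs, opts, log_env)
  } else {
    tree <- decompose(
      rs,
      leaf_solver = function(leaf) solve_leaf(leaf, opts, log_env),
      prefix_rule = opts$prefix_rule,
      infix_rule = opts$infix_rule
    )
    sel <- reassemble(tree)
  }
  leaves <- do.call(rbind, lapply(log_env$leaves, function(l) {
    data.frame(n = l$n, m = l$m, sigma = l$sigma, algorithm = l$algorithm,
               optimum = l$optimum)
  }))
  structure(
    list(selection = sel,
         optimum = sel$total_length,
         dropped = setdiff(seq_len(n_runs(rs)), sel$indices),
         leaves = leaves,
         instance = rs),
    class = "lrs_result"
  )
}

#' @export
print.lrs_result <- function(x, ...) {
  cat(sprintf("<lrs_result> optimum %d of %d tokens; %d of %d runs selected\n",
              x$optimum, x$instance$m, length(x$selection$indices),
              n_runs(x$instance)))
  if (!is.null(x$leaves)) {
    algos <- table(x$leaves$algorithm)
    cat("  leaves:", paste(sprintf("%s x%d", names(algos), algos),
                           collapse = ", "), "\n")
  }
  if (length(x$dropped)) {
    cat("  dropped runs:", paste(utils::head(x$dropped, 20L), collapse = " "),
        if (length(x$dropped) > 20L) "..." else "", "\n")
  }
  invisible(x)
}
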