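#' Build the 0/1 integer linear program for an instance
#'
#' One binary variable per run, objective = sum of selected run lengths.
#' For every ordered pair of same-symbol runs i < j, runs strictly between
#' them with a different symbol must be excluded when both i and j are
#' taken. Two equivalent constraint families are available:
#'
#' * `"pairwise"`: one constraint `x_l <= 2 - x_i - x_j` per intermediate
#'   run l with a different symbol;
#' * `"aggregated"` (default): one constraint per pair,
#'   `sum_l x_l <= (j - i) * (2 - x_i - x_j)`, which solvers tend to handle
#'   slightly faster.
#'
#' The number of pair constraints is at most `ceiling(n/2)^2`. Constraints
#' are generated in deterministic order (pairs lexicographic by symbol-run
#' occurrence) so a deterministic backend reproduces its answer.
#'
#' @param rs a [run_string()] with at least one run.
#' @param constraint_family `"aggregated"` or `"pairwise"`.
#' @return an object of class `lrs_ilp`: list with `n_vars`, `objective`
#'   (run lengths), `constraints` (each a list `idx`, `coef`, `rhs` encoding
#'   `sum coef * x[idx] <= rhs`), `pairs` (the same-symbol pairs used) and
#'   `family`.
#' @examples
#' m <- build_ilp(compress_runs(c("a", "b", "a")))
#' length(m$constraints)  # 1
#' @export
build_ilp <- function(rs, constraint_family = c("aggregated", "pairwise")) {
  stopifnot(inherits(rs, "run_string"))
  constraint_family <- match.arg(constraint_family)
  n <- n_runs(rs)
  if (n < 1L) stop("cannot build a model for an empty instance", call. = FALSE)
  constraints <- list()
  pairs <- list()
  for (sym in rs$alphabet) {
    occ <- which(rs$symbols == sym)
    if (length(occ) < 2L) next
    for (a in seq_len(length(occ) - 1L)) {
      for (b in seq.int(a + 1L, length(occ))) {
        i <- occ[a]
        j <- occ[b]
        pairs[[length(pairs) + 1L]] <- c(i, j)
        between <- seq.int(i + 1L, j - 1L)
        between <- between[rs$symbols[between] != sym]
        if (!length(between)) next
        if (constraint_family == "pairwise") {
          for (l in between) {
            constraints[[length(constraints) + 1L]] <-
              list(idx = c(l, i, j), coef = c(1, 1, 1), rhs = 2)
          }
        } else {
          d <- j - i
          constraints[[length(constraints) + 1L]] <-
            list(idx = c(between, i, j),
                 coef = c(rep(1, length(between)), d, d),
                 rhs = 2 * d)
        }
      }
    }
  }
  structure(list(n_vars = n, objective = as.numeric(rs$lengths),
                 constraints = constraints, pairs = pairs,
                 family = constraint_family),
            class = "lrs_ilp")
}

#' @export
print.lrs_ilp <- function(x, ...) {
  cat(sprintf("<lrs_ilp> %d binary variables, %d constraints (%s family)\n",
              x$n_vars, length(x$constraints), x$family))
  invisible(x)
}

# Does a 0/1 assignment satisfy every constraint of the model?
ilp_feasible <- function(model, x) {
  for (con in model$constraints) {
    if (sum(con$coef * x[con$idx]) > con$rhs + 1e-9) return(FALSE)
  }
  TRUE
}

#' Default MIP backend: exact branch-and-bound
#'
#' Returns a backend function satisfying the solver contract used by
#' [solve_ilp()]: it accepts an `lrs_ilp` model and returns a list with
#' `status` (`"optimal"`, `"infeasible"` or `"node_limit"`), `objective` and
#' `x` (the 0/1 assignment). The backend is a complete depth-first
#' branch-and-bound over the binary variables with incremental feasibility
#' and an objective bound, so `"optimal"` means proven optimality.
#'
#' @param node_limit abort with status `"node_limit"` after this many search
#'   nodes instead of returning an unproven incumbent.
#' @return a function `(model) -> list(status, objective, x, nodes)`.
#' @export
bnb_backend <- function(node_limit = 5e7) {
  function(model) {
    stopifnot(inherits(model, "lrs_ilp"))
    res <- cpp_bnb(model$objective,
                   lapply(model$constraints, `[[`, "idx"),
                   lapply(model$constraints, `[[`, "coef"),
                   vapply(model$constraints, `[[`, numeric(1), "rhs"),
                   node_limit = node_limit)
    res
  }
}

#' Solve an instance by integer linear programming
#'
#' Builds the model of [build_ilp()] and hands it to a MIP backend. Only a
#' backend answer with proven optimality is accepted; a timeout or node
#' limit raises an error rather than silently returning an incumbent.
#' Variable values above 0.5 decode to selected runs, absorbing float noise
#' from fractional backends.
#'
#' @param rs a [run_string()].
#' @param backend a backend function as returned by [bnb_backend()].
#' @param constraint_family `"aggregated"` or `"pairwise"`.
#' @return an optimal `lrs_selection`.
#' @export
solve_ilp <- function(rs, backend = bnb_backend(),
                      constraint_family = c("aggregated", "pairwise")) {
  stopifnot(inherits(rs, "run_string"))
  if (n_runs(rs) == 0L) return(selection(rs, integer()))
  model <- build_ilp(rs, constraint_family)
  res <- backend(model)
  if (!identical(res$status, "optimal")) {
    stop("ILP backend returned no proven optimum (status: ",
         res$status, ")", call. = FALSE)
  }
  selection(rs, which(res$x > 0.5))
}

#' Export an ILP model in LP file format
#'
#' Writes the model in the standard LP text dialect for inspection or for
#' feeding an external solver.
#'
#' @param model an `lrs_ilp` from [build_ilp()].
#' @param path output file path.
#' @export
write_lp <- function(model, path) {
  stopifnot(inherits(model, "lrs_ilp"))
  term <- function(coef, idx) {
    paste(sprintf("%+g x%d", coef, idx), collapse = " ")
  }
  lines <- c(
    "Maximize",
    paste(" obj:", term(model$objective, seq_len(model$n_vars))),
    "Subject To",
    unlist(lapply(seq_along(model$constraints), function(r) {
      con <- model$constraints[[r]]
      sprintf(" c%d: %s <= %g", r, term(con$coef, con$idx), con$rhs)
    })),
    "Binary",
    paste("", paste(sprintf("x%d", seq_len(model$n_vars)), collapse = " ")),
    "End")
  writeLines(lines, path)
}
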