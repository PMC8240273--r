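#' Complete weighted digraph (linear ordering instance)
#'
#' The linear ordering problem (LOP) asks for a permutation of the vertices
#' of a complete weighted digraph maximizing the total weight of forward
#' edges. LOP is NP-hard, and the package's hardness harness reduces it to
#' longest run subsequence instances.
#'
#' @param w square numeric matrix of integer edge weights; `w[i, j]` is the
#'   weight of the edge from vertex i to vertex j. The diagonal is ignored
#'   (no self-loops).
#' @return object of class `lop_instance`: list with `n`, `w` (integer
#'   matrix, diagonal zeroed) and `w_sum` (sum of all off-diagonal weights).
#' @export
complete_digraph <- function(w) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) stop("weight matrix must be square", call. = FALSE)
  n <- nrow(w)
  if (n < 2L) stop("need at least two vertices", call. = FALSE)
  storage.mode(w) <- "integer"
  diag(w) <- 0L
  if (anyNA(w)) stop("weights must be integers (no NA)", call. = FALSE)
  structure(list(n = n, w = w, w_sum = sum(w)), class = "lop_instance")
}

#' @export
print.lop_instance <- function(x, ...) {
  cat(sprintf("<lop_instance> %d vertices, total weight %d\n", x$n, x$w_sum))
  invisible(x)
}

#' Shift edge weights to be strictly positive
#'
#' The hardness construction assumes positive weights. Because a linear
#' order always has exactly n(n-1)/2 forward edges, adding a uniform offset
#' to every weight shifts every ordering's objective by the same constant
#' and preserves the optimal order. The offset is `1 - min(w)` when the
#' minimum is at most 0, else 0.
#'
#' @param g a [complete_digraph()].
#' @return list with `graph` (normalized instance) and `offset`.
#' @export
normalize_weights <- function(g) {
  stopifnot(inherits(g, "lop_instance"))
  off <- g$w[row(g$w) != col(g$w)]
  offset <- if (min(off) <= 0L) 1L - min(off) else 0L
  w <- g$w + offset
  diag(w) <- 0L
  list(graph = complete_digraph(w), offset = as.integer(offset))
}

# Canonical triangle symbol: lexicographically smallest rotation of
# (i, j, k); rotations of an oriented triangle name the same sign.
triangle_symbol <- function(i, j, k) {
  rot <- list(c(i, j, k), c(j, k, i), c(k, i, j))
  keys <- vapply(rot, function(r) sprintf("%03d%03d%03d", r[1], r[2], r[3]),
                 character(1))
  r <- rot[[which.min(keys)]]
  sprintf("D(%d,%d,%d)", r[1], r[2], r[3])
}

edge_symbol <- function(i, j) sprintf("E{%d,%d}", min(i, j), max(i, j))

#' Reduce a linear ordering instance to a longest run subsequence instance
#'
#' Builds the hardness construction: the string consists of one vertex
#' block per vertex, separated by separator runs of length M. The vertex
#' block of vertex i concatenates one edge block per ordered pair (i, j),
#' j != i; edge block (i, j) is
#' `E(i,j)^(w_ij + w_sum)  D(i,j,k)^M' ...  E(i,j)^(w_ij + w_sum)`
#' with one triangle run per k outside \{i, j\} (ascending k) padded by the
#' two edge-sign runs. `M' = 4 n^2 w_sum` exceeds all edge-sign runs
#' combined and `M = M' n^3` exceeds all triangle runs combined, which
#' forces every optimal solution to take all separators and one run per
#' triangle sign; the remaining freedom — picking the edge sign in block
#' (i, j) or (j, i) — mirrors orienting each vertex pair in an acyclic
#' tournament. The instance is kept in run-length form only; expanding it
#' is refused above a size guard since M is huge by design.
#'
#' @param g a [complete_digraph()] with at least 3 vertices and strictly
#'   positive weights (see [normalize_weights()]).
#' @return object of class `lrs_hardness`: list with `rs` (the
#'   [run_string()]), `M`, `M_prime`, `w_sum`, `alphabet` (partition into
#'   separator/edge/triangle symbols) and `provenance` (data frame mapping
#'   each run to its block: type, block vertex, edge pair, symbol, length).
#' @export
lop_to_lrs <- function(g) {
  stopifnot(inherits(g, "lop_instance"))
  n <- g$n
  if (n < 3L) {
    stop("the construction needs n >= 3 (no triangles otherwise)",
         call. = FALSE)
  }
  offd <- g$w[row(g$w) != col(g$w)]
  if (any(offd < 1L)) {
    stop("weights must be strictly positive; normalize_weights() first",
         call. = FALSE)
  }
  w_sum <- g$w_sum
  M_prime <- 4 * n^2 * w_sum
  M <- M_prime * n^3
  syms <- character()
  lens <- numeric()
  prov <- list()
  add <- function(symbol, length, type, block, i, j) {
    syms[[length(syms) + 1L]] <<- symbol
    lens[[base::length(lens) + 1L]] <<- length
    prov[[base::length(prov) + 1L]] <<-
      data.frame(symbol = symbol, length = length, type = type,
                 block = block, i = i, j = j)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i) next
      e <- edge_symbol(i, j)
      elen <- g$w[i, j] + w_sum
      add(e, elen, "edge", i, i, j)
      for (k in setdiff(seq_len(n), c(i, j))) {
        add(triangle_symbol(i, j, k), M_prime, "triangle", i, i, j)
      }
      add(e, elen, "edge", i, i, j)
    }
    if (i < n) add(sprintf("$%d", i), M, "separator", i, NA, NA)
  }
  rs <- run_string(syms, lens)
  provenance <- do.call(rbind, prov)
  provenance$run <- seq_len(nrow(provenance))
  structure(
    list(rs = rs, M = M, M_prime = M_prime, w_sum = w_sum,
         alphabet = list(
           separators = sprintf("$%d", seq_len(n)),
           edges = unique(provenance$symbol[provenance$type == "edge"]),
           triangles = unique(provenance$symbol[provenance$type == "triangle"])),
         provenance = provenance),
    class = "lrs_hardness"
  )
}

#' @export
print.lrs_hardness <- function(x, ...) {
  cat(sprintf(
    "<lrs_hardness> %d runs, M = %d, M' = %d, w_sum = %d\n",
    n_runs(x$rs), x$M, x$M_prime, x$w_sum))
  invisible(x)
}

#' Target length of the hardness reduction
#'
#' The reduction maps a LOP objective value k to the LRS length
#' `f_G(k) = (n-1) M + n(n-1)(n-2)/3 * M' + n(n-1) w_sum + 2k`:
#' all separators, one run per triangle sign, both edge-sign runs of one
#' edge block per vertex pair (each of length w_ij + w_sum). f_G is
#' strictly increasing in k, so the LOP optimum k* satisfies
#' `LRS(S) = f_G(k*)` exactly.
#'
#' @param k a LOP objective value.
#' @param g the (normalized) [complete_digraph()] the instance came from.
#' @return the integer target length.
#' @examples
#' g <- complete_digraph(matrix(1, 3, 3))
#' f_g(3, g)  # 12138
#' @export
f_g <- function(k, g) {
  stopifnot(inherits(g, "lop_instance"))
  n <- g$n
  M_prime <- 4 * n^2 * g$w_sum
  M <- M_prime * n^3
  (n - 1) * M + n * (n - 1) * (n - 2) / 3 * M_prime +
    n * (n - 1) * g$w_sum + 2 * k
}

# All permutations of 1..n, in lexicographic order.
permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (p in permutations(n - 1L)) {
      out[[length(out) + 1L]] <- c(first, rest[p])
    }
  }
  out
}

#' Solve a linear ordering instance exhaustively
#'
#' Enumerates all n! vertex permutations and returns one maximizing the
#' total weight of forward edges; ties go to the lexicographically smallest
#' permutation (the enumeration order).
#'
#' @param g a [complete_digraph()].
#' @param max_n refuse instances with more vertices than this.
#' @return list with `order` (integer permutation) and `weight` (the LOP
#'   optimum k*).
#' @export
solve_lop_bruteforce <- function(g, max_n = 8L) {
  stopifnot(inherits(g, "lop_instance"))
  if (g$n > max_n) {
    stop(sprintf("n = %d exceeds the %d! enumeration cap", g$n, max_n),
         call. = FALSE)
  }
  best <- NULL
  best_w <- -Inf
  for (p in permutations(g$n)) {
    wt <- 0L
    for (a in seq_len(g$n - 1L)) {
      wt <- wt + sum(g$w[p[a], p[seq.int(a + 1L, g$n)]])
    }
    if (wt > best_w) {
      best_w <- wt
      best <- p
    }
  }
  list(order = best, weight = as.integer(best_w))
}
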