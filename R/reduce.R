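#' Split off the shortest independent prefix of an instance
#'
#' A prefix of runs is independent when its symbols do not occur in the rest
#' of the string; by alphabet-disjoint additivity the two parts can then be
#' solved separately and the optima added. The scan starts with run 1, keeps
#' the index `p` of the last occurrence of every symbol met so far, and
#' closes when the scan position passes `p`. Linear time.
#'
#' @param rs a [run_string()] with at least one run.
#' @return `NULL` when no proper independent prefix exists, otherwise a list
#'   with elements `prefix` and `suffix` (both `run_string`s) and `at` (the
#'   run index where the prefix ends).
#' @examples
#' rs <- compress_runs(c("a", "b", "a", "c", "c"))
#' split_prefix(rs)$at  # 3
#' @export
split_prefix <- function(rs) {
  stopifnot(inherits(rs, "run_string"))
  n <- n_runs(rs)
  if (n == 0L) stop("cannot split an empty instance", call. = FALSE)
  last_of <- vapply(rs$alphabet, function(s) max(which(rs$symbols == s)),
                    integer(1))
  names(last_of) <- rs$alphabet
  p <- last_of[[rs$symbols[1L]]]
  l <- 2L
  while (l <= p) {
    p <- max(p, last_of[[rs$symbols[l]]])
    l <- l + 1L
  }
  if (p >= n) return(NULL)
  list(prefix = subset_runs(rs, 1L, p),
       suffix = subset_runs(rs, p + 1L, n),
       at = as.integer(p))
}

# Iterate the prefix rule: cut rs into maximal independent pieces.
# Returns list(pieces = list of run_string, offsets = 0-based run offsets).
prefix_pieces <- function(rs) {
  pieces <- list()
  offsets <- integer()
  off <- 0L
  rest <- rs
  repeat {
    sp <- if (n_runs(rest) > 0L) split_prefix(rest) else NULL
    if (is.null(sp)) {
      pieces[[length(pieces) + 1L]] <- rest
      offsets <- c(offsets, off)
      break
    }
    pieces[[length(pieces) + 1L]] <- sp$prefix
    offsets <- c(offsets, off)
    off <- off + sp$at
    rest <- sp$suffix
  }
  list(pieces = pieces, offsets = offsets)
}

#' Find independent infixes of an instance
#'
#' An infix of runs is independent when its symbols occur nowhere else in
#' the string. Each alphabet symbol is tried as an anchor: the interval
#' spanning its first and last occurrence is expanded whenever an enclosed
#' symbol occurs outside, until it is closed or covers everything. Closed
#' proper intervals are collected, overlapping or adjacent intervals are
#' merged, and single-run intervals are discarded (replacing one run by one
#' placeholder reduces nothing).
#'
#' @param rs a [run_string()].
#' @return list of integer vectors `c(p, q)`, disjoint, sorted, each
#'   covering at least two runs with an alphabet disjoint from the rest.
#' @examples
#' rs <- compress_runs(c("a", "c", "d", "c", "a", "b", "a"))
#' find_independent_infixes(rs)  # list(c(2, 4)): the (c)(d)(c) block
#' @export
find_independent_infixes <- function(rs) {
  stopifnot(inherits(rs, "run_string"))
  n <- n_runs(rs)
  if (n < 2L) return(list())
  first_of <- vapply(rs$alphabet, function(s) min(which(rs$symbols == s)),
                     integer(1))
  last_of <- vapply(rs$alphabet, function(s) max(which(rs$symbols == s)),
                    integer(1))
  names(first_of) <- names(last_of) <- rs$alphabet
  intervals <- list()
  for (anchor in rs$alphabet) {
    p <- first_of[[anchor]]
    q <- last_of[[anchor]]
    repeat {
      syms <- unique(rs$symbols[p:q])
      p2 <- min(first_of[syms])
      q2 <- max(last_of[syms])
      if (p2 == p && q2 == q) break
      p <- p2
      q <- q2
    }
    if (!(p == 1L && q == n)) {
      intervals[[length(intervals) + 1L]] <- c(p, q)
    }
  }
  if (!length(intervals)) return(list())
  # union of overlapping/nested, then merge adjacent (q1 + 1 == p2)
  iv <- do.call(rbind, intervals)
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  merged <- list()
  cur <- iv[1L, ]
  for (r in seq_len(nrow(iv))[-1L]) {
    nxt <- iv[r, ]
    if (nxt[1L] <= cur[2L] + 1L) {
      cur[2L] <- max(cur[2L], nxt[2L])
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- nxt
    }
  }
  merged[[length(merged) + 1L]] <- cur
  merged <- Filter(function(x) x[2L] - x[1L] >= 1L, merged)
  # a merge chain can grow to cover the whole string; that is no reduction
  merged <- Filter(function(x) !(x[1L] == 1L && x[2L] == n), merged)
  lapply(merged, as.integer)
}

# Fresh placeholder token outside the given alphabet.
placeholder_token <- function(k, taken) {
  tok <- sprintf(".ph%d", k)
  while (tok %in% taken) tok <- paste0(tok, ".")
  tok
}

#' Decompose an instance with the prefix and infix rules
#'
#' Orchestration: the prefix rule is applied to exhaustion; on every piece
#' independent infixes are searched; each infix is replaced in the outer
#' instance by a fresh placeholder run whose length is the infix's own
#' optimum, and the procedure recurses into the infixes (starting again with
#' the prefix rule) and into the reduced outer instance. Leaves are
#' irreducible sub-instances. Because placeholder lengths are child optima,
#' decomposition is interleaved with solving: `leaf_solver` is called on
#' every leaf and its solutions are stored in the tree.
#'
#' @param rs a [run_string()].
#' @param leaf_solver function taking a `run_string` and returning an
#'   `lrs_selection`; defaults to the exact dynamic program with an ILP
#'   fallback for large alphabets.
#' @param prefix_rule,infix_rule logical switches for the two rules.
#' @return a reduction tree of class `lrs_reduction`. Leaves carry their
#'   sub-instance, a leaf id and the stored solution; inner nodes record how
#'   to reassemble a global optimum via [reassemble()].
#' @export
decompose <- function(rs, leaf_solver = NULL, prefix_rule = TRUE,
                      infix_rule = TRUE) {
  stopifnot(inherits(rs, "run_string"))
  if (is.null(leaf_solver)) {
    leaf_solver <- function(leaf) default_leaf_solver(leaf)
  }
  state <- new.env(parent = emptyenv())
  state$leaf_id <- 0L
  state$ph_id <- 0L
  tree <- decompose_node(rs, leaf_solver, prefix_rule, infix_rule, state)
  tree
}

decompose_node <- function(rs, leaf_solver, prefix_rule, infix_rule, state) {
  n <- n_runs(rs)
  if (prefix_rule && n > 1L) {
    pp <- prefix_pieces(rs)
    if (length(pp$pieces) > 1L) {
      children <- lapply(pp$pieces, decompose_piece, leaf_solver = leaf_solver,
                         prefix_rule = prefix_rule, infix_rule = infix_rule,
                         state = state)
      return(structure(list(kind = "prefix", rs = rs, children = children,
                            offsets = pp$offsets),
                       class = "lrs_reduction"))
    }
  }
  decompose_piece(rs, leaf_solver, prefix_rule, infix_rule, state)
}

decompose_piece <- function(rs, leaf_solver, prefix_rule, infix_rule, state) {
  n <- n_runs(rs)
  if (infix_rule && n > 2L) {
    ivs <- find_independent_infixes(rs)
    if (length(ivs)) {
      placeholders <- list()
      # build outer instance: runs outside intervals + one placeholder each
      out_syms <- character()
      out_lens <- integer()
      outer_map <- integer()   # outer run index -> original index (NA = ph)
      ph_at <- integer()       # outer run index of each placeholder
      pos <- 1L
      taken <- rs$alphabet
      for (t in seq_along(ivs)) {
        iv <- ivs[[t]]
        while (pos < iv[1L]) {
          out_syms <- c(out_syms, rs$symbols[pos])
          out_lens <- c(out_lens, rs$lengths[pos])
          outer_map <- c(outer_map, pos)
          pos <- pos + 1L
        }
        child_rs <- subset_runs(rs, iv[1L], iv[2L])
        child <- decompose_node(child_rs, leaf_solver, prefix_rule,
                                infix_rule, state)
        child_opt <- reassemble(child)$total_length
        state$ph_id <- state$ph_id + 1L
        ph <- placeholder_token(state$ph_id, taken)
        taken <- c(taken, ph)
        out_syms <- c(out_syms, ph)
        out_lens <- c(out_lens, child_opt)
        outer_map <- c(outer_map, NA_integer_)
        ph_at <- c(ph_at, length(out_syms))
        placeholders[[t]] <- list(symbol = ph, from = iv[1L], to = iv[2L],
                                  length = child_opt, child = child)
        pos <- iv[2L] + 1L
      }
      while (pos <= n) {
        out_syms <- c(out_syms, rs$symbols[pos])
        out_lens <- c(out_lens, rs$lengths[pos])
        outer_map <- c(outer_map, pos)
        pos <- pos + 1L
      }
      outer_rs <- run_string(out_syms, out_lens)
      outer <- decompose_node(outer_rs, leaf_solver, prefix_rule,
                              infix_rule, state)
      return(structure(list(kind = "infix", rs = rs, outer = outer,
                            outer_map = outer_map, ph_at = ph_at,
                            placeholders = placeholders),
                       class = "lrs_reduction"))
    }
  }
  state$leaf_id <- state$leaf_id + 1L
  structure(list(kind = "leaf", rs = rs, leaf_id = state$leaf_id,
                 solution = leaf_solver(rs)),
            class = "lrs_reduction")
}

#' @export
print.lrs_reduction <- function(x, ...) {
  lv <- tree_leaves(x)
  cat(sprintf("<lrs_reduction> %s node over %d runs; %d leaf instance(s)\n",
              x$kind, n_runs(x$rs), length(lv)))
  invisible(x)
}

#' Leaves of a reduction tree
#'
#' @param tree an `lrs_reduction` from [decompose()].
#' @return list of leaves in leaf-id order; each has `rs`, `leaf_id` and the
#'   stored `solution`.
#' @export
tree_leaves <- function(tree) {
  acc <- list()
  walk <- function(node) {
    switch(node$kind,
      leaf = acc[[length(acc) + 1L]] <<- node,
      prefix = lapply(node$children, walk),
      infix = {
        for (ph in node$placeholders) walk(ph$child)
        walk(node$outer)
      })
    invisible(NULL)
  }
  walk(tree)
  acc[order(vapply(acc, function(l) l$leaf_id, integer(1)))]
}

#' Reassemble a global solution from leaf solutions
#'
#' Maps per-leaf selections back through the reduction tree onto the
#' original instance: concatenated prefix pieces are shifted and joined; a
#' selected placeholder run is replaced by the infix child's selected runs,
#' a dropped placeholder contributes nothing. When every leaf solution is
#' optimal the reassembled selection is optimal for the original instance.
#'
#' @param tree an `lrs_reduction` from [decompose()].
#' @param leaf_solutions optional list of `lrs_selection`s indexed by leaf
#'   id, overriding the solutions stored in the tree. Overrides must have
#'   the total length recorded for the corresponding leaf, since placeholder
#'   run lengths were fixed to the child optima when the tree was built.
#' @return an `lrs_selection` on the tree's original instance.
#' @export
reassemble <- function(tree, leaf_solutions = NULL) {
  stopifnot(inherits(tree, "lrs_reduction"))
  get_solution <- function(leaf) {
    if (is.null(leaf_solutions)) return(leaf$solution)
    if (length(leaf_solutions) < leaf$leaf_id ||
        is.null(leaf_solutions[[leaf$leaf_id]])) {
      stop("missing solution for leaf ", leaf$leaf_id, call. = FALSE)
    }
    sol <- leaf_solutions[[leaf$leaf_id]]
    if (sol$total_length != leaf$solution$total_length) {
      stop("leaf ", leaf$leaf_id, " solution length ", sol$total_length,
           " does not match the recorded optimum ",
           leaf$solution$total_length, call. = FALSE)
    }
    sol
  }
  walk <- function(node) {
    switch(node$kind,
      leaf = get_solution(node)$indices,
      prefix = {
        idx <- integer()
        for (t in seq_along(node$children)) {
          idx <- c(idx, walk(node$children[[t]]) + node$offsets[t])
        }
        idx
      },
      infix = {
        outer_idx <- walk(node$outer)
        idx <- integer()
        for (k in outer_idx) {
          ph_pos <- match(k, node$ph_at)
          if (is.na(ph_pos)) {
            idx <- c(idx, node$outer_map[k])
          } else {
            ph <- node$placeholders[[ph_pos]]
            idx <- c(idx, walk(ph$child) + (ph$from - 1L))
          }
        }
        sort(idx)
      })
  }
  selection(tree$rs, sort(walk(tree)))
}
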