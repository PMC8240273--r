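#' Run-length instance model for the longest run subsequence problem
#'
#' A `run_string` is the run-length view of a token sequence: maximal blocks
#' of one repeated token, in order. All solvers in the package work on this
#' representation, since an optimal run subsequence always takes or drops
#' whole runs. Tokens are arbitrary strings (e.g. contig names); single
#' characters are just a special case.
#'
#' @param symbols character vector of run symbols; adjacent entries must
#'   differ (maximality).
#' @param lengths positive integer vector, one length per run.
#' @return An object of class `run_string`: a list with elements `symbols`,
#'   `lengths`, `starts` (1-based position of each run's first token in the
#'   expanded string), `m` (expanded length) and `alphabet` (distinct symbols
#'   in order of first occurrence).
#' @examples
#' rs <- run_string(c("a", "b", "a"), c(2L, 1L, 3L))
#' rs$m
#' expand_runs(rs)
#' @seealso [compress_runs()], [expand_runs()], [solve_lrs()]
#' @export
run_string <- function(symbols = character(), lengths = integer()) {
  symbols <- as.character(symbols)
  lengths <- as.integer(lengths)
  if (length(symbols) != length(lengths)) {
    stop("`symbols` and `lengths` must have equal length", call. = FALSE)
  }
  if (length(lengths) && any(is.na(lengths) | lengths < 1L)) {
    stop("run lengths must be positive integers", call. = FALSE)
  }
  n <- length(symbols)
  if (n > 1L && any(symbols[-1L] == symbols[-n])) {
    stop("adjacent runs must have distinct symbols (runs are maximal)",
         call. = FALSE)
  }
  m <- sum(lengths)
  starts <- if (n) cumsum(c(1L, lengths[-n])) else integer()
  structure(
    list(symbols = symbols, lengths = lengths, starts = starts,
         m = as.integer(m), alphabet = unique(symbols)),
    class = "run_string"
  )
}

#' Run-length compress a token sequence
#'
#' @param tokens character vector of tokens (may be empty).
#' @return A [run_string()] whose expansion reproduces `tokens`.
#' @examples
#' compress_runs(c("b1", "b1", "b4", "b4", "b4", "b1"))
#' @export
compress_runs <- function(tokens) {
  tokens <- as.character(tokens)
  if (!length(tokens)) return(run_string())
  boundary <- c(TRUE, tokens[-1L] != tokens[-length(tokens)])
  grp <- cumsum(boundary)
  run_string(tokens[boundary], tabulate(grp))
}

#' Expand a run string back to its token sequence
#'
#' Inverse of [compress_runs()]: `expand_runs(compress_runs(x))` is `x`.
#'
#' @param rs a [run_string()].
#' @return character vector of tokens.
#' @export
expand_runs <- function(rs) {
  stopifnot(inherits(rs, "run_string"))
  rep(rs$symbols, times = rs$lengths)
}

#' @export
print.run_string <- function(x, ...) {
  cat(sprintf("<run_string> %d runs, %d tokens, alphabet size %d\n",
              length(x$symbols), x$m, length(x$alphabet)))
  if (length(x$symbols)) {
    enc <- paste0(x$symbols, "^", x$lengths)
    if (length(enc) > 12L) enc <- c(enc[1:12], "...")
    cat(" ", paste(enc, collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of runs in a run string
#' @param rs a [run_string()].
#' @return integer run count `n`.
#' @export
n_runs <- function(rs) {
  stopifnot(inherits(rs, "run_string"))
  length(rs$symbols)
}

# 0-based symbol ids against the instance alphabet, for the compiled cores.
sym_ids0 <- function(rs) match(rs$symbols, rs$alphabet) - 1L

check_run_index <- function(rs, i) {
  n <- n_runs(rs)
  if (length(i) != 1L || is.na(i) || i < 1L || i > n) {
    stop(sprintf("run index must be a single value in 1..%d", n),
         call. = FALSE)
  }
  as.integer(i)
}

#' Last occurrence of a symbol before a run
#'
#' The index function P: `last_occurrence(rs, sigma, i)` is the largest run
#' index `j < i` whose symbol is `sigma`, or 0 if `sigma` does not occur
#' before run `i`. This is the quantity the dynamic program's predecessor
#' sets are built from.
#'
#' @param rs a [run_string()].
#' @param sigma a token; it need not occur in `rs`.
#' @param i run index in `1..n_runs(rs)`.
#' @return integer run index, 0 when there is no earlier occurrence.
#' @examples
#' rs <- compress_runs(rep(c("b1", "b4", "b1"), times = c(2, 3, 3)))
#' last_occurrence(rs, "b1", 3)  # 1
#' @export
last_occurrence <- function(rs, sigma, i) {
  i <- check_run_index(rs, i)
  hits <- which(rs$symbols[seq_len(i - 1L)] == as.character(sigma))
  if (length(hits)) max(hits) else 0L
}

#' Predecessor set of a run for the dynamic program
#'
#' For run `i`, collects the last-occurrence indices `P_sigma(i)` of every
#' symbol (plus a virtual start, whose index is 0) that are at least
#' `P_sigma(r_i)(i)`. These are the only candidate predecessors of run `i`
#' in an optimal run subsequence: 0 is a member exactly when run `i` is the
#' first of its symbol.
#'
#' @param rs a [run_string()].
#' @param i run index in `1..n_runs(rs)`.
#' @return sorted integer vector of candidate predecessor indices (may
#'   include 0, the virtual start).
#' @export
predecessor_set <- function(rs, i) {
  i <- check_run_index(rs, i)
  thresh <- last_occurrence(rs, rs$symbols[i], i)
  p <- vapply(rs$alphabet, function(s) last_occurrence(rs, s, i), integer(1))
  keep <- sort(unique(c(if (thresh == 0L) 0L, p[p >= max(thresh, 1L)])))
  as.integer(keep)
}

#' Construct a selection of runs
#'
#' A selection is a strictly increasing set of run indices together with its
#' total selected length (the objective value) and the induced token
#' subsequence. Construction does not require validity; use
#' [is_valid_selection()] to check the one-run-per-symbol constraint.
#'
#' @param rs a [run_string()].
#' @param indices strictly increasing run indices in `1..n_runs(rs)`.
#' @return An object of class `lrs_selection` with elements `indices`,
#'   `total_length` and `subsequence`.
#' @export
selection <- function(rs, indices) {
  stopifnot(inherits(rs, "run_string"))
  indices <- as.integer(indices)
  n <- n_runs(rs)
  if (length(indices)) {
    if (anyNA(indices) || any(indices < 1L) || any(indices > n)) {
      stop("selection indices out of range", call. = FALSE)
    }
    if (any(diff(indices) <= 0L)) {
      stop("selection indices must be strictly increasing", call. = FALSE)
    }
  }
  structure(
    list(indices = indices,
         total_length = as.integer(sum(rs$lengths[indices])),
         subsequence = rep(rs$symbols[indices], times = rs$lengths[indices])),
    class = "lrs_selection"
  )
}

#' @export
print.lrs_selection <- function(x, ...) {
  cat(sprintf("<lrs_selection> %d runs, total length %d\n",
              length(x$indices), x$total_length))
  if (length(x$indices)) {
    cat("  indices:", paste(x$indices, collapse = " "), "\n")
  }
  invisible(x)
}

as_indices <- function(rs, sel) {
  if (inherits(sel, "lrs_selection")) sel$indices
  else selection(rs, sel)$indices
}

#' Is a selection a valid run subsequence?
#'
#' Valid means the induced subsequence contains at most one maximal run per
#' symbol. Selected same-symbol runs separated only by unselected runs merge
#' into one run and are legal; a selected run of another symbol in between
#' makes the selection invalid. The check is a single linear scan.
#'
#' @param rs a [run_string()].
#' @param sel an `lrs_selection` or a strictly increasing integer vector of
#'   run indices.
#' @return `TRUE` or `FALSE`.
#' @examples
#' rs <- compress_runs(c("a", "b", "a"))
#' is_valid_selection(rs, c(1, 3))  # TRUE: the two a-runs merge
#' is_valid_selection(rs, c(1, 2, 3))  # FALSE: b interrupts a
#' @export
is_valid_selection <- function(rs, sel) {
  idx <- as_indices(rs, sel)
  cpp_is_valid(sym_ids0(rs), idx - 1L, length(rs$alphabet))
}

#' Total length of a selection
#'
#' @inheritParams is_valid_selection
#' @return sum of the selected run lengths (0 for the empty selection).
#' @export
selection_length <- function(rs, sel) {
  idx <- as_indices(rs, sel)
  as.integer(sum(rs$lengths[idx]))
}

# Sub-instance over a contiguous run interval, as a fresh run_string.
subset_runs <- function(rs, from, to) {
  run_string(rs$symbols[from:to], rs$lengths[from:to])
}

#' Read instances from a plain-text file
#'
#' One instance per line. Two dialects: `"tokens"` (whitespace-separated
#' tokens) and `"chars"` (every character is one token). Lines starting with
#' `#` and blank lines are skipped.
#'
#' @param path file path.
#' @param dialect `"tokens"` or `"chars"`.
#' @return list of character token vectors, one per instance line.
#' @export
read_instances <- function(path, dialect = c("tokens", "chars")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lapply(lines, function(l) {
    if (dialect == "tokens") strsplit(trimws(l), "\\s+")[[1]]
    else strsplit(l, "")[[1]]
  })
}

#' Write instances to a plain-text file
#'
#' Counterpart of [read_instances()]; accepts token vectors or
#' [run_string()] objects (which are expanded).
#'
#' @param x a list of character vectors and/or `run_string` objects.
#' @param path file path.
#' @param dialect `"tokens"` or `"chars"`.
#' @export
write_instances <- function(x, path, dialect = c("tokens", "chars")) {
  dialect <- match.arg(dialect)
  if (!is.list(x)) x <- list(x)
  lines <- vapply(x, function(inst) {
    if (inherits(inst, "run_string")) inst <- expand_runs(inst)
    paste(inst, collapse = if (dialect == "tokens") " " else "")
  }, character(1))
  writeLines(lines, path)
}
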