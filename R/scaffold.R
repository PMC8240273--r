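#' Read pairwise alignments in PAF format
#'
#' Parses the 12 mandatory columns of the Pairwise mApping Format (optional
#' SAM-style tags are ignored). In the scaffolding adapter the query side is
#' the contig set being binned (A) and the target side the set being
#' ordered (B). Coordinates are 0-based, half-open.
#'
#' @param path path to a PAF file.
#' @return data frame of class `paf_alignments` with columns `qname`,
#'   `qlen`, `qstart`, `qend`, `strand`, `tname`, `tlen`, `tstart`, `tend`,
#'   `nmatch`, `alen`, `mapq`.
#' @export
read_alignments <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- data.frame(qname = character(), qlen = integer(),
                      qstart = integer(), qend = integer(),
                      strand = character(), tname = character(),
                      tlen = integer(), tstart = integer(), tend = integer(),
                      nmatch = integer(), alen = integer(), mapq = integer())
    class(out) <- c("paf_alignments", class(out))
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_line <- function(f, lineno) {
    if (length(f) < 12L) {
      stop(sprintf("PAF line %d: expected >= 12 columns, got %d",
                   lineno, length(f)), call. = FALSE)
    }
    num <- suppressWarnings(as.integer(f[c(2, 3, 4, 7, 8, 9, 10, 11, 12)]))
    if (anyNA(num)) {
      stop(sprintf("PAF line %d: malformed numeric column", lineno),
           call. = FALSE)
    }
    rec <- data.frame(qname = f[1], qlen = num[1], qstart = num[2],
                      qend = num[3], strand = f[5], tname = f[6],
                      tlen = num[4], tstart = num[5], tend = num[6],
                      nmatch = num[7], alen = num[8], mapq = num[9])
    if (rec$qstart >= rec$qend || rec$qstart < 0L || rec$qend > rec$qlen ||
        rec$tstart >= rec$tend || rec$tstart < 0L || rec$tend > rec$tlen) {
      stop(sprintf("PAF line %d: invalid interval (start < end within [0, len] required)",
                   lineno), call. = FALSE)
    }
    rec
  }
  out <- do.call(rbind, Map(parse_line, fields, seq_along(fields)))
  rownames(out) <- NULL
  class(out) <- c("paf_alignments", class(out))
  out
}

#' Assign each contig bin to its best-matching contig
#'
#' Every A-contig is divided into fixed-size bins (default 10 kb, the
#' empirical sweet spot between information and instance size; the last,
#' shorter bin is kept). For each bin the aligned bases of every B-contig
#' overlapping the bin are summed across records — both strands pooled,
#' since inversions inside one contig do not affect contig order — and the
#' bin is assigned to the B-contig with the most aligned bases (ties to the
#' lexicographically smaller contig id). Bins without any alignment stay
#' unassigned.
#'
#' @param records a `paf_alignments` data frame (query = A side).
#' @param a_lengths named integer vector of A-contig lengths; defaults to
#'   the query lengths found in `records`.
#' @param bin_size bin width in bases.
#' @return data frame of class `bin_assignment` with columns `a_contig`,
#'   `bin` (0-based), `b_contig` (NA when unassigned) and `bases`; one row
#'   per bin of every A-contig. Bin size is kept as attribute `bin_size`.
#' @export
assign_bins <- function(records, a_lengths = NULL, bin_size = 10000) {
  stopifnot(bin_size >= 1)
  if (is.null(a_lengths)) {
    a_lengths <- tapply(records$qlen, records$qname, function(x) x[1])
    a_lengths <- stats::setNames(as.integer(a_lengths), names(a_lengths))
  }
  unknown <- setdiff(unique(records$qname), names(a_lengths))
  if (length(unknown)) {
    stop("records reference unknown A-contigs: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (a in names(a_lengths)) {
    len <- a_lengths[[a]]
    nbin <- max(1L, as.integer(ceiling(len / bin_size)))
    rec <- records[records$qname == a, , drop = FALSE]
    # per (bin, b_contig) overlap of the query interval with the bin
    tally <- new.env(parent = emptyenv())
    if (nrow(rec)) {
      for (r in seq_len(nrow(rec))) {
        b0 <- rec$qstart[r] %/% bin_size
        b1 <- (rec$qend[r] - 1L) %/% bin_size
        for (k in b0:b1) {
          lo <- max(rec$qstart[r], k * bin_size)
          hi <- min(rec$qend[r], (k + 1) * bin_size)
          key <- paste0(k, "\r", rec$tname[r])
          tally[[key]] <- (if (is.null(tally[[key]])) 0 else tally[[key]]) +
            (hi - lo)
        }
      }
    }
    keys <- ls(tally)
    kv <- if (length(keys)) {
      parts <- strsplit(keys, "\r", fixed = TRUE)
      data.frame(bin = as.integer(vapply(parts, `[[`, character(1), 1L)),
                 b_contig = vapply(parts, `[[`, character(1), 2L),
                 bases = vapply(keys, function(k) tally[[k]], numeric(1)))
    } else {
      data.frame(bin = integer(), b_contig = character(), bases = numeric())
    }
    for (k in seq_len(nbin) - 1L) {
      cand <- kv[kv$bin == k & kv$bases > 0, , drop = FALSE]
      if (nrow(cand)) {
        cand <- cand[order(-cand$bases, cand$b_contig), , drop = FALSE]
        rows[[length(rows) + 1L]] <-
          data.frame(a_contig = a, bin = k, b_contig = cand$b_contig[1],
                     bases = cand$bases[1])
      } else {
        rows[[length(rows) + 1L]] <-
          data.frame(a_contig = a, bin = k, b_contig = NA_character_,
                     bases = 0)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bin_size") <- bin_size
  class(out) <- c("bin_assignment", class(out))
  out
}

#' Read precomputed bin assignments from TSV
#'
#' Accepts a tab-separated file `a_contig  bin_index  b_contig
#' aligned_bases` (no header), as an alternative to computing assignments
#' from alignments.
#'
#' @param path file path.
#' @param bin_size bin width the assignments were computed with.
#' @return a `bin_assignment` data frame, see [assign_bins()].
#' @export
read_bin_assignments <- function(path, bin_size = 10000) {
  out <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("a_contig", "bin", "b_contig",
                                         "bases"),
                           colClasses = c("character", "integer",
                                          "character", "numeric"))
  attr(out, "bin_size") <- bin_size
  class(out) <- c("bin_assignment", class(out))
  out
}

#' Order contigs from bin assignments
#'
#' Per A-contig, the assigned B-contigs in bin order form a token string
#' (unassigned bins are omitted: a gap carries no ordering information).
#' Solving longest run subsequence on that string keeps at most one run per
#' B-contig; the run order of the solution is the inferred B-contig order,
#' and the dropped bins are the ones in conflict with it.
#'
#' @param ba a `bin_assignment` data frame from [assign_bins()] or
#'   [read_bin_assignments()].
#' @param opts an [lrs_options()] list passed to [solve_lrs()].
#' @return named list (one entry per A-contig with at least one assigned
#'   bin) of `contig_order` objects: `a_contig`, `order` (B-contig ids),
#'   `support` (selected bins per B-contig), `conflicts` (0-based indices
#'   of dropped bins), `n_assigned` and `optimum`.
#' @export
order_contigs <- function(ba, opts = lrs_options()) {
  stopifnot(inherits(ba, "bin_assignment"))
  out <- list()
  for (a in unique(ba$a_contig)) {
    sub <- ba[ba$a_contig == a & !is.na(ba$b_contig), , drop = FALSE]
    sub <- sub[order(sub$bin), , drop = FALSE]
    if (!nrow(sub)) next
    rs <- compress_runs(sub$b_contig)
    res <- solve_lrs(rs, opts)
    sel_runs <- res$selection$indices
    # map selected runs back to bins: token t of run r is bin sub$bin[t]
    run_of_token <- rep(seq_len(n_runs(rs)), times = rs$lengths)
    kept <- run_of_token %in% sel_runs
    ord <- unique(rs$symbols[sel_runs])
    support <- vapply(ord, function(b) sum(sub$b_contig[kept] == b),
                      integer(1))
    out[[a]] <- structure(
      list(a_contig = a, order = ord,
           support = stats::setNames(support, ord),
           conflicts = sub$bin[!kept],
           n_assigned = nrow(sub),
           optimum = res$optimum),
      class = "contig_order")
  }
  out
}

#' @export
print.contig_order <- function(x, ...) {
  cat(sprintf("<contig_order> %s: %s (%d/%d bins in order, %d conflicting)\n",
              x$a_contig, paste(x$order, collapse = " -> "),
              x$optimum, x$n_assigned, length(x$conflicts)))
  invisible(x)
}
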