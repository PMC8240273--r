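paf_line <- function(q, qlen, qs, qe, strand, t, tlen, ts, te,
                     nm = qe - qs, al = qe - qs, mq = 60) {
  paste(q, qlen, qs, qe, strand, t, tlen, ts, te, nm, al, mq, sep = "\t")
}

test_that("PAF parsing keeps the mandatory columns and flags bad lines", {
  path <- withr::local_tempfile(fileext = ".paf")
  writeLines(paf_line("A1", 30000, 0, 10000, "+", "B1", 50000, 1000, 11000,
                      nm = 9500), path)
  rec <- read_alignments(path)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$qname, "A1")
  expect_equal(rec$nmatch, 9500L)
  expect_equal(rec$tend, 11000L)

  writeLines(character(), path)
  expect_equal(nrow(read_alignments(path)), 0L)

  writeLines(c(paf_line("A1", 30000, 0, 10000, "+", "B1", 50000, 0, 10000),
               paf_line("A1", 30000, 9000, 2000, "+", "B1", 50000, 0, 1000)),
             path)
  expect_error(read_alignments(path), "line 2")

  writeLines("A1\t100\t0", path)
  expect_error(read_alignments(path), ">= 12 columns")
})

test_that("bins take the best-matching contig by aligned bases", {
  path <- withr::local_tempfile(fileext = ".paf")
  writeLines(paf_line("A1", 25000, 0, 25000, "+", "B1", 40000, 0, 25000),
             path)
  ba <- assign_bins(read_alignments(path), c(A1 = 25000L))
  expect_equal(nrow(ba), 3L)
  expect_equal(ba$b_contig, rep("B1", 3))
  expect_equal(ba$bases, c(10000, 10000, 5000))

  # 6 kb of B1 vs 3 kb of B2 in bin 0: argmax picks B1
  writeLines(c(paf_line("A1", 10000, 0, 6000, "+", "B1", 40000, 0, 6000),
               paf_line("A1", 10000, 6000, 9000, "-", "B2", 40000, 0, 3000)),
             path)
  ba2 <- assign_bins(read_alignments(path), c(A1 = 10000L))
  expect_equal(nrow(ba2), 1L)
  expect_equal(ba2$b_contig, "B1")
  expect_equal(ba2$bases, 6000)

  # uncovered bins stay unassigned
  writeLines(paf_line("A1", 30000, 0, 5000, "+", "B1", 40000, 0, 5000), path)
  ba3 <- assign_bins(read_alignments(path), c(A1 = 30000L))
  expect_equal(ba3$b_contig, c("B1", NA, NA))

  expect_error(assign_bins(read_alignments(path), c(A2 = 1000L)), "unknown")
})

test_that("equal-coverage ties go to the lexicographically smaller contig", {
  path <- withr::local_tempfile(fileext = ".paf")
  writeLines(c(paf_line("A1", 10000, 0, 4000, "+", "B9", 40000, 0, 4000),
               paf_line("A1", 10000, 4000, 8000, "+", "B2", 40000, 0, 4000)),
             path)
  ba <- assign_bins(read_alignments(path), c(A1 = 10000L))
  expect_equal(ba$b_contig, "B2")
})

test_that("the bin string of the worked example yields the known order", {
  ba <- data.frame(a_contig = "A1", bin = 0:16,
                   b_contig = worked_example_tokens(), bases = 1000)
  attr(ba, "bin_size") <- 10000
  class(ba) <- c("bin_assignment", class(ba))
  co <- order_contigs(ba)[["A1"]]
  expect_equal(co$order, c("b4", "b1", "b3", "b2"))
  expect_length(co$conflicts, 4L)   # 17 assigned bins - optimum 13
  expect_equal(co$optimum, 13L)
  expect_equal(sum(co$support), 13L)
})

test_that("trivial bin strings shortcut to the obvious order", {
  mk <- function(tokens) {
    ba <- data.frame(a_contig = "A1", bin = seq_along(tokens) - 1L,
                     b_contig = tokens, bases = 500)
    attr(ba, "bin_size") <- 10000
    class(ba) <- c("bin_assignment", class(ba))
    ba
  }
  one <- order_contigs(mk(rep("B1", 5)))[["A1"]]
  expect_equal(one$order, "B1")
  expect_length(one$conflicts, 0L)

  distinct <- order_contigs(mk(c("B1", "B2", "B3")))[["A1"]]
  expect_equal(distinct$order, c("B1", "B2", "B3"))
  expect_length(distinct$conflicts, 0L)
})

test_that("conflicting bins count assigned bins minus the optimum", {
  for (i in 1:10) {
    p <- planted_instance(4, 8, noise_rate = 0.15, seed = 2600 + i)
    ba <- data.frame(a_contig = "A1", bin = seq_along(p$tokens) - 1L,
                     b_contig = p$tokens, bases = 100)
    attr(ba, "bin_size") <- 10000
    class(ba) <- c("bin_assignment", class(ba))
    co <- order_contigs(ba)[["A1"]]
    opt <- solve_lrs(p$rs)$optimum
    expect_equal(length(co$conflicts), length(p$tokens) - opt)
    expect_gte(length(co$conflicts), 0L)
  }
})

test_that("PAF to ordering round trip on a three-record toy file", {
  path <- withr::local_tempfile(fileext = ".paf")
  # A1 aligns to B2 then B1 then B3 along its length
  writeLines(c(
    paf_line("A1", 60000, 0, 20000, "+", "B2", 30000, 5000, 25000),
    paf_line("A1", 60000, 20000, 40000, "-", "B1", 30000, 0, 20000),
    paf_line("A1", 60000, 40000, 60000, "+", "B3", 30000, 10000, 30000)),
    path)
  co <- order_contigs(assign_bins(read_alignments(path)))[["A1"]]
  expect_equal(co$order, c("B2", "B1", "B3"))
  expect_length(co$conflicts, 0L)
  expect_equal(co$n_assigned, 6L)
})

test_that("TSV assignments load as an equivalent bin assignment", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A1\t0\tB2\t9000", "A1\t1\tB1\t8000", "A1\t2\tB1\t7000"),
             path)
  ba <- read_bin_assignments(path)
  co <- order_contigs(ba)[["A1"]]
  expect_equal(co$order, c("B2", "B1"))
  expect_equal(co$support, c(B2 = 1L, B1 = 2L))
})
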