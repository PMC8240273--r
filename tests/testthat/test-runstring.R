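test_that("run-length compression matches the worked example and edge cases", {
  rs <- worked_example()
  expect_equal(rs$symbols, c("b1", "b4", "b1", "b3", "b1", "b3", "b2", "b3"))
  expect_equal(rs$lengths, c(2L, 3L, 3L, 3L, 1L, 1L, 3L, 1L))
  expect_equal(rs$m, 17L)
  expect_equal(rs$alphabet, c("b1", "b4", "b3", "b2"))

  empty <- compress_runs(character())
  expect_equal(n_runs(empty), 0L)
  expect_equal(empty$m, 0L)

  one <- compress_runs(rep("a", 4))
  expect_equal(one$symbols, "a")
  expect_equal(one$lengths, 4L)
})

test_that("expand is the exact inverse of compress", {
  expect_equal(expand_runs(run_string(c("a", "b"), c(2L, 1L))),
               c("a", "a", "b"))
  expect_equal(expand_runs(compress_runs(character())), character())
  expect_equal(expand_runs(worked_example()), worked_example_tokens())
  for (i in 1:30) {
    toks <- lrsolve:::with_seed(300 + i, {
      sample(letters[1:sample(1:5, 1)], sample(1:25, 1), replace = TRUE)
    })
    expect_identical(expand_runs(compress_runs(toks)), toks)
  }
})

test_that("run_string rejects malformed runs", {
  expect_error(run_string(c("a", "a"), c(1L, 2L)), "distinct")
  expect_error(run_string("a", 0L), "positive")
  expect_error(run_string(c("a", "b"), 1L), "equal length")
})

test_that("last occurrence index P matches the printed values", {
  rs <- worked_example()
  expect_equal(last_occurrence(rs, "b1", 4), 3L)
  expect_equal(last_occurrence(rs, "b1", 3), 1L)
  expect_equal(last_occurrence(rs, "b4", 1), 0L)
  expect_equal(last_occurrence(rs, "absent", 8), 0L)
  expect_error(last_occurrence(rs, "b1", 9), "1..8")
  expect_error(last_occurrence(rs, "b1", 0), "1..8")
})

test_that("last occurrence is always below i and zero iff absent before i", {
  rs <- random_instance(30, 4, seed = 11)
  for (i in seq_len(n_runs(rs))) {
    for (s in rs$alphabet) {
      p <- last_occurrence(rs, s, i)
      expect_lt(p, i)
      expect_identical(p == 0L, !(s %in% rs$symbols[seq_len(i - 1L)]))
    }
  }
})

test_that("predecessor sets match hand-enumerated scans", {
  rs <- worked_example()
  expect_equal(predecessor_set(rs, 4), c(0L, 2L, 3L))
  expect_equal(predecessor_set(rs, 3), c(1L, 2L))
  expect_equal(predecessor_set(rs, 1), 0L)
})

test_that("predecessor sets contain the own-symbol threshold or zero", {
  rs <- random_instance(40, 5, seed = 12)
  for (i in seq_len(n_runs(rs))) {
    ps <- predecessor_set(rs, i)
    thresh <- last_occurrence(rs, rs$symbols[i], i)
    if (thresh > 0L) {
      expect_true(thresh %in% ps)
      expect_false(0L %in% ps)
    } else {
      expect_true(0L %in% ps)
    }
    expect_lte(length(ps), length(rs$alphabet) + 1L)
  }
})

test_that("selection validity follows the one-run-per-symbol definition", {
  rs <- worked_example()
  expect_true(is_valid_selection(rs, c(2, 3, 4, 6, 7)))  # b3 runs merge
  expect_false(is_valid_selection(rs, c(4, 7, 8)))       # b2 splits b3
  expect_true(is_valid_selection(rs, integer()))
  expect_error(selection(rs, c(3, 2)), "increasing")
  expect_error(selection(rs, 9), "range")
})

test_that("the all-runs selection is valid iff every symbol has one run", {
  rs1 <- compress_runs(c("a", "b", "c"))
  expect_true(is_valid_selection(rs1, seq_len(n_runs(rs1))))
  rs2 <- compress_runs(c("a", "b", "a"))
  expect_false(is_valid_selection(rs2, seq_len(n_runs(rs2))))
})

test_that("selection length sums the selected run lengths", {
  rs <- worked_example()
  expect_equal(selection_length(rs, c(2, 3, 4, 6, 7)), 13L)
  expect_equal(selection_length(rs, integer()), 0L)
  rs2 <- compress_runs(rep("a", 4))
  expect_equal(selection_length(rs2, 1L), 4L)
  sel <- selection(rs, c(1, 4))
  expect_equal(sel$total_length, selection_length(rs, sel))
})

test_that("instance files round-trip in both dialects", {
  path <- withr::local_tempfile(fileext = ".txt")
  insts <- list(c("b1", "b1", "b4"), c("x", "y"))
  write_instances(insts, path, dialect = "tokens")
  expect_equal(read_instances(path, dialect = "tokens"), insts)
  writeLines(c("# comment", "aab", "", "ba"), path)
  expect_equal(read_instances(path, dialect = "chars"),
               list(c("a", "a", "b"), c("b", "a")))
})
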