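set.seed(11)  # deterministic instance sizes for the property loops

test_that("prefix split finds the shortest independent prefix", {
  sp <- split_prefix(compress_runs(c("a", "b", "a", "c", "c")))
  expect_equal(sp$at, 3L)
  expect_equal(sp$prefix$symbols, c("a", "b", "a"))
  expect_equal(sp$suffix$symbols, "c")

  expect_null(split_prefix(compress_runs(c("a", "b", "a", "b"))))

  sp2 <- split_prefix(compress_runs(c("a", "b")))
  expect_equal(sp2$prefix$symbols, "a")
  expect_equal(sp2$suffix$symbols, "b")

  expect_error(split_prefix(run_string()), "empty")
})

test_that("prefix split preserves content and separates alphabets", {
  for (i in 1:40) {
    rs <- rand_rs(mmin = 6, mmax = 25, smax = 5, seed = 400 + i)
    sp <- split_prefix(rs)
    if (is.null(sp)) next
    expect_identical(c(expand_runs(sp$prefix), expand_runs(sp$suffix)),
                     expand_runs(rs))
    expect_length(intersect(sp$prefix$alphabet, sp$suffix$alphabet), 0)
  }
})

test_that("independent infixes are found, merged and filtered", {
  expect_equal(find_independent_infixes(
    compress_runs(c("a", "c", "d", "c", "a", "b", "a"))), list(c(2L, 4L)))
  # adjacent independent infixes chaining to the whole string reduce nothing
  expect_equal(find_independent_infixes(
    compress_runs(c("a", "c", "d", "c", "a", "b"))), list())
  # single-run infix is discarded
  expect_equal(find_independent_infixes(compress_runs(c("a", "b", "a"))),
               list())
  expect_equal(find_independent_infixes(
    compress_runs(c("a", "c", "c", "a", "b"))), list())  # (c^2) is one run
  # fully interleaved alphabet: nothing to find
  expect_equal(find_independent_infixes(compress_runs(c("a", "b", "a", "b"))),
               list())
  # two adjacent single-run infixes merge into one genuine reduction
  ivs <- find_independent_infixes(
    compress_runs(c("a", "b", "b", "c", "c", "a")))
  expect_equal(ivs, list(c(2L, 3L)))
})

test_that("returned infix intervals are disjoint and alphabet-independent", {
  for (i in 1:40) {
    rs <- rand_rs(mmin = 8, mmax = 30, smax = 6, seed = 500 + i)
    ivs <- find_independent_infixes(rs)
    if (!length(ivs)) next
    cover <- unlist(lapply(ivs, function(iv) iv[1]:iv[2]))
    expect_false(anyDuplicated(cover) > 0)
    for (iv in ivs) {
      expect_gte(iv[2] - iv[1], 1L)
      inside <- unique(rs$symbols[iv[1]:iv[2]])
      outside <- unique(rs$symbols[setdiff(seq_len(n_runs(rs)),
                                           iv[1]:iv[2])])
      expect_length(intersect(inside, outside), 0)
    }
  }
})

test_that("decompose traces the documented rule orchestration", {
  # two singleton leaves via the prefix rule
  tr <- decompose(compress_runs(c("a", "b")))
  expect_equal(tr$kind, "prefix")
  expect_length(tree_leaves(tr), 2L)

  # the worked example is irreducible: a single leaf
  tr2 <- decompose(worked_example())
  expect_equal(tr2$kind, "leaf")

  # prefix splits around an irreducible middle: a one-run infix (c^2)
  # reduces nothing and is discarded, so (b)(c^2)(b) stays one leaf
  tr3 <- decompose(compress_runs(c("a", "a", "b", "c", "c", "b", "d")))
  sizes <- sort(vapply(tree_leaves(tr3), function(l) n_runs(l$rs),
                       integer(1)))
  expect_equal(sizes, c(1L, 1L, 3L))

  # a multi-run infix is cut out and recursed into
  tr4 <- decompose(compress_runs(
    c("a", "a", "b", "c", "d", "d", "c", "b", "e")))
  lv <- tree_leaves(tr4)
  sizes <- sort(vapply(lv, function(l) n_runs(l$rs), integer(1)))
  expect_equal(sizes, c(1L, 1L, 3L, 3L))  # (a^2), (e), (c)(d^2)(c), b-ph-b
})

test_that("reassembly reproduces the optimum of the unreduced solve", {
  for (i in 1:100) {
    rs <- rand_rs(mmin = 5, mmax = 30, smax = 8, seed = 600 + i)
    tr <- decompose(rs)
    sel <- reassemble(tr)
    expect_true(is_valid_selection(rs, sel))
    expect_equal(sel$total_length,
                 solve_dp(rs)$total_length,
                 info = sprintf("instance %d", i))
  }
})

test_that("disjoint-alphabet concatenation is additive", {
  for (i in 1:25) {
    a <- rand_rs(mmin = 4, mmax = 15, smax = 4, seed = 700 + i)
    btok <- lrsolve:::with_seed(800 + i, {
      sample(LETTERS[1:3], sample(4:15, 1), replace = TRUE)
    })
    b <- compress_runs(btok)
    ab <- compress_runs(c(expand_runs(a), expand_runs(b)))
    expect_equal(solve_lrs(ab)$optimum,
                 solve_lrs(a)$optimum + solve_lrs(b)$optimum)
  }
})

test_that("an infix can be replaced by a placeholder of its optimum length", {
  for (i in 1:25) {
    s <- rand_rs(mmin = 4, mmax = 12, smax = 4, seed = 900 + i)
    t_tok <- lrsolve:::with_seed(950 + i, {
      sample(c("X", "Y", "Z"), sample(4:12, 1), replace = TRUE)
    })
    stok <- expand_runs(s)
    cut <- lrsolve:::with_seed(980 + i, sample(0:length(stok), 1))
    spliced <- compress_runs(c(stok[seq_len(cut)], t_tok,
                               stok[setdiff(seq_along(stok), seq_len(cut))]))
    lrs_t <- solve_lrs(compress_runs(t_tok))$optimum
    with_ph <- compress_runs(c(stok[seq_len(cut)], rep(".dollar", lrs_t),
                               stok[setdiff(seq_along(stok), seq_len(cut))]))
    expect_equal(solve_lrs(spliced)$optimum, solve_lrs(with_ph)$optimum)
  }
})

test_that("reassemble validates overriding leaf solutions", {
  rs <- compress_runs(c("a", "a", "b", "c", "c", "b", "d"))
  tr <- decompose(rs)
  lv <- tree_leaves(tr)
  sols <- vector("list", length(lv))
  for (l in lv) sols[[l$leaf_id]] <- l$solution
  expect_equal(reassemble(tr, sols)$total_length, reassemble(tr)$total_length)
  # a sub-optimal override contradicts the recorded placeholder lengths
  small <- lv[[which.max(vapply(lv, function(l) n_runs(l$rs), integer(1)))]]
  sols[[small$leaf_id]] <- selection(small$rs, integer())
  expect_error(reassemble(tr, sols), "does not match")
})
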