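---
title: "Exact longest-run-subsequence solving and contig ordering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact longest-run-subsequence solving and contig ordering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrsolve)
```

## The problem

In homology-based scaffolding, the contigs of one assembly (set A) are cut
into fixed-size bins and every bin is matched against a second assembly
(set B). A contig of A then reads as a string over the alphabet of
B-contig names, and its most plausible partition into B-segments is a
longest subsequence that contains **at most one maximal run per symbol**.
Each kept run is a segment attributed to one B-contig; the dropped
characters are bins in conflict with the inferred order. We call the
underlying string problem the longest run subsequence problem (LRS). It is
NP-hard (see the hardness harness below), but realistic instances can be
solved to proven optimality quickly.

Formally: for a string $S = s_1 \ldots s_m$ over a finite alphabet
$\Sigma$, find a longest subsequence $S'$ such that for all positions
$i < j$ of $S'$, $s'_i = s'_j$ implies $s'_l = s'_i$ for all $i < l < j$.
Because extending a partially taken run never hurts, an optimal solution
always takes or drops whole runs. All machinery in this package therefore
works on the run-length view (`compress_runs()` / `run_string`): $n$
maximal runs $r_1 \ldots r_n$ with symbols $\sigma(r_i)$ and lengths
$L(r_i)$, $\sum_i L(r_i) = m$.

```{r}
rs <- compress_runs(rep(c("b1", "b4", "b1", "b3", "b1", "b3", "b2", "b3"),
                        times = c(2, 3, 3, 3, 1, 1, 3, 1)))
rs
solve_lrs(rs)
```

## Reduction rules

Two safe (optimum-preserving) rules shrink instances before any solver
runs; both rest on alphabet disjointness.

* **Prefix rule.** If a proper prefix of runs uses symbols that never occur
  afterwards, the two parts are independent and their optima add. The scan
  keeps the furthest last-occurrence index of every symbol seen and closes
  when the scan position passes it; applied iteratively it cuts the string
  into maximal independent pieces in linear time.
* **Infix rule.** An interior block whose symbols occur nowhere else
  contributes either nothing or its own optimum to any solution, so it can
  be replaced by a single placeholder run of length equal to its optimum.
  Infixes are grown from each symbol's first/last occurrence, expanded
  until closed, merged when overlapping or adjacent, and discarded when
  they cover a single run (no reduction) or everything.

`decompose()` applies the prefix rule to exhaustion, then the infix rule on
each piece, recursing into infixes (starting again with the prefix rule)
and into the placeholder-reduced outer string. Because placeholder lengths
are child optima, decomposition is interleaved with solving; the resulting
tree records exactly where each child solution must be re-injected, and
`reassemble()` maps everything back to the original run indices.

Two details are deliberate choices where the rules' published description
leaves room:

* Overlapping or nested infix intervals found from different anchors are
  unioned before adjacency merging. The union of alphabet-closed intervals
  is closed, so this is the conservative completion that keeps the returned
  intervals disjoint.
* Placeholder symbols come from a reserved namespace (`.ph1`, `.ph2`, ...)
  and are re-suffixed on collision, guaranteeing they never clash with
  input tokens (contig names are arbitrary strings here, not single
  characters).

Recursion depth is bounded by the run count since every split makes strict
progress; R's own evaluation-depth error is the backstop for adversarial
inputs rather than an explicit cap.

## The two exact solvers

**Subset dynamic program** (`solve_dp()`). $D[i, F]$ is the best length of
a valid run subsequence of $r_1 \ldots r_i$ ending with $r_i$ selected and
using exactly the symbol set $F$. Candidate predecessors of run $i$ are the
last occurrences $P_\sigma(i)$ of every symbol at or after
$P_{\sigma(r_i)}(i)$, plus a virtual start when run $i$ is the first of its
symbol — skipping further back past a same-symbol run can never help. A
same-symbol predecessor extends the current run ($F$ unchanged); a
different symbol opens a new run ($F$ gains $\sigma(r_i)$). Work is
$O(|\Sigma|\, n\, 2^{|\Sigma|})$: fixed-parameter tractable in the alphabet
size, linear in the run count, and memory-bound as the alphabet grows. The
compiled core uses a dense flat table when
$(n+1)\,2^{|\Sigma|}$ entries fit a 1.5 GB guard and otherwise sparse
per-column hash maps holding only reachable states; both produce identical
tables. Values are exact integers; absent states are a sentinel, not a
float infinity. The default alphabet cap is 25 symbols, above which the
solver refuses and callers should use the ILP.

**Integer linear program** (`solve_ilp()`). One binary $x_i$ per run,
maximizing $\sum_i x_i L(r_i)$. For every same-symbol pair $i < j$, either
the pairwise family $x_l \le 2 - x_i - x_j$ (one constraint per
different-symbol run between them) or the default aggregated family
$\sum_l x_l \le (j-i)(2 - x_i - x_j)$ (one constraint per pair; at most
$\lceil n/2 \rceil^2$ of them). Both families have the same 0/1 solutions;
tests verify their optima coincide and that feasibility of an assignment is
exactly validity of the decoded selection. The backend is a contract — any
function that takes the model and reports a proven optimum — with a
built-in exact depth-first branch-and-bound (compiled, 1-branch first,
incremental row feasibility, objective-sum bound) as the default. A node
budget turns an overlong search into an explicit "no proven optimum" error;
an incumbent is never returned silently, and LP-relaxation values are never
reported as results.

**Brute force** (`solve_bruteforce()`). Full $2^n$ subset enumeration,
sharing the single validity-check code path, capped at 22 runs. It exists
to be the independent referee: the suite's central property is brute force
= DP = ILP on hundreds of random instances.

**Dispatch** (`choose_algorithm()`). The two solvers have complementary
scaling, so `solve_lrs()` in auto mode prefers the ILP iff
$m < 10\,(|\Sigma| - 13)$ and the DP otherwise, evaluated per reduced leaf
(leaves are what solvers actually see). The constants are empirical
defaults and configurable; the size measure defaults to the expanded
length $m$, with run count available as an alternative since the published
rule's $|s|$ admits either reading. Instances in which every symbol occurs
exactly once (the common case after strong reduction) shortcut past both
solvers. Deterministic tie-breaks everywhere — smallest predecessor index,
then smallest run index and smallest symbol-set key in the DP; first-found
optimum in the fixed branching order of the branch-and-bound; smallest
index set in the oracle — make co-optimal answers reproducible.

## The hardness harness

`lop_to_lrs()` embeds the linear ordering problem (LOP): given a complete
weighted digraph, order the vertices to maximize the weight of forward
edges. The constructed string has one block per vertex separated by
separator runs of length $M$; each ordered pair $(i,j)$ contributes an edge
block — two runs of the pair's shared edge sign, each of length
$w_{ij} + w_{\mathrm{sum}}$, padding one triangle-sign run of length $M'$
per third vertex. With $M' = 4 n^2 w_{\mathrm{sum}}$ and $M = M' n^3$,
every optimal solution must take all separators and one run per triangle
sign, leaving exactly the choice of which of the two blocks supplies each
edge sign — i.e., an orientation of every vertex pair whose triangles are
acyclic, hence a linear order. The optimum therefore equals
$f_G(k^\*) = (n-1)M + \tfrac{n(n-1)(n-2)}{3} M' + n(n-1)\,w_{\mathrm{sum}}
+ 2k^\*$ with $k^\*$ the LOP optimum, which the tests verify on random
digraphs against an exhaustive $n!$ LOP solver. Triangle signs are
canonicalized by the lexicographically smallest rotation; instances are
kept in run-length form only (the run lengths are huge by design), and the
harness solves them with the DP — for $n = 4$ the occurring alphabet has
$3 + 6 + 8 = 17$ symbols, comfortably inside the dense-table guard.

```{r}
g <- complete_digraph(matrix(1, 3, 3))
h <- lop_to_lrs(g)
c(M = h$M, M_prime = h$M_prime,
  f_at_optimum = f_g(solve_lop_bruteforce(g)$weight, g))
```

## Synthetic data

`random_instance(m, s, seed)` draws tokens i.i.d. uniformly and redraws the
whole string until all `s` symbols occur. Whole-string rejection (rather
than forced placement) keeps the conditional distribution exactly uniform
over full-alphabet strings at the cost of failing loudly (after 1000
tries) when `m` is barely above `s` — near `m = s` only near-permutations
qualify and rejection is hopeless, which the tests respect by keeping the
alphabet at most half the length. These strings are worst cases for the
reduction rules: no locality, so splits are rare.

`planted_instance()` emulates what real binned contigs look like — already
ordered segments plus scattered noise: segments of distinct symbols with
Poisson-distributed lengths (truncated at 1) around `mean_run_length`,
concatenated in a known order, then per-position substitution with
probability `noise_rate`. Tests use 5 segments of mean length 50 at 5%
noise, a regime where substitutions form short interior runs that merge
around, and recovery of the planted order is expected in at least 95% of
seeds. What these generators do **not** model: repeat-induced ambiguous
best matches, inversions spanning contig boundaries, coverage gaps
correlated along a contig, and segmental duplications — so green tests
here say the solver and adapter are correct, not that real assemblies are
this easy.

## The scaffolding adapter

`read_alignments()` parses the 12 mandatory PAF columns.
`assign_bins()` cuts each A-contig into bins (default 10 kb — small enough
to preserve ordering signal, large enough to keep instances tractable;
coordinates 0-based half-open, the final short bin kept), sums the aligned
query bases of every B-contig overlapping a bin with both strands pooled
(inversions confined to one contig do not affect contig order), and
assigns the argmax, with ties to more aligned bases and then the
lexicographically smaller contig id. `order_contigs()` solves LRS on the
assigned-bin string; the run order of the solution is the B-contig order
and the dropped bins are the conflicts.

Unassigned bins are **omitted** from the string rather than given unique
gap symbols: a unique symbol would always be selectable, never constrain
the order, and only inflate the instance. This is a documented choice —
published descriptions of the pipeline do not specify the treatment of
unaligned or ambiguous bins. Merging the per-A-contig orders into global
pseudo-chromosomes (orientation assignment, multi-contig path merging) is
out of scope here.

## Sizes, tolerances, degenerate inputs

All objective arithmetic is integer-exact; the only float tolerance in the
package is the $10^{-9}$ slack in branch-and-bound row checks and the 0.5
decoding threshold for binary variables. Empty instances are legal
everywhere with optimum 0. The test suite works at sizes where the
brute-force referee is instant (strings up to ~30 tokens, alphabets up to
8, hundreds of seeded replicates; hardness digraphs with $n \in \{3,4\}$;
planted recovery over 100 seeds), which keeps the default run under half a
minute while every property is still checked against an independent
oracle.
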