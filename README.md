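# lrsolve

Exact solvers for the **longest run subsequence** (LRS) problem, with a
contig-ordering adapter for homology-based genome scaffolding.

## The problem

When two incomplete assemblies of related samples are aligned against each
other, each contig of assembly A can be cut into fixed-size bins and every
bin assigned to its best-matching contig of assembly B. The contig then
reads as a string over B-contig names, and the cleanest partition of it
into B-segments is a longest subsequence containing **at most one maximal
run per symbol**: each kept run is a segment attributed to one B-contig,
the dropped characters are bins in conflict with the inferred order, and
the run order is the inferred order of the B-contigs.

Formally, for a string $S = s_1 \ldots s_m$ over a finite alphabet
$\Sigma$, find a longest subsequence $S'$ such that for all $i < j$,
$s'_i = s'_j \Rightarrow s'_l = s'_i$ for all $i < l < j$. The problem is
NP-hard; the package ships the reduction from the linear ordering problem
as a self-verifying test harness.

`lrsolve` provides:

* a run-length instance model (`compress_runs`, `run_string`, selections
  and validity checking);
* provably safe prefix/infix reduction rules with decomposition and
  reassembly (`split_prefix`, `find_independent_infixes`, `decompose`,
  `reassemble`);
* an exact subset dynamic program, fixed-parameter tractable in
  $|\Sigma|$ (`solve_dp`), and an exact 0/1 integer linear program with a
  built-in branch-and-bound backend (`build_ilp`, `solve_ilp`);
* a brute-force reference solver (`solve_bruteforce`) and a hybrid
  dispatcher (`solve_lrs`, `choose_algorithm`) that prefers the ILP iff
  $m < 10(|\Sigma| - 13)$;
* the NP-hardness construction (`complete_digraph`, `lop_to_lrs`, `f_g`,
  `solve_lop_bruteforce`);
* synthetic generators (`random_instance`, `planted_instance`) and the
  scaffolding adapter (`read_alignments` for PAF, `assign_bins`,
  `order_contigs`).

## Worked example

A contig whose 17 bins map to four B-contigs:

```r
library(lrsolve)
bins <- rep(c("b1","b4","b1","b3","b1","b3","b2","b3"),
            times = c(2, 3, 3, 3, 1, 1, 3, 1))
rs <- compress_runs(bins)
rs
#> <run_string> 8 runs, 17 tokens, alphabet size 4
#>   b1^2 b4^3 b1^3 b3^3 b1^1 b3^1 b2^3 b3^1

solve_lrs(rs)
#> <lrs_result> optimum 13 of 17 tokens; 5 of 8 runs selected
#>   leaves: dp x1
#>   dropped runs: 1 5 8
```

The optimum keeps runs 2, 3, 4, 6, 7 — the subsequence
`b4^3 b1^3 b3^(3+1) b2^3` of length 13, in which the two selected `b3`
runs merge across the dropped run 5. Four bins (runs 1, 5, 8) conflict
with the inferred contig order `b4, b1, b3, b2`. The last-occurrence index
function behind the dynamic program gives, on this instance,
`last_occurrence(rs, "b1", 4) == 3`, `last_occurrence(rs, "b1", 3) == 1`
and `last_occurrence(rs, "b4", 1) == 0`.

The same instance viewed as bin assignments:

```r
ba <- data.frame(a_contig = "A1", bin = 0:16, b_contig = bins, bases = 1000)
attr(ba, "bin_size") <- 10000; class(ba) <- c("bin_assignment", class(ba))
order_contigs(ba)[["A1"]]
#> <contig_order> A1: b4 -> b1 -> b3 -> b2 (13/17 bins in order, 4 conflicting)
```

A thin command-line front end is installed with the package:

```sh
lrs=$(Rscript -e 'cat(system.file("cli", "lrs", package = "lrsolve"))')
Rscript "$lrs" solve instances.txt          # one JSON object per instance
Rscript "$lrs" scaffold --paf aln.paf       # per-contig orders from PAF
Rscript "$lrs" lop2lrs --random 4 --seed 7  # a hardness instance
```

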