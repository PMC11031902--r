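---
title: "Methods: learning Boolean functional networks from noisy labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: learning Boolean functional networks from noisy labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisecut)
```

## The model

`noisecut` fits a two-layer tree **functional network** (FN) to binary
data. The network has `M` first-layer boxes; box `m` owns a block of
`n_m` of the `N` binary features (blocks are disjoint and consecutive in
feature order: the first `n_1` columns feed box 1, and so on). Each box
is a Boolean lookup table: its input block is converted to a decimal
code

\[ \mathrm{Decimal}(b) = 1 + \sum_{i=1}^{n} 2^{\,i-1} b_i \in \{1, \dots, 2^n\}, \]

and the table maps codes to bits. The single second-layer output box
maps the code of the `M` first-layer bits to the label. Three modelling
assumptions follow directly: features are binary; the grouping of
features into boxes (`n_input_each_box`, the only hyperparameter) is
correct prior knowledge; and boxes share no features (the "tree"
property — this is what makes box-wise identification exact, see below).

A deliberate convention used everywhere, including serialization: the
*first* element of a bit block is the least-significant bit, and codes
are 1-based. Truth tables are stored in code order, so table entry `k`
answers the input `decimal_decode(k, n)`.

## Conflict graphs

Fix a training set and a box `m`. For two samples whose codes agree in
*every other* box, the rest of the network contributes identically, so
if their labels differ, the box functions of a consistent network must
differ on the two box-`m` codes. `conflict_graphs()` counts exactly
these witnesses: every unordered, label-discordant sample pair whose
codes differ in exactly one box adds one unit of weight to the edge
between its two codes in that box's graph. Three boundary cases are
resolved as follows:

* Pairs differing in **zero** boxes (identical features, contradictory
  labels — possible after noise injection) are ignored; they constrain
  nothing and would otherwise be self-loops.
* Pairs differing in **two or more** boxes are ignored; either box could
  explain the disagreement, so they are evidence for neither.
* Edges are undirected: weights accumulate symmetrically, and all
  matrices satisfy `W == t(W)`, `diag(W) == 0`.

The implementation groups rows by the joint code of the *other* boxes
(the shared context) and accumulates one small cross-product per
context; the test suite verifies it against a literal scan over all
`choose(S, 2)` pairs.

## Exact max-cut

With noise-free, fully covering data the conflict graph of a box is
bipartite between the codes mapped to 0 and those mapped to 1, so *any*
partition separating all edges recovers the box function up to
orientation. Label noise adds spurious edges, typically of low weight —
each needs a mislabelled sample in a specific context. The fitted box
function is therefore the partition maximising the total weight of
separated pairs, i.e. the **max-cut** of the conflict graph: it honours
the strongly supported separations and sacrifices the weak ones, which
is the method's noise filter.

The solver contract is *provable optimality* — a cut without an
optimality proof is never returned (the solver raises when its time
budget expires instead). `solve_maxcut()` is a depth-first
branch-and-bound on the vertex-assignment formulation, with vertex 1
pinned to side 0 (the two orientations of a cut are equivalent, so this
is free symmetry breaking and makes output deterministic). Three
admissible upper bounds prune the search:

1. **Residual mass** — current cut, plus each free vertex's better side
   among its weights to the two fixed sides, plus all free–free weight.
   Near-exact on the sparse, nearly bipartite graphs of low-noise data.
2. **Triangle packing** — a greedy edge-disjoint triangle packing is
   computed once per solve; any bipartition leaves at least one edge of
   each triangle uncut, so every packed triangle with all vertices free
   forfeits at least its minimum edge weight from bound 1. This is what
   first makes dense graphs tractable.
3. **Spectral bound** — for the subproblem on the free vertices plus a
   virtual vertex standing for the fixed side-0 set, the maximum cut is
   bounded by \( \tfrac{k}{4}\,\lambda_{\max}(L + \mathrm{diag}(\mu)) \)
   for any correcting vector \(\mu\) with \(\sum_i \mu_i = 0\), where `L`
   is the (signed) Laplacian. The bound is tightened by projected
   subgradient steps on \(\mu\) with a Polyak step toward the pruning
   level; \(\mu\) is optimised hard once at the root and inherited down
   the search, so deeper nodes only refine it. Only the largest
   eigenpair is needed per step (computed with LAPACK's `dsyevr`).

Since conflict-graph weights are integers, every bound is floored, and a
subtree is abandoned unless it can beat the incumbent by at least 1.
The incumbent comes from deterministic multi-start local search before
the search begins. All of this is deterministic for a fixed input.

Tie-breaking: with `lex = TRUE` (the default) the returned assignment is
the lexicographically smallest optimal one, established by a greedy
sequence of per-vertex decision solves after the optimum value is known.
The fitting routine calls the solver with `lex = FALSE`: it only needs
the fixed orientation (vertex 1, the all-zeros input code, on side 0),
and `n` extra decision solves per box would dominate runtime on the
hardest graphs without changing any prediction, because first-layer
orientation is absorbed by the output box.

Graphs here have at most `2^6 = 64` vertices (box inputs are capped at
6 in the benchmark). At heavy label noise those graphs are dense with
near-uniform weights — the genuinely hard regime for exact max-cut — and
a 64-vertex solve can take tens of seconds; everything smaller, or less
noisy, solves in milliseconds.

## Output box, orientation, and degenerate cells

Every training row is routed through the learned first layer to an
output-box code; the code's label is the majority of the training labels
that arrive there. Two policies cover what majority voting leaves open:

* **Unseen or tied cells** default to the global majority training class
  (ties there fall to 0) — the minimal-risk constant.
* **Isolated vertices** of a conflict graph (codes never witnessed
  against anything) take the solver's deterministic side; the output box
  can still correct any systematic effect of that choice.

`predict(type = "prob")` returns the vote fraction
`votes1 / (votes0 + votes1)` at the routed cell, with the training
prevalence `prior_1` as the fallback for unseen cells. These scores
exist to give the classifier a ranking for ROC analysis, which a pure
hard-label method lacks; the sweep harness also reports the hard-label
operating-point AUC `(TPR + TNR) / 2` (`auc_hard`) so both conventions
are available. Hard-label metrics are unaffected by this choice.
Thresholding the scores at 0.5 (ties resolved by the default-label
policy) reproduces `predict(type = "class")`.

## Noise injection and splitting

`flip_labels()` flips the labels of exactly `floor(q * S + 0.5)`
distinct, uniformly chosen rows — deterministic half-up rounding of "a
fraction `q` of the samples". Corruption is applied to the **whole
dataset before splitting**, and test metrics are computed against the
possibly-noisy test labels. That ordering mirrors a measurement process
that corrupts labels at the source, and it gives test accuracy a natural
ceiling of about `1 - q` for a perfectly recovered function — the
benchmark numbers track that ceiling closely, which is also the
behaviour reported for this family of benchmarks. The split itself is a
plain uniform partition (no stratification), with
`floor(train_fraction * S + 0.5)` training rows.

## The synthetic benchmark generator

`make_benchmark_suite()` generates random two-layer tree networks and
their labelled datasets:

* **Structures**: per-box input counts are drawn uniformly over the
  compositions of the input dimension `d` with parts in `[2, 6]`
  (rejection from uniform parts). The benchmark uses 3 boxes and
  `d = 8..12`, six structures per dimension — 30 datasets.
* **Truth tables**: every entry is an independent Bernoulli(0.5) draw —
  the minimal-assumption reading of "randomly assigned" functions.
* **Class balance**: a candidate network is accepted only if the class-1
  fraction of its fully enumerated labels lies in `[0.1875, 0.8125]`;
  otherwise all tables are redrawn from the same stream (up to
  `max_retries`). This yields a mix of balanced and imbalanced datasets
  with exact dyadic class ratios.
* **Datasets are full enumerations** of `{0,1}^d`, in code order.
  Full enumeration is the package's reading of the benchmark design:
  reported class ratios are exact dyadic fractions such as 0.1875, and
  perfect test accuracy after a 70 % split without noise requires the
  test rows' contexts to be covered by training rows, which dense
  coverage provides. Sampling proper subsets of the input space is out
  of scope.

What the generator does *not* emulate about real data: feature noise
(only labels are corrupted), wrong or partial prior knowledge (the
fitted grouping always matches the generating one), non-tree structure
(shared features between boxes), and non-binary measurements. Passing
benchmarks therefore demonstrate noise tolerance *given correct
structural prior knowledge*, nothing more.

Every stochastic step takes an explicit seed; suite generation and the
sweep derive per-task child seeds from the master seed with a fixed
modular mixing scheme (`derive_seed()`), so a sweep is reproducible row
by row, and each repeat draws a fresh noise realization *and* a fresh
split.

## Metrics

Positive class is label 1. Recall, precision and F1 return 0 with a
`degenerate` flag when a denominator vanishes. Score-based AUC is the
Mann–Whitney rank statistic with half-credit for ties; without scores
the single-operating-point value `(TPR + TNR) / 2` is used. Table-style
aggregation reports the sample median with a seeded bootstrap percentile
confidence interval (default 2000 resamples); the percentile bootstrap
is the package's choice for a distribution-free CI on a median of a
small number of runs.

## Problem sizes and numerical choices

The test suite and the acceptance script run a reduced benchmark —
dimensions 8–10, two structures per dimension, three repeats, noise
levels `{0, 2.5, 5, 7.5, 10, 50} %` — chosen so the whole suite fits
comfortably in a routine CI run while keeping every qualitative feature
of the full 30-dataset, five-repeat benchmark (which remains a single
`make_benchmark_suite()` + `run_noise_sweep()` call). Degenerate inputs
are handled explicitly: empty training data, one-sample training sets
(a constant predictor), all-zero conflict graphs (the solver returns the
all-zeros assignment), and enumeration requests beyond `2^24` rows
(refused). Solver tolerances: integer bound flooring uses an absolute
epsilon of `1e-6`; weight matrices are validated for symmetry,
nonnegativity and zero diagonal on entry.

## Known limitations

* Boxes above ~6 inputs make the conflict graph exponentially larger
  and the exact solves rapidly harder; the design target is the 2–6
  input range.
* At very high noise the conflict graphs are dense with nearly uniform
  weights; a 64-vertex solve can take tens of seconds, and the solver
  will raise rather than silently degrade if its time budget is too
  small for such an instance.
* The method stands or falls with the prior feature grouping; a wrong
  grouping is not detected, it just fits worse.
* Continuous or categorical features require external binarization
  (e.g. one-hot encoding or binning) before use.
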