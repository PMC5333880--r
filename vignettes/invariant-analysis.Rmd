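---
title: "Qualitative Petri net analysis: invariants, MCT sets, t-clusters and knockouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative Petri net analysis: invariants, MCT sets, t-clusters and knockouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrinv)
```

## The model class

`petrinv` analyses discrete, qualitative Petri nets: bipartite directed graphs
whose two vertex classes are *places* (passive components — compounds,
states) and *transitions* (active components — elementary processes), with
positive integer arc weights and a token *marking* as system state. A
transition is enabled when every pre-place holds at least the connecting arc
weight in tokens; firing moves tokens from pre- to post-places. No rates,
delays or concentrations are represented — the analysis is purely structural
and token-game based, which is exactly the setting in which invariant
analysis is informative about a biochemical network's wiring.

The algebra runs through the incidence matrix $A \in \mathbb{Z}^{n \times m}$
($n$ places, $m$ transitions), $a_{ij}$ being the net token change of place
$i$ when transition $j$ fires.

## Minimal invariants

A **t-invariant** is $x \in \mathbb{N}^m$, $x \neq 0$, with $A x = 0$: firing
each transition $x_j$ times reproduces any marking, so the *support*
$\{t_j : x_j > 0\}$ is a self-contained subprocess. A **p-invariant** is
$y \in \mathbb{N}^n$ with $A^{\mathsf T} y = 0$: a weighted token conservation
law. Only support-minimal, gcd-normalised invariants are computed — every
other invariant is a non-negative combination of them.

`minimal_t_invariants()` implements the classical Fourier–Motzkin/Farkas
tableau $[A^{\mathsf T} \mid I]$: place rows are eliminated one at a time by
forming all non-negative combinations of opposite-sign row pairs. Numerical
choices:

* **Exact integer arithmetic** in doubles, with a hard guard that aborts if
  any tableau entry reaches $2^{52}$ (never approached at the model scales
  targeted here). Every returned vector is re-verified against $A$ before
  return; a failure is an internal error, not a warning.
* **Support pruning at every elimination step**: rows whose support strictly
  contains another row's support can never contribute a minimal invariant,
  and removing them is what keeps the tableau from exploding on nets of this
  class.
* **`limit`** (default 100,000 tableau rows) turns combinatorial blow-up into
  a structured `petrinv_limit_error` carrying the row count reached — never a
  silently truncated result.
* **Canonical order**: invariants are sorted by support size, then
  lexicographically by support, so fixture comparisons and file diffs are
  stable.

Completeness is tested against an independent bounded-exhaustive oracle
(enumeration of all coefficient vectors with entries $\le 6$ on random
4-place/6-transition nets), soundness by direct multiplication, and the
t/p duality by transposition.

Feasibility of t-invariants is reported as *preconditions only*
(`feasibility_preconditions()`): a pure net (no read arcs) whose minimal
p-invariant set is empty cannot starve any t-invariant, so all of them may be
treated as realisable. No reachability analysis is attempted; that is out of
scope by design.

## MCT sets

Transitions occurring in exactly the same invariant supports form one
*maximal common transition* (MCT) set — the smallest functional unit of the
model: no member can act without the rest. `compute_mct_sets()` groups
identical nonzero columns of the binary support matrix (hash-style grouping
on column patterns, with an $O(m^2)$ pairwise comparison kept as a test
oracle). Canonical naming `m1, m2, ...` goes to non-trivial sets ordered by
decreasing size, ties broken by first member. An MCT set may induce a
disconnected subnet; `mct_subnet_connected()` reports this (on the undirected
sense, places taken per set independently) but no further ADT-style
decomposition is performed — for the angiogenesis model that decomposition
was explicitly judged uninformative, and this package follows that choice.

## Clustering t-invariants

`distance_matrix()` offers the eight metrics used in the original grid
search: binary (Jaccard), Canberra, Pearson correlation ($1-r$), uncentered
correlation ($1-\cos$), Euclidean, Manhattan, maximum, Minkowski (default
exponent 2, configurable). Clustering operates on **binary support vectors**:
the published invariant table communicates supports only, and for an ordinary
net of this kind the coefficient structure adds little; coefficient matrices
are accepted wherever a support matrix is.

Notes on corners:

* Canberra is the plain sum $\sum |x_i-y_i|/(|x_i|+|y_i|)$ with $0/0$
  coordinates skipped — `stats::dist` additionally rescales by the number of
  used coordinates, which is not wanted here.
* A constant row has no defined Pearson correlation; its distance is defined
  as 0 to an identical row and 1 to anything else, with a warning. This keeps
  grid evaluation running on degenerate synthetic inputs instead of crashing.

`agglomerate()` delegates to `stats::hclust` — the same agglomeration the
original analysis ran through R — accepting `upgma` as the conventional alias
for average linkage. Centroid and median linkage are computed on squared
distances (their geometric definition) with heights mapped back to the
distance scale; these two may show inversions, the other five linkages are
monotone. Single and complete linkage are cross-checked in the tests against
a definition-level oracle that recomputes every cluster distance from the
original matrix.

**Cluster-quality score.** The evaluation index is implemented as the mean of
classical top-level silhouette widths,
$s(i) = (b_i - a_i)/\max(a_i, b_i)$, with elements of singleton clusters
contributing 0; per-cluster values are member means and the global value is
the element mean (equal to the member-weighted mean of per-cluster values —
an identity the tests assert exactly). This is deliberately an approximation
of the Mean Split Silhouette of the cluster-number literature: the published
per-cluster table assigns 0.00 to singletons and nonzero values to 2-element
clusters, which matches top-level silhouettes rather than a recursive
split-based index, and the published global value is close to the
element-weighted mean of its per-cluster values. Values are kept at full
precision internally; rounding (2 decimals per cluster, 4 global) happens
only in reports.

### What reproduces and what does not

With the packaged 48 × 74 support matrix, binary + UPGMA cut at 11 clusters
reproduces the published evaluation exactly: cluster sizes
$\{28,4,4,2,2,2,2,1,1,1,1\}$ and a global score of 0.5856. The Pearson
correlation + UPGMA tree cut at 13 gives sizes
$\{10,10,4,4,4,4,4,2,2,1,1,1,1\}$ and a global score of 0.4621, close to but
not equal to the published 0.5088, and its membership agrees with the
published 13-cluster table on 85% of invariant pairs. The published
membership itself scores 0.097 under $1-r$ silhouettes — inconsistent with
the per-cluster values printed next to it — so it cannot be the direct output
of the computation its table describes under any variant tried here
(uncentered cosine, $1-|r|$, square-root transforms, all seven linkages, an
MCT-collapsed input, alternative tie-breaking). The package reports what the
stated procedure actually yields; the corresponding acceptance check is left
failing rather than fitted.

## Knockout analysis

**Structural.** `structural_knockout_table()` ranks knockout units (non-trivial
MCT sets, or single trivial transitions — all members of an MCT set are
equivalent by construction) by the percentage of t-invariants whose support
intersects the unit. Percentages are rounded to 2 decimals at the report
layer. On the packaged matrix this reproduces the published 26-row ranking
exactly, from hypoxia (85.42%) down to vessel remodeling (2.08%).

**Dynamic.** `run_simulation()` plays a stochastic token game: per step, each
enabled non-disabled transition independently *wills* to fire with
probability `firing_probability` (default 0.5). The original tool's
"synchronous-like" conflict semantics are not published, so two defensible
modes are provided and both are exercised by the tests:

* `random-order` (default): willing transitions fire sequentially in
  uniformly random order, enabledness re-checked immediately before each
  firing, production immediately available. Guarantees validity (tokens can
  never go negative) by construction.
* `maximal`: a maximal concurrently-firable subset of the willing set is
  chosen greedily in random order against the step-start marking; production
  is applied at the end of the step — closer to a strict synchronous step.

Defaults are the published protocol — 10,000 steps × 4,000 repetitions from
the file's initial marking — while tests and examples run hundreds of steps ×
tens of repetitions on toy nets, which is ample for the Bernoulli-mean,
starvation, conservation and reproducibility properties they check. The
marking is sampled at the end of every step; the firing-chance denominator is
*total steps*, not steps-while-enabled, matching how the published average
firing chances read. Statuses: `OFFLINE` for manually disabled transitions,
`KNOCKOUT` for never-disabled transitions that fired zero times across all
repetitions, `ACTIVE` otherwise. Each repetition derives its own seed from
the master seed and the repetition index, so results are independent of
execution order and bit-reproducible. `compare_simulation_packages()` builds
the reference/knockout/difference table, labelling non-active transitions
instead of differencing them.

The published per-transition firing chances (e.g. 14.98% for the first
transition in the reference run) require the supplementary Snoopy net file,
whose arc list is not reprinted in the paper; the corresponding end-to-end
checks run automatically as soon as that file is placed at
`inst/extdata/angiogenesis_net.spped`, and fail visibly until then.

## Synthetic data

`generate_covered_net()` builds nets as unions of random directed circuits
sharing places: by construction ordinary, pure, connected and covered by
t-invariants (each circuit is one), which are exactly the structural
properties the downstream analysis assumes. One token is placed on a random
place of each circuit by default so every circuit can run. What it does *not*
emulate: structural conflicts of realistic density, long chains with
source/sink boundary transitions, or weighted arcs — so passing tests on
generated nets validate the algebra and the simulator, not biological
realism. `generate_block_support_matrix()` plants MCT-style column blocks
(optionally noise-flipped) and returns the planted partition for recovery
checks. Generator parameters are test-scale choices (5–9 places, 5–12
transitions, 1–4 circuits), sized so the bounded-exhaustive invariant oracle
is provably complete on the same nets.

## Files and formats

`read_net()`/`write_net()` cover Snoopy SPPED (read-only subset; logical
place copies merged, conflicting markings rejected), ISO PNML basic
place/transition nets, a native JSON dialect, and incidence-matrix CSV (pure
nets only — read arcs cancel in an incidence matrix, so the reader refuses
files flagged as coming from non-pure nets). Support matrices travel as
simple CSV (`invariant,t0,t1,...` header, 0/1 cells). All writers emit
deterministic element order, so fixed inputs give byte-identical outputs.

`run_full_analysis()` sequences the whole workflow (net or support matrix →
invariants → MCT → clustering grid → chosen clustering → structural knockout
→ optional simulations) and writes every artifact plus a manifest. Configs
are YAML — the natural choice in an R stack — mirroring the function
arguments; `inst/scripts/angiopn.R` is a thin command-line wrapper over the
same exported functions.

## Known limitations

* Reachability, liveness and boundedness are out of scope; feasibility is
  reported via preconditions only.
* The invariant engine targets desk-scale nets (tens of places/transitions);
  the row `limit` makes larger inputs fail loudly rather than slowly.
* SPPED writing, hierarchical/coarse Snoopy nodes, graphics and colored or
  timed net classes are not supported.
* The exact conflict semantics of the original (unpublished) simulator are
  unknown; the two provided modes bracket reasonable interpretations, and
  simulation-level reproduction figures should be read with that caveat.
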