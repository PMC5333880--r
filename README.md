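# petrinv

Qualitative analysis of discrete Petri net models of biomolecular networks:
minimal t-/p-invariant computation, MCT-set partitioning, t-invariant
clustering with silhouette-based model selection, and structural plus
simulation-based knockout analysis. Written for systems biologists who model
signaling or metabolic networks as place/transition nets (Snoopy, PNML) and
want the full invariant-based analysis pipeline as reproducible, tested R
code instead of a chain of GUI tools.

## The method

A Petri net is the 5-tuple Q = (P, T, F, W, M0): places P (compounds,
states), transitions T (elementary processes), weighted arcs, and an initial
token marking. Its incidence matrix A ∈ ℤ^(n×m) holds the net token change
a_ij of place p_i when transition t_j fires. The analysis chain is:

1. **Minimal t-invariants** — non-negative integer solutions of A·x = 0 with
   support-minimal, gcd-reduced coefficient vectors, computed by the
   Fourier–Motzkin/Farkas tableau [Aᵀ | I] with support pruning at every
   elimination step, in exact integer arithmetic. Each invariant's support is
   a self-contained subprocess; p-invariants (Aᵀ·y = 0) are token
   conservation laws and double as feasibility preconditions.
2. **MCT sets** — equivalence classes of transitions occurring in exactly the
   same invariant supports: the smallest functional units of the model,
   partitioning the covered transitions.
3. **t-clusters** — hierarchical clustering of the binary invariant×transition
   support matrix over a grid of 8 distance metrics × 7 linkage methods ×
   cluster counts, each clustering scored by singleton count and a mean
   silhouette index (singletons contribute 0).
4. **Knockouts** — structurally, the percentage of invariant supports hit by
   disabling each MCT set or trivial transition; dynamically, a stochastic
   token game (each enabled transition fires with probability 0.5 per step,
   10,000 steps × 4,000 repetitions by default) comparing reference and
   knockout runs, with OFFLINE/KNOCKOUT/ACTIVE statuses per transition.

A published 48-invariant × 74-transition angiogenesis model (HIF-1/VEGF/eNOS/
TGF-β signaling) ships as a packaged fixture, reconstructed from its printed
invariant and MCT tables.

## Worked example

```r
library(petrinv)
fx  <- load_angiogenesis_fixture()       # 48 x 74 binary support matrix
mct <- compute_mct_sets(fx$support)
mct
#> <mct_partition> 26 sets (11 non-trivial), 0 uncovered transitions
#>   m1   {t19, t21, t22, t23, t24, t25, t28, t36, t37, t38, t41, ...}
#>   m2   {t0, t1, t2, t3, t4, t5, t7, t14, t20, t50, t68}
#>   ...
#>   m11  {t60, t61}

head(structural_knockout_table(fx$support, knock_units(mct))[, 1:2], 5)
#>   unit affected_percent
#> 1  t12            85.42
#> 2   m2            79.17
#> 3  m11            66.67
#> 4   m8            66.67
#> 5  t18            66.67

d   <- distance_matrix(fx$support, "binary")
cl  <- cut_dendrogram(agglomerate(d, "upgma"), 11)
mss <- mean_split_silhouette(cl, d)
sprintf("largest cluster: %d of %d invariants; global score %.4f",
        max(table(cl)), length(cl), mss$global)
#> "largest cluster: 28 of 48 invariants; global score 0.5856"
```

Reading: knocking out hypoxia (`t12`) disables 85.42% of the model's
stationary subprocesses — the single most critical activity — followed by the
mitogen-activated kinase signaling unit `m2` (79.17%, identical impact for
each of its 11 transitions). Under Jaccard distance with average linkage, 28
of the 48 subprocesses fall into one dominant cluster, and the clustering as
a whole scores 0.5856.

For a full end-to-end run (invariants → MCT → clustering grid → knockouts,
with artifacts and a manifest written to a directory):

```r
run_full_analysis(list(use_fixture = TRUE, out_dir = "out"))
```

or, from a shell, via the thin wrapper `inst/scripts/angiopn.R`
(`generate`, `convert`, `invariants`, `mct`, `cluster`, `cluster-grid`,
`knockout-structural`, `knockout-sim`, `knockout-compare`, `run`).

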