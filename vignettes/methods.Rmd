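---
title: "Methods: dynamic, TAP-aware protein-complex detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic, TAP-aware protein-complex detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyncomplex)
```

`dyncomplex` detects protein complexes from a protein–protein interaction
(PPI) network in four phases: evidence-fused edge weighting, memetic
biclustering of time-course expression into dynamic subnetworks,
core–attachment detection per subnetwork, and similarity-driven aggregation.
This vignette documents the model, every tunable parameter, the numerical
and design choices that were genuinely open, and what the synthetic
validation does and does not establish.

## Phase 1 — TAP-aware edge weighting

Each PPI edge receives a GO weight and a TAP coefficient.

**GO weight.** For proteins $p_1, p_2$ and each ontology aspect (BP, CC,
MF), the SimGIC similarity is
$$\mathrm{sim}(p_1,p_2) = \frac{\sum_{t \in A_1 \cap A_2} IC(t)}
                               {\sum_{t \in A_1 \cup A_2} IC(t)},$$
where $A_i$ is the ancestral closure (direct annotations plus all `is_a`
ancestors) and $IC(t) = -\ln p(t)$ with $p(t)$ the fraction of corpus
proteins annotated (by closure) to $t$. $W_{GO}$ is the mean of the three
aspect similarities. Choices made here:

* **Only `is_a` edges are traversed.** `part_of` and other relationships are
  ignored; this is the simplest well-defined closure and the one the tests
  oracle against.
* **Missing aspects.** The three-aspect average presumes annotations in all
  aspects. When either protein lacks annotation in an aspect, that aspect is
  excluded from the mean; if no aspect is shared, $W_{GO}=0$. This avoids
  arbitrarily penalizing sparsely annotated proteins while keeping the
  weight defined on every edge.
* **IC log base.** Natural log. Any fixed base cancels in the SimGIC ratio;
  a property test asserts that rescaling the IC vector leaves pair weights
  unchanged.
* A degenerate pair whose union carries only zero-IC terms (e.g. roots)
  scores 0, not 0/0.

**TAP coefficient.** Raw purification scores from the two experiments (LCMS,
MALDI) are min–max normalized per source — the simplest faithful reading of
"normalized between 0 and 1"; rank-preserving, and degenerate tables (all
scores equal) map to 1. $W_{TAP}$ is the mean of the two normalized scores,
the available one if only one source covers the pair, and $0.5$ if neither
does. The edge weight is
$$W = \alpha \cdot W_{GO}, \qquad \alpha = 1 + (W_{TAP} - 0.5)\,\gamma,$$
so $\alpha \in [1-\gamma/2,\, 1+\gamma/2]$ and TAP-missing edges are exactly
neutral ($W = W_{GO}$). TAP pairs not present in the PPI network are
discarded: TAP modulates existing interactions, it does not create them.

*Parameters:* $\gamma \in [0,1]$ (TAP impact; presets 0.3/0.4 for the
sparse/dense network profiles); `tap_enabled = FALSE` gives the GO-only
ablation with $\alpha \equiv 1$.

## Phase 2 — binarization and memetic biclustering

**Binarization.** Per protein (row) $i$ over $n$ time points:
$\mu_i$ = mean, $\sigma_i$ = *population* standard deviation (divide by
$n$), and
$$NGE[i,j] = \mathbf{1}\!\left[GE[i,j] \ge |\mu_i - \sigma_i\,\varepsilon|\right].$$
Equality is active. $\varepsilon \ge 0$ (default 0.6) is the penalty factor:
larger values sparsify the activity matrix. Each row is binarized
independently of all others, and the call is invariant to positive rescaling
of a row (the threshold scales along). An optional per-row min–max
`prescale` step is provided and **off** by default: pure scaling never
changes the calls, but the min–max *shift* can flip the sign inside the
absolute value for rows with $\mu_i < \sigma_i \varepsilon$ and thus alter
calls, so persisting a rescaled matrix is not a no-op in general.

**Encoding and fitness.** A chromosome is a binary vector of length $m+n$
(protein part, then time-point part) decoding to a bicluster $B[I][J]$ with
fitness $F_b = \sum_{i \in I}\sum_{j \in J} NGE[i,j] / (|I|\,|J|)$. An empty
$I$ or $J$ makes the ratio undefined; such chromosomes are valid but
maximally unfit ($F_b = 0$).

**Operators.** Binary tournament (fitter of two uniform draws; ties to the
first drawn); two-point crossover applied with probability 0.9 to the
protein part only (cut positions drawn from the $m+1$ segment boundaries, so
a full protein-part swap is reachable); mutation flips protein bits with
probability 0.001 and time bits with 0.1 (crossover never touches the time
part, hence the higher rate); and a Lamarckian local search.

**Local search.** Deterministic-order hill climbing: bits are scanned left
to right (protein part, then time part), each tested with probability 0.8,
and a flip is kept only if fitness *strictly* increases; sweeps repeat until
one accepts no flip. A single sweep would leave children half-refined, and
under the steady-state replacement below such lineages lose every
tournament to the first fully converged lineage and are culled — in
validation runs only one planted expression module then survived. Running
the climb to a local optimum keeps every lineage competitive and is equally
deterministic under the seed. Incremental bookkeeping of row/column sums
makes each bit test O(1).

**Steady-state loop.** Random initial population (protein bits
Bernoulli(0.5); time bits Bernoulli(0.9), so that early candidates span most
of the time course and the search prunes time points rather than having to
rediscover them); per iteration: select two parents, cross over, mutate,
refine both children, insert them, remove the two worst. The loop stops at
`max_iterations` or when *every* individual reaches `fitness_goal` — the
population-level reading of "individuals get enough fitness"; stopping on
the best individual alone would terminate almost immediately, because any
fully active single time-point column is already a perfect bicluster.

**Returned biclusters.** The final population is sorted by fitness
descending; ties — ubiquitous, since many submatrices are perfectly dense —
are broken by bicluster area $|I|\cdot|J|$ descending (among equally dense
biclusters the larger one carries more subnetwork information), then by bit
string for determinism. Exact duplicates and degenerate chromosomes are
dropped before taking the top `n_biclusters`; if fewer remain, the rest are
returned with a message. One run yields all biclusters (no restarts).

*Parameters:* population 100, iteration budget 2000, `fitness_goal` 0.95,
`n_biclusters` presets 27/30; all configurable. `local_search_enabled =
FALSE` approximates a plain genetic algorithm for the ablation comparison
(a faithful reproduction of other genetic biclusterers is out of scope).

**Dynamic subnetworks.** Each bicluster induces the weighted subgraph on its
proteins (isolated nodes retained; proteins absent from the network are
dropped with a warning).

## Phase 3 — core–attachment detection

The node-level weighted clustering coefficient is
$$wcc(v) = \frac{\sum_{e \in L} W(e)}{|L|\,(|L|-1)},$$
with $L$ the edges incident to $v$ *within the graph under consideration*,
and $wcc(v) = 0$ when $|L| \le 1$ (a degree-one node carries no clustering
evidence; the printed denominator is zero there). The complex-level score
$WCC(C)$ is the mean of $wcc$ over members with $L$ restricted to
intra-complex edges: it rates the complex's own cohesion, not its
environment. Note the denominator decreases the score with degree — in a
unit-weight $k$-clique every node scores $1/(k-2)$ — which shapes the
choices below.

* **Seeds** are proteins whose $wcc$ reaches the `alpha_seed` quantile of
  the *nonzero* $wcc$ distribution, processed in decreasing $wcc$ order
  (ties by protein ID). A quantile, rather than an absolute threshold, makes
  the $[0.1, 0.9]$ tuning range meaningful regardless of the network's
  weight scale. `alpha_seed = 0` seeds every nonzero-wcc protein; lower
  values always yield at least as many seeds (asserted as a sweep).
* **Core growth** starts at the seed and repeatedly adds the neighbour with
  the largest summed edge weight into the core (ties by ID), accepting only
  while $WCC$ does not decrease, stopping at the first rejection. *This
  acceptance rule is a reconstruction*: the original core-growing criterion
  of the core–attachment literature is not restated in the source this
  package follows, so the rule reuses the package's own WCC machinery.
  Because a clique's $WCC$ peaks at the triangle, cores are small dense
  kernels; the attachment step is what completes a complex.
* **Attachments**: a non-core protein joins when its *count* of edges into
  the core, divided by the core size, reaches `beta` — the size
  normalization again makes the $[0.1, 0.9]$ range transferable across core
  sizes. Attachments are judged against the original core, not
  incrementally. Higher `beta` never yields larger complexes from the same
  core.
* **Redundancy filter**: complexes sorted by ($WCC$ desc, size desc, member
  list), kept only if their Jaccard with every kept complex is below 0.8.

Phase 3 is fully deterministic.

## Phase 4 — aggregation

All per-subnetwork complexes are pooled. Sizes below 3 are removed; sizes
3–5 pass straight to the final result; sizes 6+ are categorized greedily
(largest first) into groups whose members are *pairwise* similar at Jaccard
> 0.8 — the pairwise requirement (not similarity to a single
representative) matches the stated post-condition of the categorization.
The source text is contradictory about size 5 (both "below six passes
through" and "five or more is categorized"); the pass-through reading wins
here because it is stated first and unconditionally, and the alternative
would categorize complexes too small to have a meaningful common part.

Per category: (1) the common part (intersection of all members) becomes a
complex and is removed from the members; (2) every residual protein present
in at least half the members is promoted into the common part; (3) each
remaining residue, deduplicated and in lexicographic order, is added to a
*copy* of the common part and emitted only if the candidate's $WCC$ strictly
exceeds the common part's. Candidates do not accumulate, so the emitted set
is order-independent. The $WCC$ guard is computed on the full weighted
network, because a category may merge complexes originating from different
subnetworks — an interpretation, flagged as such. The final set is
deduplicated on exact protein-set equality. `postprocessing_enabled = FALSE`
returns the pooled set minus exact duplicates (the ablation mode).

## Evaluation

Matching against a benchmark catalog is existential and many-to-many, with
no one-to-one assignment: a detected complex is *true* if some benchmark
complex overlaps it at Jaccard $\ge th$, a benchmark complex is *recovered*
if some detected complex does; precision, recall, F-1 follow. The default
$th = 0.25$ is the field's convention. An empty benchmark is an error; an
empty detected set scores precision 0.

## The synthetic generator

`generate_fixture()` plants known structure inside random data so every
stage is testable without downloads. Reference conditions (all overridable
through `fixture_config()`):

* 300 proteins, 12 time points; six planted complexes of sizes
  5, 7, 8, 9, 10, 12, generated as cliques (internal edge probability 1) —
  idealized dense modules; the last two complexes share 2 proteins to
  exercise the aggregation categories; Erdős–Rényi background at edge
  probability 0.02.
* Three planted expression biclusters, each the union of two complexes
  (smallest paired with largest, so each block has 17 proteins) over 4 time
  points assigned periodically — module $b$ peaks at every third time point,
  emulating once-per-cycle activity in a repeated (cell-cycle-like) time
  course. Inside a block, activity probability `p_in = 1`: the planted
  bicluster *is* the fully active block, and degradation is explicit
  (`p_in`, `p_out` knobs) rather than baked in. Background activity is
  stratified: each time point receives the same number (rate
  `p_out = 0.05`) of background activations at randomly drawn off-module
  proteins, so no time point is accidentally favored by sampling noise;
  never-active proteins are allowed and handled by the construction below.
* Expression values are constructed *backwards* from the binary pattern:
  per row, active cells sit at level 1 and inactive cells at a level $l$
  chosen by grid search so the row's own threshold
  $|\mu - \sigma\varepsilon|$ separates the two levels with maximal margin
  (an all-zero row gets a negative $l$, keeping it stably inactive);
  Gaussian noise (sd 0.05) is added and the recovery is verified post hoc
  (`binarize_agreement`, ≈ 1 at the defaults). This isolates biclustering
  tests from binarization subtleties.
* TAP raw scores: co-complex pairs $\mathcal N(5,1)$, background
  $\mathcal N(2,1)$, 30% of edges missing independently per source. Toy GO:
  per aspect one root, five generic terms, one high-IC marker term per
  complex; every protein carries one random generic term per aspect,
  complex members additionally their marker — co-complex pairs thus score
  high SimGIC, unrelated pairs low but nonzero.

**What passing the planted-recovery tests shows — and what it does not.**
The generator produces clean, balanced modules: equal block sizes, perfect
in-block activity, cliques, well-separated GO/TAP signal. Recovery there
demonstrates that the four phases compose correctly and that the search
reliably finds planted optima; it does *not* establish performance on real
yeast data, where complexes are unbalanced and partially observed,
expression modules overlap and drift in time, and annotation depth varies by
orders of magnitude. The degradation test (lowering `p_in` toward `p_out`)
checks the monotone response, not absolute real-data accuracy. A structural
caveat discovered during validation and worth knowing when applying the
method: any fully active single time-point column is a *perfect-fitness*
bicluster of the Eq-8 objective, so the returned list usually contains such
single-column biclusters alongside the real modules; the area tie-break
ranks genuine multi-column modules above them.

## Defaults, problem sizes, determinism

Two parameter presets are published for dense and sparse yeast networks and
exposed as profiles: `biogrid` ($\alpha$ = 0.3, $\beta$ = 0.5, $\gamma$ =
0.4, $\varepsilon$ = 0.6, 30 biclusters) and `dip` (0.55, 0.7, 0.3, 0.6,
27; the package default). `alpha_seed` and `beta` outside $[0.1, 0.9]$ warn
but run.

All randomness flows from a single seed set once at the start of a pipeline
run; phases 1, 3 and 4 are deterministic, so running stages individually
with the same seed reproduces the monolithic run bit for bit (asserted in
the tests). The test suite exercises oracle equivalences on instances up to
50 nodes, search properties on matrices around 30 × 6, and the end-to-end
planted-recovery check on the 300-protein reference bundle with one memetic
run (population 100), which keeps the whole suite under a minute on one
core.

## Known limitations

* The core-growth acceptance rule and the seed/attachment normalizations
  are explicit reconstructions (see Phase 3); other readings of the
  original core–attachment method would change complex boundaries.
* Protein identifiers are matched by exact, case-sensitive string equality;
  reconciling ID namespaces across PPI, TAP, expression and GO inputs is
  the user's input preparation.
* The GO module computes SimGIC only (no Resnik/Lin variants, no
  evidence-code filtering, no `part_of` traversal), and the optional
  local-search refinement step some external GO tools apply after scoring
  is not reproduced.
* Aggregation never merges across categories and never re-scores
  pass-through complexes.
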