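---
title: "CytoBridge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CytoBridge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CytoBridge)
```

## The problem

Mitochondria and the endoplasmic reticulum (ER) are physically and
functionally coupled through mitochondria-associated membranes, and cytosolic
proteins relay signals between the two organelles. When that coupling breaks
down — as is suspected in Parkinson's disease — a natural computational
question is: *which cytosolic proteins sit on the communication routes
between ER and mitochondrial proteins in the interaction network?*

CytoBridge implements this screen end to end on a compartment-labelled
protein-protein interaction (PPI) graph: harmonize organelle catalogs, build
the graph, extract dense complexes, flag complexes enriched for
disease-associated differential expression, select the complex that spans all
three compartments, and rank its cytosolic members by a shortest-path
bridging statistic. A qPCR validation layer (delta-delta-Ct, one-way ANOVA,
Tukey) covers the downstream expression check.

Because the original inputs (localization databases, a STRING-derived
interactome, public microarray series, a patient cohort) are external and
partly irreproducible at desk scale, the package ships a seeded
synthetic-data module that emulates the statistical structure each stage
assumes and carries planted ground truth. All tests and the acceptance script
run offline against that module.

## Stage by stage

### Organelle catalog

`harmonize()` merges raw `(symbol, compartment, source)` tables: aliases are
mapped to canonical symbols (case-sensitively, after mapping), rows with
labels outside the ER / mitochondria / cytosol vocabulary are dropped with a
counted warning, and duplicate symbols merge with the union of compartments
and sources. The operation is idempotent and order-independent.

Multi-localized proteins are kept, but every downstream stage needs one
compartment per node. `assign_primary_compartment()` makes that explicit:

* `source_majority` (default): the compartment supported by the most
  distinct sources wins; ties break by a fixed priority
  (mitochondria > ER > cytosol).
* `priority_order`: the first compartment the protein carries in the
  priority order.

The majority policy is the defensible default where a manual
"localization verification" step is otherwise unspecified; both policies are
configurable and the original multi-labels are retained.

### Interaction graph

`build_graph()` is closed-world: the catalog defines the node universe and
edges with any endpoint outside it are dropped and counted, so the network
has zero external interactions. The graph is undirected and simple. Edge
confidence scores are carried but deliberately ignored downstream — paths are
counted in hops and density is unweighted, matching the hop-style reporting
the screen is built around. Density uses the loopless normalization
$2e / (n(n-1))$ (0 for a single vertex); the k-core is computed by iterative
pruning.

### MCODE-style complex detection

`find_complexes()` is a from-scratch implementation of the classic
three-stage molecular-complex detection algorithm:

1. **Vertex weighting.** For each vertex $v$, take the closed neighborhood
   $N[v]$, drop neighborhood vertices whose within-neighborhood degree is
   below `degree_cutoff`, find the highest $k$-core of what remains, and set
   $w(v) = k_{\max} \cdot \text{density}(k_{\max}\text{-core})$ — the
   core-clustering coefficient scaled by the core number. Isolated or
   too-sparse vertices weigh 0.
2. **Complex growth.** Seeds are processed in decreasing weight; from each
   unvisited seed, breadth-first growth (depth $\le$ `max_depth`) admits a
   neighbor on first encounter iff its weight is at least
   $(1 - \text{vwp}) \cdot w(\text{seed})$. Admitted nodes become globally
   visited, so pre-fluff complexes are disjoint.
3. **Post-processing.** `haircut` prunes singly-connected members
   iteratively (the 2-core of the grown complex; if pruning disconnects it,
   the seed's component is kept). `fluff` adds boundary neighbors whose
   closed-neighborhood density exceeds `fluff_density_threshold`; fluffed
   nodes may overlap between complexes and any overlap is reported, never
   silent.

Complexes are scored density × size and ranked with a *total* order:
score, then size, then lexicographically smallest member; seed ties break by
weight, degree, then name. Totality matters because determinism is part of
the package contract — identical graph and parameters give byte-identical
ranked output, and vertex insertion order is irrelevant.

Defaults are the canonical release values (`degree_cutoff = 2`, `vwp = 0.2`,
`haircut = TRUE`, `fluff = FALSE`, `fluff_density_threshold = 0.1`,
`max_depth = 100`).

A note on the growth threshold: in a planted dense complex the admission
bar is relative to the *best* vertex, so members whose internal degree sits
a couple of standard deviations below the mean can fall under it. The
recovery benchmark (below) therefore typically returns 15–20 of 20 planted
members with essentially no background contamination; this boundary loss is
a property of the algorithm, not of the implementation. Fluff is *not* a
remedy in a noisy background: a degree-1 background neighbor has a trivially
dense closed neighborhood (a single edge has density 1) and would be annexed
wholesale, which is why fluff stays off by default and is enabled only where
the boundary is known to be clean (the packaged reference fixture).

### Cross-study differential expression

`differential_expression()` fits, per gene, the two-group linear-model
contrast equivalent to a pooled-variance two-sample t statistic
(`df = n_case + n_control - 2`, two-sided p). Zero pooled variance is
guarded by an epsilon so exact separation yields a flagged, far-sub-sampling
p-value rather than a division by zero. An optional empirical-Bayes
moderated-t switch (via limma) exists but is off by default — the default
reproduces the plain per-study linear contrast.

Studies are combined per gene by **Fisher's combined-probability method**:

$$X^2 = -2 \sum_{i=1}^{k} \ln p_i \sim \chi^2_{2k} \text{ under the joint null.}$$

"Fisher's test" applied across several case/control datasets is read as this
meta-analytic combination, not as a per-gene exact test; with $k = 1$ the
combination is the identity, and the statistic is permutation-invariant and
monotone. Genes absent from some studies combine over the studies that
measure them (`df = 2 k_\text{available}`). Zero p-values are clamped to a
configurable floor (default `1e-300`) with a warning.

`call_degs()` uses a strict threshold (combined $p < \alpha$), unadjusted by
default to match the screen's stated calling rule; a Benjamini–Hochberg mode
is available. `map_degs_to_clusters()` intersects the DEG set with each
complex and flags complexes reaching `min_hits` as disease ("PD") clusters.
Direction-of-effect concordance across studies is deliberately not enforced.

### Linker scoring

`select_tricompartment_cluster()` picks, among disease clusters containing
at least one member of each compartment, the highest-ranked one and reports
its composition. Within that cluster's induced subgraph (only — the
statistic is local to the selected complex), every cytosolic member $c$ gets
a **bridge length**

$$b(c) = \min_{e \in \text{ER}, \, m \in \text{mito}} d(e, c) + d(c, m)$$

computed from two multi-source BFS sweeps. This min-sum statistic is the
weakest faithful formalization of "the shortest path for cytosolic proteins
connecting the two organelles"; ties are broken by the number of minimal
witness paths through $c$ (more routes = more central), then degree, then
name, making the ranking total. Cytosolic nodes that cannot reach both
organelle sets rank last with infinite length. `extract_witness_paths()`
materializes the minimal ER → c → mitochondria concatenations, keeping only
simple paths, in lexicographic order.

Multi-localized proteins participate through their primary compartment,
consistent with the catalog policy.

### qPCR validation statistics

`delta_delta_ct()`: per sample, $\Delta Ct = Ct_\text{target} -
Ct_\text{reference}$; $\Delta\Delta Ct$ subtracts the *control-group mean*
$\Delta Ct$ (the calibrator), and the fold change is $2^{-\Delta\Delta Ct}$.
A `group_mean` summary variant reports the fold of the group-mean
$\Delta Ct$ instead of the mean of per-sample folds. `one_way_anova()` and
`tukey_hsd()` wrap the standard sum-of-squares decomposition and
studentized-range post-hoc comparisons (Tukey–Kramer under unequal group
sizes); a zero within-group variance with unequal means is reported as
$p = 0$ with a `degenerate` flag rather than a numeric failure.

## The synthetic-data module

The generators are first-class, tested code. What they emulate — and what
they do not — determines what a passing test suite says about real data.

* `generate_catalog()` apportions compartments by largest remainder, so the
  canonical three-way split (243 ER / 1399 mitochondria / 1299 cytosol over
  2941 proteins) is reproduced exactly; a `multilocal_rate` fraction gets a
  second compartment.
* `generate_network()` plants dense complexes (edge probability `p_in`
  within each planted member set) in a sparse background. **Background
  semantics:** background edges with probability `p_bg` are drawn over all
  pairs touching at least one non-complex node; direct complex-to-complex
  pairs stay empty. The planted structures are embedded *in* a background,
  not wired to each other — with equal-weight plants, even a handful of
  direct bridges makes any seed-and-grow algorithm merge them, which would
  say nothing about either the generator or the detector. Real interactomes
  do contain complex-complex cross-talk; recovering complexes in that regime
  is outside what this benchmark claims.
* The optional linker motif injects one cytosolic node attached to two
  mitochondrial nodes, each attached to an ER node, inside the first planted
  complex — the parallel two-intermediate geometry. (Whether the two
  mitochondrial intermediates act in series or in parallel is ambiguous in
  prose; the parallel reading is implemented and gives two minimal
  witnesses.)
* `generate_expression()` works on a log2-like additive scale: per-gene
  baselines $\mu_g \sim N(8, 1.5)$ drawn once, noise $N(0, \sigma)$, and a
  planted mean shift of $\delta$ for DEGs in cases — so $\delta$ *is* the
  log2 fold change. Group sizes are free parameters per study (the
  multi-study scale test uses 57/57, 47/47, 35/34 = 277 samples, a split the
  source designs leave unstated). No probe-level artifacts, normalization,
  or batch effects are emulated.
* `generate_ct_table()` keeps the reference gene at 20 cycles in
  expectation and shifts the target by $-\log_2(\text{fold})$, so the
  delta-delta-Ct method recovers the planted folds exactly in the noise-free
  limit.

Every generator takes an explicit seed, restores the caller's RNG state, and
is byte-reproducible.

### The packaged reference fixture

`make_reference_fixture()` builds a deterministic, desk-scale data set with
the shape of the full screen: three planted complexes — a 50-clique
(mitochondria + cytosol), a 40-clique (mitochondria only), and a 44-member
tri-compartment complex (a 37-clique mitochondrial core carrying the IDE and
UBA52 intermediates, six cytosolic members including the DDO linker, and the
single ER member SEC61A1) — plus a sparse background confined to non-complex
nodes, three expression studies with DEGs planted in every complex, and a
three-group Ct table (control / istradefylline / amantadine, 25 each, true
folds 1 / 0.5 / 0.9). The motif edges are DDO–IDE, DDO–UBA52, IDE–SEC61A1,
UBA52–SEC61A1: the cytosolic linker reaches the ER in two hops through
either mitochondrial intermediate, so its bridge length is 3 with exactly
two witnesses.

The fixture's recommended configuration enables fluff: the peripheral motif
nodes have low vertex weights by construction (their closed neighborhoods
are triangles and K4s), so canonical growth finds the mitochondrial core and
fluff annexes exactly the seven peripherals — clean here because no
background node touches the complex.

## Numerical choices

* Tie-breaks are total everywhere (documented above) so all rankings are
  deterministic.
* Fisher combination clamps $p = 0$ to `1e-300` (warned); $p \notin [0, 1]$
  is rejected.
* The pooled-variance epsilon guard is `.Machine$double.eps`; with small
  per-study df the resulting p-values are representable (the t tail is
  polynomial) but dozens of orders of magnitude below any attainable
  sampling value, and flagged.
* ANOVA sums of squares of order `1e-30` (all-identical inputs, perfect
  fits) are detected relative to the data scale and mapped to the exact
  degenerate answers ($F = 0, p = 1$, or $p = 0$ with the flag).
* Unreachable nodes carry `Inf` distances; linker candidates with infinite
  bridge length rank last rather than erroring.

## Problem sizes used by the test suite

The suite is sized to run on one CPU in a few minutes: exhaustive oracle
equivalence over all 995 connected graphs on 2–7 vertices (subset-enumeration
brute force); planted-complex recovery over 10 regenerations of a 200-node
background with two 20-member plants; type-I calibration on 2000 null genes
across 3 studies of 10 + 10 samples; a 3-point effect-size ladder on 600
genes; bridge-length oracle equivalence on 100 random tri-labelled graphs of
up to 25 nodes; and 20 regenerations of the planted-linker fixture. These
sizes are the package's own benchmarking choices and are trivially scaled up
through the same functions.

## Known limitations

* The recovery benchmark's admission-threshold boundary loss (above) means
  planted complexes are typically recovered at Jaccard 0.8–1.0, not
  identically 1; the suite's recovery assertion sits deliberately at that
  operating point and one should expect occasional sub-0.8 draws.
* No confidence-weighted or directed graph support; no overlap-permitting
  complex detection beyond fluff.
* The expression layer neither collapses probes to genes nor corrects for
  batch; it assumes log-scale input (a `log2(x + 1)` switch exists for raw
  intensities).
* No amplification-efficiency correction (Pfaffl) in the Ct layer.
* Synthetic data cannot stand in for the schedule of real localization
  databases, STRING confidence structure, or cohort demographics; passing
  tests demonstrate algorithmic correctness and calibration, not biological
  conclusions.
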