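---
title: "Weighted q-gram kernels for glycan classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted q-gram kernels for glycan classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyqgram)
```

## The model

Glycans — the carbohydrate chains decorating proteins and lipids — are
modeled here as rooted trees: nodes are monosaccharides (plus occasional
non-sugar residues such as sulfate, phosphate or the aglycon, treated as
ordinary labels), edges are glycosidic bonds labeled by anomeric
configuration and carbon positions (`b1-4`, `a2-3`, ...), and chemistry
limits each residue to at most four children. Sibling order carries no
chemical meaning, so the package imposes a canonical child order (bond
label, child residue label, node id) purely for determinism of enumeration
and serialization.

A **q-gram** of a glycan is a connected subtree with $q$ nodes in which
every node has at most two neighbors inside the subtree — a path. Within a
rooted tree such a path is either a *straight* ancestor-to-descendant
chain or a *bent* path whose topmost node (the apex) carries two
descending chains; the **shape** $\sigma = (s_1, s_2)$ records the two
chain lengths (apex included in the first, $s_2 = 0$ when straight). Each
occurrence also carries the **layer** of its apex, the number of linkages
between the apex and the glycan root.

Counting occurrences of each distinct q-gram over a corpus of $n$ glycans
gives the count matrix $X_q \in \mathbb{N}^{d_q \times n}$ and the plain
q-gram kernel

$$K_q = X_q^\top X_q, \qquad K_Q = \sum_{q \in Q} K_q,$$

which implicitly assumes distinct q-grams share no similarity. The
**weighted q-gram kernel** drops that assumption by inserting a positive
semidefinite inter-q-gram weight matrix $W_q$:

$$K_{wq} = X_q^\top W_q X_q, \qquad
  K_{\alpha wQ} = \sum_{q \in Q} \alpha_q K_{wq}.$$

With $W_q = I$ the plain kernel is recovered exactly (a reduction the test
suite checks), so everything below is a strict generalization.

## Inter-q-gram similarity

Three similarity sources are implemented for $W_q$:

* **Linkage (LK).** Q-grams of different shape are treated as entirely
  dissimilar. For equal shapes the score multiplies a layer similarity,
  the per-position residue similarities, and the per-position bond
  similarities:
  $S_q(i,j) = S^l(l^i, l^j)\prod_k S^m(m^i_k, m^j_k)\prod_k S^b(b^i_k, b^j_k)$.
  Bond similarity comes from a table over the 15 most frequent bond labels,
  graded by chemical meaning (`b1-4` vs `b1-3` scores 0.9; anomer plus
  position changes score lower); residue similarity defaults to the
  identity and accepts a user TSV of graded scores (e.g. derived from a
  chemical-graph comparison such as SIMCOMP).
* **KCaM (KM).** Each q-gram is materialized as a small tree and scored
  against every other by a dynamic-programming tree alignment in the style
  of the KEGG Carbohydrate Matcher, with exact-match node scoring and
  geometric-mean self-score normalization to 0–100 (rescaled to $[0,1]$).
  This sees structure only — a near-miss bond earns nothing.
* **Linkage KCaM (LKM).** The same alignment with node scores
  $w(u,v) = S^m S^b S^l$, so partial residue/bond/layer similarity earns
  partial credit.

Because an alignment-score matrix need not be positive semidefinite,
`psd_correct()` symmetrizes, clips negative eigenvalues at zero (the
nearest PSD matrix in Frobenius norm), and adds a $10^{-9}$ ridge; a
diagonal-shift alternative is available when preserving off-diagonal
values exactly matters more than minimal distortion. The minimum
eigenvalue before and after is recorded in the returned object's
`psd_report`.

## Design choices in corners the definitions leave open

Several points are under-determined by the definitions above; the package
resolves them as follows, each behind an explicit argument.

* **Bent paths count.** "Subtree isomorphic to a path" is read as any
  connected q-node subtree of internal degree at most two, which includes
  bent paths; this is the only reading under which the shape descriptor is
  informative. A `straight_only` flag restricts enumeration to
  ancestor-descendant chains for comparison.
* **Identity of a q-gram excludes its layer.** Two identically labeled
  substructures at different depths are the same feature (the same row of
  $X_q$); layers enter only similarity computations. Keying on layer would
  prevent identical substructures from ever co-counting and the weighted
  method would no longer reduce to the classical one at $W = I$.
* **Representative layer.** Since one canonical key can occur at several
  layers, the layer attached to an index entry is its most frequent layer
  across the corpus, ties resolved toward the root. A corpus mode is the
  least arbitrary single value; the attenuation this introduces into LK
  couplings is a known cost (see Limitations).
* **Layer similarity** uses $S^l(l_i, l_j) = 1/(1 + |l_i - l_j|)$: equal
  layers score 1, the decay is strict and symmetric, and the resulting
  matrix on integer layers is positive semidefinite. The formula is an
  argument (`layer_formula`) wherever it is used.
* **Combination rule.** Layer, residue and bond components multiply, so a
  zero-similarity component annihilates a match — consistent with the
  shape gate's all-or-nothing semantics — and products of PSD structures
  stay PSD (Schur). An arithmetic-mean combination is available via
  `combine = "mean"`.
* **Canonical chain order** for bent q-grams (longer chain first, then
  lexicographic residue and bond sequences, byte-wise comparison for
  locale independence) is fixed at enumeration; similarity never
  re-matches chains, which would silently change the feature map.
* **Root bonds.** The root has no parent bond; where one is needed a
  reserved wildcard label is used that matches anything with similarity 1.
* **Table fallbacks.** Bond pairs absent from the table score 1 when the
  labels are identical and 0 otherwise — conservative and bounded.
* **Alignment recursion.** `kcam_align()` allows skipping a node of either
  tree at a configurable gap penalty (default 0, i.e. free skips as in
  approximate matching), solves each children assignment exactly by
  exhaustive injection (at most $4!$ cases at glycan branching), and reads
  the global score at the root pair; a local mode floors the recursion at
  zero and takes the best pair. On trees of up to six nodes the
  implementation agrees with an exhaustive search over all
  ancestor-order-preserving partial mappings.

## Classification and evaluation

`cv_auc()` evaluates a kernel by stratified k-fold cross-validation
repeated R times (defaults 5 × 50, the convention for glycan benchmarks),
fitting a soft-margin SVM on the training block of the precomputed kernel
(kernlab's C-SVC) and scoring held-out decision values by the Mann–Whitney
AUC with midrank ties; fold AUCs are averaged per repeat and repeats are
summarized by mean and SD. Folds are seeded as `seed + repeat`, and
samples are put in a canonical name order first, so jointly permuting
kernel and labels cannot change the result. Two numerical choices are
worth knowing: the kernel block is rescaled by its mean training diagonal
(a pure reparameterization that conditions the SMO solver), and the solver
tolerance defaults to 0.1 rather than 0.001 — decision-value *rankings*,
which are all that AUC uses, stabilize far earlier than the KKT
conditions, at a small fraction of the cost. Both are arguments.

For combining kernels across $q$, `mkl_weights()` provides a
deterministic, dependency-light weighting by centered kernel–target
alignment (negative alignments floored at zero, weights normalized to sum
one), with uniform weighting as the baseline; this stands in for
optimization-based multiple kernel learning, which is deliberately out of
scope. Cosine normalization (`cosine_normalize()`) is off by default —
the kernels are used raw unless asked — but recommended before summing
kernels whose raw scales grow with $q$-gram counts.

## The synthetic-data generator

Real glycan corpora with curated disease annotations require external
database retrieval, so the package ships a generator that makes every
stage testable. Trees grow top-down: each of up to four child slots fills
independently with probability `branch_prob` (default 0.3), growth stops
at `max_depth` (default 6), and trees are rejection-sampled into a node
range (default 5–15, the size range of typical mammalian N- and O-glycans).
Node and bond labels are drawn from the observed frequencies of the 24
most common residues and bond types in the KEGG glycan database
(GlcNAc 0.183, Gal 0.171, ..., `b1-4` 0.272, ...), the only frequency data
available without retrieval.

`planted_dataset()` builds two-class benchmarks: negatives are background
draws; positives have a small motif fragment (default examples use the
LacNAc unit Gal-β1-4-GlcNAc) grafted at a uniformly chosen node within a
layer window, with the displaced subtree reattached below the motif when
degree and depth permit and dropped otherwise. An optional bond
perturbation swaps the motif's bond (e.g. `b1-4` → `b1-3`) in a fraction
of positives, emulating a motif whose linkage varies across carriers.

What the generator does *not* emulate: biosynthetic pathway constraints
(real glycans are far from label-independent), position-specific residue
usage, database redundancy, or annotation noise. A passing benchmark here
demonstrates that the machinery recovers a planted signal under honest
cross-validation — not that any particular AUC will transfer to real
corpora.

## Problem sizes used by the shipped checks

The test suite exercises enumeration against an exhaustive
connected-subset oracle on 200 random trees of up to 12 nodes for
$q \le 5$, the aligner against an exhaustive mapping oracle on trees of up
to 6 nodes, and the classification loop on planted datasets of 200
glycans (5-fold CV, 10 repeats) — sizes chosen so the whole suite runs in
a few minutes on one core while still crossing every code path at
non-trivial scale.

## Known limitations

* The LK coupling between two variants of the same motif is attenuated by
  the representative-layer heuristic (a motif planted across layers 0–2
  yields couplings of 0.45 rather than 0.9); on desk-scale planted
  benchmarks the measured benefit of LK weighting over the plain kernel is
  positive on average in the scarce-evidence regime but its sign varies
  from dataset replicate to dataset replicate — the shipped
  weighting-benefit check is strict about this and documents the outcome
  rather than relaxing it.
* LK similarity for large $q$ multiplies many component scores and decays
  quickly; pairwise matrix construction is $O(d_q^2)$, which in practice
  restricts LK to small $q$ (2–3), matching how such kernels are used.
* The KCaM scoring here is a faithful re-implementation of the recursion
  family, not a bug-for-bug reproduction of any web service's score
  scaling.
* `mkl_weights()` is filter-style: it does not optimize the SVM objective
  jointly over weights.
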