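---
title: "Methods: compact structure embeddings, the learned cluster index, and staged TM-score ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compact structure embeddings, the learned cluster index, and staged TM-score ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

foldmatch is a self-contained engine for tertiary-structure similarity
search over collections of single protein chains. This vignette explains the
model behind each stage, the tunable parameters and the reasons for their
defaults, what the synthetic-structure generator does and does not emulate,
and the numerical choices and known limitations a user should be aware of.

## The retrieval model

Searching hundreds of millions of predicted structures with a structural
aligner is infeasible: an alignment costs on the order of a second, so the
aligner can only ever see a few dozen candidates. foldmatch therefore uses a
staged funnel:

1. **Embedding.** Every chain is compressed into a short rotation-invariant
   vector derived from its Cα distance matrix.
2. **Learned cluster index.** The embedding collection is partitioned by
   k-means; a small feed-forward classifier learns to map an embedding to
   the clusters most likely to contain its neighbours. A query probes only
   the `n_probe` top-ranked clusters (default 10).
3. **Euclidean ranking.** The probed candidates are ranked by Euclidean
   embedding distance and cut at a fixed cap of 1000.
4. **Structural scoring.** Only the top of the ranking (50 hits initially,
   expandable by 50/100/200/300) is scored by the structural aligner, which
   reports TM-score, RMSD, aligned residues and sequence identity.

Each stage trades a little recall for orders of magnitude of work: the
result is approximate by design, and the package ships a recall benchmark
(`recall_benchmark()`, `cmd_bench()`) that quantifies exactly how
approximate, against a brute-force oracle.

## Embedding: down-sampled Cα distance matrices

A chain of $n$ residues is reduced to its ordered Cα trace
$x_1,\dots,x_n \in \mathbb{R}^3$ (Å). Its distance matrix
$D_{ij} = \lVert x_i - x_j \rVert$ is invariant under rotation, translation
and reflection, and summarises the whole fold while discarding primary and
secondary structure. $D$ is resampled onto a fixed $m \times m$ grid by
corner-anchored bilinear interpolation and the strict upper triangle is
flattened row-major, giving a vector of dimension $d = m(m-1)/2$.

Parameters (`embedding_config()`):

* `grid_size` ($m$, default 8, so $d = 28$): with 32-bit storage this is
  roughly a hundred bytes per structure — small enough that a collection of
  hundreds of millions of embeddings fits in tens of GiB of memory, which is
  the regime this design targets. Larger $m$ retains finer structure at a
  linear cost in index size.
* `include_diagonal` (default `FALSE`): the resampled diagonal is near zero
  and carries no information.
* `scale` (default 1, i.e. raw Å): no per-protein normalization is applied.
  Absolute distances preserve global size, so a small domain and a large
  multi-domain chain with similar shape do not collide. Dividing by a
  constant merely rescales the metric.

Properties asserted by the test suite: exact invariance under rigid motion
(to 1e-9), determinism (bit-identical repeats), linear scaling under uniform
coordinate scaling, and — deliberately documented as a limitation —
**mirror-image blindness**: a chain and its enantiomer have identical
distance matrices, hence identical embeddings. Distinguishing chirality is
delegated to the alignment stage, whose superposition excludes reflections.

The interpolation grid maps output index $i$ to input position
$1 + (i-1)(n-1)/(m-1)$, so the four corner samples coincide with the corner
entries of $D$ and a resize with $m = n$ is the identity. Up-sampling
($m > n$) is permitted but flagged, since it adds no information.

## The learned cluster index

The index has one level: k-means partitions the embeddings into $K$ buckets
(default 64 at the desk scale used throughout the package), and a
fully connected network (28 → 128 rectifier units → $K$-way softmax) is
trained with cross-entropy and Adam (50 epochs, mini-batches of 32,
standardized inputs, seeded initialization) to predict a query's bucket.
At query time the classifier's top `n_probe` clusters are gathered and
ranked exactly. The classifier is a *router*: buckets stay fixed by the
k-means labels, and routing quality only affects which buckets are read,
never what is in them.

Numerical and design choices:

* **k-means**: k-means++ seeding followed by Lloyd iterations, written so
  that a cluster that empties mid-iteration is re-seeded deterministically
  with the point farthest from its assigned centroid. Empty clusters are a
  real occurrence here because tight structural families at $K$ larger than
  the family count produce highly unbalanced geometry. The implementation is
  cross-checked in the tests against the reference k-means objective on
  well-separated data.
* **Determinism**: every stage (seeding, Lloyd, network init, batch
  shuffling) flows from one seed; rebuilding with the same seed reproduces
  the index bit-for-bit, and probe tie-breaks use ascending cluster id.
* **Single level**: one classifier step routes straight to buckets.
  Multi-level trees can shrink routing cost further at production scale but
  add nothing at desk scale.
* **Routing accuracy vs recall**: with $K = 64$ clusters over 20 synthetic
  families, per-cluster training accuracy is deliberately *not* the target —
  clusters inside one family blob are entangled and accuracy of ~0.7 is
  expected. What matters is that the probability mass of a query's top-10
  clusters covers its family's buckets, which the recall benchmark verifies
  directly (recall@10 = 1.0 under the default study conditions; ≥ 0.9 is the
  package's acceptance bar).

## Structural scoring

The aligner is a sequence-order-dependent, TM-align-style iterative
refinement engine; it replaces an external alignment binary so the package
is self-contained.

* **Superposition** is the closed-form Kabsch solution: SVD of the
  covariance of the centred paired coordinates with the determinant
  correction that excludes reflections. Optimality is tested against a
  derivative-free optimizer over rotation angles (1e-4 agreement) and
  against 100 random rotations per pairing.
* **TM-score** of an alignment with per-pair distances $d_i$ is
  $\mathrm{TM} = \frac{1}{L}\sum_i \frac{1}{1+(d_i/d_0)^2}$, with the
  standard length scale $d_0(L) = 1.24\,(L-15)^{1/3} - 1.8$ floored at
  0.5 Å.
* **Normalization length** is the *query* chain length, always. TM-scores
  are therefore asymmetric (`align_chains(a, b)` ≠ `align_chains(b, a)` in
  general); normalizing by target or average length is available through
  `tm_params()`.
* **Refinement**: deterministic initial correspondences (gapless threads at
  offsets in multiples of ⌈min(n_a, n_b)/4⌉ in both directions, 20-residue
  fragment seeds at the same stride, plus the all-residue pairing when
  lengths match) are each refined by alternating Kabsch superposition, a
  score matrix $S_{ij} = 1/(1+(d_{ij}/d_0)^2)$, and global dynamic
  programming with linear gap penalty −0.6 and free end gaps, until the
  TM-score gain falls below 1e-6 or 30 iterations. The best alignment over
  all starts is returned; the running best is non-decreasing by
  construction. The DP recursion is exact for a linear gap model: the
  in-row dependency collapses to a running maximum, which keeps the
  implementation fully vectorised.
* Ties in the DP traceback prefer the diagonal move, so among equal-scoring
  alignments the one with more aligned pairs is chosen, deterministically.

Degenerate inputs: chains shorter than 3 residues are rejected everywhere
(no tertiary structure to speak of; this floor is this package's own rule).
An alignment with no pairs scores 0 with a warning rather than failing.

## The synthetic generator: what it emulates, what it does not

Offline testing needs a structure collection with known neighbourhood
ground truth. `generate_benchmark_db()` builds families as:

* a seed fold per family — ideal α-helix (radius 2.3 Å, twist 100°, rise
  1.5 Å), extended strand (zigzag, 3.5 Å rise, ±0.9 Å lateral pleat), or a
  self-avoiding 3.8 Å-step random coil — at a length drawn from
  `length_range` (default 50–200 residues at desk scale; the generators
  accept 20–2000);
* a coarse family-specific deformation (`family_sigma`, 2 Å) of that seed,
  so two families of the same secondary-structure class are still distinct
  folds — without it, two helix families of similar length would be
  *identical*, and family labels would not mean "same fold";
* members as fine-noise copies (`sigma`, default 0.5 Å per coordinate,
  i.e. ≈ 0.87 Å expected Cα RMSD) placed at random rigid positions.

The defaults were chosen once as the package's study conditions: member
noise well below $d_0$ of a typical chain (so intra-family TM-scores stay
high), family deformation several times the member noise (so families are
separable), and 20 × 50 members for benchmark runs.

What this does **not** emulate: real fold-space density (families here are
well-separated islands; real neighbourhoods have continuous shells of
marginal similarity), domain architecture, sequence diversity (members share
the seed's sequence, so sequence identity is uninformative within families),
and predicted-structure artefacts such as low-confidence disordered tails.
Passing the recall criterion on this generator shows the index machinery is
correct and well-routed; it does not certify recall on a real proteome-scale
collection, where cluster boundaries cut through denser neighbourhoods.

## Identifier handling and the search workflow

Queries may be UniProt accessions, PDB ids, or gene symbols, resolved in
that order: accession-shaped tokens (official UniProt pattern) pass through;
4-character PDB-shaped tokens and everything else are looked up in offline
two-column TSV tables. One-to-many mappings resolve to the lexicographically
smallest accession with the alternatives reported. The mapping layer is a
thin interface so a live backend could replace the tables; none is shipped,
which keeps every test offline. Queries must be present in the chain store —
upload-a-structure is out of scope.

Rankings and per-pair alignment metrics are cached in the chain store keyed
by query, result and scorer configuration, so repeating a query performs no
new alignments (`alignment_counter()` makes this observable) and expansion
only ever scores the next slice of the ranking. Expanding by 50 then 100
gives exactly the same scored set as 100 then 50: the scored set is always a
prefix of the ranking.

## Problem sizes and runtime

All shipped tests and the acceptance script run on synthetic data built at
run time: the standard benchmark is 1000 chains (20 × 50, lengths 50–200),
indexed at $K = 64$ in a few seconds; a full search with 50 structural
scores takes a few seconds more; the complete test suite finishes in well
under a minute on one CPU. These sizes were chosen as the smallest at which
the staged funnel (probe → cap → page) is exercised with all its constants
at their defaults.

## Known limitations

* Results are approximate; the recall benchmark quantifies the
  approximation against brute force, and probing more clusters trades time
  for recall monotonically.
* Embeddings are blind to chirality (mirror folds collide) and to sequence;
  structures dominated by unstructured regions compress to similar
  distance-matrix profiles and can crowd the candidate list.
* The aligner is sequence-order-dependent: circular permutations and
  non-sequential topological matches are out of scope, as are multimers.
* TM-scores are query-normalized; comparing hit tables across differently
  sized queries should account for the normalization length.
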