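---
title: "Similarity-fusion drug repositioning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-fusion drug repositioning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reposim)
```

## The problem

Drug repositioning asks which approved drugs might treat diseases they
were never developed for. `reposim` scores every drug--disease pair by
*guilt by association*: a pair is promising when the drug resembles a
drug already known to treat a disease resembling the target disease.
Everything therefore hinges on two similarity matrices -- one over drugs,
one over diseases -- and on how raw heterogeneous features are turned
into vectors that those similarities can compare.

## Feature encodings

**Chemical structure (`s`).** A SMILES string is validated against a
fixed 35-character alphabet (34 structural characters plus the space
pad), right-padded to 120 characters and one-hot encoded to a 120 x 35
matrix -- the input contract of character-level molecular encoders. The
continuous vector itself is produced by a pluggable encoder returning
192 dimensions. The built-in default hashes character trigrams into 192
counting slots and scales to unit norm: deterministic, dependency-free,
and sensitive to both composition and ordering of the string. Any
pre-trained molecular encoder (e.g. the latent space of a chemical
variational auto-encoder) can be plugged in as a function honouring the
same length contract; the pipeline's correctness does not depend on
which encoder fills it.

**Protein and enzyme sequences (`p`, `e`).** Each amino-acid sequence is
split into three *shifted non-overlapping* 3-gram frames (offsets 0, 1,
2; every length-3 window of the sequence lands in exactly one frame).
Each frame's 3-gram vectors -- 100-dimensional by default -- are summed
(mean optional; the sum is the usual word-vector aggregation and makes
the frame embedding additive) and the three frame vectors are
concatenated into a 300-dimensional sequence vector. A drug is
represented by the *set* of its target-protein vectors, and separately
by the set of its enzyme vectors; duplicates are retained. The built-in
3-gram table assigns each 3-gram a seeded random unit vector, which
carries composition information deterministically; a pre-trained
embedding table can be loaded from TSV instead. Unknown 3-grams map to
the zero vector with a warning (an error can be requested); an empty
frame contributes a zero block, so the empty sum is well defined.

**Expression (`g`).** The differential gene-expression profile (dGEP) of
a drug on a cell line is `mean(log2 treated) - mean(log2 control)`
per gene, replicates merged by the mean. Raw intensities are
log2-transformed here, and a non-positive raw value is an error rather
than silently shifted by a pseudo-count. A drug profiled on several cell
lines gets the mean of its per-cell-line dGEPs. dGEPs are then reduced
by a symmetric stacked auto-encoder (below) to a 20-dimensional
bottleneck vector; `dgep_encoding = "raw"` keeps the full-gene vector.

**Disease phenotype and genotype (`a`, `d`).** Disease annotations are
flat term sets, one-hot encoded over the observed vocabulary and reduced
by centered PCA to 30 (phenotype) and 20 (genotype) score dimensions.
Component signs are fixed so each component's largest-magnitude loading
is positive, making scores reproducible. Diseases missing either feature
type are excluded from disease--disease similarity.

## The auto-encoder

The dGEP auto-encoder is a symmetric feed-forward network (default
hidden widths 512--64--20--64--512, configurable; the middle layer is the
bottleneck) trained on mean squared error with the nadam optimiser
(adaptive moments with Nesterov momentum), learning rate 0.001, and a
60/15/25 train/validation/test row split. Activations are chosen per
layer from ReLU, Linear, SoftPlus and ELU; the output layer is linear.
Hyper-parameters are selected by seeded random search over user-supplied
grids on validation MSE, with the full trial log returned.

Weights are initialised by greedy layer-wise *spectral pretraining*:
each encoder layer starts at the principal-subspace projection of its
(forward-propagated) input and each decoder layer at the transposed
back-projection with the stored column means. For all-linear activations
this places the network exactly at the PCA optimum before fine-tuning --
the classical equivalence between linear auto-encoders and PCA -- which
the test suite exploits by requiring a linear bottleneck-3 network to
match the PCA-3 reconstruction error (SVD oracle) within 10% on rank-3
synthetic expression. `pretrain = "none"` falls back to seeded Glorot
noise. All randomness (splits, initialisation, minibatch shuffles)
derives from the config seed, so two runs with one seed agree to the
last bit; training aborts with diagnostics if the loss becomes
non-finite.

## Similarity and fusion

Vector features use cosine similarity. Set-valued features (targets,
enzymes) use a best-match rule: the smaller set indexes the sum, and
each of its members contributes its best cosine match in the larger set.
The raw diagonal of that matrix is the set size (each member matches
itself); the fusion step's unit-diagonal rule supplies the final
diagonal, exactly as the formulas compose. When the two sets have equal
cardinality the two directed sums differ in general, so their average is
returned: a similarity must not depend on argument order, and the
average coincides with the directed rule whenever cardinalities differ.

Per-feature matrices over a drug subset `E` (only drugs possessing
*every* feature in `E` are retained, so larger subsets keep fewer drugs)
are summed off-diagonally and min--max normalised:

$$ I^E[i,j] = \frac{\sum_{x \in E} M^x[i,j] - \min}{\max - \min},
   \quad i \ne j, \qquad I^E[i,i] = 1, $$

where `min`/`max` are the off-diagonal minimum minus 0.01 and maximum
plus 0.01. The offsets guarantee off-diagonal values strictly inside
(0, 1), which downstream scoring relies on. Negative cosines are summed
as-is -- the min--max map absorbs the range, and clipping would distort
relative similarities. The disease matrix `D` fuses the phenotype and
genotype cosine matrices the same way. With only two entities the single
off-diagonal value maps to 0.5 by construction; this degenerate case is
accepted with a warning.

## Scoring

A pair (drug *i*, disease *j*) is scored by the maximum geometric mean
over known associations $\mathcal{A}$:

$$ A^E[i,j] = \max_{(i',j') \in \mathcal{A}}
   \sqrt{I^E[i,i'] \cdot D[j,j']}. $$

Which known pairs are *eligible* is governed by the exclusion mode:

* `strict` (default): $i' \ne i$ and $j' \ne j$ -- the rule as printed;
  a drug's own other indications never contribute, for any scored cell.
* `pair`: only $(i', j') \ne (i, j)$ -- standard guilt-by-association,
  where a drug's other indications may vouch for it.
* `none`: every known pair is eligible.

Both readings of the eligibility condition are defensible, and the
ambiguity is real, so both are implemented; no behaviour is guessed
away. Cells with no eligible pair (or only negative products, impossible
with valid fused inputs) score 0 and are flagged. The optimized
implementation accumulates running maxima of per-association outer
products and repairs the rows/columns touched by the exclusion rule; the
test suite holds it equal to a brute-force triple loop to 1e-12 on
dozens of random instances per run.

## Evaluation protocols

Positives are the known associations; negatives are all other pairs of
the scored universe. AUC is the Mann--Whitney rank statistic with ties
counted one half (invariant under monotone score transforms) -- stated
explicitly because trapezoid-on-sorted implementations differ on ties.

* **Leave-one-out:** each known pair is scored with itself hidden (the
  configured exclusion mode then applies to the remainder); unknown
  pairs are scored against the full known set.
* **Sampled AUC:** per repeat, `ceiling(fraction * n)` positives and
  negatives are drawn without replacement (seeded; uniform, not
  stratified) and ranked; 10% and 20 repeats by default. With
  fraction 1 every repeat equals the full-matrix AUC exactly.
* **Per-entity AUC:** each disease ranks all drugs (or each drug all
  diseases); entities lacking either class are skipped with a log line
  and excluded from the mean and SD.
* **k-fold CV:** known pairs are partitioned into seeded folds; each
  fold's matrix is rebuilt from the remaining pairs, held-out pairs are
  the positives and all unknown pairs the negatives. With `k = |A|` the
  scheme reduces to per-pair hide-one scoring.

## The synthetic cohort generator

The generator exists so that every stage -- file parsing included, since
it emits real files -- can be exercised without any external database.
It plants a latent structure that all modalities share: each drug and
disease belongs to one of `n_clusters` therapeutic clusters and carries
a within-cluster gradient position $t \in [0,1]$.

* SMILES: one random 60-character template per cluster; a drug applies
  the first `round(t * noise_sd * 4 * 60)` substitutions of a fixed
  per-cluster mutation path, plus i.i.d. substitutions at rate
  `0.05 * noise_sd`.
* Sequences: two 90-residue templates per cluster per modality (targets,
  enzymes); every drug carries one mutated copy of each, so set
  similarity reflects sequence content rather than set cardinality.
  Mutation-path depth `round(t * noise_sd * 4 * 90)`, i.i.d. rate
  `0.05 * noise_sd`.
* Expression: 200 genes, one cell line, 2 treated replicates per drug,
  4 controls; treated = baseline + cluster signature +
  `(t - 0.5) * 8 * noise_sd` times a cluster gradient direction, with
  replicate noise `0.3 * noise_sd`.
* Disease terms: an ordered 40-term list per cluster per feature type; a
  disease takes a 20-term window starting at `round(t * noise_sd * 100)`
  with small term drop/add noise.
* Associations: rank-matched round-robin within clusters -- drugs and
  diseases ordered by gradient, paired rank-to-rank, later rounds
  shifting the disease rank by one or two -- yielding near-regular degrees
  at about 2.5 indications per drug under the defaults
  (`assoc_per_cluster = 50` on 100 drugs), the density typical of
  curated indication catalogues. Homogeneous degrees also make the
  permutation null exchangeable: with heterogeneous degrees, strict-mode
  exclusion penalises high-degree positives and biases the null AUC
  below one half.

All corruption scales with `noise_sd`, so `noise_sd = 0` collapses each
cluster to identical entities; every random draw comes from a named
sub-stream of one master seed, so one seed reproduces all files byte for
byte. `shuffle_labels = TRUE` permutes the cluster/gradient assignments
of *both* drugs and diseases before planting, leaving the features
intact but the associations carrying no signal -- the negative control.
One-sided shuffles are deliberately not used: they leave co-indicated
drugs as true cluster-mates, which leaks through same-disease pairs in
the permissive modes and interacts with strict-mode exclusion in the
other direction.

What the generator does *not* emulate: real SMILES chemistry or
grammar, homology structure of real protein families, realistic
microarray noise spectra, or ontology-graph structure in disease terms
(the method itself treats term sets as flat). Passing tests therefore
demonstrate that the pipeline recovers the kind of cluster-plus-gradient
structure the method assumes, at realistic association density -- not
performance on any real database.

## Numerical and design choices

* Entity ordering is lexicographic everywhere; all matrices inherit it.
* Matrix TSVs are written with `%.15g`, so write/read round trips are
  identities well below the 1e-12 per-cell tolerance the tests assert.
* Cosine of a zero vector is an error naming the entity, never NaN.
* PCA components are sign-fixed (largest-magnitude loading positive).
* The permutation-style exclusion ambiguity (`strict` vs `pair`) and the
  equal-cardinality tie in set similarity are the two places the printed
  formulas underdetermine behaviour; both resolutions are documented
  above.
* Test problem sizes are chosen to exercise every code path at desk
  scale: random scoring instances up to 30 x 30 with 50 known pairs,
  fusion/set-similarity property sweeps of 1,000 random cases, a
  100 x 50 x 5-cluster cohort for structure recovery with a 20-seed
  shuffled control, and 100 x 50 rank-3 expression for the
  auto-encoder/PCA comparison.

## Limitations

Scores are relative similarities, not calibrated probabilities. The
built-in encoders are deterministic stand-ins that carry composition and
ordering signal but no learned chemistry or protein semantics; for real
studies, plug in pre-trained encoders behind the documented contracts.
Strict-mode scoring leaves cells without eligible known pairs at 0,
which depresses ranks of drugs or diseases with a single association;
the flags returned with the score matrix identify those cells.
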