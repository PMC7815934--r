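---
title: "Identity-aware embedding of microcircuit graphs: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identity-aware embedding of microcircuit graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why its
defaults are what they are.  Nothing here reports an empirical number that
the test suite or `scripts/acceptance.R` does not itself recompute.

## 1. The data model

A *microcircuit* is an undirected weighted graph on the indexed vertex set
`1..k`; vertex `i` is neuron `i` in every member of a dataset, and the index
is the identifier.  Edge weights are pairwise synchrony values — in this
package Spearman rank correlations of two neurons' activity within a time
window, so weights live in `[-1, 1]`.  The S4 classes `UnweightedGraph`,
`Microcircuit` and `MicrocircuitDataset` enforce the invariants (simple
graphs, 1-based endpoints inside `1..k`, one weight per edge, a common
vertex count, binary labels).  Text serialization is a small line-oriented
edge-list dialect (`readDataset()` / `writeDataset()`): a `"k n_G"` header,
one `graph <index> [<label>]` record per graph, and `u v [w]` edge lines,
with weights printed at 17 significant digits so round-trips are exact to
1e-12.

## 2. The unweighted embedder

`ugevia()` composes three steps.

**Initial labels.**  Each vertex starts from a string fusing its degree and
its identity: `"<degree>_<index>"`, with degree-zero vertices labeled
`"Z<index>"`.  The fusion is a deliberate design choice: degree alone (the
classical Weisfeiler-Lehman start) discards identity, the index alone
discards local structure; the fused label preserves both signals that the
downstream relabeling propagates.  Two ablations are built in:
`labelingMode = "degree_only"` (the identity-agnostic graph2vec-style
baseline) and `zeroDegreeSpecial = FALSE` (identity labels without the
special zero-degree treatment).

**Relabeling sweeps.**  `extractFeatures()` runs `featureGenIters`
iterations; in each one, every vertex's feature becomes the MD5 digest of
its previous feature joined (delimiter `"_"`) with the sorted previous
features of its neighborhood.  All reads use the previous iteration's
snapshot, so the result is independent of sweep order, and neighbor features
are sorted before joining, so it is independent of edge listing order.
Sorting uses C-locale (radix) string order, fixed so libraries are identical
across platforms and locales.  The fold convention — own feature first, then
the sorted neighbor features, one delimiter between successive elements — is
the package's canonical dialect; only binary concatenation is forced by the
construction, and the n-ary layout had to be fixed somewhere.

A degree-zero vertex has no neighbors to draw from; dropping it from the
sweeps would erase the identities of silent regions, which carry real signal
in sparse microcircuits.  Instead its "neighborhood" is the pair of
wrap-around sequence neighbors `v_{i-1}, v_{i+1}` (with `v_k` preceding
`v_1`), read from the snapshot regardless of their degrees.  With the
special rule disabled, a degree-zero vertex is simply rehashed from its own
feature, which is what a plain Weisfeiler-Lehman sweep degenerates to.

**The library.**  The per-graph feature library contains one graph-level
edge-count feature (`hash("E<edgeCount>")`), the `k` initial labels, and
`k` hashed features per sweep — length `1 + k + featureGenIters * k`.
Including the initial labels means no information is lost at zero sweeps;
emitting the edge count as a corpus-level token preserves separability of
classes that differ only in edge count.  Both inclusions are package
decisions: the construction needs the edge count *somewhere*, and a
graph-level token is the natural place for a bag-of-words document.

**Document embedding.**  Libraries are bags of tokens; digests are opaque
unique words.  The embedder is a single-threaded PV-DBOW paragraph-vector
trainer with negative sampling (5 negatives), written in C++ for speed and
determinism: given one seed it reproduces bit-identical embeddings.  The
four advertised hyperparameters are learning rate 0.025 (decaying linearly
to 1e-4), frequency-downsampling threshold 1e-4, minimum count 1, and 100
epochs.  PV-DBOW (rather than the distributed-memory variant) is the
standard choice in the graph2vec lineage, where token order within a
document is meaningless.  Defaults `featureGenIters = 4` and `m = 8` match
the per-channel settings used throughout.

## 3. The weighted, multi-channel embedder

`wgevia()` thresholds the weighted dataset along the ladder
`T_j = wmax/(2 nc) + (j-1) wmax/nc`, `j = 1..nc`, with `wmax` the maximum
weight across the whole dataset, keeping edges with `W(e) > T_j` (strict:
a weight equal to the threshold is dropped, consistent with the
single-threshold conversion `weightedToUnweighted()`, which removes an edge
when `W(e) <= chi`).  Each channel is embedded by `ugevia()` at dimension
`muC` with the channel index added to the base seed, and blocks are
concatenated in channel order: `nc * muC` columns, 80 at the defaults
`nc = 10`, `muC = 8`.

Negative weights — possible for Spearman correlations — fall below every
rung of the (positive) ladder and are therefore absent from all channels.
Anticorrelation structure is thus invisible to the embedding; extending the
ladder into negative territory is an easy but deliberate non-feature, since
the channel construction is defined from `wmax` alone.

## 4. The five-vertices benchmark

`generateFiveVertices()` emits `6 * copies` graphs (3,000 at the default
500) on five common vertices: six blocks of identical copies of six
templates, labels alternating 0/1 per block.  The templates are chosen to
satisfy the benchmark's defining constraints, which the generator validates
on entry by brute force over all `5!` vertex permutations:

* templates 1 and 2 differ in edge count (separable without identity),
* templates 3/4 and 5/6 are isomorphic pairs whose edges sit on different
  vertex indices (provably inseparable without identity awareness),
* plenty of degree-zero vertices exercise the `Z` labeling.

Identical copies exist purely to give downstream classifiers enough
training instances.  Templates are configurable, so an externally published
set with the same properties can be substituted.

## 5. The integrate-and-fire simulator

`simulateCondition()` Euler-integrates, per neuron,
`dρ/dt = (ρ_rest − ρ)/τ + σ τ^{−1/2} ε` with standard-normal `ε`, spiking
when `ρ` exceeds a threshold, then resetting to rest and ignoring input for
a refractory period.  The noise term's `τ^{−1/2}` scaling is the standard
diffusive normalization for a leaky membrane.  Defaults (all overridable):
`ρ_rest = 0`, threshold 1, `τ = 20` steps, `dt = 1` (one step = one frame),
refractory 2 steps, noise `σ = 0.05`.

The network has 50 group-A neurons driven by independent Poisson stimulus
events (rate 0.05 per step, amplitude 1.5 — suprathreshold, so a stimulated
neuron spikes reliably) and 50 group-B neurons, each with a fixed parent set
drawn from A: 1–2 parents under condition 1, 3–4 under condition 2.  A
parent spike delivers a synaptic increment of 0.4 within the same frame,
and potentials are recorded before the post-spike reset, so parent-child
synchrony is visible to a same-frame correlation.  The stimulus amplitude
and the same-frame delivery are the two simulator choices that were open;
both were fixed so that the generative coupling is actually expressed in
the measured traces rather than hidden by reset artifacts.

`buildMicrocircuits()` cuts the trace into non-overlapping 40-frame windows
and builds one complete weighted graph per window (all neuron pairs;
undefined correlations from constant series become weight 0; no
pre-thresholding — the channel ladder does all thresholding).
`generateSimuDataset()` runs one simulation per condition and labels the
windows 0/1.

What the generator emulates: fixed neuron identities across windows, a
stable condition-dependent coupling skeleton, correlation-based weights in
`[-1, 1]`, and a realistic noise floor.  What it does not: calcium-indicator
dynamics, imaging artifacts, non-stationary behavior-locked modulation, and
the detailed parameterization of any external simulation pipeline.  Passing
tests on this generator demonstrate that the embedding recovers stable
identity-anchored coupling structure from windowed correlations; they do
not certify performance on real imaging data.

Two empirical facts about the generator worth knowing.  First, because the
membrane time constant (`τ = 20`) autocorrelates the potential traces, the
finite-window Spearman null between *independent* neurons is much wider
than the white-noise null; low channels therefore contain many
noise-induced edges, and the discriminative structure concentrates in the
upper channels.  Second, parent multiplicity shapes coupling strength in
opposite directions: 1–2 parents concentrate the drive into few strong
pairwise correlations, while 3–4 parents dilute it across more, weaker
partners — the property test asserts exactly this (strong-coupling counts
higher under condition 1), and either direction is equally usable by the
classifier.

## 6. The evaluation harness

`runExperiment()` performs k-fold cross-validation (default 10) with folds
stratified by label — plain random splitting can produce single-class
training folds on imbalanced data — and reports mean ± std of test and
train accuracy per classifier.  The four classifiers and their fixed
hyperparameters: a one-hidden-layer MLP (128 ReLU units), a two-layer MLP
(128 and 64), both with a 2-unit softmax output trained by Adam (learning
rate 1e-3, batches of 32, 100 epochs, no early stopping); an RBF-SVM with
`C = 100`, `γ = 0.1`; and LDA with `tol = 1e-4`.  Features are standardized
per column using training-fold statistics before every fit: the classifier
hyperparameters are held fixed across experiments, and without a common
scale the same `γ` or learning rate would face arbitrarily scaled
paragraph-vector geometries.  Plain accuracy is the default score;
`scoring = "balanced"` (mean per-class recall) is the right choice beyond
roughly 60/40 imbalance.  `pairedTTest()` compares two classifiers' fold
scores with a two-tailed paired t-test, reporting the comparison as
undefined when all fold differences are equal.  `tsneChannels()` projects
per-channel embeddings to 2-D with t-SNE (via Rtsne, fixed seed, perplexity
reduced automatically for small samples) and writes one labeled scatter per
channel.

## 7. Numerical and reproducibility notes

* All randomness is seed-derived: the PV-DBOW trainer uses its own
  deterministic generator; R-side sampling runs under `set.seed` with the
  caller's RNG state restored afterwards.  Channel `j` trains at
  `base seed + j`.
* MD5 digests are computed on UTF-8 bytes and rendered as 32 lowercase hex
  characters; tests verify them against an independent implementation and
  fixed reference vectors.
* The Euler integrator is first-order: over one membrane time constant the
  noiseless decay factor is `(1 - dt/τ)^{τ/dt}` ≈ `e^{-1}` with relative
  error about 2.5% at `τ = 20, dt = 1`; tests assert both the exact
  first-order trajectory and the closed-form envelope.
* Degenerate inputs are defined, not accidental: empty graphs serialize and
  relabel (via the wrap-around rule); a threshold at or above `wmax` yields
  edgeless channels; constant activity gives weight-0 edges; `nc = 1`
  degenerates to `ugevia` on the single thresholded channel.

## 8. Problem sizes

The shipped tests run the five-vertices experiments at the full 3,000-graph
benchmark scale and the simulation pipeline at 100 windows per condition
(200 graphs of 100 neurons), sizes chosen so the whole suite completes in
minutes on one CPU while keeping every qualitative regime (dense and empty
channels, both conditions, all four classifiers) exercised.  The
acceptance script uses the same sizes.

## 9. Known limitations

* Anticorrelations never reach any channel (section 3).
* The embedding is transductive: paragraph vectors exist only for graphs
  present at training time; embedding new graphs means re-training.
* Classifier and embedder hyperparameters are fixed, not searched; the
  package deliberately ships the tuned values as constants.
* The simulator is a purpose-built surrogate generator, not a calibrated
  model of any particular imaging preparation.
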