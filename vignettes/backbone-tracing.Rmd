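---
title: "Tracing protein backbones in cryo-EM density with voxtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing protein backbones in cryo-EM density with voxtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxtrace)
```

## The problem

A cryo-EM density map is a 3D scalar field sampled on a voxel grid with a
physical voxel size in Ångström. De novo model building asks for an atomic
model — here, the Cα backbone with per-residue amino-acid identities — using
only the map and the protein's chain sequences, with no homologous structure
as a template. `voxtrace` splits the problem into an atom *recognition* task
(which voxels hold a Cα atom, and of which amino-acid type?) and a
*registration* task (which residue of which chain sits on which predicted
atom?), solved respectively by a voxel classifier and by a hidden Markov
model decoded under a no-repeat constraint.

## Voxel classification

The classifier is a transformer encoder over 3D patches feeding a
convolutional decoder. A 32³ sub-grid with one density channel is cut into
(32/16)³ = 8 patches of edge 16, each flattened and projected to a 768-dim
embedding; a learnable 1D positional encoding is added. Twelve identical
blocks (layer norm, 12-head self-attention, layer norm, MLP of width 3072,
residual connections, dropout 0.1 during training) process the tokens.
Features tapped after blocks 3, 6, 9 and 12 are reshaped to 2³ grids and
upsampled ×2 per stage by transposed convolutions, concatenated U-Net-style
with the next-deeper stage and refined by 3³ convolutions with instance
normalization and Leaky-ReLU; the raw density enters through a stem
convolution at full resolution. A 1×1×1 convolution maps the final 16
feature channels to the per-voxel class logits. Two instances are used: 4
output classes for backbone atoms (Cα, C, N, none) and 21 for amino-acid
types (20 + none).

Not every width of this architecture is published. The encoder dimensions
are; the decoder stage widths are not, but the two published totals —
92,281,604 trainable parameters for the 4-class model and 92,281,893 for the
21-class model — pin them down tightly. Their difference, 289 = 17 × 17,
forces the final feature width to 16 channels (only the 1×1×1 head depends
on the class count), and the stage widths (121, 80, 68, 31) used here were
solved numerically so that both totals are met exactly; the remaining
freedom in how the budget is split across stages does not affect any other
published quantity. MLP width (4 × embedding) and 12 heads are the standard
choice for 768-dim encoders.

Voxel classes are extremely imbalanced (almost all voxels contain no
backbone atom), so training minimizes a weighted cross-entropy: the weight
of class c is one minus its sample share, `w_c = 1 − n_c / Σ_k n_k`, which
gives rare classes weight near 1 and sums to C − 1 across C classes. The
loss divides by the *sample count* N, not by the sum of selected weights —
a deliberate departure from common library conventions, pinned by a
regression test (the two-class case with weights 0.3/0.7 and uniform logits
must equal 0.7·ln 2). The toy training loop uses NADAM (learning rate 1e-4),
reduces the rate by a factor 0.1 after 5 epochs without validation-loss
improvement, and keeps the model with the best validation macro-F1.
Training at production scale (thousands of maps, large batches, many
devices) is out of scope; the loop here exists to demonstrate that the
architecture, loss and optimizer learn, which the suite checks by
overfitting a handful of labeled synthetic sub-grids at a reduced width.
Everything — forward pass, layer-wise backpropagation, the optimizer — is
implemented on plain BLAS matrix algebra: 3D convolutions are sums over
kernel offsets of shifted-input matrix products, so no deep-learning
framework is needed, and a full-size forward pass runs in a few seconds on
one CPU core.

At inference the map is min-max normalized (negatives clamped to zero),
tiled into non-overlapping zero-padded 32³ sub-grids, classified, softmaxed
voxel-wise and stitched back. Whether the original inference tiles overlap
is not published; non-overlap is the simplest cover consistent with the
sub-grid training regime. The prediction source is pluggable — trained
networks, precomputed probability grids, or a surrogate function — so the
geometric pipeline downstream can be exercised without trained weights.

## From voxels to atoms

Voxels with P(Cα) strictly above 0.4 become candidates; each carries its
voxel-center world coordinate and its amino-acid probability vector with the
none/unknown class dropped and the remaining 20 renormalized (emissions are
defined over 20 symbols). Candidates within 2 Å are grouped — read here as
single-linkage connected components, since the grouping rule's algorithm is
not published — and each cluster is represented by its *medoid* (the member
minimizing summed distance to the others; ties broken by higher Cα
probability, then lower coordinate order), keeping an actual voxel rather
than a synthetic centroid. Cluster probabilities are member means, with
amino-acid means renormalized. Clustering is order-independent and conserves
voxel counts; with a vanishing radius it is the identity.

## The HMM and its decoder

One hidden state per clustered atom; the model is fully connected. The
transition probability from state i to j is a Gaussian density of their
distance centered at μ = 3.8047 Å with spread Λσ = 0.36 Å (σ = 0.036 Å is
the empirical standard deviation of consecutive Cα distances; the scale
Λ = 10 deliberately widens it so that voxel-center discretization of about
half a voxel diagonal does not zero out true transitions). Rows are
normalized with a zero diagonal — a residue cannot succeed itself. All
scoring is in natural-log space; a row whose densities all underflow stays
−∞ cleanly rather than becoming NaN. Emissions are the normalized geometric
mean of the predicted amino-acid probabilities and a background frequency
vector; the bundled default background is the Swiss-Prot average
composition, configurable, since the reference background values are not
published numerically. The initial distribution is rebuilt per chain from
the chain's first residue (an open reading; rebuilding per chain matches the
emission-based definition).

The decoder is a Viterbi variant in which a state may occur at most once in
a path. The published pseudocode's update line is not index-consistent as
printed; the reading adopted here is the standard recurrence
`T1[i,j] = max_k (T1[k,j−1] + log γ[k,i]) + log δ[i,O_j]` restricted to
states not yet committed, with a greedy commit: after each column the column
argmax z_j joins the visited set and its row is frozen at −∞ from the next
column on. Freezing one column after commitment means the most recent commit
remains the natural predecessor of the current column (the chain stays
connected) while earlier commits drop out automatically. The first path
state is the backpointer of the second column's commit and is committed as
well, which makes the no-repeat property structural rather than emergent.
Ties break toward the lowest state index, making the decoder fully
deterministic. The suite holds this decoder to three oracles on hundreds of
random instances: no repeated states ever; the path's log-probability never
exceeds the exact optimum over all simple paths found by exhaustive
enumeration; and path-identity with an independently coded reference of the
same recurrence. Exact optimal simple-path decoding is NP-hard in general,
so the greedy-commit path can score below the enumeration optimum on
adversarial instances — that gap is the price of polynomial time, and on
backbone-like geometry it is rarely realized.

Chains are aligned longest-first (ties by input order; longer chains are
more geometry-constrained), and each aligned chain's states are removed —
with surviving transition rows renormalized — before the next chain. As long
as the state count is at least the total residue count, every residue is
assigned a Cα position; otherwise the run fails early with the two counts
and the advice to lower the selection threshold.

## Confidence scores

Two logistic regressions convert pipeline quantities into per-residue
probabilities of correctness: the Cα model uses the atom's predicted Cα
probability as its single feature; the amino-acid model uses the emission
probability at the aligned position, the Cα probability, and a 20-dim
one-hot of the assigned type (22 features, linear — no interactions, the
simplest reading of the published form). Training labels come from 3 Å
one-to-one matching against a reference: matched → Cα label 1; matched and
type-identical → amino-acid label 1. Fits are by maximum likelihood
(`stats::glm`); on separable data the fit is repeated with a small ridge
(1e-6) via IRLS so it stays finite and deterministic. No reference
coefficients are published, so the package ships unfit and provides
fit/apply plus planted-coefficient recovery tests (±0.15 at n = 5000).
Structure-level confidence is the mean of per-residue scores, exactly.

## Evaluation metrics

Model and reference are matched greedily: repeatedly pair the globally
closest unmatched residues within 3 Å, ties broken by model then reference
index. Recall divides matches by reference residues, precision (the Cα
match score, as a percentage) by model residues; F1 is their harmonic mean;
the sequence match score is the type-identical fraction of matched pairs;
and the Cα quality score multiplies the match fraction by model coverage
(model residues / reference residues), clamped to [0, 1]. Two caveats are
worth stating plainly. First, under this package's internal one-to-one
matching the quality score algebraically equals recall; it earns its keep
when the match counts come from external comparison tools with different
counting conventions, which is also the only way the clamp can trigger.
Second, greedy globally-nearest matching is not a maximum-cardinality
matching in the graph-theoretic sense — on dense uniform point clouds it
can pair one fewer residue than the optimum. On backbone-like inputs, where
atoms keep ≥ 3 Å separation, the suite verifies it attains the brute-force
optimum on every tested instance. The reference matcher used in the
original comparisons is a closed tool whose pairing rules are not public;
small divergences on dense structures are expected.

## The synthetic generator — what it does and does not emulate

`generate_protein()` draws self-avoiding random walks whose bond lengths
follow N(3.8047, 0.036) truncated to [3.6, 4.0] Å, bond angles uniform in
[80°, 150°], atoms at least 3 Å apart, and sequences drawn from the
background composition. The bond-length σ is kept at the transition model's
own 0.036 Å — real backbones vary more — precisely so that recovery
failures are attributable to the algorithms rather than to model mismatch.
`rasterize()` sums unit Gaussian blobs (σ = 1 Å) at Cα positions on a 1 Å
grid with 10 Å padding, adds weaker pseudo C/N blobs at the third-points of
consecutive Cα segments (cosmetic: downstream uses Cα only), min-max
normalizes, and labels the voxel nearest each atom — exactly one Cα voxel
per residue. `simulate_predictions()` mimics classifier output: mass
`correct_prob` on the true class, the rest uniform, with a configurable
false-positive rate at empty voxels. What this does **not** emulate:
resolution-dependent blurring and anisotropy, solvent noise, side-chain
density, missing density, or correlated classifier errors. Passing the
synthetic end-to-end tests therefore demonstrates the correctness of the
geometry/decoding machinery under the model's own assumptions, not
benchmark-level accuracy on experimental maps, which requires trained
weights and real data and is explicitly out of scope here.

## Numerical and design choices

* Voxel indices are 0-based; a voxel's world coordinate is its center,
  `origin + index · voxel_size`. One stated convention avoids half-voxel
  drift between label grids and coordinates.
* Map I/O accepts mode-2 (float32) MRC/CCP4 with any MAPC/MAPR/MAPS axis
  permutation and orthogonal cells; the origin falls back to
  `NxSTART · voxel_size` when the MRC2014 ORIGIN record is zero. Anisotropic
  voxel sizes are accepted with a warning.
* All stochastic components are pure functions of explicit seeds; the
  pipeline is deterministic given inputs, config and seed (the suite
  compares PDB outputs byte for byte).
* Degenerate inputs are contracts, not crashes: all-zero emission rows fall
  back to uniform with a warning, flat transition models still yield valid
  non-repeating paths, empty candidate sets are legal.

## Problem sizes used by the test suite

The suite runs entirely on one CPU core: toy proteins of 8–30 residues per
chain (50-residue two-chain complexes for the end-to-end recovery checks,
20 seeds), decoder oracles at K ≤ 7 states and T ≤ 4 observations (200
instances, exhaustive enumeration stays trivial), gradient checks and toy
training at a reduced network width, and two full-size (92M-parameter)
network builds for the parameter-count checks. These sizes were chosen so
that every oracle remains exactly computable; the algorithms themselves are
size-independent.

## Known limitations

Decoding is greedy per column, not globally optimal over simple paths;
severely fragmented or low-confidence predictions can derail the register
even when many atoms are correct (one of the twenty seeded end-to-end
replicates lands at ~82% for this reason). The evaluation matcher is a
reimplementation from the published metric definitions, not a bit-exact
replica of external tools. Output models are Cα-only; no side chains, no
C/N backbone atoms, no mmCIF. Confidence models ship unfit and must be
trained on data with a reference structure.
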