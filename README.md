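# voxtrace

De novo Cα backbone tracing from cryo-EM density maps in R.

Given a density map and the protein's chain sequences, `voxtrace` builds an
all-Cα atomic backbone in five stages:

1. **Voxel classification.** A transformer encoder over 3D patches with a
   convolutional U-Net-style decoder assigns every voxel of each 32³ sub-grid
   a backbone-atom class (Cα, C, N, none) and an amino-acid class (20 types +
   none). Training uses a weighted cross-entropy loss
   `L = -(1/N) Σₙ Σ_c w_c y_{n,c} log softmax(x_n)_c` with class weights
   `w_c = 1 − n_c / Σ_k n_k` to counter the extreme voxel-class imbalance.
2. **Cα extraction.** Voxels with P(Cα) > 0.4 are clustered
   (single linkage, 2 Å) into atoms; each cluster keeps its medoid voxel and
   the mean probabilities.
3. **HMM construction.** One hidden state per predicted Cα atom. Transition
   probabilities come from a scaled Gaussian density of the inter-atom
   distance, `f(x) = exp(−(x−μ)²/2(Λσ)²) / (Λσ√2π)` with μ = 3.8047 Å,
   σ = 0.036 Å, Λ = 10 (the consecutive-Cα distance statistics of real
   structures), row-normalized with a zero diagonal. Emissions are normalized
   geometric means `√(a_v b_v)` of the predicted amino-acid probabilities `a`
   and background frequencies `b`; the initial distribution is the normalized
   emission of the chain's first residue.
4. **Sequence alignment.** A customized Viterbi decoder aligns each chain to
   the HMM under the constraint that a hidden state occurs at most once in a
   path (one atom hosts one residue); after each chain, its states are
   removed before the next chain is aligned. Every residue gets a Cα
   position whenever the state count is at least the residue count.
5. **Confidence and evaluation.** Two logistic regressions score per-residue
   Cα and amino-acid reliability; reference-based metrics (3 Å one-to-one
   matching, recall/precision/F1, Cα match, sequence match and Cα quality
   scores) quantify model quality.

A synthetic-data generator (backbones with the exact bond-length statistics
the HMM assumes, Gaussian-blob density maps, label grids, and noisy surrogate
classifier output) makes every stage testable without experimental maps or
trained weights.

## Worked example

```r
library(voxtrace)

prot   <- generate_protein(2, c(20, 30), seed = 11)        # two-chain toy protein
bundle <- rasterize(prot)                                  # density map + labels
preds  <- simulate_predictions(bundle, correct_prob = 0.95,
                               fp_rate = 0.001, seed = 12) # surrogate classifier
run    <- run_pipeline(bundle$grid, protein_sequences(prot), preds)
run
#> <voxtrace_run> 172 candidate voxels -> 170 atoms -> 50 residues aligned over 2 chain(s)

cat(report_metrics(evaluate_model(run$model, protein_structure(prot)), "text"))
#> recall               0.980
#> precision            0.980
#> F1                   0.980
#> Ca match score       98.0%
#> sequence match score 100.0%
#> Ca quality score     0.98
#> matched / model / reference   49 / 50 / 50
```

49 of the 50 placed residues land within 3 Å of their true positions
(recall/precision 0.98) and every matched residue carries the correct
amino-acid type (sequence match 100%); the quality score 0.98 combines
precision with coverage. `write_pdb(run$model, "model.pdb")` exports the
backbone with confidences in the B-factor column.

A command-line interface wrapping the same functions is installed at
`system.file("scripts", "voxtrace", package = "voxtrace")` with subcommands
`build`, `evaluate`, `synth`, `train-toy` and `fit-confidence`.

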