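# rgtsite

Per-residue prediction of small-molecule (e.g. ATP) binding sites on
protein chains with a residual graph transformer network, in pure R (plus
two compiled attention kernels).

Binding-site identification is a severely imbalanced residue-level
classification problem: in curated ATP-binding chains roughly one residue
in 22–27 contacts the ligand. `rgtsite` represents a chain as a residue
contact graph — vertices at the C-alpha atoms, edges where the C-alpha
distance is ≤ 8 Å — and classifies every vertex.

**Vertex features (2084-dim)** concatenate three blocks: local sequence
features from a residual three-layer 1-D CNN over a learned 1024-dim
embedding of the label-encoded sequence (kernels 3/5/7, two skip
connections); 1024-dim per-residue embeddings from a pluggable protein
language model provider (a deterministic stub ships with the package); and
36 physicochemical/geometric descriptors (one-hot residue type, molecular
weight, pKa/pKb/pKx, hydrophobicity at pH 2 and 7, intra-residue and
backbone distances, phi/psi/omega/chi1 torsions). **Edge features
(6-dim)** carry the contact indicator, C-alpha and centroid distances,
min/max cross-residue atom distances, and an orientation cosine.

**The network**: Laplacian positional encodings (eigenvectors of
`I − D^{−1/2} A D^{−1/2}`) added to linear projections of the vertex
features; per block, edge-gated multi-head attention (8 heads, gates from
projected edge features applied before the softmax, residual vertex and
edge updates), an edge-weighted graph convolution
`ReLU(D^{−1/2}(A∘W+I)D^{−1/2} H Wx) + MLP(H)` whose weights are learned
from the updated edge features, dropout, and a residual feed-forward stage
with layer normalization; then a 64–16–1 sigmoid classifier head.
**Training**: asymmetric loss `L⁺ = (1−p)^{γ⁺}(−log p)`,
`L⁻ = p_m^{γ⁻}(−log(1−p_m))` with `p_m = max(p−m, 0)` (defaults γ⁺ = 0,
γ⁻ = 4, m = 0.05), Adam (lr 1e-4, weight decay 5e-5, eps 1e-7, betas
0.9/0.999), one chain per step, 10% chain-level validation split, early
stopping with patience 10. All gradients are hand-derived and verified
against finite differences in the test suite.

Everything is exercised end to end on synthetic chains: self-avoiding
C-alpha traces with planted, geometrically realistic binding pockets and a
deterministic stand-in embedding provider, so no downloads or external
models are needed. See `vignettes/rgtsite-methods.Rmd` for the full model
description and design rationale.

## Worked example

```r
library(rgtsite)

# the synthetic study system: 50 chains with planted pockets at the
# ~1:20 class imbalance of real binding-site data
ds <- make_dataset(synthetic_dataset_spec(n_chains = 50, seed = 1))
head(ds$manifest, 3)
#>     id chain_id n_residues n_positive split
#> 1 S001        A        103          8 train
#> 2 S002        A        138          8 train
#> 3 S003        A        100          5 train

# the package's standing experiment: train the tiny model on the training
# chains and score the 10 held-out chains (about 3 minutes per seed)
learnability_study(ds, seeds = 1L)
#>   seed epochs best_epoch pooled_F1 pooled_MCC  macro_F1 macro_MCC
#> 1    1    260        202  86.81319  0.8623339 87.65706 0.8754358
```

Pooled scores compute the six metrics on confusion counts summed over the
held-out chains; macro scores average per-chain metrics, the aggregation
used for per-chain case studies. An F1 of 86.8% and MCC of 0.86 mean the
planted geometric pocket signal is recovered almost completely on unseen
chains; a label-shuffled control trained identically scores MCC 0 (see
the acceptance script). Individual chains flow through
`parse_pdb_chain()` → `featurize_chain()` → `predict_chain()`, and
`category_manifest()` emits the per-residue TN/TP/FP/FN table viewers
color by.

A command-line interface wraps the same pipeline:

```sh
rgtsite make-synthetic --out data/ --n-chains 50 --seed 1
rgtsite train --data data/ --out run/ --config train.yaml
rgtsite predict --data data/ --checkpoint run/checkpoint.rds --out pred.tsv
rgtsite evaluate --counts 14,1,288,1
#> Sen 93.33 Spe 99.65 Acc 99.34 Pre 93.33 F1 93.33 MCC 0.93
```

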