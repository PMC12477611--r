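# smofuse

Joint representation learning for **two spatial omics modalities**
measured on the same tissue section — RNA with ADT surface proteins
(SPOTS, Stereo-CITE-seq, spatial CITE-seq), RNA with ATAC chromatin
accessibility (MISAR-seq, spatial ATAC-RNA-seq), or RNA with any other
non-negative assay. The package learns a fused low-dimensional embedding
of the spots and clusters it into spatial domains, for analysts who want
domain maps that exploit the complementarity of the two layers instead
of either one alone.

## The model

Spots are joined by a Gaussian kernel on physical distance,
`A_ij = exp(-d(i,j)^2 / (2 lambda^2))`, sparsified to mutual k-nearest
neighbours. Each modality is encoded by a graph convolutional network
over the symmetric-normalised operator `D^{-1/2}(A + I)D^{-1/2}`,
refined by the parameter-free global self-attention
`E_A = softmax(E E' / sqrt(g)) E`. Four losses are minimised jointly:

| term | what it does |
|---|---|
| `L_CE` | two-class cross-entropy of an omics-label head on the stacked embeddings; preserves modality-specific character |
| `L_con` | `‖C̃₁C̃₁' − C̃₂C̃₂'‖²_F / N²` between row-normalised Gram matrices of the two common-space projections; aligns cross-spot structure |
| `L_reg` | `Σ P_ij (1 − Q_ij) / N²`, spatial-kernel-weighted embedding similarity; keeps spatial neighbours close in the embedding |
| `L_Recon` | omics-specific negative log-likelihoods (below) |

with total loss `L = a L_CE + b L_con + c L_reg + d L_Recon`
(all weights default 1). The joint representation is
`Z = α E_A1 + β E_A2 + γ E_C` where `E_C` fuses the common-space
projections.

Reconstruction is omics-aware: a **zero-inflated negative binomial**
(π, μ, θ) for RNA counts, a **Bernoulli** for binarised accessibility, a
**background/foreground negative-binomial mixture** with a
GMM-initialised log-normal background prior for ADT counts (foreground
`ν_f = (1+α)ν_b ≥ ν_b` by construction), and a generic cross-entropy
decoder for anything else. Optimisation is full-batch Adam over a
reverse-mode gradient tape built into the package; runs are bitwise
reproducible on CPU given a seed.

See `vignettes/spatial-multiomics-fusion.Rmd` for the full account of
the model, its assumptions, defaults and limitations.

## Worked example

The built-in complementary benchmark generates 2024 spots in four block
domains where the RNA markers separate only top from bottom and the
ATAC markers only left from right — each modality alone resolves two
groups, only the fusion resolves four:

```r
library(smofuse)

bundle <- makeComplementaryBenchmark(seed = 1)
bundle$pair
#> SpatialOmicsPair over 2024 spots
#> OmicsMatrix [rna]: 2024 spots x 150 features (encoder input: 150 features)
#> OmicsMatrix [atac]: 2024 spots x 150 features (encoder input: 150 features)

buildSpatialGraph(bundle$pair@coords)
#> SpatialGraph: 2024 spots, 8008 undirected edges, lambda=1, k=6
#>   normalized operator: built

jr <- trainFusion(bundle$pair, config = trainConfig(epochs = 40, seed = 1))
jr
#> JointRepresentation: 2024 spots x 64 dims; 40 epochs, final loss 5.82e+05

clusterEmbedding(jr, "kmeans", k = 4, seed = 1, truth = bundle$truth)
#> ClusteringResult [kmeans]: 2024 spots, 4 clusters, ARI = 1.000

rna <- singleModalityMode(bundle$pair, 1,
                          config = trainConfig(epochs = 40, seed = 1))
clusterEmbedding(rna, "kmeans", k = 4, seed = 1, truth = bundle$truth)
#> ClusteringResult [kmeans]: 2024 spots, 4 clusters, ARI = 0.477
```

The fused embedding recovers all four planted domains exactly
(ARI = 1.0 against the generated ground truth), while the RNA-only model
tops out near ARI ≈ 0.48 — it nails its own two-way split but can only
guess within it, which is precisely the information bound the benchmark
constructs.

Real data comes in through `loadPair()` (dense CSV or MTX + TSV
sidecars per modality, plus a coordinates CSV; spots are aligned by
barcode intersection), and results leave through `saveResults()`
(spot-keyed embedding, labels, loss trace, manifest). A thin CLI wraps
the same functions:

```sh
Rscript inst/scripts/smofuse simulate --kind benchmark --seed 1 --out sim/
Rscript inst/scripts/smofuse run --config cfg.yaml --out out/
Rscript inst/scripts/smofuse cluster --embedding out/Z.csv --k 4
```

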