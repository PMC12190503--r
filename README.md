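# phidnet

Dynamic-synergy brain network analysis via integrated information
decomposition (ΦID).

Conventional functional connectivity (Pearson correlation, mutual
information) measures how similarly two brain regions fluctuate. It says
nothing about whether the two regions *jointly* carry information that
neither carries alone. `phidnet` implements the persistent-synergy
alternative for staged neurodegeneration studies: every region pair's lagged
dynamics are decomposed into the 16 information atoms of ΦID, the
syn→syn atom (information the joint past carries about the joint present
exclusively synergistically) becomes the edge weight of a subject's network,
and stage-contrast statistics then flag regions whose synergistic capacity
declines as disease progresses.

The package covers the full pipeline:

1. **Synthetic cohorts** — a stationary VAR(1) surrogate BOLD generator with
   stage-specific attenuation of coupling at designated ground-truth nodes,
   so every downstream step is testable without clinical data.
2. **ΦID core** — Gaussian minimum-mutual-information (MMI) ΦID of a
   two-region lagged system. With `A` and `B` subsets of the stacked vector
   `(x1_{t-τ}, x2_{t-τ}, x1_t, x2_t)`, mutual informations are computed in
   closed form, `I(A;B) = ½·log₂(det Σ_A · det Σ_B / det Σ_{A∪B})` bits; the
   lattice's cumulative values are 9 plain MIs, 3 forward and 3 backward MMI
   redundancies (minima over source/target components) and the predefined
   double redundancy `min_{ij} I(x_i,t-τ; x_j,t)`; atoms follow by Möbius
   inversion over the product order, and their sum equals the time-delayed
   mutual information exactly.
3. **Connectivity** — per-subject region × region matrices under `syn`
   (lagged, default τ = 1 sample) or `mi` (instantaneous) weights.
4. **Single-subject reconstruction** — against the control average `C`:
   `F = (R − C) / ((R² + C²)/2)`, `W = 1 − tanh(F) ∈ (0, 2)`, `X = W·C`.
5. **Graph metrics** on top-10 % sparsified networks — characteristic path
   length (Dijkstra over edge lengths `1/w`), weighted clustering
   `C_i = Σ_{j,k} (w_ij w_jk w_ki)^{1/3} / (k_i(k_i−1))`, communication
   capacity `D_i = Σ_j w_ij / dist_ij` (Euclidean inter-centroid mm), degree
   centrality `k_i/(n−1)`, and per-network summaries.
6. **Stage statistics** — pooled two-sample t per node, Benjamini–Hochberg
   FDR across nodes, Cohen's `d = t·√(1/n1 + 1/n2)`, change scores
   `CS(k) = (ā_k − b̄_k) / mean(ā − b̄)` (ΣCS = n), and the selection rule
   `q < 0.05 ∧ CS > 6`.

## Worked example

Decompose a cross-coupled VAR pair analytically (no estimation noise):

```r
library(phidnet)
model <- var_model(matrix(c(0.2, 0.5, 0.5, 0.2), 2, 2))
phiid_decompose(lagged_pair_model(model, 1, 2))
#> PhiID atoms (MMI, bits); tau = 1
#>       target
#> source    red     un1     un2     syn
#>    red 0.0891  0.0000  0.0000  0.2176
#>    un1 0.0000  0.0000  0.1781 -0.1781
#>    un2 0.0000  0.1781  0.0000 -0.1781
#>    syn 0.2176 -0.1781 -0.1781  0.3856
#> TDMI: 0.553746  sum of atoms: 0.553746
```

The cross-coupling puts 0.386 bits into syn→syn — the pair's persistent
synergy — while the atoms still sum exactly to the time-delayed mutual
information (0.554 bits).

Run the full pipeline on a simulated four-stage study (20 regions, 10
subjects per stage, two hub nodes attenuated to 50 % coupling from the EMCI
stage on):

```r
res <- run_pipeline(pipeline_config(profile = "small", seed = 1,
                                    out_dir = "run"))
res$bundle$ground_truth[[1]]$regions
#> [1] "ROI_018" "ROI_002"
head(as.data.frame(res$comparisons$syn_comm_capacity_CN_EMCI), 5)
#>    region      t      p     q    cs selected
#> 1 ROI_018 -2.701 0.0146 0.199 13.74    FALSE
#> 2 ROI_002 -2.217 0.0397 0.199  7.71    FALSE
#> 3 ROI_005 -2.300 0.0337 0.199  7.52    FALSE
#> 4 ROI_006 -0.983 0.3384 0.677  5.32    FALSE
#> 5 ROI_020 -1.264 0.2225 0.677  3.15    FALSE
```

The two ground-truth nodes rank first and second by change score in the
CN–EMCI synergy comparison (at this small cohort size they do not survive
FDR, hence `selected = FALSE`; the 90-region profiles do, see the vignette).
All stage artifacts — study TSVs, connectivity and reconstructed matrices,
node-metric tables, comparison tables, the before/after-reconstruction
validation table and a run manifest — are written under `run/`.

A thin command-line wrapper over the same functions ships in
`inst/scripts/phidnet.R` (subcommands `run`, `validate`, `simulate`,
`phid-atoms`).

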