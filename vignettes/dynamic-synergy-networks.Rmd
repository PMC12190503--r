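---
title: "Dynamic synergy networks: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic synergy networks: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phidnet)
```

This vignette is the package's account of its science: the information
decomposition it computes, the estimators and their assumptions, the
synthetic-data generator and what it does and does not emulate, and the
design decisions taken where the methodology was genuinely open.

## 1. The decomposition

For two regional time series, the time-delayed mutual information
$\mathrm{TDMI} = I(X_{t-\tau}; X_t)$ between the joint past
$X_{t-\tau} = (x^1_{t-\tau}, x^2_{t-\tau})$ and the joint present
$X_t = (x^1_t, x^2_t)$ measures everything the pair's past says about its
future. Integrated information decomposition (ΦID) splits that quantity
into 16 atoms indexed by a (source pattern → target pattern) pair over the
four partial-information patterns red (redundant), un1/un2 (unique) and syn
(synergistic), ordered by red ≺ un1 ≺ syn and red ≺ un2 ≺ syn with un1, un2
incomparable; the atom lattice is the product of that order with itself.

The cumulative value $I_\cap^{\alpha\to\beta}$ (the sum of atoms at or below
a lattice node) is evaluated as:

* a plain mutual information when both patterns are single variable
  collections (un1 ↔ {1}, un2 ↔ {2}, syn ↔ {1,2}): 9 nodes;
* the MMI redundancy — a minimum over the single-source (or single-target)
  mutual informations — when one side is the redundancy antichain: 3
  forward and 3 backward nodes;
* the predefined double redundancy
  $\min_{ij} I(x^i_{t-\tau}; x^j_t)$ for red → red.

That is 15 constraint equations plus the double redundancy, determining all
16 cumulative values; the atoms $I_\partial$ follow by Möbius inversion over
the product order (`phiid_decompose()` traverses the nodes in topological
order and subtracts the strictly-lower atoms; an equivalent dense
zeta-matrix solve is used as an independent oracle in the tests). Because
the syn → syn node is the lattice top, conservation
$\sum I_\partial = \mathrm{TDMI}$ holds to solver precision by construction,
and the suite verifies it to $10^{-9}$ bits against covariances it did not
construct.

The syn → syn atom — information carried about the joint future only by the
joint past, over and above everything available redundantly or uniquely —
is the **persistent synergy** used as an edge weight. Conceptually it
captures cross-regional collaborative processing that pairwise similarity
measures cannot see.

### A known property of the MMI redundancy worth stating plainly

MMI defines redundancy as a minimum of magnitudes. Two *independent*
channels of equal strength therefore count as fully redundant: for two
uncoupled AR(1) regions with coefficient 0.8, each channel's self-prediction
is $m = -\tfrac12\log_2(1-0.8^2) = 0.737$ bits, and the decomposition yields
not only $I_\partial^{un1\to un1} = I_\partial^{un2\to un2} = m$ but also
$I_\partial^{red\to syn} = I_\partial^{syn\to red} = m$, mixed atoms $-m$,
and $I_\partial^{syn\to syn} = \mathrm{TDMI} = 2m$ — nonzero "synergy"
between regions that never interact, driven purely by matched
autocorrelation. This is not an implementation artifact: it follows
directly from the definitions above, and the test suite freezes exactly
these values (verified by the independent zeta-solve oracle). Users should
read synergy networks with this in mind: edges reflect joint
predictability, which coupling *and* matched strong autocorrelation both
produce. The weaknesses of min-based redundancy are a known limitation of
the framework, not something this implementation attempts to patch.

## 2. Estimation

BOLD dynamics at the TR timescale are well described by linear Gaussian
models, so all informations are computed in Gaussian closed form — no
probability mass functions are ever materialized. `estimate_lagged_covariance()`
z-scores each series over its full length, aligns past and present segments
at lag τ, and takes the 4×4 sample covariance of the stacked vector; a
ridge of $10^{-8}$ on the diagonal keeps degenerate inputs (an exact copy
of a region) positive definite, and a condition-number guard at $10^{12}$
rejects numerically singular submatrices rather than returning noise.

Tunable parameters:

* **τ (lag, samples)** — default 1, i.e. one TR. One sample is the minimal
  nontrivial choice for slow fMRI dynamics; it is a configuration knob
  (`tau`) everywhere.
* **ridge** — $10^{-8}$, in units of (z-scored signal)²; large enough to
  regularize exact duplicates, five orders below any meaningful
  correlation structure.
* All information is reported in **bits** (log base 2).

Atoms can be slightly negative under MMI; the core reports raw values.
Flooring negative synergy estimates to zero is a connectivity-level policy
(`build_matrix()`), because the downstream cube-root triangle products and
reciprocal edge lengths are undefined for negative weights; the count of
floored entries is kept on the matrix object and surfaced in the pipeline
manifest.

`build_matrix()` computes one covariance of the stacked past/present block
per subject and hands the pair loop (~4000 pairs at 90 regions) to a small
RcppArmadillo kernel; a pure-R reference engine computes identical values
(asserted to $10^{-12}$) and serves as the readable specification. The `mi`
method is the instantaneous (zero-lag) Gaussian mutual information
$-\tfrac12\log_2(1-\rho^2)$ of the z-scored pair — the conventional static
counterpart against which synergy is compared.

## 3. Single-subject reconstruction

Raw connectivity matrices vary strongly between individuals. The
reconstruction step re-expresses each subject relative to the control
average $C$: $F = (R-C)/((R^2+C^2)/2)$, $W = 1-\tanh F \in (0,2)$,
$X = W\cdot C$. Properties the tests pin down: the control average is a
fixed point; $X = 0$ wherever $C = 0$ (no edges are invented); cells with
$R = C = 0$ take $F = 0$ by continuity (the transform is otherwise 0/0
there). Note the transform's direction: a subject *weaker* than the
reference gets $W > 1$, i.e. deviation from the control mean is amplified
relative to $C$ — this is what restores statistical power at group level.

The reference includes **all** control subjects by default, including any
control later compared against it; no leave-one-out protocol is prescribed
for the reference in the source methodology. Because that choice leaks a
small optimism into control-group comparisons, `reconstruct_cohort(...,
loo = TRUE)` excludes each control from its own reference as a robustness
option.

## 4. Graph metrics

Sparse graphs retain the top `ceiling(fraction × n(n−1)/2)` upper-triangle
weights (default fraction 0.10; at 90 regions, exactly 401 of 4005), with
ties broken lexicographically by index so results are deterministic.
Ceiling rounding is monotone and never empties a graph at positive
fractions. Retained cells whose weight is exactly zero (possible after
synergy flooring) contribute no edge.

* **Characteristic path length** uses edge lengths $1/w$ — the standard
  weighted-connectome convention, and nonnegative as Dijkstra requires
  (igraph provides the shortest paths). Unreachable pairs are excluded
  from the mean rather than imputed; their count is attached to the result.
* **Weighted clustering** uses the cube-root triangle form with *binary*
  degree $k_i$ in the denominator, on raw weights exactly as retained (no
  max-weight normalization), so values exceed 1 when weights do. Nodes
  with degree < 2 score 0.
* **Communication capacity** $D_i = \sum_j w_{ij}/\mathrm{dist}_{ij}$
  divides each retained weight by the Euclidean distance between region
  centroids (mm); connected regions with identical centroids are rejected
  by name.
* **Per-network summaries** pair each network's members with their
  *complement* (network-to-rest), the reading adopted for "between a
  network and other brain regions"; a network covering all nodes has no
  such pairs and reports `NA` with a warning.

All four metrics are verified against brute-force oracles (Floyd–Warshall,
literal triple loops) to $10^{-9}$ on random graphs, and the documented
scaling laws (weights × c ⇒ L/c, D×c, C×c, degree unchanged) are asserted.

## 5. Stage statistics

`two_sample_t()` is the pooled-variance Student t by default — the printed
effect sizes in the source tables are consistent with
$d = t\sqrt{1/n_1+1/n_2}$ applied to the printed t values, which presumes
the pooled form — with Welch behind `var_equal = FALSE`. The implementation
is the direct formula (vectorizes across thousands of simulated
comparisons); `stats::t.test` is the reference oracle in the suite.
FDR correction is Benjamini–Hochberg (`stats::p.adjust`), the conventional
reading of "FDR correction" absent a stated procedure.

**Change score sign.** The printed definition has numerator
$\bar a_k - \bar b_k$ (earlier minus later stage) but a denominator that
averages $\bar b_i - \bar a_i$; for any coherent decline the two signs
cancel and every CS would come out negative, yet declining nodes are
reported with positive scores above a threshold of 6. The sign-corrected
form $CS(k) = (\bar a_k - \bar b_k) / \mathrm{mean}(\bar a - \bar b)$ is
therefore the default — each node's decline relative to the mean decline,
with $\sum_k CS = n$ exactly — and the literal printed form is available as
`as_printed = TRUE` for auditability (its scores sum to $-n$).

**A degeneracy worth knowing.** Under proportional thresholding every
subject's graph has the same number of retained edges, so when none of them
are zero-weight the *total* degree is a per-subject constant and the
network-average change of degree centrality is exactly zero — the change
score is then undefined. `change_score()` rejects this case per contract;
the pipeline logs and skips such comparisons instead of aborting the run.
Synergy matrices escape the degeneracy in practice because floored
zero-weight cells make the effective edge count vary.

`compare_stages()` treats a node whose metric is constant *and equal* in
both groups (isolated in every subject) as neutral (t = 0, p = 1) rather
than fatal; the standalone `two_sample_t()` keeps its strict zero-variance
rejection.

## 6. The synthetic-data generator

The generator's purpose is ground truth, not biophysical realism. Subjects
are draws from a stationary VAR(1) process
$x_t = A\,x_{t-1} + \varepsilon_t$, the minimal generative model consistent
with the lagged Gaussian framework:

* **Base coupling** (`default_base_model()`): heterogeneous self-coupling
  0.25–0.45 (regions differ in autocorrelation, as real parcels do), a ring
  lattice of local couplings (weights ≈ 0.12–0.18) plus n/2 long-range
  couplings (≈ 0.10–0.15), rescaled off-diagonal so the spectral radius is
  exactly 0.90 — comfortably stationary yet strongly reverberant. With
  these values the analytic pairwise synergy of coupled pairs lands at
  0.1–0.5 bits, the same order as the estimation noise floor at a few
  hundred time points, which is what makes recovery nontrivial.
* **Innovations** standard normal; **burn-in** 200 samples, far beyond the
  mixing time at radius 0.9.
* **Attenuation**: from a designated stage onward, the off-diagonal row and
  column of each affected node are multiplied by a factor in (0, 1],
  cumulatively across transitions. Rescaling toward zero can only shrink
  the spectral radius, so every stage model stays stationary. Self-coupling
  is left untouched — it is not inter-regional coupling.
* **Ground-truth nodes are hubs.** Affected nodes in the canned profiles
  are designated among the base model's synergy hubs
  (`synergy_hubs()`: top degree in the sparsified *analytic* synergy
  network). A node with no edges in the top-10 % graph is invisible to the
  sparsified metrics, so attenuating it would be untestable by
  construction; hub-preferential degeneration is also the realistic case.
* **Profiles** (`study_profile()`): `clinical` mirrors the clinical cohort
  shape (90 regions; CN/EMCI/LMCI/AD = 34/60/59/50; 140 time points;
  progressive attenuation of six hubs), `recovery` is the
  parameter-recovery study (90 regions, 30 vs 30 subjects, 300 time
  points, five hubs at factor 0.4), `small`/`null-small` (20 regions,
  10 per stage, 120 time points) keep tests and examples fast.
* **Determinism**: every random draw descends from the design seed through
  a fixed multiplicative derivation; equal configurations are bit-identical,
  and study TSVs are written with 17 significant digits so the round trip
  is exact.

What the generator deliberately does **not** emulate: hemodynamic response
convolution, scanner/physiological noise spectra, spatial autocorrelation
of parcels, subject-level coupling heterogeneity within a stage, and any
claim about what actually raises or lowers synergy in diseased brains — the
attenuation scheme is a testability device. Consequently, passing the
recovery tests demonstrates that the *pipeline* recovers known coupling
attenuation under its own model class; it is not evidence about real BOLD.

## 7. Problem sizes and numerical tolerances used in the tests

The suite was sized to what the analyses genuinely need: lattice-solver
equivalence on 100 random positive-definite systems at $10^{-9}$ bits;
sampling checks at $10^4$–$10^5$ time points (law-of-large-numbers
tolerances 0.02–0.05); the Lyapunov invariant at $10^5$ samples within 2 %
relative Frobenius error; false-discovery control over 2000 simulated
null comparisons at the clinical cohort dimensions (90 nodes, 34 vs 60),
flagged fraction ≤ 0.07; and ground-truth recovery — at least 4 of 5
attenuated hubs in the top 10 by change score — in at least 18 of 20
seeded replicates of the `recovery` profile. The within-control
coefficient-of-variation contrast between synergy and MI metrics is
computed and reported alongside but not hard-asserted: its direction
depends on generator details the tests should not be tuned to.

## 8. Known limitations

* MMI's equal-magnitude pathology (section 1) makes synergy edges between
  strongly autocorrelated but uncoupled regions nonzero; interpret hub
  structure accordingly.
* Bivariate decompositions only: triplet and higher-order synergy are out
  of scope, as are redundancy functions other than MMI and
  discrete/non-Gaussian estimators.
* The `mi` matrices are instantaneous; whether a lagged MI would be the
  fairer comparison is a methodological choice this package exposes (τ is
  configurable) but does not decide.
* Covariate adjustment (age, sex), longitudinal modelling and permutation
  inference are not implemented.
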