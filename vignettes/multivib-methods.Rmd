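---
title: "multivib: methods and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{multivib: methods and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model implemented by `multivib`, the exact
numerical conventions used, and the rationale behind every default that the
method description leaves open. It is a reference document; the code chunks
are illustrative and not evaluated when the vignette is built.

# Overview

`multivib` integrates single-cell datasets from different molecular
modalities (RNA, ATAC, histone marks, ...) into one shared latent space.
Three regimes are supported by the same architecture:

- **horizontal**: unpaired datasets, different modalities, aligned through
  biologically constrained translators (`train_horizontal()`);
- **vertical**: jointly profiled modalities, aligned through paired-cell
  contrastive learning (`train_vertical()`);
- **mosaic**: an ordered schedule of horizontal and vertical stages sharing
  one encoder (`train_mosaic()`).

# Architecture

## Modality translators

Each modality's feature matrix `X_m` (cells x features) is mapped into a
shared gene-centric space of dimension `g` by a linear translator.

**Masked dense**, `h = X_m (W ⊙ M) + b`. The binary mask `M` (features x
genes) encodes biological plausibility: a peak may only load on a gene whose
body, extended by `window_bp` on both sides, it overlaps. Intervals are
0-based half-open throughout (`build_gene_proximity_mask()`); a peak ending
exactly at the extended start, or starting exactly at the extended end, does
*not* overlap. The default window is 2000 bp, a standard promoter-proximal
regulatory distance. Overlap computation uses `GenomicRanges`; BED input is
0-based half-open, GFF3 1-based closed, and both are converted exactly.
Strand is ignored (the window is symmetric). The mask is applied at
construction and re-projected (`W <- W ⊙ M`) after **every** optimizer step,
so excluded weights are exactly zero at all times, not merely penalised.

**Low rank**, `h = X_m A B + b` with inner dimension `d`. Used in three
places:

1. *Phase-2 continuation* of a masked translator: `decompose_translator()`
   splits `W = U S Vᵀ` into `A = U √S`, `B = √S Vᵀ`. At `d = rank(W)` the
   handoff is exact (verified to ~1e-15 relative Frobenius error); for
   smaller `d` it is the Eckart–Young optimal rank-`d` approximation. The
   square-root split balances the scale of the two factors, which keeps the
   subsequent Adam steps well conditioned.
2. *Vertical initialisation*: `init_translator_by_regression()` solves the
   minimum-norm least-squares problem mapping one modality's features to the
   other's shared-gene profile over paired cells (via the SVD
   pseudo-inverse, tolerance `max(dim) * eps * s_1`), then splits the
   solution as above. This is the paired-data analogue of the biological
   mask: it anchors the translator before any contrastive gradient is taken.
3. *Random initialisation* (`train_vertical(..., translator_init =
   "random")`): `A ~ N(0, 1/f)`, `B ~ N(0, 1/d)` entrywise. This exists to
   define an honest *untrained* baseline — with 0 epochs it is the
   "no training at all" reference used by the blinded-pairing stress test.

Datasets already in the shared gene space use the identity translator.

## Shared variational encoder

`encoder_params()` builds a 3-hidden-layer MLP (default widths 512-256-128
for real-scale data; tests and examples use smaller widths) with, per layer,
an affine map, **layer normalization**, and ReLU. Two linear heads output
`μ` and `log σ`; `log σ` is clamped to `[-10, 5]` for numerical safety
before exponentiation. During training the *input* is subjected to inverted
dropout with rate 0.25 (scaling by `1/(1-p)` so evaluation needs no
correction); evaluation is deterministic. Sampling uses the
reparameterization `z = μ + σ ε`, `ε ~ N(0, I)`, so gradients flow through
both heads.

## Projector

A single linear map from `[z; one-hot(covariates)]` to a `p`-dimensional
contrastive space (`projector_params()`, `project()`). Concatenating the
covariate one-hots lets the contrastive loss discount nuisance structure
(batch, modality) without a separate adversary. Default `p = k + 16`, which
must exceed `k`; the latent default is `k = 32`.

# Losses

## Decoupled contrastive (DC) loss

For a batch of `N` cells with two views `y¹, y²` in the projection space,
cosine similarities `S(u, v) = uᵀv / (‖u‖‖v‖)` and temperature `τ`:

- the positive term for anchor `y¹_n` is `-S(y¹_n, y²_n)/τ`;
- the normalizer `U_n` sums `exp(S/τ)` over the `2(N-1)` *negative* pairs —
  both views of every other cell — explicitly **excluding** the positive
  pair (this exclusion is what "decoupled" means);
- the loss symmetrises over the two views, giving `2N` anchor terms.

`reduction = "mean"` (default) divides by `2N`; `"sum"` returns the raw
total. Closed form used in tests: two orthonormal cells with identical
views at `τ = 1` give exactly `4(ln 2 − 1)` (sum) i.e. `ln 2 − 1` per
anchor. Default `τ = 0.1`, the standard operating point for
cosine-similarity contrastive losses; smaller `τ` sharpens hard negatives,
larger `τ` washes them out. Similarities are computed with a norm floor of
`1e-12`; degenerate inputs (all-zero rows, `N < 2`) raise errors rather
than producing NaN.

## KL regulariser

`kl_to_standard_normal(μ, σ)` is the analytic KL of a diagonal Gaussian to
`N(0, I)`, averaged over cells: `0.5 Σ_j (μ_j² + σ_j² − 1 − 2 log σ_j)`.
A unit mean shift with unit variance contributes exactly `0.5` per
dimension. The total objective is `L = L_DC + β · KL` with `β = 0.05`: a
light information bottleneck that regularises the posterior without
collapsing it.

All gradients (DC core, KL, projector, encoder including layer-norm
backward, translators) are analytic, hand-written in base R, and verified
against central finite differences in the test suite.

# Training

Optimisation uses Adam (`lr = 1e-3`, `β₁ = 0.9`, `β₂ = 0.999`,
`ε = 1e-8`), batch size 256, with seeded epoch shuffles. All randomness is
controlled by a single `seed` in `train_config()`; independent streams are
derived with `derive_seed(seed, tag, key)` (a string-hash mix), so adding a
dataset never perturbs another dataset's stream.

**Horizontal** training is two-phase. Phase 1 optimises masked-dense
translators (mask re-projected after every step) with the DC loss on two
augmented views (seeded unit-variance Gaussian augmentation, `augment()`)
plus the KL term. Phase 2 converts each masked translator to low-rank at
the configured `d` (exact at full rank) and continues with fresh optimizer
state — Adam moments are not transferable across the reparameterisation.

**Vertical** training regresses the non-shared modality onto the shared
gene space over paired cells, then optimises the DC loss between the two
modality embeddings of each paired cell (sampled `z`, not `μ`, so the
bottleneck is felt by the alignment) plus the symmetric sum of both views'
KL terms. Cells without a partner in the batch — including the
`holdout_fraction` of pairs reserved for evaluation — contribute KL only;
held-out cells therefore influence the geometry only through the prior,
never through a pairing signal.

**Mosaic** training executes a schedule of stages sequentially. The encoder
and projector are inherited across stages; per-stage seeds are
`derive_seed(config$seed, "stage", i)`, so any stage can be reproduced in
isolation. Encoder snapshots are recorded at the start and end of every
stage (`state$encoder_snapshots`), which makes inheritance auditable:
stage `i+1`'s start snapshot is bitwise identical to stage `i`'s end
snapshot.

`extend_projector()` grows the covariate vocabulary between stages; new
one-hot rows are zero-initialised so existing projections are unchanged.
`save_model_state()` / `load_model_state()` serialise the full state to
JSON at 17 significant digits (round trip accurate to ~1e-14).

# Preprocessing

- `normalize_rna()`: per-cell scaling to 10,000 counts, `log1p`, per-gene
  z-scoring. All-zero cells and genes map to zeros, never NaN.
- `tfidf_transform()`: per-cell term frequency times an IDF weight, then
  per-feature z-scoring. Two IDF dialects are in common use; the default is
  `smoothed_plus1`, `log((1+n)/(1+n_p)) + 1`, which is bounded below by 1
  and defined for features present in every cell; `log1p_ratio`
  (`log(1 + n/n_p)`) is also provided.
- `bin_histone_features()`: peak counts are pooled into fixed genomic bins
  (default 10 kb) by *midpoint* assignment to half-open bins, then
  `log1p` + z-scored.
- `select_hvg()`: dispersion-based selection with mean-binned z-scoring of
  the dispersion (20 bins), combined across datasets by median rank; ties
  break deterministically by gene name.
- `preprocess_dataset()` dispatches on modality and data sign:
  non-negative integer RNA counts are normalised, ATAC counts get TF-IDF,
  signed (already-continuous) data are only standardised.

# Evaluation

- `mixing_score()`: mean entropy of group composition over the `k = 50`
  nearest neighbors of resampled pooled neighborhoods (default 100 cells
  per group, 20 repetitions, seeded). Natural log, so the ceiling for `G`
  groups is `ln G`.
- `asw_cell_type()`: `(ASW + 1)/2` of the cell-type silhouette (Euclidean,
  via `cluster::silhouette`), mapped to `[0, 1]`.
- `asw_modality()`: `mean_t (1 − |ASW_modality within type t|)` — 1 means
  modalities are indistinguishable within every type; types containing a
  single modality are skipped with a warning.
- `laes()`: local annotation enrichment score for one cell type —
  `(N/k) · mean_i (own-modality share among the k within-type neighbors of
  cell i − population share)` where `N` is the type's population. Balanced
  populations whose neighborhoods are purely own-modality give exactly 2;
  a perfectly mixed type gives ~0. Values are signed; magnitude is what
  matters.
- `transfer_labels()`: k-nearest-neighbor majority vote with ties broken by
  summed inverse distance (floor `1e-12`); reports accuracy and macro F1.
- `nmi()` uses arithmetic-mean normalisation (matches
  `igraph::compare(method = "nmi")`); two constant clusterings define
  NMI 1, one constant clustering NMI 0. `ari()` matches
  `mclust::adjustedRandIndex`.
- `rank_methods()`: metrics are ranked per column (best = 1, ties
  averaged), averaged within category, and combined with weights
  BCS 0.2, MAS 0.2, CPS 0.3, CMS 0.3, renormalised over the categories
  present. A method ranked first everywhere scores exactly 1.

# Cross-species gene programs

For cross-species analyses the trained low-rank translator factor `B`
(latent x genes) is treated as a gene-loading matrix.
`cluster_shared_genes()` groups genes by their loading profiles (k-means on
standardised columns, seeded); `call_species_specific_genes()` z-scores the
reconstruction restricted to one species' cells *globally* (one mean and
standard deviation over the whole restricted block, so scores are
comparable across genes) and calls a gene species-specific when its maximal
per-cell-type z-score exceeds `species_z_cutoff(0.01) = qnorm(0.99) ≈
2.3263` in at least `min_links` cell types.
`classify_program_speciesness()` labels programs shared / specific / mixed
from the fraction of species-specific member genes.

# Synthetic data generator

`simulate_multiome()` draws cells from `n_cell_types` Gaussian clusters in
a `latent_dim_true`-dimensional latent space and renders each modality
through a seeded linear map, either as `gaussian` (linear read-out plus
noise) or `counts` (softplus rate + Poisson). The exact linear ground-truth
map between modalities (`truth$true_maps`) is retained, which enables exact
oracle tests (noiseless Gaussian rendering recovers the map to ~1e-8 by
regression). Defaults (5 types x 100 cells, 150 genes / 200 peaks, latent
dimension 8) are the generator's *study conditions*: small enough for
minutes-scale CPU training, large enough that chance 1-NN transfer is 20%.

`make_blinded_benchmark()` implements the blinded-pairing stress test:
chosen cell types have their pairing withheld from the visible training
data while the truth table retains it. Its `evaluate()` hook reports, for
the blinded types only, mean |LAES|, cross-modal label-transfer macro F1
(anchored on the unblinded types), and modality mixing. The honest
no-training baseline is `train_vertical(..., phase2_epochs = 0,
translator_init = "random")` — the regression initialisation is already a
paired-data training signal and must not be part of the baseline. The
stress test uses the `gaussian` rendering because the Poisson `counts`
read-out breaks global linearity, which confounds the question the test
asks (does *contrastive training* align blinded types, not does the
translator family extrapolate a non-linear read-out).

# Numerical conventions and limitations

- Full determinism: every stochastic step is seeded from a single integer;
  repeated runs are bitwise identical.
- Embeddings serialise to TSV at 17 significant digits; model state and
  evaluation reports to JSON with unrestricted digits.
- Genomic coordinates are 0-based half-open internally; conversion to and
  from `GenomicRanges` (1-based closed) is exact and tested at boundaries.
- `.h5ad` input is not supported (no HDF5 binding is available in the
  target environment); `read_dataset()` raises an informative error and the
  MatrixMarket + TSV layout is supported as the exchange format.
- The dense base-R backward passes target datasets up to a few thousand
  cells and features per batch; the implementation favours auditability
  over large-scale throughput.
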