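---
title: "Voxel-scale mitochondrial phenotyping: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-scale mitochondrial phenotyping: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitovoxel)
```

`mitovoxel` implements an end-to-end analysis pipeline for plate-based
mitochondrial phenotyping of physically voxelized brain tissue: hundreds of
3×3×3 mm tissue voxels cut from a frozen coronal slab, randomized into
96-well assay plates, measured by kinetic colorimetry, frozen-tissue
respirometry and duplex qPCR, batch-corrected with pooled loading controls,
reduced to per-voxel mitochondrial features, mapped into a stereotaxic
volume, and finally coupled to neuroimaging metrics by stepwise linear
models. Because the single-donor dataset this design comes from is not
deposited, the package ships a first-class synthetic-data generator whose
defaults encode the study conditions; every analysis stage is tested by
parameter recovery against that generator's ground truth.

This vignette documents the measurement models, the tunable parameters, and
the design decisions taken where the underlying procedure left genuine
freedom.

## The measurement model

Each voxel $v$ carries five latent mitochondrial quantities
$L_{f,v}$, $f \in \{\mathrm{CS}, \mathrm{mtDNA}, \mathrm{CI}, \mathrm{CII},
\mathrm{CIV}\}$, drawn from normal distributions whose means differ by
tissue class (GM, WM, mixed). The *raw observables* are powers of the
latents:

* surface-area-like OxPhos activities: $\mathrm{CI}, \mathrm{CII},
  \mathrm{CIV} = L^2$,
* volume-like content markers: $\mathrm{CS}, \mathrm{mtDNA} = L^3$.

This is the spheroid-organelle argument: when roughly spherical organelles
have normally distributed radii, surface-proportional readouts follow a
square-root-normal law and volume-proportional readouts a cube-root-normal
law. The raw observables are therefore **right**-skewed (long upper tail),
and the $\sqrt{\cdot}$ / $\sqrt[3]{\cdot}$ transforms in
`volumetric_transform()` normalize them exactly in the zero-noise limit.
(The narrative term "left-skewed" is sometimes used for these assay
distributions; only positive skew is compatible with root-transform
normalization, so the generator produces positive skew. The transform
diagnostics — CV, moment skewness, and the Kolmogorov–Smirnov distance to a
matched normal, `distribution_diagnostics()` — quantify the improvement.)

GM–WM separation is parameterized directly as Hedges' $g$ on the latent
scale (`effect_config()`); defaults span 1.8–2.6 across the five features,
the range observed for annotated voxels. Mixed-class voxels sit halfway
between the GM and WM means. A second generator mode
(`coupling = "proportional"`) scales a single per-voxel latent by
feature-specific constants, which makes every mitochondrion identical in
OxPhos capacity — the null under which MRC (below) must be constant.

## Assay forward models and their inversion

**Colorimetry.** Kinetic absorbance traces are linear in time with slope
proportional to `plate_factor × (activity + nonspecific)`; the nonspecific
(inhibitor) background is an assay-wide constant, by default 10% of the
cohort-mean activity. Each assay has an early and a late integration
window (CS 150–250/250–500 s, CI 50–300/300–600 s, CII 100–400/400–700 s,
CIV 50–150/150–300 s); nonspecific traces are integrated once over the
union window. Because the windows have different lengths, every integral is
converted to a per-second slope before any comparison — this is what makes
the "take the higher of the two windows" selection and the nonspecific
subtraction dimensionally coherent, and it matches the convention of
converting linear slopes into activities. Per sample the pipeline then
keeps the two closest of the three replicate-plate values
(`select_two_closest()`, ties keep the lowest-index pair), averages them,
and subtracts the nonspecific activity, clipping at zero with a
below-detection flag. CIV has a single nonspecific plate, whose plate-mean
background is applied to all samples of that batch. Extinction
coefficients, dilution and path-length corrections are exposed in
`od_to_activity()` with unit defaults (their true values are
instrument-specific and cancel in the mean-normalized features).

**Respirometry.** Phase plateaus follow
`plate_factor × (floor + activity × protein)` above inhibitor floors;
complex OCRs are phase differences (NADH−antimycin, succinate/rotenone−
antimycin, TMPD−azide), protein-normalized afterwards. Acceptance requires
CI, CII ≥ 0.5 and both CIV values ≥ 1.5 pmol/min/μg, and each CIV value
must exceed 80% of its companion complex on the same plate type. Samples
failing at 15 μL are re-assayed at 25 μL (simulated with halved relative
noise); failure after rerun excludes the sample. Note that this acceptance
rule is *not* monotone in CI/CII — raising a companion complex tightens
the relative CIV bound — so the property tests assert the two invariants
that do hold: acceptance is monotone in the CIV values, and invariant
under joint scaling of all OCRs.

**qPCR.** Triplicate Ct values for ND1 (mtDNA) and B2M (nDNA) are averaged
with a mean-Ct exclusion cutoff of 33 cycles.
`mtDNAcn` $= 2^{\Delta Ct} \times 2$ with $\Delta Ct = Ct_{B2M} -
Ct_{ND1}$. Densities linearize Ct as $10^{12} \times 2^{-Ct}$ — the
monotone-decreasing form required by qPCR chemistry (one extra cycle means
half the template); a `literal = TRUE` switch reproduces the increasing
variant for comparison. The generator's reference is chosen so that
$2^{Ct_{\mathrm{ref}}} = 10^{12}$, making the zero-noise round trip an
exact identity rather than a proportionality.

## Batch correction

Every plate carries duplicate wells of three pooled loading controls (GM,
WM, mixed — each the pooled mean of 30 synthetic voxels of its class).
Correction factors are control values divided by their cross-plate grand
means, averaged over duplicates and then over the three control types with
equal weight. Corrected values are obtained by **dividing** by the plate
factor; this equalizes the corrected controls across plates exactly in the
zero-measurement-noise case. (The literal reading — multiplying by the
factor — would amplify a high-reading plate; it is available via
`direction = "multiply"`.)

Two caveats are inherent to the scheme and documented rather than patched:

* the grand-mean batch level is unidentifiable, so corrected values are
  recovered up to one global factor; recovery error is therefore assessed
  on the mean-normalized scale, which is the scale every downstream stage
  actually uses;
* applying the ratio correction to Ct values operates on a logarithmic
  quantity; it is retained for fidelity to the assay convention, while
  `mtDNAcn` is computed from uncorrected Ct differences, where equal plate
  shifts cancel exactly.

## Derived metrics

After transformation, every feature is scaled to a cohort mean of one
(`mean_normalize()`), and the colorimetric and respirometric estimates of
each complex are averaged (`integrate_complex()`); colorimetric CI is
excluded by default from the integration. The derived metrics are

$$\mathrm{MitoD} = \tfrac12\!\left(\widehat{CS^{1/3}} +
\widehat{mtDNA^{1/3}}\right), \quad
\mathrm{TRC} = \tfrac13\!\left(\widehat{CI^{1/2}} + \widehat{CII^{1/2}} +
\widehat{CIV^{1/2}}\right), \quad
\mathrm{MRC} = \mathrm{TRC} / \mathrm{MitoD},$$

where hats denote mean-normalized transformed values. MitoD is tissue
mitochondrial density, TRC the OxPhos capacity per tissue unit, and MRC the
capacity per mitochondrion; MRC is undefined where MitoD is not positive.
The composition order — transform, mean-normalize, average — is fixed by
convention here; averaging before normalizing would mix scales across
assays. A voxel's completeness flag requires all five base features, the
criterion used to select voxels for embedding and modeling.

## Spatial mapping

Stereotaxic registration itself (a manual, software-assisted warp in the
original workflow) is out of scope: the package consumes a user-supplied
grid-to-world affine and annotation table, and writes per-feature NIfTI-1
volumes with float64 data so lattices round-trip bit-exactly. The
partial-volume filter discards voxels with GM+WM probability below 0.70,
keeping the boundary (exactly 0.70 passes). Region summaries (mean by
default, median optional) feed a Spearman correlation against an ordinal
phylogenic-age ranking of regions.

## Embedding and cluster accuracy

Voxel profiles are z-scored per feature and embedded with UMAP (uwot,
single-threaded so a fixed seed reproduces coordinates exactly). The
original analysis delineated embedding clusters visually; the package
substitutes seeded k-means on the embedding (k = 3 for all-voxel runs,
k = 4 conventionally for GM-only runs). Each cluster predicts its majority
tissue class; per-class accuracy is compared against the class prevalence
(rounded percent), which for the annotated composition 325 GM / 132 WM /
176 mixed gives chance levels of 51% and 21% for GM and WM.

## Stepwise regression of MRI metrics

Each of the six responses (CI, CII, CIV, MitoD, TRC, MRC, on their
normalized scale) is regressed on 22 standardized neuroimaging metrics with
backward elimination: the least significant remaining predictor is the
removal candidate, and removal proceeds while an F-change test is
non-significant at α = 0.05. The stopping sentence ("until the comparison
between two consecutive models is not statistically significant") admits
two readings, and they behave very differently:

* comparing only the two consecutive models (the candidate's partial F)
  retains at least one pure-noise predictor in roughly 60% of null
  datasets with 22 candidates, because the last survivor is effectively
  the minimum of 22 p-values;
* comparing the running reduced model against the **initial full model**
  (a joint F of everything removed so far) keeps the family-wise rate of
  retaining any noise predictor near α, and recovers a planted 6-predictor
  support with standardized |β| = 0.3 at n = 431 in >90% of replicates.

The package defaults to the joint-F reading (`baseline = "full"`), with
the single-term variant available. Prediction accuracy is reported as the
squared Pearson correlation between observed and predicted values (the
scatterplot convention), with regression-$R^2$ as a switch; a
scrambled-pairing permutation null (expected $r^2 \approx 1/(n-1)$)
calibrates significance. Predicted component features can be recombined
into TRC and MRC and correlated with their directly predicted counterparts
as a consistency check (`derived_consistency()`).

**MRI generator calibration.** Metrics are linear combinations of the five
standardized latent features plus isotropic Gaussian noise,
$X = F C + E$. The noise SD is solved by root-finding so that the
population $R^2$ of the best linear predictor of a latent feature from all
22 metrics, averaged over features, equals the configured target (the
single-predictor special case is the familiar
$\sigma^2 = \mathrm{Var}(signal)(1-R^2)/R^2$). Fitted models estimate 22
coefficients from 431 training voxels, so their out-of-sample $r^2$ sits
slightly below the population target (≈0.25 at a target of 0.30); the
calibration tolerance bands account for this estimation shrinkage.

## Pseudobulk mitotype scoring

Expression is modeled on an additive (log-like) scale: gene baseline +
gene-by-region effect + gene-by-cell-type effect + noise, with the region
scale 3× the cell scale by default and nucleus counts per voxel matching
the recovered campaign (8,945 / 7,044 / 6,176 / 10,350; 32,515 total).
Pathway scores are gene-set means of pseudobulk (per voxel, or per
voxel × cell type) expression; a toy 10-pathway annotation ships with the
package and real annotations load from a two-column pathway/gene file.

Three z-scoring views are provided. *Global* (per gene across all samples)
preserves sample-level offsets, so hierarchical clustering of raw or
globally scored profiles groups samples by region. *Within-voxel* (per
gene across the samples of one voxel) removes every effect that is
constant within a voxel — region effects vanish identically — so the same
clustering then groups samples by cell type. This is the mechanism of the
region-to-cell-type clustering flip, and it is exact: gene-wise
standardization within a voxel annihilates gene-by-region terms
regardless of their shape. A *within-sample* (per-column) mode is also
provided for completeness; note that per-column standardization cannot
remove gene-specific region effects, and that correlation-based distances
are already invariant to per-column affine changes, so the flip
specifically requires the within-voxel view. Clustering uses average
linkage on 1−Pearson distance (Euclidean optional).

## What the generator does and does not emulate

Defaults are the study conditions: a 20×43 grid slab yielding 703 tissue
voxels (325 GM / 132 WM / 176 mixed annotated, 70 unannotated), 27 mg
expected voxel mass (SD 4.5 mg), 8 base plates of 90 samples + 6 control
wells, three replicate plates per colorimetric assay (one nonspecific
plate for CIV, three for the others), duplicate-plate-type respirometry
at 15/25 μL, triplicate duplex qPCR, log-normal plate factors with
σ = 0.2, and ~15% of voxels below the 0.70 partial-volume threshold.

Deliberately not emulated: optical plate-reader physics and injection
kinetics (traces are linear, phases are plateaus), spatial autocorrelation
of features beyond tissue class and region labels, heteroskedastic
detection limits (WM dropout is driven by the acceptance rules, not by a
censoring model), inter-individual variability (single synthetic donor),
and the covariance structure of real population-template MRI metrics
(metrics share a common latent signal plus isotropic noise). Passing
parameter-recovery tests therefore demonstrates the correctness and
calibration of the analysis machinery under the stated model — not
performance on real tissue data.

## Numerical choices and degenerate inputs

* Latents are redrawn on the rare event of a non-positive value (class
  means sit ≥4 SDs above zero), keeping power observables invertible.
* Window integrals interpolate linearly at window edges; windows outside a
  trace's span are errors, not extrapolations.
* Replicate and tie handling: two-closest ties keep the lowest-index pair;
  incomplete triplicates pass through with a QC flag rather than failing.
* Clipped (below-detection) activities are zero with a flag; missing
  features propagate as `NA` and are excluded by the completeness flag.
* The two-Gaussian deconvolution uses finite-mixture EM (unequal
  variances, deterministic hierarchical initialization); non-convergence
  is reported as a flag, and components are always ordered by mean.
* Stepwise ties in p-values resolve by column order; the elimination trace
  records every removal with its candidate and F-change p-values.
* Test problem sizes: the unit suite runs 40–100-voxel slabs; the
  campaign-scale checks (703 voxels, 8 plates; 50-replicate stepwise and
  calibration studies; full 32,515-nucleus expression) live in the
  acceptance test file and complete in about a minute.

## Known limitations

The control-ratio batch correction recovers activities only up to a global
campaign-level factor; all reported features are mean-normalized, where the
factor cancels. Ct-scale ratio correction is unconventional (kept for
fidelity); copy number is computed from uncorrected Ct differences. The
regression stage models linear feature–metric relationships only, and MRC,
a ratio, is only approximately linear in the latents — its out-of-sample
accuracy runs below the linear features'. UMAP coordinates are
seed-reproducible but not stable across library versions.
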