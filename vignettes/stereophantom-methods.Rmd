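---
title: "Validating design-based neuroanatomy estimators on brain phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating design-based neuroanatomy estimators on brain phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereophantom)
```

# Scope and model

`stereophantom` re-implements, as tested reusable code, the computational
chain of a quantitative neuroanatomy study of a two-genotype mouse cohort:
design-based stereology (Cavalieri volume with 2D-nucleator areas, optical
fractionator, disector-density counts, coefficient-of-error accounting),
label-volume morphometry with Laplace-equation cortical thickness,
cell-type enrichment of differentially expressed genes, and qPCR
standard-curve quantification. Because no raw data accompany such studies
— results are printed as group summaries — validation proceeds in two
complementary ways:

* **exactly**, by re-entering printed group summaries (mean, SD, n) as
  inputs to closed-form two-sample tests and percent-change definitions;
* **by property**, on synthetic phantoms whose ground truth is known by
  construction: analytic solid volumes, exact cell totals, injected group
  effects.

The phantom is deliberately idealized anatomy: regions are ellipsoids,
boxes and spherical shells with closed-form volumes, voxelized on a
regular grid (voxel centers at `(i − 0.5) · voxel_size`, 0-based physical
frame, continuous µm coordinates). What passing tests show is that the
*estimators* are correct and unbiased under systematic-uniform-random
(SUR) sampling; they do not show robustness to real-tissue complications
— irregular region boundaries, tissue shrinkage, lost caps, staining
artifacts — which are explicitly out of scope.

# The synthetic cohort as study conditions

The generator's defaults are the emulated study's conditions, not free
dials:

* Stereology arm: 7 wild-type vs 6 mutant animals; left caudate-putamen
  (CPu) wild-type mean volume 10.90 mm³ with between-animal CV 0.06 and a
  −11 % mutant effect; 666 016 neurons with CV 0.14–0.16 and a ~−21 %
  effect. Sections: 40 µm, every 6th sampled (the sectioned extent of
  4 400 µm yields 110 sections at a zero start); counting frame
  2 000 µm² (50 × 40 µm) on a 400 × 400 µm grid; optical disector from 5
  to 15 µm below the upper cut surface (height 10 µm, hsf = 10/40).
* Cortical interneuron arm: 8 vs 6 animals; an anterior-cingulate (aCC)
  box phantom of 3 mm³ with laminar bands I–III/V/VI (depth fractions
  0.45/0.35/0.20 — a field-typical laminar split; the study does not print
  band geometry), ~10⁴ marker-positive neurons with CV 0.17–0.25, a
  layer-V-concentrated deficit, and 7 confocal stacks per hemisphere on 4
  sections allocated 3/3/1 across the bands.
* Volumetry arm: 9 vs 10 animals over a bilateral multi-region template
  with a region → structure hierarchy (striatal sub-structures, amygdala,
  globus pallidus, thalamus) and CV 0.06.
* Enrichment: a 27-set marker panel over an explicit gene universe; DEG
  lists with controlled overlap enrichment and down-regulation bias
  (e.g. 100 % down among medium-spiny-neuron-set overlaps).
* qPCR: serial ten-fold five-point dilution standards (the study does not
  print its dilution scheme), 4 candidate reference genes, Gaussian Cq
  noise of 0.2 cycles, per-sample loading factors, injected 0.6× fold
  change on a target gene.

Animal-level true values are drawn log-normal with the requested mean and
CV (volumes and counts are positive quantities with CVs up to 0.25, where
a Gaussian would put mass near zero); a Gaussian option exists for
degenerate-variance checks. Mutant means are the wild-type means scaled by
`1 + effect`. Each animal's phantom is the template with every shape
rescaled isotropically to the animal's drawn volume — self-similar
anatomy, no registration. Cells are placed by uniform voxel choice plus
uniform within-voxel jitter, so every cell provably lies in a voxel of its
region; totals are realized exactly (marker flags alone are binomially
thinned). The cell's reference point for all counting rules is its single
coordinate (the nucleus-centroid convention of fractionator practice).

One open point in the source material is the between-animal correlation
structure across regions; the generator exposes a shared latent size
factor in tests but asserts no particular value.

# Estimator details and numerical choices

**Sectioning.** Slabs of thickness `T` partition the full grid extent with
a random start in `[0, T)`; partial end slabs are kept. Per section and
region an *equivalent area* (voxel–slab intersection volume / `T`) is
stored, making `Σ A · T` exactly the voxelized volume — the identity that
anchors the exhaustive (`k = 1`) Cavalieri check.

**Counting frame.** Left/bottom edges and their infinite extensions
exclude; top/right include. Implemented as half-open intervals
`(x0, x0+w] × (y0, y0+h]` with exact coordinate comparison (no epsilon):
ties are resolved by the rule itself, and a complete tiling counts every
point exactly once — tested on random point sets with points snapped onto
edges.

**Fractionator.** Section offset and grid phase are SUR; the disector
window is a fixed depth interval inside the slab (cells are uniform in
depth relative to the random sectioning, so a fixed window is unbiased).
The estimate is `ΣQ⁻/(ssf·asf·hsf)` with per-section tallies retained for
error prediction.

**Nucleator.** `π · mean(l²)` over `n` systematically rotated rays with a
uniform random phase (default 4 rays, configurable) — unbiased over the
phase for profiles star-shaped about the seed. Three input forms: radial
functions (exact), polygons (exact ray–segment intersection), and binary
masks (subpixel ray marching at 0.25 px, used on section masks).

**Error prediction.** The sources print `CE²/CV²` but no CE formula; the
package adopts the standard systematic-sampling form
`Var = (3A − 4B + C)/240` (smoothness class m = 1) on the ordered area
sequence for Cavalieri, and `CE² = 1/ΣQ⁻ + CE²_SURS(Q⁻ sequence)` for
counts. The open-ended sum leaves a small end-term remnant
(`CE_SURS = sqrt(2/240)/n`) on perfectly flat sequences; it contributes
under 1 % to a count CE, which the tests pin down exactly rather than
forcing to zero. At the study design the predicted count CE
(≈ `1/sqrt(ΣQ⁻)` ≈ 0.05) sits well below the between-animal CV, giving
`CE²/CV²` ratios in the 0.05–0.2 range that a healthy design should show.

**Disector-density counts.** Stacks are placed uniformly within each
laminar band on sections where the region fills the whole slab thickness
(stacks on partial end slabs would probe empty space and bias the density
down — the one subtlety this phantom exposed during development). The
whole-region estimate `ΣQ⁻/Σv(dis) · V(ref)` uses the label volume's voxel
volume as `V(ref)` (how the reference volume was obtained is not printed
in the emulated study; voxel counting over the sampled sections is the
package's choice). When stack volume is allocated proportionally to band
volume, band estimates add exactly to the pooled estimate; the 3/3/1
layout is not proportional, so the layer-wise path with band-specific
reference volumes is the primary laminar readout.

**Laplace thickness.** The potential is solved on the cortex ribbon with
Dirichlet values 0 (inner) and 1 (outer) by a direct sparse Cholesky
factorization of the 7-point Laplacian — exact to machine precision, so
the configured tolerance (1e-5) is an assertion on the residual, not an
iteration stop. Streamlines follow the normalized gradient by RK4 at 0.2
voxel steps from every outer-surface cortex voxel, in both directions,
and the two path lengths are summed; integration stops within 0.02 of the
boundary potentials. Two discretization facts matter when comparing with
closed forms: Dirichlet data sit at *neighbor voxel centers*, widening the
effective ribbon by up to half a voxel per face (thickness errors up to
~1 voxel on a flat slab, within the 1.5-voxel acceptance band), and the
staircase boundary makes the potential agree with the concentric-sphere
closed form only to O(h) — bounded by `h/(R_out − R_in)` = 0.125 for the
20/28-voxel validation shell, with ~0.08 observed. Group t-maps require
fields on a shared grid (phantoms are built on one template; no surface
registration is attempted) and are thresholded at uncorrected p < 0.05 by
design.

**Volumetry and statistics.** Percent change is
`100 · (mean_mut − mean_wt)/mean_wt` (reductions negative, wild-type
denominator). Correlation matrices pool both genotypes by default (a
per-genotype option exists). "Student's t-test" is read as the
pooled-variance two-sided test, but Welch is always co-reported: the
emulated study's own printed p-values for the neuron count (0.012 in a
figure, < 0.01 in a table; the pooled summary-statistic value is 0.016)
are not reproducible under any single convention, so the package reports
both and arbitrates nothing. The two-way genotype × layer ANOVA uses
type-II sums of squares with Tukey HSD, and *additionally* reports
Bonferroni-adjusted within-layer t contrasts, because the sources name
Tukey as the post hoc test yet print Bonferroni-corrected values — both
are labeled. Shapiro–Wilk (gate at p > 0.05) precedes group contrasts.

**Enrichment.** Two-sided Fisher p by the point-probability convention
(sum of hypergeometric point probabilities not exceeding the observed
one, with a 1e-7 relative guard for floating-point ties — the same
convention as `fisher.test`, against which, and against brute-force
enumeration, it is tested). The gene universe is always explicit, never
inferred from set unions. The fabricated marker panel is pairwise
disjoint so injected overlaps are exact; real cell-type panels overlap
slightly, which changes nothing in the estimator but means the generator's
per-set expectations are only exact under disjointness. Marker-panel
contrasts treat markers (not animals) as units — the convention the
emulated analysis appears to use, flagged here as such.

**qPCR.** `Cq = intercept + slope · log10(q)` with
`E = 10^(−1/slope) − 1`; non-monotone dilution responses reject the curve.
Reference stability is a deliberately simplified NormFinder-style
decomposition: log2 quantities are sample-centered (removing loading),
then each gene's stability combines intergroup bias variance with mean
intragroup variance, and the best pair minimizes the stability of the
pair-averaged signal. Sample-centering has a known identifiability limit:
with one biased candidate among four, "one gene up in mutants" and "three
genes down" are the same data, so pair selection between equally-stable
pairs is not forced — the individually biased gene is still ranked last.
Fold changes are computed on group means of normalized relative
quantities (the standard-curve convention), not per-sample ΔΔCq; no Cq
outlier filtering is applied by default.

# Problem sizes

The validation suite uses: 500 SUR draws for estimator unbiasedness at
full study scale (666 016 cells); 200 simulated cohorts at group sizes
7 vs 6 for effect recovery; a 20/28-voxel-radius shell (≈ 58 000 cortex
voxels, ≈ 8 000 surface streamlines) for thickness; 1 000 replicates for
FDR control and ANOVA calibration and 2 000 for the normality gate;
200 plates for qPCR recovery. Module-level unit tests run the same
machinery at roughly one-tenth scale. These sizes put Monte-Carlo
standard errors comfortably inside the asserted tolerances (e.g. the
200-cohort mean recovered count change has SE ≈ 0.5 percentage points
against a 2-point band).

# Known limitations

* Anatomy is idealized (ellipsoids/boxes/shells); no atlas meshes,
  curvature, or hemispheric asymmetry.
* No tissue shrinkage or lost-cap modeling: the fractionator's height
  sampling fraction uses the nominal 40 µm section thickness.
* The thickness pipeline assumes isotropic voxels and a shared grid
  across animals (no surface registration).
* The DEG generator's non-enriched sets are depleted very slightly
  (unnamed sets draw from the universe minus the enriched sets'
  members); their overlap expectation is hypergeometric only when no
  enrichment is requested.
* Reference-gene pair selection inherits NormFinder's centering
  ambiguity described above.
* Uncorrected p-values are reported where the emulated analyses report
  them (thickness maps, regional volumetry); no multiplicity correction
  is added on top.
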