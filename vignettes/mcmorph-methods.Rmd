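---
title: "Methods: 3D microcalcification morphometry with mcmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D microcalcification morphometry with mcmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mcmorph)
```

## The model

The package quantifies the three-dimensional shape of breast
microcalcifications (MC) segmented from micro-CT volumes of biopsy
specimens (isotropic voxels, 9 um by default). The central descriptor
is the structure model index

$$\mathrm{SMI} = 6\,\frac{S'\,V}{S^2},$$

where $V$ is the object volume, $S$ its surface area and
$S' = dS/dr$ the rate at which the surface area changes when the
object is uniformly thickened. For ideal solids the index is 0 for a
plate ($S$ does not grow when a slab thickens), 3 for a cylinder
($S = 2\pi r L$, $S' = 2\pi L$) and 4 for a sphere ($S = 4\pi r^2$,
$S' = 8\pi r$); intermediate values indicate mixed structure. On
digitized objects the index is *not* clamped to $[0, 4]$ —
discretization can push it slightly outside, and values beyond
$[-0.5, 4.5]$ are flagged rather than truncated.

Sample-level shape statistics (mean SMI, SD of the SMI across a
sample's objects, equivalent diameters of the mean volume) feed a
rule scheme analogous to the mammographic BIRADS calcification
descriptors:

| flag | definition |
|------|------------|
| fine linear (fl) | mean $d_{cube} < 200$ um **and** mean SMI $\in [2.92, 3.08]$ |
| fine pleomorphic (fp) | mean $d_{cube} < 250$ um **and** SD(SMI) $> 0.29$ |
| coarse heterogeneous (ch) | max $d_{sphere} > 500$ um **and** SD(SMI) $> 0.5$ |
| not suspicious (ns) | none of the above |

The flags are evaluated independently (a sample can be fl and fp at
once), and `ns` is by construction the negation of their union. The
boundary conventions — strict `<` on sizes, closed SMI interval,
strict `>` on SDs — are pinned by the packaged reference cohort: one
sample sits exactly at SD 0.29 and is printed `ns`, another exactly at
mean SMI 3.08 and is printed `fl`.

Histology enters as the B-classification of the biopsy, collapsed to
group A (B1-B2, benign), B (B3-B4, uncertain) and C (B5, malignant).
Group comparisons use the Kruskal–Wallis test for the continuous
morphometry and Pearson chi-square (no continuity correction) for the
2x3 flag presence tables, Bonferroni-corrected over the four-flag
family ($m = 4$).

## Surface estimators

**Surface area.** $V$ is exact voxel accounting
($V = n_{vox} h^3$); $S$ is estimated from a triangulated isosurface.
The binary mask is first relaxed with a Gaussian of $\sigma = 1$ voxel
and the level-0.5 isosurface is extracted by marching tetrahedra (a
uniform six-tetrahedron split of each cell around its main diagonal;
opposite cube faces are cut along the same diagonal, so the mesh is
crack-free and closed). Meshing the raw 0/1 staircase instead
overestimates the area of curved surfaces by 8–10% — on a digitized
ball of radius 20 voxels the raw mesh sits ~8.5% high, while the
smoothed mesh is within 0.5% of $4\pi r^2$ (see
`analysis/01_phantom_morphometry.R` and the morphometry tests).
Smoothing is therefore the default, not an option; `sigma = 0`
restores the raw-mask mesh for convergence studies.

*Thin-structure fallback.* A one-voxel-thick object would vanish under
$\sigma = 1$ (the smoothed field never reaches the level). The sigma
is halved until the field clears the level with a 0.1 margin, down to
the raw binary mesh. Near-voxel-scale objects are consequently
approximate: an isolated voxel meshes to about 60% of its 6 $h^2$
face area. Since $V$ never depends on the mesh, only $S$, $S'$ and
SMI carry this caveat.

**Surface derivative.** $S'$ uses the classic simulated-thickening
construction: every mesh vertex is offset along its area-weighted
vertex normal by $\delta = 0.1$ voxel and the forward difference
$(S(\delta) - S)/(\delta h)$ is returned. On digitized phantoms this
recovers the analytic derivatives ($8\pi r$ for spheres within 1% at
$r = 20$ voxels, $2\pi L$ for long rods within 7%, near zero for
plates).

A morphological-dilation alternative (`method = "dilation"`: dilate by
the radius-1 digital ball, difference over one voxel) is provided for
comparison but is *not* the default, because the lattice "ball" of
radius 1 is the 6-neighbour cross: it advances the surface by
$\max_i |u_i| \in [0.58, 1]$ voxels depending on direction, not by 1.
Measured on a digitized ball of radius 20 voxels, the cross-dilation
forward difference lands at $0.87 \times 8\pi r$ and drags the sphere
SMI to about 2.96 — indistinguishable from a rod and useless for the
fl/ns contrast the classification needs. The mesh-normal estimator has
no such anisotropy.

**Padding.** Objects are measured on their own sub-volumes with 4
voxels of zero padding; an object (or its offset surface) touching the
volume border is refused with instructions to pad, because a truncated
isosurface silently underestimates $S$.

## Segmentation choices

* Global thresholding only (Otsu on a 256-bin histogram, or a fixed
  intensity for reproducibility across samples). When the two classes
  are well separated the Otsu criterion is flat across the empty
  intensity gap; the threshold is placed at the midpoint of the
  maximal plateau, so the cut falls between the modes rather than at
  the background tail. A constant-intensity volume has no separable
  classes and is an error.
* Foreground connectivity is 26 (background 6), chosen so that thin,
  obliquely-running linear calcifications are not fragmented.
  Components are labelled deterministically in `(z, y, x)` scan order.
* No minimum object size by default (`min_voxels = 1`); the cutoff is
  configurable and means "smaller than": objects of exactly
  `min_voxels` voxels survive.
* The absolute threshold used by the original vendor software is
  unpublished, so absolute object counts on real specimens are not
  reproducible; every downstream quantity is.

## Sample aggregation and exclusion

* The SD of the SMI uses the $n-1$ denominator and is defined as 0 for
  a single object (matching the "±0" convention of the reference
  table).
* `mean_d_cube` is the cube-equivalent edge of the *mean volume* when
  derived from published per-sample aggregates, and the mean of
  per-object edges when objects are measured directly; both exist on
  measured data, the sample mean drives classification.
* The `ch` size predicate uses the *largest* object's
  sphere-equivalent diameter. The rule's source states only "estimated
  diameter > 500 um"; the single ch-flagged reference sample has a
  mean diameter far below 500 um under either convention, so only a
  per-sample maximum is compatible with the printed flag. Published
  aggregates do not contain that maximum — which is exactly why that
  sample is one of the two documented discordances.
* Samples with exactly one MC are flagged `excluded` and refused by
  the classifier: a single deposit cannot carry the sample-level SD
  statistics, and such biopsies were considered non-representative.
  They stay in the cohort table.

On the packaged cohort the scheme reproduces the printed flags for 25
of 27 evaluated samples. The two discordances (samples 3 and 15) are
enumerated in `classification_expectations()` and shipped as a CSV;
thresholds were not adjusted to absorb them.

## Statistics

`kruskal.test`, `chisq.test(correct = FALSE)` and `ks.test` stand
behind the module's surface; brute-force oracles (literal rank sums,
literal $(O-E)^2/E$, enumerated KS distance) guard them in the test
suite. Yates' continuity correction is off because it applies only to
2x2 tables and would not reproduce the reference analyses. The
Bonferroni family defaults to $m = 4$ (the four flag tests); the
correction is the literal $\min(1, mp)$ so that families larger than
the vector are expressible. The Kruskal–Wallis tests run on the 27
non-excluded samples; the inclusion set used in the original analyses
is not documented, so their printed p-values are treated as soft
checks (recomputed values: 0.113 / 0.879 / 0.778 / 0.962). KS
normality is descriptive only and flagged approximate, since testing
against a normal with estimated parameters biases the asymptotic
p-value upward (no Lilliefors correction is applied).

## The synthetic generator

`make_cohort()` emulates the *statistical* structure of a 29-sample
biopsy cohort: per group it draws per-sample MC counts and mean
volumes from log-normal distributions and SMI means/SDs from normals,
then per-object volumes (log-normal, CV 1) and SMI values (normal)
around the sample parameters. Log-normal families were chosen because
counts and volumes in such cohorts are strongly right-skewed (group
SDs of the same order as the means); all defaults are moment-matched
to the reference group summaries. Only means and SDs of the original
within-sample distributions are published, so the object-level
defaults are moment-matched stand-ins, stated once and not tuned.

`render_sample_volume()` turns simulated objects into voxel phantoms
so the image pipeline can be validated end to end: target SMI
$\le 1.5$ renders a one-voxel-thick plate, $(1.5, 3.5]$ a rod whose
aspect ratio inverts the finite-cylinder SMI
$3(1 + 4r/L)/(1 + r/L)^2$ (clamped to 6–40, so targets at the
long-rod limit render 40:1), and $> 3.5$ a sphere. This map is a
validation device, not a claim about real MC geometry. What passing
end-to-end tests show is that the measurement chain recovers planted
volume and shape; they do not show that real calcifications follow
these distributions, carry no reconstruction artifacts, beam
hardening, or tissue background beyond Gaussian noise.

## Problem sizes and numerical conventions

The validation suite uses digitized spheres of 5–20 voxel radius
(within 0.4 of SMI 4 at radius 20, errors 0.64 → 0.13 → 0.01 as the
radius doubles), 40:1 rods of 3–6 voxel radius (within 0.3 at radius
6) and one-voxel plates of 30–60 voxel side (within 0.4 at side 60);
a fixed 180 um sphere re-sampled at 18 um and 9 um shifts by less
than 0.2. These sizes make the whole suite run in well under a
minute while leaving each tolerance a comfortable margin. Iso level
0.5, offset $\delta = 0.1$ voxel, 4-voxel padding and the
$4\sigma$-truncated Gaussian kernel are fixed conventions; all
classification thresholds, the Bonferroni family and the significance
level $\alpha = 0.05$ are configurable through
`classification_rules()` and `pipeline_config()`, and every threshold
actually applied is echoed into the pipeline log.

## Known limitations

* Surface quantities of objects only a few voxels across are
  estimator-limited (documented fallback above); volumes are always
  exact voxel counts.
* A finite rod's SMI exceeds 3 by construction
  ($3(1+4r/L)/(1+r/L)^2$); "rod = 3" is the infinite-length limit.
  The same applies to plates: $\mathrm{SMI} \to 24t/a$ for side $a$
  and thickness $t$, so only wide thin plates approach 0.
* The reference cohort stores volumes at the printed precision
  ($10^5$ um³), so diameters derived from it carry that quantization.
* Fractal dimension and other 3D descriptors, local/adaptive
  thresholding, artifact correction and projection-space processing
  are out of scope.
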