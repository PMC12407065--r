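---
title: "Volumetric body mass properties from segmented skeletal hulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric body mass properties from segmented skeletal hulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hullmass)
```

## The estimation problem

Body mass and its distribution across the body are foundational quantities in
vertebrate palaeobiology: they condition locomotor mechanics, posture,
physiology and macroevolutionary inference. For fossil taxa neither is
observable, and freehand soft-tissue reconstruction around a skeleton is
notoriously subjective. `hullmass` implements the convex-hull expansion
approach: divide a digitised skeleton, posed in a standardised reference pose
(axial skeleton anteroposteriorly extended, limbs ventral), into functional
segments; compute each segment's *minimal convex hull*; expand each hull
volume to an estimated soft-tissue volume using scaling relationships
calibrated on extant sauropsids; assign per-segment densities; and assemble
whole-body mass, centre of mass (COM) and uncertainty bounds.

The coordinate convention is fixed throughout: origin at the mid-acetabular
point, +x anterior, +z dorsal, y mediolateral. COM positions are therefore
displacements from the hip, which makes the glenoacetabular (GA)
normalisation (0 = acetabulum, 1 = glenoid) native.

## The model, step by step

**Hulls.** Each segment's hull is computed by a randomised-incremental
(beneath-beyond) algorithm over the segment's vertex cloud; meshes need not
be watertight or manifold because only vertices matter for a hull. Volume is
the sum of signed tetrahedra spanned by the facets and an interior reference
point, and the segment centroid is the volume-weighted mean of those
tetrahedra's centroids. Under the uniform within-segment density assumption
this centroid is the segment COM, and it is *kept fixed* when the volume is
expanded: expansion scales each segment's volume, not its shape.

**Expansion.** For a hull volume $V_h$ (m³), a scaling model predicts the
soft-tissue volume either allometrically,
$V = 10^{\,a + b\,\log_{10} V_h}$, or isometrically, $V = k\,V_h$. Four
uniform model sets pair the two modes with two calibration sources
(non-avian sauropsid, "NAS", and bird), two "preferred" sets apply per-taxon
source/mode overrides on top of a uniform base, and a `sellers21` set applies
the classic uniform 1.21 factor (minimal whole-skeleton hulls underestimate
body mass by roughly 21% in large mammals). Bird-source sets automatically
fall back to NAS factors for tail segments, because the reduced tails of
birds are contained in the torso hull in the calibration data and no bird
tail factor exists.

Two policy rules temper the power laws. *Floor rule*: for segment classes
whose hulls adhere tightly to the skeleton the hull is a biological minimum,
so the predicted volume is clamped from below by $V_h$. The published account
gives the neck and metatarsal segments as examples without enumerating a
complete list, so the default floor set `{neck, metatarsus}` is a
configurable package choice. *Exemption*: dermal structures (ornament,
osteoderm, sail) are never expanded — their envelopes wrap tightly — and
carry zero expansion error.

**Uncertainty.** Each scaling model carries its mean absolute percentage
prediction error (mPPE), applied as symmetric multiplicative bounds
$V \cdot (1 \mp \text{mPPE})$, each bound itself subject to the floor.
Whole-body bounds place every segment simultaneously at its lower (or upper)
volume and sum — a deliberately conservative envelope; whether published
whole-body bars combine segment bounds simultaneously or in quadrature is
not stated, and the simultaneous sum is this package's contract.

**Masses and COM.** Segment mass is density times point volume. The primary
heterogeneous density scheme uses 1000 kg/m³ for head, tail and limb
segments, 800 and 850 kg/m³ for neck and torso (respiratory structures), and
2000 kg/m³ for ornaments and osteoderms. Sensitivity presets cover
homogeneous extremes from plucked birds (731 and 1169 kg/m³), a low sauropod
neck (500 kg/m³), light ornament (1000 kg/m³) and a compact sail
(2000 kg/m³). The whole-body COM is $\sum m_i x_i / \sum m_i$. The
mediolateral component is reported but expected to sit in (or negligibly
off) the sagittal plane.

**Reposing.** Sensitivity to posture (e.g. pitching a neck 45° dorsally) is
modelled on segment COMs as point masses rotated rigidly about a joint
pivot; hulls are measured in the reference pose only. The pivot ("base of
the neck") has no precise osteological definition here, so the manifest must
supply it. The default rotation axis is stored as $(0,-1,0)$ so that, by the
right-hand rule in this frame, positive angles pitch anterior points
dorsally.

**Comparative layer.** COM coordinates are normalised two ways: by the
anteroposterior and dorsoventral GA distances, and by total body mass to the
one-third power. Allometries are fitted by OLS and by phylogenetic GLS with
Brownian-motion covariance (exact GLS; ML variance; no Pagel's λ or OU
options, matching the stated Brownian assumption), with $t$-based 95% slope
intervals, AICc ($k$ includes the variance), and an isometry verdict against
a caller-supplied expectation (1 for mass–mass, 1/3 for length–mass).
Ancestral states are maximum-likelihood Brownian reconstructions
(equivalently the GLS solve), and phylomorphospace coordinates couple
observed tips with those reconstructions along the tree's edges. Taxa whose
dorsoventral GA spacing is below an epsilon are flagged and their DV
GA-normalised coordinate omitted, since the normalisation explodes.
Stylopodial (limb-bone circumference) mass estimates use a log10-linear
equation with user-supplied coefficients.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| scaling table (`a`,`b`,`k`, mPPE) | log10 m³ / – | bundled synthetic placeholder | real coefficients are external calibration data, consumed as config |
| `floor_classes` | – | neck, metatarsus | hulls adhere tightly there; configurable because the full list is not published |
| `exempt_classes` | – | ornament, osteoderm, sail | dermal structures are not expanded |
| `sellers21_factor` | – | 1.21 | minimal hulls underestimate mass by ~21% |
| densities | kg/m³ | see above | published heterogeneous scheme + sensitivity presets |
| `dv_epsilon` | m | 1e-6 | flags degenerate dorsoventral GA spacing |
| hull degeneracy `tol` | – | 1e-12 | relative simplex-volume threshold for coplanar input |

The bundled scaling table (`inst/extdata/scaling_factors_synthetic.csv`) is
a clearly-labelled synthetic placeholder: its isometric factors are merely
plausible (NAS necks more voluminous than bird necks, bird torsos more
voluminous than NAS, bird neck allometry strongly negative so that large
necks hit the floor rule), and only its three published mPPE values (tail
0.52; torso 0.10 NAS / 0.14 bird) are calibrated quantities. Substantive
applications must supply the real coefficients via `read_scaling_table()`.

## What the synthetic generator emulates — and what it does not

`generate_skeleton()` instantiates body plans built from primitives whose
hull truths are analytic: boxes (exact volume and centroid), polygonal
frusta (exact closed form, converging to the circular frustum with ring
count), and ellipsoid surface clouds (bounded above by the solid volume,
approached with point count). This keeps the hulling oracle honest: curved
solids are emitted as dense clouds precisely because hulls are polytopes.
`generate_cohort()` simulates a pure-birth ultrametric tree (depth rescaled
to 1), evolves log10 body mass by Brownian motion affinely rescaled to span
0.2 kg–60 t across 53 taxa by default — the realistic span for a broad
dinosaur cohort — and constructs log10 segment dimensions as
`intercept + slope·log10(mass) + Brownian noise`, recording the truth for
parameter-recovery experiments.

Synthetic skeletons are abstract volumetric stand-ins: they do not mimic
real osteology, scan noise, missing elements, asymmetry, or the judgement
involved in articulating a shoulder girdle. Passing tests therefore
demonstrate that the *computational* pipeline is correct under its stated
assumptions, not that any particular fossil reconstruction is accurate; the
latter depends on mesh quality and on calibrated scaling coefficients that
are consumed as configuration.

## Numerical choices

* Hull degeneracy is handled by a relative tolerance (default 1e-12 on
  simplex volume, scaled by the cloud's bounding-box diagonal); exact
  arithmetic is not attempted. Collinear/coplanar segments are hard errors
  naming the segment.
* Facet visibility during incremental insertion uses a 1e-10·diameter
  slack; points on the surface are treated as interior, which only drops
  duplicated hull vertices.
* PGLS uses ML (not REML) variance; the generalised $R^2$ compares the fit
  against the GLS mean under the same covariance, then is sample-adjusted.
* Zero-length terminal branches in ancestral reconstruction are replaced by
  1e-8 of tree depth, with a warning.
* Brownian simulation accumulates per-branch normal increments in preorder
  under R's default Mersenne-Twister generator, so equal seeds regenerate
  identical cohorts across platforms.

## Problem sizes used in the checks

The bundled verification uses sizes chosen to be decisive yet quick: a
Monte-Carlo hull oracle with 10⁶ bounding-box samples (3-standard-error
agreement), 16-tip trees for the explicit GLS ancestral-state oracle, and a
200-replicate recovery experiment on 64-tip cohorts with true slope 1/3,
checking ~95% CI coverage and mean slope bias below 0.02. These are the
package's own choices of scale; the same machinery runs unchanged at larger
sizes.

## Known limitations

* The hull algorithm is pure R and quadratic in the worst case; it is
  comfortable at the 10²–10⁴ vertices per segment typical of decimated scan
  meshes, but is not tuned for million-vertex raw scans (decimate first —
  hull volume only needs the cloud's extremes).
* Whole-body error bars are conservative envelopes, not probabilistic
  intervals; segment errors are treated as perfectly correlated.
* Reposing moves point-mass COMs only; it does not re-hull overlapping
  geometry and says nothing about joint feasibility or muscle moments.
* Binary PLY faces are skipped (vertices only), and meshes are never
  repaired; degenerate inputs are rejected, not fixed.
* PGLS assumes strict Brownian residuals; no λ/OU relaxation is offered.

## A compact worked example

```{r example, eval = FALSE}
g <- generate_skeleton(template_quadruped(armoured = TRUE), seed = 7)
body <- body_mass_props(g$manifest, expansion_policy("NAS_isometric"))
body
normalize_com(body, g$manifest)

# sensitivity: homogeneous minimal density, osteoderm exclusion, 45° neck pitch
variant_redensify(body, density_scheme("homogeneous_min"))$total_mass
variant_exclude_osteoderms(body)$total_mass
b45 <- repose(body, repose_spec(c("neck_midline_1", "neck_midline_2",
                                  "head_midline_1"),
                                pivot = g$manifest$segments[["neck_midline_1"]]$pivot,
                                angle_deg = 45))
neck_pitch_report(body, b45, g$manifest)

# comparative: PGLS allometry on a synthetic cohort
co <- generate_cohort(n_taxa = 64, true_slope = 1/3, sigma2 = 0.01, seed = 1)
fit_allometry(setNames(co$data$log10_dim, co$data$taxon),
              setNames(co$data$log10_mass, co$data$taxon),
              tree = co$tree, method = "PGLS", iso_slope = 1/3)
```
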