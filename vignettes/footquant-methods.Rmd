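---
title: "Measurement model and simulation design in footquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement model and simulation design in footquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footquant)
```

## The measurement model

`footquant` computes fifteen standard anthropometric measurements from a
3-D surface scan of a foot and six named anatomical landmarks: the
centre of the heel (`HEEL`), the heads of the first and fifth
metatarsals (`MT1`, `MT5`), the apex of the medial longitudinal arch
(`ARCH`), and the two malleoli (`MED_MAL`, `LAT_MAL`). All coordinates
are millimetres; there is no unit autodetection, because a silent
inch/mm guess would corrupt every girth by a factor of 25.4.

### Registration

The three plantar landmarks define the anatomical frame: the heel is
the origin, the longitudinal Y axis is the in-plane unit component of
heel → midpoint(MT1, MT5), the vertical Z axis is the plantar-plane
normal oriented dorsally, and the mediolateral X axis completes the
right-handed frame (pointing MT1 → MT5). Two choices here were
genuinely open:

* the longitudinal axis is *projected into* the plantar plane rather
  than used raw — projection guarantees an orthonormal frame even when
  the metatarsal midpoint sits slightly off-plane;
* the dorsal orientation of Z is disambiguated by the `ARCH` point
  (falling back to the malleoli midpoint), because the arch point is
  present in every usable landmark set, whereas "towards the ankle" is
  not a marked point.

Left and right feet keep their native geometry — no mirroring. All
fifteen measurements are unsigned, so side never affects values; this
is verified by the rigid-invariance property tests. Frames whose
plantar triangle has area ≤ 1 mm² are refused as numerically
meaningless.

### The fifteen measurements

Lengths use the malleoli-trimmed bounding box: vertices above the mean
malleoli height are discarded (removing distal-leg geometry) and the Y
extent of the remainder is the foot length; truncated lengths run from
the rear box face to the Y coordinates of MT1/MT5. Landmark distances
are plain 3-D Euclidean distances.

Widths come from the *plantar trace*, the outline of the lower surface
projected onto the support plane. Forefoot width is the planar distance
between the projected MT1 and MT5 (the projected connecting line);
midfoot and heel widths are mediolateral (X-parallel) chords of the
trace through the projected ARCH and HEEL points. The two conventions
coexist deliberately: the forefoot definition measures the projected
landmark separation, while the chord definition measures the silhouette
at an anatomical station.

The trace itself is computed as the boundary of the projected
downward-facing faces lying entirely below a height cutoff (default:
mean malleoli height). For any scan whose lower surface is a height
field — true of a foot resting on a base plane — these faces tile the
silhouette exactly once, so the outline is the chain of projected edges
used by exactly one such face. This is cheaper and more robust than a
general polygon union and is *exact* for the test geometries; it would
under-report only for a surface overhanging its own sole, which a
weight-bearing foot cannot do. The trace is a genuine (possibly
concave) outline, not a convex hull, so the midfoot waist survives.

Girths are perimeters of closed mesh–plane cross-sections: the ball
girth on the plane through MT1 and MT5 perpendicular to the plantar
plane; the instep girth on the plane perpendicular to Y through the
midpoint of HEEL and MT1; the hindfoot girth on the inclined plane
through the rearmost heel surface point and the midpoint of the medial
malleolus and arch point, the plane containing the mediolateral
direction. Where the geometric constraints were under-determined, the
missing third constraint was fixed for determinism (forefoot plane
vertical; hindfoot plane containing X). Among multiple intersection
loops the one whose centroid is nearest a per-girth anchor point is
selected — a deterministic rule that picks the anatomically intended
loop (e.g. around the metatarsal heads, not a toe). Vertices exactly on
the cutting plane are nudged by 10⁻¹² mm to one side, which keeps the
segment chaining combinatorial and exact. Section accuracy is limited
only by tessellation: an inscribed polygon under-estimates a smooth
perimeter by O(n⁻²), about 0.01% at 128 segments — the tests assert
0.5% against analytic circle and Ramanujan ellipse perimeters.

Arch height is the registered elevation of the `ARCH` point above the
plantar plane, and the arch height index divides it by the truncated
heel–MT1 length, matching the landmark-based convention. The ankle
angle is the angle between the heel → malleoli-midpoint line and the
registered vertical; the "reference line" is taken as +Z, the only
direction the registration makes canonical.

With a partial landmark set (no malleoli) the pipeline still runs:
foot length falls back to the untrimmed bounding box (flagged), and the
two malleoli-dependent values (`hindfoot_girth`, `ankle_angle`) are
`NA` with a `partial_landmarks` flag, mirroring four-landmark clinical
workflows.

## Reliability statistics

Reliability uses the absolute-agreement, single-rater intraclass
correlation from the two-way crossed ANOVA without replication
(ICC(A,1)):

$$\widehat{ICC} = \frac{MS_R - MS_E}
{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$

The intra-user design (one rater, repeated attempts) is tagged as the
two-way *mixed* model and the inter-user design (multiple raters, one
attempt) as the two-way *random* model; both share this computational
form, so the model tag is interpretive metadata. Confidence intervals
use the F-based interval with Satterthwaite-approximated denominator
degrees of freedom. In the MSE → 0 limit (perfect within-subject
agreement) those degrees of freedom tend to k − 1 and the interval
formulas stay finite; the implementation uses that limit explicitly
rather than dividing by a vanishing mean square. Classification bands
are half-open with the conventional cut points: below 0.5 poor, 0.5 to
below 0.75 moderate, 0.75 to below 0.9 good, 0.9 and above excellent.

Study size uses the Walter–Eliasziw–Donner closed form with ceiling
rounding ("sufficient" requires at least the real-valued solution).
With a null reliability of 0.5, expected 0.8, three raters, two-tailed
α = 0.05 and 80% power it returns:

```{r}
icc_sample_size(rho0 = 0.5, rho1 = 0.8, k = 3)
```

The calculation's rater count is not uniquely pinned down by the study
description; k = 3 matches the three-user design and reproduces the
published requirement of 18 scans, and is adopted.

## The synthetic foot and what it does (not) establish

The generator lofts superelliptical cross-sections along the length
axis: a flat plantar half (exponent 8) and a domed dorsal half
(exponent 2.2), with smooth spline profiles for half-width and height,
pole caps at heel and toe, a medial plantar concavity (smooth
compactly-supported cosine window, depth = `arch_height`) and the
distal leg realised as raised hindfoot sections — one closed loft that
is provably manifold at every resolution. Sections are parametrised by
polar angle so vertices stay evenly spread; a power parametrisation
would leave the flat sole almost unsampled and starve the arch
concavity (measurable as a slowly converging instep girth).

Defaults describe an adult foot: length 250 mm, forefoot width 95 mm,
heel width 65 mm, arch height 15 mm at 40% of length, instep 60 mm,
malleoli at 65 mm. The population sampler draws length 250 ± 15 mm
with proportional widths and arch height 15 ± 3 mm — ordinary adult
variation. Ground-truth landmarks are emitted analytically: the three
plantar landmarks exactly on the support plane (1–2 mm inside the
surface, as palpated bony landmarks are), so the canonical frame is
exact and parameter recovery is sharp (length/widths within 2 mm, arch
within 0.5 mm, verified by test).

Weight bearing is modelled linearly in load: arch depth × (1 − 0.5
load), widths × (1 + 0.05 load). The direction (arch flattening,
widening) is physiological; the magnitudes are engineering choices —
the simulator needs a controllable, documented mechanism, not a
validated biomechanical model.

Rater noise: guided landmarking gets 1 mm isotropic jitter; scan-derived
gets 4 mm on the plantar landmarks (which lack visual reference points
on a bare mesh), 3 mm on the arch, 2 mm on the malleoli, plus a 3 mm
anterior bias on the plantar points. Jitter is restricted to each
landmark's local tangent plane (raters click on the surface) and
truncated at ±3σ per axis — a rater visibly off target re-places the
point, and unbounded tails would occasionally violate the
landmarks-near-mesh invariant and abort a simulated study. The arch
point's tangent plane is taken sagittal (it sits on the medial
border), so its height *is* noisy under scan-derived placement;
perturbed arch points are clamped to at least 1 mm above the support
plane, since a click below the sole is physically impossible.

A green simulation test therefore establishes: the pipeline is exact
on known geometry, rigid-invariant, scale-equivariant, and its
reliability statistics respond to landmark noise in the right direction
and order (guided beats scan-derived for heel-referenced distances;
ICC falls monotonically with rater sigma). It does **not** establish
agreement with any human study's numerical ICC values: real scans
carry soft-tissue deformation, scanner artefacts, stitching seams and
pathological shape variation that the loft does not emulate, and no
simulated ICC is claimed to reproduce published per-measurement
values.

## Deviation analysis

Design consistency compares two meshes by signed point-to-surface
distance: for every test-mesh vertex, the exact nearest point on the
reference surface (point–triangle distances with a
centroid-plus-circumradius pruning bound, so the result is exact, not
k-nearest approximate), signed by the nearest face's outward normal.
Sampling at test vertices is deterministic and adequate at scan
resolution — a documented difference from proprietary samplers.
Summaries report the fractions inside/above/below a symmetric band
(default ±1 mm, the orthotic-industry acceptance band), with the
boundary counted as in-tolerance ("within" read inclusively). Meshes
are compared in the coordinates given — no ICP pre-alignment — because
designs derived from the same scan share its frame; aggregate
conformity percentages from any real orthotic data set depend on those
proprietary geometries and are reproduced here only as a statistic
definition.

## Numerical choices, in one place

* vertex merge on STL read: 1 mm × 10⁻⁶;
* plantar-triangle degeneracy threshold: 1 mm² area;
* on-plane vertex nudge for sections: 10⁻¹² mm;
* downward-face test for the trace: face normal z < −10⁻⁹;
* heel rear point: minimum-Y vertex within ±5 mm of the heel's X, at
  or below malleoli height;
* rater jitter truncation: ±3σ (keeps per-axis SD at 0.987σ);
* angles computed in full precision, rounded only at output.

## Known limitations

The trace assumes the lower surface is a height field; the generator
assumes the canonical pose for weight-bearing deformation and landmark
perturbation; PLY support is ASCII-only; meshes with incoherent face
orientation will sign deviations and select trace faces incorrectly
(orientation is the STL convention and is guaranteed by the
generator).
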