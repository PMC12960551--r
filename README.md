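# footquant

Landmark-based foot morphometry from 3-D surface scans, with the
reliability and design-consistency machinery needed to validate such a
measurement pipeline — aimed at orthotists, podiatric researchers and
anyone building digital workflows around foot scans.

Clinical orthotic design increasingly starts from a 3-D scan instead of
a plaster cast. The quantitative step in that workflow is: register the
scan into an anatomical coordinate frame defined by palpable landmarks,
then derive the standard measurements (lengths, widths, girths, arch
height) that drive insole design. `footquant` implements that step
end to end, plus the statistics used to ask whether it is *reliable* —
within one user, across users, and across the landmarking method
(palpation-guided stickers vs. landmarks guessed on the bare mesh).

## What it computes

Given a triangle mesh (binary/ASCII STL or ASCII PLY, millimetres) and
up to six named landmarks (`HEEL`, `MT1`, `MT5`, `ARCH`, `MED_MAL`,
`LAT_MAL`), the package:

1. builds the anatomical frame — heel at the origin, Y towards the
   midpoint of the metatarsal heads, Z the dorsal plantar-plane normal,
   X mediolateral — and rigidly registers the scene;
2. derives **15 measurements**: foot length (malleoli-trimmed bounding
   box), heel→MT1 and heel→MT5 truncated lengths, the three pairwise
   landmark distances, forefoot/midfoot/heel widths from the plantar
   trace, forefoot/midfoot/hindfoot girths from mesh–plane
   cross-sections, arch height, arch height index (AHI = arch height /
   heel–MT1 length), and the ankle angle.

Reliability of a panel of such measurements is summarised by the
two-way absolute-agreement single-rater intraclass correlation
(McGraw–Wong ICC(A,1)):

    ICC = (MSR − MSE) / (MSR + (k−1)·MSE + (k/n)·(MSC − MSE))

with F-based 95% confidence intervals (Satterthwaite df), the standard
poor/moderate/good/excellent bands at 0.5 / 0.75 / 0.9, and the
Walter–Eliasziw–Donner sample-size formula. Surface consistency between
two design meshes is measured by signed point-to-surface deviation and
the fraction of the surface within a symmetric tolerance band (default
±1 mm).

A parametric synthetic foot generator (closed manifold loft with
ground-truth landmarks, weight-bearing deformation, and per-landmark
rater noise models) makes the whole study design simulable with no
external data.

## Worked example

```r
library(footquant)

g <- generate_foot(foot_params(), resolution = 64, seed = 1)
measure_foot(g$mesh, g$landmarks, condition = "NWB")
```

```
measurement_report for 'synthfoot_L250_seed1' (guided, NWB)
               name    value units
        foot_length 250.0000    mm
 heel_to_mt1_length 180.0000    mm
 heel_to_mt5_length 180.0000    mm
      dist_mt1_heel 157.3412    mm
       dist_mt1_mt5  95.0000    mm
      dist_mt5_heel 157.3412    mm
     forefoot_width  95.0000    mm
      midfoot_width  57.3759    mm
         heel_width  64.9870    mm
     forefoot_girth 250.0048    mm
      midfoot_girth 219.1368    mm
     hindfoot_girth 319.1181    mm
  arch_height_index   0.0833 ratio
        arch_height  15.0000    mm
        ankle_angle  17.1027   deg
```

The generated foot has length 250 mm, MT1–MT5 separation 95 mm and arch
height 15 mm, and the pipeline recovers them exactly; the AHI of 0.0833
is 15 mm over the 180 mm truncated length. Under full weight bearing
the simulated arch drops by half:

```r
wb <- apply_weight_bearing(g$mesh, g$landmarks, g$params, load = 1)
measure_foot(wb$mesh, wb$landmarks)[["arch_height"]]
#> [1] 7.5
```

A simulated inter-user reliability study (three guided raters, 12
scans), analysed per measurement:

```r
des <- study_design(n_subjects = 6, feet_per_subject = 2,
                    conditions = "NWB",
                    raters = list(A = rater_model("guided"),
                                  B = rater_model("guided"),
                                  C = rater_model("guided")),
                    seed = 42, resolution = 32)
panel <- simulate_reliability_study(des)
tab <- reliability_table(panel, design = "inter")
head(tab[order(tab$estimate),
         c("measurement", "estimate", "ci_low", "ci_high", "class")], 5)
#>          measurement estimate ci_low ci_high     class
#> 15       ankle_angle    0.542  0.192   0.819  moderate
#> 13 arch_height_index    0.909  0.781   0.970 excellent
#> 14       arch_height    0.913  0.791   0.972 excellent
#> 12    hindfoot_girth    0.943  0.858   0.982 excellent
#> 5       dist_mt1_mt5    0.975  0.937   0.992 excellent
```

Even with millimetre-level guided noise, the angle (a short lever arm
between noisy points) is the least reliable quantity — the kind of
conclusion the simulator exists to explore. How many scans would a
reliability study need to distinguish ICC 0.8 from a 0.5 floor with
three raters?

```r
icc_sample_size(rho0 = 0.5, rho1 = 0.8, k = 3)
#> [1] 18
```

## Landmark file schema

CSV with header `id,x,y,z` (mm), ids from the six above; or JSON
`{"HEEL": [x, y, z], ..., "side": "right", "source": "guided"}`. Sets
without the malleoli are accepted and flagged; the three
malleoli-dependent outputs are then `NA`/untrimmed.

## Command line

```sh
Rscript -e 'footquant::foot_cli()' measure foot.stl landmarks.csv --out out/
Rscript -e 'footquant::foot_cli()' reliability panel.csv --design inter --out out/
Rscript -e 'footquant::foot_cli()' compare design_a.stl design_b.stl --tol 1.0 --out out/
Rscript -e 'footquant::foot_cli()' simulate design.cfg --out out/
```

Each run appends a reproducibility record (seed, arguments, package
version) to `run_log.jsonl` in the output directory. Exit codes: 0
success, 1 domain error, 2 usage error.

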