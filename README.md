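# lvfuse

Fusion analysis of left-ventricular (LV) surface models from different
cardiac imaging modalities — typically cardiac magnetic resonance (CMR,
the reference standard) and 3D echocardiography. The package is for
imaging methodologists who need to compare LV geometry across modalities
or segmentation tools: it brings both models into a common cardiac
coordinate system, registers them rigidly per cardiac phase, re-fits them
to one template so point-wise correspondence exists, and quantifies their
agreement regionally, globally and statistically.

## What it computes

**Cardiac frame.** From fiducial landmarks: origin at the basal centroid,
`e_long` toward the apex, `e_rv` toward the RV centroid (mean of the RV
insertion points; for echo, estimated as 70° clockwise from the inferior
insertion viewed apex-to-base), `e_norm = e_long × e_rv`.

**Registration.** Closed-form coarse alignment of the two frames, then
trimmed point-to-point ICP (SVD updates), independently for end-diastole
and end-systole.

**Common template.** Each surface is re-fitted by regularized linear
least squares to a periodic radial field r(u, φ) on an n<sub>u</sub> × n<sub>v</sub>
grid, giving node-wise correspondence between modalities.

**Regional error.** The AHA partition (16 endocardial segments, 17
epicardial including the apical cap) and, per segment,

&nbsp;&nbsp;&nbsp;&nbsp;MSD<sub>AHA</sub> = (1/N<sub>p</sub>) Σ<sub>p</sub> d(M<sub>p</sub>, E<sub>p</sub>),

the mean Euclidean distance between corresponding points of the reference
model M and the re-fitted test model E.

**Global indices.** EDV, ESV, EF = 100·(EDV−ESV)/EDV, LV mass
(shell volume × 1.05 g/ml), and BSA-indexed variants, all computed with
one divergence-theorem volume operator on the fitted surfaces.

**Image intensity.** Per-AHA-segment mean signal intensity of a
co-registered 3D volume, as a percentage of the peak after per-image
normalization between 0 and the 95th percentile (myocardial-shell
sampling in cardiac coordinates).

**Agreement statistics.** Paired t-tests with a Bonferroni-corrected
threshold (two-tailed P < 0.0167 for three comparisons), two-way
absolute-agreement average-measure ICC(A,k), and Bland–Altman limits of
agreement for two methods or for k ≥ 3 methods against the per-subject
mean.

**Phantoms.** A deterministic truncated-prolate-spheroid phantom
generator with known rigid misalignments, known regional inward
deformations, echo-like intensity volumes with circumferential dropout,
and cohort sampling — the ground truth every pipeline stage is validated
against.

## Worked example

Generate a phantom whose echo copy is misaligned by a known rigid
transform and underestimates the basal anterolateral wall (segment 6) by
8 mm, then run the full fusion:

```r
library(lvfuse)

ph  <- make_phantom(phantom_spec(seed = 42))
ph  <- apply_regional_bias(ph, segment = 6, amplitude = 8)
res <- fuse_subject(ph$echo, ph$cmr, bsa = ph$bsa, subject = "P001")

res$registration$ED
#> Registration [ED]: total rotation 5.722 deg, RMS residual 1.5265 mm, 9 iteration(s), converged

res$volumetrics
#>   subject method   EDV   ESV    EF   LVM  BSA  EDVI  ESVI  LVMI
#> 1    P001    CMR 142.4 56.94 60.00 141.0 1.88 75.72 30.29 74.98
#> 2    P001   echo 136.5 53.27 60.96 138.9 1.88 72.59 28.34 73.91

m <- res$msd[res$msd$phase == "ED" & res$msd$surface == "endo", ]
head(m[order(-m$msd), c("segment", "segment_name", "msd", "n_points")], 3)
#>            segment        segment_name   msd n_points
#> ED endo.6        6 basal anterolateral 7.841       32
#> ED endo.5        5 basal inferolateral 1.703       32
#> ED endo.12      12   mid anterolateral 0.914       32
```

The registration recovers the (unknown to it) 5.7° misalignment; the CMR
volumetrics land on the phantom's analytic targets (EF exactly 60%); the
echo volumes are smaller because of the imposed wall underestimation; and
the regional report localizes that 8 mm deformation to segment 6 at
7.84 mm — the residual being re-fit discretization and smoothing.

Cohort-scale runs, with agreement statistics and CSV/JSON reports:

```r
res <- run_pipeline(list(simulate = list(n = 20, seed = 1),
                         out_dir = "reports"))
```

A command-line driver with `simulate`, `fuse`, `fit`, `msd`, `indices`,
`intensity`, `stats` and `run` subcommands is installed at
`inst/cli/lvfuse.R` (see its header for the directory conventions).

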