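# qsmfid

Automatic detection of implanted gold fiducial markers in prostate MRI
by quantitative susceptibility mapping (QSM), for MRI-only radiotherapy
planning workflows.

Gold markers guide X-ray-based patient positioning, but on MRI they
appear only as signal voids on T2\*-weighted gradient-echo images —
indistinguishable by eye from air pockets and calcifications. Their
magnetic susceptibility is distinctive: gold reads near −36 ppm relative
to tissue, calcification near −21 ppm, air near zero. `qsmfid`
reconstructs the susceptibility map from a multi-echo gradient-echo
acquisition and extracts marker candidates from it:

1. per-voxel nonlinear fit of the complex signal
   `s_j = A exp(i φ0) exp((i 2π f − R2*) TE_j)` → total field map;
2. Laplacian phase unwrapping (used to resolve temporal alias branches);
3. background field removal by projection onto the dipole field (PDF);
4. characterization of signal voids by their equivalent dipole moment
   `m = χ·V`, first-echo rescue of dephased rim voxels, and
   model-consistent inpainting of the void core;
5. zero-referenced, morphology-regularized dipole inversion
   (`min ‖W(D*χ − b)‖² + λ1‖M_G ∇χ‖₁ + λ2‖M_ref(χ − χ̄_ref)‖²`),
   with a thresholded k-space division (TKD) baseline;
6. histogram threshold at −28 ppm inside the dilated prostate mask,
   discrete-pixel removal, slice-connected region labeling, centroid
   localization, and classification into gold / calcification / air
   susceptibility bands.

The package also provides a digital pelvis phantom (partial-volume
rasterization, dipole field, intra-voxel static dephasing, seeded
complex noise) with ground-truth marker positions, the rigid
frame-coordinate calibration from MR-visible rods (Kabsch fit), and the
evaluation metrics used for validation (detection rate, centroid
displacement, signed/absolute mean error, Dice coefficient). The
methods vignette (`vignettes/qsm-fiducial-detection.Rmd`) documents the
models, the parameter choices and their rationale.

## Worked example

Simulate the default pelvis phantom (three 3 mm gold markers, one
calcification, one rectal air pocket, 1% complex noise) and run the
detection chain:

```r
library(qsmfid)

phantom <- simulate_phantom(default_phantom(compact = TRUE, seed = 42))
det <- detect_markers(phantom)
det
#> qsm_detection: 3 candidate region(s), 3 gold detection(s)
#>    x_mm  y_mm  z_mm n_voxels slice_span chi_mean label detected
#> 1 -1.44  7.56  6.32       32          2    -32.4  gold     TRUE
#> 2 -9.50 -4.50 -4.99       31          3    -32.0  gold     TRUE
#> 3  9.50  2.50  3.00       31          3    -31.7  gold     TRUE

match_markers(as.matrix(det$candidates[det$candidates$detected,
                                       c("x_mm", "y_mm", "z_mm")]),
              phantom$truth$marker_positions)
#> eval_report: 3/3 matched (rate 1.000), mean displacement 0.23 mm, 0 FP, 0 FN
```

All three markers are found within a fraction of a millimeter; their
region-mean susceptibility sits in the gold band near −36 ppm, while the
calcification and the air pocket never enter the candidate list (their
dipole moments are incompatible with a nominal gold marker). Per-void
diagnostics — fitted dipole moment in ppm·mm³ and its susceptibility
equivalent — are in `det$diagnostics$voids`.

A command-line interface wraps the same functions
(`inst/cli/qsmfid`): `simulate`, `recon`, `detect`, `evaluate` and
`frame-calib` subcommands, each writing a `log.json` with configuration
hash, seed, stage timings and convergence diagnostics. Identical
configuration and seed reproduce the marker CSV byte for byte.

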