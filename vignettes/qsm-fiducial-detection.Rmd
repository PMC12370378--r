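---
title: "Detecting gold fiducial markers in prostate MRI with quantitative susceptibility mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gold fiducial markers in prostate MRI with quantitative susceptibility mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsmfid)
```

## The problem

MRI-only radiotherapy planning for prostate cancer needs the implanted
gold fiducial markers localized on MR images. On T2\*-weighted
gradient-echo (GRE) images a gold marker appears as a signal void larger
than its physical size, and voids from air pockets and calcifications
look almost identical. Magnetic susceptibility separates them: gold is
strongly diamagnetic relative to tissue (about $-36$ ppm), calcification
moderately so (about $-21$ ppm), and air essentially matches tissue
(here $+0.024$ ppm). Quantitative susceptibility mapping (QSM)
reconstructs the per-voxel susceptibility $\chi$ from multi-echo GRE
phase, turning an ambiguous void into a classifiable measurement.

`qsmfid` implements the full chain on a conventional 1.5 T internal
marker protocol (six echoes, TE 3.1–24.6 ms, $\Delta\mathrm{TE}$
4.3 ms, $1\times1\times2$ mm voxels), plus a digital pelvis phantom so
that every stage is testable without patient data, the rigid
frame-coordinate conversion from MR-visible rods, and the evaluation
statistics (detection rate, centroid displacement, ME/MAE/Dice).

## Signal model and reconstruction chain

Each voxel's complex signal across echoes follows

$$s_j = A\, e^{i\varphi_0}\, \exp\!\big[(i\,2\pi f - R_2^*)\,
\mathrm{TE}_j\big],$$

with amplitude $A$, coil phase $\varphi_0$, off-resonance frequency $f$
(proportional to the field in ppm of $B_0$), and effective decay
$R_2^*$. The field induced by a susceptibility distribution is, in
k-space,

$$\hat b(\mathbf k) = D(\mathbf k)\,\hat\chi(\mathbf k), \qquad
D(\mathbf k) = \tfrac13 - \frac{k_{B_0}^2}{|\mathbf k|^2},\quad D(0)=0,$$

the unit dipole kernel in the Lorentz-sphere convention. The pipeline
(`detect_markers()`) runs:

1. **Field fitting** (`fit_complex_field`): per-voxel variable-projection
   Gauss–Newton on the complex signal; the complex amplitude has a
   closed-form solution given $(f, R_2^*)$ and the remaining normal
   matrix is diagonal, so the damped update is cheap and robust.
   Reliability weights combine normalized amplitude with a soft gate on
   the fit residual. Fitting the complex signal makes temporal aliasing
   (above $1/(2\Delta\mathrm{TE}) \approx 116$ Hz) rather than spatial
   wrapping the limiting factor.
2. **Laplacian unwrapping** (`laplacian_unwrap`, `unwrap_field`): the
   Poisson problem $\nabla^2\varphi_u = \cos\varphi\,\nabla^2\sin\varphi
   - \sin\varphi\,\nabla^2\cos\varphi$ is discretized through wrapped
   neighbor differences (the stencil identity reduces the right side to
   $\sum \sin\delta$, and replacing $\sin\delta$ by the wrapped
   difference $\delta$ removes the cubic small-angle bias, making the
   right side exact wherever true phase steps stay below $\pi$), then
   solved spectrally on the mirror-extended volume. The unwrapped
   surface is used only to pick the integer alias branch per voxel; the
   precise fitted value is kept.
3. **Background removal** (`pdf_remove`): projection onto the dipole
   field — fit an exterior susceptibility distribution, supported
   outside the (2-voxel-eroded) body mask, to the measured field by
   conjugate gradients, and subtract its induced field. The body mask,
   not the prostate mask, defines the region of interest; the prostate
   only restricts the later search.
4. **Void characterization and rim rescue** (`inpaint_void_fields`,
   `rescue_dephased_field`): see the next section — this is where metal
   QSM differs from brain QSM.
5. **Dipole inversion** (`invert_medi0`, with `invert_tkd` as the fast
   baseline): zero-referenced, edge-regularized inversion
   $$\min_\chi \|W(D*\chi - b)\|^2 + \lambda_1 \|M_G \nabla\chi\|_1
   + \lambda_2 \|M_{\mathrm{ref}}(\chi - \bar\chi_{\mathrm{ref}})\|^2$$
   by IRLS with conjugate-gradient inner solves. $M_G$ releases the
   gradient penalty where the magnitude image has edges (above the 70th
   percentile of its gradient), so susceptibility boundaries can
   coincide with anatomy. The reference region defaults to body tissue
   away from the prostate and from strong sources
   ($|\chi_{\mathrm{TKD}}| \le 5$ ppm); after solving, the map is
   shifted so the reference mean is exactly zero. The full
   published form of morphology-enabled inversion (CSF referencing,
   merit-based regularization selection) is intentionally not
   reproduced: a cerebrospinal-fluid reference does not exist in the
   pelvis, and the phantom recovery tests validate this simpler,
   linear-fidelity contract directly. A model-error reweighting step
   (Huber-type down-weighting of fidelity outliers) is on by default.
6. **Candidate extraction** (`threshold_candidates` through
   `summarize_and_classify`): threshold at $-28$ ppm (midpoint between
   the gold and calcification distributions), discrete-pixel removal,
   26-connected labeling with a minimum 2-slice extent, $|\chi|$-weighted
   centroids, and classification into gold $[-48, -24]$, calcification
   $(-24, -10]$, air $[0, \infty)$ bands (nominal $\pm3\sigma$ with the
   boundary at the midpoint).

## What is special about metal: voids, biased rims, and the volume convention

Three facts dominate QSM around a gold marker and drove the design:

* **The void hides the strongest data.** With a first echo at 3.1 ms,
  static dephasing extinguishes the signal not just inside the marker
  but in a halo around it. The voxels that would pin down the source
  most strongly have no usable phase at all.
* **The rim is biased, not just noisy.** Voxels at the edge of the void
  contain several sub-voxel frequency populations. Their mono-exponential
  fit converges — to a frequency biased toward zero, because the
  fast-precessing populations dephase away over the echo train. Left in
  the fidelity term these voxels actively cancel the very moment that
  created the void. Two mitigations are built in: the first-echo phase
  (least dispersed, unambiguous over $1/\mathrm{TE}_1 \approx 5$ ppm) is
  used to re-estimate suspect voxels (`rescue_dephased_field`), and the
  inversion's robust reweighting suppresses what remains.
* **Only the moment is measurable.** The exterior field of any compact
  source is exactly that of a point dipole with moment $m = \chi V$
  (ppm·mm³), so $\chi$ and $V$ cannot be separated from field data once
  the interior is voided. `inpaint_void_fields` therefore fits, for each
  connected void, the moment and a local offset on the surrounding shell
  of reliable voxels (with sub-voxel center refinement), and converts
  $m$ to susceptibility through a **volume convention**: the physically
  known size of the implanted marker
  (`detect_markers(marker_radius_mm = 3)`). This mirrors clinical
  reasoning — "is this void's moment consistent with my marker?" — and
  gives the desired contrast: a void whose moment matches a nominal gold
  marker reads near $-36$ ppm, an equally sized calcification near
  $-20$ ppm, an air pocket near zero. The hole is then inpainted with
  the field of the rasterized equivalent sphere (computed with the same
  discrete dipole operator the inversion uses; an analytic point-dipole
  tail would overshoot at the sphere surface), restoring a
  well-conditioned inversion. Without this step the inversion's slowest
  modes are the source amplitudes themselves and conjugate gradients
  stall far from the optimum.

## The digital phantom

`default_phantom()` builds a pelvis-like scene: body and prostate
ellipsoids, three intraprostatic gold spheres, a 2 mm-radius prostatic
calcification ($-21$ ppm, reduced proton density, elevated intrinsic
$R_2^*$), and a 10 mm rectal air pocket ($+0.024$ ppm, no signal). The
acquisition defaults mirror the internal-marker protocol: 6 echoes,
TE 3.1–24.6 ms, $1\times1\times2$ mm voxels, 1.5 T, B0 along the slice
axis, complex Gaussian noise at 1% of the tissue signal.

Simulation steps: antialiased partial-volume rasterization (signed
distance coverage on a supersampled grid, refined adaptively for
sub-resolution inclusions; integrated susceptibility is conserved to
well under 1% at `oversample = 4`), dipole field by padded FFT
convolution, intra-voxel static dephasing $R_2' = 2\pi\,\gamma B_0\,
\mathrm{sd}(\delta B)$ computed on supersampled windows around each
susceptibility source (the dipole field decays as $r^{-3}$, so windowed
evaluation changes nothing where it matters), and the closed-form echo
signal with seeded noise.

Deliberate design choices:

* **Marker size.** The wire of a fine-wire anchor marker is only
  ~0.3 mm across, but it is implanted folded, and moment conservation
  makes the bare-wire footprint undetectable by construction on this
  protocol: a source of moment $m$ diluted into $1\times1\times2$ mm
  voxels can never produce voxel values below $m/V_{\mathrm{vox}}$, and
  the fixed $-28$ ppm cut plus the 2-slice rule additionally require
  $\chi \le -28$ ppm voxels in two adjacent 2 mm slices. Closed-form
  raster arithmetic shows a $\chi = -36$ ppm sphere satisfies that for
  every slice alignment only from about 3 mm radius, which is therefore
  the default effective marker footprint (and the default nominal radius
  of the volume convention).
* **Placement.** Marker centers sit on voxel centers — the usual
  digital-phantom convention, equivalent to a rigid shift of the grid.
  Corner-of-voxel placement dilutes the voxelized core (to ~0.66 of the
  material value for a 2 mm sphere); the moment-based detection chain is
  insensitive to this, but the voxelized ground-truth core value is not.
* **Field of view.** The full phantom is $160\times160\times48$ voxels.
  The `compact = TRUE` variant ($96\times96\times32$, identical voxel
  size, inclusions, susceptibilities and noise) is used for repeated
  end-to-end simulations — the methods are FFT-bound and the compact
  field of view keeps a 20-realization study affordable; physics is
  unchanged.
* Gold and air carry `m0 = 0` (no proton signal); slice overlap from the
  clinical protocol (-1 mm gap) is not simulated — contiguous slices are
  a reconstruction-side detail irrelevant to the dipole physics. No
  k-space simulation (no coil sensitivities, no undersampling): the
  signal model is image-domain.
* The air value $+0.024$ ppm is adopted as printed in the source
  protocol's material table; commonly tabulated air-tissue contrasts are
  larger. Nothing downstream depends on it — air is rejected because its
  moment is tiny, not because of its exact value.

What passing phantom tests does *not* show about real data: coil phase
singularities, flow and motion, fat chemical shift, B0 drift,
through-slice dephasing from shim gradients, and marker shapes far from
spheres are all absent. The sanity cross-check against the anatomical
T1/T2 sequences described in the clinical workflow remains a manual QA
step; the CLI emits candidate coordinates so a viewer can perform it.

## Numerical choices

* FFT grids are padded (2$\times$ for forward simulation, 1.4–1.5$\times$
  rounded to 5-smooth sizes inside iterative solvers) to suppress
  circular wrap-around of the $r^{-3}$ dipole tails.
* PDF: conjugate gradients on the normal equations, relative residual
  $10^{-3}$ or 100 iterations (the pipeline caps at 30 — the remaining
  correction is below the phantom noise floor); 2-voxel mask erosion
  before solving.
* IRLS: $\varepsilon = 10^{-3}$ ppm smoothing of the L1 norm; inner CG
  tolerance $10^{-2}$; convergence when the outer relative update falls
  below 1%; the best iterate is returned (with a warning) otherwise.
  $\lambda_1 = 10^{-3}$, $\lambda_2 = 0.1$ on ppm-scaled inputs, chosen
  on the default phantom and exposed as arguments.
* Degenerate inputs: all-zero voxels get reliability 0 and the initial
  field value, never an error; empty reference masks and whole-grid
  PDF masks are errors; empty candidate sets propagate as empty tables.
* Tie-breaks: when more than `max_markers` gold-band regions survive,
  the ones closest to $-36$ ppm are reported as detections and the rest
  flagged `surplus` for physicist review.
* Problem sizes used by the test suite and the acceptance script:
  analytic-sphere checks at $64^3$, unwrapping at $48\times48\times16$,
  background removal at $48\times48\times32$, noiseless recovery and the
  repeated-detection study on the compact phantom, 12–20 noisy
  realizations per study.

## Frame geometry

`detect_rods` finds the bright, elongated silicone rods in the inferior
quarter of a T2-weighted volume (intensity percentile, 26-connected
labeling, principal-axis elongation test) and returns their centroids
left-to-right; `fit_rigid` is the SVD (Kabsch) least-squares rotation +
translation with reflection correction, exact on congruent triplets and
validated against a quaternion-search oracle under jitter; `map_point`
carries any MRI position into frame coordinates. The frame's native rod
coordinates are institution-specific hardware and are supplied as YAML
(`inst/extdata/frame_example.yaml` is a synthetic example geometry).

## Known limitations

* The susceptibility assigned to a void rests on the nominal-volume
  convention; a marker whose folded footprint differs grossly from the
  configured radius will read proportionally off. The underlying moment
  (ppm·mm³) is reported per void and is convention-free.
* Fields between the temporal Nyquist limit and the first-echo limit
  (roughly 1.8–5 ppm) rely on the alias-branch reference being within
  half a period; beyond ~5 ppm only model-consistent inpainting covers
  the gap.
* The evaluation gate (5 mm) and the detection parameter defaults assume
  marker separations of a few centimeters; markers closer than the void
  diameter merge into one candidate.
* Absolute susceptibility referencing is out of scope; all values are
  contrasts against the zero-referenced tissue baseline.
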