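---
title: "Benchmarking PET radionuclides on synthetic phantoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking PET radionuclides on synthetic phantoms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petbench)
```

## The problem

The radionuclide used in a PET study shapes the reconstructed image through
three physical channels: the positron range (higher emission energies blur the
annihilation point further from the decay site), the positron branching ratio
(fewer positrons per decay mean fewer counts per becquerel), and co-emitted
prompt gammas (extra high-energy photons that feed spurious coincidences).
`petbench` packages the machinery needed to compare radionuclides —
¹⁸F, ⁶⁴Cu, ⁶⁸Ga and ⁴⁴ᵍSc in the built-in library — on equal footing:
decay-equalized acquisition planning, a synthetic phantom image simulator with
radionuclide-specific degradation, and the NEMA NU 4-2008-style metric suite
(uniformity %SD, recovery coefficients, spill-over ratios, Derenzo rod
contrast, and noise-equivalent count rates).

## Decay-equalized planning

Comparing nuclides at equal *activity* confounds count statistics with decay
physics. The planner instead equalizes the number of positron annihilations:
for initial activity $A_0$, branching ratio $BR$ and decay constant
$\lambda = \ln 2 / T_{1/2}$, the annihilations accumulated in time $t$ are

$$N(t) = A_0\, BR\, \frac{1 - e^{-\lambda t}}{\lambda},$$

inverted in closed form to find the time each nuclide needs to match a
reference ¹⁸F scan (3.7 MBq, 1200 s — typical mouse-imaging conditions):

```{r}
equalized_time_table()
```

By default the reference yield is rounded to 3 significant figures before
inversion, matching the precision at which planning tables quote it; pass
`round_reference = FALSE` for the unrounded inverse. ⁶⁸Ga planning uses its
*total* positron branching ratio (0.888) rather than the dominant-branch
value (0.877): the total is what determines annihilation statistics.

The radioscandium composition from natural-calcium irradiation is shipped as
`scandium_mixture()` (94.9% ⁴⁴ᵍSc at end of beam). `mixture_composition_at()`
evolves each component by its own exponential; ⁴⁴ᵐSc → ⁴⁴ᵍSc isomeric
in-growth (a two-member Bateman term) is available behind
`include_feeding = TRUE` but is off by default — the published composition
columns verify against pure per-component decay, and at < 1% parent abundance
the in-growth correction is below the rounding of the table.

## Phantom models and voxelization

Three parametric phantoms mirror the standard preclinical set:

* **NEMA IQ phantom** (`build_iq_phantom()`): 30 mm active diameter;
  a rod section (fillable rods of 1–5 mm drilled in solid PMMA), a uniform
  region, and two 8 mm cold chambers (one water, one air) surrounded by
  activity. Published drawings do not pin every wall thickness, so defaults
  follow the NU 4-2008 nominal phantom (20/15/15 mm sections, rods at 7 mm
  radius, chambers at ±7.5 mm) and every dimension is an argument.
* **Derenzo phantom** (`build_derenzo()`): six 60° sectors with rod diameters
  2.5–0.8 mm, triangular lattices at center-to-center spacing twice the
  diameter. Rows grow outward from an apex rod at 1.5 d from the center and
  stop at 12.5 mm, which fills the 30 mm field with at least three rows per
  sector; exact rod counts are layout choices, not metric inputs, and are
  exposed as arguments.
* **NEC phantom** (`build_nec_phantom()`): 50 × 150 mm high-density
  polyethylene cylinder with a 140 mm line source 17.5 mm off axis.

`voxelize()` paints z-aligned cylindrical primitives in order with
sub-voxel-coverage weighting (analytic overlap axially, `supersample`²
sub-pixels in-plane), producing anti-aliased activity and attenuation grids.
The μ map uses the five-material segmentation convention (background 0,
bed 0.015, water 0.095, bone 0.178, aluminum 0.22 cm⁻¹); PMMA and HDPE bodies
are water-equivalent at that segmentation. Totals agree with analytic
cylinder volumes to better than 0.5% at the default 0.2 mm grid with
`supersample = 3`.

## The image-domain degradation model

Tomographic reconstruction itself is out of scope; the simulator works
directly in image space with the degradation structure the metrics assume:

1. **Positron-range blur.** No canonical annihilation-point kernel exists, so
   the package uses a two-component radial kernel: a Gaussian core whose
   width tracks the range at the *mean* emission energy and an exponential
   tail scaled to the endpoint-energy range, both from a Katz–Penfold-style
   empirical range–energy fit and scaling inversely with medium density.
   Absolute widths are a modeling choice; analyses and tests rely only on
   the monotone energy → width mapping (¹⁸F < ⁶⁴Cu < ⁴⁴ᵍSc < ⁶⁸Ga).
   The sampled kernel support is capped at 5 mm and renormalized.
2. **System blur.** An isotropic Gaussian whose FWHM emulates the
   detector-plus-reconstruction point spread; reconstruction algorithms are
   represented as width presets (wider for analytic reconstruction, narrower
   with optional ringing for resolution-modelled iterative reconstruction).
   Default 1.5 mm.
3. **Air cavities.** Annihilations landing inside air-filled regions are
   suppressed by the air/water density ratio (~1.2 × 10⁻³): positrons
   ranging into air mostly traverse it. This makes spill-over into the air
   insert scatter-driven and nearly radionuclide-independent, while the
   water insert collects genuine positron-range spill — the two regimes the
   phantom is designed to separate.
4. **Scatter background.** A spatially uniform field over the phantom
   support carrying `scatter_fraction` of the counts (default 0.15).
   "Scatter corrected" subtracts the *expected* background, as an estimated
   correction would, leaving its noise behind.
5. **Poisson noise.** The expected image is scaled so its total equals
   `detection_efficiency × positron decays` (efficiency default 0.02; only
   relative quantities are asserted), each voxel drawn independently
   Poisson, then rescaled to concentration units. Seeded draws are
   bit-reproducible.
6. **Gibbs ringing** (optional). An unsharp mask whose gain is calibrated
   analytically so a step edge overshoots by the requested relative
   amplitude at the voxel adjacent to the edge; the smoothing is DC-neutral
   so the image mean is preserved.

`expected_recon_image()` exposes the deterministic part separately from
`add_counting_noise()` so multi-seed studies pay the FFT cost once per
nuclide.

## Metric conventions

* VOIs are analytic cylinders; a voxel belongs to a VOI when its center is
  inside. Sample (n−1) standard deviations are used throughout (the
  convention is not universal; population-SD would shrink the hand-checked
  three-voxel example from 10% to 8.2%).
* Recovery coefficients follow the max-pixel procedure: average the central
  10 mm of slices, search a circular ROI of *twice the rod diameter* (read
  as diameter, not area) for the maximum of the averaged image, then profile
  the original volume axially at that pixel. Ties resolve to the lowest
  (row, column) index. The percent-scale uncertainties
  $\sigma_{RC}, \sigma_{SOR} = 100\sqrt{(STD/C)^2 + \dots}$ keep the
  conventional 100× factor despite multiplying fraction-scale metrics.
* Derenzo contrast uses a profile from the sector's apex rod to the
  outermost rod on the sector bisector (a deterministic choice among the
  "outer" rods), sampled at 0.1 mm with bilinear interpolation, on the
  central slice of the rod region. $C = (C_{max}-C_{min})/(C_{max}+C_{min})$
  with the valley search excluding half a diameter at each end so the
  endpoint rods define the peaks.
* NU-4 rate extraction: mask radial bins beyond the phantom radius + 8 mm,
  center each angular row on its maximum, sum rows, and count trues inside
  the central ±7 mm band above the linearly interpolated band-edge
  background. Randoms come from the delayed sinogram under the same mask;
  scatter is the remainder; $NECR = R_T^2/(R_T+R_S+R_R)$.

## Count-rate model

The paper-level rate model is parametric
(`rate_model_params()`): paralyzable dead time on the trues
($R_T = sBRA\,e^{-sBRA\tau}$, default $\tau = 2\times10^{-7}$ s), scatter at
a fixed scatter fraction (default 0.30, a typical rat-phantom value),
randoms growing as activity squared, and a spurious-coincidence load
proportional to the summed prompt-gamma yield, split between scatter-like
(∝ A) and random-like (∝ A²) shares by `spurious_random_share`. The split is
a modeling knob: standard rate extraction cannot distinguish spurious events
from scatter and randoms, so only the direction of the prompt-gamma effect
(NECR strictly depressed at every activity) is asserted. Sinograms default
to 128 radial bins × 0.8 mm × 160 angles, single direct plane; frame
durations obey the quarter-half-life rule (15 min for ¹⁸F/⁶⁸Ga, 30 min for
⁴⁴ᵍSc), and ⁶⁴Cu is excluded from the count-rate study by default since
matching positron rates would need ~5.5× the ¹⁸F activity and a > 3 day
decay from 100 to 1.5 MBq.

## What the synthetic data can and cannot show

The generator reproduces the *structure* of radionuclide-dependent
degradation — blur that grows with positron energy, scatter/spill
backgrounds, count statistics under decay-equalized budgets, prompt-gamma
rate loads — so orderings and scalings (which nuclide recovers more, spills
more, resolves finer structure; how noise scales with counts) are
meaningful. It does not model scanner-specific physics: detector-block
geometry, sinogram-domain reconstruction artifacts, attenuation and its
correction, energy-window photon transport, or Monte-Carlo positron
trajectories. Absolute metric values from real acquisitions are therefore
not reproduced, and the test suite asserts orderings, invariants and
hand-computable formula values rather than absolute published measurements.

## Numerical choices and problem sizes

Simulation grids default to 0.2 mm isotropic (finer than the 0.388 mm
reconstructed pixel convention, so rasterization error is small against the
0.8 mm smallest rod) with `supersample = 3`. Convolutions are zero-padded
FFTs (5-smooth lengths), exact to linear convolution within the padded
field. The Derenzo analyses run on a single-slice grid by default: the rods
are z-invariant over scales much longer than the kernels, so the slab is the
axial projection of the rod region: the in-plane result is unchanged, the
full coincidence budget contributes to it, and the cost drops by the slice
count. The ordering
test suite uses the full 0.2 mm IQ grid (188 × 188 × 270 voxels) across five
seeds and four nuclides; unit tests use 0.4 mm grids. Degenerate inputs fail
loudly: empty VOIs, zero-mean regions with spread, infeasible count targets,
overlapping rods, profiles leaving the image, and degenerate fit designs all
raise errors rather than returning silent zeros.

## Known limitations

* The positron-range kernel is empirical; swapping in a published
  medium-specific kernel only requires replacing `positron_range_kernel()`.
* The scatter background is spatially uniform inside the support; real
  scatter is broad but object-dependent.
* Air-insert spill combines annihilation-in-air and scatter contributions in
  reality; the simulator exposes them separately
  (`air_annihilation_fraction`, `scatter_fraction`) rather than asserting a
  physical mix.
* Attenuation maps are produced for completeness but the emission simulator
  works in the attenuation-corrected image domain.
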