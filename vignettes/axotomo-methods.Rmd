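---
title: "Methods: simulated micro-CT of freeze-dried brain tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated micro-CT of freeze-dried brain tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axotomo)
```

# The problem

Synchrotron X-ray microtomography of soft tissue ordinarily shows almost no
contrast: water dominates both the tissue and its attenuation, masking the
small differences between cellular constituents.  Freeze drying removes the
water and exposes the intrinsic contrast of the dry matter, which for brain
tissue is dominated by differences in water content (and secondarily in
phospholipid content) between the lipid-rich myelin sheaths of axons and
everything else.  Myelinated axonal tracts then appear as high-attenuation
tubes in the reconstructed attenuation map, dense enough to be traced into a
skeletonized "wire model" of the striatal network.

`axotomo` packages that whole chain in simulation: a composition model that
predicts attenuation coefficients of wet, dried and resin-embedded tissue; a
seeded phantom generator producing striatum-like volumes with exact ground
truth; a parallel-beam forward model (Beer-Lambert transmission, Poisson
counting noise, optional Fresnel free-space propagation); filtered
back-projection with single-distance phase retrieval; histogram, resolution
and SNR analyses; and an automatic tract tracer with a Protein Data Bank
format dialect for the resulting models.  No proprietary beamline data is
required anywhere; every quantitative claim in the test suite is validated
against synthetic phantoms whose ground truth is known by construction.

# Composition model

The model works entirely with bulk mass fractions.

* Wet tissue: \(\mu = (\mu/\rho)\,\rho\), with the brain-tissue mass
  attenuation coefficient at 7.13 keV taken as 16.7 cm^2/g (the linear
  interpolation of the ICRU/NIST 6 and 8 keV gray/white-matter values) and
  \(\rho = 1.03\) g/cm^3, giving 17.2 cm^-1.
* Water removal: \(\mu_{dry} = \mu_{wet} - w \cdot (1.00\,\mathrm{g/cm^3})
  \cdot (\mu/\rho)_{water}\), where \(w\) is the water mass fraction (0.8
  for whole brain, 0.4 for myelin) and \((\mu/\rho)_{water} = 16.6\)
  cm^2/g at 7.13 keV.
* Phospholipid density: \((1-w)\,\rho\,f_{lipid}\,f_{PL}\).
* Phosphorus contribution: phospholipid density \(\times\) (P atoms per
  molecule \(\times\) 30.97 / 750 Da) \(\times\) 109.0 cm^2/g.

Two numerical conventions deserve comment because the printed predictions
pin them down:

* **Interpolation is linear in energy, not log-log.**  Linear interpolation
  of the standard water values (24.63 at 6 keV, 10.37 at 8 keV) gives
  16.6 cm^2/g at 7.13 keV; log-log interpolation would give about 14.7 and
  is inconsistent with the rest of the arithmetic.  Photoabsorption varies
  smoothly enough over a 2 keV window that the linear choice is defensible
  on its own terms; it is also the only choice that reproduces the chain.
* **The water partial density is \(w \times 1.00\) g/cm^3 of tissue**, not
  \(w \times \rho_{tissue}\).  The former yields 3.9 / 10.6 cm^-1 for dried
  whole brain / myelin; the density-weighted variant yields about 3.5 /
  10.4 and is available behind the `density_weighted` flag of
  `dried_attenuation()` for sensitivity analysis.

Comparisons against printed values round half-up to the printed precision
(one decimal for cm^-1, three for phospholipid densities, two for the
phosphorus terms); `round_half_up()` implements this because base R's
round-half-to-even is not how fixed-precision figures are typically quoted.

```{r composition}
composition_report("myelin")
```

# Phantom generator

`phantom_spec()` defaults describe the simulated model-building region:
400 x 400 x 167 voxels at 2.76 um (about 1.1 x 1.1 x 0.46 mm^3), a uniform
background at the dried whole-brain prediction of 3.9 cm^-1, 20 tube-like
tracts at 6.5 cm^-1 (the upper part of the observed 2.5-8.0 cm^-1 peak)
anchored on the +x face and ending at scattered interior points, 150
low-density spherical nuclei of 4-8 um diameter at 1.5 cm^-1, and one 12 um
radius vessel running along the bottom edge of the field.  The vessel's
default attenuation (1.0 cm^-1) is *below* background on the reasoning that
a dried vessel lumen is air-filled; it is configurable.  Tract radii
(5-9 um, i.e. 10-18 um diameters) are a stated assumption: the source
imagery does not resolve single axons, so no literature radius distribution
exists for "tracts" at this scale.

Centerlines are natural cubic splines through 4-8 jittered control points,
kept monotone along x (hence non-self-intersecting) and mutually separated
by at least the sum of tube radii plus 2.5 voxels; anchors keep at least one
tract diameter of clearance.  Placement that fails after 150 bounded
retries raises a generation error naming the tract, rather than silently
packing fewer objects.  Tube and sphere surfaces are rasterized with
8-point supersampling in boundary voxels so edge voxels carry mixed
(partial-volume) values, which keeps thresholding and resolution analysis
honest.  The exact centerlines are returned as a wire model, along with a
per-voxel label volume (0 background, 1..n tract ids, -1 nuclei, -2
vessel).

What the phantom deliberately does **not** emulate: anatomically curved
cortical geometry, tract bifurcation/convergence (available behind an
option, off by default so counts stay unambiguous), spatially varying
background texture, detector blur, and ring-producing gain errors (the
last is available as an option on the scanner).  Tests passing on these
phantoms therefore demonstrate correctness of the algorithms under clean
geometry, not robustness to every artefact of real beamline data.

# Forward model

Projection is parallel-beam (synchrotron geometry), slice-by-slice
perpendicular to the rotation axis, by rotate-and-sum with bilinear
interpolation at 0.5-pixel steps; 1,800 frames over 180 degrees is the
default angle set (0.1 degrees per frame).  Optical depth uses lengths in
cm so reconstructed values are cm^-1 directly.  Transmission is
\(I/I_0 = e^{-d}\) with Poisson counts at mean \(I_0 e^{-d}\) per pixel and
flat/dark corrections assumed already applied.  The wavelength constant is
\(\lambda[\mathrm{nm}] = 1.2398/E[\mathrm{keV}]\).

Free-space propagation uses the projection approximation: amplitude
\(e^{-d/2}\), phase \((\delta/\beta)\,d/2\), propagated by the Fresnel
transfer function \(e^{-i\pi\lambda z f^2}\) with edge-replicated padding
to at least twice the detector width.  The transfer function is unimodular,
so total intensity is conserved to FFT round-off.  \(\delta/\beta = 400\)
is the package's stated working assumption for dried organic tissue at
8 keV — the quantity is not a measured input — and is configurable
everywhere it is used.

# Inverse model

Reconstruction is standard convolution-back-projection: the band-limited
ramp (Ram-Lak) kernel is built in the spatial domain, transformed, applied
to zero-padded (>= 2x) projection FFTs to avoid circular-convolution wrap,
and back-projected with linear detector interpolation; cosine apodization
is optional.  The rotation center defaults to the detector midline with
fractional offsets supported.  Non-positive transmission values under heavy
noise are clipped to the smallest positive double, logged, and counted in a
QC field rather than silenced.  Ring-artefact correction is deliberately
off by default — rings are part of plain reconstructions — with an optional
sinogram median-detrend behind a flag.

Phase retrieval is the single-material single-distance low-pass filter
\(1/(1 + C|k|^2)\), \(C = z\,(\delta/\beta)\,\lambda/(4\pi)\) (angular
frequency \(k\)), applied before the log.  Its gain is exactly 1 at DC.  On
a knife edge propagated 7 mm at 8 keV with 0.5 um pixels, retrieval
suppresses the Fresnel overshoot by far more than the five-fold bound the
tests assert, and on noisy propagated phantom data the retrieved
reconstruction has a higher tract/background contrast-to-noise ratio than
absorption-style processing of the same frames.

# Metrics

**Histograms** count pixels in 0.1 cm^-1 bins aligned so an edge falls at
0.0 cm^-1, over an optional micrometer-box ROI, and summarize the mode bin
center plus the contiguous peak range above a stated fraction of the mode
count (default 10%).

**Resolution** is estimated from a Fourier-domain plot: Hann-windowed 2D
power spectrum, azimuthally averaged in 64 radial bins; a flat noise floor
is taken as the median log power above 80% of Nyquist; a line is fit to
log power versus squared frequency where the spectrum stands at least one
log unit above the floor; the resolution is the inverse of the crossing
frequency, floored at two pixel widths (Nyquist).  Pure-noise images
return an explicit failure status instead of a number.  The two-component
fit is this package's documented choice of method; it is validated against
known imposed Gaussian blurs on spectrally flat scenes (blurred white noise
plus a noise floor), where it recovers the imposed FWHM well within a
factor of 1.5.  On scenes with strongly decaying intrinsic spectra (e.g.
smooth phantom slices) the object spectrum adds to the blur decay and the
estimate biases high; the monotonicity of the estimate in blur still holds
and is tested there.  This bias is a known limitation shared by any
resolution estimate that cannot separate scene from system spectrum.

**SNR scaling**: photons per voxel grow with the voxel volume, so SNR (mean
over standard deviation of Poisson counts) should grow as width^{3/2}.
`snr_scaling()` simulates counts at mean `photons_per_um3 * width^3`
(default 20 photons/um^3, a regime where the smallest voxel still sees
~20 counts), computes SNR per width and fits the log-log slope.  With
widths {1, 2, 4, 8} um and 1e5 samples per width the fitted exponent lands
within three standard errors of 1.5.

# Tracing

The reference procedure for wire-model building was manual: nodes placed
and connected interactively while viewing the attenuation map, tracking the
distribution down to a floor of 3.3 cm^-1 (equivalently 6.0 sigma of the
model-building volume).  This module keeps the threshold semantics but
automates the rest, and that divergence should be kept in mind when
comparing against manually built models:

1. threshold at the resolved floor (`floor` in cm^-1, or
   `sigma_multiple` x the standard deviation over the full volume);
2. label 26-connected components;
3. thin each component to a curve skeleton (sequential directional
   thinning deleting simple points, Malandain-Bertrand characterisation,
   endpoint-preserving, lexicographic scan order for determinism);
4. prune leaf spurs shorter than `spur_length_um` (default 15 um, about
   one tube radius's worth of surface bumps);
5. place nodes every `node_step` um (default 6 um) along each branch path,
   always at endpoints and junctions, junction nodes shared between
   branches; node diameter = 2 x the Euclidean distance transform at the
   skeleton voxel;
6. one trace per component; traces with fewer than `min_nodes` nodes are
   dropped and the rest renumbered serially.

Evaluation against ground truth matches traces greedily by centerline
overlap and reports per-tract recall and precision at a stated tolerance
(2 voxels in the acceptance tests).  On noise-free default phantoms the
tracer recovers 20/20 tracts with recall above 0.99; the residual
deviation is sub-voxel except for the ~1 tube radius of retraction at tube
tips that is inherent to topological thinning.

Models serialize to a PDB dialect (coordinates in micrometers in the x/y/z
fields, trace id in the residue-sequence field with chain-letter paging
beyond 9999, node diameter in the temperature-factor column, CONECT
connections; see `inst/extdata/wire-model-pdb-dialect.md`).  Writing is
canonical so a write-read-write cycle is byte-identical.  SWC export is an
interoperability extension for neuron-morphology tools, not part of the
dialect.

Open conventions resolved here: a branch point belongs to a single trace
(one component = one trace); convergence between distinct tracts would
merge components and is excluded from the default phantom; and section
counts (`count_tracts_in_section()`) take an explicit minimum-area cutoff
because a cutoff-free count is ill-defined under partial-volume edges.

# Pipeline, seeds and problem sizes

`run_pipeline()` chains phantom, scan, reconstruction, metrics, tracing and
evaluation, writing every intermediate as a TIFF stack with a YAML sidecar
(voxel width, units, value scale/offset, append-only provenance) and a
deterministic plain-text summary.  A single global seed fans out to
per-stage child seeds as `(seed * 7919 + stage_offset) mod (2^31 - 1)`, so
each stage is reproducible in isolation; rerunning a config byte-reproduces
the summary.

Problem sizes used by the test suite are chosen to exercise the stated
claims at full fidelity where the claim demands it — 256^2 slices with
1,800 angles for the reconstruction bounds, ten full-size
(400 x 400 x 167) phantoms for the tracing claim, 1e5 samples per width for
the SNR exponent — and reduced sizes elsewhere, where the property under
test (linearity, determinism, round-trips, error paths) does not depend on
scale.

# Known limitations

* The phantom's geometric realism is limited (see above); accuracy numbers
  on phantoms bound algorithmic error only.
* The resolution estimator conflates scene and system spectra on
  non-flat scenes (bias documented above).
* \(\delta/\beta\) is an assumption, not a fit; phase-retrieval contrast
  scales with it.
* The tracer is not a reimplementation of interactive model building:
  bifurcating axons that rejoin other tracts are not split into separate
  traces the way a human curator might choose to.
* Real-data figures of merit from the source study (tract counts in the
  hundreds, micrometer resolutions, histogram peak positions of beamline
  scans) are anchors for the synthetic validations, not reproduction
  targets: the underlying image sets are not publicly archived.
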