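---
title: "Locating protein crystals in opaque mounts by propagation-based phase-contrast tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating protein crystals in opaque mounts by propagation-based phase-contrast tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaseCT)
```

## The problem

Membrane-protein crystals grown in lipidic cubic phase (LCP) become
optically invisible once the mount is cryocooled: the mesophase turns
opaque, and the crystals (often below 20 µm) cannot be centred in the
X-ray beam with the on-axis microscope. Diffraction raster scans can locate
them, but burn a substantial fraction of the tolerable dose and resolve no
better than the microbeam size. On a low-emittance synchrotron, the beam of
a standard macromolecular crystallography beamline is coherent enough for
in-line holography: letting the beam propagate ~0.1 m after the sample turns
refractive-index boundaries into measurable intensity fringes at a dose
orders of magnitude below a raster scan. phaseCT implements the
quantitative toolbox around that idea: beamline coherence and
compound-refractive-lens (CRL) calculators, a thin-sample dose model, a
partial-coherence Fresnel simulator with voxel phantoms, an
effective-source-size fitter, and the processing chain from raw detector
frames to a segmented, meshed tomogram.

## Coherence and optics model

The transverse coherence length of a source of FWHM $d$ at distance $L$ and
wavelength $\lambda$ is taken as
$$\ell_c = \frac{\lambda L}{d},$$
the prefactor-free convention under which a 35 µm effective source at 61 m
and 12.7 keV gives $\ell_c \approx 170$ µm. Essentially coherent imaging at
resolution $\Delta$ requires $\ell_c \gtrsim 15\,\Delta$, which inverts to a
maximum admissible source size $d_\mathrm{max} = \lambda L / (15 \Delta)$
(400 µm for 1 µm resolution at $\lambda = 1$ Å, $L = 60$ m).

The monochromator adds angular spread $\Delta\Phi$ that, projected back to
the source plane from distance $L_\mathrm{DCM}$, broadens the effective
source. For Gaussian profiles the FWHMs add in quadrature,
$$d_\mathrm{eff} = \sqrt{d^2 + (\Delta\Phi\, L_\mathrm{DCM})^2},$$
turning the nominal 13 µm vertical source into ~34 µm for
$\Delta\Phi = 0.7$ µrad at 45 m — consistent with the ~35 µm values measured
on comparable beamlines. The horizontal 330 µm source is essentially
unaffected.

CRL optics use the standard parabolic-lens results: focal length
$F = R/(2N\delta)$, absorption-limited Gaussian effective aperture
$A_\mathrm{eff} = 2\sqrt{R/(\mu N)}$, and diffraction limit
$\delta_\mathrm{res} = 0.75\,\lambda L_1 / A_\mathrm{eff}$. Effective
aperture conventions in the literature differ by order-unity prefactors;
`crlResolution()` exposes a `correction` hook, and the default reproduces
published figures for a 20-lens beryllium stack at 10 keV to well within
25%.

```{r optics}
coherenceLength(Beam(12.7), 61, 35e-6) * 1e6       # um
crlFocalLength(CRLStack(20, 50e-6, "beryllium", 10))
```

## Optical constants

Constants are embedded as compact per-element mass attenuation and mass
energy-absorption tables (5–30 keV, log grid) assembled from the standard
NIST compilations, combined by mass fraction and interpolated log-log.
The refractive-index decrement is computed from the electron density,
$\delta = r_e \lambda^2 n_e / 2\pi$, which is accurate away from absorption
edges; $\beta$ is tied to the attenuation table by
$\mu = 4\pi\beta/\lambda$, so that identity holds exactly by construction.
Tungsten and tantalum tables start above their L1 edges (12.5 keV) because
a coarse log grid cannot represent the 10.2–12.1 keV edge structure;
lookups below that refuse rather than mislead. Accuracy is a few per cent
for the light materials, which is ample for contrast and dose planning;
the supported set covers the beamline context (beryllium lenses, boron
fiber with tungsten core, water, an average protein, LCP as a
monoolein/water mix, kapton mounts, tantalum test patterns).

## Dose model

Absorbed dose uses the thin-sample kerma model
$$D = n\, \Phi_A\, t\, E_\gamma\, (\mu_\mathrm{en}/\rho),$$
with no depth attenuation — appropriate for tens of micrometres of organic
material above 10 keV. With water as absorber this reproduces the headline
numbers of the imaging workflow: ~80 Gy for a single 17 ms unfocused
projection at $10^{13}$ photons s⁻¹ mm⁻², ~15 kGy for a 180-projection
tomography — five orders of magnitude below the ~30 MGy cryo limit, and
~7000× less than a single diffraction raster scan. For scanned-beam modes
`doseReport()` quotes the dose to the irradiated region (per-point
exposure); focused-beam doses depend on beam-profile and sample-composition
details beyond this model and are order-of-magnitude only.

## Synthetic data

`makeCrystalMountPhantom()` generates the study object: a 150 µm LCP slab,
500 µm across, held by a 12 µm kapton frame that reaches the lateral field
borders (as a real mesh mount does), containing non-overlapping convex
protein crystals — random polyhedra, since the pipeline only needs
boundaries and density contrast, not crystallographic habit. Defaults are
the experimental situation the package emulates: 20 crystals of 10–50 µm in
a 614 µm field at 2.4 µm voxels (a 256³ grid; the paper-scale instrument
has 0.6 µm pixels over 1024², which the same code reproduces at 16× the
cost). Crystal count and sizes follow the reported ~20 diffracting regions
and the 10–50 µm crystal dimensions of the emulated experiment. All
generation is bit-reproducible from a seed.

`makeFiberPhantom()` provides the coherence test object (100 µm boron
fiber, 15 µm tungsten core) with analytic chord thicknesses.

The forward model is deliberately minimal but quantitative: projection
(thin-object) transmission through per-material thickness maps; Fresnel
transfer-function propagation (unitary, so intensity is conserved to
numerical precision); partial coherence as a detector-plane Gaussian blur
of FWHM $d_\mathrm{eff}\, z/L$ per direction (shadow geometry — exact to
first order for $z \ll L$); Poisson counting through a flat-field gain.
Divergence matters only for the 5 m fiber geometry and is handled by the
effective distance $z_\mathrm{eff} = zL/(L+z)$. Monochromatic treatment is
justified by the <0.5% harmonic content of the emulated beamline. What the
simulator does *not* emulate: scintillator blur and detector MTF beyond
pixel integration, polychromaticity, mesophase texture, crystal mosaicity —
so passing tests demonstrate the correctness and robustness of the
processing chain under controlled conditions, not detector-specific
performance on real data.

## Effective-source-size fitting

The coherence measurement exposes the fiber at 12.7 keV with the camera
5 m downstream and fits simulated fringe profiles to the observed one.
`fitSourceSize()` minimizes the sum of squared differences between the
column-averaged observed profile and the noiseless forward model, over the
effective source size: amplitude and offset are solved in closed form,
lateral registration uses cross-correlation with parabolic sub-pixel
refinement, and the 1D search runs a 2.5 µm coarse grid (5–100 µm) followed
by golden-section refinement to 0.1 µm. The quoted uncertainty is the
half-width of the region whose residual stays within a factor $(1 + 1/n)$
of the minimum — a deliberate, documented heuristic, since the emulated
measurement quotes "±3 µm" without a stated convention. Under the
experiment's flux and exposure, recovery of a 35 µm truth is comfortably
within ±3 µm (the package's acceptance suite checks the median absolute
error over 20 seeded replicates).

## Processing chain

1. **Flat selection and correction** — each frame is divided by the most
   similar flat of the sample-free pool, similarity being mean SSIM on
   mean-normalized images (conventional parameterization: Gaussian window
   σ = 1.5, K₁ = 0.01, K₂ = 0.03, data range from the flat pool).
   Mean normalization makes the choice exposure-invariant.
2. **Paganin retrieval** — single-distance, single-material inversion
   $$t = -\tfrac{1}{\mu}\ln \mathcal{F}^{-1}\!\left[
   \frac{\mathcal{F}[I/I_0]}{1 + \pi\lambda z (\delta/\beta)\, |f|^2}
   \right],$$
   frequencies in cycles per length, $I_0 = 1$ after flat correction,
   non-positive filtered values clipped to a floor with a reported count.
   The default ratio is the empirically favoured $5\times10^3$ for crystals
   in cryocooled LCP. Note that this exceeds the physical water ratio at
   12.7 keV several-fold: empirical ratios tuned on real detectors absorb
   instrument response. For synthetic data the physically matched
   inclusion–matrix ratio $(\delta_A-\delta_B)/(\beta_A-\beta_B)$
   (`contrastDeltaOverBeta()`, ~7×10² for protein in LCP at 12.7 keV)
   renders interfaces faithfully, and the package's end-to-end validation
   uses it; with $5\times10^3$ the retrieval point-spread tail spans tens of
   micrometres and small-crystal contrast drops below the deterministic
   artifact floor.
3. **Destriping** — the wavelet-Fourier method: Daubechies-4 decomposition,
   Gaussian damping $1-\exp(-k^2/2\sigma^2)$ of near-zero angle frequencies
   in the horizontal-detail bands (defaults: 4 levels, σ = 2). Deeper
   decompositions suppress constant detector-column offsets more strongly
   (≥10× column-offset dispersion at 6 levels); the cost, measured here, is
   that the angle-DC damping also removes genuine content whose sinogram
   trace is nearly angle-invariant — i.e. structures close to the rotation
   axis. At the counting statistics of the emulated experiment (~10⁶
   counts/pixel) ring artifacts are negligible, so the validated end-to-end
   chain runs without destriping; the stage matters for noisier or
   drift-affected data and is fully tested standalone.
4. **Center of rotation** — registration of the first projection against
   the horizontally mirrored last one (the series spans 180°), by circular
   cross-correlation of vertically averaged profiles with parabolic
   sub-pixel refinement. Needed because absolute angles are not registered
   by the camera clock.
5. **Reconstruction** — slice-wise parallel-beam filtered backprojection
   with the Shepp–Logan filter (band-limited ramp
   $(2f_N/\pi)\,|\sin(\pi f/2f_N)|$), zero-padded to twice the detector
   width, linear interpolation in the backprojection, scaled so gray values
   are proportional to the attenuation coefficient of whatever quantity the
   sinograms carry. Parallel geometry is exact to 0.2% here (source 61 m
   away, z ≤ 110 mm).
6. **Segmentation** — replaces interactive carving with reproducible
   rules. Bimodal data use Otsu's threshold; crystals in a matrix use the
   `inclusions` rule: band-pass (background σ = 5 voxels), running local
   standardization (window σ = 12 voxels), local z-threshold (k = 2.5)
   inside a slightly eroded Otsu material mask, 6-connected components,
   a size window, and exclusion of border-touching regions (the mount
   frame reaches the border by construction). Local statistics are
   essential: the retrieval low-pass leaves a smooth dome an order of
   magnitude stronger than the crystal contrast, so no global threshold
   separates crystals. An optional seeded watershed (priority flood on the
   gradient magnitude) refines touching regions.
7. **Mesh export** — each region's closed voxel-boundary surface as a
   named group of a Wavefront OBJ file, two triangles per exposed voxel
   face, vertex coordinates in micrometres.

## Numerical choices and degenerate inputs

Frequencies place zero at the first FFT element; all units are SI
internally with explicit unit suffixes at interfaces. `propagate()` refuses
under-sampled geometries ($\lambda z/\Delta x$ beyond the field extent).
Fresnel fringes at the tomography distance are at the 1–2 pixel scale of
the scaled-down 2.4 µm grid; simulations at 2× finer sampling with detector
binning change tomogram statistics by <10%, so the direct grid is used by
default. Poisson recording switches to the exact expectation when no seed
is given, which the tests exploit to separate deterministic from stochastic
effects. Empty phantoms, zero exposures, empty foregrounds and boundary
fit minima all return well-defined results or explicit warnings rather
than errors.

## Problem sizes

The validation suite runs the full chain at the emulated experiment's
field of view on a 256³ grid (2.4 µm voxels) with 180 × 1° projections,
which completes in a few minutes on one CPU; unit tests use 32–128 px
grids. The same code paths handle the 1024² instrument-scale geometry.

## Known limitations

- Optical constants are few-per-cent accurate and exclude the W/Ta L-edge
  region; anomalous dispersion is ignored in $\delta$.
- The partial-coherence model is a detector-plane blur, not mutual-
  coherence propagation; it is first-order accurate for $z \ll L$.
- The dose model has no depth resolution or photoelectron escape.
- Automated inclusion detection assumes compact bright inclusions of
  roughly known size in a smooth matrix; it is not a general segmenter.
- The wavelet-Fourier destriper attenuates genuine near-axis structure;
  use it when ring artifacts actually dominate.
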