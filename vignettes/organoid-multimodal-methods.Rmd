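---
title: "Models and methods behind organoidKit"
author: "organoidKit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind organoidKit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

organoidKit quantifies drug-induced changes in stem-cell-derived brain
organoids along three complementary axes: internal mechanics from
reverberant optical coherence elastography (Rev-OCE), surface mechanics
from Brillouin light scattering guided by OCT structural imaging, and
gene expression from bulk RNA-seq count matrices. Because the raw
instrument data are rarely public, every estimator in the package is
paired with a seeded generator that synthesises inputs with known ground
truth; the tests and the acceptance script quantify recovery of that
truth. This vignette explains the models, the defaults, and the choices
made where the design was genuinely open.

## Reverberant elastography

### Measurement model

A piezoelectric ring drives a quasi-harmonic shear excitation at
F = 3 kHz into an organoid embedded in agarose. Phase-sensitive OCT
acquires M-mode records of 500 sequential A-lines at a 25 kHz A-line
rate (inter-A-line interval 40 µs) at each point of a 101 × 101 lateral
grid spanning 2 × 2 mm (up to 2.8 × 2.8 mm for large organoids). The
phase shift between sequential A-lines encodes the axial particle
velocity

\[ v_z = \frac{\lambda_0\,\Delta\varphi}{4\pi n \Delta t}, \]

with source wavelength λ₀ = 840 nm and tissue refractive index
n = 1.34. `fieldToPhaseVolume()` / `phaseToVelocity()` implement this
pair exactly; phases are wrapped into (−π, π], and the unwrapped
round-trip is exact below the wrap velocity λ₀/(4nΔt) ≈ 3.918 mm/s. The
synthetic fields default to an RMS amplitude of 0.5 mm/s so that
wrapping never occurs; per-pixel temporal unwrapping is available but
off by default.

### Field model and simulator

The excitation is modelled as an ideal isotropic reverberant field: a
superposition of `nPlaneWaves = 1000` shear plane waves with directions
uniform on the sphere, uniformly random transverse polarizations, and
i.i.d. phases. One thousand waves is empirically sufficient for the
angular average to be isotropic at the analysed window sizes;
the count is configurable. Per-wave amplitudes are constant by default
(Rayleigh-distributed optionally). Whether organoid interiors support an
ideally diffuse field at 3 kHz is unknown; the simulator adopts ideal
isotropy as a modelling idealisation, which is exactly the assumption
under which the wavenumber estimator is derived, so passing tests
demonstrate estimator correctness under its own model, not the physical
diffuseness of real organoids.

Heterogeneity uses local-wavenumber synthesis: each compartment of the
two-compartment spherical phantom (stiff shell, softer core, agarose
background) contributes a plane-wave sum with its own
k = 2πF/v_s, blended over a 2-pixel cosine band at the compartment
boundaries. Exact elastodynamic scattering is out of scope; since the
estimator is local and windowed, local-k synthesis is the standard test
harness for reverberant estimators. All waves share the excitation
frequency, so the field factorises into a complex spatial amplitude
times a temporal tone — which also makes simulation fast. Fields are
evaluated on the lateral plane through the phantom equator.

### Wavenumber estimation

`extractHarmonic()` demodulates each pixel with a windowed DFT at the
bin nearest F (3 kHz is exactly bin-centred at the default timing, so
the rectangular window is exact; flat-top is available off-bin). With
500 temporal samples the demodulation suppresses additive velocity noise
by roughly a factor √(nt/4), which is why 20 dB velocity SNR barely
perturbs the wavenumber maps.

For an ideal isotropic reverberant shear field the normalised spatial
autocorrelation of the axial velocity at transverse lag Δr is

\[ B(k\Delta r) = \tfrac{3}{2}\left[j_0(k\Delta r) -
   \frac{j_1(k\Delta r)}{k\Delta r}\right], \]

derived by averaging \(p_z^2 e^{i k \mathbf{n}\cdot\Delta\mathbf{r}}\)
over directions and transverse polarizations (`reverberantKernel()`).
The package requires this closed form to agree with a simulation-derived
numerical kernel within 2% RMS over kΔr ∈ [0, 2π] — a dual-route check
kept in the acceptance tests.

`estimateWavenumberMap()` slides a square window (default 0.5 × 0.5 mm,
50% overlap) over the harmonic field, computes the unbiased 2D
autocorrelation by zero-padded FFT, radially averages its real part
(each radial bin carries the mean radius of its member lags — using the
bin label instead biases k upward by a few percent), and least-squares
fits B(kΔr) over lags up to half the window, excluding the zero-lag bin
because it carries the noise variance. The search is a 120-point
log-spaced grid refined locally, with ties broken toward smaller k.
A window is valid when the fit R² ≥ 0.6 *and* the fitted profile
amplitude is within [0.3, 3] of the unit normalisation: the
autocorrelation of spatial noise is near zero beyond the origin, so its
best-fitting kernel amplitude collapses, and this gate empirically
rejects essentially all pure-noise windows while keeping real ones.
Speed maps follow as v_s = 2πF/k.

Two numerical regimes matter. When the window spans at least one shear
wavelength the per-window estimate is nearly unbiased. When the
wavelength exceeds the window (fast media: v_s ≥ 2 m/s at 3 kHz and a
0.5 mm window) the single-realisation autocorrelation within a window is
dominated by cross-terms between plane waves that spatial averaging
cannot suppress, and the per-window median acquires a downward speed
bias of several percent along with large field-level fluctuations. The
recovery benchmark (`benchmarkSpeedRecovery()`) therefore follows the
estimator's own precondition: it widens the analysis window to 1.1
expected wavelengths (capped just below the scan extent) and pools valid
windows over several independently seeded fields before taking the
median. With 8 fields at 1–2 m/s and 20–24 fields at 3–5 m/s the pooled
median is reproducibly within ±3% of truth; region-wise contrast mapping
(shell versus core) keeps the 0.5 mm window, where the bias cancels in
the comparison.

### Bandpass and region summaries

`spatialBandpass()` applies a tapered annular mask in the 2D spatial
frequency domain. Cut-offs are not prescribed by the measurement
protocol; the pipeline default is [0.25, 4] × k_nominal with
k_nominal = 2πF/v_expected, fully configurable, and the filter warns if
the nominal ring falls outside the band. Note that aggressive bandpass
before autocorrelation fitting reshapes the field's spatial spectrum and
can bias k in the sub-wavelength-window regime, so the estimator itself
is run on unfiltered harmonics in the benchmarks.

`regionSpeedSummary()` splits masked windows into a surface region (the
outer 20% of the radial extent from the mask centroid, configurable) and
a core region. Whether the original instrument analyses used OCT-derived
masks or manual ROIs is not documented; the mask-based definition here
is a declared convention. Volumetry assumes sphericity:
d̄ = (d_horizontal + d_vertical)/2, r = d̄/2, V = (4/3)πr³, with
diameters measured through the segmentation centroid.

## Brillouin–OCT

Brillouin spectra are modelled as a symmetric Stokes / anti-Stokes
Lorentzian pair (shared linewidth, default FWHM 0.3 GHz) around the
elastic line, mapped onto 512 spectrometer pixels through an affine
pixel→GHz relation (default ≈31 MHz/pixel spanning ±8 GHz) with Gaussian
read noise, 0.2 s exposure. `calibrateSpectrometer()` locates both peaks
of each reference liquid and regresses known shifts (±ν) on refined peak
pixel positions; two liquids determine the map exactly, three
(water / acetone / methanol) leave a residual that is reported. The
reference shifts at the 660 nm source are configuration defaults
computed from standard acoustic-velocity and refractive-index tables
(ν = 2nV/λ: water 5.96, acetone 4.83, methanol 4.42 GHz) — instruments
should supply their own measured values. `fitBrillouinShift()` fits the
symmetric pair by Levenberg–Marquardt least squares; spectra whose
maximum rises less than 5 noise SDs above the baseline are declared
invalid rather than fitted. A single Lorentzian pair with shared
linewidth is the simplest model supporting a shift-only readout;
conversion of shifts to longitudinal moduli is deliberately out of scope
because it requires density and refractive-index assumptions.

OCT volumes are rendered as a bright sphere over dim background with
multiplicative Gamma speckle of SD 1/√SNR. `segmentOrganoid()` box-blurs
(3×3×3, skipped for binary input), thresholds by Otsu's method, rejects
volumes whose foreground/background intensity contrast is below 2
(pure-speckle histograms are unimodal and would otherwise percolate),
keeps the largest 6-connected component, fills internal cavities, and
erodes to extract a boundary shell (default 3 voxels). Surface-wise
shift summaries average valid fitted shifts over that shell; the precise
surface ROI used on real instruments is undocumented, so the
mask-boundary convention is again declared, not inferred.

## Transcriptomics

Counts are summarised exactly as a pooled-organoid design permits:
CPM = 10⁶·counts/library size, log₂CPM with a pseudocount of 1 CPM
(recorded in the object metadata; the log transform needs a guard
against zeros and 1 CPM is the conventional choice), fold changes as
pseudocounted ratios of arm-mean CPM against control (per-stratum means
available via `splitBy`), gene lists thresholded at FC > 15 (up and
down lists kept separate; the Venn partition uses up-lists by default),
exact Venn region counts, and PCA of gene-centred (not unit-scaled)
log₂CPM with samples as observations — unscaled because a transcript
spanning orders of magnitude *should* dominate. PCs carry a
deterministic sign (largest-magnitude loading positive). No
multiple-testing machinery is attached: selection is threshold-based by
design, and formal differential-expression testing is out of scope.

The count simulator draws negative-binomial counts with variance
μ + φμ² (default dispersion φ = 0.1, Poisson at φ = 0), library-size
factors varying up to 2-fold, a planted FOLR1 induction of log₂FC = 8
in all four exposure arms — 256-fold, realising an induction spanning
several orders of magnitude while remaining finite — and moderate mixed
effects (|log₂FC| 1–2) on a nine-gene neurodevelopment panel (DVL3,
GATA2, KIF22, LHX2, NEUROG1, NKX2-2, NTF3, SEMA6B, WNT8B). The design
is five arms (control, DTG 10 µM, DTG 20 µM, DTG 10 µM + FA 10 µM,
DTG 20 µM + FA 20 µM) × two timepoints (day 20, day 24) × three
replicates; replicate counts per arm in the real deposited data are not
printed, so three per arm-timepoint mirrors the three-samples-per-group
elastography design. PCA defaults to all genes with an option for the
top-N most variable, since the gene subset used in the original analysis
is unstated. The simulator does not attempt realistic single-cell
structure, batch effects, or mechanistic folate-rescue modelling.

## Group statistics

`oneWayAnova()` computes the classical between/within decomposition from
explicit sums of squares (the independent cross-check in the tests is
base R's `aov`). `bonferroniPairwise()` runs all pairwise two-sided
pooled-variance t tests (the classical post-hoc companion; Welch and
versus-control variants available — whether the original comparisons
were all-pairs or versus-control is unstated, so all-pairs is the
default) and multiplies each raw p by the number of comparisons, capped
at 1, with stars at 0.05 / 0.001 / 0.0001. Family-wise error control is
verified by a 1000-replicate null simulation. `prevalence()` reports
100k/n to two decimals with a Clopper–Pearson exact interval — exact
rather than asymptotic because the surveillance counts of interest are
small (4/426, 5/1683, 10/9460 → 0.94%, 0.30%, 0.11%).

## Pipeline, reproducibility and problem sizes

`validateRunConfig()` merges a YAML-serialisable configuration over
defaults that mirror the printed acquisition values, rejects unknown
keys, aggregates all validation problems into one error, and resolves
derived quantities (Δt = 40 µs from the 25 kHz rate). `runPipeline()`
executes simulation → estimation → summaries → statistics for the full
5 × 2 × 3 design (30 organoids), writes TSV/CSV tables and a manifest
with MD5 checksums, and is bit-reproducible from config + seed. Arm
effects in the demo generator encode the study conditions qualitatively:
DTG slows day-24 growth (control grows ~15%, exposed arms shrink ~10%),
stiffens the surface (higher shell speed and Brillouin shift, escalated
further by folate), and softens the core (~25% lower core speed); a 3%
log-normal jitter differentiates replicates.

Problem sizes in the shipped tests and acceptance script are chosen to
exercise every estimator at full acquisition geometry where it matters
(101 × 101 × 500 fields for the recovery, contrast and kernel checks)
while keeping unit tests on reduced grids (31–41 pixels, 100
timepoints); the acceptance benchmarks pool 8–24 seeded fields per speed
as described above, use 20 seeded runs for the shell/core ordering, 100
noisy spectra for the Brillouin bias, 2000-gene count matrices, and 1000
null replicates for the family-wise error simulation. Volumetric
run-time artifacts are written as `.rds` files and tables as CSV/TSV.

## Known limitations

* The reverberant simulator realises the estimator's own idealisation;
  mode conversion, attenuation, boundary reflections and non-diffuse
  excitation in real organoids are not modelled.
* Sub-wavelength analysis windows carry an intrinsic few-percent
  downward speed bias per window; absolute speeds for fast media should
  use wavelength-sized windows, while fixed-window maps remain valid
  for contrast.
* Brillouin shifts are not converted to moduli; OCT rendering ignores
  depth-dependent attenuation and speckle correlation.
* The count simulator plants marginal NB effects only — no correlation
  structure between genes.
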