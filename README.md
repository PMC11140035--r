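# organoidKit

Multimodal quantification of drug-exposed brain organoids: reverberant
optical coherence elastography (Rev-OCE), Brillouin–OCT surface
stiffness mapping, OCT volumetry, and bulk RNA-seq expression
summarisation, with seeded synthetic-data generators carrying ground
truth for every estimator.

## The problem

Dolutegravir (DTG), a first-line HIV integrase inhibitor, has been
associated with neural tube defects when taken around conception, and
antagonises the folate receptor FOLR1. Stem-cell-derived brain organoids
exposed to DTG (with or without folic acid) show altered gene expression
and altered tissue mechanics. Quantifying those changes requires four
analysis chains that this package implements as reusable, tested
components:

1. **Rev-OCE** — a diffuse superposition of shear plane waves is imaged
   by phase-sensitive OCT. The phase shift between sequential A-lines
   gives the axial particle velocity
   `vz = λ₀·Δφ / (4π·n·Δt)` (λ₀ = 840 nm, n = 1.34, Δt = 40 µs at a
   25 kHz A-line rate). Demodulating at the 3 kHz excitation and fitting
   the reverberant autocorrelation kernel
   `B(kΔr) = (3/2)[j₀(kΔr) − j₁(kΔr)/kΔr]`
   in sliding 0.5 × 0.5 mm windows yields local wavenumber maps and
   shear-wave speeds `vs = 2πF/k`, summarised over surface and core
   regions.
2. **Brillouin–OCT** — spectrometer traces are calibrated against
   reference liquids (water / acetone / methanol), Stokes / anti-Stokes
   Lorentzian pairs are fitted for the frequency shift ν_B (a stiffness
   proxy), and OCT segmentation restricts averaging to the organoid
   surface. Volumes follow from sphericity: `V = (4/3)πr³` with
   r from the mean of horizontal and vertical diameters.
3. **Transcriptomics** — counts per million (CPM), log₂CPM with a
   1-CPM pseudocount, arm-versus-control fold changes, FC > 15 gene
   lists, exact four-way Venn partitions, and PCA of gene-centred
   log₂CPM.
4. **Statistics** — one-way ANOVA from explicit sums of squares,
   Bonferroni pairwise comparisons, and exact binomial (Clopper–Pearson)
   prevalence intervals for surveillance counts.

## Worked example

```r
library(organoidKit)

## simulate a stiff-shell / soft-core organoid and recover the contrast
acq <- AcquisitionConfig()                 # 25 kHz, 3 kHz, 101x101, 2 mm
ph  <- OrganoidPhantom(vsShell = 3, vsCore = 1.5, vsBackground = 3)
vf  <- simulateReverberantField(ph, acq, SimSpec(seed = 1))
vel <- phaseToVelocity(fieldToPhaseVolume(vf))   # phase round trip
sm  <- wavenumberToSpeed(estimateWavenumberMap(extractHarmonic(vel)))
regionSpeedSummary(sm, phantom = ph)
#>    region     mean   median        sd  n nTotal
#> 1 surface 3.338695 3.826393 0.9426705 12     12
#> 2    core 1.955516 1.837091 0.4355075  9      9
```

The surface windows average 3.3 m/s against 2.0 m/s in the core —
the simulated stiff-shell/soft-core contrast (3 vs 1.5 m/s, blurred by
the 0.5 mm analysis windows) is recovered with the correct ordering.

```r
## volumetry and the printed-value spot checks
organoidMorphometry(1.0, 1.0)
#> Morphometry: d = (1 + 1)/2 = 1 mm, V = 0.5236 mm^3
prevalence(4, 426)$percent
#> [1] 0.94
```

A full synthetic study (30 organoids across 5 exposure arms and 2
timepoints, plus RNA-seq summarisation and group statistics) runs with

```r
runPipeline(validateRunConfig())        # writes CSV/TSV + manifest.json
```

or from a shell via `inst/scripts/run-pipeline.R`.

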