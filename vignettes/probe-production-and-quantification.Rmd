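---
title: "Designing, quality-controlling and quantifying enzymatically labeled smFISH probe sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing, quality-controlling and quantifying enzymatically labeled smFISH probe sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probefish)
```

## Overview

Single-molecule fluorescence in situ hybridization (smFISH) detects
individual mRNA molecules by hybridizing dozens of short, singly labeled
antisense DNA oligos to one transcript, so that each mRNA shows up as a
diffraction-limited spot. Probe sets for this purpose can be produced
in-house by enzymatic 3' end-labeling: terminal deoxynucleotidyl
transferase (TdT) appends a single dye- or biotin-conjugated ddUTP to each
oligo, guaranteeing at most one label per molecule. `probefish`
implements the computational workflow around that production route:

1. designing the tiled antisense probe set (`design_set()`);
2. quality-controlling the labeling reaction — concentration, degree of
   labeling (DOL) and recovery from UV-Vis absorbance, gel densitometry
   and the HABA/avidin assay (`estimate_dol()`, `gel_dol()`,
   `haba_dol()`, `dol_regression()`), plus a yield planner
   (`plan_experiments()`);
3. quantifying probe-set performance on two-color smFISH stacks: 3D spot
   detection (`detect_objects()`), copy-number decomposition of spot
   intensities (`fit_mixture()`), the single-molecule gate, the
   two-channel codetection rate (`codetect()`), and the false-positive
   detection rate from compartment densities (`density_fpdr()`).

Because raw microscopy and spectroscopy data of this kind are rarely
portable, the package ships a synthetic-data generator
(`gen_object_table()`, `gen_image_stack()`, `gen_spectro_read()`,
`gen_target_sequence()`) that produces every input the pipeline consumes
with known ground truth. All validation in the test suite runs against
these generators.

## Probe design

Candidates are all windows of 18–22 nt whose GC fraction lies in
[0.45, 0.60] (inclusive). Each candidate is reported as the reverse
complement of its sense-strand window (coordinates 0-based, half-open),
with a nearest-neighbor melting temperature.

**Tm model.** The duplex Tm uses the unified DNA/DNA nearest-neighbor
parameter set with duplex initiation terms, the entropic salt correction
`dS + 0.368 (L-1) ln[Na+]`, and `Tm = dH / (dS + R ln(Ct/4)) - 273.15` at
50 mM monovalent salt and 250 nM total strand — a typical probe working
solution. The salt and strand concentrations are arguments; the model
identity is recorded in the design parameters attribute. For design
purposes only the relative ordering of Tm values matters, since probes
are filtered to a window of ±2.5 °C around the candidate median
("similar melting temperature"; the half-width is a tunable with no
canonical value).

**Selection.** Among the Tm-filtered candidates a maximum-cardinality
non-overlapping subset with inter-probe gaps of at least 2 nt is chosen
by the earliest-compatible-end greedy sweep, which is provably optimal
for interval scheduling; a dynamic-programming enumeration in the test
suite confirms optimality on hundreds of random targets. Ties among
candidates sharing an endpoint are broken in favor of candidates whose
appended 3' ddU base-pairs with the target (i.e. the sense-strand base
immediately 5' of the window is an A), then in favor of longer probes.
The ddU criterion is a soft preference, never a filter: labeling
chemistry works either way, pairing merely adds one more hybridizing
base. Historically such sets were curated by hand; the greedy optimum is
a reproducible stand-in, not a reconstruction of any published set.

`interleave()` deals a designed set alternately into two subsets (sizes
differing by at most one, e.g. 35 → 18 + 17). Labeling the two halves
with spectrally distinct dyes gives the alternating two-color arrangement
used for codetection controls, where both halves independently tile the
same transcript.

## Labeling arithmetic

For a 1-cm path absorbance reading of a labeled pool,

$$c = \frac{OD_{260} - cf_{260}\,OD_{dye}}{\varepsilon_{oligo}}, \qquad
DOL = \frac{OD_{dye}}{\varepsilon_{dye}\, c}, \qquad
\mathrm{Recovery\%} = 100\,\frac{c\,V}{n_{initial}},$$

where `eps_oligo` is the mean of the per-oligo extinction coefficients at
260 nm plus 9000 L mol⁻¹ cm⁻¹ for the incorporated ddU, `cf260` is the
dye's relative absorbance at 260 nm, and `V`, `n_initial` are the
reconstituted volume and starting amount. Units are mol/L internally,
pmol in reporting. DOL is deliberately not clamped at 1 — spectroscopy
slightly overestimates DOL relative to densitometry and values a few
percent above 1 are routine — but estimates above 1.2 raise a warning.
`gen_spectro_read()` inverts these formulae exactly, so the noise-free
round trip `estimate_dol(gen_spectro_read(c, dol, ...))` is an identity
to machine precision; the test suite verifies `< 1e-9` relative error
over 1000 random parameter draws.

Gel densitometry gives `DOL = 1 - n_unlabeled / n_loaded`, and the
HABA/avidin assay converts the absorbance loss at 500 nm into displaced
biotin with a default extinction coefficient of 34 000 L mol⁻¹ cm⁻¹ (the
standard assay value; configurable). `dol_regression()` compares the two
modalities by least squares through the origin. Its goodness of fit is
the no-intercept coefficient of determination `1 - RSS / Σy²`; we state
the definition because no-intercept R² conventions differ between
packages.

The planner `plan_experiments()` floors
`n_initial (1 - loss) / (n_probes × conc × volume)`. With the standard
scale — 1000 pmol pool, 30 probes, 2.5 nM per probe in 100 µL, 22%
purification loss — it yields 104 experiments, i.e. "about a hundred
hybridizations per synthesis".

## Spot detection

Detection follows the classical per-slice scheme: in every z-slice of the
reference channel, pixels that are local maxima of their 8-neighborhood
and lie in the upper `q` percent of that slice's intensity distribution
become 2D peaks; peaks in adjacent slices whose centers are within
`r_xy` voxels (default 2) are chained greedily in order of increasing
distance; chains spanning fewer than 3 slices are discarded. Per-slice
(rather than global) thresholding matches how such detectors are actually
run and adapts to slice-wise background drift.

**Plateau handling.** On photon-count images, intensities are small
integers and a spot's peak frequently lands on a two-pixel plateau. A
strictly-greater-than-all-neighbors rule silently loses such slices and
breaks z-chains (we measured recall dropping to ~0.87 at peak SNR 5). We
therefore use the standard non-maximum-suppression tie-break: a peak must
be strictly greater than its raster-preceding neighbors, at least equal
to the following ones, and strictly greater than at least one in-image
neighbor. A flat-topped peak yields exactly one maximum; a constant image
yields none.

**Photometry.** Intensities in both channels are background-subtracted
sums over a cylindrical aperture (default radius 2 voxels) on the
object's member slices, with identical geometry in both channels — a sum,
not a mean, because summed photons stay proportional to the number of
labeled mRNAs in the object, which is what the mixture model assumes. The
per-slice background is the median of pixels outside all apertures.
Negative background-subtracted sums are clamped at zero.

**Threshold choice.** The default `top_percentile = 1` suits dense
tissue fields where real spots fill the upper percentile. In the sparse
synthetic benchmark scenes used for validation (20 spots in a
64×64×32 stack), true in-focus spots occupy only ~0.4% of pixels, so the
benchmark uses `q = 0.4`; with a data-driven percentile threshold, `q`
should always be matched to the expected signal density, otherwise the
quota is filled by noise maxima.

**FPDR.** Compartments expressing and not expressing the target (nurse
cells and follicle cells in the canonical egg-chamber setting) act as
internal positive and negative controls. `density_fpdr()` converts the
object-density fold excess between them into a false-positive detection
rate `FPDR = 100 / fold` (20-fold excess → 5%, 100-fold → 1%).

## Copy-number mixture and codetection

Reference-channel object intensities are modeled as a Gaussian mixture in
which component `k` collects objects containing `k` mRNA copies. In the
constrained mode, component `k` has mean `k·mu1` and SD `sqrt(k)·sigma1`
— the scaling implied by summing `k` independent single-mRNA signals —
leaving only `(mu1, sigma1)` and the weights free; the free mode fits
unconstrained means and SDs. `K` is selected by minimum BIC. EM details
(the literature leaves them open): initialization by K-quantile partition
of the sorted data, 5 restarts with means jittered by `0.2 sd(x)`,
convergence at `1e-6` relative log-likelihood change, at most 500
iterations, and component variances floored at `(1e-3 sd(x))²` to prevent
collapse. Restart jitter derives from a user seed, so fits are
reproducible. The free-mode fit is cross-checked against an independent
EM implementation (mclust) in the test suite.

Objects below the single-molecule gate `mu1 + 2 sigma1` of the
lowest-mean component are taken to contain one mRNA. The codetection
statistic then asks: of these single-mRNA objects (found via the
reference probe set), what fraction would also be detected by the second
probe set?

* the reference detection threshold is the 0.1th percentile of all
  objects' reference intensities (linear interpolation between order
  statistics);
* a zero-intercept line of target on reference intensity is fitted to
  the non-single fraction — the zero intercept keeps the derived
  threshold a pure product and matches the convention used for the
  DOL regression;
* the target threshold is `slope × ref_threshold`, and the codetection
  rate is the percentage of single-mRNA objects whose target intensity
  reaches it.

The fit quality is reported as the squared Pearson correlation between
the channels over the fitted objects. We do not use the no-intercept
`1 - RSS/Σy²` form here: on strictly positive intensities that statistic
equals the squared cosine between the two data vectors and stays near
0.6–0.9 even for completely unrelated channels, so it cannot express the
"no linear relation" null that a second, unrelated probe set should
produce. The Pearson form gives 1 for exact proportionality and ~0 for
shuffled or unrelated channels, which is the behavior a negative control
must show.

Two second-order properties of this estimator are worth knowing.
First, the minimum-reference object always falls below an interpolated
0.1th percentile, so even a perfectly proportional data set scores
marginally below 100%. Second, when a fraction `1 - p` of objects is
undetected in the target channel, those zeros shrink the zero-intercept
slope toward `beta·p`; the codetection rate itself is unaffected (the
threshold scales with the slope), but per-object fold differences
(`expected_target()`) center at `1/p` rather than 1. Both effects are
asserted quantitatively in the test suite.

## The synthetic-data generator

The generator emulates exactly the statistical structure the estimators
assume, with ground truth recorded per object:

* **Object tables** (`gen_object_table()`): copy number
  `k ~ Categorical(w)`; reference intensity `Normal(k·mu1, sqrt(k)·sigma1)`
  clamped at 0 (photon counts cannot be negative; clamping, not
  rejection); target intensity `beta·ref·Bernoulli(p) + noise` clamped at
  0, with noise SD defaulting to `0.05·mu1` — small relative to signal so
  the codetection threshold stays clean, and configurable down to 0 for
  exact limits. The non-expressing compartment holds
  `round(n/fp_fold)` objects (half away from zero) drawn from the
  single-copy component. Defaults `w = (0.7, 0.3)`, `mu1 = 100`,
  `sigma1 = 15`, `beta = 0.8`, `p = 0.91`, `fp_fold = 20` describe the
  regime reported for *oskar* mRNA in nurse cells: mostly single- with a
  minority of two-copy particles, ~90% codetection, 20–100-fold
  compartment contrast. The intensity scale (photons) is a free
  simulation parameter, not an estimate of any particular data set.
* **Image stacks** (`gen_image_stack()`): each spot deposits its
  integrated amplitude as a 3D Gaussian (PSF sigma defaults 1.3 voxels
  lateral, 1.5 axial), integrated exactly over voxels via differences of
  the normal CDF and truncated at ±4σ per axis (<0.01% mass loss); voxel
  values are Poisson draws of background + signal. Channels share
  geometry and differ by per-spot brightness and detection events.
* **Spectroscopy** (`gen_spectro_read()`): exact inversion of the
  absorbance formulae plus optional Gaussian noise.
* **Sequences** (`gen_target_sequence()`): i.i.d. bases at a prescribed
  expected GC fraction.

All randomness derives from a single user seed through a counter-based
stream scheme (`derive_seed()`), so generating one data type never
perturbs another and module call order is irrelevant. A YAML config
(seed mandatory) can drive all generators at once
(`simulate_from_config()`).

**What passing tests do and do not show.** The generators reproduce the
distributional assumptions of the estimators — Gaussian copy-number
components, proportional channels, Poisson shot noise, uniform
backgrounds, isotropic-in-xy Gaussian PSFs. Real stacks add spectral
bleed-through, chromatic shifts, aberrations, autofluorescence,
hybridization-efficiency variation along the transcript and non-uniform
backgrounds, none of which are simulated. Ground-truth recovery here
therefore validates the implementation of the estimators, not their
robustness to optical artifacts.

## Problem sizes and numerical choices

Validation uses problem sizes at which the relevant sampling errors are
well below the tested tolerances: 3000–5000 objects for mixture and
codetection recovery (SE of a rate at n≈2000 singles is ~1%), 20-spot
64×64×32 stacks across 10 seeds for detection (a scale at which a run
completes in seconds), 50 random targets for tiling optimality, and 1000
draws for the spectroscopy round trip. Degenerate inputs fail loudly:
zero-variance intensity vectors, readings where dye absorbance dominates
OD260 (concentration would be non-positive), non-positive slopes, empty
images and non-ACGT targets all raise errors naming the problem rather
than returning quietly wrong numbers.

## Known limitations

* The Tm scale is model-dependent; only relative Tm matters for the
  built-in filter, and probes intended for other salt regimes should
  pass explicit `na_molar`/`oligo_molar`.
* The z-linker connects adjacent slices only; a spot whose support is
  interrupted for a whole slice splits into two chains (mitigated, but
  not eliminated, by plateau-aware maxima).
* The constrained mixture assumes exact `k`-fold intensity scaling;
  partial hybridization or quenching in real data violates this and the
  free mode should be compared via BIC.
* No off-target screening, secondary-structure prediction or spectral
  unmixing; compartment masks are user-supplied.
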