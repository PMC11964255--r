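---
title: "Methods: quantifying radiation effects on collagen fibrils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying radiation effects on collagen fibrils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collafib)
```

## Scope

`collafib` implements the computational side of a four-channel assay of
ionizing-radiation effects on type I collagen fibrils: (i) automated
morphometry of AFM height images with per-metric linear discriminant
classifiers and a consistency-derived change threshold, (ii) Hertzian
pyramid indentation-modulus extraction from force-distance curves,
(iii) tri-exponential TCSPC lifetime fitting with amplitude-weighted
average lifetimes, (iv) ATR-FTIR amide-band metrics with a denaturation
signature, plus the photon-dosimetry arithmetic that frames the doses.
A seeded synthetic-data module generates phantoms for all four channels
so every stage is testable without instrument data. No instrument control
and no neural-network feature extractor are included; the texture
descriptors here are a deterministic re-specification, not a port of any
trained network.

## The synthetic world

The generators' defaults are the conditions of the emulated experiment;
they are stated once and not tuned.

**AFM images.** 10 µm × 10 µm fields sampled at 51 px/µm (510 × 510 px),
patched into one hundred 1 µm (51 × 51 px) regions of interest (ROIs).
Fibrils are thick anti-aliased polylines with a semicircular height
cross-section (default width 220 nm, apex 40 nm), composited by maximum
height because AFM topography records the tallest surface. Axial
D-banding is a cosine height modulation with the canonical 67 nm
collagen repeat (the period is not stated by the source experiment;
67 nm is the field's standard value) and fractional depth 0.35 by
default. Orientation is uniform-random or aligned with 4° jitter; a
per-fibril kink (one abrupt 35-60° direction change) occurs with
probability `kink_prob`. Degradation is a Gaussian blur plus additive
height noise.

**Ground-truth labels** are functions of the generating geometry, never
of rendered pixels. The cutoffs live in `collafib_constants`: banding
present iff depth ≥ 0.10 and blur ≤ 30 nm; clear iff blur ≤ 30 nm and
noise ≤ 2 nm; randomly oriented iff the generator mode is random; linear
unless a kink vertex falls inside the ROI. These cutoffs are generator
conventions — the source assay defines its four classes only by visual
exemplars — chosen so tests can place phantoms unambiguously on either
side. Labels also carry `covered`/`n_cover`, the number of fibril
centerlines passing within half a fibril width of the ROI, used to build
evaluation sets (below).

**Force curves** follow
$F(\delta) = \frac{\tan\theta}{\sqrt2}\,\frac{E}{1-\nu^2}\,\delta^2$
with a zero-force baseline before contact, truncated at the 100 nN
protocol cap. With $E$ in GPa and $\delta$ in nm, $F$ is in nN.

**Decays** are Poisson draws around the analytic per-bin integral of
$I(t)=\sum_{i=1}^3 \alpha_i e^{-t/\tau_i}$ over 50 ps bins in a 200 ns
window, normalized to the configured photon total.

**Spectra** are sums of Gaussian amide bands over 800-4000 cm⁻¹:
native collagen has Amide A/I/II, a CH-bend band and the Amide III
triplet at 1205/1235/1280 cm⁻¹ with an Amide I:II amplitude ratio of
1.6; the denatured state shifts Amide I to ~1641 cm⁻¹, reduces Amide II
and removes the triplet.

What the phantoms do **not** emulate: tip convolution, scanner drift,
cantilever calibration error, the TCSPC instrument response function,
ATR penetration-depth dispersion, or biological heterogeneity between
scaffolds. A green test therefore establishes that the pipeline recovers
what its own forward models encode, at realistic sampling and noise — not
that it would reproduce any instrument's systematics.

## Texture morphometry

Each ROI is summarized by a fixed-schema descriptor vector
(`extract_features`): radially averaged 2-D power-spectral-density
fractions in six annuli plus a dedicated band at the D-banding frequency
(1/67 nm⁻¹ ± 20%) and its peak-to-background ratio; spectral entropy;
the angular concentration of the low-frequency spectrum (doubled-angle
resultant — a straight fibril's envelope concentrates along one axis
through the origin); structure-tensor coherence, secondary-axis energy
fraction and doubled-angle circular variance; quadrupled-angle gradient
statistics; radius-6 px pooled gradient-contrast and local-SD
statistics; and orientation-field curvature.

Two numerical choices matter and were forced by the banding physics.
First, banding adds axial gradients orthogonal to the cross-fibril ones;
in doubled-angle statistics the two populations cancel, so raw gradient
orientation is summarized modulo 90° (quadrupled angles), which
identifies the fibril axis regardless of which population a pixel
belongs to. Second, the structure tensor is computed on a low-passed
copy of the ROI (Gaussian σ of half the banding period) so coherence and
the orientation field track the fibril envelope rather than the banding
texture; orientation statistics are gated to pixels above 5% of the
maximum tensor energy so bare substrate does not contribute noise
orientations.

Per metric, a two-class LDA (`train_metric_classifier`) uses an
MLE-pooled covariance with a diagonal ridge of `1e-4 × mean(diag)`
(positive-definite on small sets; MLE pooling makes a duplicated
training set reproduce the identical model). Boundary ties go to the
positive class. Priors are empirical by default; the pipeline trains
with **balanced** priors because prevalence estimation with empirical
priors majority-votes rare classes (kinked ROIs) away and suppresses
exactly the changes the assay is meant to detect.

Reliability is leave-one-out consistency (`loo_consistency`): the
literal refit-all-holdouts loop, with the change-detection threshold
defined as exactly `100 − consistency`. Change tables compare paired
prevalences per metric; linearity is stored as linear% and differenced
on kinked% so increased kinking is a positive change.

**Clean-class evaluation.** The recovery property ("each metric ≥ 90%
LOO consistency on clean, well-separated classes, 100 ROIs per class")
requires saying what a *clean* class is. The definitions in
`clean_class_rois`, fixed from label semantics: banding and clarity are
evaluated on fibril-covered ROIs (bare substrate carries no class
information — a human rater would skip empty patches); orientation on
ROIs crossed by ≥ 3 fibrils (one fibril is always locally "aligned", so
scan isotropy is undecidable below that); the kinked class is ROIs whose
kink vertex lies ≥ 250 nm inside the ROI (both arms visible) and the
straight class is ROIs traversed by exactly one straight fibril, because
crossings of two straight fibrils are locally indistinguishable from
kinks. All restrictions are geometry-derived.

## Indentation mechanics

The fit model is the quadratic-pyramid Hertz law above. The prefactor
convention is $\tan\theta/\sqrt2$; the Bilodeau constant
$0.7453\tan\theta$ (≈ 5% larger) is available via
`prefactor = "bilodeau"` since the analysis software behind the original
numbers does not print its constant. ν defaults to 0.5 (incompressible),
the common AFM assumption; it is exposed as a flag because the protocol
does not state it. Only extend segments are fitted.

Contact-point detection is baseline-relative (mean + 3 SD of the leading
20% of samples, two consecutive exceedances), then the contact point is
refined as a free fit parameter: for any candidate contact $z_c$ the
modulus has the closed-form least-squares solution
$E = \sum F\delta^2 / (C\sum\delta^4)$, so $z_c$ is found by a 64-point
coarse scan plus local refinement over a window extending well *before*
the detected contact (threshold detection always fires late; an early
version that searched only ± 10 samples around the detected point biased
$E$ upward ~20% at 1% noise). Group summaries use medians over converged
fits with percent variation computed from unrounded medians.

Rank statistics: Mann-Whitney U with the exact null distribution for
tie-free samples of ≤ 20 per group and a tie-corrected,
continuity-corrected normal approximation otherwise (identical samples
return p = 1 by the zero-variance guard); Kruskal-Wallis with tie
correction and Dunn's pairwise z tests under Bonferroni adjustment (the
source analysis names Dunn's test without an adjustment family).

## Lifetime fitting

`fit_triexponential` is a tail fit from the histogram peak onward with
Poisson weights `1/max(counts, 1)` — no instrument-response
deconvolution, a documented systematic difference from full-reconvolution
vendor software. Because counts are bin *integrals*, the design matrix
uses the analytic per-bin integral of each exponential from the peak
bin's lower edge; evaluating point intensities at bin centers instead
distorts the short-lifetime amplitudes and biases the amplitude-weighted
mean by ~2-3% at 50 ps bins. Lifetimes are optimized on the log scale by
Nelder-Mead from six deterministic log-spaced starts; at fixed lifetimes
the amplitudes solve by non-negative weighted least squares (active-set
clamping), so the search is a 3-parameter variable projection and the
whole fit is deterministic. Components are reported sorted by ascending
lifetime; zero-amplitude components are retained so
$\bar\tau = \sum\alpha_i\tau_i / \sum\alpha_i$ is always evaluable.
Condition summaries are means ± SD of $\bar\tau$ with percent change vs
the paired control rounded to integer percent for the report column
(unrounded retained).

## FTIR metrics

Preprocessing is rubber-band baseline correction (lower convex hull by
monotone chain; adding any affine baseline leaves the output unchanged,
and the operation is idempotent) followed by normalization to unit
Amide I peak height; a linear-endpoint baseline is available behind
`method = "linear"`. Peaks are local maxima of a Savitzky-Golay-style
quadratic smooth (9-point window, a named constant) above a height floor
of 0.02, searched in documented windows: Amide I 1600-1700, Amide II
1500-1590, and ± 10 cm⁻¹ sub-windows around 1205/1235/1280 for the
triplet. The I/II ratio uses baseline-corrected peak heights (area mode
behind a flag — the original report says "ratio" without defining it).
The denaturation signature is `Amide I ≥ 1637 cm⁻¹ AND triplet absent`.

## Dosimetry

Constants are pinned at the rounding the irradiation arithmetic
evidently used — e = 1.602×10⁻¹⁹ C, h = 6.626×10⁻³⁴ J s,
c = 2.998×10⁸ m/s — so 100 keV → exactly 1.602×10⁻¹⁴ J.
`energy_budget` reports the exact products dose × mass and
m·c_p·ΔT.

## Known discrepancies

These are reported by the package as computed and intentionally not
reconciled:

* **Co-60 1.33 MeV photon energy.** 1.33 MeV × 1.602×10⁻¹⁹ =
  2.13066×10⁻¹³ J. The published figure 2.12966×10⁻¹³ J appears to be a
  digit typo (its companion wavelength 0.00093 nm is consistent with
  either value). One acceptance assertion is left failing against the
  printed number by design.
* **Energy balance.** 25 kGy × 8.9 mg = 0.2225 J, not the published
  0.623 J; 8.9 mg × 3.8×10³ J/(kg·°C) × 65 °C ≈ 2.2 J, not 2.2 kJ. The
  module returns the exact products; the orders-of-magnitude argument
  (radiation ≪ thermal energy input) survives either way.
* **Threshold pairing.** The published threshold row pairs 14% with
  D-banding and 16% with clarity in its own column order, while the
  accompanying text swaps them (and 6/7 for linearity/orientation). The
  change-table reproduction uses the table's own pairing — the only one
  that yields the reported "three of four" wet-sterilization
  exceedances. `loo_consistency` itself always reports
  `threshold = 100 − consistency`, which matches the text's 16 = 100 − 84
  for D-banding.
* **Indentation depth.** At 4.82 GPa, 100 nN, θ = 20.8°, ν = 0.5 the
  force law inverts to δ = 7.6 nm, on the reported ~10 nm scale but
  below the quoted 10 ± 1 nm; dropping the (1−ν²) divisor gives 8.8 nm.
  The generator test asserts exact agreement with the closed-form
  inversion and a documented 7-13 nm band.
* **Published variation column.** The percent variations printed beside
  the modulus medians cannot be recomputed from the printed (rounded)
  medians themselves (e.g. 3.92/5.43 → −27.8%, not −26.4%); they were
  presumably computed from unrounded values, so no exact-match test is
  keyed to them and `summarize_group` reports variation from unrounded
  medians.

## The emulated experiment

`default_experiment_config` declares six paired groups (dry/wet ×
diagnostic/therapeutic/sterilization). Control moduli sit at the
observed control medians with the reported percent variations applied to
the irradiated members; average lifetimes change by +6% (dry
sterilization) and −5% (wet sterilization) and are null elsewhere; all
FTIR states are native (the assay found no denaturation at any dose).
Morphometry is null in every group except wet sterilization, whose
irradiated member loses banding, gains blur and noise just beyond the
label cutoffs (32 nm, 2.5 nm) and gains kinks in 80% of fibrils — a
*partial* degradation, because the degraded scans in the source
experiment remained analyzable. The classifier training set spans every
condition, including degraded variants; omitting those makes all four
classifiers drift under the blur/noise covariate shift of degraded
samples, which shows up as spurious orientation flags.

`run_pipeline` emits consistency, change, prevalence, modulus and
lifetime tables plus FTIR metrics and a manifest of all seeds; stages
fail independently. A paired group whose irradiated phantom config is
identical to its control reuses the control's seed stream — emulating
re-imaging an unchanged sample — so a null experiment produces exactly
zero change.

## Limitations

The texture descriptors are one defensible re-specification of an
unpublished feature extractor; consistency percentages on real AFM data
(the published 86/84/94/93) are benchmarks this artifact cannot and does
not reproduce. Lifetime fits without IRF deconvolution are biased for
lifetimes comparable to the instrument response; the phantoms have no
IRF, so this bias is invisible here by construction. The rubber-band
baseline assumes convex background; strongly scattering ATR spectra can
violate that. Kink detection is local: a kink vertex sitting on an ROI
boundary is labelled by vertex position, not appearance, which bounds
achievable consistency on dense kinked phantoms.
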