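---
title: "Methods: intraoperative Raman tissue classification with ramanclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intraoperative Raman tissue classification with ramanclass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ramanclass)
```

## The problem and the model

A handheld Raman probe pressed against brain tissue during surgery records,
per probed location, a sequence of short CCD exposures. Each exposure mixes
the inelastic-scattering (Raman) fingerprint of the local biochemistry with
a fluorescence background one to two orders of magnitude larger, detector
dark counts, shot noise, and occasional cosmic-ray spikes. The analysis task
is to decide, per location, whether the tissue is bulk tumor or non-tumoral
brain, with histopathology of a colocalized biopsy as the label.

`ramanclass` models a measurement at wavenumber $\nu$ (cm$^{-1}$) as

$$\lambda(\nu) \;=\; R(\nu)\,\bigl[B(\nu) + S(\nu)\bigr] + D,$$

where $R$ is the smooth instrument response, $B$ a smooth fluorescence
baseline, $D$ the mean dark count, and
$S(\nu) = \sum_k A_k\, e^{-(\nu-\mu_k)^2/2\sigma_k^2}$ the Raman signal as a
Gaussian band mixture. The diagnostic contrast lives in the band amplitudes
$A_k$: tumor tissue carries more protein signal (phenylalanine at
1004 cm$^{-1}$, tryptophan at 1340 cm$^{-1}$) and less lipid signal
(1299 cm$^{-1}$ and the CH$_2$ lipid/protein band at 1441 cm$^{-1}$); the
amide-I/C=C band at 1659 cm$^{-1}$ does not discriminate and is configured
with equal class means. Raw counts are Poisson-distributed about
$\lambda(\nu)$ with additive Gaussian read noise.

## The nine-step conditioning chain

`preprocess_acquisition()` applies, in order: (1) dark-frame subtraction;
(2) cosmic-ray removal; (3) truncation to the 800–1750 cm$^{-1}$
fingerprint (closed interval — on the factory axis, whose bins fall exactly
on 800 and 1750 cm$^{-1}$ with spacing 950/520 cm$^{-1}$, exactly 521 bins
survive); (4) wavenumber calibration; (5) instrument response correction;
(6) averaging of the 20 repeats; (7) BubbleFill baseline removal;
(8) Savitzky–Golay smoothing (order 3, window 11); (9) SNV normalization.

Choices a reader should know about:

- **Truncation before calibration.** The enumeration puts truncation ahead
  of the axis fit, so bins are selected on the provisional factory map and
  re-checked afterwards; a bin is dropped only if calibration moves it more
  than half a bin spacing outside the window. Without that guard, sub-0.1
  cm$^{-1}$ calibration noise on a bin sitting exactly at 800 cm$^{-1}$
  would toggle the 521-bin contract at random.
- **Cosmic-ray removal** exploits the 20 repeats: per bin, values deviating
  from the across-repeat median by more than $k = 8$ scaled MADs are
  replaced by the median. Bins whose repeats are constant are never touched,
  so noiseless data pass through bit-identically.
- **Calibration** detects the reference material's peaks, refines each apex
  by a least-squares parabola over ±3 pixels of the (lightly smoothed)
  reference, and fits a degree-1 polynomial pixel → cm$^{-1}$ map. On the
  generator's references this recovers the true axis to < 0.1 cm$^{-1}$
  RMS.
- **Response correction** divides by the ratio of the measured standard to
  its known emission curve, Savitzky–Golay-smoothed (the physical response
  is smooth; smoothing keeps the reference's shot noise out of every
  spectrum) and normalized to unit mean so it changes shape, not scale.
- **SNV** uses the population (divide-by-$n$) standard deviation; outputs
  satisfy mean 0, sd 1 to 10$^{-9}$.

### BubbleFill

The baseline estimator normalizes the spectrum to the unit square and grows
circular-arc "bubbles" from below: for the current segment, an arc with
chord equal to the segment width is raised until it first touches the
spectrum (leftmost bin on ties), recorded into the baseline (pointwise
maximum), and the segment is split at the touch point; recursion stops when
a segment is narrower than the minimum bubble diameter (default 60
cm$^{-1}$, the width of the ubiquitous 1441 cm$^{-1}$ band). Two
refinements proved necessary in validation: segments touching a spectrum
edge keep recursing below the minimum width (otherwise the steep
fingerprint-edge baseline leaves a several-percent residual in the first
bins — the corollary is that edge features narrower than the minimum bubble
are not protected), and the accumulated baseline is smoothed with an
order-2 Savitzky–Golay of window equal to the minimum bubble width (a plain
moving average is slope-biased at the edges), then clipped to stay at or
below the spectrum.

On a featureless smooth background the residual is below 1 % of the dynamic
range; narrow bands ($\sigma \approx 5$ cm$^{-1}$) retain their heights
within a few percent. A band whose width *equals* the minimum bubble
diameter — by construction the 1441 cm$^{-1}$ band — is partially eroded
(roughly half its pedestal is absorbed into the baseline). This is a
structural property of any baseline filter whose feature-size cutoff
matches the band width; it rescales that band consistently across classes,
so the SNV-domain class contrast survives (Cohen's d at 1441 cm$^{-1}$
stays near 3 under the default conditions), but absolute band ratios are
not preserved.

## Spectral quality factor

For an SNV spectrum $r$, $\mathrm{QF} = \frac1N \sum_i \mathrm{sgn}(r_i)
r_i^2 = 1 - 2E^-$, with $E^-$ the mean squared negative part; unit SNV
variance bounds it in $[-1, 1]$. Noise-dominated spectra score near 0,
peak-bearing spectra well above. QF is computed on the final (smoothed,
SNV) stage. The cutoff search (`select_qf_threshold()`) scores each
candidate cutoff by cross-validated AUC of the retained data, subject to
the retained minority-class fraction staying at or above 0.4 (the balance
bound is a config knob; no principled value exists). Two pragmatics, both
deliberate: the workflow inside the search runs at fixed default
hyperparameters (15 bands, 5 peak features, C = 1) rather than a full grid
— a full (N, C) search per cutoff multiplies cost for no ranking benefit —
and the CV AUC is the *mean of per-fold AUCs*, because decision scores from
folds with different fitted feature sets are not on a common scale and
pooling them inflates the null variance. Preset cutoffs of 0.5
(glioblastoma, metastasis) and 0.3 (meningioma) are the pipeline default.

## Features and classification

Peak features come from Gaussian-plus-offset fits (window ±3 initial
widths, Levenberg–Marquardt, apparent-value fallback) to local maxima with
prominence ≥ 0.1 and height ≥ 0.5 above the spectrum minimum; peaks present
in ≥ 50 % of measurements (inclusive) are retained as consensus positions,
at most 11, each contributing height and width columns. Unmatched spectra
are imputed with height 0 and the consensus median width (an invented but
conservative rule: absence of a peak is itself informative). Band and peak
columns within 1500–1620 cm$^{-1}$ (haemoglobin) are excluded.

Selection ranks band and peak columns separately by impurity importance of
a 200-tree random forest fit on training folds only, keeping the top
`n_band` ∈ [5, 25] and `n_peak` ∈ [2, 20]. The split of the total feature
budget N into per-type quotas is the only reading consistent with both
stated ranges. The classifier is a linear SVM with inverse-class-frequency
weights; `grid_search_cv()` minimizes summed false positives plus false
negatives over patient-grouped five-fold CV (ties → smaller N, then smaller
C). Folds, like the 80/20 holdout, are grouped by patient — grouping the
folds is stricter than grouping only the holdout, and prevents
patient-effect leakage into hyperparameter choice. The holdout split is a
greedy, seeded, per-site assignment of whole patients targeting 20 % of
measurements, which keeps the holdout's site mix near the training mix.
Evaluation reports the trapezoidal AUC and accuracy/sensitivity/specificity
at the ROC point minimizing FP + FN (ties → higher sensitivity).

## The synthetic cohort: what it emulates, and what it does not

`cohort_config()` defaults define the study conditions: 2 sites × 3
pathologies × 4 patients × 30 locations (balanced tumor/brain within each
patient), 20 repeats per location, fluorescence baseline ~4000 counts with
exponential decay (length 700 cm$^{-1}$), dark mean 100, Poisson shot noise
plus read noise (sd 5), 0.2 cosmic spikes per frame (1–3 bins, 10–100×
local signal), log-normal per-patient band-group effects (sd 0.10) and
per-location amplitude jitter with tumor (0.12) below brain (0.20) —
tumor spectra show lower variance — and a ±10 % smooth per-site gain curve.
26 % of locations are "low quality": their photon throughput is scaled by
0.01 so the dark/read-noise floor dominates, which is what drives their QF
toward 0. Band amplitude contrasts were calibrated once so that the
a-posteriori per-pathology Cohen's d at 1441 and 1004 cm$^{-1}$ (computed
on quality-filtered processed spectra) exceeds 1.8, matching the regime the
acceptance conditions prescribe; at those settings the default cohort is
separable and holdout metrics sit at or near 1.0.

Not emulated: tissue optics (scattering/absorption), probe geometry,
within-patient spatial correlation beyond the patient effect, label noise
from imperfect histopathology, site differences beyond the gain curve
(inter-site variability is not quantified in the literature this design
follows; the ±10 % curve is a stand-in), and asymmetric per-site cohort
sizes. Passing tests on this generator therefore demonstrate correctness of
the pipeline's mechanics and its statistical contracts — not clinical-level
performance on real tissue.

## Numerical choices and degenerate inputs

- Problem sizes: the default cohort is 720 locations (about 100+ per
  category per pathology after filtering, consistent with the power
  analysis below); validation studies in the tests use 1000+ locations per
  class in truth-only mode (`generate_cohort(frames = FALSE)`).
- Power: `power_sample_size()` iterates the exact noncentral-t power
  upward/downward from the normal-approximation start; d = 0.5, α = 0.05,
  power 0.95 (two-sided) gives 105 per group (the usual rounded requirement
  is 100). The d → ∞ floor is n = 2.
- Degenerate inputs fail loudly with stage-tagged errors in
  `run_raman_pipeline()`: zero-dispersion SNV, empty truncation, fewer than
  3 calibration peaks, nonpositive response, quality filters that empty a
  class, single-class folds (re-drawn once, then error).
- Determinism: every stochastic stage draws from a seed derived from the
  config seed; rerunning a config reproduces reports, weights and manifest
  bit-identically.

## Known limitations

- The clean separability of the default generator leaves headline holdout
  metrics at ceiling; structural comparisons (QF filtering helps, the
  all-tumor model is no better than per-pathology models) are trends, not
  guarantees, at this cohort size.
- BubbleFill's erosion of bands at the cutoff width (above) means absolute
  band intensities after preprocessing are not quantitative.
- `select_qf_threshold()` inherits the noise of small-fold AUCs; on small
  cohorts adjacent cutoffs often tie, and the tie-break (smallest cutoff)
  is then the operative rule.
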