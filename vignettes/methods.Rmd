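---
title: "Models and methods behind ohtcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ohtcohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohtcohort)
library(dplyr)
```

`ohtcohort` implements the computational analysis of a two-group,
bilateral rodent chronic ocular-hypertension (OHT) experiment: one eye of
each animal receives a circumlimbal suture that chronically elevates
intraocular pressure (IOP), the fellow eye serves as its contralateral
control, and a sham group receives the suture transiently (removed on
day 2). Retinal function is phenotyped with the dark-adapted full-field
electroretinogram (ERG), structure with OCT morphometry and flat-mount
ganglion-cell counts, perfusion with Doppler pixel counting, and
molecular state with absolute qPCR. This vignette explains each model,
its assumptions, the tunable parameters, and the design choices that were
genuinely open.

## ERG component decomposition

A dark-adapted flash ERG is treated as the sum of four components, which
the pipeline strips off in sequence.

**P3 (photoreceptors).** The leading edge of the a-wave is modeled by the
delayed-Gaussian saturating function

$$P3(i, t) = Rm_{P3}\,\{1 - \exp[-\,i\,S\,(t - t_d)^2]\}, \qquad t > t_d,$$

with $Rm_{P3}$ the saturated (negative) amplitude in µV, $S$ the
sensitivity in m²·cd⁻¹·s⁻³ (time in seconds inside the exponent), and
$t_d$ a short delay in ms. `fit_p3()` fits a single $(Rm_{P3}, S, t_d)$
triple jointly to the brightest flashes (the two brightest by default;
configurable) by least squares. Choices that the model itself does not
dictate:

* *Fit window.* The delayed-Gaussian is valid only on the a-wave leading
  edge, so the window runs from flash onset to 1 ms past the a-wave
  trough of the brightest flash, found within 0–50 ms. Beyond the trough
  the rising P2 dominates and would bias the fit.
* *Optimization.* The loss surface is smooth and low-dimensional;
  box-constrained quasi-Newton from heuristic starts ($Rm_{P3}$ from the
  minimum voltage, $S = 10^3$, $t_d = 3$ ms), with a Nelder-Mead polish
  and multi-start recovery on failure. A brute-force 50×50×10 grid
  search over the parameter box serves as an independent quality oracle
  in the tests: the fit must never lose to the grid.
* *$t_d$ shared* across the ensemble energies; flash energy enters as
  linear cd·s/m² converted from the log grid.

**P2 (ON-bipolar cells).** `derive_p2()` subtracts the fitted P3 from
each raw waveform on its own time grid, so `raw = P3 + P2` holds to
machine precision by construction. The per-energy P2 amplitude is the
maximum positive excursion from the pre-stimulus baseline in 0–150 ms,
and `fit_naka_rushton()` models amplitude versus linear energy with the
hyperbola $V(i) = V_{max}\, i/(i + k)$. At $i = k$ the model gives
exactly $V_{max}/2$. Sensitivity is reported as $\log_{10}(1/k)$; the
transform is a convention adopted here (the amplitude-based sensitivity
scale for P2 is not uniquely standardized) and is flagged as such in the
documentation. Fits whose $k$ lands more than 10× outside the sampled
energy range are flagged as non-spanning.

**Oscillatory potentials.** OPs are isolated from the brightest-flash P2
trace with a digital band-pass of 50–180 Hz at −3 dB. The filter is a
Butterworth band-pass (order-2 prototype, i.e. a 4th-order band-pass)
applied forward–backward so the phase is exactly zero and implicit times
are not shifted. Because two passes square the magnitude response, the
single-pass corners are pre-widened numerically so that the *two-pass*
gain is −3 dB at exactly 50 and 180 Hz. The order-2 prototype is the
lowest order that meets both that corner condition and ≥ 20 dB
attenuation at 10 and 400 Hz; an order-1 prototype cannot. OP amplitude
is defined as the largest trough-to-peak excursion among the wavelets in
the 10–60 ms window (an alternative convention sums the wavelet peaks;
the window and definition are configurable), implicit time as the time
of the largest filtered peak.

**pSTR (ganglion cells).** The positive scotopic threshold response is
measured on the raw, unfiltered waveforms at the three dim analysis
energies −5.31, −5.01 and −4.90 log cd·s/m², as the positive peak in a
80–160 ms window, then arithmetic-averaged across the three energies.
Energy labels are matched with a ±0.05 log-unit tolerance because the
same nominal step is variously labeled (e.g. −4.90 vs −4.87).

## Longitudinal IOP

Each timepoint is the mean of 10 tonometer readings; fewer than 10 is
accepted with a protocol-deviation warning and no outlier rejection is
applied (a trimmed mean is available behind a flag but is off by
default). Baseline is the mean of the five pre-surgical daily values.
The chronic plateau statistic is the mean over weeks 2–12 — week 1 is
excluded because the post-surgical decay has not fully settled by then.
Elevation is reported both as mean of per-animal treated/control ratios
and as the ratio of group means; the two differ slightly and both are
retained.

## Morphometry

Thicknesses are measured along the A-scan (axial) direction between
manually segmented boundaries: RNFL from the inner limiting membrane to
the RNFL posterior boundary, total retinal thickness to Bruch's
membrane, averaged over 100–800 µm on either side of the optic nerve
head and pooled across all B-scans. BMO width is the Euclidean distance
between the two Bruch's-membrane-opening endpoints per scan, averaged
over scans. Minimum rim thickness is the brute-force minimum Euclidean
distance from each BMO endpoint to any ILM sample; the two endpoint
minima are averaged per scan, then over scans (whether a per-endpoint or
global per-scan minimum is intended is ambiguous in common usage; the
per-endpoint average is adopted and documented). Doppler flow is the
supra-threshold pixel count per channel; the default threshold is Otsu's
method per channel, recorded in the output for reproducibility. RGC
density is count over field area (290.62 µm square fields), averaged per
quadrant over eccentricities.

## qPCR quantification

Each run carries four-point external standard dilutions (default
10²–10⁵ copies, an assumption stated here rather than a measured fact);
`fit_standard_curve()` fits $Ct = b + m\log_{10}(\text{copies})$ and
derives efficiency $10^{-1/m} - 1$, flagging curves outside 60–130%.
Samples are quantified by inverting the line; triplicates are averaged
on the linear copy scale (averaging Cts would bias low by Jensen's
inequality; the choice is configurable). Curves are never pooled across
runs. Expression is normalized to Hprt copies from the same sample, and
the P2X7/A3 balance is the ratio of normalized P2x7 to Adora3.

## Cohort statistics

Treated-vs-contralateral comparisons use two-sided paired t-tests;
control-vs-control comparisons across groups use the pooled-variance
unpaired t-test (Welch fallback when variance screening fails).
Normality (Shapiro-Wilk) and homogeneity of variance (Bartlett) are
screened beforehand. The two-way repeated-measures ANOVA for the IOP
course is implemented in-repo from the split-plot sums-of-squares
decomposition (group × time with subject as the repeated factor; F for
group over subject-within-group, F for time and interaction over the
within-subject residual) because software conventions vary; it is tested
to 10⁻⁸ against `stats::aov()` with an `Error(subject)` term on random
balanced designs. No sphericity correction is applied, and no
multiple-testing correction is applied by default; a Holm column is
available as a clearly marked extension. Attrition is accounted with
success percentage over attempted surgeries and per-cause shares over
failures.

## The synthetic cohort generator

`simulate_study()` generates every input table with known ground truth.
Waveforms are the sum of the delayed-Gaussian P3, a gamma-shaped P2
transient $((t/t_p)^8 e^{8(1 - t/t_p)}$, peak 45 ms) scaled by the
Naka-Rushton energy dependence, a Gaussian-windowed 110 Hz cosine
wavelet (σ = 4 ms, centered 42 ms) riding the b-wave at bright energies,
a Gaussian pSTR bump (peak 110 ms, σ = 15 ms) whose saturating energy
dependence (half-saturation 10⁻⁴·⁶ cd·s/m², normalized at −5.01) puts
the three analysis energies on its rising limb, and white Gaussian
noise. The IOP course has a post-surgical spike decaying exponentially
(τ = 2.9 d) toward the chronic plateau; sham treated eyes revert to
baseline from day 2. Boundary traces are flat at the configured
thicknesses so morphometry recovers them exactly; RGC counts are Poisson
with mean density × field area; Cts follow the configured log-linear
standard curve.

Key generator conditions and why:

* Group sizes default to 23 OHT and 17 sham animals, bilateral; the
  qPCR subset is 9 + 9 animals and the flat-mount subset 12 + 8.
* Control-eye means are the study's printed control values (RmP3
  −624 µV, log S 2.63, Vmax 863 µV, P2 log sensitivity 3.26, OP 114 µV
  at 42.3 ms, pSTR 16 µV; baseline IOP 13.8 mmHg, spike 38 mmHg,
  plateau +5.7 mmHg; RNFL 12.3 µm, MRT 150.4 µm; quadrant RGC densities
  3531/3678/3772/3592 cells/mm²; Entpd1/Hprt 0.28). TRT (230 µm) and
  BMO (700 µm) are typical murine values because only figures, not
  numbers, report them; remaining panel genes have order-of-magnitude
  plausible levels. The P3 delay td = 3 ms is a standard murine value.
* Treated-eye effect multipliers encode the chronic-OHT phenotype:
  −15% P3 and P2, −19% pSTR, −9% OPs, −20% RNFL, −4.6% MRT, quadrant
  RGC losses of 8–17%, +10.7% Entpd1, no change elsewhere.
* Biological variability is a lognormal animal-level scale factor
  (CV 0.15) shared by both eyes plus an independent eye-level factor
  (CV 0.06), which reproduces group SEMs of the observed magnitude while
  preserving the pairing that the contralateral design exploits. Gene
  expression carries an animal-level per-gene factor (CV 0.08); whole
  sample RNA scale cancels in the Hprt normalization.
* Waveform noise defaults to 1.5 µV per sample, representing records
  after the usual sweep averaging at dim energies; tonometer reading
  noise is 1.5 mmHg per reading (0.47 mmHg after the 10-reading
  average); Ct noise is 0.08 cycles per well. These noise levels are
  generator configuration, stated here, not literature values.

### What the generator does and does not emulate

The generator reproduces the *structure* the analysis assumes — additive
ERG components with saturating energy dependence, spike-decay-plateau
pressure dynamics, ordered layer boundaries, Poisson counts, log-linear
Cts — but not waveform shape variability (fixed kernel shapes and peak
times), OCT curvature or speckle, spatial cell clustering, or
inter-operator segmentation differences. Passing recovery tests
therefore demonstrates that the estimators are correct and stable under
realistic noise and effect sizes, not that they are robust to every
physiological shape deviation in real recordings.

Two deliberate consequences of the additive design are worth noting.
First, OP wavelets ride the b-wave near its peak, so the measured P2
amplitude of a composite waveform slightly exceeds the P2 kernel's own
amplitude — exactly as in real recordings, where the conventional b-wave
amplitude includes the OPs. Treated/control *ratios* are essentially
unaffected because both eyes carry proportional OPs. For this reason the
parameter-recovery benchmarks isolate one component at a time (a pure-P3
family for the P3 fit, a pure-P2 family for the Naka-Rushton fit), which
is also how the recovery tolerances are meaningful at the 0.1% level.
Second, near threshold the pSTR bump is part of the measured "P2"
amplitude, as it is in real data; the Naka-Rushton fit is dominated by
the mid-to-bright energies where this does not matter.

## Replicate detection study

`run_replicate_study()` simulates complete cohorts at the configured
effect sizes and reports, per endpoint, the fraction of replicates in
which the treated-vs-contralateral OHT contrast is significant at
α = 0.05 (power), alongside the pooled rate of significant sham
contrasts (type-I behavior; no chronic effect is simulated in sham
eyes). The pooled sham rate is used rather than requiring *every* sham
contrast in a replicate to be non-significant because with five
endpoints per replicate the latter event has probability well below 90%
even for a perfectly calibrated test; the pooled rate estimates the
per-test error directly. Because the three ERG endpoints of an eye share
biological scale factors, their sham p-values are positively correlated
and the pooled estimate is clustered — its sampling variability is
larger than an independent-binomial calculation suggests. Default
problem sizes (20 replicates of the full 23 + 17 cohort; 50 replicates
for noisy-recovery medians) keep a full validation run to a few minutes
while leaving the binomial margins interpretable.

## Numerical choices and degenerate inputs

Constant paired differences short-circuit the t-test (t = 0, p = 1 for
all-zero differences; p → 0 for a deterministic shift) rather than
erroring inside `t.test`, so zero-noise simulations flow through the
statistics layer. All-zero waveforms, empty windows, missing analysis
energies, inconsistent attrition totals, non-positive denominators and
unbalanced ANOVA designs raise errors naming the offending input. Energy
matching uses a ±0.05 log-unit tolerance; time grids must be uniform to
1 ppm; boundary tables must satisfy ILM ≤ RNFL-posterior ≤ BM at every
sample.

## Known limitations

* Single-flash (non-ensemble) P3 fitting carries no recovery guarantee;
  the ensemble is the supported interface.
* OP amplitude recovery is measured in ratio terms, not absolute: the
  trough-to-peak statistic of a Gaussian-windowed wavelet is ~1.9× the
  wavelet's peak amplitude, so absolute OP truth values and measured
  values differ by a fixed shape factor.
* The RM ANOVA assumes a complete balanced subject × time table and
  applies no sphericity correction (noted in its output).
* Percent-change conventions (mean-of-ratios vs ratio-of-means) diverge
  for skewed data; both are always reported.
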