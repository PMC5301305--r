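# ohtcohort

Analysis pipeline for preclinical **chronic ocular hypertension (OHT)
cohorts** with a bilateral design: one eye of each animal carries a
circumlimbal suture that chronically elevates intraocular pressure
(IOP), the fellow eye is its contralateral control, and a sham group
receives the suture only transiently. The package is written for
visual-neurophysiology labs that phenotype such models with dark-adapted
full-field electroretinography (ERG), rebound tonometry, OCT
morphometry, flat-mount ganglion-cell counts and qPCR — and for anyone
who wants a fully synthetic, ground-truth-known replica of such a study
to validate analysis code against.

## What it computes

**ERG decomposition.** Each eye's intensity series is decomposed into
four components:

- **P3** (photoreceptors): the a-wave leading edge is fit with the
  delayed-Gaussian saturating model
  *P3(i,t) = Rm<sub>P3</sub>·{1 − exp[−i·S·(t−t<sub>d</sub>)²]}*,
  jointly over the brightest flashes, giving the saturated amplitude
  Rm<sub>P3</sub> (µV), sensitivity S (m²·cd⁻¹·s⁻³) and delay
  t<sub>d</sub> (ms).
- **P2** (ON-bipolar cells): the fitted P3 is subtracted from each raw
  waveform; P2 amplitude versus energy follows the Naka-Rushton
  hyperbola *V(i) = V<sub>max</sub>·i/(i+k)*, giving V<sub>max</sub> and
  the semi-saturation energy k.
- **Oscillatory potentials**: a zero-phase 50–180 Hz (−3 dB) band-pass
  isolates the wavelets riding the b-wave; amplitude is the largest
  trough-to-peak excursion, implicit time the largest peak.
- **pSTR** (ganglion cells): positive peak amplitude and implicit time
  averaged over the −5.31, −5.01 and −4.90 log cd·s/m² flashes.

**IOP course.** Ten-reading averages per timepoint, 5-day baseline,
post-surgical spike, and the chronic plateau over weeks 2–12, with the
elevation as Δ mmHg and percent increase.

**Morphometry.** RNFL and total retinal thickness over 100–800 µm either
side of the nerve head, Bruch's-membrane-opening width, minimum rim
thickness (shortest BMO-to-ILM distance), Doppler supra-threshold pixel
counts, pupil diameter, and RGC densities per quadrant from
290.62 µm-square counting fields.

**qPCR.** Absolute quantification against per-run four-point standard
curves, Hprt normalization, and the P2x7/Adora3 balance ratio.

**Cohort statistics.** Paired t (treated vs contralateral), pooled
unpaired t (control groups), two-way repeated-measures ANOVA
(implemented from the split-plot sums of squares and oracle-tested
against `aov`), Shapiro-Wilk/Bartlett screening, percent change,
attrition accounting, and a three-contrast study report per endpoint.

**Synthetic cohorts.** `simulate_study()` generates every input table —
waveforms, tonometry, boundary traces, Doppler maps, counts, Ct values —
from known ground truth with configurable effect sizes and noise, so the
entire pipeline is testable end-to-end.

## Worked example

```r
library(ohtcohort)
library(dplyr)

study <- simulate_study(cohort_config(n_oht = 6, n_sham = 6),
                        study_truth(), seed = 42)

# one eye's full ERG decomposition
eye <- study$waveforms |> filter(animal == "OHT01", eye == "control")
erg_decompose_eye(eye)
#> Delayed-Gaussian P3 ensemble fit
#>   RmP3 = -682.5 uV   S = 411.8 m^2.cd^-1.s^-3 (log S = 2.61)   td = 2.91 ms
#>   window 0.0-14.2 ms, 116 samples over energies {1.07, 2.07}, residual RMS 4.49 uV
#> Naka-Rushton intensity-response fit
#>   Vmax = 1060.3 uV   k = 0.000538 cd.s/m^2   log sensitivity = 3.27
#>   residual RMS 3.59 uV over 13 energies
#> Oscillatory potentials (50-180 Hz, zero-phase): amplitude 186.2 uV, implicit time 42.00 ms
#> pSTR: amplitude 19.49 uV, implicit time 111.0 ms (mean over energies -5.31, -5.01, -4.90)
```

This animal's control eye has a saturated photoreceptor amplitude of
−682 µV reached with sensitivity 10^2.61 after a 2.9 ms delay, a bipolar
V<sub>max</sub> just above 1 mV with half-saturation near 5×10⁻⁴
cd·s/m², OP wavelets peaking at 42 ms, and a ~19 µV ganglion-cell pSTR
at 111 ms. The full study then runs end-to-end:

```r
an <- analyze_study(study)
an$report$comparisons |>
  filter(contrast == "OHT_treated_vs_control",
         endpoint %in% c("pstr_amplitude", "rnfl", "expr_Entpd1")) |>
  select(endpoint, statistic, df, p_value, pct_ratio_of_means)
#> # A tibble: 3 × 5
#>   endpoint       statistic    df p_value pct_ratio_of_means
#> 1 expr_Entpd1         4.17     5 0.00871               8.20
#> 2 pstr_amplitude     -3.49     5 0.0175              -12.5
#> 3 rnfl               -6.57     5 0.00123             -16.5
```

Even at n = 6 the simulated chronic-pressure phenotype — reduced
ganglion-cell function and RNFL thinning with Entpd1 upregulation — is
detected in the paired contrast; the group IOP plateau comes out at
19.7 vs 14.1 mmHg (+40%). `autoplot()` methods exist for P3 and
Naka-Rushton fits and for study reports; `plot_iop_course()` draws the
group tonometry profile; `tidy()`/`glance()` return fitted parameters
as tibbles.

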