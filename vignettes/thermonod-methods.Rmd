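---
title: "Thermal and phosphorus-limitation traits from plate-reader growth assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal and phosphorus-limitation traits from plate-reader growth assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermonod)
```

## The analysis in one paragraph

`thermonod` turns raw chlorophyll-a fluorescence time series from a crossed
temperature x phosphorus growth experiment on phytoplankton strains into
strain-level ecophysiological traits, and then asks whether those traits track
the environment of each strain's lake of origin. The chain is: per-well
exponential growth rates (segmented log-linear models selected by AICc, after
a detection-limit filter); thermal performance curves (TPCs) per strain and
phosphorus level, yielding the optimum temperature, the area under the TPC
(AUTPC) and Arrhenius activation energies; Monod curves per strain and
temperature, yielding the maximum growth rate, the half-saturation constant
and the minimal phosphorus requirement P*; penalized-spline summaries of how
each trait responds to the opposing gradient; growing-season lake summaries
from monitoring records; and finally a two-stage, inverse-variance weighted
test for temperature-dependent local adaptation of P* to source-lake
phosphorus.

## Growth rates from fluorescence series

Fluorescence (RFU) is a proxy for cell density, so the log of RFU grows
linearly in time during exponential growth. Readings below the operational
detection limit — half the median fluorescence of blank media, 2.25 RFU at
the default blank level — are discarded before the log is taken. Four
candidate mean structures are fitted to log-RFU versus time by exact least
squares: a single line; flat-then-line (lag); line-then-flat (saturation);
and flat-line-flat. Breakpoints are restricted to observed timepoints, the
growth segment always spans at least two points, and the boundary timepoints
are admitted as degenerate breakpoints so that every richer model nests the
plain line; an exhaustive scan over this discrete grid is exact and cheap for
the 11-point series the experimental design produces. Model choice uses the
small-sample corrected AICc in its Gaussian constant-dropped form,
$n \log(\mathrm{RSS}/n) + 2p + 2p(p+1)/(n-p-1)$, with $p$ counting intercept,
slope and breakpoints; exact ties go to the model with fewer parameters, and
the RSS is clamped at $10^{-300}$ before the log so that noiseless series
remain comparable (their AICc is then dominated by the common log term and
selection falls through to the parameter penalty). In every model the
reported rate $\mu$ is the slope of the line segment. Negative rates are
legitimate outputs (cultures can decline) and are passed downstream, where
each stage applies its own exclusion rules.

## Thermal performance curves

Growth rate as a function of temperature is modelled as an exponential
envelope times a downward quadratic,
$$R(T) = a\,e^{bT}\left(1 - \left(\frac{T - T_{\mathrm{ref}}}{w/2}\right)^2\right),$$
with structural zeros at $T_{\mathrm{ref}} \pm w/2$ (the thermal niche
limits, $w$ the niche width). The optimum has the closed form
$T_{\mathrm{opt}} = T_{\mathrm{ref}} + (\sqrt{1 + b^2 (w/2)^2} - 1)/b$,
reducing to $T_{\mathrm{ref}}$ as $b \to 0$. Fitting is least squares by
bounded Levenberg-Marquardt from many random starts drawn inside documented
bounds ($a \in (0, 10]$, $b \in [-1, 1]$, $T_{\mathrm{ref}} \in [0, 40]$,
$w \in (5, 80]$; 250 starts by default, fewer inside the pipeline where 48
curves are fitted per run), plus one fixed default start; the seed makes the
whole procedure reproducible, and the multi-start winner can never be worse
than the default start. AUTPC is the trapezoidal integral of the fitted
curve on a 0.1 degC grid over the experimental range (12-26 degC by
default); at that resolution refining the grid changes the value by less
than 0.1%.

Activation energies come from the Arrhenius view of the rising limb: positive
rates at temperatures up to the fitted $T_{\mathrm{opt}}$ (all positive rates
when the optimum lies above the warmest treatment; an `empirical_max` switch
uses the observed maximum instead) are regressed as $\ln \mu$ on $1/kT$ with
$T$ in Kelvin and $k = 8.62 \times 10^{-5}$ eV/K. We report
$E_a = -\text{slope}$, so growth that accelerates with temperature has
positive $E_a$, consistent with $R = A e^{-E_a/kT}$. Per strain, the
activation energies across phosphorus levels are summarised by mean, SD and
a two-sided one-sample t-test against 0.32 eV, the expectation derived from
the temperature sensitivity of Rubisco carboxylation in C3 photoautotrophs.

## Monod curves and minimal phosphorus requirements

Growth against phosphate concentration follows
$\mu(S) = \mu_{\max} S / (K_s + S)$. The minimal requirement is
$P^* = K_s m / (\mu_{\max} - m)$ with the mortality (loss) rate fixed at
$m = 0.1\,\mathrm{d^{-1}}$ (a configuration knob). Fitting mirrors the TPC
machinery: bounded multi-start Levenberg-Marquardt with
$\mu_{\max} \in (0, 5]$ and $K_s \in (10^{-4}, 100]$ and a data-driven
default start. Negative-rate observations are kept in the least squares by
default (the Monod form cannot go negative, so they penalize the low-S end);
a switch drops them. Flat substrate responses push $K_s$ to its lower bound
— the fit is then flagged and, like any fit with non-positive $P^*$ or
$\mu_{\max} \le m$, excluded from the $K_s$/$P^*$ trait analyses
($\mu_{\max}$ itself is retained). These exclusions are the synthetic
counterpart of real strains whose growth barely responds to the phosphate
gradient.

## Bootstrap intervals

Uncertainty for both curve families uses the nonparametric case bootstrap:
resample the observed (x, rate) pairs with replacement, refit starting from
the point estimate, and take 2.5/97.5 percentiles (1000 resamples is the
study-scale convention; tests use fewer). Resamples that lose too many
distinct levels to be fittable are skipped and counted. Resampling is
pooled rather than stratified by level: with only four replicates per
level, per-stratum resampling deflates the bootstrap variance by a factor
of $(r-1)/r = 3/4$ per stratum and produces intervals that are visibly too
narrow, whereas pooled resampling loses only $(n-1)/n$ overall. A
`stratify` argument restores the stratified variant for designs with many
replicates per level. Percentile intervals on 24-point nonlinear fits are
still slightly anti-conservative — the test suite measures their coverage
and requires it to sit in the 90-98% band around the nominal 95%.

## Trait responses and linearity

Whether a trait responds linearly or nonlinearly to the opposing gradient is
summarised by a penalized cubic regression spline (basis dimension k = 3,
Gaussian response, smoothness by REML, fitted with mgcv). The effective
degrees of freedom (EDF) of the smooth measure curvature: the penalty shrinks
a truly linear relationship to EDF near 1, while real curvature holds EDF
toward 2 (the maximum for this basis). The package labels EDF < 1.5 "linear"
and EDF >= 1.5 "nonlinear"; the cut is configurable and sits halfway between
the two regimes this basis can express. The smooth-term p-value is mgcv's
approximate Wald-type test and is reported as approximate; EDF values from
other spline bases can differ in the second decimal, which is why the label,
not the raw EDF, is the interface.

## Lake environment summaries

Growing-season conditions are the mean of August-October measurements at 5 m
depth (tolerance 1 m; records with missing depth are treated as
depth-integrated samples and flagged), averaged first within and then across
the years 2018-2022 so unevenly sampled years carry equal weight. Lakes with
sparse temperature monitoring (fewer than 15 in-window records by default)
are densified with a seasonal regression — temperature on calendar year plus
one annual harmonic — and the growing-season mean is then taken over six
model predictions evenly spaced from 1 August to 31 October of each year,
two choices (single harmonic; inclusive endpoints) the package fixes because
the convention is not otherwise determined. Phosphorus is never modelled:
it lacks the strong seasonal cycle that justifies the harmonic, so only
direct means are used, and a lake with no usable chemistry is dropped from
the trait-environment stage with a warning.

## The two-stage local-adaptation test

Stage 1: at each experimental temperature, ordinary least squares of a
strain trait (canonically P*) on a lake environmental variable (canonically
growing-season total phosphorus) across strains, keeping slope, SE, p and n;
temperatures with fewer than three complete strain pairs are flagged
untestable. Stage 2: weighted least squares of those slopes on experimental
temperature with weights $1/\mathrm{SE}^2$, so imprecise stage-1 slopes
(e.g., from cold treatments where P* is hardest to estimate) carry little
influence. A positive stage-2 trend means the trait-environment association
steepens with assay temperature — the signature of temperature-dependent
local adaptation. The machinery is generic over any trait/environment pair;
no multiple-testing correction and no multi-predictor adjustment are
applied, matching the single-predictor design it serves.

## The synthetic-data generator

The generator exists so every stage above is testable end to end with known
ground truth. It emulates the study design: 8 strains (one per lake), six
temperatures {12, 16, 20, 22, 24, 26} degC crossed with six phosphate levels
{1.94, 3.87, 7.75, 15.50, 31.00, 47.47} umol/L (the molar equivalents of
60-1470 ug/L PO4-P), four replicate wells per treatment, inoculation at 10
RFU, and 11 readings over 6 days (twice daily for four days, then daily).
Each strain's truth holds TPC parameters, a half-saturation constant that
rises quadratically away from a strain-specific coolest-K temperature
($K_s(T) = K_{s,0} + c\,(T - T_{\min})^2$, giving the expected U-shaped
P*(T)), a mean lag, and its lake's total phosphorus. The true rate surface
is $R(T, S) = \mu_{\max}(T)\, S / (K_s(T) + S)$.

Latent well trajectories are flat for an exponentially distributed lag, then
exponential at $R(T, S)$ (optionally logistic under a finite carrying-cap
flag); observed RFU multiply the latent value by mean-one lognormal noise.
The noise CV defaults to 0.1 — a free choice, since within-replicate noise
magnitude is not reported for the emulated study; 10% is a realistic figure
for plate-reader fluorescence at these densities. Multiplicative lognormal
noise was chosen over additive Gaussian because fluorescence error scales
with signal and positivity is preserved. Blank media are lognormal around
twice the detection floor, so the half-median rule recovers the floor.

Local adaptation is planted by making the $K_s$ temperature-sensitivity
coefficient a deterministic increasing function of source-lake phosphorus,
$c_i = 0.001 + s \cdot 4\times 10^{-4}\, P_{\mathrm{lake},i}$, scaled by the
`adaptation_strength` $s$; at $s = 0$ all strains share one sensitivity and
the stage-2 trend is null by construction. The coefficient was calibrated
once, at design time, so that the default study (strength 1) reproduces a
clearly significant positive stage-2 trend of the strength the emulated
study reports; individual truth draws still vary widely in significance, as
small-n lake samples do. Lake monitoring records come from the same
linear-trend-plus-harmonic model the summariser assumes, with a configurable
fraction of lakes sampled only quarterly to exercise the seasonal-model
path.

What the generator does not emulate: nutrient depletion within wells (the
latent rate is constant in time, so there is no Droop-style quota dynamics
and no growth slowdown at low phosphorus late in the assay), multi-species
interactions, plate position effects, or measurement dropout. Passing tests
therefore demonstrate correctness of the estimation chain under the stated
generative model, not robustness to every failure mode of real plate data.

## Numerical choices and degenerate inputs

* Per-stage seeds are derived from one master seed by fixed offsets, so any
  stage can be re-run alone and reproduce its outputs bit for bit.
* Multi-start optima never lose to the documented default start; refits
  inside bootstraps start from the point estimate.
* The AICc RSS clamp ($10^{-300}$) only matters for exactly interpolated
  series, where the parameter penalty then decides selection; the AICc of
  such a fit is finite but enormous in magnitude, and on truly noiseless
  input the simplest adequate model wins.
* Series shorter than three usable points are excluded per well and counted;
  models are only fitted when at least one more point than free parameters
  is available, and AICc comparison additionally requires $n > p + 1$.
* Seasonal models refuse records clustered on a single day of year (the
  harmonic would be collinear with the intercept) and require at least 8
  records spanning two calendar years.
* All CSV interfaces are plain long-format tables; nested outputs (bootstrap
  bands, manifests, trends) are JSON.

## Known limitations

* A continuous lag rarely coincides with an observed timepoint, so the
  discrete-breakpoint lag model absorbs part of the early rise into the flat
  segment and underestimates the growth rate slightly (well under a percent
  of the rate at the default design). The bias vanishes for lag-free wells
  and is negligible for trait contrasts, but it is visible to bootstrap
  coverage of sharply estimated parameters, which is why interval
  calibration is assessed on lag-free simulations.
* $K_s$ is poorly identified when it falls below the lowest substrate level;
  the fit then leans on one or two informative levels and its relative error
  grows accordingly. This mirrors the real design constraint rather than an
  estimator defect.
* Percentile bootstrap intervals on 24-point nonlinear fits run slightly
  narrow even with pooled resampling; users needing strict nominal coverage
  at this sample size should treat the intervals as approximate.
* The EDF linearity label inherits mgcv's basis and REML choices; other
  penalized-spline implementations can differ in the second decimal of EDF.

## Problem sizes used by the test suite

The suite verifies oracle equivalences on 5-11-point series, parameter
recovery and bootstrap coverage over 200 simulated experiments per check,
and end-to-end signal detection over 200 replicate studies each for planted
and null adaptation — sizes chosen to keep Monte-Carlo error on the checked
proportions near one percentage point while the whole suite stays
comfortably runnable on a laptop.
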