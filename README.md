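# thermonod

Strain-level thermal and phosphorus-limitation growth traits for
phytoplankton, from raw plate-reader fluorescence to a two-stage test of
temperature-dependent local adaptation.

## The problem

Lakes are warming while nutrient loading changes, and phytoplankton
populations experience both gradients at once. Strains of one species
isolated from different lakes may be locally adapted: their
temperature-dependent phosphorus requirements may track the nutrient status
of their home lake. Testing that hypothesis from a crossed temperature x
phosphorus growth experiment requires a long chain of estimation steps, each
with its own filtering and exclusion rules. `thermonod` implements the whole
chain as composable, seeded, tested R functions — for experimentalists
running factorial plate-reader assays on algal or microbial strains, and for
methodologists who want a ground-truth generator to probe the chain's power
and calibration.

## What it computes

- **Per-well growth rates**: fluorescence readings below the detection limit
  (half the median blank, 2.25 RFU by convention) are discarded; four
  segmented log-linear models (line, lag, saturation, lag + saturation) are
  fitted by exact least squares over a discrete breakpoint grid and selected
  by AICc; the growth rate `mu` is always the slope of the line segment.
- **Thermal performance curves**: `R(T) = a e^{bT} (1 - ((T - T_ref)/(w/2))^2)`,
  fitted by seeded multi-start bounded least squares; derived `T_opt`
  (closed form), trapezoidal area under the curve (AUTPC), and bootstrap
  bands.
- **Activation energies**: OLS of `ln mu` on `1/kT` over the rising limb,
  `E_a = -slope` (eV), with per-strain one-sample t-tests against the
  0.32 eV Rubisco-based expectation.
- **Monod curves and P\***: `mu(S) = mu_max S / (K_s + S)`, and the minimal
  requirement `P* = K_s m / (mu_max - m)` at mortality `m = 0.1/d`;
  negative or boundary-degenerate `K_s`/`P*` are flagged and excluded from
  trait analyses.
- **Trait-response smooths**: penalized cubic splines (k = 3, REML, via
  mgcv) classify each trait-gradient response as linear (EDF < 1.5) or
  nonlinear.
- **Lake summaries**: August-October means at 5 m depth across 2018-2022,
  with a year + annual-harmonic regression to densify sparsely monitored
  lakes.
- **Local adaptation**: per-temperature OLS of P\* on lake phosphorus across
  strains, then a `1/SE^2`-weighted regression of those slopes on
  experimental temperature; a positive trend means phosphorus requirements
  of strains from P-rich lakes rise faster with warming.
- **Synthetic data**: `make_truth()` / `simulate_study()` generate the full
  factorial experiment (8 strains x 6 T x 6 P x 4 replicates, 11 readings
  over 6 days) with known ground truth and a tunable planted adaptation
  signal, plus blank media and lake monitoring records.

## Worked example

Simulate the default study with a planted adaptation signal and run the full
pipeline:

```r
library(thermonod)

sim <- simulate_study(n_strains = 8, adaptation_strength = 1, seed = 11)
res <- run_pipeline(sim$series, sim$blanks, sim$lake_records, sim$strain_lake,
                    config = pipeline_config(seed = 11))
print(res)
#> <trait_pipeline> 1152 wells read, 0 excluded (< 3 points above 2.26 RFU)
#>   TPC fits: 48 (0 non-estimable)
#>   Monod fits: 48 (1 excluded from P*/K_s analyses)
#>   local adaptation: <slope_trend> 0.001274 per degC (SE 0.000482), p = 0.0575, n = 6
```

1152 wells is the full factorial (8 strains x 36 treatments x 4 replicates).
One of the 48 Monod fits hit the `K_s` boundary (a flat substrate response)
and was excluded from the P\*/K_s analyses, the same rule applied to real
strains whose growth barely responds to phosphate. The stage-1 slopes of P\*
on lake phosphorus steepen with assay temperature:

```r
res$adaptation$slopes
#>  temperature   slope      se p_value n_strains testable
#>           12 0.00415 0.00896  0.6628         7     TRUE
#>           16 0.00392 0.00523  0.4824         8     TRUE
#>           20 0.00629 0.00314  0.0923         8     TRUE
#>           22 0.01401 0.00800  0.1305         8     TRUE
#>           24 0.01787 0.00735  0.0510         8     TRUE
#>           26 0.02435 0.01468  0.1483         8     TRUE
```

The weighted stage-2 trend (0.0013 per degC here) is the headline quantity:
P\* rises with lake phosphorus, and that association is about six times
steeper at 26 degC than at 12 degC. Individual fits are ordinary S3 objects:

```r
g <- res$growth
rates <- data.frame(
  phosphorus = g$phosphorus_umol_L[g$strain == "strain_03" & g$temperature_C == 22],
  mu         = g$mu_per_day[g$strain == "strain_03" & g$temperature_C == 22])
fit_monod(rates, seed = 1)
#> <monod_fit> mu_max = 0.267 /day, K_s = 0.966 umol/L, P* = 0.5768 umol/L (m = 0.1)
#>   rss = 0.00931, valid
```

`print`, `coef`, `predict`, `plot` and (where meaningful) `residuals`
methods exist for growth, TPC, Monod, smooth, seasonal and trend objects.

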