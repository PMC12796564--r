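# fetterp

Quantitative terpene profiling of cannabis flowers by headspace **full
evaporation technique (FET) GC-MS**, for forensic and analytical
laboratories that need validated, guideline-style terpene quantification
and for developers of FET methods who need the accompanying statistics.

In FET, a few milligrams of ground flower are heated in a sealed
headspace vial until the volatiles evaporate completely, so the method is
calibrated to the absolute amount of analyte in the vial (µg); flower
content is the derived view `content [µg/g] = amount / (weight[mg]/1000)`.
Quantification uses the ratio of each analyte's SIM target-ion area to
the area of its assigned internal-standard n-alkane from a co-spiked
C10–C17 retention-index ladder, which simultaneously anchors van den
Dool–Kratz retention indices
`RI = 100·(n + (rt − rt_n)/(rt_{n+1} − rt_n))` for identification.

The package provides:

- the packaged 45-terpene panel (16 monoterpenes, 16 monoterpenoids, 7
  sesquiterpenes, 6 sesquiterpenoids) with SIM masses, isomer fractions,
  reference retention times, ISTD assignments and published validation
  figures, plus the 11-level calibration design (0.050–10.0 µg ≙
  10–2000 µg/g at 5 mg);
- experimental verification of full evaporation: thermostatting
  temperature/time scans with ±30% bands and plateau detection,
  sample-size linearity with a saturation probe, and multiple headspace
  extraction (MHE) log-depletion fits with sample-vs-standard slope
  comparison (`q̂ = 1 − exp(slope)`);
- unweighted linear calibration with Cochran variance-homogeneity and
  Mandel linearity tests at 99% significance, automatic entire /
  restricted / split / split-restricted range selection, and inverse
  prediction with range and transition-zone flags;
- DIN 32645 analytical limits (calibration-curve method, iterated LOQ),
  GTFCh-style bias and intra-/inter-day ANOVA precision, and
  spike-recovery checks;
- ISTD-normalised quantification with re-weigh verification of
  above-range values and strain-profile summaries (class sums, wt-%
  totals, >100 µg/g radar subsets);
- a synthetic peak-table generator emulating FET physics (evaporation
  kinetics, thermal degradation above a class onset, flower matrix
  suppression of high-boiling alkanes, geometric MHE depletion, detector
  saturation, lognormal noise), so the entire pipeline is testable
  without instrument data.

## Worked example

```r
library(fetterp)

panel <- load_panel()
panel
#> Terpene panel: 45 analytes; 8 alkane ISTDs (C10-C17)
#>     monoterpene   monoterpenoid   sesquiterpene sesquiterpenoid
#>              16              16               7               6

# calibrate every analyte from a simulated triplicate 11-level series
cfg <- synthetic_config(panel)
cal <- simulate_calibration(cfg, panel, n_rep = 3, seed = 11)
models <- calibrate_panel(cal$peaks, cal$amounts, panel)
table(vapply(models, function(m) m$kind, character(1)))
#> entire restricted
#>     40          5

# verify full evaporation by multiple headspace extraction
mhe <- simulate_mhe(NULL, 5, cfg, seed = 12)
d <- mhe[mhe$analyte == "eucalyptol", ]
f <- mhe_fit(d$area_target[order(d$injection_index)])
round(c(slope = f$slope, q_hat = f$q_hat, r_squared = f$r_squared), 4)
#>     slope     q_hat r_squared
#>   -0.3507    0.2958    0.9992

# quantify a flower sample and summarise its profile
fl <- simulate_flower_samples(cfg, panel, seed = 13)
q <- quantify_sample(fl$peaks, models, panel)
head(q[order(-q$content), c("analyte", "amount_ug", "content", "below_loq")], 5)
#>               analyte amount_ug   content below_loq
#> 4        beta-myrcene  9.188828 1817.8691     FALSE
#> 11           limonene  8.333803 1648.7155     FALSE
#> 35 beta-caryophyllene  8.119500 1606.3189     FALSE
#> 1        alpha-pinene  6.346994 1255.6557     FALSE
#> 17        terpinolene  4.576147  905.3208     FALSE

prof <- build_profiles(q, panel)
round(prof$total_wt_percent, 3)
#> sample1
#>   1.043

retention_index(24.5, panel$alkanes)   # limonene, between C10 and C11
#>     rt lower_carbon upper_carbon retention_index extrapolated
#> 1 24.5           10           11        1045.833        FALSE
```

Reading: five calibration ranges were restricted because the measured
top-level scatter made the Mandel test reject the full span; the MHE
slope of −0.351 corresponds to a per-injection extraction fraction of
about 0.30 with an essentially perfect log-linear depletion (r² = 0.999),
confirming full evaporation; the simulated strain carries about 1.0 wt-%
total terpenes dominated by β-myrcene, limonene and β-caryophyllene, with
contents in µg/g flower.

`run_pipeline(run_config(seed = 1))` executes the stages end to end
(calibration, analytical limits, quantification, profiles) and writes CSV
artifacts plus a JSON summary carrying the seed.

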