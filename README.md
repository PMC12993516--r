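# rsil — reverse stable isotope labelling analysis of oil-mineralization microcosms

`rsil` quantifies anaerobic mineralization of complex substrates — typified
by a drop of crude light oil incubated with anoxic formation water and
sulfate — from time series of δ¹³C measurements of the dissolved inorganic
carbon (DIC). It is aimed at environmental microbiologists and
biogeochemists running sealed-microcosm incubations where the rates are far
too small for total-CO₂ or pressure measurements to resolve.

## The method

In **reverse stable isotope labelling (RSIL)** the bicarbonate buffer is
enriched to ~10 atom% ¹³C. Respiration of substrate carbon at natural ¹³C
abundance releases CO₂ that *dilutes* the label, so the δ¹³C of the DIC
declines as mineralization proceeds. Two exact pieces of arithmetic convert
each reading into produced CO₂:

1. **δ¹³C → atom fraction.** With R′ = (δ/1000 + 1)·R_VPDB
   (R_VPDB = 0.0111802),

   x(¹³C) = R′ / (1 + R′),  atom percent A = 100·x.

2. **Two-pool mixing inversion.** A buffer of T mM DIC at A_b atom%
   mixed with P mM of substrate-derived CO₂ at A_s atom% has
   A = (T·A_b + P·A_s)/(T + P); solving for P,

   P = T·(A_b − A)/(A − A_s).

Rates are estimated per replicate by endpoint differences (or OLS),
averaged within treatment groups, converted from mM/yr to mmol/yr via the
aqueous volume, and normalized per gram of oil, per mol of CH₂ units
(M = 14.0266 g/mol) or per m² of oil–water contact (OWC) area. An electron
balance compares donor electrons (6 e⁻ per CH₂ carbon oxidised to CO₂) with
acceptor electrons (8 e⁻ per SO₄²⁻ reduced to sulfide); the shortfall is
attributed to biomass synthesis. A synthetic-microcosm generator with known
ground truth makes the whole chain testable end to end.

## Worked example

Simulate a six-bottle experiment (four live, two autoclaved controls,
sampled on days 0/30/60/91/122/857) and analyse it:

```r
library(rsil)
sim <- simulate_microcosms(simulation_params(seed = 1))
rep <- run_analysis(sim$measurements)
print(rep)
#> RSIL analysis report (rsil 0.1.0)
#>   pooled live, days 0-857 [endpoint, per_microcosm_mM]: 3.402 mM/yr
#>   pooled live, days 0-122 [endpoint, per_microcosm_mM]: 16.94 mM/yr
#>   pooled live, days 0-857 [endpoint, per_microcosm_mmol]: 0.3402 mmol/yr
#>   pooled live, days 0-857 [endpoint, per_g_oil]: 1.031 mmol/g/yr
#>   pooled live, days 0-857 [endpoint, per_mol_ch2]: 14.46 mmol/molCH2/yr
#>   pooled live, days 0-857 [endpoint, per_owc_area]: 2.873 gCH2/m2/yr
#>   electron fraction to sulfate: 0.880, to biomass: 0.120
#>   oil consumed: 11.2 mg
#>   flags: 3
```

The pooled early-phase rate (16.94 mM/yr here) scatters around the
configured 17.6 mM/yr because each replicate draws a rate multiplier
(CV 10%) and every δ¹³C reading carries 0.5 ‰ Gaussian noise; the electron
split recovers the configured 12% biomass sink because the simulator
couples sulfate to CO₂ stoichiometrically. The three flags are noise-driven
negative produced-CO₂ points, which are reported, never clipped.

The same pipeline runs from the shell:

```sh
Rscript inst/scripts/rsil simulate --seed 1 --out microcosms.csv --truth-out truth.json
Rscript inst/scripts/rsil analyze --input microcosms.csv --out report.json \
    --rates-out rates.csv --flags-out flags.csv
Rscript inst/scripts/rsil report --input report.json
```

Endpoint summaries can also be pushed through the whole headline chain in
one call:

```r
str(transparent_chain(8.31, 857, 20.6, 15.2), digits.d = 4)
#> $ cum_co2_mM                  : num 8.31
#> $ total_co2_mmol              : num 0.831
#> $ overall_rate_mmol_yr        : num 0.3539
#> $ rate_per_g_oil_mmol_g_yr    : num 1.073
#> $ rate_per_mol_ch2_mmol_mol_yr: num 15.04
#> $ rate_per_owc_g_m2_yr        : num 2.989
#> $ oil_consumed_mg             : num 11.66
#> $ sulfate_reduced_mmol        : num 0.54
#> $ sulfate_rate_mmol_yr        : num 0.23
#> $ fraction_to_sulfate         : num 0.8664
#> $ fraction_to_biomass         : num 0.1336
```

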