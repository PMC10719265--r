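# n2otracer

Rate inference for coastal-ocean nitrogen cycling studies that use 15N
tracer incubations. Eutrophied, turbid estuaries are among the strongest
marine sources of N2O, and disentangling *which* microbial pathway produces
it — aerobic ammonia oxidation or the reductive nitrite/nitrate pathway
(partial denitrification) — requires parallel labelling experiments, careful
isotopologue bookkeeping, and a chain of derived statistics. This package
implements that chain as tested, reusable functions, for biogeochemists who
have time-course concentration tables and want rates, fluxes and source
attributions with propagated uncertainty.

## What it computes

**Gross transformation rates.** For a pool amended to 15N atom fraction
`F = [15N]/([14N]+[15N])`, the gross rate is the OLS slope of the 15N
product time course divided by F (ammonia oxidation, nitrite oxidation,
nitrate reduction), with replicate bottles pooled so triplicate scatter
informs the standard error, and a p >= 0.05 detection rule.

**N2O production with isotopologue accounting.** Under single-pool binomial
pairing the 44/45/46 N2O shares are `(1-F)^2, 2F(1-F), F^2`; the
unmeasurable mass-44 rate is inferred as `R44 = R46 ((1-F)/F)^2` and the
gross rate is `R45 + R46 + R44` (doubled into nmol N L-1 d-1). A
`binomial_consistency` diagnostic flags violations of the single-pool
assumption.

**Air-sea flux.** Equilibrium N2O from the Weiss & Price (1980) moist-air
solubility, Schmidt number from the Wanninkhof (2014) polynomials (with
freshwater-seawater interpolation for estuarine salinities), transfer
velocity `k = 0.251 u^2 (Sc/660)^-0.5`, flux `F = k (C_obs - C_eq)` in
umol m-2 d-1. Plus DO unit conversion and the 62.5 umol L-1 hypoxia flag.

**Partitioning statistics.** N2O yields per NO2- produced, oxidative vs.
reductive source fractions with delta-method (or Monte-Carlo) errors,
PN-normalized size-spectrum rates, nir:amoA gene ratios, a Pearson
significance screen, Student's t comparisons, and depth-integrated
production-to-flux ratios.

**Synthetic ground truth.** `scenario()` / `simulate_incubation()` generate
the full six-experiment incubation set (plus station/profile tables) with
known rates, binomial or hybrid isotopologue structure, and seeded Gaussian
noise, so the whole pipeline is testable end to end without field data.

## Worked example

```r
library(n2otracer)
sc <- scenario(seed = 7L)              # stated-world defaults, 5% noise
series <- simulate_incubation(sc)

transformation_rate(series$AO)
#> <rate_estimate> AO: 974.9 +/- 41.98 nmol N L-1 d-1 (p = 6.96e-08)

out <- n2o_production_rate(series$`N2O-NO3`)
out$rate
#> <rate_estimate> N2O-NO3: 2.053 +/- 0.06593 nmol N L-1 d-1 (p = 2.69e-09)
out$iso
#> <isotopologue_rates> r44 0.7729 (inferred), r45 0.2331, r46 0.02048 | total 1.026 nmol N2O L-1 d-1 = 2.053 nmol N L-1 d-1
round(out$consistency, 3)
#> 0.926
```

The AO truth is 1000 and the N2O-NO3 truth is 2.0 nmol N L-1 d-1: both are
recovered within their standard errors, and the consistency diagnostic sits
near 1 because the generator used single-pool pairing. Combining pathways
and hydrography:

```r
tb <- station_rate_table(list(
  transformation_rate(series$AO), transformation_rate(series$NR),
  n2o_production_rate(series$`N2O-NH4`), n2o_production_rate(series$`N2O-NO2`),
  n2o_production_rate(series$`N2O-NO3`)))
fc <- fractional_contributions(tb)
sprintf("f_red = %.2f +/- %.2f", fc$f_red, fc$sd_f_red)
#> "f_red = 0.75 +/- 0.01"   # reductive pathways dominate, as configured

air_sea_flux(surface_record(25, 30, c_obs = 45, x_air = 332, wind_u10 = 6))
#> <flux_result> c_eq 6.83 nmol L-1, saturation 659.0%, Sc 538, k 10 cm h-1, flux 91.7 umol m-2 d-1
```

A supersaturated estuarine surface (45 vs. 6.8 nmol L-1 at equilibrium)
outgasses ~92 umol N2O m-2 d-1 at 6 m s-1 wind.

## Command line

```sh
Rscript -e 'n2otracer::n2o_cli()' simulate  --seed 5 --out-dir run/
Rscript -e 'n2otracer::n2o_cli()' rates     --incubation run/incubation.csv --out run/rates.csv
Rscript -e 'n2otracer::n2o_cli()' flux      --stations run/stations.csv --out run/flux.csv
Rscript -e 'n2otracer::n2o_cli()' partition --rates run/rates.csv --flux run/flux.csv --profile run/profile.csv --out run/partition.csv
Rscript -e 'n2otracer::n2o_cli()' report    --run-dir run/
```

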