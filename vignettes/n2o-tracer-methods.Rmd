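---
title: "Methods: rate inference from 15N tracer incubations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rate inference from 15N tracer incubations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2otracer)
```

## The model

Gross N transformation rates in `n2otracer` come from the standard
slope-based 15N tracer formalism. A substrate pool (NH4+, NO2- or NO3-) is
amended with 15N tracer so that its atom fraction becomes

F = [15N] / ([14N] + [15N]),

and the product pool's 15N concentration is measured over a short time
course. Because only a fraction F of the substrate consumed is labelled, the
gross rate is the product accumulation slope divided by F:

R = (d[15N-product]/dt) / F.

This yields ammonia oxidation (15NH4+ -> 15NO2-), nitrite oxidation
(15NO2- -> 15NO3-) and nitrate reduction (15NO3- -> 15NO2-). The slope is an
ordinary least-squares fit pooling all replicate bottles as independent
points, so triplicate scatter informs the slope standard error; hours are
converted to days by the exact factor 24.

### N2O isotopologue accounting

N2O production is traced through the labelled isotopologue masses. If N2O
molecules assemble two N atoms drawn independently from a single pool with
atom fraction F, the isotopologue shares are binomial:

p44 = (1 - F)^2, p45 = 2 F (1 - F), p46 = F^2.

The 45N2O and 46N2O accumulation slopes are measured; the mass-44 rate is
invisible against the ambient N2O background and is inferred from mass 46:

R44 = R46 x ((1 - F) / F)^2,

which is algebraically identical to the squared 14N/15N concentration ratio
(we compute through F because it makes the domain constraints explicit:
F must lie strictly in (0, 1), so a pure-tracer pool is rejected rather than
silently producing zero). The gross rate is the sum R45 + R46 + R44 in
molecule units; the reported value doubles it into nmol N L-1 d-1, the
convention used for field rates. Both numbers are retained on the
`isotopologue_rates` object because the literature is not consistent about
which unit the summation is quoted in.

Uncertainty is propagated to first order:
se_mol^2 = se45^2 + (1 + ((1-F)/F)^2)^2 se46^2, doubled into N units.

### Detection and degenerate designs

A slope with two-sided p >= alpha (default 0.05) is below detection: the
rate is reported as 0 with its standard error retained, so downstream error
propagation still works. A *significant* negative slope is reported as
negative with a consumption warning rather than zeroed — hiding it would
mask real net consumption. When mass 46 is below detection but mass 45 is
not, the primary estimate keeps only the measured channels and an
alternative `r45 / p45` scaling is reported alongside, flagged; neither is
silently preferred. Two-point exact designs return the exact slope with
`NA` uncertainty (a saturated fit has no residual degrees of freedom).

## Gas exchange

Surface saturation and air-sea flux use:

- solubility: the Weiss & Price (1980) moist-air solubility function for
  N2O, evaluated at (T, S) and multiplied by the atmospheric dry mole
  fraction (ppb) and total pressure (atm), giving nmol L-1 directly.
  Evaluation outside the published fit range (0-40 degC, S 0-40) is an
  error, never a silent extrapolation.
- Schmidt number: the Wanninkhof (2014) fourth-order polynomials for N2O;
  since estuarine salinities span 0-35, Sc is linearly interpolated between
  the freshwater and seawater polynomials in S (the endpoints reproduce the
  published polynomials exactly).
- transfer velocity: k = 0.251 u^2 (Sc/660)^-0.5 in cm h-1, the quadratic
  wind-speed power law. Alternative k parameterizations are out of scope.
- flux: F = k (C_obs - C_eq), converted with the exact factor 0.24 from
  cm h-1 x nmol L-1 to umol m-2 d-1. Positive flux is outgassing.

The atmospheric N2O mole fraction is a per-campaign configuration value
(e.g. the monthly Mauna Loa mean); the package never fetches it.

Dissolved oxygen in mg L-1 converts to umol L-1 with a molar mass of exactly
32.00 g mol-1, so the conventional 2 mg L-1 hypoxia threshold is exactly
62.5 umol L-1. Using 31.998 would shift the boundary by 0.006%, less than
any DO sensor precision, but would break the threshold equality that the
hypoxia convention is defined by.

## Derived statistics

- **N2O yield**: N2O-N produced per NO2--N produced by the paired pathway
  (ammonia oxidation or nitrate reduction), in percent. Undefined (missing,
  never zero) when the denominator rate is non-positive or below detection.
- **Source partitioning**: f_AO = R(N2O-NH4) / total and f_red = 1 - f_AO
  with total the sum of the three pathway rates. Standard deviations use the
  delta method under independence — the three rates come from separate
  bottles, and reported propagated errors in this literature state no
  covariance — with a Monte-Carlo mode (`method = "mc"`) kept for
  validating the linearization.
- **Depth integration**: trapezoidal, with the shallowest rate extended
  unchanged to 0 m and the deepest to a configured bottom depth. Field
  profiles have 1-3 depths, so any scheme is a convention; the trapezoid
  with end-member extension is the least-structured choice and is exact for
  linear profiles.
- **Correlation screen**: pairwise-complete Pearson r with two-sided
  p-values, masked at p >= 0.05 with no multiplicity correction — matching
  the screening convention the study states. A Benjamini-Hochberg option
  exists but is off by default.
- **t-tests**: classical pooled-variance Student's t, two-sided, 0.05.

## The synthetic generator

`scenario()` states one eutrophied upstream station: tracer additions of
5 / 5 / 20 umol L-1 onto ambient pools sized to tracer shares of
0.38 / 0.31 / 0.14 (the campaign means), timepoints 0/6/12 h in triplicate,
transformation rates AO 1000, NO 400, NR 900 nmol N L-1 d-1 and N2O pathway
rates 0.9 / 0.5 / 2.0 nmol N L-1 d-1. Those defaults put the N2O yields at
the reported medians (about 0.09% for ammonia oxidation and 0.22% for
nitrate reduction) and the reductive share of N2O production near 74%, i.e.
a station where partial denitrification dominates the N2O source — the
study's central regime.

Products accumulate linearly (zero-order kinetics), consistent with the
slope-based inference; substrate depletion over 12 h is < 2% at these rates
and pools, so no depletion mode is simulated. Noise is Gaussian and
homoskedastic within a series: sd = rel x (full-scale true signal) + floor.
"Relative" noise is anchored to the series amplitude rather than to each
measurement because the inference model is *unweighted* OLS; per-measurement
proportional noise would call for weighted regression the field does not
use. Default rel = 0.05 spans the stated instrument precisions (about 3%
for N2O, 1-3% for nutrients); floors default to 0 and can be set per
analyte class in concentration units. Negative simulated concentrations are
truncated at zero and counted in the `truncated` attribute so recovery
tests can exclude censored draws.

What a green recovery test does **not** establish: robustness to isotope
dilution, NO2- re-oxidation cascades, bottle effects, or non-linear time
courses — none of which the generator emulates.

## Hybrid pairing and the limits of the isotopologue sum

`hybrid_fraction` h sends a fraction of N2O molecules through hybrid
formation: one atom from the labelled pool (probability F of being 15N) and
one from an unlabelled pool. The expected measured shares become

r45/mol = (1-h) 2F(1-F) + hF,  r46/mol = (1-h) F^2,

and the summed estimate R45 + R46 + R44(inferred) recovers exactly
((1-h) + hF) of the true molecule rate: the relative error is h(1-F).
At h = 0.5 and F = 0.38 the estimate captures 69% of the truth, and even
against the weaker target of substrate-derived N (2-h atoms per molecule)
the deficit is 8%. A 5% accuracy claim under h = 0.5 therefore cannot hold
for any F below 0.43 (or 0.9, depending on the truth convention); it holds
only for h <= 0.05/(1-F), about 0.08 at the default enrichment. The
corresponding acceptance test is deliberately left failing at its stated
tolerance rather than weakened. What *is* true, and what the
`binomial_consistency` diagnostic delivers, is that the violation is
detectable: at h = 0.5 the observed-to-expected 45/46 ratio is 1.8, far
from 1. The diagnostic is reported and never used to adjust rates, because
correcting would require knowing the second pool's enrichment.

## Other decisions

- Time courses are fitted on pooled replicates, not per-timepoint means;
  with equal replication the slope is identical and the residual degrees of
  freedom are larger. The source protocol does not state its choice.
- The atom fraction is computed from the t0 pools and held constant; tracer
  consumption over these short incubations is small (the linearity of the
  observed time courses is the operational check). A numeric F override is
  accepted anywhere a pool is, for sensitivity analyses.
- CSV dialects are plain UTF-8 with a header row and '.' decimal; the
  deposited field spreadsheets must be mapped to these columns by the user
  (column naming in deposits varies; the mapping is deliberately not
  guessed).

## Known limitations

No site-preference / natural-abundance source attribution, no two-pool
hybrid partitioning, no compartment model of isotope dilution, no
bubble-mediated or skin-corrected gas flux, no sedimentary production
modelling. Size-fraction summaries consume gene copy tables as given; qPCR
efficiency and standards are upstream of this package.
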