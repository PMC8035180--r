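---
title: "Reconstructing atmospheric pCO2 from C3-plant carbon isotope fractionation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing atmospheric pCO2 from C3-plant carbon isotope fractionation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c3pco2)
```

## The proxy

Photosynthetic carbon isotope fractionation in C3 plants,
$\Delta^{13}\mathrm{C} = (\delta^{13}\mathrm{C}_{CO_2} -
\delta^{13}\mathrm{C}_p)/(1 + \delta^{13}\mathrm{C}_p/1000)$, increases with
atmospheric CO2 following a hyperbola

$$\Delta^{13}\mathrm{C} = \frac{A\,B\,(p\mathrm{CO}_2 + C)}
{A + B\,(p\mathrm{CO}_2 + C)},$$

where $A$ (per mil) is the saturation value, $B$ the curvature, and
$C = A \times 4.4 / ((A - 4.4)\,B)$ is pinned so that the fractionation at
$p\mathrm{CO}_2 = 0$ equals 4.4 per mil. Because absolute plant
$\delta^{13}$C values carry section- and preservation-specific offsets, the
package inverts the *change* in fractionation relative to a pre-excursion
reference time,
$\Delta(\Delta^{13}\mathrm{C}) = \Delta^{13}\mathrm{C}(t) -
\Delta^{13}\mathrm{C}(t{=}0)$, for which the hyperbola has a closed-form
inverse (`invert_pco2()`). The inversion is exact: the round trip through
`frac_forward()` recovers pCO2 to better than $10^{-9}$ relative error over
1--100,000 ppmv, verified in the test suite against an independent
root-finding oracle.

The atmospheric $\delta^{13}\mathrm{C}_{CO_2}$ needed by the fractionation
definition is not observed directly. It is derived from marine carbonate:
$\delta^{13}\mathrm{C}_{DIC} = \delta^{13}\mathrm{C}_{carb} - 1$ per mil
(temperature-independent carbonate--DIC fractionation), then a
temperature-dependent DIC--CO2 fractionation using sea surface temperature,

$$\delta^{13}\mathrm{C}_{CO_2} = \delta^{13}\mathrm{C}_{DIC} -
\bigl(0.91\,(-0.1141\,T + 10.78) + 0.08\,(-0.052\,T + 7.22)\bigr),$$

an offset of 10.39 per mil at 0 °C shrinking by 0.108 per mil per degree.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| $A$ | 28.26 ± 0 | per mil | saturation fractionation |
| $B$ | 0.22 ± 0.028 | -- | hyperbola curvature |
| $C$ | derived | ppmv | anchors $\Delta^{13}$C(0) = 4.4 per mil |
| $p\mathrm{CO}_2(t{=}0)$ | 425 ± 68 | ppmv | pre-excursion level (stomatal estimates) |
| $\delta^{13}\mathrm{C}_p(t{=}0)$ | -24.42 ± 0.5 | per mil | pre-excursion plant baseline |

Uncertainties are treated as 1-sigma throughout; the quoted baseline
uncertainty is not explicitly labelled 1-sigma in its source compilation,
and treating it so is a package choice. $A$'s uncertainty is exactly zero,
but the Monte Carlo layer still draws it (with zero variance) so every
parameter is handled uniformly.

A sensitivity note that surprises many users: with the fractionation-change
profile held fixed, a *larger* $B$ yields a *higher* reconstructed peak,
not a lower one. A steeper hyperbola saturates sooner, so a fixed
fractionation increment corresponds to more CO2. The test suite pins this
direction against the root-finding oracle.

## Stacking scattered records

Sections are pooled per substrate and smoothed by LOESS (tricube weights,
local degree-1 polynomials -- conventional defaults) onto a regular age grid
with 0.002 Myr spacing; `fit_stack()` reports the fitted value and its
standard error per gridpoint. Gridpoints outside the data span are missing
values, never extrapolations. The span is chosen by 5-fold cross-validation
over a log-spaced grid in $[0.1, 1]$; folds interleave samples in age order
so the selection is deterministic. The fitted LOESS value is used as the
central estimate per gridstep (the alternative of a per-bin density mode
was considered and rejected as less stable at realistic sample densities).
`robustness_refits()` reproduces the usual perturbation checks: random 80%
subsamples and leave-one-section-out refits.

## Monte Carlo propagation

`mc_reconstruct()` draws, per Monte Carlo draw (default 10,000):

* the proxy parameters $A$, $B$, $p\mathrm{CO}_2(t{=}0)$,
  $\delta^{13}\mathrm{C}_p(t{=}0)$, and the reference-age carbonate and SST
  values -- **once per draw**, shared across all gridsteps (systematic
  errors);
* the plant, carbonate and SST stack values at each gridstep from
  Gaussian(centre, standard error) -- independently per gridstep
  (measurement error).

The split is a modelling choice (the alternative, fully independent
redrawing per gridstep, is available via `share_params = FALSE`). Each draw
is chained through the equations above and inverted; draws beyond the
hyperbola's asymptote (flagged `NA` by `invert_pco2()`, not thrown) or
outside the validity bounds $(0, 10^6]$ ppmv are excluded, and the
fraction excluded is reported per gridstep. Survivors are summarised by
their median and 16th/84th percentiles (type-7 quantiles, i.e. linear
interpolation between order statistics -- stated because percentile
conventions differ between ecosystems). The positive and negative errors
reported by `report_interval()` are 84th-minus-median and
median-minus-16th; the band is strongly right-skewed at high pCO2 because
the proxy loses sensitivity as the hyperbola saturates.

Randomness comes from a single seed with a fixed, documented draw order, so
a reconstruction is bit-reproducible for identical inputs.

## The synthetic generator

`generate_true_history()` builds piecewise-linear "true" trajectories over
four stages -- pre-excursion plateau, onset ramp (default 75 kyr), excursion
body (optionally with a transient dip), and recovery -- for pCO2
(425 to 2500 ppmv by default), carbonate $\delta^{13}$C (+2.2 to -1.3 per
mil, a -3.5 per mil excursion) and SST (25 to 35 °C, co-timed).
Piecewise-linear shapes are a deliberate minimal choice: only the
endpoints and durations are constrained by the application, and corners
make smoothing bias visible rather than hiding it.
`forward_model_plant_d13c()` then produces the plant record implied by the
truth -- with the default six-fold CO2 rise the -3.5 per mil marine
excursion amplifies to about -7.0 per mil in plants -- and
`sample_sections()` scatters noisy, unevenly-aged samples across sections
(defaults: 4 plant, 10 carbonate, 5 SST sections of 40 samples; Gaussian
noise 0.3 per mil plant, 0.25 per mil carbonate, 1 °C SST, combining
roughly 0.2 per mil analytical precision with modest geological scatter --
the analytical/geological split is a choice, not a measured fact).

What the generator does *not* emulate: hiatuses and facies effects,
autocorrelated noise, age-model error, and any dynamic carbon-cycle
response (the injection is prescribed). Passing tests therefore validate
the statistical machinery, not the geological assumptions.

## Validation design

Two complementary checks separate inversion error from smoothing error:

* **Closed-form round trip.** Stacks taken directly from the truth
  (`stack_from_truth()`, zero standard error) with all parameter
  uncertainties zeroed must return the true pCO2 within 0.5% at every
  gridpoint; in practice the error is at floating-point level.
* **Calibrated coverage.** `coverage_experiment()` draws each dataset's
  true parameters from the same Gaussians the reconstruction uses as
  priors, so the 68% band should cover truth at close to 68% of gridsteps.
  Over 20 datasets (2,000 draws each; sizes chosen to keep the experiment
  inside routine test runs) pooled coverage lands near 0.64 -- within the
  58--78% acceptance window, slightly below nominal because LOESS corners
  bias the stacks where trajectories kink. Per-dataset coverage is strongly
  bimodal: shared systematic parameter draws shift a whole curve, so a
  single dataset tends to be covered almost everywhere or almost nowhere.

The LOESS path itself is held to a separate tolerance (within 0.3 per mil
of the true carbonate curve at 95% of gridpoints at default noise); it
cannot meet 0.5% in pCO2 at ramp corners, which is precisely why the
round-trip check bypasses it.

## Compilation statistics and mass balance

`compile_cie_magnitudes()` measures each section's excursion as peak minus
background. Background is the mean of the five youngest pre-excursion
samples (the "immediately before" convention does not fix a window, so the
window length is a documented knob); the peak is the raw minimum over
onset and body stages (`peak_k` averages the k most negative samples if a
guard against single-sample outliers is wanted).
`compare_substrate_magnitudes()` runs Kruskal--Wallis across substrates and
a two-sided marine-versus-terrestrial rank-sum test -- exact by exhaustive
enumeration (tie-safe) up to 20 values per group, normal approximation
above.

`scenario_table()` evaluates the single-box isotope mass balance
$M_{added} = -\mathrm{CIE} \times M_{background} /
(\delta^{13}\mathrm{C}_{peak} - \delta^{13}\mathrm{C}_{added})$ over a grid
of excursion sizes (-1 to -8 per mil), source compositions (volcanic -6,
organic matter -25, thermogenic methane -40, biogenic methane -60 per mil)
and reservoir sizes (66,000--82,000 Gt C), converts to a CO2 rise at
0.3 ppmv per Gt C, and classifies each scenario against the proxy's
asymmetric 68% band (`compare_with_proxy()`). Sources too heavy to produce
the requested excursion are flagged infeasible rather than dropped.
Climate metrics: `earth_system_sensitivity()` is
$\Delta T / \log_2(p\mathrm{CO}_2^{peak}/p\mathrm{CO}_2^{background})$, and
`pco2_sst_correlation()` reports the Pearson correlation between the median
pCO2 curve and the SST stack (computed on the median curve, not per draw;
the per-draw distribution can be obtained by mapping over seeds).

## Degenerate inputs and numerical choices

* `invert_pco2()` returns `NA` (never an error) when the requested
  fractionation change is at or beyond the asymptote; the Monte Carlo layer
  counts and excludes these, per the validity rule.
* Grids are integer-derived from (old end, young end, step) and half-open
  at the young end, so float step error cannot accumulate.
* Stage assignment sends a sample lying exactly on a boundary to the older
  stage.
* A flat series has excursion magnitude exactly 0; identical groups give a
  rank-sum p of exactly 1 under the enumeration test.
* All $\delta$ values are per mil floats everywhere; there is deliberately
  no fraction/per-mil dual representation.

## Worked example

```{r example, eval = FALSE}
ds <- synthetic_dataset()                       # truth + noisy sections
stacks <- lapply(split(ds$samples, ds$samples$substrate),
                 fit_stack, grid = ds$truth$age_ma)
params <- proxy_params(d13c_p_ref = ds$truth$d13c_p_true[1])
rec <- mc_reconstruct(stacks$plant, stacks$carbonate, stacks$sst, params,
                      n_draws = 10000, seed = 1)
rec                                              # peak median + errors
report_interval(rec, 252.014)
pco2_sst_correlation(rec, stacks$sst)
```

## Limitations

The proxy's uncertainty grows with pCO2 (asymptote proximity), so peak
estimates carry wide, asymmetric bands. The reconstruction inherits
whatever bias the reference pCO2 and plant baseline carry, since only
changes relative to them are inverted. The mass balance is a single-box,
instantaneous model without weathering or burial fluxes, and so tends to
understate the carbon required. None of the statistical machinery corrects
for age-model error between sections: ages are taken as given.
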