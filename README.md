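# c3pco2

Reconstruction of atmospheric pCO2 across a negative carbon isotope
excursion (CIE) from the CO2 dependence of photosynthetic carbon isotope
fractionation in C3 land plants — the proxy behind continuous pCO2 records
across events such as the Permian–Triassic mass extinction, where marine
carbonate records a ~−3.5‰ excursion while coeval plant tissue records
~−7‰, the amplification carrying the CO2 signal.

It is written for stable-isotope geochemists and palaeoclimate modellers
who have age-tagged δ¹³C series (plants, marine carbonate) and sea surface
temperatures from several sections and want a pCO2 curve with honest,
asymmetric uncertainty bands — plus the standard companion analyses:
CIE-magnitude compilation statistics, carbon isotope mass-balance source
scenarios, and climate metrics.

## The model

C3-plant fractionation Δ¹³C = (δ¹³C_CO2 − δ¹³C_p)/(1 + δ¹³C_p/1000)
responds hyperbolically to CO2:

    Δ¹³C = A·B·(pCO2 + C) / (A + B·(pCO2 + C)),      C = A·4.4/((A − 4.4)·B)

with A = 28.26 ± 0‰, B = 0.22 ± 0.028, anchored at Δ¹³C(0) = 4.4‰. The
package inverts the *change* in fractionation relative to a pre-excursion
reference (pCO2(t=0) = 425 ± 68 ppmv, δ¹³C_p(t=0) = −24.42 ± 0.5‰) in
closed form. Atmospheric δ¹³C_CO2 comes from marine carbonate via
δ¹³C_DIC = δ¹³C_carb − 1‰ and a temperature-dependent DIC–CO2
fractionation. Scattered multi-section records are stacked by LOESS
(tricube, degree 1, cross-validated span) onto a 0.002 Myr grid; a Monte
Carlo layer (10,000 draws, Gaussian inputs, invalid draws excluded,
16th/84th percentile bands) propagates every uncertainty. A single-box
mass balance M_added = −CIE·M_background/(δ¹³C_peak − δ¹³C_added)
(1 Gt C = 0.3 ppmv) evaluates candidate carbon sources against the proxy
band.

A synthetic-record generator with a known true pCO2/δ¹³C/SST history makes
every stage testable end to end; see the methods vignette
(`vignettes/pco2-reconstruction.Rmd`).

## Worked example

```r
library(c3pco2)

ds <- synthetic_dataset()                      # 4-stage CIE, known truth
stacks <- lapply(split(ds$samples, ds$samples$substrate),
                 fit_stack, grid = ds$truth$age_ma)
params <- proxy_params(d13c_p_ref = ds$truth$d13c_p_true[1])
rec <- mc_reconstruct(stacks$plant, stacks$carbonate, stacks$sst, params,
                      n_draws = 10000, seed = 1)
rec
#> pCO2 reconstruction: 175 gridpoints (173 valid), 10000 draws, seed 1
#>   peak median 2357 ppmv (+3516/-1025) at 252.014 Ma
```

The generator's true history ramps 425 → 2500 ppmv; the reconstruction
recovers a peak median of 2357 ppmv with the expected right-skewed band
(the proxy loses sensitivity near the hyperbola's asymptote, so the
positive error dwarfs the negative one). Comparing the implied rise with
mass-balance scenarios for a −3.5‰ excursion on a 66,000 Gt reservoir:

```r
ok <- which(is.finite(rec$median))
bg <- rec$median[ok[1]]                         # 428 ppmv background
iv <- report_interval(rec, rec$age_ma[which.max(rec$median)])
tab <- compare_with_proxy(scenario_table(cie_grid = -3.5,
                                         m_background = 66000),
                          mid = iv["median"] - bg,
                          pos_err = iv["pos_err"], neg_err = iv["neg_err"])
tab[, c("source_permil", "m_added_gt", "ppmv_rise", "band_flag")]
#>   source_permil m_added_gt ppmv_rise band_flag
#> 1            -6      49149     14745     above
#> 2           -25       9747      2924    within
#> 3           -40       5969      1791    within
#> 4           -60       3935      1181    within
```

Volcanic CO2 alone (−6‰) overshoots the proxy band by an order of
magnitude — producing a −3.5‰ excursion with so heavy a source takes
~49,000 Gt C — while organic-matter and methane sources (−25‰ to −60‰,
3,900–9,700 Gt C) fall within it. The same run gives an Earth system
sensitivity `earth_system_sensitivity(10, iv["median"], bg)` of about
4.1 °C per CO2 doubling, and `pco2_sst_correlation(rec, stacks$sst)`
returns r = 0.97 on the co-timed synthetic ramps.

A YAML-configured pipeline (`run_pipeline()`) chains
simulate → stack → reconstruct → massbalance → metrics, writing documented
CSV artifacts, a config echo and a seeded, byte-reproducible log.

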