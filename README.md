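# halven

Coupled carbon and biodiversity assessment of a nitrogen-fertilizer-reduction
policy for EU-like agricultural landscapes.

## The problem

Halving mineral nitrogen use in European agriculture changes land use, and the
direction of the environmental outcome depends on *how* the agricultural
economy responds. Two archetypal responses bracket the possibilities:

* **land abandonment** — cultivated area shrinks in favor of fallow and
  pasture, with a large drop in agricultural production;
* **crop extensification** — cropland expands onto grazing land at lower
  per-hectare yields, with a smaller production drop.

`halven` is a desk-scale, fully synthetic re-implementation of the analysis
chain used to compare such scenario pairs: gridded Baseline / Halving-N
land-use maps → crosswalk to biodiversity land-use×intensity classes and
land-surface-model plant functional types (PFTs) → biodiversity projection
and ecosystem-carbon accounting → area/intensity decomposition and Win/Loss
quadrant comparison. A scenario generator with controlled statistical
structure stands in for the economic models and the process-based
land-surface model, so every stage is testable without any external data.
It is aimed at researchers who want a transparent, reproducible harness for
this class of policy assessment.

## Methods at the core

* **Biodiversity projection.** Per land-use×intensity class `i` with fraction
  `f_i` in a cell, species richness uses a Poisson log link,
  `SR% = 100 · Σ f_i · exp(β_i − β_primary)`; total abundance a square-root
  scale, `A% = 100 · Σ f_i · (a_i / a_primary)²`; compositional similarity an
  asymmetric Jaccard index on an adjusted-logit scale,
  `s_i = (plogis(x_i) − 0.01)/0.98`, with intensity coarsened away except for
  perennial crops. The Biodiversity Intactness Index is the product
  `BII% = A% · S% / 100`. Cropland intensity shares (minimal/light/intense)
  are monotone ordered-logistic functions of yield; yield follows a
  Michaelis–Menten response to the N rate,
  `y(n) = y_min + (y_max − y_min) · n/(k_half + n)`.
* **Carbon accounting.** Per-PFT densities (NPP tC ha⁻¹ yr⁻¹, soil and
  biomass C tC ha⁻¹) are weighted by PFT fractions, differenced Halving-N
  minus Baseline, and aggregated with spherical-band cell areas to MtC.
  Soil carbon relaxes to its new equilibrium as
  `c(t) = c_eq + (c₀ − c_eq)·exp(−t/τ)`. Significance of annual-mean
  differences uses a one-sample t-test with the standard error corrected for
  serial correlation via `n_eff = n(1 − r₁)/(1 + r₁)`.
* **LMDI decomposition.** Each land use's indicator difference splits exactly
  into an area effect `L(E_hN, E_b)·ln(A_hN/A_b)` and an intensity effect
  `L(E_hN, E_b)·ln(e_hN/e_b)`, with `L` the logarithmic mean and `e = E/A`;
  the two effects add to `E_hN − E_b` with no residual.
* **Quadrants.** Cells are classified by the joint sign of ΔC and
  Δbiodiversity into Win–Win / Loss–Win / Loss–Loss / Win–Loss, plus a
  no-change residual; shares partition to 100% of grid points.

## Worked example

```r
library(halven)
run <- run_pipeline(pipeline_config(seed = 1))
print(run)
```

```
<halven_run> seed 1, 68 x 87 cells
  abandonment      EU: dNPP +56.19 MtC/yr, dSoilC +2009.31 MtC, dSR +0.82 pp, dBII +0.91 pp
  extensification  EU: dNPP -35.37 MtC/yr, dSoilC -970.44 MtC, dSR -0.17 pp, dBII +1.24 pp
```

The two archetypes produce opposite EU-scale carbon responses: abandonment
sequesters soil carbon (cropland converted to fallow/grass, which holds more
soil C per hectare) while extensification loses it (pasture converted to
cropland). The LMDI table attributes the abandonment gain to grassland, and
splits it into the effect of grassland *area* growing versus the per-hectare
*intensity* of the stock:

```r
print(run$families$abandonment$breakdown$soil, digits = 4)
```

```
<breakdown_result> soil_c_mtc
  land_use     E_b    E_hN    A_b   A_hN    dE dE_area dE_intensity flagged
  cropland 20055.1 17117.6 399.03 339.18 -2938   -3014        76.82   FALSE
 grassland 27291.4 32238.3 323.39 383.24  4947    5043       -96.07   FALSE
    forest 26688.7 26688.7 281.09 281.09     0       0         0.00   FALSE
     other   806.8   806.8  99.68  99.68     0       0         0.00   FALSE
```

`dE_area + dE_intensity` equals `dE` on every row — the defining LMDI
identity. A single-row example with round numbers:

```r
lmdi_breakdown(data.frame(land_use = "grassland",
                          E_b = 100, E_hN = 150, A_b = 10, A_hN = 12))
```

```
  land_use E_b E_hN A_b A_hN dE dE_area dE_intensity flagged
 grassland 100  150  10   12 50    22.5         27.5   FALSE
```

A 20% area increase carries 22.5 of the 50-unit change; the denser remainder
is the intensity effect.

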