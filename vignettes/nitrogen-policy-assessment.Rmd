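---
title: "Assessing a halving of nitrogen fertilizer: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing a halving of nitrogen fertilizer: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halven)
```

`halven` implements a desk-scale version of a coupled assessment chain for a
policy that halves mineral nitrogen fertilizer use: two contrasting economic
responses are expressed as gridded Baseline / Halving-N land-use scenario
pairs, pushed one way through a biodiversity projection and an ecosystem
carbon accounting, and compared through an exact area/intensity
decomposition and a Win/Loss quadrant classification. This vignette is the
package's own account of the science: the models and their assumptions, the
parameters that matter, what the synthetic generator does and does not
emulate, and the numerical decisions taken where the design was open.

## The assessment chain and its assumptions

The chain is strictly one-way: each stage consumes the previous stage's
outputs and mutates nothing upstream.

1. **Scenario generation** (`generate_scenario_pair()`): per-cell area
   fractions over economic-model land-use categories for a Baseline and a
   Halving-N scenario.
2. **Crosswalk** (`economic_to_predicts()`, `economic_to_pft()`): economic
   categories are reallocated to biodiversity land-use × intensity classes
   and to land-surface-model plant functional types (PFTs), conserving area
   exactly.
3. **Biodiversity projection** (`project_biodiversity()`): species richness
   (SR), total abundance, compositional similarity and their product, the
   Biodiversity Intactness Index (BII), all as percentages of the
   primary-vegetation level.
4. **Carbon accounting** (`generate_carbon_fields()`,
   `scenario_difference()`, `aggregate_totals()`): per-PFT densities weighted
   into cell totals, differenced between scenarios and aggregated to
   regional MtC.
5. **Decomposition and comparison** (`lmdi_breakdown()`,
   `classify_quadrants()`).

The biodiversity stage assumes *space-for-time substitution*: coefficients
estimated across sites that differ in land use are read as the consequence
of changing land use in place. It also assumes cell-level indicators are
fraction-weighted means of class-level values — biodiversity responds to
the composition of each cell, not to landscape configuration, adjacency, or
the amount of natural vegetation embedded in agricultural land. Pesticides
are not represented; yield serves as the single proxy for management
intensity. The carbon stage assumes per-PFT carbon densities are attributes
of the vegetation type (plus a static spatial pattern), so land-use change
moves a cell between equilibria rather than simulating process dynamics;
only soil carbon gets a transient (a single-pool relaxation).

## Biodiversity models

Per class $i$ with per-cell fraction $f_i$ (fractions close to 1 in every
cell):

* **SR** (Poisson log link): relative richness $r_i = e^{\beta_i -
  \beta_{primary}}$ and cell $SR\% = 100\sum_i f_i r_i$.
* **Abundance** (square-root scale): $a\%$ uses the squared ratio of
  sqrt-scale predictions $(a_i/a_{primary})^2$.
* **Compositional similarity** (asymmetric Jaccard against
  primary-vegetation baseline sites, adjusted-logit scale): the data-scale
  value is $s = (\mathrm{plogis}(x) - \epsilon)/(1 - 2\epsilon)$ with
  $\epsilon = 0.01$, clipped to $[0,1]$. The adjustment inverts a symmetric
  compression of the unit interval; this convention is a package choice — the
  adjustment magnitude (0.01) is standard, its inversion is not uniquely
  defined — and is applied consistently everywhere. Similarity coefficients
  are *coarsened*: intensity levels share one coefficient except for
  perennial crops (validated at load time).
* **BII** $= a\% \times s\% / 100$, exactly, on every cell.

Two ordering choices were open and are fixed as follows. Relative values are
formed *per class first, then fraction-weighted* (ratio before weighting);
abundance and similarity are aggregated to the cell separately and
multiplied afterwards. Relative values are *not* capped at 100%: a class
richer than primary vegetation is allowed to exceed it (a cap would break
the linearity that the decomposition stage relies on).

Coefficients are external inputs with a documented CSV schema. The packaged
default set is synthetic — the mixed-effects models behind the real
coefficients cannot be refit without their site database — and encodes the
qualitative orderings that drive the analysis: SR declines primary ≥
secondary ≥ pasture ≥ cropland; pasture communities are compositionally far
from primary vegetation while (annual) cropland communities are close;
minimal-intensity annual cropland (the fallow class) is species-poorer per
hectare than light-intensity cropland. `fit_biodiversity_coefficients()`
demonstrates that the coefficients are recoverable from simulated site-level
data by fixed-effects maximum likelihood (Poisson GLM for SR, per-class
means on the transformed scales); random effects are deliberately omitted.

**Intensity shares.** The original analysis estimated shares of
minimal/light/intense management from yield (and of light/intense pasture
from ruminant density) with GAMs trained on external maps. Those maps are
not reproducible here, so the same monotone link is represented by an
ordered-logistic curve: cumulative share up to class $k$ is
$\mathrm{plogis}(c_k - s\,y)$. Defaults $c = (3.5, 6.5)$ tDM/ha and $s = 1$
place the light-dominated region over typical European cereal yields;
pasture uses one cutpoint at 1.2 heads/ha with slope 1.5. Shares always sum
to one, the minimal share is non-increasing and the intense share
non-decreasing in yield.

## Carbon models

Default per-PFT equilibrium densities (`carbon_means()`) encode the two
orderings the assessment turns on: grass and forest soils hold more carbon
per hectare (80–95 tC/ha) than cropland soils (50 tC/ha), and permanent
herbaceous/forest vegetation fixes more carbon per year (4.8–5.2 tC/ha/yr)
than annual crops (4.0–4.5), which spend part of the year as bare soil and
export harvest. Converting cropland to fallow/grass therefore gains soil
carbon and NPP; converting pasture to cropland loses both.

Soil carbon follows a single-pool exponential relaxation,
$c(t) = c_{eq} + (c_0 - c_{eq})e^{-t/\tau}$, with $\tau = 40$ yr and a
150-year horizon: one parameter, a steady approach to equilibrium, ~98% of
the transition completed at the horizon. A two-pool model could match both
an early-decade stock change and a late stabilization time simultaneously;
that refinement is out of scope, and the single time constant is the
acknowledged compromise.

**Significance.** Annual-mean differences are tested per cell with a
one-sample t-test whose standard error uses the effective sample size
$n_{eff} = n(1-r_1)/(1+r_1)$. Numerical choices: the moment estimate of
$r_1$ is biased low in 50-year series, which makes the corrected test
anti-conservative, so the first-order Marriott–Pope/Kendall correction
$\hat r_1 + (1+3\hat r_1)/n$ is applied; the result is clipped to
$[0, 0.99]$ (negative estimates never *inflate* the sample); $n_{eff}$ is
floored at 2 so the t reference distribution stays defined; zero-variance
series are significant iff their constant difference is nonzero. Under an
AR(1) null with $r_1 = 0.5$ and $n = 50$ the acceptance suite measures the
empirical size by Monte Carlo and checks it stays near the nominal 5%,
while the uncorrected test rejects several times too often.

## LMDI decomposition

For each land use, the indicator difference splits into
$\Delta E^A = L(E^{hN}, E^b)\,\ln(A^{hN}/A^b)$ and
$\Delta E^I = L(E^{hN}, E^b)\,\ln(e^{hN}/e^b)$ with $e = E/A$ and $L$ the
logarithmic mean; additivity $\Delta E^A + \Delta E^I = E^{hN} - E^b$ is an
algebraic identity with no residual. Numerical choices:

* $L(a,b)$ is evaluated as $b\,d/\mathrm{log1p}(d)$ with $d = (a-b)/b$,
  which avoids the catastrophic cancellation of $\ln a - \ln b$ as
  $a \to b$ (the decomposition is continuous through the equal-level
  limit, which the tests check by $\pm 10^{-8}$ perturbation).
* Levels and areas below a floor of $10^{-9}$ (indicator units) are raised
  to it, with a warning, before taking logs; the decomposition always
  operates on positive *levels*, never on differences.
* A land use present in exactly one scenario gets the whole difference as
  area effect (the limit convention) and is flagged in the output.
* BII is refused: a product of two indicators is not an extensive level,
  and decomposing it would be meaningless. The error message says so.

For species richness, the per-land-use levels are each group's additive
contribution (in percentage points) to the area-weighted EU mean SR. Because
the projection is linear in fractions, letting only one land-use group
change at a time recovers exactly these contributions, and the per-group
differences sum to the overall SR change — the suite verifies this against
a direct projection to $10^{-6}$ relative.

## The synthetic generator: what it emulates, and what it does not

`generate_scenario_pair()` draws the baseline landscape as a softmax of
per-category Gaussian random fields around archetype-specific mean weights —
an EU-like composition (forest-dominated natural land, roughly a third
cropland including a few percent fallow, a substantial pasture share) with
smooth spatial variation. The policy response is deterministic given the
baseline:

* *abandonment*: a fraction `abandon_frac` (default 0.15) of every
  cultivated cropland category moves to fallow (2/3) and pasture (1/3);
* *extensification*: a fraction `convert_frac` (default 0.10) of pasture
  converts to cropland in proportion to the local crop mix; yields drop with
  the halved N rate via the Michaelis–Menten response (defaults
  $y_{min} = 2$, $y_{max} = 8$ tDM/ha, $k_{half} = 100$ kgN/ha, baseline
  150 kgN/ha), and the stocking proxy falls by 0.1 heads/ha.

Both responses scale with the severity of the cut,
$(1 - f_{policy})/0.5$, so keeping all fertilizer reproduces the baseline
bit-for-bit. The default magnitudes (0.15, 0.10) were chosen once to produce
visible but non-degenerate land-use change; they are configuration, not
fitted quantities.

Spatial noise is a Gaussian random field built by separable convolution of
white noise with a Gaussian kernel — the simplest construction with a
controllable correlation length (default 3 cells, the lag at which
autocorrelation falls to $1/e$; the tests check the empirical semivariogram
flattens beyond it). Carbon noise is seeded by the scenario configuration
only, so both scenarios see identical per-PFT density fields and their
difference isolates land-use change.

What the generator does **not** emulate: economic optimization, prices and
elasticities, livestock feed substitution, meteorological forcing, crop
phenology, rotations, organic inputs, and the real spatial covariance
between land use and carbon (e.g. cropland concentrating on good soils).
Passing tests therefore demonstrate that the *analysis machinery* is
correct and that the archetypes' qualitative signatures (sign of the EU
soil-carbon change, grassland dominating the abandonment gain, the modal
Win–Win vs Loss–Loss quadrant) follow from the encoded mechanisms — not
that any particular real-world magnitude is reproduced.

The default domain is a 0.5° grid over 35.25–69.25°N, 9.25°W–34.25°E
(68 × 87 = 5916 cells; spherical-band cell areas, $R = 6371$ km). The
eastern bound is configurable. All shipped analyses — tests and the
acceptance script — run on this grid or smaller cutouts; the full
two-archetype pipeline takes a few seconds at this size.

## Crosswalk details and open points

The shipped table follows the published correspondence between the two
economic models' categories and the biodiversity/PFT vocabularies, with
these package-level resolutions, each configurable by supplying a custom
CSV:

* primary vs secondary attribution of forest and other natural areas uses a
  scalar split, default 0.5/0.5, instead of an external harmonization map;
* the partial-equilibrium model's "Other" category splits annual/perennial
  0.8/0.2;
* pasture and rangeland split C3/C4 natural grass 0.9/0.1;
* fallow is minimal-intensity annual cropland for biodiversity and C3
  natural grass for carbon (so it contributes to the *cropland* SR group
  but the *grassland* carbon group — intended, and the reason the two
  breakdowns use different group definitions);
* the supply-side model's soybean and other legumes map to the C3 natural
  grass PFT, as printed in the source table, even though the
  partial-equilibrium model's soybean maps to a crop PFT; the inconsistency
  is preserved rather than harmonized;
* the supply-side "Perennial" category has no printed PFT correspondence;
  it is mapped to C3 natural grass because closure requires every category
  to land somewhere.

## Known limitations

* Coefficients, carbon means and scenario magnitudes are synthetic; EU-scale
  magnitudes from a run are internally consistent but not calibrated to any
  observed dataset.
* One soil pool, one time constant; no transient for biomass or NPP.
* The significance stage tests cells independently; no field significance
  or multiple-testing control across cells.
* Regions are longitude bands, not countries; they exercise the
  partition-and-aggregate contract, nothing more.
* The no-change band in the quadrant classification defaults to exact zeros
  (tolerance 0, configurable); with fully synthetic continuous fields,
  exact zeros occur only where the scenarios genuinely coincide.
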