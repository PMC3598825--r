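---
title: "Stoichiometric balancing of lignocellulose fermentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stoichiometric balancing of lignocellulose fermentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermbalance)
```

## The problem

Thermophilic consolidated-bioprocessing experiments pair cellulolytic
bacteria (which hydrolyze crystalline cellulose and hemicellulose and
ferment the released sugars) with saccharolytic partners (which ferment
soluble sugars only, often with a strongly ethanologenic product
profile). The primary data are simple: a substrate loading and its
compositional analysis, end-point concentrations of ethanol, acetate and
lactate (sometimes CO₂, H₂ and cell dry weight), and initial/final
substrate dry mass. Everything of scientific interest — how much of the
substrate's fermentable carbohydrate was used, how the product spectrum
shifted in co-culture, whether the measurements are internally
consistent — is stoichiometric arithmetic on those numbers. This package
makes that arithmetic explicit, validated and reusable.

## Sugar equivalents

Compositional analysis reports polymer mass fractions of dry substrate.
The repeating unit of a polysaccharide is the condensed (anhydro)
monomer, so a loading $L$ (g/l) with polymer fraction $w$ contains

$$ C = \frac{L\,w}{M_\text{anhydro}} \times 1000 \quad \text{mM} $$

monomer equivalents, with $M = 162.14$ g/mol for hexosans and $132.11$
g/mol for pentosans. Galactan and mannan are treated identically to
glucan, arabinan identically to xylan; this is exact for the molar
bookkeeping because the isomers share elemental composition.

Published compositional tables are not always consistent about the
second decimal of the anhydrohexose mass (162 vs 162.14; a 10 g/l
cellulose loading prints as 61.68 mM under 162.14 but a 6.05 g/l
loading's 21.70 mM implies 162). We adopt 162.14 uniformly — the
anhydroglucose formula mass — and reproduce table values at one-decimal
precision, which both conventions satisfy. Masses live in the compound
registry (`inst/extdata/compounds.csv`), so a user who needs the other
convention can supply an edited registry rather than patch code.

Compositions arriving as percentages are divided by 100 at parse time
(`read_composition_table()` accepts a `percent` column); internally
everything is a fraction in $[0,1]$, validated to sum to at most 1 plus
a 2% analytical-closure allowance.

## Capacity, utilization and yield statistics

Mixed-acid catabolism routes each hexose through two and each pentose
through five-thirds pyruvate-equivalent C3 units, and each unit yields
one ethanol, acetate or lactate. The theoretical capacity is therefore
$2.0 \sum C_6 + 1.67 \sum C_5$ mM of total organic products. The pentose
factor is stored as the conventional rounded 1.67 rather than $5/3$: the
capacities this package is checked against were published with 1.67, and
reproducing them bit-for-bit matters more than the third decimal.
Both factors are fields of `yield_constants()` and can be overridden.

Utilization is total organics over capacity ×100, deliberately excluding
CO₂, H₂ and cells — the capacity is defined on the three organic
products. Ethanol mol% and the `1 : acetate/ethanol : lactate/ethanol`
ratio summarize the product spectrum; when ethanol is zero the ratio is
renormalized to the largest component and flagged rather than failing.

Replicates are aggregated per replicate first: a group's ethanol mol% is
the mean of the replicate mol% values, not the mol% of the mean profile.
Published tables show the same convention (printed mol% values differ by
±0.1 from what their own printed mean concentrations give). Display
rounding is half-away-from-zero at one decimal, applied only at report
time; internal arithmetic is double precision throughout.

## Carbon and electron recovery

Consumed substrate (measured directly for defined sugars, or as dry
weight loss attributed to cellulose for washed polymeric substrates,
divided by 162.14) is compared against products and cells:

* carbon: 2 C/mol for ethanol and acetate, 3 for lactate, 1 for CO₂,
  plus cell carbon;
* available electrons: $\gamma = 4C + H - 2O - 3N$ per mole, i.e. 24
  for glucose and for anhydroglucose, 12 for ethanol and lactate, 8 for
  acetate, 2 for H₂, 0 for CO₂ and water.

Acetate and lactate are treated as their free acids (ionization ignored),
the standard convention consistent with $\gamma$ values 8 and 12. Cell
dry weight interconverts with cell carbon through the empirical
per-carbon formula CH₂N₀.₂₅O₀.₅ (25.53 g per C-mol); both directions are
provided because balance protocols differ in which quantity is measured.
Biomass $\gamma = 4.25$ assumes an NH₃ nitrogen source (the reference
state); it is an argument (`gamma_biomass`) rather than a constant
because nitrogen-source corrections are a known source of disagreement
between laboratories. Carbon from yeast extract and extracellular
protein is excluded, and balance runs assume bicarbonate-free medium, as
balance protocols prescribe.

Species measured as `NA` are omitted from the product side rather than
counted as zero, so a recovery computed from a gas-free record is a
recovery over the measured species only — reports mark the columns
absent instead of silently deflating the balance.

## The synthetic generator

`generate_outcome()` emulates end-point records; `generate_timecourse()`
emulates product curves. The model is deliberately minimal:

* **Catabolism at the C3 level.** Consumed sugar carbon is split between
  cells (`biomass_fraction`, 0–0.15) and catabolism; catabolized carbon
  forms C3 units (2 per hexose, 5/3 per pentose) that become ethanol,
  acetate or lactate per the strain's `product_split`. The 2.0/1.67
  yield factors *emerge* from this mechanism instead of being imposed,
  which keeps products, gases and capacity mutually consistent.
* **Gases by closure.** Ethanol- and acetate-forming units each release
  one CO₂; H₂ is set so available electrons balance exactly
  (`closure_gases()`): per mol hexose,
  $2\,\mathrm{H_2} = 24 - 12e - 8a - 12l - 4.25\,c_\text{bio}$.
  Splits that would need negative H₂ (e.g. nearly pure ethanol plus
  biomass, which is more reduced than the substrate allows) raise an
  infeasibility error rather than generate impossible data.
* **Co-cultures.** The cellulolytic partner gates hydrolysis of
  polymeric substrates; released sugars are partitioned between the two
  strains by a `share` parameter, default 50:50. End-point data cannot
  identify the true partition, so it is an explicit knob, not an
  inference.
* **Flask acidification.** Unbuffered flask cultures stall when the
  accumulating acids acidify the medium. We model this as a hard cap:
  consumption stops once acetate+lactate reaches `acid_threshold`
  (default 30 mM, chosen so default flask-mode totals land in the
  20–40 mM range typical of unbuffered flasks while fermentor mode runs
  to the set extent, >60 mM on 10–20 g/l loadings). This stop rule is a
  stand-in for pH chemistry, not a claim about the organisms; no
  quantitative pH-inhibition relation is modeled.
* **Noise.** Multiplicative Gaussian per analyte, independent across
  analytes, truncated at zero. Seeds are explicit `noise_model()`
  fields; the generator restores the caller's RNG state.

Because gases close the balances by construction, every noise-free
record shows exactly 100% carbon and electron recovery — the package's
strongest self-test, exercised over a thousand randomized
strain/substrate combinations in the test suite. What passing those
tests shows is internal consistency of the whole pipeline; what it does
not show is anything about real measurement error structure (correlated
HPLC drift, gas headspace losses, wall growth), which the noise model
deliberately does not attempt.

The time course anchors a logistic consumption trajectory at zero
consumption at $t=0$ (steepness 0.08 h⁻¹, midpoint 60 h, horizon 144 h —
the scale of thermophilic cellulose fermentations, which run for days);
products accumulate proportionally to consumption, and the final point
reproduces `generate_outcome()` under the same seed.

`estimate_split()` inverts the generator in the obvious way — organic
product mole fractions — and is exact at zero noise and unbiased under
symmetric noise; the tests verify mean recovery within 0.02 over 200
replicates at 5% relative noise.

## Records, fixtures and reports

Records travel as CSV, one row per replicate-condition, comma-separated
with decimal points (a published "61,7" is a typographic decimal comma,
not our dialect), concentrations in mM, substrate and cell dry weight in
g/l. Shipped fixtures under `inst/extdata/` encode the published
mono-/co-culture product table (11 of its 15 condition rows carry data;
"no growth" rows do not), the four-substrate flask balance table, and
the in-text fermentor results (acetate and lactate of the fermentor
rows are back-computed from the printed ethanol and
ethanol:acetate:lactate ratios, the form in which they were published).
The washed-miscanthus glucan fraction (0.580) is back-derived from that
table's own "100% = 21.8 mM glucose equivalents at 6.09 g/l" statement;
no direct compositional analysis of it was published. Totals are always
recomputed from components (published totals occasionally disagree with
their own components by 0.1 from replicate rounding).

## Numerical choices and degenerate inputs

* Zero loading, zero products and empty files are defined results
  (zeros, empty tables), not errors; zero capacity, zero consumption
  and zero-reference fold changes are errors, because the statistic is
  undefined.
* Validation reports every offending row with its file line number in
  one pass rather than failing on the first.
* Balance linearity (a pooled record's recovery is the
  consumption-weighted mean of its parts) and the equality of the
  formula-weight path with brute-force per-atom accounting are tested to
  1e-9; equality there is exact arithmetic, not approximation.

## Known limitations

* No kinetics: `consumption_extent` and the logistic time course are
  descriptive, not Monod-style mechanisms; hydrolysis rates, osmotic
  effects and gas–liquid transfer are out of scope.
* Nitrogen and oxygen balances are not computed; the electron balance
  assumes NH₃-referenced degrees of reduction.
* The generator's co-culture sugar partition and acidification threshold
  are model knobs — useful for scenario studies, not identifiable from
  end-point data.
* Published replicate-mean statistics are generally *not* exactly
  recomputable from published rounded means; this package asserts its
  own recomputed values and treats published ones as tolerance checks.

## Problem sizes

The test suite's property checks use 1,000 randomized zero-noise records
for closure, 200 noisy replicates for parameter recovery, and dozens of
randomized profiles for the balance oracle — sizes at which the law of
large numbers has visibly converged for these estimators while the whole
suite runs in well under a minute.
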