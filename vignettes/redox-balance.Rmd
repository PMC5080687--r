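---
title: "Carbon and redox bookkeeping for isopropanol–butanol fermentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon and redox bookkeeping for isopropanol-butanol fermentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibferm)
```

## The balance model

`ibferm` treats a fermentation endpoint as a small stoichiometric ledger.
The inputs are net consumed substrates and final product titers in g/L; the
registry converts each to millimolar through fixed molar masses, and three
families of quantities follow.

**Carbon.** Total consumed carbon is `sum(mM_i * C_i)` over substrates
(mM C). Carbon recovery of a product set is the product-carbon sum divided
by consumed carbon, as a percentage. Per-carbon-mole production
(`buoh_c`, `ipa_c`, …) is product mM over consumed carbon mM — by default
mol product per C-mol substrate; a `"cmol"` switch multiplies by the
product's carbon count for the C-mol/C-mol normalisation, since published
carbon-flow plots use either convention and rarely say which.

**Redox.** Glycolytic NAD(P)H generation is 2 mol per mol of consumed
glucose or glycerol. Requirement is 4, 2, 1, 0, 0 mol per mol of produced
butanol, butyric acid, isopropanol, acetone, acetic acid. Both are linear
in the millimolar amounts, so all intensive metrics (yields, ratios,
NAD(P)H_C, the ferredoxin fraction, per-C-mole values, recoveries) are
invariant under rescaling every concentration — a property the test suite
exercises on random records. The single generation coefficient of 2 is
taken at face value for both substrates; whatever NAD(P)H the
pyruvate–ferredoxin route contributes is accounted separately as the
shortfall fraction

$$ f_{Fd} = \frac{\max(0,\; \mathrm{required} - \mathrm{generated})}{\mathrm{required}}, $$

clipped at zero: when generation exceeds the requirement the surplus is
reported as "no ferredoxin-derived NAD(P)H", not as a negative fraction.
A record with zero requirement has no defined fraction; the dedicated
function raises an error and the aggregate analysis flags the field as `NA`.

**Process metrics.** Yields are mass ratios over *total* consumed
substrate (mixed feeds divide by the summed mass), productivities are
final titer over the stated sampling time (the overall convention —
instantaneous or maximum-slope productivities are deliberately out of
scope), and B/I is the butanol/isopropanol titer ratio, undefined (`NA`,
rendered as a dash) when no isopropanol was formed.

### Registry choices

Endpoint tables print concentrations, not moles, so the registry must fix
molar masses. It uses standard two-decimal values (glucose 180.16,
glycerol 92.09, butanol 74.12, isopropanol 60.10, acetone 58.08, acetic
acid 60.05, butyric acid 88.11, 1,3-propanediol 76.09 g/mol, …). Published
tables that were computed from unrounded instrument readings can
therefore differ from recomputed values by a few tenths of a mM on
carbon totals (two-decimal rounding of a glucose concentration alone is
worth ±0.17 mM C); the bundled acceptance checks compare at tolerances
reflecting that input rounding.

Coefficients carried directly by the scheme above are tagged `core`.
1,3-propanediol, the reduced by-product of glycerol-only cultures, is not
covered by it; the registry supplies 1 mol NAD(P)H per mol (one reduction
of the glycerol backbone) tagged `extrapolated`, and every balance
function refuses extrapolated coefficients unless
`allow_extrapolated = TRUE`, so a reproduced reference number can never
silently depend on a package-supplied coefficient. Sugars other than
glucose (pentoses, galactose, disaccharides) are registered for carbon
accounting only; asking for their generation coefficient is an error, as
the redox balance is only meaningful for the glucose/glycerol scheme.
Ethanol is registered but ignored by the requirement sum (titers in the
reference fermentations were below 0.1 g/L).

## Degenerate inputs and numerical conventions

* Zero consumption: yields, NAD(P)H_C, per-C-mole values and recoveries
  raise a computation error (class `ib_computation_error`, CLI exit 3).
* Zero products: yields and requirement are 0; the ferredoxin fraction is
  flagged rather than computed.
* Acid/solvent tie in `classify_mode()` (including the all-zero record):
  resolved as solventogenic with a warning.
* All conversions are exact arithmetic; nothing is rounded until display.
  The report layer (`--decimals`, default 2) rounds only the rendered
  text; CSV and JSON outputs carry full precision.

## The synthetic fermentation generator

`simulate_batch()` exists so the whole pipeline — write a time course,
read it back, extract an endpoint, run the balance — can be tested end to
end with known ground truth. It is a *descriptive* model of the biphasic
batch phenomenology, not a mechanistic kinetic model:

* logistic biomass growth `dX = mu_max · X · (1 − X/K) · dt`
  (`mu_max = 0.35 /h`, capacity `K = 3 g/L` by default — typical orders
  for anaerobic clostridial batches);
* substrate draw `uptake · X · dt` (`0.4 g/gDCW/h` default), split between
  glucose and glycerol by `glycerol_preference` (default: glycerol's mass
  share of the feed) while glycerol lasts; exhausted substrates leave the
  split and pools floor at zero;
* before `switch_time_h` (default 10 h) the draw becomes acids at
  `acid_yields`; afterwards solvents at `solvent_yields`, with first-order
  acid re-assimilation into butanol (`acid_reassimilation_rate`, default
  0.03 /h; 1 g butanol per g acid by default) and first-order
  acetone→isopropanol conversion at molar equivalence
  (`acetone_conversion_rate`, default 0.15 /h);
* pH is emitted as a bounded descriptive proxy (6.2 minus 0.35 per g/L of
  total acids, clipped to [4.5, 6.2]) for plotting; it drives nothing;
* Gaussian measurement noise (`noise_sd`, truncated at 0) is applied only
  to the emitted measured series; the latent truth is attached unchanged
  as `attr(tc, "latent")`, and a fixed `seed` makes runs bit-identical
  without touching the caller's RNG stream.

The integrator is explicit Euler — the dynamics are monotone and
saturating, so no implicit solver is warranted — with a default step of
`dt = 0.02 h`. The step was chosen so that halving it moves every preset
endpoint titer by well under 0.5%; at coarser steps (e.g. 0.05 h) the
O(dt) error through exponential-phase biomass already shifts endpoint
acids by almost 1%, which blurs parameter-recovery tests.

Preset `scenario()` configurations (`glucose_20`, `glucose_40`,
`mix_14_8`, `glycerol_only`) were calibrated once against the bundled
endpoint tables so their noiseless endpoints land within ±15% of the
corresponding reference titers; their kinetic constants are fits to
endpoints only and carry no biological meaning.

What the generator does *not* emulate — and what passing tests therefore
do not certify about real data: product inhibition and butanol toxicity,
gas stripping and H2/CO2 evolution, pH feedback on the phase switch
(switching is a fixed time, not a pH trigger), correlated or
heteroscedastic measurement error, replicate-to-replicate biological
variance, and any genotype-specific regulation. Analyses of real
fermentations inherit none of these assumptions — the balance engine only
ever sees concentrations — but parameter-recovery results quoted from the
simulator should be read as software verification, not biology.

## Test design and problem sizes

Property tests run on generated random records (100 for the
composition/aggregation equivalence, 20 for scale invariance) under fixed
seeds; simulator checks use the four presets plus a 50-replicate
noisy-recovery experiment (`noise_sd = 0.15 g/L`), sizes at which the
whole suite completes in well under two minutes on a single CPU while the
Monte-Carlo standard error is small enough to detect a meaningful bias.
Reference-value checks compare recomputed metrics to printed values at
the precision the source tables carry (two decimals), with molar-row
tolerances of order 0.1–0.3 mM reflecting the propagation of that input
rounding.

## Known limitations

* The redox ledger covers the glucose/glycerol IB scheme; it is not a
  genome-scale stoichiometric model, does not track ATP or H2, and
  applies no flux optimisation.
* Replicate standard deviations in source tables pass through as metadata
  only; no inference on error bars is attempted.
* The 1,3-propanediol coefficient is an extrapolation (see above) and is
  excluded from any reproduced reference number.
* Whether per-C-mole plots should be mol/C-mol or C-mol/C-mol is genuinely
  ambiguous in the field; both are provided, mol/C-mol is the default.
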