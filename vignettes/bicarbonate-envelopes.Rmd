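---
title: "Bicarbonate-constrained production envelopes for 3-HP in yeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bicarbonate-constrained production envelopes for 3-HP in yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxenv)
library(ggplot2)
```

## The question the package answers

3-hydroxypropionic acid (3-HP) is made in engineered *Saccharomyces
cerevisiae* through the malonyl-CoA reductase (MCR) route: acetyl-CoA
carboxylase (Acc1) fixes one bicarbonate ion into each malonyl-CoA, and two
NADPH-dependent reductions turn malonyl-CoA into 3-HP. Every mole of product
therefore requires a mole of HCO3-. Because cytosolic inorganic carbon at
near-neutral pH is mostly bicarbonate but its *supply* is limited to what
carbonic anhydrase can form from metabolic CO2 (plus whatever the medium
provides), the attainable 3-HP yield is a function of bicarbonate
availability, not only of carbon, redox and ATP balances.

`fluxenv` quantifies that dependence with constraint-based analysis:

* flux balance analysis (FBA) on a stoichiometric model, `max c'v` subject
  to `S v = 0`, `lb <= v <= ub`;
* a production envelope: at fixed glucose uptake, growth rate is swept from
  0 to its maximum and product secretion is minimised/maximised at each
  point, once per bicarbonate availability setting;
* overlay of measured fermentation endpoints (titre, glucose consumed,
  biomass) onto the same yield plane.

## Bicarbonate availability: two modes

The bicarbonate constraint enters in two distinct ways, both normalised to
the glucose uptake rate:

* **formation cap** (`cap_bicarbonate_formation()`): an upper bound
  `ratio x |v_glc|` on the carbonic-anhydrase-type CO2 -> HCO3- reaction.
  This emulates the *native* supply: the cell can only convert the CO2 its
  own metabolism releases.
* **uptake allowance** (`enable_bicarbonate_uptake()`): a lower bound
  `-ratio x |v_glc|` on the bicarbonate exchange, emulating medium
  supplementation through a transporter. The one-to-one
  bicarbonate:glucose boundary is `ratio = 1` in this mode.

Both are swept by `compute_envelope()` because they answer different
questions: the formation cap bounds what an unsupplemented culture can do,
the uptake allowance bounds what supplementation can add.

## The bundled core model

`build_core_model()` returns a curated, hand-balanced yeast central-carbon
network (about 30 reactions, one lumped compartment). It is **not** a
reduction of the Yeast8 genome-scale model and is not claimed to reproduce
Yeast8-specific values (such as its 0.781 g/g theoretical maximum); it is
built so that every flux the analysis reasons about is an individually
boundable reaction:

* lumped glycolysis (net 2 ATP + 2 NADH per glucose), oxidative PPP with
  CO2 release and 2 NADPH, a non-oxidative PPP return, and the
  phosphoketolase (PK) bypass X5P -> acetyl-phosphate + GAP ->
  acetyl-CoA, which supplies cytosolic acetyl-CoA without CO2 loss;
* the PDH bypass (Pdc/Ald6/Acs) as the native cytosolic acetyl-CoA route,
  paying the activation cost (lumped as 2 ATP) and releasing CO2;
* pyruvate oxidation lumped as PDH + TCA: 4 NADH + 1 FADH2 + 1 ATP per
  pyruvate, so that full oxidation of glucose yields 4 substrate-level ATP
  plus 10 NADH + 2 FADH2;
* oxidative phosphorylation parameterised by a single P/O ratio applied to
  both NADH and FADH2. With the yeast-typical P/O = 1 the model yields
  exactly 16 ATP per glucose (4 substrate-level + 12 respiratory), and 22
  at P/O = 1.5 -- the audit `solve_fba(..., "ATPM", "max")` reproduces
  this by construction of the stoichiometry, not by fiat;
* carbonic anhydrase CO2 <-> HCO3-, Acc1, pyruvate carboxylase, and a
  malate-dehydrogenase/malic-enzyme loop that can transhydrogenate NADH to
  NADPH at ATP cost;
* an ethanol branch for the fermentative (Crabtree) regime;
* a biomass pseudo-reaction of Cmol composition CH1.8O0.5N0.2
  (24.63 g/Cmol, computed from the composition). Its coefficients are
  derived programmatically: carbon from glucose, nitrogen from ammonium,
  growth-associated maintenance (GAM) ATP, and H2O/H+ closure, so the
  reaction is elementally exact and flux 1 equals 1 g biomass/gDCW/h
  (i.e. the flux is the specific growth rate).

Defaults: P/O = 1 (the value the energy discussion assumes), GAM = 30 mmol
ATP/gDCW and NGAM = 0 mmol/gDCW/h. Maintenance energies are conventional
stoichiometric-modelling defaults -- the analysis itself never turns on
them, and NGAM = 0 keeps the zero-growth corner of the envelope a pure
product optimum. Glucose uptake is fixed at 1 mmol/gDCW/h in all sweeps, so
bicarbonate ratios read directly as mmol HCO3- per mmol glucose.

Species use charged BiGG-style formulas; `validate_elemental_balance()`
checks every internal reaction element-by-element, and because the biomass
reaction is exactly closed, carbon crossing the exchanges of *any* FBA
solution sums to zero (`carbon_exchange_balance()`), which the test suite
asserts as a property.

```{r core-audit}
m <- build_core_model()
audit <- fix_flux(m, "EX_glc", -1) |> fix_flux("BIOMASS", 0)
solve_fba(audit, "ATPM", "max")$objective_value  # mol ATP / mol glucose
```

## The LP engine and determinism

The package solves its LPs with an internal bounded-variable two-phase
revised simplex (`R/simplex.R`): Bland's smallest-index rule throughout (no
cycling), basis systems re-solved exactly at every iteration, feasibility
and optimality tolerances of 1e-9, and all infinite bounds capped at the
conventional 1000 mmol/gDCW/h so every LP is bounded. This favours
robustness and reproducibility over speed and is sized for core-model LPs
(tens to a few hundred reactions); genome-scale models load and edit fine,
but sweeping envelopes on them is slow with this engine. The engine is
validated in the test suite against an independent brute-force enumeration
of basic solutions on all small bundled fixtures and random LPs.

Optimal *values* are unique; optimal flux *vectors* are generally not. All
single-point fluxes the package reports come from `parsimonious_refine()`
(the minimal total |v| among the optima, via the standard irreversible
split), and ranges from `flux_range_at_optimum()`. This is a deliberate
convention: a different solver will reproduce the envelope values but not
necessarily any particular degenerate flux distribution.

Numerical edge handling: grid points that return infeasible near the growth
maximum are retried once with the growth rate relaxed by 1e-9 and otherwise
marked infeasible (never dropped); the growth grid is linear in growth
*fraction* so that different ratios (whose growth maxima differ) remain
comparable; and the envelope's yield axes are computed from species
formulas, not hard-coded molecular weights.

## What the sweep produces

```{r envelope, fig.width = 7, fig.height = 4.5}
mp <- add_3hp_pathway(m)
env <- compute_envelope(mp, envelope_spec(
  bicarbonate_ratios = c(0.25, 0.5, 1, Inf), n_growth_points = 21))
glance(env)
autoplot(env, strains = strain_endpoints())
```

At ratio 0 the product axis collapses to zero -- no bicarbonate, no
malonyl-CoA, no 3-HP. Caps below the unconstrained demand bind one-to-one:
the attainable molar yield equals the supplied ratio, which is the
analysis's central observation restated as an LP fact
(`bicarbonate_ratio_at_optimum()` reports the supply:glucose ratio at the
parsimonious optimum together with its FVA range).

`overlay_strains()` places endpoint measurements on the same plane (product
yield = titre/glucose, biomass yield = DCW/glucose, DCW imputed as
0.7 x OD600 when not measured) and classifies each against each ratio's
upper envelope with a 1e-3 g/g tolerance.

## The 3-HP pathway edit

`add_3hp_pathway()` adds exactly three reactions (MCR-C, MCR-N, secretion).
Choices where the source description is open:

* **Cofactor**: NADPH for both reduction steps by default (MCR chemistry);
  NADH is selectable because the stoichiometric description does not pin it.
* **Compartment**: cytosol, where malonyl-CoA and Acc1 live.
* **Secretion only**: the 3-HP exchange is bounded (0, +Inf); re-uptake and
  export energetics are outside the model's scope.
* For third-party models the species ids involved are arguments, since id
  schemes differ between reconstructions; the same applies to the role map
  used by `read_sbml()` (exact id, then annotation, then name regex, and a
  role that matches nothing stays unset rather than being guessed).

## Carbonate speciation

`species_fractions()`, `dissolved_co2()`, `bicarbonate_from_co2()` and
`speciate()` implement standard diprotic speciation with Henry's law.
Default apparent constants (pKa1 6.06, pKa2 10.33, kH 0.039 mol/(L atm),
pCO2 4.0e-4 atm, near 20 degrees C) are configuration with conventional
values, not assertions about any publication's constant set; activity and
ionic-strength corrections are out of scope. The frequently quoted
air-equilibrium pair (0.012 mM CO2, 0.26 mM HCO3- at pH 7.4) is internally
consistent with an apparent pKa1 of about 6.06, and the test suite checks
exactly that consistency rather than asserting the constants.

```{r speciation}
speciate(carbonate_params(ph = 7.4))
```

## The synthetic strain generator

`generate_strain_table()` emulates shake-flask endpoints: titre and DCW are
true yields times glucose with multiplicative Gaussian noise of a given CV,
under an explicit seed (no global random state). It emulates endpoint
*measurement* noise only -- no time courses, no correlated errors between
titre and biomass, no batch effects, and no biology linking yield to growth
rate. Passing the recovery tests (noiseless tables map back to the truth
exactly; 200 strains at 5% CV recover mean yields within 1%) therefore
shows the overlay arithmetic is correct, not that real fermentation data
are this well behaved.

## Problem sizes and runtimes

The shipped tests and the acceptance script run envelopes at 5-21 growth
points over 2-4 ratios on the ~35-reaction core model (a few hundred LPs,
seconds on one CPU). Genome-scale sweeps were intentionally left out of the
test surface: they need an external model file and a faster LP backend.

## Known limitations

* The core model is a lumped fixture; yields computed on it are
  internally consistent but not Yeast8 numbers. Reproducing
  reconstruction-specific values requires loading that reconstruction via
  `read_sbml()`.
* One compartment: mitochondrial/cytosolic pool separation is represented
  only through the route structure (TCA lumped away from the cytosolic
  acetyl-CoA pool), not through transporters.
* No thermodynamics, enzyme kinetics or regulation: favourability claims
  about bicarbonate versus CO2 fixation are outside what stoichiometry can
  show, and engineered regulatory changes enter only as bounds the user
  sets.
* SBML support is read-only and limited to the FBC constructs FBA needs.
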