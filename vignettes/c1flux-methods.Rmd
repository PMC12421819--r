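---
title: "Modelling synthetic formatotrophy and methylotrophy with c1flux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling synthetic formatotrophy and methylotrophy with c1flux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c1flux)
```

## The problem

Engineered *Pseudomonas putida* strains can grow on formate or methanol as
the sole carbon and energy source through the reductive glycine pathway
(rGlyP): formate is activated onto tetrahydrofolate and reduced to
5,10-methylene-THF (module M1), condensed with CO~2~ and NH~3~ by the
glycine cleavage system running in reverse (M2), and extended to serine and
deaminated to pyruvate (M3). Energy comes from oxidising additional C1
substrate — formate via a heterologous formate dehydrogenase (the energy
generation module, EGM), or methanol via an NAD^+^-dependent methanol
dehydrogenase whose product formaldehyde is further oxidised to formate.

Three quantitative questions recur when characterising such strains, and
c1flux implements one module for each:

1. **Flux balance analysis** on a curated core model: what growth rate,
   yield and flux partition does the stoichiometry predict at a measured
   uptake rate?
2. **^13^C atom-fate simulation**: which positional isotopomers of the
   reporter amino acids (Gly, Ser, Ala, Asp, Glu) does each candidate
   TCA-replenishment route produce under a given tracer design, and which
   route best explains measured mass-isotopomer distributions (MIDs)?
3. **Kinetics**: estimating the specific growth rate
   $\mu$, doubling time $DT = \ln(2)/\mu$, specific uptake rates
   $q_S = \frac{1}{X}\frac{\Delta S}{\Delta t}$ and biomass yields
   $Y_{X/S} = \Delta X / \Delta S$ from OD~600~ and substrate time series.

A fourth module corrects raw GC-MS fragment MIDs for natural isotope
abundance, and a fifth generates synthetic datasets so the whole pipeline
is testable without measurements.

## The core model

`build_core_model()` assembles ~40 reactions: C1 uptake, the THF cycle
(lumped into one M1 reaction: formate + ATP + NADPH → methylene-THF), the
reverse glycine cleavage system, serine hydroxymethyltransferase and
serine deaminase, formate/methanol/formaldehyde dehydrogenases, acetate
activation, pyruvate dehydrogenase, pyruvate carboxylase, a full TCA cycle
with glyoxylate shunt, the glycine oxidase branch (ThiO), malic enzyme,
transhydrogenase, lumped oxidative phosphorylation, ATP maintenance,
lumped gluconeogenesis and a biomass drain. Strain presets (`rG1`,
`rG1.T`, `rG.F`, `rG.M`) encode the published genotypes as knockouts
(bounds fixed to `[0, 0]`) and module additions.

Deliberately lumped parts: gluconeogenesis, the pentose-phosphate pathway
and amino-acid anabolism appear only as precursor drains, because the
isotope logic of the study concerns only the five reporter amino acids,
whose skeletons are taken one-to-one from their keto-acid precursors
(Ala ← pyruvate, Asp ← oxaloacetate, Glu ← 2-ketoglutarate, Ser/Gly
direct).

### Energy and biomass parameters

All are documented defaults, **not measured values**, and are deliberately
chosen once, a priori:

| parameter | default | unit | note |
|---|---|---|---|
| P/O (NADH) | 1.5 | ATP/NADH | aerobic respiration |
| P/O (FADH~2~) | 1.0 | ATP/FADH~2~ | |
| GAM | 40 | mmol ATP/gCDW | growth-associated maintenance |
| NGAM | 0.92 | mmol ATP/gCDW/h | non-growth maintenance |
| biomass | see `biomass_coefficients()` | mmol/gCDW | standard precursor-demand tables, upper metabolism lumped into 3-carbon units |

With these defaults the rG.F model at the measured formate uptake
($q_F = 18.5$ mmol gCDW^-1^ h^-1^) predicts $\mu \approx 0.115$ h^-1^, a
theoretical yield of ~6.2 gCDW per mol formate, and routes ~80% of formate
through Fdh and ~10% through glycine — genome-scale analyses of such
strains report the same qualitative partition. None of the defaults were
tuned to reach those numbers.

A note on degenerate inputs: with zero substrate and NGAM enforced the LP
is *infeasible* (the cell cannot even pay maintenance), which the solver
reports as a status rather than $\mu = 0$; pass `maintenance = 0` to
recover the bare "no carbon, no growth" limit.

### The LP solver

No linear-programming package ships with the supported R stack, so the
package carries a dense two-phase tableau simplex (`solve_lp()`),
adequate for these tens-of-variables problems and verified in the test
suite against closed forms, a vertex-enumeration oracle and (at
development time) an external HiGHS solve of the exported matrices.
Reversible reactions are split into non-negative forward/backward
variables; alternate optima are resolved for reporting by a second LP
minimising total $|v|$ at the fixed optimum (parsimonious FBA), making
flux maps deterministic. Feasibility tolerance is 10^-9^; map exports
round to 3 significant figures.

## Isotope simulation

Carbon indexing is 1-based with fixed conventions: glycine C1 is the
carboxyl derived from CO~2~ and C2 the methylene-THF carbon; pyruvate
C1–C3 inherit serine C1–C3; the pyruvate-carboxylase CO~2~ enters
oxaloacetate at C4; acetate C1/C2 map to acetyl-CoA C1/C2; and
citrate/isocitrate carbons are ordered [OAA C1..C4, AcCoA C1, C2], with
the isocitrate-dehydrogenase CO~2~ taken from the OAA C1 carboxyl — the
classical result that the first-turn decarboxylations release
oxaloacetate-derived, not acetate-derived, carbon.

Each metabolite pool carries a probability vector over its $2^n$
positional isotopomers. `simulate_labeling()` iterates the balance
synchronously — every non-source pool is replaced by the flux-weighted
mixture of the label patterns its producing reactions generate, assuming
independent substrate pools — until the largest change falls below
10^-10^ (cap 10 000 sweeps; non-convergence is reported with the
residual). Succinate and fumarate are averaged with their carbon-reversed
distributions (rotational symmetry). Full positional enumeration was
chosen over an EMU decomposition because no metabolite here exceeds six
carbons, and the direct representation is easy to verify against the
brute-force oracle bundled with the tests.

The assimilated CO~2~ pool defaults to the headspace label
(`co2_reassimilation = 0`), matching cultivation under a 10% (vol/vol)
CO~2~ excess; the parameter mixes in flux-weighted internally released
CO~2~ to reproduce the minor enriched fractions seen experimentally.
Tracer purity defaults to 0.99 (commercial tracer purities are rarely
reported alongside labelling data); all dominant-isotopomer predictions
are purity-robust down to 0.99 by a property test.

### Route hypotheses

`predict_fingerprints()` compares three canonical routes that replenish
oxaloacetate: full cyclic TCA turnover, glycine oxidation plus malate
synthase, and anaplerotic pyruvate carboxylation. Each hypothesis is a
unit-flux pattern over its route reactions on top of the always-active
rGlyP backbone; only branch-point flux *ratios* matter for the fixed
point. Two simplifications are documented design choices: acetyl-CoA
comes entirely from acetate in mixotrophic scenarios (acetate is the
dedicated energy source once the glyoxylate shunt is deleted) and
entirely from pyruvate otherwise; and the Fdh:assimilation flux ratio is
fixed at 4:1 in formatotrophic scenarios, which only matters when CO~2~
reassimilation is switched on. `discriminate_hypotheses()` scores
observed against predicted MIDs by summed squared differences — a
deliberate formalisation of what is otherwise a qualitative visual
comparison.

One known mismatch: under ^13^C-formate + ^12^CO~2~, strict atom
accounting on the anaplerosis route gives a dominant M+4 glutamate
(oxaloacetate M+2 plus doubly labelled acetyl-CoA), whereas measured
glutamate pools are reported dominantly M+2. No single route reproduces
that observation without invoking unlabelled pre-existing biomass; the
simulator reports the atom-accounting answer and leaves the discrepancy
visible.

## Natural-abundance MID correction

Derivatized fragments (TBDMS chemistry, [M−57]^+^ ions at m/z 260, 246,
390, 418 and 432 for Ala, Gly, Ser, Asp, Glu) contain the complete
amino-acid backbone plus reagent atoms. The correction matrix convolves
the isotope distributions of all *non-tracer* atoms — reagent C, H, N, O,
Si and the non-backbone carbons — while excluding natural ^13^C of the
backbone (tracer) carbons, the standard convention for this workflow.
Fragment elemental formulas are editable defaults: fragment masses alone
under-determine the correction, and published workflows typically cite
correction software rather than printing formulas. The matrix is
rectangular: rows extend beyond the tracer mass shifts until ≥ 99.9% of
the heaviest column's natural envelope is captured, because silicon's
+1/+2 isotopes push substantial signal above M+n. Correction solves
$C x \approx \mathrm{raw}$ by non-negative least squares (via quadprog)
— robust to the truncated mass window where plain inversion is not — and
renormalises, reporting the residual.

## Kinetics

$\mu$ is the slope of $\ln(\mathrm{OD})$ against time over an exponential
window selected as the maximal-length sliding window with $r^2 \ge 0.99$
(growth-physiology reports rarely state their windowing rule; this one is
the package's choice), then *refined* by trimming an endpoint while its
residual is > 2.2 interior standard deviations — without the refinement
the maximal window absorbs lag/stationary corner points and biases $\mu$
low by several percent. On noiseless data the refinement recovers $\mu$
exactly. $DT = \ln(2)/\mu$ holds identically. The aggregate $q_S$ divides
$\mu$ by the slope of biomass against substrate concentration (units
cancel: mM is mmol L^-1^); per-interval estimates use the centred average
biomass between sampling points. OD→CDW conversion uses a strain-specific
factor, default 0.4 gCDW L^-1^ OD^-1^ (documented, not measured).

## Synthetic data: what it emulates, what it does not

`generate_growth_run()` produces OD and substrate tables with lag,
exponential and stationary phases; stationary onset is substrate
exhaustion through $Y_{X/S}$, and pre-noise tables satisfy
$\Delta X = Y_{X/S}\,\Delta S$ exactly. Noise is multiplicative
log-normal on OD and MIDs (2%) and additive Gaussian on concentrations
(0.5 mM) — levels chosen once to match the order of magnitude of the
reported replicate standard deviations. Regime defaults state the
measured world: formatotroph $\mu = 0.0248$ h^-1^, $q_F = 18.5$, 80 mM
formate; methylotroph $\mu = 0.0288$ h^-1^, $Y_{X/S} = 4.49$, 300 mM
methanol; mixotroph $\mu = 0.0603$ h^-1^, $q_F = 12.9$, 60 mM formate +
20 mM acetate. Because $\mu$, $q_S$ and $Y_{X/S}$ are tied by mass
balance, each regime pins two of the three and derives the third — the
published formatotroph values (18.5, 1.38, DT 27.9) are not exactly
mass-balance consistent, so the recovered third quantity sits within a
few percent of, not exactly at, its printed value.

What a green test does **not** establish: the generator knows nothing of
diauxie, pH drift, evaporation, CO~2~ limitation, instrument saturation
at high OD, chromatographic artefacts, or the unlabelled pre-existing
biomass fraction that real labelling experiments carry. Recovery tests
certify the estimators against the stated noise model only.

## Other design decisions

* Configs and scenario files are JSON (`jsonlite`); no YAML parser is
  available in the supported stack.
* Exchange fluxes are uptake-positive, so flux maps normalised to
  `uptake = 100` read directly as percentages.
* Methanol oxidation is modelled as methanol → formaldehyde → formate
  with one NADH per step; which native activity oxidises the
  formaldehyde in vivo is left open, so the step is generic.
* The genome-scale SBML import reads the Level-3 FBC subset only and is
  intended for reproducing full-model predictions when a reconstruction
  is available locally; no genome-scale model is bundled, and the
  package's dense simplex is not sized for 2000+ reaction models.
* `dominant_isotopomer()` breaks MID ties toward the lower label count
  and flags the tie.

## Limitations

No thermodynamic constraints, no regulation, no flux-variability or
dynamic FBA, no continuous ^13^C-MFA flux regression, no non-stationary
labelling dynamics, and no modelling of promiscuous glycine
oxidase/aminotransferase activities. The core-model FBA numbers are
analogues of, not substitutes for, genome-scale predictions: with the
shipped defaults they land within ~10–20% of the published full-model
values on formate and further away for the methylotroph flux partition,
which is sensitive to the lumped energy stoichiometry.
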