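---
title: "Methods: thermodynamics, isotopes, zonation and succession of the sedimentary methane cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermodynamics, isotopes, zonation and succession of the sedimentary methane cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedmeth)
library(dplyr)
```

This vignette documents the models behind `sedmeth`, the choices made where
the design was genuinely open, and what the synthetic test conditions do and
do not establish about real data.

## The thermodynamic model

Six catabolic reactions span the sedimentary methane cycle as analysed here:
hydrogenotrophic CO₂ reduction, aceticlastic methanogenesis, methanol
disproportionation, H₂-dependent methyl reduction, anaerobic acetate
oxidation (AAO), and sulfate-dependent anaerobic methane oxidation (AOM).
Each is evaluated as

$$\Delta G_r = \Delta G_r^0(T,P) + RT\ln Q_r$$

with R = 0.008314 kJ mol⁻¹ K⁻¹. The standard-state correction uses the
integrated Gibbs–Helmholtz relation with constant reaction enthalpy and a
linear pressure term,

$$\Delta G_r^0(T,P) = \Delta G_r^0\frac{T}{T_{ref}}
  + \Delta H_r^0\Big(1-\frac{T}{T_{ref}}\Big)
  + \Delta V_r^0\,(P-P_{ref})\times10^{-4},$$

which is accurate to well under 1 kJ mol⁻¹ for the cold (< 30 °C), shallow
(< 100 bar) conditions of margin porewaters; no heat-capacity or
compressibility terms are carried. Formation properties ship as an editable
TSV (`inst/extdata/thermo_constants.tsv`) of standard 25 °C aqueous
standard-state values, deliberately exposed as auditable inputs rather than
hard-coded constants.

Activities are fixed-coefficient: a = γ·c with γ(HCO₃⁻) = 0.532,
γ(CH₄) = 1.24, γ(SO₄²⁻) = 0.104, γ(HS⁻) = 0.685, γ(H₂) = γ(CH₄) and
γ(acetate) = γ(HCO₃⁻) — coefficients appropriate for seawater-like ionic
strength. No ionic-strength model (Debye–Hückel, Pitzer) is applied; the
coefficients are data, not derived quantities. Three conventions deserve
explicit statement:

* **Proton.** a(H⁺) = 10^−pH. (Any reading that equates an activity with a
  pH *value* is dimensionally impossible; the negative-log reading is the
  only coherent one.)
* **DIC.** Measured DIC is treated as bicarbonate. At porewater pH of
  7–8 bicarbonate is ≥ 90 % of DIC, so the error in ln a is below 0.1 —
  small against scenario uncertainty in H₂. Full carbonate speciation is
  intentionally out of scope.
* **Methanol.** γ = 1 applied to the molar concentration, so methanol
  scenarios sweep actual concentrations. A unit-activity mode (methanol
  pinned at a = 1 regardless of concentration) is available by setting the
  species' `phase_rule` to `fixed_activity` in the constants table; the
  concentration-based default is what makes a methanol concentration sweep
  meaningful at all.

When temperature or pressure are not measured, temperature defaults to the
site bottom-water value (278.15 K if no metadata) and pressure to the
hydrostatic approximation 1.013 + 0.1013·(water depth + sediment depth, m)
bar.

### Consistency structure

The reaction set is internally dependent: AAO + CO₂ reduction equals
aceticlastic methanogenesis, and four methyl reductions minus one CO₂
reduction equals methanol disproportionation. `hess_check()` evaluates both
cycle residuals under arbitrary conditions; they must vanish to machine
precision because every shared activity term cancels exactly. This audit is
independent of whether any individual energy is *correct* — it verifies the
stoichiometric and algebraic integrity of the implementation, which is why
the test suite also compares every energy against a term-by-term
re-computation on randomized conditions.

## Scenario sweeps and the H₂ window

H₂, methanol and sulfide are rarely measured in porewater, so reactions
containing them are evaluated at assumed lower and upper in situ extremes:
H₂ 0.1 and 10 nM (spanning sulfate-reducing to methanogenic sediments),
methanol 1 nM and 1 μM, HS⁻ 1 nM and 10 mM. Sweeps evaluate only these
endpoints by default — the energy is linear in the log of each assumed
activity, so the endpoints bound the range — with dense grids available
through the window and crossover functions.

Because ΔG(CO₂ reduction) = C_MG − 4RT·ln a(H₂) and
ΔG(AAO) = C_AAO + 4RT·ln a(H₂), the H₂ range in which both are exergonic is
closed-form: a_min = exp(C_MG/4RT), a_max = exp(−C_AAO/4RT), with equal
energies at exp((C_MG − C_AAO)/8RT). The implementation uses these exact
roots; the tests confirm them against a 10⁶-point log-grid search. The same
linearity makes the per-methanol energy difference between
disproportionation and methyl reduction equal to −ΔG(CO₂ reduction)/4, so
the methylotrophic pathway crossover sits exactly at the H₂ concentration
where CO₂ reduction is at equilibrium — one crossover, independent of the
methanol concentration.

Energies are classified against a biological energy quantum of −10 kJ per
mol reaction (configurable). The boundary convention is that ΔG = 0 counts
as exergonic and ΔG exactly at the BEQ counts as beyond it; the boundary
rules only matter for values printed exactly on the thresholds.

## Isotope fractionation

The fractionation factor convention is substrate over product,
α = (δ¹³C-DIC + 1000)/(δ¹³C-CH₄ + 1000), which exceeds 1 when methane is
isotopically depleted; CO₂-reduction-dominated systems show α ≈ 1.05–1.09.
`estimate_alpha_profile()` summarises α and the permil offset per
geochemical zone, with the methanic zone as the headline: under
CO₂-reduction dominance the MZ offset is near constant, and the per-zone
mean of per-depth α is the estimator. No Rayleigh distillation model is
fitted — the quantity of interest is a fixed offset, not a closed-system
evolution — and no AOM enrichment model is included, which is why α
estimates from SMTZ samples should be interpreted with caution.

## Geochemical zonation

Operational definitions, configurable because transition boundaries are
conventionally drawn by eye on profile figures:

* **BZ**: depths within the site's macrofaunal *reworking* depth (not the
  shallower ventilation depth — reworking is what homogenises the solid
  phase that community samples come from). Sites without macrofauna have no
  BZ.
* **SMTZ**: from the shallowest depth with CH₄ ≥ 0.1 mM down to the deepest
  depth, before sulfate first drops below 0.5 mM, at which SO₄²⁻ still
  meets that threshold. Using the *first* downward crossing makes the
  bottom boundary robust to noisy re-exceedances in an otherwise
  sulfate-free methanic zone.
* **SZ** between BZ and SMTZ; **MZ** below the SMTZ. When methane never
  reaches its threshold there is no SMTZ and no MZ; when sulfate depletion
  and methane onset fail to form a contiguous interval by more than one
  sampling step, the profile is rejected with a diagnostic rather than
  silently labelled.

Both thresholds are monotone by construction: raising the methane threshold
can only deepen the SMTZ top, raising the sulfate threshold can only
shallow its bottom.

## Community succession

Absolute abundances are qPCR totals × per-sample read fractions, computed
from raw counts without rarefaction — the absolute transform already
conditions on library size, and rarefaction would only discard reads.
Below-detection qPCR values propagate as missing and are excluded from
means, never imputed as zero. Trend classification merges BZ and SZ (their
communities overlap strongly) and assigns each taxon to the zone group with
the highest mean abundance, provided that mean reaches 10³ copies g⁻¹ and a
two-sided, tie-corrected Wilcoxon rank-sum test against at least one other
group is significant at 0.05; everything else is "ubiquitous rare". The
10³ copies g⁻¹ rarity floor is this package's operational choice for "only
low average abundances" — roughly the qPCR quantification limit in sediment
extracts. The rank-sum and Spearman statistics are implemented in-package
(normal and t approximations, tie-corrected) and validated against the
reference implementations in `stats`; Bray–Curtis and Pielou evenness are
validated against `vegan`.

## The synthetic stations

The generator emulates four margin stations along a water-depth and
trophic gradient, because that is the regime in which all of the above is
scientifically meaningful:

| preset | water depth | reworking | SO₄ penetration | CH₄ max | α (MZ) |
|---|---|---|---|---|---|
| S1 | 586 m | 8 cm | beyond core (> 400 cm) | background only | — |
| S2 | 319 m | 40 cm | 95 cm | 4 mM | 1.080 |
| S3 | 43 m | 35 cm | 75 cm | 3 mM | 1.080 |
| S4 | 37 m | none | 20 cm | 5 mM | 1.085 |

Shapes are the simplest ones consistent with observed margin profiles:
linear sulfate decline below the irrigated interval, logistic methane
onset, saturating DIC, Gaussian acetate/formate peaks, piecewise-linear
δ¹³C-DIC through surface/minimum/deep anchors with a steep recovery
completing ~5 cm below the transition bottom (the upper-MZ DIC pool is
dominated by methanogenic CO₂ consumption, which drives δ¹³C-DIC positive
quickly), and MZ methane tied to DIC through the true α. S4's α of 1.085
follows from its own anchors (deep δ¹³C-DIC of +22 ‰ with methane near
−58 ‰). Noise is Gaussian per analyte (1 ‰ on δ values, relative 5 % on
methane), clipped at zero, fully seeded. Measured methane is additionally
capped at a 3 mM degassing ceiling to mimic outgassing during core
recovery; the cap is recorded as metadata and never applied to the stored
truth. Ground truth (zone boundaries from the noise-free skeleton, true α,
taxon categories) is stored alongside every generated table.

The community generator assigns 15 % of taxa to each of the three trend
categories and the remainder to the ubiquitous-rare class (relative weight
0.02), gives each trend taxon a 10^`effect_log10`-fold weight increase in
its peak zone group (default effect 3, matching observed 2–4
order-of-magnitude increases), draws reads from a Dirichlet-multinomial at
10⁴ reads per sample, and draws mcrA totals log-normally around zone-group
means of 10^4.5, 10^(4.5+effect/3) and 10^(4.5+effect/2) copies g⁻¹
(10^4.5/10^5.5/10^6 at the default effect) so that the null model
(effect = 0) is genuinely structureless. 16S totals are log-normal around
10^8.5, giving mcrA:16S ratios in the observed 10⁻⁵–10⁻² range.

**What passing tests show — and what they do not.** The synthetic
conditions verify algebraic exactness (cycle closure, window roots,
sensitivity slopes), statistical calibration (α recovery to ±0.005 at 1 ‰
noise, ≥ 90 % trend-category recovery at effect 3) and end-to-end
determinism. They do not validate the formation constants against
measurements, nor the fixed activity coefficients outside seawater-like
ionic strength, nor zonation behaviour under non-monotone (e.g. brine- or
seep-influenced) profiles, nor classifier performance under compositional
artefacts the Dirichlet-multinomial does not produce (chimeras, primer
bias, cross-talk).

## Numerical choices and degenerate inputs

* Zero measured concentrations are log-singularities: the quotient refuses
  them by name; profile sweeps treat them as missing for the affected
  reaction and skip the row with a warning (a sulfate-free methanic-zone
  depth simply contributes no AOM row).
* Window endpoints are analytic, so the |ΔG| < 10⁻⁶ kJ root criterion is
  satisfied to rounding error; `exists` is the strict inequality
  h2_min < h2_max.
* Pielou evenness is undefined for richness ≤ 1 and reported missing, not
  zero. Zone groups with fewer than two samples are skipped in rank-sum
  testing and flagged.
* All randomness is seed-derived; `run_pipeline()` output is byte-identical
  across invocations with the same seed, and the manifest records seed,
  thresholds and package version.

## Problem sizes

The shipped tests and the acceptance script run the four stations at their
native grids (40–60 depths each, 177 depths total), 100-replicate noisy
zonation checks, 200-replicate isotope Monte-Carlo at 10 MZ depths, a
200-taxon community simulation over ~60 samples, and 50–100 randomized
thermodynamic conditions per property — sizes at which every statistical
criterion is comfortably powered while a full run stays within minutes on
one CPU.

## Known limitations

No reactive-transport or kinetic modelling; no diffusive flux estimates; no
carbonate-system or gas-solubility solver; no NMDS/PERMANOVA (standard
ordinations are available directly from `vegan` on the Bray–Curtis matrix
this package produces); formate is carried in profiles but no formate
reaction is evaluated, as none is in the built-in set. The interface is the
R API and `run_pipeline()`; there is no shell CLI.
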