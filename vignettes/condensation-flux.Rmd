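---
title: "Deriving the in vivo formaldehyde-THF condensation rate from growth phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving the in vivo formaldehyde-THF condensation rate from growth phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c1flux)
```

## The problem and the model

Formaldehyde condenses spontaneously with tetrahydrofolate (THF) to give
5,10-methylene-THF, the metabolite from which all cellular one-carbon (C1)
moieties derive. Whether this uncatalysed reaction is fast enough in vivo to
matter for C1 assimilation cannot be read off in vitro kinetics, because the
cytosol is not a dilute buffer. The route this package implements infers the
in vivo rate indirectly, from growth: in an *E. coli* strain whose two native
routes to 5,10-methylene-THF (serine hydroxymethyltransferase, glycine
cleavage) are deleted, any growth that depends on C1 biosynthesis is limited
by the condensation flux. The chain of inference is

1. **Phenotypic phase plane.** On a curated genome-scale stoichiometric
   model, fix the growth rate $\mu$ and minimise/maximise the flux $v$
   through the condensation reaction (`THFSPONT`,
   `thf_c + fald_c -> mlthf_c + h2o_c`) under the steady-state constraint
   $S\,v = 0$ and the medium's exchange bounds. The slope $s$ of the lower
   envelope (mmol gCDW$^{-1}$) is the stoichiometric demand for
   5,10-methylene-THF per unit of biomass formed.
2. **Intersection with measurement.** A measured growth rate
   $\mu \pm \sigma$ then gives the condensation flux
   $v = s\,\mu + c$, with $\sigma_v = s\,\sigma$ propagated linearly
   (the envelope is a line; the intercept $c$ is zero up to numerical
   noise and is flagged if it is not).
3. **Growth bound.** For a hypothetical organism assimilating formaldehyde
   as sole carbon source through the serine cycle, the same construction
   yields a much steeper slope $s' > 20$ mmol gCDW$^{-1}$; inverting it at
   the derived flux bounds the achievable growth rate,
   $\mu_{max} = (v - c')/s'$, and $\ln 2/\mu_{max}$ its doubling time.
4. **In vitro comparison.** The volumetric rate law
   $k_{fwd}\,[\mathrm{HCHO}]\,[\mathrm{THF}]\,[\mathrm{H^+}]$ with
   $k_{fwd} = 8.7\times10^{8}\ \mathrm{s^{-1}M^{-2}}$, converted to
   mmol gCDW$^{-1}$ h$^{-1}$ through the intracellular biomass density,
   is compared with the in vivo flux as a fold difference.

Two measured growth conditions (thymidine medium, $0.036 \pm 0.006$ h$^{-1}$,
$n=18$; thymidine + methionine, $0.047 \pm 0.004$ h$^{-1}$, $n=18$) have
different slopes (methionine lowers the C1 demand), so deriving the *same*
flux from both is an internal consistency check, not a coincidence: the
package verifies $|v_{thy} - v_{thy+met}| \le \sigma_{thy} + \sigma_{thy+met}$.

## Model curation

`base_curation_recipe()` encodes, as an ordered list of declarative edits,
the adjustments that turn the iML1515 reconstruction into the C1-auxotroph
model: removal of reactions absent in vivo (POR5, GLYCK) or oxygen-sensitive
(PFL, OBTFL), removal of FTHFLi (direct THF charging with formate),
irreversibility of FTHFD/GARFT/AICART (no THF charging by nucleotide
degradation), a one-proton stoichiometry for the transhydrogenase THD2pp,
reversibility of the thymidine symporter THYMt3pp, knockouts of GLYCL and
GHMT2r mirroring the *gcvTHP* and *glyA* deletions, and addition of
`THFSPONT`. `serine_cycle_recipe()` adds, on top, the serine-cycle and
ethylmalonyl-CoA reactions and removes potential carbon-fixation shortcuts.

Choices the recipes had to make where the printed lists are silent:

* **THFSPONT is irreversible** and its flux is read as the *net*
  condensation rate (condensation minus 5,10-methylene-THF dissociation);
  no reverse reaction is added because no reverse constant is available.
* **FDH stoichiometry** is the standard cytosolic NAD-dependent formate
  dehydrogenase, `for_c + nad_c -> co2_c + nadh_c`.
* **GHMT2r is restored** (made reversible) by the serine-cycle recipe. The
  knockout models the engineered strain, but the hypothetical serine-cycle
  methylotroph needs serine hydroxymethyltransferase to condense glycine
  with 5,10-methylene-THF — it is the cycle's carbon-entry step; without it
  the formaldehyde-only model is infeasible.
* **SGAT1/SGAT2 are added reversible.** Aminotransferases are canonically
  reversible, and the assimilatory direction of the glycine-glyoxylate
  transamination is glyoxylate + glutamate → glycine + 2-oxoglutarate, the
  reverse of the direction in which the reaction is written.
* **THD2pp one-proton edit**: the periplasmic and cytosolic proton
  coefficients are both set to one, preserving the redox participants.

Edits are validated (removal targets must exist, additions must not), an
edit log is accumulated for provenance, and recipe application is
order-insensitive for both shipped recipes — asserted by applying them in
shuffled order in the tests.

## Media

`build_medium()` exposes the cultivation scenarios as exchange-bound maps.
Glucose uptake defaults to the conventional 10 mmol gCDW$^{-1}$ h$^{-1}$;
supplements (glycine, formaldehyde, thymidine, methionine, pantothenate)
default to an effectively unlimited 1000. The lower-envelope slope is
insensitive to these supply bounds (tested by doubling glucose uptake):
it reflects biomass stoichiometry, not carbon supply. Whether the
experimental formaldehyde uptake should be capped at the rate the ~100 µM
external concentration can sustain is unknowable from the data in hand; it
is left free, which is conservative for the slope. Exchanges of inorganic
species (gases, water, protons, minimal-medium salts) stay open in every
scenario; all other uptakes are closed.

## The LP kernel

No linear-programming backend is available among the package's allowed
dependencies, so the FBA engine carries its own dense two-phase simplex:
variables are shifted to be non-negative, upper bounds become slack rows,
artificial variables are pivoted out after phase 1 (so equality rows can
never be silently violated later), and pricing is Dantzig's rule with a
permanent fall-back to Bland's rule after fifty degenerate pivots, which
guarantees termination. Feasibility tolerance is $10^{-9}$, and every
optimum is re-checked against $\max|S\,v| \le 10^{-9}$ independently of the
solver's status — a solution failing that check is reported as a solver
failure, never as an optimum. The kernel is deterministic and
single-threaded. It is sized for the bundled toy models (tens of reactions,
milliseconds per LP); a genome-scale model is solvable but slow, and is in
any case an optional, user-supplied input.

## The toy oracle models

`gen_toy_model(b, scenario)` builds BiGG-dialect models whose phase-plane
slope is known analytically, so the entire pipeline can be verified against
exact answers:

* **auxotroph**: glucose feeds a linear pathway to a biomass precursor
  (10 units per unit growth, giving $\mu_{max}=1$ at the default glucose
  bound); biomass additionally consumes `b` C1 units per unit growth, a
  fraction of which (`met_share`, default $0.16/0.7$) are methyl groups
  that methionine can supply directly. The slope is exactly `b` on
  thymidine medium and `b (1 - met\_share)` with methionine — defaults
  0.7 and 0.54 mmol gCDW$^{-1}$, the values computed from the curated
  genome-scale model.
* **serine**: a miniature serine cycle (SHMT running toward serine, the
  SGAT transaminase couple, a lumped hydroxypyruvate→malate leg including
  the carboxylation, malate thiokinase, malyl-CoA lyase) builds biomass
  from acetyl-CoA, `b` per unit growth (default 20.8, the ratio of the
  derived flux to the derived growth bound); formaldehyde is the sole
  carbon source and ATP regeneration is a free closure reaction, since
  energy metabolism is not what this toy is for.

Both toys contain every curation target — mechanistically where the edit is
load-bearing (GLYCL, GHMT2r, THD2pp, THYMt3pp), as dead-end decoys
otherwise — so the real recipes apply to them unchanged, and the uncurated
toys reproduce the designed phenotypes (no growth without formaldehyde after
curation; no thymidine uptake before THYMt3pp is reversed). Seeded filler
pathways are dead ends that cannot carry steady-state flux, and therefore
provably never move the envelope (tested across seeds). A `C1WASTE`
reaction (5,10-methylene-THF hydrolysis to formate) separates the upper
envelope from the lower one, mimicking the C1-wastage the real network
allows.

The toy slopes are *calibrated constants of the study conditions*, not free
parameters: the genome-scale slopes are printed results, and the toys exist
to let every downstream step run against them exactly. With a local copy of
iML1515 the same recipes, media and phase-plane code run on the full
reconstruction (`c1_config(model_path = ...)`).

## Growth fitting, statistics, assay calibration

Exponential fits use OLS of $\log \mathrm{OD}$ against time — the
maximum-likelihood estimator of $N = N_0 e^{\mu t}$ under multiplicative
noise — over an automatically chosen window: all contiguous windows of at
least 4 points with OD in $[0.04, 0.5]$ (the photometer's reliable range
and the usual exponential regime) are scanned, the best $r^2$ wins, and the
longest window wins near-ties, so that noiseless exponentials are recovered
to machine precision regardless of windowing. A fit with $r^2 < 0.95$ or
$\mu \le 0$ is an error, not a number.

Group comparisons use the Welch unequal-variance $t$-test from summary
statistics (mean, SD, $n$); the equal-variance Student form is available
via `pooled = TRUE`. Welch is the default because nothing licenses assuming
equal variances across media; on the reported summaries both forms agree to
well within the reported inequalities ($p > 0.4$ for pantothenate,
$p < 10^{-5}$ for methionine).

The Nash assay calibration is an OLS line of absorbance on concentration
over the assay's linear 0–1 mM range, with a free intercept (reagent blanks
are nonzero); inversions outside the calibrated range are returned but
flagged.

## Unit conversions and the rate law

Rates are carried in SI (M, s) internally and converted at the interface:
a volumetric rate $r$ (M s$^{-1}$) corresponds to
$r \times 3600 / \rho \times 1000$ mmol gCDW$^{-1}$ h$^{-1}$ with
$\rho = 300$ gCDW L$^{-1}$ the intracellular biomass density. A pool
measured per culture volume per OD$_{600}$ converts to an intracellular
concentration via the 0.39 mgCDW mL$^{-1}$ OD$^{-1}$ biomass factor: the
23 pmol mL$^{-1}$ OD$^{-1}$ THF pool becomes 17.7 µM. $[\mathrm{H^+}]$ is
$10^{-7.5}$ M (31.6 nM) at the assumed cytosolic pH 7.5. Two acknowledged
approximations: the extracellular formaldehyde concentration (~100 µM
during growth) proxies the intracellular one, and the whole
THF + 5,10-methylene-THF pool is counted as free THF
(`free_thf_fraction = 1`, exposed as a parameter); both make the in vitro
rate an upper estimate, so the reported ~43-fold gap to the in vivo flux is
a lower bound on the discrepancy.

## Synthetic data

`gen_growth_curve()` produces lag → exact exponential → logistic
saturation with multiplicative lognormal noise (photometer behaviour);
`gen_formaldehyde_series()` reproduces the two observed regimes
(monotone accumulation towards ~1000 µM in non-growing cultures; rise to a
~100 µM plateau then stationary-phase decline in growing ones) with
matching Nash absorbances through a configurable linear calibration plus
truncated Gaussian noise. The generators are phenomenological shape
emulators meant to exercise parsers, fitting and calibration; they do not
model sarcosine-oxidation kinetics, formaldehyde toxicity, or biological
replicate structure beyond independent seeds. Passing tests on them
demonstrates correctness of the estimators under the stated noise model,
not robustness to everything real plate readers do. All generators are
bit-reproducible given their seed and restore the caller's RNG state.

## Numerical choices

* Phase-plane grid: 30 evenly spaced points from 0 to the FBA maximum;
  slope/intercept by OLS over the feasible lower envelope. OLS is robust
  to mild curvature near the feasibility edge, and the intersection uses
  the fitted line rather than the nearest grid point, decoupling results
  from grid resolution. The intercept is flagged when
  $|c| > 0.01\,s\,\mu_{max}$.
* LP tolerances: $10^{-9}$ for feasibility and the independent
  mass-balance check; simplex pricing tolerance $10^{-9}$.
* Degenerate alternate optima are irrelevant here: only the objective
  value and the min/max of the single target reaction are consumed.
* Problem sizes: toy models of 31–44 reactions, 30-point grids, 18
  synthetic replicates in the recovery study — the full analysis runs in
  about a second, the test suite in well under a minute.

## Known limitations

* The genome-scale reconstruction is not distributed with the package
  (size); the genome-scale slopes are therefore reproduced only when a
  local iML1515 file is supplied, and may drift a few percent across model
  releases. The serine-cycle slope is reported as a computed value checked
  against the $>20$ bound, since its exact value depends on release and
  medium closure details.
* The simplex kernel is dense; genome-scale LPs work but take minutes,
  not milliseconds.
* No gene–protein–reaction logic beyond reaction knockouts, no loopless
  or parsimonious FBA, no dynamic FBA, and no mechanistic modelling of
  the formaldehyde source reaction (sarcosine oxidase) — all outside the
  question this package answers.

## Reproducing the chain

```{r, eval = FALSE}
report <- run_c1_analysis(c1_config())
print(report)
```

The numbered scripts under `analysis/` run the same chain stepwise
(synthetic data → growth fits → curation → phase planes → derived rates)
and write their tables under `results/`.
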