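---
title: "Constraint-based analysis of antibiotic-producing networks with fluxscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of antibiotic-producing networks with fluxscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxscape)
library(dplyr)
```

## The model and its assumptions

A genome-scale metabolic reconstruction lists reactions with
stoichiometry, flux bounds and gene–protein–reaction (GPR) rules. Under
the pseudo-steady-state assumption — internal metabolite pools neither
accumulate nor deplete on the timescale of growth — any flux vector
$v$ must satisfy $S v = 0$ with $lb_j \le v_j \le ub_j$, where $S$ is
the $m \times n$ stoichiometric matrix. Metabolite concentrations
appear only through this balance; they are never stored or predicted.
Flux balance analysis (FBA) selects among the feasible states by
maximizing an objective reaction, conventionally the biomass assembly
pseudo-reaction whose flux is the specific growth rate $\mu$ (1/h).
All other fluxes are in mmol/gDW/h; by convention a negative flux on
an exchange reaction is uptake, positive is secretion.

Two further assumptions are inherited by everything downstream:

- **Optimality**: the cell (or the engineered objective) operates at an
  optimum of the stated LP. Trade-off questions are asked by
  constraining one objective and re-optimizing the other, not by
  weighting.
- **Boundedness**: media are expressed purely as uptake bounds on
  exchange reactions (`medium_spec()`); kinetics, regulation and
  dynamic re-allocation are out of scope.

## Alternate optima and the parsimonious representative

FBA objective values are unique; FBA flux *vectors* usually are not.
Any quantity read off a flux vector (an FSEOF profile, an activity
census) would otherwise depend on solver internals. This package
therefore reports the parsimonious representative everywhere: among
the vectors attaining the optimum, the one minimizing
$\sum_j |v_j|$ (`pfba()`). This removes thermodynamically meaningless
internal cycles and makes results reproducible across orderings and
solvers; it is recorded in the scan metadata
(`glance(scan)$flux_representative`). The trade-off: a parsimonious
vector is one defensible representative, not the unique truth, and
reactions whose support is confined to non-parsimonious optima will
show zero flux.

## The built-in solvers

No LP or MILP solver is available as an R dependency in this package's
target environment, so both are implemented here and treated as
first-class, tested code:

- a dense **bounded-variable two-phase primal simplex** (`solve_lp()`).
  Bland's smallest-index rule is used for both entering and leaving
  choices, so cycling is impossible; the basis system is re-solved
  densely at every iteration, trading speed for numerical hygiene.
  This is appropriate for the desk-scale networks the package
  generates (tens of reactions) and would not be the right tool for a
  1000-reaction genome-scale model.
- a **branch-and-bound MILP** over binary indicators (`solve_milp()`).
  A relaxation that merely *looks* integral is never trusted: with a
  big-$M$ of $10^3$ and an activation flux of $10^{-3}$, a binary at
  $1 - 10^{-6}$ passes any reasonable integrality tolerance while
  voiding its indicator constraint, so candidate incumbents are
  re-solved with all binaries pinned to their rounded values and
  rejected if that system is infeasible.

Numerical choices, fixed package-wide: solver pivot tolerance
$10^{-9}$; phase-1 infeasibility threshold $10^{-7}$; downstream
zero-flux threshold `FLUX_ZERO` $= 10^{-6}$ mmol/gDW/h (used for
"flux-carrying" censuses and for the FSEOF increase/sign tests);
integrality tolerance $10^{-6}$; infinite bounds clamped at
$\pm 10^{6}$ with solutions pressed against the clamp reported as
unbounded. The simplex-vs-vertex-enumeration and
MILP-vs-pattern-enumeration equalities are asserted in the test suite
on seeded random networks.

## Growth media and validation

`simulate_minimal_medium()` encodes the usual validation recipe:
salts opened at a non-limiting uptake of 10 mmol/gDW/h, the single
carbon source at its measured uptake, biomass maximized.
`simulate_complex_medium()` emulates a rich medium by opening each
amino-acid-style exchange at a common small uptake (default 0.015
mmol/gDW/h, a conventional stand-in when individual uptake rates are
unknown), pinning growth to its measured value (equality bounds via
`fix_flux()`), and maximizing the product synthesis rate.
`compare_growth()` is the Pearson product–moment comparison of
predicted versus observed growth across media.

The packaged `minimal_media_synthetic.tsv` illustrates the media file
format against the toy network; as its name and header state, its
"observed" column is synthetic, not literature data.

## The Pareto front

`compute_pareto()` traces the growth–production trade-off by the
stepwise recipe: (i) the minimal and maximal biomass flux (flux
variability on biomass alone), (ii) biomass fixed by equality bounds
at `n_steps` evenly spaced values spanning that range inclusive,
(iii) product maximized at each. Sweeping with the objectives
exchanged (`direction = "b_fixed"`) traces the same boundary and is
available for cross-checking. Defaults: `n_steps = 20` — the source
procedure says only "different steps", and 20 gives a smooth
piecewise-linear front at trivial cost on any model this package
targets. Fixing means equality (not a lower bound): that is what
"fixing the flux" denotes and what makes infeasible steps detectable;
such steps are recorded with their status, never dropped.

## FSEOF: enforced-objective flux scanning

The scan asks which reactions would need more flux if the cell were
forced to make more product while still growing as fast as possible:

1. fix the product rate at the measured base value, maximize biomass,
   record the parsimonious fluxes (baseline, step 0);
2. maximize the product alone for the theoretical maximum $v^\*$;
3. for $k = 1 \dots n$ (default $n = 10$ optimizations), fix the
   product at $base + k\,(v^\* - base)/n$ — strictly above base, with
   the endpoint included — and re-maximize biomass;
4. select reactions whose $|v|$ exceeds the baseline by more than
   `FLUX_ZERO` in at least one step, provided all fluxes above
   `FLUX_ZERO` share one sign (no direction change; the test is on
   $|v|$, so flipping a reversible reaction's written direction cannot
   change selection).

Where the enforcement semantics were genuinely open we fix the product
by equality rather than a lower bound — the two coincide whenever more
product only costs growth, and equality keeps each step's meaning
("the cell makes exactly this much") sharp; the choice is recorded in
`glance(scan)$enforcement`.

`filter_targets()` applies the three actionable-target exclusions:
gap-filled reactions (no gene to amplify; a reaction is gap-fill iff
its GPR is empty and it is not an exchange — the biomass
pseudo-reaction deliberately falls in this class too), exchange
reactions (modeling artifacts for nutrient import/export; internal
transporters are *not* excluded, since the exclusion exists to remove
boundary artifacts, not biology), and reactions with two or more
distinct genes (complexes and paralog alternatives, where the single
gene to amplify is ambiguous). Gene counts are unions over the
surviving single-gene rules, so a gene recurring behind several
reactions is counted once. `report_targets()` ranks survivors by the
least-squares slope of $|v|$ per enforcement step, ties broken by
reaction id.

## Expression integration: quartiles, GPR mapping, iMAT

Per time point, the first and third quartiles of the RPKM distribution
(type-7 linear-interpolation quantiles — the source does not name a
definition, so R's default is used and tested against hand values)
define lowly and highly expressed genes. Quartiles are computed over
the **whole** expression table by default, not only model genes,
matching the plain reading of "quartiles of the RPKM values"; restrict
the table first if you want the other convention. Gene values map to
reactions through the GPR with AND $\to$ min and OR $\to$ max — the
standard iMAT-family convention (a complex is limited by its scarcest
subunit; isozymes add alternatives). Reactions above Q3 are HIGH,
below Q1 LOW, everything else (including empty GPRs and rules broken
by genes missing from the table) MODERATE.

`imat()` then maximizes the number of satisfied calls — HIGH reactions
carrying at least $\varepsilon$ flux in either direction, LOW
reactions carrying none — subject to mass balance, bounds, and any
fixed fluxes (measured growth and production; when no growth was
observed, a token rate such as $10^{-10}$/h keeps maintenance
demands active while being numerically zero). $\varepsilon$ defaults
to 0.001 mmol/gDW/h: no activation threshold is stated by the source,
and 0.001 sits three orders of magnitude above the zero-flux threshold
while staying far below typical uptake scales. Big-$M$ constants are
derived per reaction from its own bounds, keeping the relaxation as
tight as the bounds allow. The reported flux vector is the
parsimonious representative *within* the optimal activity pattern, so
`census_active()` (total and per-subsystem counts of reactions with
$|v| >$ `FLUX_ZERO`) is deterministic.

## What the synthetic generator does and does not emulate

`generate_toy_model()` builds the smallest network in which every
pipeline question is non-trivial: one carbon exchange, a linear core,
a salt-fed cofactor branch used only by biomass, and a product branch
draining up to three distinct precursors (the malonyl-CoA-family
analogs) of which the last — the planted `CCR` step, echoing the
crotonyl-CoA carboxylase/reductase supply of ethylmalonyl-CoA — is
rate-limiting. Decoys give the FSEOF filters real work: an AND-ruled
supply (complex), a gene-less supply (gap-fill), an OR-ruled assembly
(paralogs), and the product exchange. All optima have closed forms
(`ground_truth`, `toy_max_product_at()`): with uptake $U$, yield $Y$,
total precursor stoichiometry $a$ and planted capacity $K$,
$\mu_{max} = UY$, $q_{p,max} = \min(K, U/a)$, and the carbon-limited
front is the line $\mu/Y + a\,q_p = U$ clipped at $K$. Default
parameters state a deliberately round world — uptake 10 mmol/gDW/h
(the conventional non-limiting bound), yield 0.1 gDW/mmol, capacity 2
mmol/gDW/h — chosen once for clean closed forms, not tuned to any
result.

`generate_expression()` draws planted-active genes from a high
log-normal component (default mean 200 RPKM) and the rest from a low
one (mean 2 RPKM, straddling the conventional RPKM > 10 expression
baseline), both with `noise_sd` on the log scale; the default 1.2
yields roughly 5% component overlap, i.e. a realistic but solvable
classification problem. Two boundary behaviors are intentional: at
`noise_sd = 0` every inactive gene sits exactly at Q1, so the strict
$< Q1$ rule makes no LOW call — zero noise means zero *wrong* calls,
with the HIGH side recovered exactly (provided active genes are fewer
than a quarter of the table) — and recovery degrades monotonically as
noise grows.

What a green test on this world does **not** establish: performance on
genome-scale models (the dense simplex is not sized for them),
correctness of any particular organism's reconstruction, RPKM
normalization quality, or biological validity of iMAT's
consistency-maximization premise. The generator has no growth-curve
dynamics, no sequencing-read noise model, and no correlation structure
between time points beyond the planted active sets.

## Known limitations

- The simplex and MILP are desk-scale by design; a genome-scale run
  needs an industrial solver behind the same interfaces.
- SBML support covers Level 3 `fbc` (v2) and the common Level 2
  COBRA conventions; exotic dialects (species-reference math,
  `fbc:strict` bound semantics) are not interpreted. Explicit
  gap-fill flags are not an SBML concept, so the flag is re-derived
  from the GPR on read.
- No thermodynamic (loopless) constraints, no quadratic objectives,
  no knock-out search, no dynamic FBA — all deliberately out of
  scope.
- Pareto fronts are two-objective only.

## A compact end-to-end run

```{r}
toy <- generate_toy_model(toy_model_spec(seed = 1))
model <- toy$model
glance(fba(model))

front <- compute_pareto(model, "BIOMASS", "EX_product", n_steps = 10)
glance(front)

scan <- fseof_scan(model, "EX_product", base_rate = 0.5, n_steps = 10)
report_targets(filter_targets(scan, model), model)

genes <- c(model$genes, sprintf("bg%03d", 1:40))
expr <- generate_expression(genes, toy$ground_truth$genes_product_mode,
                            noise_sd = 1.2, seed = 1)
cl <- classify_reactions(model, expr, "T3")
res <- imat(model, cl, fix = c(BIOMASS = 1e-10,
                               EX_product = toy$ground_truth$max_product))
glance(res)
census_active(res, model = model)
```
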