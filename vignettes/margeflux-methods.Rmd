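---
title: "Methods: relative-expression constrained flux prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relative-expression constrained flux prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(margeflux)
```

## The problem

Flux balance analysis (FBA) predicts steady-state reaction fluxes of a
metabolic network from stoichiometry, flux bounds and an objective, but a
single-condition FBA solution says little about how metabolism *shifts*
between two cellular states — say, a proliferating tumor population and
dormant treatment-surviving cells. Transcript levels alone cannot fix
absolute fluxes (there is no reliable proportionality between mRNA and
catalytic rate), but the *relative* expression of metabolic genes between
two conditions carries directional information about transcriptional flux
control. margeflux implements a two-step linear program that uses exactly
that relative signal, together with exometabolome-derived exchange
constraints, to predict a coupled pair of flux distributions and the
redistribution between pathways.

## Enzyme-usage extension of the stoichiometric system

Gene–protein–reaction (GPR) rules are parsed into disjunctive normal
form: each conjunction (an *isozyme*) is one independent enzyme able to
carry the reaction, a multi-gene conjunction being an enzyme complex.
Every GPR-bearing reaction is expanded into nonnegative *usage*
variables, one per (isozyme, direction); a usage column repeats the
reaction's stoichiometry (negated for the backward direction), so

$$ v_j \;=\; \sum_{i \in \mathrm{iso}(j)} u^{f}_{ji} - \sum_{i \in \mathrm{iso}(j)} u^{b}_{ji} $$

and mass balance of the extended matrix $S^{ext}$ is equivalent to that
of $S$. Reactions without a GPR — including all boundary exchanges —
keep one ordinary flux column. Per-usage bounds are
$[0, |\text{reaction bound}|]$ and the aggregate reaction bounds
$lb_j \le v_j \le ub_j$ are enforced in every solve, so any solution of
the extended system maps to a feasible flux vector of the original
model.

Two deliberate choices here:

* **`and` binds tighter than `or`** in un-parenthesized rules, the usual
  convention in constraint-based modeling exchange formats.
* **Simultaneous forward and backward usage is permitted by the LP.**
  Binary exclusivity constraints would turn the program into a MILP;
  futile forward/backward pairs are instead suppressed by the Step-2
  parsimony objective, keeping both steps pure linear programs.

## The two-step program

Let $r_i = e^b_i / e^a_i$ be the expression ratio of enzyme group $i$
between conditions $b$ and $a$, and $E$ the set of groups with measured
ratios. Step 1 fits relative usage to relative expression:

$$ \min\; obj_1 = \sum_{i \in E} \left| u^b_i - r_i\, u^a_i \right| $$

subject to, for both conditions, $S^{ext} x = 0$, flux and usage bounds,
the exchange constraint set (below), optional biomass floors
(`growth_frac` times each condition's own constrained FBA maximum),
optionally a fixed total-usage budget, and activation constraints
$\sum_{i \in g} u_g \ge u_{min}$ for every measured group $g$ in each
condition. The activation threshold is the LP-representable form of the
requirement that an expressed enzyme carries at least a minimal flux;
a strict inequality cannot be represented, and $u_{min}$ (default 0.001
flux units) is itself the tolerance.

Step 2 adds a parsimonious enzyme-usage criterion: minimize
$\sum u^a + \sum u^b$ over **all** usage variables subject to all Step-1
constraints plus the relaxed agreement cap

$$ \sum_{i \in E} \left| u^b_i - r_i u^a_i \right| \;\le\; obj_1\,(1 + \varepsilon), $$

with $\varepsilon$ = `step2_tol` = 0.1 by default. Absolute values are
linearized with one nonnegative deviation variable per term, bounded by
two inequalities. The cap receives an absolute slack of $10^{-9}$ so the
fully symmetric case ($obj_1 = 0$) stays feasible in floating point.

If Step 1 is infeasible the activation constraints are dropped first and
the retry logged — genome-scale expression input could otherwise force
flux through blocked reactions; if the program is still infeasible, a
typed error reports which constraint family breaks feasibility.

### Expression input and aggregation

Only significantly differentially expressed genes enter (the
conventional q-value < 0.1 gate); ratios are computed from log2 fold
changes alone, since only $e_b/e_a$ appears in the objective. Gene
to enzyme-group aggregation is unspecified territory: the default is the
geometric mean of member fold changes ($2^{\overline{lfc}}$ — symmetric
in log space), with a `min` rule (a complex limited by its
least-changed subunit) available. Groups with no measured member stay
out of $E$ entirely, governed only by constraints and parsimony; a
config flag can instead assign them ratio 1.

### Biomass floors versus a constant flux budget

Two normalizations are provided and are mutually compatible:
`growth_frac_a/b` (default 0.8) floors each condition's biomass at a
fraction of its own constrained FBA maximum, and `total_flux_budget`
pins $\sum u$ per condition, implementing a constant total metabolic
flux assumption. They embody different biological idealizations — near
maximal growth versus fixed enzymatic capacity — and the package leaves
both exposed rather than resolving the tension silently.

## Exchange constraints from spent-medium metabolomics

For each measured metabolite mapped to an exchange reaction, with
condition abundance $m_c$, pure-medium baseline $m_0$ and upstream
significance flags:

* **Direction**: secretion if $m_c > m_0$ and significant versus the
  medium, uptake if $m_c < m_0$ and significant, otherwise
  unconstrained. The pure-medium measurement is what distinguishes
  active secretion from incomplete consumption.
* **Magnitude floor**: $\varphi \cdot$ (per-exchange maximum uptake
  rate), default $\varphi = 1\%$, imposed in the called direction — a
  minimum activity consistent with the data. The reference maximum is a
  per-exchange flux-variability optimization by default; a global-bound
  mode is available since the choice is not uniquely determined.
* **Ratio interval**: for metabolites significantly changed *between*
  conditions whose baseline-subtracted deltas share a direction, the
  fold change $FC = |m_b - m_0| / |m_a - m_0|$ becomes the two
  inequalities $FC(1-\tau) \le |v_b|/|v_a| \le FC(1+\tau)$ on the
  signed exchange fluxes, with a deviation tolerance $\tau = 50\%$ for
  measurement error. Endpoint-concentration differences stand in for
  rates because the cultivation interval between medium change and
  sampling is equal across conditions.

Metabolites whose two conditions call opposite directions get floors
only: a signed magnitude ratio has no linear encoding, and the skip is
logged rather than silently absorbed. A zero denominator delta likewise
skips the ratio with a log entry.

## Reporter metabolites

Gene-level p-values are aggregated over each metabolite's neighboring
genes (genes in the GPR of any producing or consuming reaction; sets of
size ≥ 1 are kept):

$$ Z = \frac{1}{\sqrt{k}} \sum_{g=1}^{k} \Phi^{-1}(1 - p_g). $$

Four classes are scored: non-directional (p-values as given),
distinct-directional (one-tailed p oriented by fold-change sign, the
usual $p/2$ convention), and mixed-directional up/down (the same-sign
subset of each set against a same-sign background). The background
corrects for set size: for every class and exact set size $k$,
`n_perm` (default 10,000) random same-size gene sets give $\mu_k$,
$\sigma_k$, a corrected $Z = (Z - \mu_k)/\sigma_k$ and a permutation
p-value $(1 + \#\{Z^{perm} \ge Z\})/(n_{perm}+1)$. Benjamini–Hochberg
adjustment is applied within each class, and the significance flag
combines adjusted p < 0.01 with a cap at the top 5% of all tested
metabolites per class. P-values are clipped to $[10^{-10}, 1-10^{-10}]$
before the quantile transform.

## The synthetic generator

`make_toy_model()` is a fixed 12-reaction, 10-metabolite network:
glucose uptake into glycolysis (a two-gene complex), a fermentative
branch secreting lactate (an isozyme pair), an oxygen-consuming
oxidative branch with high ATP yield, a reversible two-isozyme glutamine
transporter, and a biomass sink consuming pyruvate, ATP and glutamine.
At full glucose uptake the optimum is glutamine-limited with both
branches active, so flux can redistribute between fermentation and
respiration without structural change — the regime the method probes.
The qualitative template is a glycolytic shift between two cell states:
condition b doubles the fermentative branch.

`simulate_condition_pair()` first solves the ground-truth flux pair
(parsimonious FBA at fixed substrate uptake; condition b re-solved with
the planted exchange ratios imposed as equalities and verified feasible
at generation time), then emits observations:

* gene log2 fold changes = planted branch regulation + Gaussian noise
  (sd `sigma_expr`, default 0.1), with rank-based synthetic q-values
  under which exactly the planted genes pass q < 0.1 (the differential
  expression pipeline itself is out of scope);
* spent-medium abundances = medium + 1 time unit × true exchange flux,
  under multiplicative log-normal noise (sd `sigma`, default 0.1), with
  significance flags from a 3-sigma rule of that noise model. One time
  unit between medium change and sampling makes concentration deltas
  equal average fluxes, matching the constraint builder's convention.

What the generator does *not* emulate: GC-MS peak processing and
normalization artifacts, growth dynamics within the sampling interval,
compositional effects between metabolites, or realistic q-value
distributions. Passing recovery tests therefore demonstrates the
correctness and directional sensitivity of the optimization machinery
under controlled noise — not performance on real chromatograms.

## Numerical choices

* **LP backend.** All programs are dense and tiny (tens of variables,
  around a hundred rows), so the package ships its own two-phase
  tableau simplex: Dantzig pricing with an automatic switch to Bland's
  rule to exclude degenerate cycling, explicit substitution of fixed
  (`lb == ub`) variables, and nonnegative-rhs normalization. Steady-state
  systems are heavily degenerate — many optima sit at $v = 0$ facets —
  and this implementation is exercised against an independent external
  solver (scipy's HiGHS, through a different problem encoding) across
  the test suite.
* **Determinism.** Variables are ordered by (reaction, isozyme index,
  forward before backward) and the pivot rules are deterministic, so
  degenerate alternative optima resolve reproducibly; identical inputs
  give identical solutions.
* **Tolerances.** Mass-balance and bound checks use 1e-6 absolute;
  simplex pivoting uses 1e-9; infinite bounds are encoded as ±1000 flux
  units (configurable) so every program stays bounded.
* **Degenerate inputs.** Exchanges with no feasible uptake get floor 0
  (1% of a zero maximum); empty ratio sets make Step 1 trivially 0 and
  reduce the method to constrained parsimonious FBA; a biomass-free
  model simply skips growth floors.

## Problem sizes in the shipped tests

The suite cross-checks objective values on the 12-reaction network and
seed-perturbed variants (≤ 15 reactions), runs 20-seed recovery of the
planted fermentative shift at the default noise, and calibrates the
reporter null on 100 random gene sets at 1,000 permutations; the
package defaults (10,000 permutations) are used for real analyses.
These sizes were chosen so the whole suite exercises every code path in
about a minute while keeping Monte-Carlo error well inside the asserted
tolerances.

## Known limitations

* Two conditions per run; multi-condition designs are handled pairwise.
* No kinetic constants, proteomics, or thermodynamic constraints; no
  integer-programming variants of expression integration.
* Whether activation constraints should extend beyond the measured
  (differentially expressed) gene set is not identifiable from the data
  conventions this package targets; both behaviors are exposed
  (`activation`, and the ratio-1 fill for unmeasured groups).
* The magnitude-ratio skip for opposite-direction metabolites loses the
  (rare) information in a sign flip between conditions.
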