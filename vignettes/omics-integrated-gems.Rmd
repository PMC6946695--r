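---
title: "Omics-integrated genome-scale metabolic modeling: methods and design"
author: "remiflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Omics-integrated genome-scale metabolic modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remiflux)
```

## The problem

A genome-scale metabolic model (GEM) describes an organism's metabolism as
a stoichiometric matrix $S$ over metabolites and reactions, gene-reaction
(GPR) rules, and a biomass reaction whose flux is interpreted as specific
growth rate $\mu$ (1/h). Flux balance analysis (FBA) predicts steady-state
fluxes by solving

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; l \le v \le u,$$

usually with $c$ selecting the biomass flux. FBA alone assumes the cell is
always geared toward maximal growth; it cannot capture regulated states
such as stationary phase or the adaptation shock of a soil environment.
This package implements the complementary machinery that makes a GEM
condition-specific:

1. **Thermodynamics-based flux analysis (TFA)** couples reaction
   directionality to Gibbs energies and metabolite concentrations.
2. **Connectivity curation** detects blocked reactions and gap-fills them
   with a minimal number of database reactions, prioritized by omics
   evidence.
3. **Two-condition consistency maximization** integrates relative gene
   expression and exometabolite abundance ratios between two conditions
   as flux-ratio constraints, maximizing the number of data points the
   network can accommodate simultaneously (the REMI family of methods:
   TGex, TM, TGexM).
4. **Biomass building-block (BBB) analysis** compares the maximal
   producibility of every biomass precursor across conditions.

Everything is exercised end-to-end on synthetic networks with planted
ground truth, so each optimization outcome can be certified against an
exhaustive oracle.

## Thermodynamic constraints

For every reaction $r$ with a known standard reaction Gibbs energy
$\Delta_r G'^\circ$ (given directly or summed from formation energies),
TFA introduces

$$\Delta G_r = \Delta_r G'^\circ + RT \sum_m s_{mr} \ln c_m,$$

with $\ln c_m$ bounded by concentration limits, and couples flux
direction to the sign of $\Delta G_r$ through binary use variables
$u^+_r, u^-_r$:

$$f_r \le M u^+_r,\quad b_r \le M u^-_r,\quad u^+_r + u^-_r \le 1,$$
$$\Delta G_r \le -\delta + K(1 - u^+_r),\qquad
 -\Delta G_r \le -\delta + K(1 - u^-_r),$$

where $f_r, b_r \ge 0$ are the forward/backward half-fluxes
($v_r = f_r - b_r$). Reactions lacking Gibbs data (or containing a
metabolite without data) are constrained by their bounds only, so with an
empty annotation TFA reduces exactly to FBA; thermodynamic constraints
can only remove flux solutions, never add them.

Parameter choices, with units and rationale:

* concentration bounds $10^{-7}$–$10^{-1}$ mol/L per metabolite
  (physiological intracellular range; overridable per metabolite);
* $T = 303.15$ K (cultures at 30 °C), $R = 8.314\times10^{-3}$
  kJ/mol/K;
* minimal driving force $\delta = 0$ kJ/mol by default (directionality
  coupling without a forced margin);
* flux coupling constant $M = 1000$, matching the default flux bounds of
  $\pm1000$ mmol/gDW/h;
* protons and water are excluded from the $\ln c$ terms (fixed-activity
  convention); the excluded list is an argument of
  `thermo_annotation()`.

A numerical note: the Gibbs-energy coupling constant $K$ is not a fixed
large number. Each $\Delta G_r$ variable receives explicit finite bounds
computed from its own data,
$|\Delta_r G'^\circ| + RT\sum_m |s_{mr}| \max|\ln c_m| + 1$, and $K$ is
that bound plus $\delta + 1$. This is mathematically equivalent to a
global big-$K$ but keeps the simplex tableau well conditioned, which
matters because the package ships its own dense solver (below).

## Blocked reactions and gap-filling

A reaction is *blocked* when it cannot carry flux under any exchange
configuration; detection opens all exchanges to $\pm1000$ and runs flux
variability analysis at objective fraction zero. Blocked reactions are
grouped into *blocked pathways* — maximal sets of blocked reactions
connected through shared non-currency metabolites. The currency list
(ATP, ADP, NAD(P)(H), CoA, and common inorganics) applies only to graph
decomposition, never to the flux mathematics, and is configurable.

Gap-filling is a MILP over the model merged with a universal reaction
database: binary indicators $y_j$ select database reactions,
steady state must hold on the union network, the target must carry at
least $\varepsilon_{gf} = 10^{-3}$ mmol/gDW/h, and $\sum_j y_j$ is
minimized. Equal-size alternative sets are enumerated with integer cuts.
Omics-guided prioritization scores each blocked pathway by its count of
significantly differentially expressed genes (fold-change $\ge 2$, FDR
$< 0.05$) plus measured exometabolites among its participants; only
positive-score pathways become tasks.

Note that a missing enzyme in the middle of a linear pathway splits the
blocked pathway into an upstream and a downstream fragment in the
connectivity graph; the omics evidence of a route is therefore the union
of its fragments' evidence. The two curated fixtures
(`fixture_blocked_pathways()`) reproduce this situation: a toluene
degradation route restored by a single CoA-transferase (EC 2.8.3.6), and
a phenylalanine route via phenethylamine, phenylacetaldehyde,
2-hydroxyphenylacetate and homogentisate requiring three additions
(EC 4.1.1.28, EC 1.14.14.54, EC 1.14.13.-). They are topological
replicas with unit stoichiometry and synthetic formulas — the published
pathway structure fixes the connectivity, not the balanced equations.

## Two-condition consistency maximization

The model is duplicated into a *reference* and a *perturbed* copy with
split fluxes and shared thermodynamic structure. Differential data enter
as candidate constraints with binary indicators $z_i$:

* **Gene candidates.** Significant genes (FDR $< 0.05$,
  $|\log_2\mathrm{FC}| \ge \log_2\theta$, $\theta = 2$) are aggregated
  through each reaction's GPR (AND = min, OR = max over fold-changes;
  genes without data are dropped from the aggregation). A reaction with
  aggregate ratio $\rho \ge \theta$ becomes an up-candidate enforcing,
  when active,
  $(f+b)^{pert} \ge \rho\,(f+b)^{ref}$ and $(f+b)^{ref} \ge \varepsilon$;
  a ratio $\le 1/\theta$ gives the symmetric down-candidate with the
  activity floor $\varepsilon = 10^{-3}$ mmol/gDW/h on the perturbed
  side. Ratios are capped at $\rho_{\max} = 100$ to keep the big-M
  linearization numerically stable.
* **Metabolite candidates.** For a measured exometabolite, "production"
  is the total producing turnover
  $P_m = \sum_{s_{mr} > 0} s_{mr} f_r + \sum_{s_{mr} < 0} |s_{mr}| b_r$
  (not net exchange, since a secreted compound may be simultaneously
  consumed). An abundance ratio $> 1$ forces, when active,
  $P^{pert} \ge \rho_m P^{ref}$ with $P^{ref} \ge \varepsilon$, and
  symmetrically for depletion.

The objective maximizes $\sum_i z_i$. The number of candidates is the
theoretical maximum consistency score (TMCS); the optimum is the maximum
consistency score (MCS). Because the wording "number of
genes/metabolites" admits two bookkeeping conventions, both are
reported: `tmcs` counts one candidate per regulated reaction and per
regulated metabolite, and `tmcs_gene_level` counts the underlying genes.
Alternative optima are enumerated by fixing $\sum z = \mathrm{MCS}$ and
adding integer cuts $\sum_{i \in Z_k} z_i \le \mathrm{MCS} - 1$ until
infeasibility.

Growth is reported by post-hoc maximization of the biomass flux in each
condition copy with the indicators fixed to an active set. The growth
floor $\gamma$ (fraction of the per-condition unconstrained optimum)
defaults to 0 — i.e. feasibility only — because a near-arrest perturbed
state is exactly the phenotype of interest and any strong floor would
exclude it; $\gamma$ remains an explicit knob.

The *representative* alternative is the one whose stacked vector of
per-precursor maximal productions (both conditions) minimizes the L1
distance to the element-wise median vector over all alternatives, with
deterministic first-index tie-breaking.

## Biomass building blocks

`list_bbbs()` extracts the biomass substrates; groups (amino acids, DNA
nucleotides, RNA nucleotides, lipids, carbohydrates, cofactors and
vitamins, minerals) come from a user-supplied mapping table, with
unmapped precursors flagged "unclassified". Production ceilings use a
transient irreversible demand sink (bounds [0, 1000] mmol/gDW/h) added
per precursor; under consistency constraints the sink is embedded closed
in both condition copies and opened one probe at a time. Fold-changes
come from the representative alternative; the per-precursor p-value is a
two-sided Wilcoxon signed-rank test over paired per-alternative
productions — the original significance procedure is not specified, so a
distribution-free paired test was chosen and is exposed as a documented
choice. Fewer than two alternatives yields fold-changes with p-values
marked unavailable, and a denominator below $10^{-9}$ flags the ratio
instead of dividing.

## The solver

No LP/MILP library is part of this package's dependency footprint;
src/ contains a self-contained bounded-variable two-phase primal simplex
(dense tableau, Dantzig pricing with a Bland anti-cycling fallback,
deterministic tie-breaks) and a depth-first branch-and-bound for the
binary variables. Two details matter for the MILPs this package builds:

* **Verification before acceptance.** A relaxation solution that is
  integral only within tolerance is never accepted directly; the integer
  variables are fixed at their rounded values and the LP re-solved, so a
  loose big-M constraint can never smuggle an infeasible point into the
  incumbent.
* **Support-driven repair.** Thermodynamic direction indicators are
  *determined* by the fluxes they gate ($u^+ = 1$ iff $f > 0$). Each
  indicator declares its half-flux as a support variable
  (`lp_set_support()`); at every node the solver proposes indicators
  from their supports, fixes and re-solves, and obtains a verified
  incumbent without branching through dozens of direction binaries.
  This collapses the consistency-maximization search to a handful of LP
  solves on the instances this package targets.

Tolerances: reduced-cost and pivot thresholds $10^{-9}$, integrality
$10^{-6}$, feasibility verification $10^{-5}$ relative. Determinism:
single-threaded, fixed branching order (most fractional, up-branch
first), no randomized perturbation; identical inputs yield identical
solutions, which the pipeline turns into byte-identical serialized
reports (wall-clock timings are kept out of the serialized report for
this reason).

## The synthetic generator

`generate_toy_model()` builds a carbon-limited toy cell: one substrate
uptake (bound 10 mmol/gDW/h), a linear catabolic backbone ending in a
biomass precursor, parallel isoenzyme branch pairs whose flux split
differs between conditions (0.8/0.2 vs 0.2/0.8 by default), cleavage
steps that secrete measurable byproducts through transport and exchange
reactions, and dead-end side reactions that can never carry flux.
Elemental formulas are assigned by backward propagation over a small
C/H/O/N alphabet so the balance checker is exercised honestly, and the
thermodynamic annotation is derived from a potential function decreasing
along the backbone, guaranteeing the planted directions are
thermodynamically reachable. Default Gibbs coverage is 76% of
metabolites and 84% of reactions.

Two flux states are planted by construction and satisfy $Sv = 0$ to
$10^{-9}$: a reference state at full uptake and a perturbed state scaled
to a growth ratio of 0.01 — the near growth arrest of a stationary-phase
culture relative to exponential growth. Consistent gene signals carry
the planted per-reaction activity ratios (all down-regulations, which is
the dominant signature of a starving culture); inconsistent signals
claim activation of the dead-end reactions, which no flux state can
satisfy, so the expected MCS equals the consistent-signal count exactly.
Metabolite signals carry the planted secretion ratios. Noise is Gaussian
on the log2 scale; FDR assignment is deterministic (0.01 for signals,
0.8 for background) so differential-expression selection stays a pure
threshold gate.

What the generator does *not* emulate: cofactor and energy metabolism
(no ATP/NADH coupling), enzyme promiscuity, absolute expression levels,
measurement missingness structured by chemistry, and compartment-specific
concentration regimes. Passing the planted-recovery tests therefore
demonstrates correctness of the optimization machinery under known
ground truth, not predictive performance on a real transcriptome or
exometabolome.

```{r example, eval = FALSE}
spec <- synthetic_spec(seed = 1)
gen <- generate_toy_model(spec)
omics <- generate_condition_omics(gen$model, gen$truth, spec)
problem <- build_remi_problem(gen$model, gen$thermo, omics,
                              remi_settings("tgexm"))
res <- enumerate_alternatives(problem, solve_mcs(problem))
condition_growth(problem, res$alternatives[[1]])
```

## Problem sizes and test design

The validation suite works at sizes where every answer can be certified:
toy networks of about 20 metabolites and 30 reactions, candidate counts
of at most 12 (exhaustive subset search), gap-fill databases of at most
8 reactions ($2^8$ subsets), and direction-pattern enumeration over at
most $2^4$ patterns with shared concentration variables. The acceptance
checks run 50 seeded consistency instances, 50 gap-fill instances and 50
blocked-detection models against their oracles, plus exact
planted-recovery and bit-for-bit reproducibility checks. These sizes are
the package's validation design: large enough to contain branching,
conflicts, alternative optima and degeneracy, small enough that brute
force is the judge.

## Known limitations

* The dense simplex targets hundreds of variables; genome-scale models
  with thousands of reactions would need a sparse LP engine behind the
  same `lp_problem()` interface.
* Gap-fill candidate databases beyond a few dozen reactions make
  integer-cut enumeration slow; the MILP remains correct but brute-force
  certification is no longer possible.
* Metabolite "production" uses total producing turnover; isotopically
  distinguishable routes (which tracer experiments could separate) are
  not modeled.
* GPR aggregation is a fixed min/max strategy; the functions accept
  alternative aggregation functions but no complex-stoichiometry model.
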