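---
title: "Screening redox cofactor engineering targets with FBA, MOMA and f_PH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening redox cofactor engineering targets with FBA, MOMA and f_PH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxscreen)
```

## The problem

NADPH-dependent product pathways — isobutanol synthesis, which consumes two
NADPH per molecule (one in ketol-acid reductoisomerase, one in the terminal
aldehyde reduction), is the case this package was built around — compete for
a cofactor that microaerobic *E. coli* makes poorly, while glycolysis
produces NADH faster than a limited respiratory chain can reoxidize it.  The
cell balances its books by secreting reduced byproducts (lactate, ethanol,
succinate), which wastes carbon.  A redox engineering intervention should
therefore (a) increase NADPH supply and (b) relieve NADH overflow, without
(c) collapsing growth.

`redoxscreen` formalizes this as a screen over every NAD(H)/NADP(H)-coupled
reaction of a stoichiometric model, simulating the three standard
interventions — knockout, overexpression, cofactor swap — and ranking them
by a single phenotypic score.

## Model and procedure

A model is the usual constraint-based object: stoichiometric matrix $S$
(metabolites $\times$ reactions), flux bounds $l \le v \le u$
(mmol/gDCW/h), a biomass objective, boundary exchanges with negative flux
denoting uptake.

**Reference state.** Growth is maximized by FBA
($\max v_{\mathrm{biomass}}$ s.t. $Sv = 0$, bounds, plus measured
uptake/secretion constraints), then, because FBA optima are degenerate, the
flux vector is made unique by minimizing $\sum_j |v_j|$ at fixed optimal
growth (parsimonious FBA).  Reproducibility of the reference is essential:
the MOMA distances and the overexpression/swap equalities are all anchored
to $v^{\mathrm{ref}}$.

**Candidate screen.** Reactions touching any of the four cofactor species
are candidates unless excluded as: carrying no flux (both $|v^{\mathrm{ref}}|
< 10^{-6}$ *and* FVA maximum absolute flux $< 10^{-6}$ at 99.9% of the
optimum — the double test avoids calling an alternate-optimum reaction
"blocked"); essential (knockout growth below 1% of reference growth);
orphan (no associated gene) or spontaneous; in a blocklisted subsystem
(membrane/envelope assembly, tRNA charging, ion transport — categories
whose oxidoreductases are not practical engineering levers); boundary; or
the objective itself.

**Modes.** The net direction of each surviving reaction at
$v^{\mathrm{ref}}$ decides what can be done with it: reactions *producing
NADH* or *consuming NADPH* (and touching a single cofactor pair) can be
cofactor-swapped; reactions *consuming NADH or NADPH* can be knocked out;
reactions *producing NADPH* can be overexpressed.  We assign overexpression
to NADPH producers — the transhydrogenase and the oxidative pentose
phosphate shunt are the canonical members of this class — because
amplifying an NADH producer could only deepen the imbalance the screen is
trying to fix.  Reactions touching both pairs (transhydrogenase) are never
swapped, which the `dual_cofactor` guard enforces.

**Perturbations.** Knockout: bounds $[0, 0]$.  Overexpression: flux fixed
at $N v^{\mathrm{ref}}$ for $N = 1.1, 1.2, \dots, 2.0$, sign-preserving, so
a reaction running backwards is amplified in its own direction.  Cofactor
swap: the model gains a twin reaction with NAD(H) and NADP(H) interchanged
(coefficients untouched — the members of each pair differ by the same
phosphate, so elemental balance is preserved), the native copy is silenced
and the twin fixed at $M v^{\mathrm{ref}}$ for $M = 0.1, \dots, 2.0$.  The
grids emulate promoter-strength titration around the native flux.

**MOMA.** The perturbed cell is not assumed to re-optimize growth; its
immediate response is the closest feasible flux state,

$$v^{\mathrm{mod}} = \arg\min_v \; \lVert v - v^{\mathrm{ref}} \rVert^2
 \quad \text{s.t.} \quad S v = 0,\; \text{perturbed bounds},$$

a strictly convex QP.  The distance runs over all reactions, exchanges
included; a swap-added reaction enters with reference flux 0, so its
activation is part of the adjustment being minimized (inert under the
equality that fixes its flux, but the convention matters if the equality is
relaxed).  Infeasible grid points are logged and dropped rather than scored
zero — infeasibility means "the cell cannot satisfy this flux program at
all", not "this program has a poor phenotype".

**Scoring.** Each optimal MOMA state is scored by the phenotypic fraction

$$f_{\mathrm{PH}} = f_{\mathrm{biomass}} \times f_{\mathrm{isobutanol}}^2
 = \frac{\mu^{\mathrm{mod}}}{\mu^{\mathrm{ref}}} \times
   \left(\frac{v_{\mathrm{isb}}^{\mathrm{mod}}}{v_{\mathrm{isb}}^{\mathrm{ref}}}\right)^{2}.$$

The square weights production over growth: a perturbation may spend growth
to gain product, but not to extinction (the growth factor still multiplies
in).  Per (target, mode) the grid maximum is reported with its arg-max
factor, and targets are ranked by that score.

## Numerical choices

No dedicated LP solver is assumed; all programs run through the dual
active-set QP method of `quadprog`:

* **LPs by exact regularization.** $\max c'v$ is solved as
  $\min \tfrac{\varepsilon}{2}\lVert v\rVert^2 - c'v$; for small enough
  $\varepsilon$ the minimizer is exactly the least-norm LP optimum
  (exact Tikhonov regularization of linear programs), which doubles as a
  deterministic tie-break.  An $\varepsilon$ ladder
  ($10^{-7}, 10^{-6}, 10^{-5}$) absorbs numerical stress.
* **Proximal verification.** Every LP solution is certified (and, where the
  fast path failed, computed) by proximal-point iteration
  $v_{k+1} = \arg\max\, c'v - \lVert v - v_k\rVert^2/(2t)$: each step is a
  well-conditioned strictly convex QP, a fixed point is exactly an LP
  optimum, and for polyhedral objectives the iteration terminates finitely.
  The dual active-set method is much more reliable on these unit-Hessian
  steps than on nearly-singular regularized LPs, which is the failure mode
  the iteration exists to cover.
* **pFBA in epigraph form.** $\min \sum_j |v_j|$ uses auxiliary variables
  $-t \le v \le t$ rather than the classical $v = v^+ - v^-$ split: the
  split doubles every column of $S$ with its negation, and that exact
  collinearity reliably breaks the active-set method, while the epigraph
  form is stable across ridges.
* **Feasibility is decided, not guessed.** The solver reports genuine
  infeasibility and numerical stress with the same error, so a dedicated
  phase separates them: first a least-norm point of the polytope (strictly
  convex, robust — success is a feasibility certificate), then a
  slack-minimization program whose *measured* residual decides.  Tolerances:
  steady state $|Sv|_\infty \le 10^{-6}\max(1, |v|_\infty)$ post-hoc, bound
  violations $10^{-9}$ at solver level.
* **KKT certification.** `verify_kkt()` checks a MOMA solution by fitting
  the gradient $2(v - v^{\mathrm{ref}})$ into the cone spanned by the
  equality normals (free multipliers) and active bound normals
  (sign-constrained): the fit residual is the stationarity report, with
  pass at $10^{-6}$.  Degenerate equality systems are reduced to a maximal
  independent row set (QR with pivoting) before any solve; fixed fluxes
  ($l = u$) join the equality block, which the active-set method handles
  far better than razor-thin boxes.
* Bounds default to $\pm 1000$ mmol/gDCW/h (BiGG convention); infinite
  bounds are clamped to $\pm 10^6$ and a solution at the clamp is reported
  `unbounded`.

## The toy network: what it emulates, what it does not

`build_toy_model()` is a deterministic ~38-reaction network reproducing the
redox *structure* of a microaerobic, formate-lyase-deleted,
isobutanol-producing *E. coli*:

* EMP glycolysis with a single NAD-dependent GAPDH lump (G3P → PEP,
  producing NADH and ATP) that dominates carbon flux;
* an oxidative pentose phosphate lump producing 2 NADPH per glucose-6-P,
  recycled by a non-oxidative lump;
* a cofactor-free methylglyoxal-like bypass (G3P → pyruvate) whose only
  role is to keep GAPDH non-essential, as the genome-scale host's bypasses
  do — without it the screen's essentiality filter would discard the most
  interesting target;
* NADH-consuming lactate, ethanol and succinate branches and *no formate
  branch* (the pflB deletion);
* an ATP-coupled transhydrogenase (ATP standing in for the proton-motive
  force) and an O₂-capped respiratory chain;
* a biomass lump consuming precursors, 4 NADPH and 15 ATP, plus a
  growth-independent ATP maintenance flux;
* the 2-NADPH isobutanol pathway with a secretion floor.

Default conditions: glucose uptake ≤ 10, O₂ uptake ≤ 2, ATP maintenance 3
(all mmol/gDCW/h), isobutanol secretion ≥ 0.5 — glucose-limited,
oxygen-limited, with a measured-production surrogate pinning the product
pathway on.  These are fixture units chosen so that the reference state
shows the diagnostic phenotype (byproduct secretion, NADH flux-sum
2.7-fold the NADPH flux-sum); they are not calibrated to any measured
strain, and the toy's absolute fluxes mean nothing outside the fixture.

What passing tests on this fixture do show: the filtering rules, the
perturbation algebra, the MOMA optimality (certified against KKT residuals
and random feasible competitors), and the qualitative ranking — the NAD→NADP
swap of the dominant glycolytic NADH source outranks byproduct knockouts
and transhydrogenase/pentose-shunt overexpression.  What they do not show:
quantitative agreement with genome-scale predictions (absolute growth
rates, flux-sums, per-target scores), which depend on the full iJO1366-class
network and its measured constraint set.  Those runs are supported —
`read_model()` accepts BiGG JSON and SBML L3/FBC, and every function takes
`extra_constraints` — but carry their own inputs.

Phosphate, water and protons are omitted from the lumped reactions, so
elemental mass balance does not apply to the toy; a carbon bookkeeping table
(`toy_carbon_counts()`) and a dedicated test stand in for it.
`validate_mass_balance()` does full elemental accounting on models that
carry formulas and lists formula-free reactions as skipped rather than
failed.

## Design decisions taken where the procedure was open

* **Reference disambiguation** is parsimonious-FBA-style minimal total
  flux; plain FBA optima are solver-dependent, and a screen whose scores
  depend on the solver's vertex choice would not be reproducible.
* **Overexpression rule**: NADPH producers (see *Modes* above).  The two
  overexpression targets any such screen keeps producing — transhydrogenase
  and glucose-6-phosphate dehydrogenase — both generate NADPH, which fixes
  the rule unambiguously even though one could also read "NADH producers"
  as the class to amplify.
* **Reversible candidates** are classified and scaled by their *net
  direction at the reference*; zero-flux reversible reactions fall back to
  the written forward direction and are flagged.  "N-fold of the initial
  flux" is read as magnitude-and-direction.
* **Per-target reporting** is the grid maximum with its arg-max factor —
  the "best achievable by titrating this target" reading of a one-row-per-
  target summary.
* **Transhydrogenase variant** (`modify_transhydrogenase()`) defaults to a
  no-op that records provenance: the membrane-coupled form a specific study
  substitutes is configurable input (`parse_reaction_string()` parses
  direction strings), not something to guess.
* **Isobutanol pathway augmentation** adds exactly five reactions
  (decarboxylase, NADPH-dependent dehydrogenase, cytosol→periplasm and
  periplasm→extracellular transport, boundary exchange) with deterministic
  ids, mirroring the three-compartment convention of iJO1366-class models.
* **Essentiality threshold** 1% of reference growth: conservative enough
  that bypass-rescued central reactions (GAPDH) stay in the candidate set.

## Problem sizes and runtime

The test suite solves a few thousand LPs/QPs on the 38-reaction fixture and
the ≤ 50-reaction random property models, including a 1000-point random
audit of MOMA optimality; it completes in well under a minute on one CPU.
The full campaign on the toy fixture (7 candidates, 45 grid points) takes
under a second.  Genome-scale screens scale with candidate count × grid
size × (dense QP at ~2600 reactions) and are the intended use of an
external QP solver hook rather than this package's bundled method.

## Known limitations

* Dense linear algebra: fine to a few thousand reactions, not tuned beyond.
* MOMA only (Euclidean); linear-MOMA and regulatory on/off variants are out
  of scope, as are combinatorial multi-target designs and bilevel methods.
* Loopless/thermodynamic constraints are not modeled; the toy's ATP-coupled
  transhydrogenase is a deliberate thermodynamic caricature.
* The fermentation arithmetic uses rounded molecular weights (74, 180
  g/mol) by default because published summaries round the same way; exact
  masses are a `fermentation_record()` field away.
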