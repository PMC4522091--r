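# redoxscreen

Constraint-based prediction of **redox cofactor engineering targets** in
stoichiometric metabolic models, for metabolic engineers working on
NADPH-limited production strains.

Many fermentation products — isobutanol is the motivating case — drain NADPH,
while glycolysis floods the cell with NADH.  Under microaerobic conditions the
excess NADH is recycled into reduced byproducts (lactate, ethanol, succinate)
that steal carbon from the product.  `redoxscreen` asks, for every
NAD(H)/NADP(H)-dependent reaction in a model: *would knocking it out,
overexpressing it, or swapping its cofactor specificity rebalance the redox
state in favor of the product?*

## Method

1. **Reference state** — flux balance analysis (maximize growth subject to
   `S v = 0`, flux bounds and measured uptake/secretion constraints),
   disambiguated by minimizing total absolute flux (parsimonious FBA), gives
   the "initial fluxes" `v_ref`.
2. **Candidate screen** — all reactions touching NAD⁺/NADH/NADP⁺/NADPH are
   located; no-flux (by reference flux *and* flux variability analysis),
   essential, orphan, spontaneous, blocklisted-subsystem, boundary and
   objective reactions are excluded.  The net cofactor turnover at `v_ref`
   assigns modes: **cofactor swap** to NADH producers and single-pair NADPH
   consumers, **knockout** to NADH/NADPH consumers, **overexpression** to
   NADPH producers.
3. **Perturbation grids** — knockout fixes `v = 0`; overexpression fixes
   `v = N·v_ref` (N = 1.1 … 2.0); a cofactor swap adds the NADP(H) twin of the
   reaction, silences the native copy and fixes the twin at `M·v_ref`
   (M = 0.1 … 2.0).
4. **MOMA** — each perturbed network is re-solved by minimization of
   metabolic adjustment: the quadratic program
   `argmin ‖v − v_ref‖²  s.t.  S v = 0`, perturbed bounds — the immediate,
   non-reoptimized response of the cell.
5. **Ranking** — each outcome is scored by the phenotypic fraction

   ```
   f_PH = f_biomass × f_isobutanol²
        = (μ_mod / μ_ref) × (v_isb,mod / v_isb,ref)²
   ```

   and the per-target grid maximum is ranked; the top reaction is the
   predicted engineering target.

The package also ships the closed-form fermentation arithmetic used to
interpret batch outcomes (percent titer changes, mol/mol yields, NADPH demand
of a titer gain, and the fraction of glucose that must flow through an
NADP-dependent glyceraldehyde-3-phosphate dehydrogenase to supply it).

All linear and quadratic programs are solved with the dual active-set method
of `quadprog`; linear programs go through exact Tikhonov regularization with
a proximal-point verification pass, and every MOMA solution can be certified
by its KKT residuals (`verify_kkt()`).

## Worked example

The packaged toy network (`build_toy_model()`) emulates a microaerobic,
formate-lyase-deleted, isobutanol-producing *E. coli*: EMP glycolysis with an
NAD-dependent GAPDH lump, an NADPH-producing pentose phosphate shunt,
NADH-consuming fermentative branches, a proton-motive-force-coupled
transhydrogenase, and a 2-NADPH-per-molecule isobutanol pathway.

```r
library(redoxscreen)

model <- build_toy_model()                 # 33 metabolites, 38 reactions
cof   <- toy_cofactor_spec()
ref   <- reference_state(model)            # pFBA reference
cs    <- filter_candidates(model, ref, cof)
camp  <- run_campaign(model, cs, ref, cof, "EX_iboh_e")
campaign_ranking(camp)[, c("target_id", "mode", "factor", "f_ph")]
```

prints

```
   target_id           mode factor     f_ph
1       GAPD  cofactor_swap      1 142.9024
2 G6PDH_lump overexpression      2  50.2716
3        LDH       knockout     NA  18.9360
4        ETC       knockout     NA   1.5829
5        THD overexpression      2   1.0300
6       ADHE       knockout     NA   1.0000
7  SUCC_lump       knockout     NA   1.0000
8        THD       knockout     NA   0.9977
```

The NAD→NADP cofactor swap of the glycolytic GAPDH step dominates: it
converts the cell's largest NADH source into an NADPH source feeding the
product pathway directly, where knockouts of the fermentative branches or
overexpression of the transhydrogenase only shuffle the existing imbalance.
At the reference state the NADH flux-sum exceeds the NADPH flux-sum
2.7-fold (`flux_sum(ref, model, "nadh")`), and 79% of NADH is recycled
through the lactate/ethanol branches (`cofactor_shares()`).

The fermentation arithmetic:

```r
fermentation_report(
  baseline   = c(isobutanol = 2.70, ethanol = 1.60, lactate = 12.60),
  engineered = c(isobutanol = 8.68, ethanol = 1.32, lactate = 6.08),
  glucose_consumed_gL = 35.25)
```

```
               quantity   value    unit
      isobutanol_change 221.481       %
         ethanol_change -17.500       %
         lactate_change -51.746       %
  isobutanol_gain_molar  80.811  mmol/L
     extra_nadph_demand 161.622  mmol/L
 gapdn_glucose_fraction  41.265       %
       isobutanol_yield   0.599 mol/mol
```

i.e. a 221% titer increase whose 80.8 mmol/L isobutanol gain requires
41.3% of the consumed glucose to be catabolized through the NADP-dependent
GAPDH route (2 NADPH per isobutanol, 2 NADPH per glucose).

## The analysis workflow

`analysis/` contains numbered drivers that run the full study on the toy
network and write tables under `results/`:

| script | step |
|---|---|
| `01_build_model.R` | build host network, add the isobutanol pathway, write JSON/SBML |
| `02_reference_state.R` | pFBA reference, flux table, NADH/NADPH balance sheets |
| `03_screen_targets.R` | locate cofactor reactions, apply exclusion filters |
| `04_campaign.R` | knockout/overexpression/swap grids, MOMA, f_PH ranking |
| `05_flux_report.R` | flux maps (% of glucose uptake), cofactor shares |
| `06_fermentation_arithmetic.R` | batch fermentation comparison report |

Run them in order from the repository root: `Rscript analysis/01_build_model.R` etc.

## Scope

Reader/writer support covers BiGG-style JSON and SBML Level 3 FBC, so
genome-scale models can be screened with the same functions
(`read_model("iJO1366.xml")`).  The published genome-scale predictions
depend on a measured constraint set that travels with that model; they are
exposed through the `extra_constraints` argument rather than baked in.
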