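---
title: "Constraint-based modelling of photoautotrophic metabolism with cyanoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modelling of photoautotrophic metabolism with cyanoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanoflux)
```

## The modelling framework

cyanoflux analyses genome-scale stoichiometric models of photoautotrophic
(cyanobacterial) metabolism. The state of the cell is a flux vector $v$
(mmol gDCW$^{-1}$ h$^{-1}$) over the model's reactions; the steady-state
assumption $N v = 0$, with $N$ the stoichiometric matrix (metabolites by
reactions), together with flux bounds $l \le v \le u$ defines the feasible
flux cone. Two linear programmes are the workhorses:

* **FBA** — maximise an objective $c^\top v$ (usually the biomass
  pseudo-reaction) subject to $Nv = 0$, $-1000 \le v \le 1000$.
* **Parsimonious FBA (pFBA)** — with the physiology pinned (growth rate
  fixed at its measured value, the O$_2$ evolution flux confined to its
  measured window, the maintenance ATP hydrolysis fixed), minimise the
  total absolute flux $\sum_i |v_i|$. The absolute values are linearised
  by splitting each flux into non-negative forward and reverse parts
  ($v = v^+ - v^-$); reversible reactions are therefore doubled internally
  and mapped back on output.

All linear programmes are solved by a dense two-phase bounded-variable
revised simplex written for this package (deterministic: variables ordered
by sorted reaction id, Bland's rule for pivoting, feasibility and
optimality tolerances $10^{-9}$). Every optimal state is verified to
satisfy $\lVert Nv\rVert_\infty \le 10^{-6}$. An independent backend
(scipy's HiGHS solver, reached through a Python subprocess) is wired into
the same interface; the test suite requires objective agreement between
backends to $10^{-6}$ relative, and the SBML writer's output is
cross-validated against cobrapy/libSBML.

### The oxygen window

The photoautotrophic simulation fixes growth exactly but encodes the
measured O$_2$ evolution rate $y \pm h$ as an *interval* constraint
$y - h \le v_{\mathrm{O_2}} \le y + h$ on the O$_2$ exchange rather than an
equality. A hard equality would force the flux state to reproduce the
measurement's central value even when the network's electron balance
prefers a different (still physiological) value inside the measured
uncertainty; the interval lets the parsimony objective decide within the
data. This is the package's own reading of the constraint set and is
configurable (`o2_halfwidth = 0` restores the equality).

### Alternate optima

pFBA flux maps can be non-unique. Downstream counts (active reactions)
inherit that ambiguity, so `flux_variability()` can re-examine any
reaction's admissible range at the parsimonious optimum (the total
absolute flux is capped at its minimum via one extra constraint row), and
activity calls can be flagged as range-dependent. The default report uses
the single parsimonious solution, which is what published model papers
tabulate.

## The biomass objective

`compose_biomass_reaction()` converts a measured macromolecular
composition (mass fractions, mg per mg dry cell weight) into a biomass
pseudo-reaction. For a polymeric component with mass fraction $w$, monomer
mole fractions $x_m$, and mole-fraction-weighted mean residue mass
$\bar M = \sum_m x_m M_m$ (g/mol, polymerised = monomer minus water), the
coefficient of monomer $m$ is

$$ c_m = 1000 \cdot w \cdot x_m / \bar M \quad \text{(mmol gDCW}^{-1}). $$

Monomer profiles are supplied as replaceable templates
(`inst/extdata/monomer_templates.yaml`): a typical bacterial amino-acid
usage for protein and phycobiliproteins, equimolar NMPs/dNMPs for RNA and
DNA, glucosyl residues (162.141 g/mol) for glycogen and residual
carbohydrate, and a C16:0/C18:1-dominated acyl profile for lipid. These
templates are the package's documented defaults for quantities the
composition assay does not resolve; they can and should be replaced when
organism-specific profiles are available. Elemental bookkeeping covers
C, H, O, N, P and S only — the magnesium of chlorophyll *a* is kept in the
residue mass (so mass closure is exact) but not in the elemental formula.

Mass closure is checked as $\sum_m c_m M_m \approx 1000$ mg/gDCW. Measured
composition tables rarely sum to exactly 1 (soluble pool, inorganic ions
and peptidoglycan are usually adopted from literature rather than
measured); a deviation of up to 0.05 is tolerated before a warning asks
for an explicit remainder component.

### Elemental formula and degree of reduction

The per-carbon biomass formula is $\sum_m c_m \cdot$ (residue formula),
normalised to C = 1 (energy species — ATP, ADP, P$_i$, water — are
bookkeeping and excluded). The degree of reduction is
$\gamma = \sum_e w_e \, n_e$ with reference electrons C = 4, H = 1,
O = $-2$, P = 5, S = 6; nitrogen depends on the N source reference:
$-3$ on the ammonia convention, $+5$ on the nitrate convention, the two
differing by exactly $8 n_N$. Published biomass $\gamma$ values do not
always state their N reference; the package computes and labels **both**
and reports the ammonia convention by default, because that is the common
biomass convention in the bioprocess literature. The photosynthetic
quotient follows as $PQ = \gamma_{NO_3}/4$ (each O$_2$ carries four
electrons; on nitrate medium the nitrate reference is the appropriate
one), giving a flux-model-independent O$_2$ evolution estimate
$PQ \times$ CO$_2$ uptake.

### Maintenance energies

Growth-associated maintenance (GAM) enters as the ATP coefficient of the
biomass equation (mmol gDCW$^{-1}$); non-growth-associated maintenance
(NGAM) as a fixed flux through a separate ATP hydrolysis reaction
(mmol gDCW$^{-1}$ h$^{-1}$). Strain-specific values are rarely measured;
the defaults (GAM = 53, NGAM = 1.3) are at the magnitudes adopted by
published *Synechococcus*/*Synechocystis* reconstructions, and both are
plain function arguments. Because these are the least-constrained numbers
in any such model, `energy_sensitivity_scan()` re-derives the biomass
equation over a GAM grid and re-pins the hydrolysis flux over an NGAM
grid, re-solves the pFBA in every cell (infeasible cells are marked, the
scan continues), and reports photon uptake, O$_2$ evolution, CO$_2$ uptake
and the L1 distance of central-carbon fluxes from the base solution. On
the synthetic model the scan shows the expected structure: photon demand
rises with NGAM (two extra photons per ATP via cyclic electron flow)
while the central-carbon flux distribution, which is fixed by the biomass
equation and the network, does not move.

## Curation checks

* **Gap finding** (`find_gaps()`): for every biomass precursor a temporary
  demand reaction is added and maximised under the photoautotrophic
  medium; a maximal flux below $10^{-8}$ flags the precursor as not
  producible. The model is never modified in place.
* **Infeasible loops** (`detect_infeasible_loops()`): all exchanges are
  fixed to zero and the ATP synthase flux to a positive value; if the
  problem remains feasible, the reactions carrying flux in the
  minimal-total-flux solution are the loop. The result is invariant to
  the fixation value (1 vs 10), which the tests assert. Repairs are
  applied as explicit directionality patch files
  (`apply_bounds_patch()`), not automated database lookups, so every
  repair is recorded and reproducible.
* **ATP from nothing** (`check_atp_from_nothing()`): all carbon-bearing
  uptakes (including CO$_2$) are closed and the maintenance flux
  maximised, in two variants — photons closed (any positive value is an
  energy-generating cycle) and photons open (a positive value is
  photophosphorylation, reported but not an error).

## Essentiality and yields

The essentiality screen fixes one reaction at a time to zero bounds and
maximises growth; a post-deletion maximum at or below $10^{-4}$ h$^{-1}$
(infeasibility counts as zero) marks the reaction essential. The active
threshold for flux states is $10^{-8}$ mmol gDCW$^{-1}$ h$^{-1}$. Both
thresholds live in `analysis_settings()`. The screen releases any growth
fixation but keeps the medium, the O$_2$ window and the maintenance flux —
the constraint set under which essentiality is biologically meant — and
this choice is logged in the report attributes. Deletion is
reaction-level; gene-level deletion through gene–protein–reaction rules is
out of scope.

Maximum theoretical yields (`max_product_yield()`, `yield_panel()`)
maximise a product exchange subject to growth staying at or above a
fraction (default 0.8) of the wild-type optimum. "Wild type" is the FBA
maximum under the same medium — not a measured rate — because the floor is
defined relative to what the model can do; a measured rate can be supplied
explicitly (`wild_type_growth`). The floor is implemented as an inequality
(at *least* the fraction), the Methods-style reading; a fixed-growth
variant is one `simulation_constraints()` away. Yields are mol product per
mol CO$_2$, with bicarbonate uptake folded into the denominator when such
an exchange exists. Products lacking transport/exchange get them added
automatically and reported; heterologous products are declared as minimal
reaction lists (YAML), inserted as `gap_filled` evidence, and every added
reaction must pass the elemental balance check.

## The synthetic photoautotroph

`generate_toy_photoautotroph()` builds a 25–35 reaction model that
exercises every pipeline stage with analytically known answers:

* lumped linear electron flow (8 photons + 2 H$_2$O + 2 NADP →
  O$_2$ + 2 NADPH + 12 pmf), cyclic electron flow (1 photon → 2 pmf),
  ATP synthase (4 pmf per ATP), a Mehler-like alternative electron sink
  and a proton leak;
* lumped CBB fixation (3 CO$_2$ + 9 ATP + 6 NADPH → triose phosphate),
  lower glycolysis, pyruvate oxidation/carboxylation, an oxidative TCA
  branch to 2-oxoglutarate with the decarboxylase/succinic-semialdehyde
  shunt to succinate (the cyanobacterial bypass of the missing
  2-oxoglutarate dehydrogenase), nitrate reduction and GS-GOGAT (or a
  glutamate-dehydrogenase variant), glycogen and C16 fatty-acid branches;
* a biomass equation composed from a three-pool composition (glutamyl
  0.41, glucosyl 0.52, palmitoyl 0.07 mg/mg — the high-polyglucan
  composition magnitudes measured in the organism this package grew out
  of).

All stoichiometries are integer and exactly CHONPS-balanced; cofactor pairs
differ by H$_2$ so no proton/charge bookkeeping is needed; photons and the
proton-motive force are massless pseudo-species. Because the network has a
single route to each precursor plus a known set of bypasses, the maximal
growth has a closed form. With net per-gram demands $A$ (ATP) and $N$
(NADPH), linear electron flow supplies NADPH at 4 photons per pair plus
1.5 ATP-equivalents of pmf, and cyclic flow tops up ATP at 2 photons each,
so in the ATP-limited regime (asserted at generation)

$$ \mu_{\max} = \frac{P - 2\,\mathrm{NGAM}}{N + 2A}, $$

with $P$ the photon bound. The default $P = 26$ puts $\mu_{\max}$ at the
~0.05 h$^{-1}$ scale of fast-growing marine picocyanobacteria, with
O$_2$ evolution and CO$_2$ uptake emerging near 2.4 and
2.0 mmol gDCW$^{-1}$ h$^{-1}$ — the magnitudes such organisms actually
show — so the biomass arithmetic is exercised with realistic numbers. The
generator also emits the full minimal-total-flux map (water closes the
elemental balance; the map is verified against $Nv=0$ at generation time)
and the essential set: every reaction carrying flux in the unique optimum
except cyclic electron flow (bypassable through the Mehler sink) and the
maintenance hydrolysis (whose flux is imposed, not required). Fixture
injectors create known defects: `inject_gaps()` removes chosen reactions;
`inject_loop()` adds an isomer pair whose cycle releases proton-motive
force from nothing — the classic wrong-directionality loop that lets ATP
synthase run in the dark.

**What the toy does not emulate:** genome-scale redundancy (hundreds of
parallel and blocked reactions, isozymes), compartment-specific proton
and charge balancing, photorespiration, alternative carbon routes, and
measurement noise. Passing tests on the toy therefore validate the
*algorithms* — LP correctness, parsimony, screen logic, detector
recovery — not the biological fidelity of any genome-scale
reconstruction; tier-3 style reproduction of published model numbers
requires the published SBML itself, which the pipeline loads when the
user supplies it.

## Numerical choices and degenerate inputs

* LP tolerances $10^{-9}$ (feasibility/optimality), steady-state residual
  bound $10^{-6}$, loop/active membership $10^{-8}$, essentiality
  threshold $10^{-4}$ h$^{-1}$ — all in configuration objects.
* Default bounds when SBML carries none: $\pm1000$ for reversible, $0/1000$
  for irreversible reactions, with a warning naming the reactions.
* Exchange detection prefers the explicit category tag; the
  single-metabolite heuristic is a logged fallback.
* Organic vs inorganic carbon in the medium is decided from metabolite
  formulas (carbon-bearing and not CO$_2$/bicarbonate/carbonate), so the
  medium builder works on any model with formulas, not just the toy.
* Empty models, zero-fraction composition components, contradictory
  fixations and unknown ids raise early, specific errors; screens and
  panels record per-item failures and continue.

## Known limitations

* No quadratic or MOMA-style objectives, no dynamic FBA, no elementary
  flux mode enumeration, no automated gap-filling from universal reaction
  databases, no gene-level deletion semantics, no strain-design
  optimisation.
* The SBML layer targets Level 3 + FBC v2 (reading legacy Level 2 bound
  annotations); SBML groups, annotations (MIRIAM/SBO) and units are not
  preserved beyond the constructs the data model carries.
* The composition-to-biomass conversion does not propagate measurement
  uncertainty into coefficient uncertainty.
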