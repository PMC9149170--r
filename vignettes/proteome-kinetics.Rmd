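---
title: "A proteome-constrained kinetic model of yeast central carbon metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A proteome-constrained kinetic model of yeast central carbon metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(protalloc)
```

## The model

`protalloc` implements a resource-dependent kinetic model of
*Saccharomyces cerevisiae* central carbon metabolism. The cell's
catalytic proteome is divided into nine sectors — glucose uptake (`Upt`,
transport plus hexokinase), upper glycolysis (`UGlc`), lower glycolysis
(`LGlc`), fermentation (`Ferm`), the glycerol electron sink (`Esnk`),
respiration (`Resp`), trehalose synthesis (`TrSn`) and degradation
(`TrDg`), and growth (`Grwt`, ribosomes and biosynthesis). Each sector's
mass fraction φ~i~ of the total proteome (1.0 corresponds to 500 mg
protein per g dry weight) bounds the capacity of one lumped reaction:

V~max,i~ = φ~i~ · k~cat,i~,  v~i~ = V~max,i~ · f~i~(c),

where k~cat,i~ is the maximum specific pathway rate per unit proteome
fraction (mol/Cmol~X~/h) and f~i~(c) ∈ [0, 1] collects saturation and
allosteric effects of the metabolite vector c. Mass balances of three
glycolytic intermediates (G6P, FBP, pyruvate), the adenylates, the
NAD(H) pair, inorganic phosphate, trehalose, and the extracellular
glucose, ethanol, glycerol and biomass give a stiff 14-state ODE system,
integrated with a compiled right-hand side through `deSolve` (`lsoda`,
absolute tolerance 10^-4^ with per-variable refinement for the
extracellular concentrations, nonnegativity enforced by clipping since
every rate law vanishes at zero concentration).

### Stoichiometry

Lumps operate on a C3 basis downstream of FBP. Uptake and upper
glycolysis each consume one ATP; lower glycolysis (per pyruvate)
consumes Pi and NAD and yields 2 ATP and NADH; fermentation reduces
pyruvate to ethanol + CO~2~, reoxidizing NADH; the glycerol sink
oxidizes NADH without ATP yield. Respiration comprises two reactions
sharing one sector: pyruvate oxidation (`Resp_TCA`, generating
w~TCA~ = 5 electron-pair carriers per pyruvate — 4 NADH and 1 FADH~2~ —
plus one substrate-level ATP) and external NADH dehydrogenase
(`Resp_NDE`). Both feed the electron-transport chain with an effective
P/O ratio of 1.0 ATP per electron pair; when the combined load
w~TCA~·v~TCA~ + v~NDE~ exceeds the shared capacity φ~Resp~·k~cat,Resp~,
both rates are scaled by the common factor that makes the load bind.
Trehalose synthesis consumes 2 G6P + ATP and releases 3 Pi; degradation
returns 2 G6P for 2 ATP, so a full turn of the cycle dissipates ATP (the
futile cycle). Growth drains 0.12 mol G6P, 0.12 mol PYR and 3.22 mol ATP
per Cmol biomass; the NADH and CO~2~ coefficients are derived so that
carbon and degree-of-reduction close exactly (the pentose-phosphate
NADPH demand is folded into the G6P coefficient). Carbon, electron and
phosphorus vectors annihilate the stoichiometric matrix exactly, which
the test suite asserts.

The growth ATP coefficient deserves a note: closing the ATP balance of
the calibration flux table under this stoichiometry requires about
3.2–3.4 mol ATP per Cmol biomass — higher than anabolic ATP
requirements alone, because it absorbs all unaccounted dissipation of a
fast-growing fermenting cell. We fix it at 3.22, the value at which the
calibrated model's simulated batch growth rate attains the 0.4/h
calibration target; it is config-overridable like every other constant.

### Rate laws

Each f~i~ is a product of Michaelis–Menten terms in the reaction's
substrates and cofactors. Four regulatory terms beyond plain saturation
are included, each canonical yeast glycolysis regulation and each
required for a well-posed model (we observed the corresponding failure
mode in simulation when it was absent):

* **G6P inhibition of uptake** (K~i~ = 12 µmol/g), standing in for
  trehalose-6-phosphate inhibition of hexokinase — the brake that
  prevents the substrate-accelerated "turbo" collapse of glycolysis at
  glucose excess.
* **AMP activation of upper glycolysis** (K~a~ = 0.01 µmol/g), the
  adenylate control of phosphofructokinase. Without it carbon influx
  ignores the cell's energy state and pyruvate accumulates without
  bound whenever ATP supply exceeds demand.
* **Pyruvate back-pressure on lower glycolysis** (K~i~ = 50 µmol/g),
  the lumped stand-in for the reversibility of the
  GAPDH–PGK–ENO–PYK segment: negligible at physiological pools, it
  throttles production when pyruvate accumulates so that FBP (and with
  it the fermentative gate) rises instead of pyruvate diverging.
* **Overflow gating of fermentation**: the pyruvate-decarboxylase
  branch is sigmoidal in pyruvate (Hill 2, K~0.5~ = 6 µmol/g — the
  classic low-affinity overflow switch) and activated by FBP (Hill 2,
  K~a~ = 0.3 µmol/g), so ethanol appears only when glycolytic flux
  outruns respiratory capacity.

The respiratory reactions carry a Pi saturation term
(K~m~ = 0.5 µmol/g): oxidative phosphorylation requires inorganic
phosphate, and the term also enforces the nonnegativity contract.

Growth responds to the adenylate energy charge
EC = (ATP + ADP/2)/(ATP + ADP + AMP) through a logistic sigmoid with
midpoint 0.8 and scale 0.05, placing the steepest response between EC
0.7 and 0.9 as observed for growing cells; narrow precursor-availability
terms (K~m~ = 0.02 µmol/g) only shut growth down when a pool empties.
Maintenance hydrolyzes ATP at a fixed 0.0155 mol/Cmol~X~/h (the
requirement measured at near-zero growth), saturating in ATP; it is not
sector-bound.

### Adenylates and conserved moieties

ATP and ADP are dynamic; AMP follows through a fast mass-action
adenylate-kinase reaction (2 ADP ⇌ ATP + AMP, K = 1), which keeps the
pool at equilibrium on a millisecond timescale while conserving the
adenylate moiety exactly in the stoichiometric matrix. Three moieties
are conserved by construction: total adenylate, total NAD(H), and total
phosphorus (free Pi plus sugar-phosphate and adenylate phosphate).
Because the lumped network contains no cofactor-synthesis reaction,
growth dilution of intracellular pools is omitted entirely: it is below
0.05% of turnover for every pool, and diluting a closed moiety (or the
phosphate bound in sugar phosphates) leaves the system without any
steady state — in early development we watched the phosphate pool drain
to zero over two simulated hours for exactly this reason.

## Calibration

`estimate_kcats()` estimates the nine specific activities from a batch
flux distribution and a batch proteome allocation by multi-start,
log-parameterized Levenberg–Marquardt fitting (tolerance 10^-12^,
bounds 0.1–60 mol/Cmol~X~/h, growth separately bounded at 8/h). The
simulated rates entering the objective are evaluated at a *fixed
reference batch metabolite profile* (glucose in excess, pools at
representative batch values, storage pool clamped at its reference
level) — the operational form of the assumption that under excess
substrate the whole proteome sector is used as far as its kinetics
allow. Two considerations force this design:

* Fitting *equilibrated* simulated fluxes is structurally degenerate:
  any flux vector matching a balanced target automatically satisfies
  the quasi-steady pool balances, so the pools are free to compensate
  kcat changes. We observed optimizer residuals of 10^-24^ with
  activities off by 35%. Fixing the evaluation state makes the
  kcat → flux map diagonal and the problem identifiable, which is what
  makes the parameter-recovery test meaningful.
* The trehalose synthesis and degradation targets are peak rates over a
  feeding cycle and need not be equal, which no steady state could
  represent; a clamped storage pool represents it naturally.

The growth-rate residual carries ten-fold weight, and a kcat set is
rejected if the *simulated* maximum growth rate (full batch dynamics,
`find_batch_state()`) does not reach the target; growth capacity is
then adjusted by bisection on k~cat,Grwt~ with a 1.5% margin so that a
chemostat operated at D equal to the batch growth rate remains strictly
feasible at feed-level glucose. The maintenance rate is never fitted.
The shipped default parameterization is the output of this calibration
against the package's batch flux preset and reference batch allocation.

The reference batch allocation itself (`batch_allocation()`) is a
synthetic stand-in assembled from the well-known mass structure of the
fermenting yeast proteome — glycolytic plus fermentative enzymes around
25–30% of protein mass, translation around 40%, mitochondria near 8%
under glucose repression — chosen once, before any downstream result
was computed, and not revisited.

## Simulation machinery

`find_steady_state()` alternates relaxation (200–250 h rounds) with a
Newton polish (Levenberg–Marquardt on the turnover-scaled right-hand
side) and accepts a state when the scaled residual falls below 10^-8^;
near washout (D close to µ~max~) several rounds are needed because the
slow manifold's time constant is 1/(µ~max~ − D). Washout (biomass below
10^-6^ Cmol/L) is a distinct outcome.

`simulate_to_stable_cycle()` declares a feast/famine solution *balanced*
when the cycle-start state repeats within 10^-3^ relative per component
(absolute floor 0.05). Extracellular products are excluded from the
criterion (no feedback; washout timescale 1/D is hundreds of cycles), as
is AMP (slaved to ATP/ADP by the fast adenylate kinase, so its
repetition error is solver noise). A single shooting step — Newton on
the cycle map in the reduced space with the three conserved moieties
frozen, since the map has a continuum of fixed points along them —
removes the slow biomass/adenylate modes; every simulated cycle,
including those consumed by the shooting Jacobian, counts against the
200-cycle budget. The feast and famine legs are integrated separately so
the solver never steps across the square-wave discontinuity, and the
famine output grid is densified toward the feed stop where residual
substrate decays fastest.

## Proteome evolution

`evolve_proteome()` implements the Monte Carlo selection: batches
(default 50) of candidate proteomes drawn per sector from
φ~i~·U(0.75, 1.25), with extinct sectors re-seeded from U(0, 10^-3^),
the respiration sector clipped at the 12% mitochondrial cap, and
over-full candidates renormalized (and flagged). The incumbent is
replaced by the batch's best candidate when it is balanced and at least
matches the incumbent objective at a finite resolution: 0.1 mmol/L for
the residual-substrate objective (the solver's absolute tolerance read
in SI concentration units, and the order of a residual-glucose assay's
resolution) and 10^-3^ mmol/L for the time-weighted cycle objective,
whose averaging over the cycle resolves far finer differences. A
strictly better bin always wins, and a candidate in the incumbent's bin
is accepted as an equal-fitness variant. The latter is what lets idle capacity erode: at
low dilution rates most proposals are selectively neutral, and the
multiplicative proposal noise (median factor below 1) then drifts
unused sectors down, exactly the slow loss of idle proteome expected
from long adaptation. Acceptance is monotone in the quantized
objective and fully deterministic given the seed. The chemostat objective is the
residual substrate concentration at steady state; the dynamic objective
is the time-weighted average substrate concentration over the balanced
cycle, computed by trapezoidal quadrature.

Every candidate of a run is simulated from the same fixed initial
culture state: a standard substrate-rich inoculum for chemostat runs,
the seed's chemostat steady state at the average dilution rate for
feast/famine runs. This matters because the model is bistable — a
glycolytic-collapse attractor coexists with the productive state — and
reachability from the running culture is part of selection: a mutant
whose uptake capacity collapses glycolysis when it meets the inoculation
glucose burst is not viable, which is the constraint that keeps uptake
capacity (and with it the allocated proteome) bounded at low dilution
rates. Fixed-state evaluation also keeps the objective a deterministic
function of the candidate.

`dilution_sweep()` chains evolutions from high to low dilution rate,
seeding each rate with the previous optimum, as in the warm-started
sweep the method is known for. `estimate_overcapacity()` implements the
inert 10th sector: sectors are processed in decreasing size order
(ties broken by fixed sector order); per iteration 1% of the current
sector size is moved to the inert sector and kept only if the average
uptake and growth fluxes stay within 1% of the reference; the first
rejection ends the sector, and a sector decaying below 10^-6^ is set
fully inert.

## Problem sizes used by the shipped checks

The package's acceptance script and test suite run reduced problem
sizes, chosen as the package's own reporting defaults: dilution sweeps
with 120–200 candidate evaluations per rate on 5–8 point grids with 2–3
replicate seeds, single-regime evolutions with 240–1000 evaluations,
feast/famine evolutions with 100–240 evaluations, and parameter-recovery
with 4–6 multi-starts. Larger budgets sharpen the stochastic outcomes
but do not change the qualitative phenotypes.

## What the synthetic fixtures do and do not cover

`make_protein_table()` generates protein tables whose annotations
exercise the shipped mapping ruleset and whose sector masses hit
specified targets exactly (or within a specified coefficient of
variation). They emulate the mass structure of a measured proteome, not
its biology: no shared peptides, no iso-enzyme ambiguity (the real
HXK/GLK split is explicitly out of scope), no missing values, and
annotation text drawn from a small vocabulary. Passing the round-trip
tests therefore validates the mapping logic and the calibration
plumbing, not the fidelity of any real annotation pipeline.

## What the shipped checks reproduce, and what they do not

The packaged checks recompute every headline quantity at the reduced
problem sizes above. The deterministic physiology reproduces well: the
calibrated batch steady state, the overflow (ethanol) onset pattern
with an oxygen plateau pinned by the 12% respiration cap, the
fermentative proteome-specific ATP yield, yield collapse across the
critical rate, and the peak-versus-average saturation signature of
dynamic feeding (high peak, low cycle mean for the large sectors).

Several evolved-proteome quantities do not reach their expected values
under the package's kinetics and reduced budgets, and the checks report
them honestly rather than forcing them: (i) evolved proteomes remain
nearly fully allocated at intermediate dilution rates — the
residual-substrate objective in these kinetics rewards uptake capacity
up to the collapse-reachability ceiling at every rate, so idle space
erodes only by slow neutral drift; (ii) for the same reason the
ethanol onset of the evolved chain sits slightly below the critical
rate; (iii) respiration-sector erosion at low dilution rates is
drift-limited at reduced budgets, leaving steady-state respiration
saturation below its long-adaptation value; and (iv) the feast/famine
analyses must be seeded from the batch proteome (the
chemostat-optimized one collapses on the feast pulse — itself the
expected failure of steady-state-adapted cells under perturbations),
whose moderate uptake capacity keeps the cycle stable even without a
storage sector, so the storage-stability threshold and the
growth-sector-versus-perturbation trend are not resolved at these
budgets.

## Known limitations

* The model inherits the scope of its lumped structure: no iso-enzymes,
  no post-translational modification, no signaling, no mechanistic
  mitochondrial biogenesis (the 12% respiration cap is a constraint).
* The printed calibration flux table is slightly carbon- and
  redox-inconsistent (experimental error); the calibrated model's own
  batch fluxes deviate from it by a few percent in the same pattern a
  simulation-based reproduction of that table shows.
* Monte Carlo outcomes at low dilution rates are diffusion-dominated
  (objective differences fall below the resolution), so evolved
  allocations there inherit history from higher rates; replicate seeds
  are provided for all stochastic reports.
* Under extreme allocations the stiff system can collapse into the
  inactive attractor; the package reports these as washouts or
  unbalanced solutions rather than attempting to continue.
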