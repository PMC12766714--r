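---
title: "Cycle-based flux simulation and comparative genomics for PAOs: models and methods"
author: "ebprgem authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cycle-based flux simulation and comparative genomics for PAOs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebprgem)
```

# The scientific setting

Polyphosphate-accumulating organisms (PAOs) such as *Candidatus*
Accumulibacter drive enhanced biological phosphorus removal (EBPR) in
activated-sludge plants. Their defining physiology is cyclic: in the
anaerobic feed phase they take up volatile fatty acids and store them as
polyhydroxyalkanoates (PHA), paying the ATP cost by hydrolysing
intracellular polyphosphate (releasing phosphate) and drawing redox
equivalents from glycogen; in the subsequent aerated phase they respire the
stored PHA to grow and to rebuild their storage pools. `ebprgem`
implements a constraint-based, time-resolved simulation of exactly this
cycle on genome-scale metabolic models (GEMs), together with the
genome-comparative procedures that typically accompany a genome-resolved
study of the lineage: pangenome partitioning and ancestral gene-content
reconstruction, quality-aware ANI dereplication, CRISPR-spacer host
linkage, and biogeographic/co-occurrence summaries. Every analysis can be
exercised end-to-end on seeded synthetic inputs with known ground truth.

# The dynamic flux-balance cycle

## Steady-state core

A model is a stoichiometric matrix $S$ over metabolites in three
compartments. Cytosolic and extracellular metabolites are balanced at
quasi-steady state, $S v = 0$, with fluxes $v$ bounded by
$l \le v \le u$ (mmol gDW$^{-1}$ h$^{-1}$; exchange fluxes negative for
uptake). Metabolites in the `pool` compartment — PHA, glycogen and
polyphosphate — are *not* balanced: a `storage_sink` reaction deposits
into (positive flux) or mobilizes from (negative flux) a pool, and the
integrator, not the LP, owns the pool amounts. Three solves are provided:

* `solve_fba()` — maximize (or minimize) one flux, typically biomass;
  the optimal biomass flux is the specific growth rate $\mu$ (h$^{-1}$).
* `solve_pfba()` — parsimonious FBA: fix biomass at its optimum scaled by
  $(1-10^{-6})$ (the slack avoids numerical infeasibility of an exact
  pin), then minimize $\sum_j |v_j|$ over **all** reactions via the
  standard split of each flux into two irreversible halves.
* `solve_min_total_flux()` — fix a substrate exchange to a prescribed
  uptake and minimize $\sum_j |v_j|$, an "energy-efficient storage
  metabolism" objective for the anaerobic phase, where growth is not the
  driving force.

The linear programs are solved by a dense bounded-variable two-phase
primal simplex written for this package (compiled code, Dantzig pricing
with a Bland fallback, primal/dual tolerances $10^{-9}$). At the scale of
these models (tens of metabolites, up to a few hundred split variables) a
fresh LU factorization per iteration is affordable and numerically the
most stable choice. The solver is validated in the test suite against
exhaustive vertex enumeration on small models and against an external LP
implementation; any solver outcome other than optimal/infeasible raises
rather than returning silently.

## Phase constraints

`apply_anaerobic()` closes the oxygen exchange to uptake and fixes every
ETC-tagged reaction to zero, following the convention that anaerobic
operation removes the whole electron-transport chain rather than just the
terminal oxidase. `apply_aerobic()` restores oxygen uptake to the model's
configured limit (default $-1000$, i.e. effectively unbounded, since no
value is prescribed), closes every carbon exchange to uptake (secretion
stays open), and opens the storage sinks in the pool-consuming direction.
ETC membership is a reaction tag assigned at model load, because automated
reconstructions do not agree on a single annotation convention; the tag
list is under user control.

## Forward-Euler integration

`simulate_cycle()` advances a 1.5 h anaerobic / 3.5 h aerobic cycle in
0.2 h steps. Each step solves one LP on the phase-constrained model and
updates every tracked amount with first-order (forward Euler) rules:

$$Q(t+\Delta) = Q(t) + v_Q \, X(t) \, \Delta, \qquad
  X(t+\Delta) = X(t)\,(1 + \mu \Delta),$$

for substrate, CO$_2$, the three pools, and biomass $X$. Design choices
worth stating explicitly:

* **Fractional phase lengths.** $1.5/0.2 = 7.5$, so the final anaerobic
  step is truncated to 0.1 h (and analogously for any fractional phase);
  the phase boundary and cycle end land exactly at 1.5 h and 5.0 h.
* **No anaerobic growth.** Biomass bounds are $[0,0]$ during anaerobic
  solves (configurable): the anaerobic objective is storage, not growth.
* **Uptake capping.** The effective anaerobic uptake is
  $\min(q,\ \mathrm{substrate}/(X\Delta))$ for configured rate $q$, so
  the explicit substrate pool can never go negative.
* **Pool capping and aerobic pacing.** Anaerobically, pool-consuming sink
  fluxes are capped by amount$/(X\Delta)$ — the rates are set by the fixed
  uptake, so the cap only guards non-negativity. Aerobically the cap uses
  the *remaining phase time* as the horizon: growth maximization is
  greedy, and with a bare per-step cap it strips every reserve in the
  first aerobic step, after which the maintenance demand has no ATP
  source and the remainder of the phase is infeasible. Pacing mobilization
  over the remaining time spreads growth across the phase — the
  discrete analogue of a storage-limited mobilization rate — and keeps
  maintenance satisfiable to the end of the cycle.
* **Maintenance.** A constant non-growth-associated demand of 0.398 mmol
  ATP gDW$^{-1}$ h$^{-1}$ is enforced as the lower bound of the ATP
  hydrolysis reaction in every solve.
* **Units.** The reactor volume is fixed at 1 L, so extracellular mmol and
  mM coincide; pools are absolute C-mmol (PHA, glycogen) or P-mmol
  (poly-P); biomass is gDW.
* **Infeasible steps** terminate the trajectory with a status flag instead
  of raising; the batch substrate screen maps this to "not utilizable".

An infeasibility can also arise legitimately: a model whose anaerobic
network cannot regenerate ATP (no polyphosphate or glycolytic route) has
no flux vector satisfying maintenance, which is the mechanistic signature
of a non-PAO under this protocol.

`carbon_balance()` audits the scheme: substrate carbon plus glycogen
drawdown against CO$_2$, net PHA and biomass carbon. Because every tracked
quantity is updated with the same $vX\Delta$ rule and each LP solution is
internally balanced, this ledger closes to rounding error at any step
size; the audit is therefore a regression guard on the integrator's
bookkeeping (a genuinely first-order quantity is the trajectory itself,
not the conservation ledger), and the step-halving check asserts the
residual is non-increasing.

## Initial conditions and the open aerobic-replenishment question

The cycle needs initial amounts; none are prescribed, so the defaults are
fixture-calibrated and recorded in the trajectory metadata: 15 mmol
substrate, 10 C-mmol glycogen, 10 P-mmol polyphosphate, 0 PHA, 1 gDW
biomass, uptake 3 mmol gDW$^{-1}$ h$^{-1}$. Under these conditions the
anaerobic acetate phase consumes about half the polyphosphate and the
aerobic phase consumes the accumulated PHA with biomass growth of roughly
45% per cycle. How aerobic glycogen/poly-P resynthesis should be *driven*
under a growth objective is genuinely open: here replenishment sinks are
open with zero objective weight, so parsimonious FBA uses them only when
they help growth — meaning pools are rebuilt only implicitly. This
conservative default is documented rather than hidden behind an ad-hoc
multi-objective weighting.

# Phenotype screens

`screen_auxotrophy()` places a model aerobically in a defined minimal
medium (one carbon source — acetate by default at $-10$ — plus NH$_4^+$,
P$_i$ and the other inorganic exchanges the model carries), opens all 20
amino-acid uptakes at $-10$ (no value is prescribed; the bound is
configurable), and solves 21 FBAs: a baseline and one per amino acid with
exactly that uptake closed. A drop of the predicted growth rate below
0.01 h$^{-1}$ calls the model auxotrophic for that amino acid. Outside the
time-resolved cycle the storage sinks are closed in the consuming
direction — without amounts to cap them they would otherwise act as
phantom carbon and ATP sources.

`screen_secretion()` is this package's operationalization of an
amino-acid secretion call (no published procedure exists to follow): with
amino-acid uptakes closed and biomass pinned at a fraction (default 0.5)
of its optimum, the export flux of each amino-acid exchange is maximized
in turn; exports above $10^{-6}$ are called secretable. Both knobs are
exposed, and the nesting property (higher growth fraction $\Rightarrow$
subset) is tested.

`screen_substrates()` runs one full cycle per model $\times$ substrate and
stages failures mechanistically: `no_transporter` when the substrate's
extracellular metabolite is touched by no reaction besides its exchange
(the genomic signature of a missing uptake system), `anaerobic_infeasible`
when a step LP has no solution, `zero_yield` when the cycle completes but
the biomass yield — $\Delta X$ per C-mmol consumed — does not exceed
$10^{-6}$ gDW/C-mmol. A utilizable call requires both anaerobic-phase
feasibility and positive aerobic yield, the stricter of the two readings
of an "EBPR-feasible substrate".

# Comparative-genomics procedures

**Pangenome partitioning.** A family is *core* when present in at least
$\lceil 0.8\,n\rceil$ genomes (109 of 136), and *clade-specific* when
present in strictly more than 75% of one clade's members and absent from
every genome outside it.

**Wagner parsimony.** Ancestral copy numbers minimize
$\sum_{\text{branches}} [\,2\max(0, \Delta^+) + \max(0, \Delta^-)\,]$
(gain penalty 2, loss penalty 1, both configurable) by Sankoff dynamic
programming over states $0..K$, $K$ defaulting to each family's observed
maximum. The root state minimizes total cost with no prior, matching
unrooted-style parsimony; all ties — root and backtrace — break toward
the smaller count, which makes output deterministic and biases ambiguous
reconstructions toward recent gains. With equal unit penalties on binary
data the event counts coincide with Fitch parsimony, which the tests use
as an independent cross-check. Families with a positive reconstructed
count at the designated LCA node are *ancestral*; those absent there but
present below are *derived*.

**Dereplication.** Quality score is $QS = \mathrm{completeness} - 5
\times \mathrm{contamination}$. Genomes join when symmetrized ANI and
aligned fraction both reach the thresholds (99%/0.85 for dereplication,
95%/0.30 for species clustering; boundaries inclusive); clusters are
connected components (single linkage) and the representative is the
highest-QS member, ties to the lexicographically smallest id. Single
linkage is a deliberate simplification of greedy two-stage clustering;
on block-structured inputs the partitions coincide, on real data cluster
counts may differ slightly.

**Spacer linkage.** Spacers are matched ungapped on both strands at 97%
identity, 90% coverage and at most one mismatch, all jointly. With at
most one mismatch permitted, gapped alignment cannot change the outcome,
so indels are not modeled. Interior full-length hits come from
`Biostrings` pattern matching; sub-100% coverage arises only from hits
overhanging a contig end, which are scanned directly. The "at most one"
reading of the mismatch rule is the strict one and is flagged as a
configurable. Host infection rate is reported truncated toward zero
(92/136 → 67%), with the exact fraction alongside.

**Ecology.** Representative samples minimize Bray–Curtis dissimilarity
($\sum_i |a_i-b_i| / \sum_i (a_i+b_i)$) to the within-plant centroid;
continent proportions normalize summed clade abundances per continent;
co-occurrence networks retain Spearman correlations with $|\rho| > 0.3$
and Benjamini–Hochberg adjusted $p < 0.05$, adjusted across all tested
pairs (per-focal adjustment is the other defensible reading; across-pairs
is the default). P-values come from `stats::cor.test` — exact for small
tie-free samples, the $t$ approximation otherwise; constant taxa cannot
be ranked and are skipped with an explicit reason.

# The synthetic generators and what they do (not) show

Every input class has a seeded generator; one master seed fans out through
fixed offsets so adding a generator never perturbs existing fixtures.

The PAO model from `make_pao_model()` is a ~90-reaction network whose
*architecture* — storage pools, an ETC, per-amino-acid biosynthesis, and
knockout-able transporters — matches a PAO reconstruction, but whose
stoichiometry is condensed: glycolysis, TCA and the glyoxylate route are
lumped, all amino acids cost one pyruvate + ATP + NADH, and biomass draws
0.5 mmol of each amino acid and 40 mmol ATP per gDW, which puts predicted
growth rates on the usual single-digit h$^{-1}$ scale. Substrate-level
ATP is deliberately routed through polyphosphate anaerobically so that
the generator reproduces the canonical anaerobic phenotype (P release
with PHA accumulation) for the right mechanistic reason. Consequences:
passing screens on these fixtures demonstrates that the *procedures*
recover planted genotypes exactly, not that real gapseq reconstructions
would yield any particular auxotrophy spectrum or yield value.

The gene-matrix generator evolves binary families root-to-tips with
per-branch gain/loss probabilities (defaults 0.02/0.1, root presence
0.6). At much harsher loss rates deep ancestral families survive in so
few tips that no reconstruction method can classify them — the ≥90%
recovery property holds in regimes where the signal is recoverable at
all, and the defaults are chosen inside that regime. ANI fixtures are
block matrices with ±0.1 jitter; spacer fixtures plant protospacers at
controlled identity/coverage (sub-100% coverage plants overhang the
contig end); abundance fixtures combine plant-level log-normal profiles
with replicate jitter and Gaussian-copula pairs at planted rank
correlations. None of the generators attempt realistic sequence content,
viral genomes, or compositional effects of relative abundance.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which every property is informative: 12 models for
the screens, a 20-leaf tree with 500 families, 9 genomes in 3 ANI
clusters, 40 spacers against a 20 kb contig, 10 plants × 3 samples.
Exhaustive oracles run on all rooted topologies with ≤4 leaves (all count
vectors ≤2) plus randomized 5–6-leaf instances, and LP vertex enumeration
on models small enough to enumerate. Solver tolerances are $10^{-9}$;
steady-state residuals are asserted below $10^{-6}$; comparisons of
floating thresholds (core counts, infection-rate truncation) round before
ceiling/floor so binary noise cannot shift a printed integer.

# Known limitations

* No kinetics: uptake is a fixed rate, not a Monod term; no pH,
  temperature, or population structure. The cycle evaluates metabolic
  *feasibility*, not reactor dynamics.
* Aerobic storage replenishment is not actively driven (see above).
* Single-linkage dereplication approximates greedy two-stage clustering.
* The secretion criterion is an explicit stand-in for an unpublished
  procedure.
* Gapped spacer alignments and multi-mismatch regimes are out of scope by
  construction of the thresholds.
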