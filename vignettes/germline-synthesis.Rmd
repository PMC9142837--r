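---
title: "Synthesizing Boolean networks for the germline stem-cell fate decision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing Boolean networks for the germline stem-cell fate decision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolsynth)
```

## The model class

`boolsynth` reasons over *Abstract Boolean Networks* (ABNs). An ABN is a
tuple ⟨G, E, E?, R⟩: components G that are active or inactive, definite
signed interactions E present in every model, optional signed
interactions E? that the synthesizer may include or exclude, and for each
component a non-empty menu R_g of admissible update rules. A *concrete
network* fixes one subset of E? and one rule per component; it is an
ordinary Boolean network updated synchronously, q′(g) = R_g(q) for all g
at once. Synchronous semantics makes a trajectory a deterministic
function of its initial state and clamps, and makes a state that repeats
once repeat forever — experiments therefore pin steady outcomes by
constraining two equal consecutive steps.

### Regulation conditions

Update rules are not arbitrary Boolean functions. A rule sees only the
*occupancy* of the component's regulators: whether none, some or all of
its activators (respectively repressors) are currently active. A
component with no regulator of a given sign has occupancy *none* for that
sign — never *all* — so absent regulators cannot activate anything
spuriously. The admissible rules are exactly the functions on this 3×3
grid that are monotone (non-decreasing in activator occupancy,
non-increasing in repressor occupancy) and non-constant. Enumerating all
2⁹ = 512 grid functions leaves 20 monotone tables of which 2 are
constant: 18 templates. This count is recomputed, not assumed, both in
the test suite and in `scripts/acceptance.R`.

The package orders the 18 templates canonically: tables are sorted by
their 9-bit string (cells activator-major: (none,none), (none,some), …,
(all,all)), then a single transposition places at index 5 the template

> AllActivators ∨ (NoRepressors ∧ ¬NoActivators)

which is the one template whose numbering is externally fixed. The full
table ships in `inst/extdata/regulation_conditions.tsv`. Any other
permutation of the remaining 17 indices would be equally valid; nothing
in the package depends on their order beyond determinism.

### Degenerate cases

Three conventions close the semantics:

* a component with **no effective incoming interaction** (and no clamp)
  decays to inactive at the next step. This is what makes a
  *self-degrading signal* — active at step 0, gone at step 1 —
  expressible, and it prevents isolated nodes from holding state.
* **clamps** (knockout = always inactive, forced expression = always
  active) override regulation at every step *including step 0*.
* initial values not fixed by a step-0 constraint and not clamped are
  **free**: the solver chooses them existentially, per experiment.

## The synthesis engine

Given an ABN and an experiment suite, synthesis asks for one shared
choice of optional edges and rules, plus per-experiment free initial
values, such that every experiment's timed constraints hold on the
simulated trajectory. The engine (`synthesize()`, C++ core) sweeps the
concretization space as a fixed mixed-radix odometer — optional-edge bits
first, then menu positions — simulating each experiment incrementally
and abandoning a candidate at the first violated observation; free
initial values are enumerated innermost with early exit. The sweep is
exhaustive and deterministic: the same problem always yields the same
solution list, and an `UNSAT` answer is a proof of absence over the
whole space (the engine refuses spaces above 5·10⁷ candidates;
`verify_model()` likewise bounds the free-initial search at 2²⁰).

Two design points deserve comment. First, the engine is explicit search
rather than a SAT/SMT encoding of the unrolled transition relation; at
the problem sizes this package targets (the germline space has 2 048
concretizations; the synthetic fixtures used in testing stay below 10⁴)
exhaustive sweep with incremental checking is faster than encoding
overhead, and it yields the full solution set for free. Second,
correctness is never trusted to one code path: `brute_force_synthesize()`
re-derives the solution set by enumerating concretizations in pure R and
re-simulating with the R simulator, and the test suite asserts engine ≡
oracle (status and full solution set) on 100 random instances, plus
simulation-based re-verification of every returned witness.

`test_null_hypothesis()` replaces one experiment by its outcome-negated
copy and re-solves. By default the other experiments' constraints are
retained, so `SAT` means: *some network consistent with everything else
realizes the opposite outcome of this experiment*. An `isolate = TRUE`
mode solves the negated experiment alone instead; the packaged analyses
use the retained mode.

## The germline network

`germline_abn()` encodes the stem-cell-fate versus meiotic-development
decision circuit of the young adult *C. elegans* hermaphrodite germ line:
24 components, 40 interactions (32 definite, 8 optional),
edge-by-edge in `inst/extdata/germline_edges.tsv`. Functional modules:

* **Notch core** — DTC ligands (LAG-2, APX-1) activate GLP-1; the
  intracellular domain requires the presenilins (HOP-1/SEL-12, redundant)
  and is turned over by SEL-10; LAG-1 with SEL-8 transduces the signal.
* **Effectors** — LAG-1 activates LST-1, SYGL-1 and FBF-2. LST-1 and
  SYGL-1 are redundant: their targets use *some-activator* (OR)
  templates, and the menus also admit the *all-activator* (AND)
  alternative for FBF-1 binding so that the solver, not the modeler,
  rules it out against the single-knockout data.
* **Two-state FBF-1** — FBF-1 appears as two components: `FBF1B`
  (bound to LST-1/SYGL-1, repressing GLD-1, GLD-3, SCF^PROM-1^ and the
  axis/SC proteins) and `FBF1U` (unbound, promoting GLD-3). LST-1 and
  SYGL-1 activate the bound form and repress the unbound form; `FBF1U`
  uses the *no-repressors* template, so it is present exactly when no
  partner sequesters it.
* **Meiotic entry** — GLD-3→GLD-2→GLD-1 with NOS-3 as an optional
  redundant activator of GLD-1 accumulation; SCF^PROM-1^ and the axis/SC
  proteins as parallel routes, basally on unless repressed (their
  repression edges are optional — a model without them leaves the route
  constitutively absent, since a component with no effective regulator
  decays).
* **Fate readout** — `MeioticDev` is activated by any of GLD-1 (optional
  edge), GLD-2 (definite), SCF^PROM-1^ and axis/SC (optional);
  `StemcellFate` requires CYE-1/CDK-2 and is repressed by `MeioticDev`.

The definite/optional split follows the rule that well-characterized
interactions are definite while redundant or hypothesized routes are
optional. One boundary case was settled analytically: the GLD-2 →
`MeioticDev` edge is definite. With it optional, a concretization exists
(GLD-1 as sole fate route under the anchored template with both of its
optional activators chosen) that passes all eight perturbation
experiments yet retains the stem fate in the lst-1 sygl-1 double
knockout, which would make that null hypothesis satisfiable — the GLD-2
arm is precisely the well-characterized meiotic-entry route, so pinning
it is both biologically and formally the right call.

### Signaling setups and experiment contexts

The DTC signal is driven by an auxiliary self-sustaining signal `S0`
(`S0 → S0`, `S0 → DTC`, both definite), a setup-level addition not
counted in the core 24/40. An experiment started with `S0 = 1` models a
cell inside the niche: the DTC signal is constitutive. Started with
`S0 = 0`, the DTC signal is active at step 0 only and decays — a cell
losing the signal as it moves proximally. The `"reduced"` setup adds a
second auxiliary, self-degrading signal `SD` gating CYE-1/CDK-2 (whose
menu then requires an activator), modeling reduced proliferative input.

Each packaged experiment is 21 steps (indices 0..20, so "after 20 steps"
is state index 20), has a fully specified initial state (all components
off except the signal context), and constrains the fate readouts at
steps 19 and 20. In the `"niche"` suite, experiments whose phenotype is
about *maintaining* the stem fate (wild type, GLP-1 KO, LST-1/SYGL-1
single and double KO) run in the niche context, while experiments whose
phenotype is *failure to enter meiosis* (GLD-1 GLD-2 double KO and the
three forced-expression experiments) describe cells that would normally
differentiate and run in the signal-losing context. This split is what
lets a single suite express both directions of the decision: under
constitutive Notch the meiotic routes are necessarily repressed in every
consistent model, so a meiosis-failure constraint would be vacuous there
and its null hypothesis unsatisfiable for structural rather than
biological reasons. The GLD-1 GLD-2 and FE outcomes constrain only
`MeioticDev` (the phenotype speaks to meiotic entry, and in the losing
context the stem readout necessarily decays with its CYE-1/CDK-2 input
in part of the model family).

With these conventions the packaged suite is satisfiable (800 consistent
concretizations out of 2 048), every witness reproduces the perturbation
fate matrix, and the null hypothesis is satisfiable for the GLD-1 GLD-2
double knockout only — the witness showing meiotic entry carried by
SCF^PROM-1^ or the axis/SC proteins with both GLD arms clamped off —
exactly the asymmetry the perturbation data leave open.

```{r null, eval = FALSE}
p <- germline_problem("niche")
vapply(germline_perturbation_names(), function(lab)
  test_null_hypothesis(p$abn, p$suite, lab)$status, "")
```

## Synthetic fixtures

`random_abn()` and `plant_and_observe()` generate the test bed: seeded
random ABNs (edges drawn uniformly over signed source–target pairs,
activation and repression equally likely, self-loops allowed; random
condition menus), a hidden concretization, and observation suites sampled
from its simulated trajectories. The planted network satisfies its suite
by construction, so recovery — synthesis is SAT and the hidden network
is in the exhaustive solution set — is a ground-truth check of the whole
pipeline, and flipping a single later-step observation of a fully
observed, fully determined fixture (no optional edges, singleton menus)
must yield UNSAT because the trajectory is forced from step 0.

What these fixtures emulate is the *structure* of the reasoning problem:
uncertainty in topology and logic, partial observation, perturbation
clamps. What they do not emulate is biological realism — no scale-free
topology, no modular organization, no correlated observations — so
passing recovery tests certifies the solver and semantics, not any claim
about real regulatory networks.

Default problem sizes in the tests (4–6 components, 2–4 optional edges,
menus of 2, two experiments of length 6–8, 100 seeds for the
equivalence and recovery harnesses, 10⁴ monotonicity cases) were chosen
so that the brute-force oracle remains exact over the full
concretization space while the suites still exercise every code path;
they are the package's own testing conditions, and all are reproducible
from literal seeds.

## Numerical and degenerate-input choices

* Determinism everywhere: the engine takes no random decisions; fixture
  randomness is confined to `fixture_spec(seed)` with R's default RNG,
  and the global RNG state is saved and restored around generation.
* Enumeration order (and therefore *which* witness or first model is
  reported) is part of the package's contract only up to determinism;
  solution-set comparisons in the tests are order-free.
* Duplicate observation constraints collapse if they agree and error if
  they contradict; perturbed components may not be observed at the
  opposite value; constraint times must lie inside the experiment.
* Empty networks, empty suites (trivially SAT), zero-optional ABNs and
  zero-free-initial experiments are all legal boundary cases and tested.

## Known limitations

* Asynchronous update semantics are out of scope; all results are
  statements about synchronous dynamics.
* The engine's exhaustive sweep is exponential in the number of optional
  edges and menu sizes; it is intended for the regime where the full
  solution set is wanted and the space is bounded (≲ 10⁷), not for
  large-scale synthesis.
* Boolean abstraction: no partial knockouts, dosage, or quantitative
  pathway strengths. The GLD-1 GLD-2 null-hypothesis satisfiability is a
  direct symptom — the formalism weighs the three meiotic-entry routes
  equally, which is precisely what quantitative data would refine.
* The packaged germline edge roster beyond the printed interaction table
  (the two-state FBF-1 expansion, fate-readout wiring, definite/optional
  flags) is a documented reconstruction; `inst/extdata/germline_edges.tsv`
  is the authoritative ledger of what this package encodes.
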