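# boolsynth

Synthesis of Boolean gene-regulatory networks from experimental
constraints, with a packaged model of the *Caenorhabditis elegans*
germline stem-cell fate decision.

## The problem

Many regulatory circuits are known only up to uncertainty: some
interactions are firmly established, others are hypothesized or redundant,
and the logic by which multiple regulators combine is rarely measured
directly. `boolsynth` works with **Abstract Boolean Networks** (ABNs): a
tuple ⟨G, E, E?, R⟩ of components G, *definite* signed interactions E,
*optional* signed interactions E?, and, for each component g, a non-empty
menu R_g of admissible update rules. A *concrete network* selects a subset
of E? and one rule per component; the space of concretizations has size
2^|E?| · ∏ |R_g|.

Update rules are drawn from the 18 **regulation conditions**: every
Boolean function over the 3×3 grid of activator/repressor occupancy
(*none / some / all* of a component's activators and repressors active)
that is non-decreasing in activators, non-increasing in repressors, and
non-constant. Exhaustive enumeration of all 2⁹ = 512 grid functions yields
exactly 20 monotone tables, two of them constant — hence 18 templates.
Index 5 is pinned to

> R(c, q) = AllActivators(c, q) ∨ (NoRepressors(c, q) ∧ ¬NoActivators(c, q))

Dynamics are synchronous: q′(g) = R_g(q) for every g simultaneously; a
knockout (KO) clamps a component inactive and a forced expression (FE)
clamps it active at every step. **Experiments** are bounded scenarios —
a length k, clamps, and timed observation constraints (e, t, c, v) such as
"the DTC signal is active at step 0 and inactive at step 20".
**Synthesis** asks whether any concretization satisfies every experiment
at once (with per-experiment free initial values chosen existentially),
enumerates all consistent networks, and proves absence when none exists.
A **null-hypothesis test** re-solves with one experiment's outcome
negated: SAT means some consistent network realizes the opposite
phenotype.

The search engine is an exhaustive, deterministic sweep of the
concretization space (compiled code, incremental constraint checking with
early abandon); `brute_force_synthesize()` and `verify_model()` provide an
independent pure-R oracle against which the engine is property-tested.

## The germline model

`germline_abn()` builds the packaged decision circuit of the young adult
hermaphrodite germ line: 24 components and 40 signed interactions — the
DTC niche signal, the core GLP-1 Notch pathway, the redundant LST-1/SYGL-1
effectors, a two-state (bound/unbound) FBF-1, the GLD-1 accumulation and
GLD-2/GLD-3 meiotic entry pathways, the SCF^PROM-1^ and chromosome
axis/SC routes, CYE-1/CDK-2, and the two fate readouts `StemcellFate` and
`MeioticDev`. 32 interactions are definite, 8 optional; the edge-by-edge
ledger ships in `inst/extdata/germline_edges.tsv`. `germline_suite()`
encodes the wild type plus eight KO/FE perturbation experiments (GLP-1
KO/FE, LST-1 and SYGL-1 single/double KO and FE, GLD-1 GLD-2 double KO),
each 21 steps long with fates constrained at the last two steps.

## Worked example

```r
library(boolsynth)

net <- germline_abn()
net
#> Abstract Boolean network
#>   components:        24
#>   interactions:     40 (32 definite, 8 optional)
#>   state space:      16,777,216
#>   concretizations:  2,048

p   <- germline_problem("niche")      # setup-augmented ABN + suite
res <- synthesize(p$abn, p$suite, limit = 10)
res
#> Synthesis result: SAT
#>   concretization space: 2,048 (10 examined, stopped at limit)
#>   solutions collected:  10
```

`SAT` means concrete networks consistent with all nine encoded
experiments exist; each returned model carries one witness trajectory per
experiment, re-verified by independent simulation. The wild-type witness
reproduces the expected order of gene activity — the Notch cascade fires,
the effectors silence the meiotic pathways after a transient, and the
stem-cell fate locks in:

```r
render_trajectory_table(res$models[[1]]$witnesses$wild_type)[
  c(1, 6, 11, 21), c("step", "DTC", "GLP1", "LST1", "FBF1B",
                     "GLD2", "StemcellFate", "MeioticDev")]
#>  step DTC GLP1 LST1 FBF1B GLD2 StemcellFate MeioticDev
#>     0   1    0    0     0    0            0          0
#>     5   1    1    1     0    1            0          1
#>    10   1    1    1     1    0            1          0
#>    20   1    1    1     1    0            1          0
```

Null-hypothesis tests negate one experiment's outcome and re-solve. Only
the GLD-1 GLD-2 double knockout admits the opposite phenotype — some
consistent networks let the SCF^PROM-1^ or axis/SC routes sustain meiotic
entry with both GLD arms removed — while every other perturbation's null
hypothesis is unsatisfiable:

```r
test_null_hypothesis(p$abn, p$suite, "gld1_gld2_ko")$status
#> [1] "SAT"
test_null_hypothesis(p$abn, p$suite, "glp1_ko")$status
#> [1] "UNSAT"
```

A command-line interface wraps the same functions
(`inst/scripts/abn-tool.R`): `synth`, `simulate`, `nullhyp`, `export`
(DOT/GraphML), `fixtures` and `summary`; exit status 0 means SAT, 1
UNSAT, 2 error.

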