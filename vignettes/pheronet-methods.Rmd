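---
title: "Modelling the yeast pheromone response with qualitative Petri nets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the yeast pheromone response with qualitative Petri nets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pheronet)
```

## The model

When a MATa yeast cell senses alpha-factor, the Ste2 receptor activates a
heterotrimeric G protein; the released G-beta-gamma dimer nucleates, via
Cdc42 and Ste20, the Ste5-scaffolded MAP-kinase cascade
(Ste11 &rarr; Ste7 &rarr; Fus3); doubly phosphorylated Fus3 finally frees the
transcription factor Ste12 from its Dig1/Dig2 repression complex, committing
the cell to the mating program.  `pheronet` represents this pathway as a
discrete place/transition Petri net: species are places, reactions are
transitions, and a transition is *enabled* when every pre-place holds at
least the connecting arc's weight in tokens.  Firing consumes those tokens
and deposits the outgoing arc weights in the post-places.

Three modelling devices carry the biology:

* **Pooled pre-places.**  Reaction strengths (kd values) are unknown, so a
  reaction with several reactants is rewired through a single *pool* place
  `s_k` fed by per-reactant *dummy* transitions (`p_j -> e_j -> s_k -> t_k`).
  The pool accumulates the weighted cumulative concentration of all
  reactants, and the single arc `s_k -> t_k` carries the reaction's
  threshold.  Reactions among Ste-family proteins only are left unpooled
  (the exemption is recorded per transition in the model file, so the
  alternative reading — exempting any transition with *some* Ste-type
  reactant — is a data edit, not a code change).
* **Regulatory edges.**  Weight-1 read arcs express catalysis and ordering:
  a gated transition cannot fire until the controlling place holds a token,
  and firing leaves that place untouched.  Kinase action is catalytic — a
  kinase does not lose activity by phosphorylating a substrate — so every
  Fus3PP-dependent step (Ste12 release and phosphorylation, inhibitor
  phosphorylation, Far1/Sst2 activation, the degradation labellings and the
  Kss1 deactivation) takes its substrate as an ordinary pre-place and
  Fus3PP through a regulatory edge; the accelerated GTP hydrolysis is
  likewise gated on cytosolic Sst2.  This also keeps the gates functional
  under the deterministic scheduler: a place consumed by pooled reactions
  is drained to a residue by its dummy before lower-priority transitions
  are scheduled, so only places without ordinary consumers gate reliably.
* **Additional proteins.**  Forty-one accessory interactors (the lambda
  set) join the reactions of their annotated neighbors: each becomes a new
  place `a_n` feeding, through its dummy `ea_n`, the pool of every reaction
  its neighbor participates in (or the reaction directly, where no pool
  exists).

### The curated arc list

The core arc list shipped in `inst/extdata/pheromone_core.andl` is a
curated reconstruction: it reproduces the published species and event
rosters exactly (46 places, 48 transitions) and realizes each event's
documented reactants and products, but the upstream source topology is not
machine-readable, so the file is explicitly replaceable — any net in the
same format passing `validate_model()` is accepted.  Three curation choices
deserve mention:

* **Feed-forward structure.**  Negative feedback (G-protein reassociation,
  Ste12 re-repression, kinase-complex and Kss1 recycling) is deliberately
  not implemented; the corresponding transitions are present as
  consumers — dissipation and degradation-labelling events — but do not
  re-supply upstream species.  This is not only a scope decision: because a
  pool retains contributions after its reaction fires, a pooled feedback
  cycle is decoupled from its finite co-substrates and becomes
  token-amplifying for roughly half of random weight draws, which would
  make almost every simulation non-terminating.
* **Technical-presence places.**  Only the ten core proteins (psi) and the
  41 additional proteins receive experimental concentrations.  Species that
  the pathway consumes but nothing in the model synthesises — the
  receptor-coupled G-protein trimer, Cdc24, and the repressed Ste12
  complex — ship with 300 tokens (the low end of the psi scale) as
  technical presence, tagged `fixed` in the model file.  The
  phosphatase/Kss1 branches start empty and stay dynamically silent; their
  edges still exist and still receive randomized weights.
* **Component name map.**  Roster neighbors are protein names; the model
  file maps them to places.  Ste4/Ste18 map to the G-beta-gamma dimer,
  Tec1 (which has no place of its own) to Ste12, Ste3 to the receptor
  place, and Far1 to its active cytosolic form.

## Execution semantics

The published rules say which transitions *may* fire but not in which
order.  The engine's default policy, `deterministic_sweep`, repeatedly
fires the first enabled transition in lexicographic-numeric identifier
order (`e2 < e10 < ea1 < t1`), which makes every ensemble result exactly
reproducible; a seeded `random_order` policy exists for sensitivity
checks.  Two further rules keep runs meaningful:

* A *source* transition (no pre-places) fires at most once per run; the
  supply it models is carried by the initial marking.
* Every run has a firing budget (`max_steps`, default 10,000).  With
  thresholds drawn from 1..100 and concentrations of a few hundred, token
  counts grow multiplicatively along the cascade (each production/threshold
  hop multiplies by about 2.6 on average), so full drainage of the net can
  take 10^5–10^6 firings.  A run that exhausts its budget is *flagged* and
  counted as a negative response — the response criterion is therefore
  "Ste12 is released within bounded work", and budget-flagged cells are
  reported separately (`n_budget`) so they can never silently distort
  ensemble fractions.  Tests that need guaranteed completion (for example
  the all-ones-weights check) raise the budget through `firing_policy()`.

Internally the scheduler is implemented in C++ with an incremental
enabled-set and exact batch-firing: consecutive firings of one transition
are applied as a single batch whose size provably matches the step-by-step
schedule (bounded by the transition's token capacity and by the first point
at which an earlier-priority transition would become enabled).  An optional
margin-tracked period fast-forward can additionally skip exactly repeating
firing patterns; it is off by default because the budget-bound tails of
this model are quasi-periodic with periods beyond practical detection
windows, so detection costs more than it saves.  Both paths are
cross-checked against a pure-R reference scheduler in the test suite.

## The experimental protocol

`experiment1()` draws an ensemble of weight configurations (every
non-regulatory edge uniform on {1..100}; regulatory edges stay at 1),
sweeps each over the full grid of initial concentrations — the ten psi
proteins move together through 300..400, the additional proteins through
100..150 — and classifies each network from the literal grid:

* **negative** — no cell fires the Ste12-release transition `t23`;
* **type a** — positive from some psi threshold `x` at the group minimum
  (the accessory proteins play no role);
* **type b** — positive only once the group value also exceeds a threshold
  `y`.

The default target is `t23` (the first appearance of free Ste12); the
alternative reading — the phosphorylation step `t24` — is one argument
away.  Classification takes the minimal-psi-then-minimal-group corner of
the positive region; a per-network flag records whether the grid was
actually monotone, since the dynamics do not guarantee it.

`experiment2()` re-runs exactly the negative networks (identical weights)
with the additional proteins at 151..200, asking whether a larger accessory
supply can rescue the response.  `experiment3()` takes the rescued networks
and splits the accessory set: the 14 proteins proposed as more important
(sigma) stay at 151..200 while the remaining 27 (varsigma) drop back to
100..150.  Each network is then classed CS (positive with the same (x, y)
combination, y read on sigma), CD (positive with a different combination)
or CN (negative).  Because the two split ranges have 51 and 50 members,
the joint group axis runs over 51 levels with sigma's top value repeated at
the last level, keeping the grid at 101 x 51 = 5151 cells; thresholds are
read on the sigma value.

Per-network seeds derive from the master seed through a small labelled
integer hash, so any subset of an ensemble replays independently.

## Decision-tree mining

To ask *which* thresholds decide the outcome, each network becomes one row
of a dataset: every randomized edge weight is a numeric attribute (named
`<src>TO<dst>`, e.g. `s5TOt5` is the G-protein dissociation threshold) and
the class is the network's response.  Regulatory edges are constant and
excluded.  Because positives are rare, datasets are built at several class
compositions (all positives with 1x, 3x, 4x as many sampled negatives) to
expose how the class prior shifts accuracy and attribute selection.

The learner is a C4.5-style tree built in the package: binary numeric
splits chosen by gain ratio, ties broken by attribute name then lower
threshold, a minimum leaf size of 2, and pessimistic error-based pruning
(upper binomial confidence limit at CF = 0.25).  No installed R package
provides gain-ratio trees, and contract-level C4.5 behaviour — not
bit-compatibility with any toolkit — is what the analysis needs; CART
(`rpart`) and an exhaustive single-split enumeration serve as independent
cross-checks in the tests.  `crossval()` runs stratified 10-fold
cross-validation and reports accuracy per class (the class's recall,
since overall accuracy is meaningless under shifted priors), and
`summarize_levels()` counts, for the first four tree levels, which
attributes are tested in at least 6 of the 10 fold-trees at the same
level, with the median split threshold.

## What the synthetic ensembles do and do not show

All experimental inputs are generated internally: uniform integer weights
and the stated concentration grids.  The ensemble emulates *ignorance of
kinetics on a known topology* — it does not emulate measurement noise,
expression variability, spatial effects, or kinetic rates, and the
curated arc list stands in for an authoritative topology.  Passing tests
therefore demonstrate the protocol's internal behaviour (determinism,
classification logic, threshold mining on planted signals), not biological
predictions; ensemble fractions (how many networks respond, or fall in
CS/CD/CN) depend on the curated topology, the scheduler and the budget,
and are expected to differ from any other realization of the model.

## Numerical and scale choices

Default problem sizes keep a full desk run comfortable: the bundled
pipeline (`run_pipeline()`) defaults to 200-network ensembles, about a
minute of compute per stage, while the full published scale (14,443
networks) is one argument away.  Tolerances that matter: tree thresholds
on the planted-signal checks are required within +/-2 of the planted
cutoff (discreteness of midpoints); the weight-uniformity check uses a
chi-square test at alpha = 0.001; all determinism checks are exact
(byte-identical tables, identical R objects).  Degenerate inputs are
defined, not errors: single-class tables give single-leaf trees, empty
rosters and empty regulatory lists are identities, an all-false grid is a
negative profile, and a zero-network pipeline writes empty, well-formed
tables.

## Limitations

* The arc list is curated; conclusions about *specific* edges (which
  threshold gates the response) are conditional on it.
* Pooling trades co-substrate bookkeeping for threshold arithmetic: a pool
  retains contributions, so a reaction can fire on one reactant's
  contributions alone.  In particular the receptor/G-protein arm is not
  structurally necessary for Ste12 release — with favourable weights the
  scaffold arm alone can cross the MAPK pool thresholds.  The
  response-critical chain runs through the Ste11-phosphorylation pool
  (`s17TOt17`), which is the sole route to activated Fus3.
* The budgeted-response criterion makes the negative class
  scheduler-dependent: a different firing order could classify some
  networks differently.  The deterministic sweep makes this reproducible
  but not canonical.
* Tokens are integers and thresholds are hard; fractional kinetics and
  graded responses are out of scope.
* Negative feedback — and hence adaptation, recovery and cell-cycle
  re-entry — is deliberately absent.
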