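---
title: "Qualitative CTL model checking for multi-valued signaling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative CTL model checking for multi-valued signaling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modeling formalism

`qualmc` works with *multi-valued logical networks*: each node (a protein,
transcript or cell-fate readout) holds one of a small number of discrete
levels `0..n-1` — typically 0 = absent/inactive, 1 = active, 2 =
overexpressed — and advances in discrete time under a *transfer function*
driven by its regulators.  For a node with activators $A_i$, inhibitors
$I_j$, basal production $b$ and $n$ levels, the additive rule is

$$X(t+1) = \mathrm{clamp}\!\left(b + \sum_i A_i(t) - \sum_j I_j(t),\; 0,\; n-1\right),$$

i.e. the level tracks the net regulatory drive, saturating at the top
level and at zero.  A second rule, `joint_min`, replaces the activator sum
with the *minimum* over activator levels; it expresses that all activators
are jointly required (for example a substrate and the protease that
processes it).  Edges carry unit weight; all quantitative detail is
deliberately abstracted away, which is what makes exhaustive verification
of a 30-node network feasible where parameterised ODE or stochastic models
are not.

Nodes are classified as **inputs** (chosen nondeterministically at time 0,
then frozen — they represent the experimental condition, e.g. the strength
of ER stress sensed by a receptor), **internal** nodes (three levels by
default, starting from `{0, 1}`), and Boolean **output** nodes (cell-fate
readouts, starting off).  The product of these per-node initial sets is
the initial-state set $S_0$.

## Update semantics

Two transition relations over the same state space:

* **Synchronous**: every non-input node updates simultaneously.  Given the
  frozen inputs the relation is deterministic — each state has exactly one
  successor, so each initial state generates exactly one path and `AF`/`EF`
  (and `AG`/`EG`) coincide pointwise.  The checker exploits this by
  rewriting universal operators to their existential forms, which run as
  least fixpoints from the (usually small) target set.
* **Asynchronous**: exactly one *update process* — one per non-input
  node — executes per step, chosen nondeterministically; all other nodes
  keep their value.  This interleaving semantics models reactions that
  proceed at unknown, different rates.  Stuttering steps (the chosen
  process does not change its node's value) are retained so the relation
  stays total.

Because a nondeterministic scheduler may simply never execute some
process, asynchronous liveness properties are checked under **process
fairness**: only paths along which *every* process executes infinitely
often count.  The package materialises the textbook reduction: a `sched`
variable records the last-executed process, the fairness family is
$\{ \text{sched} = p \}$ for every process $p$, and fair CTL is computed
with the Emerson–Lei greatest-fixpoint iteration (fair `EG`), with
`EX`/`EU`/`EF` relativised by conjoining the fair-state set to their
targets.  The initial `sched` value is a distinguished "uninitialized" tag
belonging to no constraint, so fairness refers only to suffix behaviour.

## The symbolic engine

State spaces of $3^{27} \cdot 2^3 \approx 6\times 10^{13}$ configurations
rule out explicit enumeration, so sets of states are represented as
reduced ordered binary decision diagrams (BDDs), implemented from scratch
in C++ (`src/bdd.cpp`): hash-consed nodes, an ITE computed-table,
existential quantification, conjunctive quantification (the relational
product) and monotone variable renaming.  Each $n$-level node is encoded
in $\lceil \log_2 n \rceil$ bits with current- and next-state bits
interleaved in declaration order; invalid codes are excluded by a care
set.  The transition relation is kept partitioned — one update constraint
per node — and preimages use early quantification.  For asynchronous
systems the per-process preimage renames only the updated node's bits and
conjoins that node's constraint, avoiding frame axioms entirely, and least
fixpoints are iterated chaotically (one process at a time), which
converges much faster than full-relation sweeps.

Two further standard devices matter in practice:

* **Cone-of-influence reduction** — before checking a formula the network
  is restricted to the ancestors of the formula's atoms; removed nodes
  cannot affect the verdict at the initial states.
* **Reachability restriction** (synchronous systems only) — all fixpoints
  are intersected with the forward-reachable set, computed once per
  system by image iteration.  Synchronous reachable sets are a small,
  structured fraction of the space; asynchronous interleavings reach
  almost everything, so there the restriction only costs and is skipped.

Witness and counterexample traces are extracted by walking the onion
rings of the fixpoint computations, with ties broken by minimal process
index so traces are reproducible.  Failed universal properties are negated
into existential form; globally-shaped witnesses are lassos whose cycle,
on fair systems, executes every process at least once.  Formula shapes
with no linear witness (e.g. a passing `AG`) return an explicit no-trace
marker rather than an artificial path.

## The explicit-state oracle

Every algorithm above has a deliberately independent, brute-force
counterpart (`build_graph()`, `explicit_check()`): reachable states are
enumerated by breadth-first search, CTL is evaluated with textbook
set-vector fixpoints, and fairness is decided through strongly connected
components — a state admits a fair path iff it reaches a nontrivial SCC
intersecting every fairness constraint.  On every system small enough to
enumerate, the two routes must agree exactly, satisfying set by satisfying
set; the acceptance suite fuzzes this over 200 seeded random networks
times 50 seeded random formulas under both semantics with fairness on and
off.  The explicit route refuses (with an error naming the state count) to
enumerate systems beyond a configurable cap — a truncated oracle would be
worse than none.

## The ER–Golgi case study

The shipped model reconstructs a 30-node network of ER-stress signaling:
the unfolded-protein-response sensors ATF6, PERK and IRE1 plus the Golgi
proteases S1P/S2P as inputs, 23 three-level signaling nodes, and Boolean
fate readouts Cancer, Apoptosis and Alzheimer.  The backbone arms are
canonical:

* ATF6 arm: ATF6 and S1/2P jointly (via `joint_min`) produce ATF6f, which
  drives XBP1 → {cMYC, Bcl-2} → Survival;
* PERK arm: PERK → eIF2α → ATF4 → CHOP → GADD34 → P53 → Apoptosis, closed
  by the GADD34 ⊣ eIF2α negative feedback (the ATF4-related oscillation);
* IRE1 arm: IRE1 → TRAF2 → ASK1 → JNK → BACE1 → Aβ → Alzheimer;
  TRAF2 → IKK ⊣ IκB ⊣ NF-κB → {CyclinD, BACE1, A20}, with A20 ⊣ IKK and
  NF-κB ⊣ CHOP; JNK → BAX → Cyto-c → Caspase-9 → Apoptosis.

Reconstruction from prose leaves genuine freedom, which was *calibrated*:
candidate wirings were scored against the published verdict table with the
explicit oracle on subnetworks (exhaustively, over 1700 NF-κB-loop
configurations) and with the symbolic checker on the full model, and then
frozen.  The decisive choices, each also biologically canonical:

* **NF-κB loop**: NF-κB has basal production 1, is activated by IKK and
  inhibited by IκB; IκB is produced under NF-κB (the classic negative
  feedback) and inhibited by IKK; A20 is NF-κB-induced and inhibits IKK.
  This is the only loop family found whose clamped-sum dynamics oscillate
  from *every* admissible initial state synchronously while admitting a
  fair asynchronous schedule that keeps NF-κB high — exactly the published
  sync-true / fair-async-false / EF-relaxed-true verdict pattern.
* **Apoptosis gating**: BAX requires JNK and is blocked by Bcl-2; JNK
  inactivates Bcl-2; Survival requires both cMYC and Bcl-2 (`joint_min`);
  Survival suppresses Caspase-9.  Together these make mild stress
  (IRE1 = 1) reversible but sustained stress (IRE1 = 2) commit every fair
  schedule to apoptosis, reproducing the j = 1 / j = 2 split.
* **p53 suppression**: routed through the NF-κB pathway with a one-step
  delay (IκB ⊣ P53, a stand-in for the NF-κB → MDM2 → p53 axis), which
  aligns the P53 = 0 windows with CyclinD-high windows as the
  oncogene-driven properties require.

## What the reproduction does and does not establish

`reproduce()` checks all 32 printed properties under synchronous
semantics and under fair asynchronous semantics and compares against the
published table; 55 of the 64 verdict cells match.  The nine that do not
(`tier = "calibration"` in the shipped property file) are not tuning
failures but consequences of this package's *deterministic* clamped-sum
updates, and ship red deliberately:

* *Async Props 2, 5, 7* (eventual Aβ/Alzheimer forced by PERK, TRAF2 or
  ASK1 overexpression): with deterministic per-node updates a fair
  scheduler can always time BACE1's updates to the joint low phase of its
  oscillating regulators, unless some regulator is pinned high.  IRE1 = 2
  pins JNK high, which is why Props 1, 3, 4 *are* fair-async-true — but
  the same pinning argument forces Props 5 and 7 true as well, while
  PERK = 2 pins nothing (its arm oscillates by design, as Prop 19
  requires), forcing Prop 2 false.  Matching the published combination
  requires update nondeterminism (set-valued `next`), which the original
  checker's modeling language had and our transfer function, by
  specification, does not.
* *Sync Props 9, 9′, 13, 13′*: these need a transient window
  (Cancer without Apoptosis, or the converse) on *every* deterministic
  path.  Adversarial initial states — admissible under the `{0, 1}`
  internal-init convention — phase-lock the caspase chain against the
  NF-κB and PERK oscillators so the window never opens; simulation search
  over every calibration variant confirmed some initial state always
  defeats the window.
* *Prop 10*: its "P53 = 2" conjunct on PERK-silent paths requires a
  JNK → P53 drive, but that same drive (through the PERK-arm's frozen
  midpoint state) makes P53 = 0 unreachable on other paths, falsifying the
  published async verdicts of Props 11′/12′.  One cell was traded for
  four, and the choice is frozen.

A green criterion here therefore establishes that the *checker* is sound
(the oracle-equivalence and identity suites) and that the reconstruction
reproduces the published table wherever the stated semantics admit it; it
does not establish biological correctness of the model, and the red cells
above delimit precisely where the published table depends on modeling
devices outside this package's update rule.

## Numerical and procedural choices

* BDD variable order: declaration order with current/next bits
  interleaved, inputs first, then each arm upstream-to-downstream; the
  shipped model orders the NF-κB loop before its many consumers, which
  empirically keeps fixpoint intermediates small.
* Fixpoints iterate to exact convergence (BDD equality is id equality);
  there are no tolerances anywhere — every computation in the package is
  exact and deterministic, and reruns are bit-identical.
* Random generators (`random_network()`, `random_ctl()`,
  `simulate_trace()` under asynchrony) draw from an isolated, seeded RNG
  stream and restore the caller's stream afterwards.
* Degenerate inputs: nodes with no parents and no basal decay to 0;
  empty initial sets (contradictory scenarios) and formulas over unknown
  nodes or out-of-domain constants are errors, not silent defaults.

## Limitations

* The update rule is deterministic given the regulator levels;
  set-valued/noisy updates and rate constants are out of scope.
* Fairness is unconditional process fairness; weak/strong fairness over
  arbitrary predicates and priority schedulers are not modeled.
* The witness extractor covers the linear-shaped fragment (paths and
  lassos); branching witnesses for arbitrary nested path quantifiers are
  reported as no-trace.
* The explicit oracle is capped (default $2\times 10^6$ states) and the
  symbolic engine's BDD store is grow-only: pathological orderings can
  exhaust memory before returning.
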