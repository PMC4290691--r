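# qualmc — qualitative CTL model checking for signaling networks

`qualmc` is an R toolkit for building **multi-valued logical models** of
cell signaling networks and formally verifying their temporal behaviour
with **computation tree logic (CTL) model checking**.  It is aimed at
systems biologists who want exhaustive, parameter-free answers to
questions like *"does sustained ER stress force every possible trajectory
into apoptosis?"* or *"can NF-κB oscillate without an external
stimulus?"* — questions that simulation can only sample but a model
checker can decide.

## The model and the logic

Each node holds a discrete level `0..n-1` (typically 0/1/2 =
off/active/overexpressed) and advances by the clamped
activator-minus-inhibitor transfer rule

```
X(t+1) = clamp( basal + Σ activators(t) − Σ inhibitors(t), 0, n−1 )
```

(optionally `min` over activators when all are jointly required).  Input
nodes are fixed nondeterministically at time 0 and frozen; with *m* nodes
of *n* levels the system has up to *n^m* configurations — the shipped
30-node case study has 3^27·2^3 ≈ 6·10^13, far beyond simulation, which
is why sets of states are manipulated symbolically as binary decision
diagrams (a small BDD engine ships in `src/`).

Two update semantics are supported: **synchronous** (all nodes update
simultaneously; deterministic) and **asynchronous** (one
nondeterministically chosen node per step, checked under process
fairness — every node's update process must run infinitely often).
Properties are CTL formulas over node levels, e.g.

```
AG (ASK1 = 2 -> AF (Abeta >= 1 & Alzheimer = True))
```

("whenever ASK1 is overexpressed, amyloid-β production and Alzheimer's
fate eventually follow on every path").  Verdicts are decided by symbolic
fixpoint computation; a brute-force explicit-state checker acts as an
independent oracle on small systems, and witness/counterexample traces
(paths and fair lassos) can be extracted and replayed.

## Worked example

The classic NF-κB/IκB negative feedback as a two-node toy — NF-κB with
basal production 2 inhibited by IκB, IκB produced under NF-κB:

```r
library(qualmc)
net <- network(
  list(node_spec("NFkB", basal = 2), node_spec("IkB")),
  data.frame(from = c("IkB", "NFkB"), to = c("NFkB", "IkB"),
             sign = c("-", "+")))

simulate_trace(net, c(NFkB = 0L, IkB = 0L), 5, "sync")
#>   step NFkB IkB
#> 1    0    0   0
#> 2    1    2   0
#> 3    2    2   2
#> 4    3    0   2
#> 5    4    0   0
#> 6    5    2   0
```

The period-4 oscillation is visible in the trace.  Is it *guaranteed*?
Model checking says no — and produces the counterexample:

```r
ts <- transition_system(net, semantics = "sync")
v <- check(ts, "AG ((NFkB >= 1 -> AF (NFkB = 0)) & (NFkB = 0 -> AF (NFkB >= 1)))")
v
#> qmc_verdict [sync]: FALSE  --  AG ((NFkB >= 1 -> (AF NFkB = 0)) & (NFkB = 0 -> (AF NFkB >= 1)))

witness(check(ts, "AF (NFkB = 2)"))
#> qmc_trace: 1 states (lasso; cycle starts at row 1)
#>   step NFkB IkB
#> 1    0    1   1
```

The initial state `NFkB = 1, IkB = 1` is a fixed point of the clamped
update rule — the oscillation claim fails exactly there.  (The shipped
30-node case study resolves this with the canonical IKK → NF-κB
activation; see the vignette.)

## The ER–Golgi case study

The package ships a reconstructed 30-node model of ER-stress (unfolded
protein response) signaling — sensors ATF6, PERK, IRE1 and the Golgi
proteases S1P/S2P driving survival, apoptosis and amyloid-β pathways into
three Boolean cell-fate readouts — together with its published suite of
32 CTL properties and expected verdicts:

```r
net <- er_golgi_network()   # 30 nodes, validates cleanly
rep <- reproduce()          # full table, sync + fair async (~10 min)
sum(rep$match); nrow(rep)
#> [1] 55
#> [1] 64
```

55 of 64 published verdict cells reproduce exactly; the remaining 9 are
provably unattainable under this package's deterministic update rule and
ship flagged as `tier = "calibration"` — the analysis is in
`vignettes/qualmc-methods.Rmd`.  From the shell:

```sh
Rscript inst/cli/qualmc.R casestudy --reproduce --report report.tsv
Rscript inst/cli/qualmc.R check --model inst/extdata/er_golgi.model.json \
    --props inst/extdata/er_golgi.props.json --semantics sync
```

## Package layout

- `R/network.R` — network construction, validation, JSON serialisation,
  DOT export, cone-of-influence reduction
- `R/dynamics.R` — initial states, synchronous/asynchronous successors,
  seeded simulation
- `R/ctl.R` — CTL parser (atoms, Boolean connectives, `EX/AX/EF/AF/EG/AG`,
  `E[. U .]`, `A[. U .]`)
- `R/symbolic.R`, `src/bdd.cpp` — BDD engine, transition systems,
  fixpoint checking, Emerson–Lei fairness
- `R/witness.R` — witness/counterexample lasso extraction
- `R/explicit.R` — explicit-state oracle, random network/formula
  generators
- `R/casestudy.R`, `inst/extdata/` — the ER–Golgi model, property suite,
  reproduction harness
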