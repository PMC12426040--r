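---
title: "A verifiable state-machine controller for automated peritoneal dialysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A verifiable state-machine controller for automated peritoneal dialysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdfsm)
```

## The controller model

An automated peritoneal dialysis (PD) machine cycles dialysate through fill,
dwell and drain phases, flushes its reusable tubing before and after use, and
halts on any fault. The controller studied here is a clocked (synchronous)
Moore machine: a 5-bit state register, realised as five D flip-flops A..E
with A most significant, steps once per clock tick as a function of sixteen
boolean inputs — operator buttons (start, dialysis mode, flush mode, audible
instructions, pass, start dialysis) and thresholded sensor signals
(temperature, four flow meters, level, pressure, turbidity, a danger-value
flag and a system-fault flag).

Seventeen register codes `00000`..`10000` name the treatment stages, from
standby through written/audible instructions, heater on/off, filling,
filling end, downward movement, draining, valve sequencing, the loop stage
and the flush stage, back to standby. The alarm is `11111`; the fourteen
codes `10001`..`11110` are unused and trap straight to the alarm. The
machine's behaviour is a 49-row ternary transition table: each row gives a
current code, a 16-symbol pattern over the inputs (`0`, `1`, or `X` for
don't-care) and the next code. A row matches when the state agrees and every
specified symbol equals the corresponding input bit; its *coverage count* —
the number of full input vectors it matches — is 2 raised to its number of
don't-cares, which is what the table's "Cases" column prints. The complete
behavioural universe is $2^{5+16} = 2{,}097{,}152$ (state, input) pairs.

```{r}
tbl <- pd_transition_table()
tbl
validate_table(tbl)
```

## Reading the table as written: overlaps and the priority rule

Transcribed symbol-for-symbol, the published table contains two pairs of
rows with the same current state, intersecting patterns and different next
states:

* in heater-off (`00100`), the self-loop (T = 1) overlaps the exit to
  filling (T = 1, SD = 1);
* in the flush stage (`01101`), the self-loop overlaps the exit to the
  valve-off stage (F4 = 0).

In both pairs one pattern strictly contains the other, and the evident
design intent is that the more specific row wins: pressing start-dialysis
leaves heater-off, and the flush advances once flow 4 stops. `next_state()`
therefore resolves strict-containment overlaps by *specificity priority*
(the row with more specified symbols takes precedence), while
`validate_table()` still reports every overlap, and classifies as *hard*
conflicts only those that specificity cannot resolve (none in the shipped
table). We deliberately ship the table verbatim rather than editing the two
self-loop rows (e.g. adding SD = 0 or F4 = 1), because the printed per-row
case counts — which `audit_cases()` reproduces exactly, all 49 of them — are
part of the table's published surface. One consequence worth knowing: for
those two states the sum of row coverage counts exceeds the size of the
covered input region, so the tiling identity that holds everywhere else
(pairwise-disjoint rows plus uncovered residue = 65,536 vectors) holds there
only for the *union* of the row cubes.

The table is also deliberately incomplete. Examples: no row covers standby
with the start button released and a mode button held, and the draining-end
state `01010` has no fault-free exit at all (it is surfaced as a sink, not
patched). A **completion policy** decides these uncovered (state, input)
pairs: the default `hold` keeps the current state, mirroring the table's
own self-loop idiom; the alternative `alarm` escalates to `11111`. The
policy is a constructor argument so the safety trade-off stays visible.
Relatedly, the per-state alarm rows all require S = 1 as printed, so a fault
raised while the start button is off does *not* alarm from standby; the
verifier reports this stricter unguarded property separately as an advisory
rather than silently strengthening the published behaviour.

## Excitation-function synthesis and exhaustive checking

Each flip-flop's next value $D_A, \dots, D_E$ is a boolean function of the
21 variables $A..E, T_S..T_F$. `synthesize_sop()` reads a sum-of-products
form off the table: one product term per row whose next-state bit is 1 —
five state literals plus one literal per specified input symbol — with two
refinements:

* where a row is overlapped by a more specific row with a different next
  state, its term is restricted to the unshadowed region (on the shipped
  table this only trims SD = 0 into the heater-off self-loop and F4 = 1
  into the flush self-loop); without this, the flush self-loop would assert
  $D_E$ on inputs the resolved machine sends to `01110`, where E = 0;
* completion terms are added for the unused-code trap and for each state's
  uncovered residue (computed as the ternary-cube complement of its rows),
  so the expression agrees with `next_state()` on the whole universe, not
  just on covered rows. A covered-rows-only variant
  (`include_completion = FALSE`) is also provided, with the equivalence
  check restricted to row-covered assignments, since a printed equation
  derived from the table alone need not define the uncovered region.

Equivalence is then *proved by enumeration*, not argued: `check_equivalence()`
evaluates the expression and the table-derived bit on all 2,097,152
assignments (bit-parallel over the 65,536 input vectors per state) and
reports counterexamples, capped at 100. `simplify_sop()` performs iterated
adjacency merging and absorption — enough to collapse, for example, the 32
state-minterm trap/residue terms of a degenerate table to the constant 1 —
and re-verifies the on-set bit-for-bit afterwards; it never increases the
term count. No attempt is made at exact two-level minimisation: the
acceptance surface is equivalence, not minimality.

```{r}
d_a <- synthesize_sop(tbl, "D_A")
check_equivalence(d_a, tbl, "D_A")
n_terms(d_a); n_terms(simplify_sop(d_a))
```

## The session simulator and its synthetic traces

`run_session()` stands in for the physical machine. Once per tick it updates
a simple phase-driven analog model, thresholds it into the 16 inputs with
`generate_inputs()`, and advances the register with `next_state()`. The
analog model is deliberately minimal — threshold crossings, not physics:

* the heater ramps the solution temperature at `heater_rate` (default
  0.5 °C/s) toward the 37 °C setpoint (one degree of overshoot margin keeps
  the thresholded signal stable under sensor noise);
* filling drains the 1,000 ml upper tank (the machine carries two 1 l
  tanks) at `fill_flow_rate` 200 ml/min until the level sensor drops below
  its 10 ml mark;
* draining runs flow 4 at 200 ml/min and stamps the effluent turbidity for
  the cycle; the loop and valve stages zero the flows and present a full
  receiving tank to the level sensor;
* the flush stage pumps at 200 ml/min for at least 2 minutes per cycle —
  the two calibrated values the design fixes for tubing sterilisation — and
  then stops flow 4, which is what lets the flush-exit row fire;
* every reading carries additive Gaussian noise (sd 0.05, seeded), small
  relative to all thresholds by construction.

Turbidity drives session termination. The drained effluent starts at 100
turbidity units and is multiplied by the decay ratio 0.5 on each
fill–dwell–drain cycle; the machine loops back to heater-on while the
turbidity input reads 1 and returns to standby once a cycle drains below
the threshold of 10 units — four cycles under the defaults, and
`turbidity_cycles()` computes the count in closed form for any
configuration. To avoid premature termination the turbidity input asserts
only after the reading has stayed at or above threshold for a persistence
window of consecutive ticks (default 3; the design mandates persistence over
a window but fixes no length). None of the turbidity numbers is a clinical
claim — the design publishes no units or threshold — they are configuration
values chosen once to exercise the loop.

Three modelling choices deserve explicit statement:

* **Timed states.** The rows leaving filling-end, downward-movement and the
  valve stages are annotated "with delay" but no duration is printed. The
  simulator models each delay as a timer gating the register's clock enable:
  the state holds (ticks flagged `delay_hold` in the log) until the timer
  elapses, then the row fires. Gating at the input level instead is not
  uniformly possible — the row leaving the valve-456 stage matches *every*
  vector with S = 1 and no fault, so no benign input could withhold it.
  Alarm transitions preempt the gate, preserving one-tick fault latency.
  Filling-end uses `dwell_duration` (default 1,800 s — 30 simulated minutes,
  a deliberately compressed stand-in for clinical multi-hour dwells); the
  other timed states use `delay_duration` (default 5 s).
* **Controller-driven mode bits.** The post-dialysis flush rows
  pattern-match dialysis mode off and flush mode on, and standby re-entry
  pattern-matches the reverse, although the operator pressed neither button
  mid-session; the simulator treats DM/FM in those states as
  controller-driven mode signals.
* **Fault flags.** Every per-state alarm row requires both DV = 1 and
  F = 1, so an injected fault of either kind asserts both inputs; otherwise
  no fault would ever alarm.

A nominal dialysis run visits the sixteen-code canonical path (standby,
written instructions, heater on/off, filling, filling end, downward
movement, draining, valve 4 off, loop stage, valves 3+1 off, flush, valves
4+5+6 off, valves 3+1 on, valve 1 off, standby); the audible-instructions
state and the draining-end sink are off the nominal path by design (the
nominal operator presses Pass, and flow 4 stays live until the valve-4
branch). Every log is replay-validated: each consecutive record pair must
satisfy the next-state relation exactly, except delay-gated ticks, which
must hold. With one-second ticks the default session is about 9,000 ticks
and runs in under a second; identical configuration and seed give
bit-identical logs.

```{r}
log <- run_session(tbl, sim_config())
log
flush_metrics(log)
```

What passing these simulations does and does not show: the traces exercise
every transition guard of the nominal, flush, audible, fault and recovery
paths against the real next-state function, but the analog trajectories are
idealised ramps. Real sensors drift, flows pulse, dwell chemistry is not a
geometric decay, and operator behaviour is not a fixed intent vector — so
the simulator validates the *controller*, not the hydraulics or the
therapy.

## Safety verification

Safety claims are one-step properties checked by exhaustive enumeration
(`verify_controller()`):

* **fault-to-alarm** — from every defined state, every input with S = 1,
  DV = 1, F = 1 steps to `11111` (18 × 2¹³ pairs);
* **alarm recovery** — every vector matching the recovery row (S = 1,
  DV = 0, F = 0) returns the alarm to standby (8,192 vectors);
* **unused-code trap** — all fourteen unused codes map to the alarm on all
  65,536 inputs each;
* **totality** — the next-state function is defined on all 2,097,152 pairs.

Reachability is computed twice: symbolically over the row graph (plus the
trap edges and, under the alarm policy, the residue edge) and by brute-force
enumeration of successors; the two must agree, and on the shipped table
exactly the 18 defined states are reachable from standby. The one-step
properties deliberately stop short of temporal-logic model checking.

```{r}
verify_controller(tbl)
```

## Numerical and design choices, in one place

* Input order is fixed everywhere (files, vectors, logs) to the catalog
  order S, DM, FM, AI, P, T, SD, F1..F4, L, PR, TU, DV, F; codes print as
  ABCDE strings with A most significant.
* Specificity priority resolves strict-containment row overlaps; identical
  patterns with different next states are hard conflicts and
  `next_state()` refuses ties at equal specificity.
* Exact duplicate rows are dropped with a warning (transcription
  robustness); any pattern symbol outside {0, 1, X} is a parse error naming
  row and column.
* The completion policy defaults to `hold`; `alarm` is one argument away.
* Enumeration (2²¹, bit-parallel) is the equivalence oracle — no BDDs or
  SAT; at this size the exhaustive check costs well under a second per
  flip-flop.
* Counterexample reports are capped at 100 assignments.
* Simulation defaults: 1 s ticks, 100,000-tick cap, 25-cycle cap, noise sd
  0.05, seed 1. All problem sizes above (9,000-tick sessions, 2²¹
  enumeration) were chosen as the package's own desk-scale study
  conditions.

## Known limitations

The printed flip-flop input equations accompanying the published table are
typographically garbled (missing operators, merged terms) and are treated as
non-normative; the table is the ground truth and the synthesised expressions
are checked against it, not against the printed equations. The draining-end
sink and the S-guarded alarm rows are reported, not repaired. The simulator
has no solute-kinetics, thermal or hydraulic model, and the turbidity scale
is arbitrary. Whether the published equations were meant to cover uncovered
inputs at all is unknowable from the text, which is why both synthesis
variants exist.
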