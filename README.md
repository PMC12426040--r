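# pdfsm

A verifiable software model of the finite-state-machine controller of an
automated peritoneal dialysis (PD) machine.

Automated PD cyclers fill the peritoneal cavity with dialysate, let it
dwell, drain it, and repeat, flushing their reusable tubing before and after
each session; any fault must halt the machine. The controller here is a
clocked Moore machine: a 5-bit register (D flip-flops A–E, A most
significant) driven by 16 boolean inputs — operator buttons and thresholded
sensor readings (temperature, four flows, level, pressure, turbidity, a
danger-value flag and a system-fault flag). Seventeen register codes
`00000`–`10000` name the treatment stages, `11111` is the alarm, and the
fourteen codes in between are unused and trap to the alarm. Behaviour is a
49-row ternary transition table: each row is a current code, a pattern over
the inputs in {0, 1, X} (X = don't-care) and a next code; a row's *coverage
count* is 2^(#X), the number of full input vectors it matches; the joint
universe is 2^(5+16) = 2,097,152 (state, input) pairs.

The package is aimed at people who design or review embedded medical-device
controllers: it ships the table as a plain-text fixture, evaluates and
validates the next-state function, synthesises the five flip-flop excitation
functions

D_b = Σ (product terms over A..E, T_S..T_F),  b ∈ {A,…,E}

as sum-of-products expressions and **proves them equivalent to the table by
enumerating all 2^21 assignments**, simulates whole dialysis/flush sessions
against synthetic sensor traces with fault injection, and machine-checks the
safety properties (fault→alarm, alarm recovery, unused-code trap,
reachability).

## Worked example

```r
library(pdfsm)

tbl <- pd_transition_table()
tbl
#> Transition table: 49 rows over 20 current-state codes (.../transition_table.tsv)
#>   completion policy: hold

validate_table(tbl)
#> 49 rows, 0 hard conflict(s), 2 containment overlap(s)
#> sink state(s) (no fault-free exit): 01010
#> mean uncovered input fraction per state: 0.807

audit_cases(tbl)
#> case audit: 49 rows, 0 mismatch(es)
```

The two containment overlaps are real features of the published table (the
heater-off and flush self-loops overlap their more specific exit rows);
`next_state()` resolves them by specificity priority, and the draining-end
state `01010` genuinely has no fault-free exit. The printed per-row case
counts (32,768 for the standby hold, 128 for the filling self-loop, 8,192
per alarm row, …) all equal the recomputed 2^(#X).

Synthesis plus the exhaustive equivalence proof:

```r
d_a <- synthesize_sop(tbl, "D_A")
check_equivalence(d_a, tbl, "D_A")
#> D_A: EQUIVALENT over 2097152 assignments (0 mismatch(es))
n_terms(d_a); n_terms(simplify_sop(d_a))
#> [1] 42
#> [1] 16
```

A full simulated session under the default configuration (37 °C setpoint,
1,000 ml exchanges, 30 min dwell, flush at 200 ml/min for ≥ 2 min, effluent
turbidity decaying by 0.5 per cycle against a threshold of 10):

```r
log <- run_session(tbl, sim_config())
log
#> Session (dialysis mode): 9023 ticks, returned to standby
#>   path: 00000 -> 00001 -> 00011 -> 00100 -> 00101 -> 00110 -> 00111 -> 01000
#>         -> 01001 -> 01011 -> 01100 -> 01101 -> 01110 -> 01111 -> 10000 -> 00000
#>   cycles: 4, flush intervals: 4 (1600 ml), alarm ticks: 0

flush_metrics(log)
#>   interval start_tick end_tick duration_min volume_ml
#> 1        1       2146     2266     2.016667       400
#> ...                                2.016667       400

verify_controller(tbl)
#> fault_to_alarm     HOLDS  (universe 147456)
#> alarm_recovery     HOLDS  (universe 8192)
#> unused_trap        HOLDS  (universe 917504)
#> totality           HOLDS  (universe 2097152)
```

The session walks the sixteen-code canonical path, performs
`turbidity_cycles(sim_config())` = 4 fill–dwell–drain cycles, delivers 400 ml
per ≥ 2-minute flush interval, and every log replays exactly against the
table (`replay_check`). Inject `fault_spec(tick, "sensor_fault")` to watch
the machine alarm on the next tick and recover to standby once cleared.

A thin command-line wrapper ships at `inst/cli/pdfsm.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","pdfsm.R",package="pdfsm"))')" validate
#> 49 rows, 0 conflicts, 0 case mismatches
```

with subcommands `validate`, `audit-cases`, `synthesize`, `simulate`,
`verify` (exit status 0 iff the check passes).

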