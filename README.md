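# dsdlogic

Digital logic circuits built from **domain-label DNA strand-displacement
gates**: compiled to strand-level species, closed into a chemical reaction
network (CRN) under toehold-mediated displacement semantics, integrated
under deterministic mass-action kinetics, and threshold-decoded back into
bits.

## The problem

DNA strand-displacement circuits conventionally encode a logical wire as a
concentration: ~1 unit (10,000 nM) of a signal strand is logic 1, ~0 is
logic 0. That encoding needs dual-rail logic and threshold gates, and a
threshold near the edge of either band can flip an output. The
domain-label encoding instead carries the logic value *inside* the strand:
a signal strand `<aL^ x aR^ T^ bL^ y bR^>` is logic 1 iff its right-hand
label domain `y` is the distinguished domain `t` (and 0 iff `f`).
Hybridization — not a concentration comparison — separates the two values,
so the value is determined at every instant of the reaction.

`dsdlogic` is for people studying molecular logic architectures: it
provides the gate library (K-input mapping modules — `2^K` double strands,
one per input label pattern, `2^(2^K)` distinct modules; catalytic
amplification and fan-out gates; fluorophore reporter gates), a
displacement-reaction enumerator and CRN closure, a stiff mass-action
integrator, and compilers for the three reference circuits:

* a 1-bit full adder (two 3-input mapping modules: sum = parity, carry =
  majority),
* a 4×4 binary multiplier (16 AND gates, 4 half adders, 8 full adders),
* an 8-bit ripple-carry adder/subtractor (8 XOR gates, 8 full adders, 24
  amplification gates, one 9-fan-out, two's-complement subtraction under a
  mode-switch strand).

Every compiled circuit carries a logic-level netlist twin, so CRN decodes
are verified bit-for-bit against pure Boolean evaluation and integer
arithmetic. A minimal dual-rail seesaw baseline reproduces the
threshold-edge instability that the domain-label encoding avoids.

## Worked example

```r
library(dsdlogic)

fa  <- compile_full_adder()
res <- simulate_circuit(fa, adder_inputs(1, 1, 0))
res
#> <dsd_result full_adder> word = 10 (settled)
tidy(res)
#> # A tibble: 2 × 6
#>   name  index t_units f_units   bit status
#>   <chr> <int>   <dbl>   <dbl> <int> <chr>
#> 1 S1        1   0.999   0         1 ok
#> 2 S0        0   0       0.999     0 ok
```

`1 + 1` (carry-in 0) decodes to the word `10`: the carry reporter's
t-fluorophore settles at 0.999 units (≥ 0.9 ⇒ bit 1) and the sum
reporter's f-fluorophore at 0.999 units (⇒ bit 0) — the strand-level
system agrees with `boolean_oracle(fa, adder_inputs(1, 1, 0))`. The same
pipeline runs the larger circuits:

```r
m <- compile_multiplier_4x4()
simulate_circuit(m, multiplier_inputs("1111", "1111"))$word
#> [1] "11100001"        # 15 x 15 = 225

s <- compile_adder_subtractor()
simulate_circuit(s, addsub_inputs("00101101", "10010110", 1))$word
#> [1] "010010111"       # S8..S0, two's-complement subtraction
```

The dual-rail comparison, on the same 1 + 1 case:

```r
simulate_dual_rail_adder(0.50, c(a = 1, b = 1))$verdict  # "correct"
simulate_dual_rail_adder(0.85, c(a = 1, b = 1))$verdict  # "incorrect"
```

A thin command-line front end lives in `inst/exec/dsdlogic`
(`compile`, `simulate`, `verify`, `enumerate-modules`, `dualrail-demo`,
`fixtures`; exit codes 0 pass / 1 mismatch / 2 ambiguous / 3 input
error), driven by YAML run configs. CRNs export to plain-text reaction
lists and SBML Level 3; trajectories to CSV-friendly tibbles.

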