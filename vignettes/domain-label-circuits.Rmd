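---
title: "Domain-label strand-displacement logic: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-label strand-displacement logic: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The encoding

DNA strand-displacement circuits usually carry a logical wire as a
*concentration*: roughly one unit (10,000 nM here) of a signal strand means
logic 1, near zero means logic 0. That convention forces dual-rail
constructions and threshold gates, and the thresholds are the fragile part:
a threshold that sits near the edge of either band can mis-absorb or
under-absorb a signal and flip an output.

`dsdlogic` implements the alternative *domain-label* encoding. Every signal
strand has the canonical shape

```
<aL^ x aR^ T^ bL^ y bR^>
```

where `T^` is the universal toehold, `aL^/aR^` and `bL^/bR^` are the
flanking toehold domains of the upstream and downstream wire *ports*, and
`x`, `y` are one of two distinguished long domains `t` and `f`. The
right-hand label `y` *is* the logic value (`t` = 1, `f` = 0); the left
label only records where the strand came from. Because `t` and `f` are
different domains, hybridization itself — not a concentration comparison —
distinguishes the two logic values, at every instant of the reaction.

## Species, notation, and the displacement rule

Species are written in the segment notation used throughout the strand
listings: `{...}` an unpaired stretch of the lower backbone, `[...]` a
duplex (written as its upper-strand tokens), `<...>` an upper-strand
overhang, `^` a toehold, `*` a complement, `:` joining segments.
`parse_species()` and `render_species()` are exact inverses on canonical
text, and every complex in the gate architecture is a single backbone with
upper strands pairing contiguous runs of it.

Reaction enumeration uses one rule, applied symmetrically. A free strand
whose toehold lands on an exposed backbone toehold adjacent to a duplex
displaces the incumbent upper strand if its flanking arm matches the full
paired run (complete displacement) or the run minus a terminal toehold
(toehold exchange; the incumbent's last toehold hold dissociates on its
own). In the default *lumped* mode each such event is a single
irreversible bimolecular step; nothing else is special-cased. The
catalytic fuel steps of amplifier and fan-out gates, the structural
reverse of every exchange, and the reporter's irreversible final
displacement all emerge from the same rule. `close_crn()` iterates the
rule to a fixed point; closure is idempotent and order-independent, only
free strands invade (no complex-complex interactions), and waste
complexes with no exposed toehold are inert, so the closure is finite for
every gate-library circuit.

A *detailed* mode expands each lumped step into reversible toehold binding
(`k_on`, `k_off`) followed by unimolecular branch migration (`k_migrate`),
for kinetic studies; unproductive toehold flaps are omitted since they
only renormalise effective rates.

## The gate library

**K-input mapping module.** `2^K` gate double strands, one per input label
pattern; the pattern is spelled in the duplex, so an input strand can only
invade the gates whose next segment carries its own label. Inputs invade
left to right by toehold exchange and the final exchange releases the
output strand bearing the table's label. With all `2^K` gate species at
one unit and inputs at one unit, the first input splits over the
`2^(K-1)` matching gate species, so the completed output amounts to
`2^-(K-1)` units (1 unit at K = 1, 0.5 at K = 2, 0.25 at K = 3). This
attenuation is intrinsic to the encoding — and is exactly what the
amplification gate exists to repair.

**Amplification gate.** Per label channel, one gate double strand at the
target concentration and one fuel strand at twice that. The upstream
signal releases the output by exchange and is displaced back into solution
by the fuel: it is a catalyst, so the restored output amplitude equals the
gate concentration regardless of the (positive) input amplitude. The two
label channels share no species, so an `f` input can never produce the `t`
output.

**Fan-out gate.** N parallel amplifier-style doubles per channel, one per
output port, with a shared fuel at N times the gate concentration (the
catalytic cycle consumes one fuel per released output; at N = 2 this
coincides with the amplifier's two-times rule). An alternative reading of
the reference figure — one N-segment backbone carrying all N outputs —
was prototyped and discarded: because every fuel and output strand shares
the same invasion arm, interior segment boundaries admit combinatorially
many occupancies and the enumerated network explodes with N, while the
parallel form is linear in N and preserves the stated behaviour
(catalytic input, per-port outputs at gate concentration).

**Reporter gate.** Per channel, a fluorophore/quencher duplex whose upper
strand `<bL^ x bR^ fluor>` is *fully* displaced by a matching signal — no
residual toehold, hence irreversible. The released fluorophore strand has
no free toehold complement anywhere in the system and is inert; its
concentration is the readout. Reporters are the only true sinks in a
circuit, which is why every fluorophore trajectory is monotone
non-decreasing.

## Rates, units, solver

Concentrations are nM internally; 1 unit = 10,000 nM. The lumped
displacement rate defaults to `3e-5 /nM/s`. The choice is deliberate:
every step in these gates is a toehold *exchange* — the invader gains no
net toehold — and effective exchange rates sit one to two orders of
magnitude below the ~`1e6 /M/s` of fresh-toehold displacement. At unit
concentrations this puts single-stage completion at tens of seconds and
full cascades at a few hundred to a couple of thousand seconds, the scale
on which the reference traces settle (about 540 s for the 1-bit adder,
about 2100 s for the multiplier); the comparison is made only in order of
magnitude, never as a fitted quantity, because the reference rate set is
not published. `dsd_rates()` exposes all rates.

Integration uses `deSolve::lsodes` (the stoichiometry is sparse) with
`rtol = 1e-8`, `atol = 1e-6` nM, over a log-spaced grid to `t_end =
10,000` s. "Settled" is a derivative criterion: every fluorophore's rate
of change below `1e-6` units/s at the end of the run. Left null vectors
of the stoichiometry matrix (per-strand conservation laws) are checked to
drift by less than `1e-6` units along full circuit runs, and halving the
solver tolerances moves final readouts by less than `1e-4` units. The
right-hand side clips transient negative concentrations at zero before
forming mass-action fluxes.

## Decoding

A bit reads 1 when its `t`-fluorophore is at or above 0.9 units and its
`f`-fluorophore at or below 0.1 units; 0 in the mirrored case; anything
else is reported as *ambiguous* and never silently coerced. On a settled
run of a correctly compiled circuit no bit is ambiguous.

## The compiled circuits

Every compiler gate also emits a row in a logic-level *netlist twin*, so
each circuit can be evaluated as pure Boolean logic (`boolean_oracle()`)
and compared bit-for-bit with the threshold-decoded CRN simulation. The
twin is in turn checked against plain integer arithmetic.

**1-bit full adder** — two 3-input mapping modules (sum = parity, carry =
majority of A, B, carry-in). Ports are domain pairs, so an input that
feeds both modules physically requires a 2-fan-out; there are three, plus
one amplifier per output. The published stage list ("1 XOR, 3
amplification gates, one 2-fan out") conflicts with the two-module
description; the two-module form is adopted because the 8-bit circuit's
total of 24 amplifiers = 8 stages x (XOR amp + sum amp + carry amp)
anchors it. The two-operand demonstration cases hold the carry-in at 0.

**4x4 multiplier** — 16 AND mapping modules form the partial-product
array (each operand bit reaches its four ANDs through a 4-fan-out), four
half adders and eight full adders sum the columns with reporters omitted
inside, and eight reporters read S7..S0. Attenuated module outputs that
feed catalytic gates (fan-outs, amplifiers) need no restoration — the
catalytic output amplitude is set by gate concentration, not input
amplitude — so amplifiers sit only where a stoichiometric reporter
follows.

**8-bit adder/subtractor** — per stage, an XOR module conditionally
inverts `B_i` under the mode switch `A#S`, whose strand one 9-fan-out
distributes to the eight XORs and the initial carry-in; a full adder per
stage ripples the carry; nine reporters read S8..S0. With `A#S = 1` the
circuit computes `A + (2^8 - B)`, the two's-complement subtraction. Input
ports follow the reference listing (`A0..A7` on `S2..S9`, `B0..B7` on
`S10..S17`, switch on `S0`), so `encode_inputs()` reproduces its input
strands verbatim. The reference text's decimal narrative for the worked
subtraction (77 and 183) does not match its own binary operand words
(00101101 is 45, and the listed output bits spell 010010111 = 151 =
45 - 150 mod 256); the package follows the binary words, which are
internally consistent, and `twos_complement_sub()` separately reproduces
the 77 - 150 -> 183 = 10110111 arithmetic.

## The dual-rail baseline

The comparison circuit is modelled at the seesaw-ODE level, not at strand
level, because the reference lists the strand names of its dual-rail
adder but not the full gate set; reconstructing it base-by-base would be
guesswork. The fragment models the *restoration stage* of each output
wire: per rail, an irreversible threshold species (absorption at
`1e-3 /nM/s`, about thirty times the exchange rate, as seesaw designs
prescribe) competes with a catalytic gate/fuel pair that restores the
surviving signal to one unit. The rail carrying the arithmetically
correct value arrives attenuated at 0.85 units and the opposite rail
carries 0.15 units of spurious chatter — the midpoints of the two
instability bands (0.8–0.9 and 0.1–0.2 units), fixed before any
simulation was run. A mid-range threshold (0.5) absorbs the chatter and
lets the true signal restore fully; a threshold at or below the chatter
level lets the wrong rail fire outright; a threshold near the true
signal's level annihilates slowly against it (a second-order near-tie),
leaving the output stranded mid-band. "Incorrect" means any output bit
that differs from binary arithmetic *or* is ambiguous at settle time.
The domain-label adder run on the same cases decodes correctly at every
threshold, because no threshold exists in that architecture.

## Synthetic conditions and what the tests show

There is no external dataset: all inputs are operand words, and the study
conditions are fixed by the model — 1 unit = 10,000 nM input strands,
gate species at 1 unit, fuels at 2 (amplifier) or N (fan-out) units,
decode bands 0.9/0.1. Random-pair verification sweeps draw uniform
operand words under fixed seeds (20 pairs per circuit and mode; the
worked examples 1111 x 1111 and 00101101 - 10010110 always included).
Problem sizes: the compiled 1-bit adder closes to about 90 species, the
8-bit circuit to about 900, the multiplier to about 1200; suite-scale
sweeps use these sizes directly.

Passing these tests shows the *model* is internally consistent — gates
compose, the CRN semantics conserve strands, decodes match arithmetic —
not that a wet-lab realization would behave identically: no leak
reactions (zero-toehold displacement), no spurious remote-toehold or
4-way branch migration, no sequence-design effects, and no stochastic
fluctuations (deterministic mass action only) are modelled, and absolute
time scales are matched only in order of magnitude.

## Known limitations

- Gate-gate (complex-complex) interactions are not enumerated; all
  reference reaction diagrams involve a free strand, but this is an
  assumption, not a theorem.
- The enumerated "reverse chatter" (structural reverses of each exchange)
  makes some waste complexes transiently sequester signal; reporters
  drain it eventually, which is physical, but it lengthens settle tails.
- The 8-bit compiler fixes width 8; the construction generalises, but no
  other width is wired up or tested.
- The dual-rail baseline is a deliberately minimal restoration-stage
  model; it reproduces the threshold dichotomy qualitatively and makes no
  claim about the full dual-rail adder's exact traces.
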