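---
title: "A chemical Turing machine: model, encoding, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A chemical Turing machine: model, encoding, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemturing)
```

## The model

A Turing machine is a head on a tape of discrete cells, driven by a
look-up table: for each pair (current state, symbol under the head) the
table prescribes a symbol to write, a move (one cell left or right) and
a next state, until the designated HALT state is reached.  The claim
this package operationalizes is that a synthesis robot executing unit
operations — add, transfer, empty, measure — can simulate any such
machine, provided its procedure language supports *conditional
execution*.  The argument is constructive: compile an arbitrary
transition table into a procedure, run the procedure on a simulated
robot, decode the vials back into machine configurations, and check
the decoded run against an ordinary reference interpreter.  If the two
agree step for step for arbitrary machines, the procedure language can
do whatever a Turing machine can.

Three deliberate simplifications frame everything below:

* **The tape is finite** (default 8 cells).  A physical row of vials is
  finite; a head pushed off either end is a hard runtime failure, not a
  silent clamp.
* **The only variables are booleans** written by `Measure` steps and
  read by `condition` guards.  There are no integers or strings in the
  dialect, which forces the compiler's fully unrolled design.
* **Loops cannot run forever.**  Every `Repeat` carries an iteration
  cap (default 10,000) and hitting it is an explicit `halt(cap)`
  outcome — the practical concession to the undecidability of halting.

## The physical encoding

The platform carries `N` tape vials, `N` head vials, two state vials,
one stock flask per color, and a waste container, all connected through
a pump/valve backbone.

* **Symbols** map to vial colors in alphabet order, blank first:
  blank &rarr; white (an *empty* vial), then orange, blue, green.  Four
  colors bound the alphabet at 4 symbols.
* **The head** is the single orange vial in the head row; all other
  head vials are empty.
* **States** map to ordered pairs of colors on the two state vials:
  states are taken in declaration order, HALT last, and the state's
  index is written base-4 over (white, orange, blue, green) into
  (vial 1, vial 2).  Two vials of four colors encode 16 states.  The
  coding is a package convention — any injective assignment works — and
  it is recorded in the `ColorEncoding` object that travels with every
  compiled program.

`encodeConfiguration()` and `decodeConfiguration()` convert between
configurations and platform states; decoding demands exactly one head
marker and a recognizable state pair, so a corrupted platform surfaces
as an error rather than a wrong answer.

## What the compiler emits

For a machine with rule set *R* on an `N`-cell tape:

* `ReadState` measures the two state vials against every color used by
  the state coding, yielding booleans `s1_is_<color>`, `s2_is_<color>`.
* `ReadTape` measures `head_at_<i>` for every head vial and
  `read_<i>_is_<a>` for every cell *i* and symbol *a*.
* For each rule (S, a) &rarr; (w, d, S'), a blueprint `Rule_S_a` holds the
  Write (empty the tape vial under the head, refill with w's color),
  Move (shift the orange marker to vial i&plusmn;1) and Switch (recolor the
  state vials to S''s pair) steps, each guarded by `head_at_<i>`.
* `LookUpTable` invokes every rule blueprint behind the guard
  `s1_is_p1 and s2_is_p2 and ((head_at_1 and read_1_is_a) or ...)`;
  exactly one guard is true per iteration because the stored booleans
  are a snapshot taken before any rule fires.
* `TuringMachine` is `ReadState` followed by
  `Repeat("not (s1_is_h1 and s2_is_h2)", cap)` over
  `[ReadTape; LookUpTable; ReadState]`.

Three design points deserve their rationale:

* **Per-position read booleans.**  Step_ids are unique per document, so
  a single `read_is_a` boolean written by N alternative Measures is not
  expressible; instead each cell gets its own `read_<i>_is_<a>`,
  measured unguarded so every variable a condition mentions is always
  set (reads of unset variables are errors by design, and the
  evaluator is strict precisely so that mis-wired tables fail loudly).
  The disjunctive guard above recovers "the symbol under the head".
* **Where ReadState runs.**  The loop condition is checked before every
  iteration, so the state booleans must exist before entry (hence the
  ReadState ahead of the loop) and must reflect the *post-switch* state
  when the check repeats (hence ReadState at the iteration's end,
  after the look-up table acted).  Re-measuring at the start of the
  body instead would leave the exit check one iteration stale and
  append a spurious no-op iteration to every halting run.
* **Falling off the tape.**  A rule moving left from cell 1 (or right
  from cell N) compiles to an `Add` on a phantom head vial (`head_0` /
  `head_9`) that is declared in the document but absent from the
  platform.  The move therefore fails at run time, exactly like the
  finite physical rig — and the reference interpreter's overrun error
  is required to land on the same step.

Document size grows as &Theta;(|R| &middot; N); `compiledStepCount()`
states the exact counting formula and the tests pin it to the emitted
documents (242 steps for the six-rule Busy Beaver at N = 8).

## Parameters and conventions

| parameter | default | why |
|---|---|---|
| tape length N | 8 cells | matches the worked examples' 8-digit tapes |
| unit write volume | 1.0 mL | one "symbol" of liquid; any fixed value works |
| vial capacity | 10 mL | an order above the write volume; overflow then only signals faults |
| camera detection threshold | 0.1 mL | below this a vial reads white; makes empty-after-drain robust |
| stock volume | 1000 mL | a one-liter reservoir; a 200-iteration run draws at most a few hundred mL, so stocks never run dry mid-sweep |
| Repeat cap | 10,000 iterations | generous for the shipped machines (14 and 88 iterations) |
| comparison boundaries | strict `less_than`/`greater_than`, inclusive `between` | "below 50 °C" and "between 4 and 9" read naturally this way |

All results are volume-scale invariant: the decoded configurations
depend only on *which* color dominates a vial, never on how much
liquid implements it.

## Numerical choices

Volumes are whole microliters internally, stored as doubles but always
integral, so conservation of liquid is exact and tested with `==` over
thousands of random operations.  Proportional splits of mixtures use
largest-remainder rounding with ties broken by solution id; color ties
in the camera are broken by lexicographic label.  Both tie-breaks exist
only for fault scenarios — the compiler always empties a vial before
refilling it, so mixtures never occur in a healthy run — but they keep
every trace bit-reproducible.  Degenerate inputs are pinned by tests:
emptying an empty vial (and the waste itself) is a no-op, a `Repeat`
whose condition starts false runs zero iterations, and a machine
started in HALT compiles to a program that performs no liquid handling.

## What the random-machine generator emulates

`generateMachine()` draws total transition tables (uniform writes,
moves and next-states, with at least one HALT-targeting rule) under a
fixed seed.  This emulates the *space of programs* the robot might be
asked to run, not any chemical reality: random machines mostly wander
off the finite tape or spin until the cap, which is exactly what makes
them good probes — the equivalence sweep must reproduce halting,
cap-limited and overrun behavior alike, not just happy paths.  What
passing sweeps do **not** show: anything about sensor noise, liquid
losses, timing, or real camera classification.  The twin is
deterministic and noise-free by construction; on hardware, the same
procedures would additionally need the robustness the conditional
dialect is meant to enable.

The test suite runs the sweep at 50 machines with 2–4 states, 2–4
symbols and a 200-iteration cap on an 8-cell tape (a few seconds of
compute); the dual-interpreter cross-check uses 200 random machines at
100 steps on a 12-cell tape.  These sizes were chosen to cover all
three termination modes many times over while keeping the default test
run fast.

## Limitations

* At most 4 symbols and 16 states — the color gamut's budget.  Larger
  machines need more colors or more state vials, not a new idea.
* The emitted documents are unoptimized by intent: no dead-branch
  pruning, no sharing between rules.  They are meant to be read and
  verified, not to be short.
* No fluid dynamics, kinetics, pH chemistry or image processing; the
  pH and temperature sensors read settable attributes, existing so
  that the condition grammar can be exercised over numeric quantities.
* The dialect is deliberately not byte-compatible with any upstream
  XDL release; attribute names for `Measure` follow this package's
  schema.
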