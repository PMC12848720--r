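# chemturing

Chemical procedures become programs once a robot can *branch* on what it
measures.  `chemturing` implements, in software, the full stack that
makes a liquid-handling synthesis robot (a "Chemputer") Turing complete:

1. **A conditional dialect of XDL** (the XML chemical description
   language).  A `Measure` step reads a sensor, applies a comparison
   (`equal`, `less_than`, `between`, ...) and stores the boolean under
   its unique `step_id`; any step may carry a
   `condition="..."` attribute — a boolean expression over those
   step_ids with `not`/`and`/`or` (precedence NOT > AND > OR) — and is
   skipped when it evaluates false.  `Repeat` loops re-check their
   condition before every iteration under a mandatory iteration cap,
   and `Blueprint`s are the dialect's nestable functions.
2. **A digital twin of the robot**: rows of vials holding colored
   solutions (orange / blue / green; an empty vial reads white), stock
   flasks, a waste container, a pump-and-valve transfer backbone, and
   virtual sensors.  Volumes are accounted in exact microliters, so
   conservation of liquid holds with equality.
3. **A reference Turing machine**: a head on a finite tape of cells,
   driven by a look-up table mapping (state, read symbol) to
   (write, move L/R, next state) until the HALT state.
4. **A compiler** from any transition table to nested XDL blueprints.
   Tape cells become tape vials (symbol = color), the head becomes the
   single orange vial in the head row, the state becomes a pair of
   colored state vials (4 colors x 2 vials = 16 states).  Each loop
   iteration measures the state and tape vials into booleans and
   dispatches exactly one condition-guarded rule blueprint, which
   writes, moves and switches by emptying and refilling vials.  A
   decoder reads the platform back into machine configurations, so a
   compiled run can be compared step for step against the reference
   interpreter — the simulation argument that makes the dialect Turing
   complete.

The two classic worked examples ship as fixtures: a 3-state Busy
Beaver that writes six consecutive ones (witnessing Σ(3) ≥ 6), and a
3-bit binary adder over the alphabet `{0,1,x,y}`.

## Worked example

```r
library(chemturing)

prog <- compileMachine(busyBeaverMachine(), busyBeaverConfiguration())
prog
#> CompiledProgram: 6 rules over 8 tape cells, cap 10000
#>   document: 10 blueprints, 242 step elements

run <- runCompiled(prog)
cat(runReport(run$configs, run$platform), sep = "\n")
#> iter  state  head  tape
#>    0  A         3  00000000
#>    1  B         4  00100000
#>    2  C         5  00100000
#>  ...
#>   13  A         4  01111110
#>   14  HALT      5  01111110
#>
#> resources (mL):
#>   stock orange  remaining    968.0  consumed     32.0
#>   stock blue    remaining    994.0  consumed      6.0
#>   stock green   remaining    999.0  consumed      1.0
#>   waste           collected     31.0
```

Each row is one loop iteration of the compiled program, decoded from
the vial colors: the machine halts after 14 iterations with tape
`01111110` — six consecutive ones.  `countMaxConsecutive(run$configs[[15]]@tape)`
returns `6`, and `verifyMachine(busyBeaverMachine(), busyBeaverConfiguration())$equivalent`
confirms the decoded sequence is identical to the reference
interpreter's.  The binary adder runs the same way:

```r
res <- tmRun(binaryAdderMachine(), adderConfiguration(5, 3))
tapeString(res$config)
#> [1] "00001000"        # cells 5-8 hold 1000 binary = 8
```

A command-line entry point with subcommands
`compile | run | simulate-tm | verify | generate | report` is installed
at `system.file("cli", "chemturing", package = "chemturing")`.

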