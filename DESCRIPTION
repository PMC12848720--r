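Package: chemturing
Title: Conditional Chemical Procedures and Turing-Machine Compilation on a
    Virtual Chemputer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: An interpreter for a conditional dialect of the chemical
    description language XDL, a digital twin of a liquid-handling robot
    (vials of colored solution, reagent stocks, a transfer backbone, and
    virtual sensors), and a compiler that turns any finite Turing-machine
    transition table into a nested-blueprint XDL procedure whose execution
    on the virtual platform reproduces the machine step for step.  Ships a
    reference Turing-machine interpreter used as an independent oracle,
    plus builders for a 3-state Busy Beaver and a 3-bit binary adder.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    xml2,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'conditions.R'
    'platform.R'
    'platform-io.R'
    'turing.R'
    'machines.R'
    'xdl-parse.R'
    'xdl-serialize.R'
    'execute.R'
    'trace-io.R'
    'encoding.R'
    'compile.R'
    'run-compiled.R'
    'report.R'
    'show-methods.R'
    'chemturing-package.R'
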