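Package: glycoswitch
Title: Bistability and Hysteresis in a Kinetic Model of Mammalian Glycolysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mechanistic ordinary differential equation model of mammalian
    glycolysis with isozyme-specific allosteric regulation of
    phosphofructokinase (PFK), pyruvate kinase (PK) and the bifunctional
    6-phosphofructo-2-kinase/fructose-2,6-bisphosphatase (PFKFB).  Provides
    multistart steady-state enumeration with eigenvalue stability
    classification, bifurcation and hysteresis scans over glucose and
    regulatory parameters, transient glucose-pulse simulations, and
    sensitivity analyses over enzyme levels and fixed-environment
    concentrations.  Includes an analytically solvable one-dimensional
    bistable toy system used as a solver oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
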