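Package: carbontrace
Title: Carbon-Atom Fate Simulation and Pathway Attribution for Stable-Isotope
    Tracing of Central Carbon Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for positional carbon-13 isotopomer analysis of central
    carbon metabolism in cell models, built around the tracer pair
    [1,2-13C]glucose and [U-13C]glutamine. Provides an atom-transition network
    for glycolysis, the pentose phosphate pathway and the TCA cycle; a
    deterministic isotopomer simulator predicting positional labelling
    patterns, GC-MS mass isotopomer distributions (MIDs) and 2D-HSQC NMR
    multiplet profiles under configurable pathway-usage fractions; a
    constrained least-squares engine that inverts combined MID and multiplet
    observations back to positional isotopomers and attributes them to pathway
    classes (glycolysis, PPP, pyruvate dehydrogenase versus pyruvate
    carboxylase entry, multi-round TCA cycling, reverse glycolysis); derived
    statistics (m+2 lactate/pyruvate ratio, phosphocreatine/creatine ratio,
    fold changes, natural-abundance correction, one-way ANOVA with Dunnett's
    post hoc test); and a synthetic-data generator emulating an NAD+
    depletion/repletion study design in skeletal-muscle myotubes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    mvtnorm
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite
Config/testthat/edition: 3
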