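Package: nmrsubstr
Title: Molecular Substructure Determination from 1D NMR Chemical Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for correlating 1D 13C/1H NMR chemical-shift data with
    molecular substructures. Reads and writes nmrshiftdb2-style SDF records
    (connection table plus per-atom shift, multiplicity and
    experimental-condition metadata), encodes each carbon's one-bond
    environment as an 8-integer neighbor label or as an ordered-SMARTS
    functional-group class, converts records into fixed and variable
    model inputs, trains small neural classifiers (MLP+LSTM, 1D CNN,
    MLP+RNN) on them, and evaluates predictions with micro-averaged
    metrics and per-class top-k accuracy tables. A seeded synthetic
    spectrum generator provides desk-scale benchmarks for every stage.
License: MIT
Encoding: UTF-8
Imports:
    ChemmineR,
    jsonlite,
    graphics,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
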