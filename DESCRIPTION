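Package: nmrcase
Title: NMR-Constrained Constitution Generation with Statistical
    Environment Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-assisted structure elucidation (CASE) from 2D NMR
    correlation data. Compiles COSY, HMBC (13C and 15N) and 1,1-ADEQUATE
    correlation lists into bond-path-length constraints between heavy
    atoms, exhaustively enumerates all molecular constitutions compatible
    with a molecular formula, per-atom proton counts and those
    constraints (with open or fixed atom hybridizations), and
    deduplicates the results canonically. A statistical filter then
    removes candidate constitutions containing one-sphere (radius-1) atom
    environments never observed in a user-supplied reference corpus of
    known molecules, without ever removing a candidate whose environments
    are all covered. Includes a forward model that simulates the
    correlation sets a known structure would show, seeded toy-structure
    and reference-corpus generators, SMILES/SDF input and output, a JSON
    input dialect and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    tibble,
    tidyr,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
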