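Package: nofpair
Title: Electron-Pairing Natural Orbital Functionals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Natural orbital functional (NOF) theory with electron-pairing
    occupation constraints. Implements the PNOF5, GNOF and GNOFm functionals
    over spin-free one- and two-electron integrals (FCIDUMP format), with
    occupation-number and orbital-rotation optimization, brute-force FCI and
    restricted Hartree-Fock reference oracles for small systems, a Hubbard
    model generator for self-contained testing, correlation-energy analysis,
    complete-basis-set extrapolation, and dipole moments from the one-particle
    reduced density matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
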