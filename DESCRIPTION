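Package: eptlig
Title: Templated Oligonucleotide Ligation Kinetics and Hybridization Equilibria
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative modelling of template-directed chemical ligation of
    oligonucleotides via electrophilic phosphorothioester (EPT) chemistry.
    Provides nearest-neighbor and van't Hoff duplex thermodynamics with
    two-state melting-curve fitting, equilibrium speciation of the
    donor/acceptor/template ternary complex, Henderson-Hasselbalch amine
    protonation fractions, forward simulation of ligation with competing
    electrophile hydrolysis, pseudo-first-order rate-constant estimation
    from time-course data, gel-band yield quantitation, and seeded synthetic
    data generators for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    seqinr,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
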