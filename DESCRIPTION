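Package: vibronicCD
Title: Vibronic Exciton Absorption and Circular Dichroism Spectra of
    Chlorophyll Monomers and Dimers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates homogeneous and inhomogeneously broadened linear
    absorption and circular dichroism (CD) spectra of chlorophyll-like
    pigments with a Frenkel exciton model that includes non-adiabatic
    (vibronic) mixing of the Qy and Qx transitions through a dedicated
    coupling mode, Franck-Condon progressions of intramolecular vibrations,
    purely electronic Soret (Bx/By) states, a super-Ohmic low-frequency
    bath with lifetime broadening and energy renormalization, point-dipole
    excitonic couplings derived from pigment geometry, rotational strengths
    from magnetic transition dipoles, and Monte-Carlo averaging over
    Gaussian site-energy disorder.  Ships parameter presets for chlorophyll
    a in ether (monomer) and for the strongly coupled dimer of the
    water-soluble chlorophyll-binding protein (WSCP), together with a
    synthetic open-sandwich dimer geometry generator and readers for
    PDB-format and tabular pigment coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
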