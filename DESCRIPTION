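Package: mnoxstate
Title: Predicting Manganese Oxidation States from Octahedral Coordination Geometry
Version: 0.1.0
Authors@R:
    person("mnoxstate", "developers", email = "mnoxstate@example.org", role = c("aut", "cre"))
Description: Predicts per-ion oxidation states of octahedrally coordinated
    manganese directly from atomic coordinates. Extracts Mn sites from PDB or
    mmCIF files, resolves the three antipodal ligand pairs, and reduces each
    site to two features: the mean equatorial and mean axial Mn-ligand bond
    lengths, which separate Mn(II), Mn(III) and Mn(IV) because bonds contract
    with oxidation and Mn(III) shows a Jahn-Teller axial elongation. Labels
    are corrected by K-means clustering before fitting Gaussian naive Bayes
    and entropy decision-tree classifiers. For photosystem II structures the
    package locates the Mn4CaO5 oxygen-evolving complex in each monomer,
    predicts the four Mn oxidation states, and assigns the Kok-cycle S-state
    from the total Mn charge. A bond-valence-sum module provides an
    independent cross-check with calibratable R0 parameters. Synthetic
    generators produce feature tables and coordinate fixtures with known
    ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
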