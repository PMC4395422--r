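Package: bzjunction
Title: Geometric Detection of Mismatch-Induced B-to-Z DNA Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric analysis of DNA duplex structures and trajectories
    aimed at A...A-mismatch-induced B-to-Z transitions in CAG trinucleotide
    repeats. Computes backbone and glycosyl torsions, C1'...C1'-vector
    helical twist, groove widths, hydrogen-bond distances and RMSD; maps
    torsions into conformer classes (syn/anti glycosyl bins, gauche/trans
    wells, BI/BII/BIII backbone families and Z-form signatures); quantifies
    base-pair nonisomorphism via residual twist and radial difference;
    labels B/Z/junction steps and detects hydrogen-bond registry changes,
    base flipping, base extrusion and intercalation. Includes idealized
    fiber-model builders for B- and Z-form duplexes, modeled A...A mismatch
    pairs, and seeded mock trajectories with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
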