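Package: mc3dqsar
Title: Three-Dimensional Quantitative Structure-Activity Relationships for RNA
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the solvent-exposed base chemical groups that determine
    the activity of an RNA motif from a reference high-resolution structure and
    a table of active/inactive sequence variants, and scores new variants for
    predicted activity on [0,1]. Variant 3D models are built by atomic
    superimposition of idealized base templates onto the reference structure;
    per-group solvent accessibility is computed with a deterministic
    Shrake-Rupley engine; hydrogen-bond donor/acceptor pharmacophores are
    matched between structures with a distance- and direction-weighted score;
    and an activity profile is assembled from the groups present in all active
    variants and absent in at least one inactive variant. Includes
    synthetic-fixture generators with planted ground truth and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
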