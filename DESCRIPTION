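Package: pepdigest
Title: Peptidomic Profiling of Gastrointestinal Digestion Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for duodenal digest peptidomics comparing an
    intact protein substrate against its enzymatic hydrolysate. Maps identified
    peptides onto mature casein reference sequences, builds per-residue
    intensity and occurrence profiles, peptide size distributions and
    per-time-point count summaries, computes terminal-residue cleavage logos,
    discriminates substrates and sampling times by principal component analysis
    and hierarchical clustering, and compares postprandial plasma amino-acid
    time courses with two-way ANOVA and Bonferroni-corrected per-time
    contrasts. Includes a seeded in-silico digestion and plasma simulator so
    every stage is testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
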